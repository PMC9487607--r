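test_that("composition distance follows its closed forms", {
  a <- amp_records("a", "KWKL")
  expect_equal(composition_distance(a, a), 0)
  expect_equal(composition_distance(amp_records("x", "AAAA"),
                                    amp_records("y", "CCCC")),
               sqrt(2))
  expect_error(composition_distance(character(), "KKK"), "empty")
})

test_that("composition distance matches a two-pass hand computation", {
  withr::with_seed(12, {
    for (i in 1:10) {
      sa <- random_peptides(5, 12, seed = i)
      sb <- random_peptides(4, 9, seed = i + 100)
      freq <- function(s) {
        ch <- strsplit(paste(s, collapse = ""), "")[[1]]
        vapply(AA20, function(a) mean(ch == a), numeric(1))
      }
      expect_equal(composition_distance(sa, sb),
                   sqrt(sum((freq(sa) - freq(sb))^2)))
    }
  })
})

test_that("composition distance is a metric on random triples", {
  for (i in 1:20) {
    s <- lapply(1:3, function(j) random_peptides(3, 15, seed = i * 3 + j))
    d12 <- composition_distance(s[[1]], s[[2]])
    d21 <- composition_distance(s[[2]], s[[1]])
    d13 <- composition_distance(s[[1]], s[[3]])
    d23 <- composition_distance(s[[2]], s[[3]])
    expect_equal(d12, d21)
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("mad_ratio matches hand arithmetic and flags degeneracies", {
  expect_equal(mad_ratio(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3)),
               0.5)
  expect_true(is.infinite(mad_ratio(c(1, 1, 1, 5, 5, 5, 9, 9, 9),
                                    rep(c("a", "b", "c"), each = 3))))
  expect_true(is.nan(mad_ratio(rep(2, 6), rep(c("a", "b"), each = 3))))
  expect_error(mad_ratio(1:3, rep("a", 3)), "2 groups")
})

test_that("mad_ratio is shift-invariant and scale-equivariant", {
  withr::with_seed(14, {
    v <- stats::runif(30)
    g <- rep(letters[1:5], each = 6)
    base <- mad_ratio(v, g)
    expect_equal(mad_ratio(v + 7, g), base)
    expect_equal(mad_ratio(3 * v, g), base)
  })
})

fake_grid <- function(d_auc = 0.9, o_auc = 0.8, archs = c("A1", "A2"),
                      methods = c("m1", "m2", "m3"), reps = 2) {
  g <- expand.grid(architecture = archs, train_method = methods,
                   bench_method = methods, replicate = seq_len(reps),
                   stringsAsFactors = FALSE)
  g$auc <- ifelse(g$train_method == g$bench_method, d_auc, o_auc)
  tibble::as_tibble(g)
}

test_that("bias summary computes the diagonal improvement", {
  s <- bias_summary(fake_grid())
  expect_equal(s$per_architecture$improvement_pct, rep(12.5, 2))
  expect_equal(unname(s$overall), c(0.9, 0.8))
  expect_error(bias_summary(fake_grid()[1, ]), "diagonal")
  # group means recompute exactly from the raw table
  g <- fake_grid()
  withr::with_seed(3, g$auc <- stats::runif(nrow(g)))
  s2 <- bias_summary(g)
  manual <- mean(g$auc[g$train_method == g$bench_method &
                         g$architecture == "A1"])
  expect_equal(
    s2$per_architecture$mean_auc_same[
      s2$per_architecture$architecture == "A1"], manual)
})

test_that("correlation analyses recover monotone relations and flag ties", {
  g <- fake_grid(archs = "A1", methods = paste0("m", 1:4), reps = 1)
  d <- compute_distances_stub <- tibble::tibble(
    tsm = g$train_method, bsm = g$bench_method, replicate = g$replicate,
    composition_distance = 1 - g$auc,
    median_length_abs_diff = g$auc,
    bench_neg_vs_pos_median_length_diff = seq_len(nrow(g)))
  g$auc <- seq(0.5, 0.9, length.out = nrow(g))
  d$composition_distance <- 1 - g$auc
  d$median_length_abs_diff <- g$auc
  res <- correlation_analyses(g, d)
  expect_equal(res$rho[res$analysis == "composition_distance"], -1)
  expect_equal(res$rho[res$analysis == "median_length_abs_diff"], 1)
  g$auc <- rep(0.7, nrow(g))
  res2 <- correlation_analyses(g, d)
  expect_true(all(res2$flagged))
  expect_error(correlation_analyses(g[1:2, ], d[1:2, ]), "3")
})

test_that("grouped tests behave on degenerate and shifted groups", {
  g <- fake_grid(d_auc = 0.8, o_auc = 0.8)
  res <- group_tests(g)
  expect_true(all(res$kruskal$p_value == 1))
  # constant shift between two architectures: paired Wilcoxon significant
  g2 <- fake_grid(archs = c("lo", "hi"), methods = paste0("m", 1:4),
                  reps = 3)
  withr::with_seed(6, {
    base <- stats::runif(nrow(g2) / 2, 0.6, 0.9)
  })
  g2$auc[g2$architecture == "lo"] <- base
  g2$auc[g2$architecture == "hi"] <- base + 0.05
  res2 <- group_tests(g2)
  expect_lt(res2$pairwise$architecture$p_adjusted[1], 0.05)
  expect_equal(res2$fraction_significant[["architecture"]], 1)
})

test_that("Bonferroni adjustment is min(1, p * m)", {
  p <- c(0.01, 0.2, 0.5)
  expect_equal(bonferroni(p), pmin(1, p * 3))
})
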