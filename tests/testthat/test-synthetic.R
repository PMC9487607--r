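test_that("positive sequences respect the configured length range", {
  cfg <- synthetic_config(n_positive = 100, n_background = 10, seed = 5)
  pos <- generate_positives(cfg)
  expect_equal(nrow(pos), 100L)
  expect_true(all(nchar(pos$residues) >= 5 & nchar(pos$residues) <= 190))
  expect_true(all(pos$source == "positive"))
})

test_that("a degenerate composition gives the degenerate law", {
  comp <- stats::setNames(rep(0, 20), ampbench:::AA_ORDER)
  comp["K"] <- 1
  cfg <- synthetic_config(n_positive = 10, n_background = 10,
                          positive_composition = comp, seed = 1)
  pos <- generate_positives(cfg)
  expect_true(all(grepl("^K+$", pos$residues)))
  expect_error(synthetic_config(positive_composition =
                                  stats::setNames(rep(0, 20),
                                                  ampbench:::AA_ORDER)),
               "sum to 1|degenerate")
})

test_that("positives are K/R-enriched relative to the background", {
  cfg <- synthetic_config(n_positive = 2000, n_background = 2000, seed = 9)
  pos <- generate_positives(cfg)
  bg <- generate_background(cfg)
  kr_count <- function(x) {
    all_res <- paste(x$residues, collapse = "")
    c(sum(strsplit(all_res, "")[[1]] %in% c("K", "R")), nchar(all_res))
  }
  p <- kr_count(pos)
  b <- kr_count(bg)
  test <- stats::prop.test(c(p[1], b[1]), c(p[2], b[2]),
                           alternative = "greater")
  expect_lt(test$p.value, 0.01)
})

test_that("keyword and localization prevalences are honoured", {
  cfg <- synthetic_config(
    n_positive = 10, n_background = 10000,
    keyword_prevalence = c(antimicrobial = 0.01),
    localization_prevalence = c(cytoplasm = 0.3), seed = 21)
  bg <- generate_background(cfg)
  n_amp <- sum(vapply(bg$keywords, function(k) "antimicrobial" %in% k,
                      logical(1)))
  interval <- stats::qbinom(c(0.005, 0.995), 10000, 0.01)
  expect_gte(n_amp, interval[1])
  expect_lte(n_amp, interval[2])
  frac_cyt <- mean(vapply(bg$localization, function(l) "cytoplasm" %in% l,
                          logical(1)))
  expect_lt(abs(frac_cyt - 0.3), 0.02)
})

test_that("zero prevalences give annotation-free records", {
  cfg <- synthetic_config(n_positive = 10, n_background = 500,
                          keyword_prevalence = c(antimicrobial = 0),
                          localization_prevalence = c(cytoplasm = 0),
                          mislabeled_amp_rate = 0, seed = 2)
  bg <- generate_background(cfg)
  expect_true(all(lengths(bg$keywords) == 0))
  expect_true(all(lengths(bg$localization) == 0))
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- synthetic_config(n_positive = 60, n_background = 300, seed = 13)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_synthetic(cfg, d1)
  write_synthetic(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("the default background supports every built-in sampling method", {
  fx <- small_fixture()
  for (spec in builtin_specs()) {
    ds <- assemble_negative_sample(spec, fx$bg, fx$split,
                                   n_replicates = 1, seed = 11)[[1]]
    expect_gt(nrow(ds$neg_train), 0)
    expect_gt(nrow(ds$neg_bench), 0)
  }
})
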