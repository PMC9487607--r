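test_that("the built-in specs reproduce the published method table", {
  specs <- builtin_specs()
  expect_length(specs, 11L)

  rows <- list(
    Wang = list(kw = c("secreted", "antimicrobial"),
                policy = "similar_to_positive", clust = 0.7,
                balanced = FALSE),
    `CS-AMPPred` = list(kw = "antimicrobial", policy = "range",
                        range = c(16, 90), clust = 0.4, balanced = TRUE),
    `iAMP-2L` = list(kw = c("antimicrobial", "antibiotic", "fungicide",
                            "defensin"),
                     policy = "range", range = c(5, 100), clust = 0.4,
                     balanced = FALSE),
    `Gabere&Noble` = list(kw = "antimicrobial", policy = "equal_to_positive",
                          clust = NULL,
                          loc = c("golgi", "cytoplasm",
                                  "endoplasmic reticulum", "mitochondria"),
                          balanced = FALSE),
    AMAP = list(kw = "antimicrobial", policy = "similar_to_positive",
                clust = 0.4, balanced = FALSE),
    AMPScannerV2 = list(kw = c("antimicrobial", "antibiotic", "antiviral",
                               "fungicide", "secreted"),
                        policy = "equal_to_positive", clust = NULL,
                        loc = "cytoplasm", sim = TRUE, balanced = TRUE),
    dbAMP = list(kw = c("transmembrane", "toxin", "secreted", "defensin",
                        "antimicrobial", "antibiotic", "antiviral",
                        "fungicide"),
                 policy = "range", range = c(10, 100), clust = 0.4,
                 balanced = FALSE),
    `Witten&Witten` = list(kw = c("antimicrobial", "antibiotic",
                                  "antiviral", "fungicide", "secreted"),
                           policy = "equal_to_positive", clust = 0.4,
                           loc = "cytoplasm", cfree = TRUE,
                           balanced = TRUE),
    AmpGram = list(kw = c("antimicrobial", "antibacterial", "antiviral",
                          "fungicide", "secreted", "transit peptide"),
                   policy = "equal_to_positive", clust = NULL,
                   balanced = TRUE),
    `ampir-mature` = list(kw = "antimicrobial", policy = "range",
                          range = c(10, 40), clust = 0.9,
                          balanced = FALSE),
    AMPlify = list(kw = c("antimicrobial", "antibiotic", "defence",
                          "defensin", "bacteriocin", "fungicide"),
                   policy = "equal_to_positive", clust = NULL,
                   potamp = TRUE, balanced = TRUE))

  for (nm in names(rows)) {
    s <- specs[[nm]]
    r <- rows[[nm]]
    expect_setequal(s$excluded_keywords, r$kw)
    expect_equal(s$length_policy, r$policy, label = nm)
    if (!is.null(r$range)) expect_equal(s$length_range, r$range)
    expect_equal(s$clustering_threshold, r$clust, label = nm)
    if (!is.null(r$loc)) expect_setequal(s$localization_whitelist, r$loc)
    expect_equal(s$cysteine_free_substrings, isTRUE(r$cfree), label = nm)
    expect_equal(s$remove_potential_amps, isTRUE(r$potamp), label = nm)
    expect_equal(s$amp_similarity_screen, isTRUE(r$sim), label = nm)
    expect_equal(s$balanced, r$balanced, label = nm)
  }
  expect_equal(sum(vapply(specs, `[[`, logical(1), "balanced")), 5L)
})

make_db <- function(n = 100, seed = 5) {
  res <- random_peptides(n, 30, seed = seed)
  kws <- withr::with_seed(seed + 1, {
    lapply(seq_len(n), function(i) {
      if (stats::runif(1) < 0.07) "antimicrobial" else character()
    })
  })
  locs <- withr::with_seed(seed + 2, {
    lapply(seq_len(n), function(i) {
      if (stats::runif(1) < 0.3) "cytoplasm" else character()
    })
  })
  amp_records(sprintf("db%03d", seq_len(n)), res, keywords = kws,
              localization = locs)
}

test_that("keyword filtering matches a brute-force count", {
  db <- make_db()
  kept <- filter_by_keywords(db, "antimicrobial")
  manual <- sum(!vapply(db$keywords,
                        function(k) "antimicrobial" %in% k, logical(1)))
  expect_equal(nrow(kept), manual)
  expect_false(any(vapply(kept$keywords,
                          function(k) "antimicrobial" %in% k, logical(1))))
  expect_identical(filter_by_keywords(db, character()), db)
  one <- amp_records("x", "KKKK", keywords = list("ANTIMICROBIAL"))
  expect_equal(nrow(filter_by_keywords(one, "antimicrobial")), 0L)
})

test_that("localization whitelist keeps intersecting records only", {
  db <- make_db()
  kept <- filter_by_localization(db, "cytoplasm")
  manual <- sum(vapply(db$localization,
                       function(l) "cytoplasm" %in% l, logical(1)))
  expect_equal(nrow(kept), manual)
  none <- amp_records("x", "KKKK")
  expect_equal(nrow(filter_by_localization(none, "cytoplasm")), 0L)
})

test_that("length-range filtering is inclusive on both ends", {
  db <- amp_records(c("a", "b", "c"),
                    c(strrep("K", 90), strrep("K", 4), strrep("K", 16)))
  kept <- filter_by_length_range(db, 16, 90)
  expect_setequal(kept$id, c("a", "c"))
  expect_equal(nrow(filter_by_length_range(db, 5, 100)), 2L)
})

test_that("the potential-AMP screen removes the six flagged keywords", {
  db <- amp_records(c("a", "b"), c("KKKK", "LLLL"),
                    keywords = list("bacteriocin", "toxin"))
  kept <- remove_potential_amps(db)
  expect_equal(kept$id, "b")
})

test_that("cysteine-free substring sampling enumerates admissible windows", {
  out <- cysteine_free_substrings("KKCKKK", 3, seed = 1)
  expect_equal(out$fragment, "KKK")
  expect_gte(out$start, 3)
  expect_null(cysteine_free_substrings("CCCC", 2, seed = 1))
  # brute force count of eligible windows on random strings
  for (s in 1:20) {
    str <- random_peptides(1, 15, seed = s)
    len <- 4
    wins <- vapply(0:(15 - len), function(st) {
      substr(str, st + 1, st + len)
    }, character(1))
    n_ok <- sum(!grepl("C", wins))
    got <- ampbench:::eligible_starts(str, len, cysteine_free = TRUE)
    expect_equal(length(got), n_ok)
  }
})

test_that("greedy clustering follows the identity contract", {
  # duplicates merge at 0.9, disjoint sequences never do
  dup <- amp_records(c("a", "b"), c("KWKLFKKIEK", "KWKLFKKIEK"))
  expect_equal(nrow(greedy_identity_cluster(dup, 0.9)), 1L)
  far <- amp_records(c("a", "b"), c("KKKKKKKKKK", "LLLLLLLLLL"))
  expect_equal(nrow(greedy_identity_cluster(far, 0.1)), 2L)
  # one substitution in a 10-mer: identity 0.9 exactly
  pair <- amp_records(c("a", "b"), c("KWKLFKKIEK", "KWKLFKKIEW"))
  expect_equal(sequence_identity("KWKLFKKIEK", "KWKLFKKIEW"), 0.9)
  expect_equal(nrow(greedy_identity_cluster(pair, 0.9)), 1L)
  expect_equal(nrow(greedy_identity_cluster(pair, 0.95)), 2L)
})

test_that("the positive-similarity screen is a shared-k-mer rule", {
  positives <- amp_records("p", "KWKLFKKIEKVGQNIRDGIIKAGPAVAVVGQATQIAK")
  shared10 <- paste0("AAAA", substr(positives$residues, 5, 14), "LLLL")
  shared9 <- paste0("AAAA", substr(positives$residues, 5, 13), "LLLLL")
  cand <- amp_records(c("equal", "k10", "k9"),
                      c(positives$residues, shared10, shared9))
  kept <- amp_similarity_screen(cand, positives)
  expect_equal(kept$id, "k9")
})

test_that("equal-length fragment sampling returns the exact multiset", {
  db <- make_db(80, seed = 3)
  lens <- c(5L, 10L, 10L, 22L)
  out <- sample_lengths_equal(db, lens, seed = 4)
  expect_equal(sort(nchar(out$residues)), sort(lens))
  expect_true(all(out$frag_end - out$frag_start == nchar(out$residues)))
  # provenance points at a real window of the parent
  for (i in seq_len(nrow(out))) {
    parent <- db$residues[db$id == out$parent_id[i]]
    expect_equal(substr(parent, out$frag_start[i] + 1, out$frag_end[i]),
                 out$residues[i])
  }
  out2 <- sample_lengths_equal(db, lens, seed = 4)
  expect_identical(out$residues, out2$residues)
  # a single record of exactly the requested length forces the whole record
  one <- amp_records("only", "KWKLFKKI")
  forced <- sample_lengths_equal(one, 8L, seed = 1)
  expect_equal(forced$residues, "KWKLFKKI")
  expect_error(sample_lengths_equal(one, 9L, seed = 1), "length")
})

test_that("similar-length sampling degenerates to equal without clustering", {
  db <- make_db(80, seed = 3)
  lens <- rep(c(8L, 12L), 10)
  eq <- sample_lengths_similar(db, lens, seed = 9, threshold = NULL)
  expect_equal(sort(nchar(eq$residues)), sort(lens))
  cl <- sample_lengths_similar(db, lens, seed = 9, threshold = 0.4)
  expect_lte(nrow(cl), length(lens))
})

test_that("similar-length sampling tracks the positive length law", {
  fx <- small_fixture()
  pool <- filter_by_keywords(fx$bg, "antimicrobial")
  lens <- nchar(fx$split$train$residues)
  sim <- sample_lengths_similar(pool, rep(lens, 2)[1:240], seed = 3,
                                threshold = 0.4)
  ks <- suppressWarnings(stats::ks.test(nchar(sim$residues),
                                        lens)$statistic)
  expect_lte(unname(ks), 0.2)
})

test_that("different sampling methods separate in composition more than
           replicates of one method do", {
  fx <- small_fixture()
  d_db <- assemble_negative_sample(builtin_specs()[["dbAMP"]], fx$bg,
                                   fx$split, 2, seed = 4)
  d_ag <- assemble_negative_sample(builtin_specs()[["AmpGram"]], fx$bg,
                                   fx$split, 2, seed = 4)
  between <- composition_distance(d_db[[1]]$neg_train, d_ag[[1]]$neg_train)
  expect_gt(between, 0)
  expect_gt(between,
            composition_distance(d_db[[1]]$neg_train, d_db[[2]]$neg_train))
  expect_gt(between,
            composition_distance(d_ag[[1]]$neg_train, d_ag[[2]]$neg_train))
})

test_that("assembly fails with a named stage when a filter empties the pool", {
  fx <- small_fixture()
  no_loc <- fx$bg
  no_loc$localization <- rep(list(character()), nrow(no_loc))
  expect_error(
    assemble_negative_sample(builtin_specs()[["Gabere&Noble"]], no_loc,
                             fx$split, n_replicates = 1, seed = 1),
    "localization")
})

test_that("replicates are deterministic, pairwise distinct, and leak-free", {
  fx <- small_fixture()
  spec <- builtin_specs()[["AmpGram"]]
  reps <- assemble_negative_sample(spec, fx$bg, fx$split,
                                   n_replicates = 3, seed = 20)
  reps2 <- assemble_negative_sample(spec, fx$bg, fx$split,
                                    n_replicates = 3, seed = 20)
  for (r in 1:3) {
    expect_identical(reps[[r]]$neg_train$residues,
                     reps2[[r]]$neg_train$residues)
  }
  sets <- lapply(reps, function(d) sort(d$neg_train$residues))
  expect_false(identical(sets[[1]], sets[[2]]))
  expect_false(identical(sets[[2]], sets[[3]]))
  for (d in reps) {
    expect_length(intersect(d$neg_train$id, d$neg_bench$id), 0)
    expect_false(any(c(d$neg_train$residues, d$neg_bench$residues) %in%
                       c(fx$split$train$residues, fx$split$bench$residues)))
    expect_equal(sort(nchar(d$neg_train$residues)),
                 sort(nchar(fx$split$train$residues)))
  }
})
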