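# Shared fixtures, built in code once per test run.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_peptides <- function(n, len, seed = 1, prob = NULL) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(AA20, len, replace = TRUE, prob = prob), collapse = "")
    }, character(1))
  })
}

# small synthetic study system shared across test files
small_config <- function(seed = 7) {
  synthetic_config(n_positive = 150, n_background = 4000, seed = seed)
}

.fixture_env <- new.env()

small_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    cfg <- small_config()
    pos <- generate_positives(cfg)
    bg <- generate_background(cfg)
    split <- split_positive(pos, 0.8, seed = 1)
    .fixture_env$fx <- list(cfg = cfg, pos = pos, bg = bg, split = split)
  }
  .fixture_env$fx
}

# brute-force helpers (independent oracles)

brute_auc <- function(sp, sn) {
  s <- 0
  for (p in sp) for (q in sn) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(sp) * length(sn))
}

brute_ig <- function(x, y) {
  n <- length(x)
  tab <- table(factor(x, 0:1), factor(y, 0:1)) / n
  s <- 0
  for (i in 1:2) {
    for (j in 1:2) {
      if (tab[i, j] > 0) {
        s <- s + tab[i, j] * log(tab[i, j] / (sum(tab[i, ]) * sum(tab[, j])))
      }
    }
  }
  s
}

# exhaustive permutation p-value of the IG statistic (all label orders,
# collapsed to distinct positive-position sets)
brute_quipt <- function(x, y) {
  n <- length(y)
  k <- sum(y)
  if (k == 0 || k == n || sum(x) %in% c(0, n)) return(1)
  obs <- brute_ig(x, y)
  sets <- utils::combn(n, k)
  hits <- 0
  for (c in seq_len(ncol(sets))) {
    yy <- integer(n)
    yy[sets[, c]] <- 1L
    if (brute_ig(x, yy) >= obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(sets)
}
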