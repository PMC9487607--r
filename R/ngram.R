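# Binary n-gram features (AmpGram-style) and the exact Quick Permutation
# Test used to select informative n-grams.

#' Distinct n-grams of each sequence
#'
#' Contiguous 1-, 2- and 3-grams plus 2- and 3-grams with a single-position
#' gap (marked `_`, e.g. `K_L`, `KW_L`).
#'
#' @param residues Character vector of peptides.
#' @return List of character vectors, one per peptide.
#' @export
ngram_sets <- function(residues) {
  ngram_sets_cpp(as.character(residues))
}

#' Build the n-gram vocabulary observed in a training set
#'
#' @param residues Character vector of training peptides.
#' @return Sorted character vector of distinct n-grams.
#' @export
build_ngram_vocabulary <- function(residues) {
  sort(unique(unlist(ngram_sets(residues))))
}

#' Binary presence/absence n-gram features
#'
#' @param residues Character vector of peptides.
#' @param vocabulary Vocabulary from [build_ngram_vocabulary()]; n-grams
#'   outside the vocabulary are ignored.
#' @return Sparse binary matrix (`Matrix::dgCMatrix`), peptides in rows,
#'   vocabulary n-grams in columns.
#' @export
ngram_features <- function(residues, vocabulary) {
  sets <- ngram_sets(residues)
  ij <- lapply(seq_along(sets), function(i) {
    j <- match(sets[[i]], vocabulary)
    j <- j[!is.na(j)]
    cbind(i = rep.int(i, length(j)), j = j)
  })
  ij <- do.call(rbind, ij)
  Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1,
                       dims = c(length(sets), length(vocabulary)),
                       dimnames = list(NULL, vocabulary))
}

ig_for_counts <- function(a, n1, k, n) {
  # information gain (mutual information, natural log) of the 2x2 table
  # with cells a, n1-a, k-a, n-n1-k+a
  cells <- cbind(a, n1 - a, k - a, n - n1 - k + a)
  rowm <- matrix(c(n1, n1, n - n1, n - n1), nrow = length(a), ncol = 4,
                 byrow = TRUE)
  colm <- matrix(c(k, n - k, k, n - k), nrow = length(a), ncol = 4,
                 byrow = TRUE)
  p <- cells / n
  term <- ifelse(cells > 0, p * log(p * n^2 / (rowm * colm)), 0)
  rowSums(term)
}

#' Quick Permutation Test (QuiPT) for a binary feature
#'
#' Exact permutation p-value of the information-gain statistic for a binary
#' feature against a binary target.  Because the statistic depends only on
#' the 2x2 contingency table, all tables with the observed margins are
#' enumerated and weighted by the hypergeometric distribution; the p-value
#' sums the probabilities of tables with information gain at least the
#' observed one (ties included, tolerance 1e-12).
#'
#' @param feature_column Binary (0/1) vector.
#' @param target Binary (0/1) vector of equal length.
#' @return The exact permutation p-value.
#' @export
quipt <- function(feature_column, target) {
  x <- as.integer(feature_column)
  y <- as.integer(target)
  if (length(x) != length(y)) stop("unequal lengths")
  if (!all(x %in% c(0L, 1L)) || !all(y %in% c(0L, 1L))) {
    stop("both columns must be binary")
  }
  n <- length(x)
  n1 <- sum(x)
  k <- sum(y)
  if (n1 == 0L || n1 == n || k == 0L || k == n) return(1)
  a_obs <- sum(x == 1L & y == 1L)
  a_all <- max(0L, n1 + k - n):min(n1, k)
  probs <- stats::dhyper(a_all, k, n - k, n1)
  ig <- ig_for_counts(a_all, n1, k, n)
  ig_obs <- ig[match(a_obs, a_all)]
  sum(probs[ig >= ig_obs - 1e-12])
}

# Vectorized QuiPT over the columns of a sparse binary matrix: p-values are
# grouped by the feature margin n1, for which the hypergeometric
# enumeration is shared.
quipt_pvalues <- function(X, y) {
  y <- as.integer(y)
  n <- length(y)
  k <- sum(y)
  n1 <- Matrix::colSums(X)
  a <- as.numeric(Matrix::crossprod(X, y))
  p <- numeric(ncol(X))
  if (k == 0L || k == n) return(rep(1, ncol(X)))
  for (m in unique(n1)) {
    cols <- which(n1 == m)
    if (m == 0 || m == n) { p[cols] <- 1; next }
    a_all <- max(0, m + k - n):min(m, k)
    probs <- stats::dhyper(a_all, k, n - k, m)
    ig <- ig_for_counts(a_all, m, k, n)
    cum <- vapply(seq_along(a_all),
                  function(i) sum(probs[ig >= ig[i] - 1e-12]), numeric(1))
    p[cols] <- cum[match(a[cols], a_all)]
  }
  p
}

#' LZ76 phrase-count complexity
#'
#' Number of phrases in the exhaustive Lempel-Ziv parsing of each string.
#'
#' @param x Character vector.
#' @return Integer vector of complexities.
#' @export
lz76_complexity <- function(x) {
  lz76_cpp(as.character(x))
}

#' LZ-complexity similarity profile (SVM-LZ-style)
#'
#' Entry `(i, j)` is `1 - (C(x_i . r_j) - min(C(x_i), C(r_j))) /
#' max(C(x_i), C(r_j))` where `C` is the LZ76 phrase count and `.` is
#' concatenation; each peptide is described by its similarity to a fixed
#' reference panel.
#'
#' @param residues Character vector of peptides.
#' @param reference_set Character vector of reference sequences.
#' @param expected_size If not `NULL`, error unless the reference panel has
#'   exactly this size.
#' @return Numeric matrix, peptides in rows, references in columns.
#' @export
lz_similarity_profile <- function(residues, reference_set,
                                  expected_size = NULL) {
  if (!is.null(expected_size) && length(reference_set) != expected_size) {
    stop("reference set must contain ", expected_size, " sequences")
  }
  out <- lz_profile_cpp(as.character(residues),
                        as.character(reference_set))
  colnames(out) <- paste0("ref", seq_along(reference_set))
  out
}
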