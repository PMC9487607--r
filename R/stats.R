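# Bias diagnostics over the cross-benchmark grid: diagonal vs off-diagonal
# AUC, MAD ratios, dataset-distance correlations and grouped nonparametric
# tests.

pooled_frequencies <- function(x) {
  residues <- if (is.character(x)) x else x$residues
  if (length(residues) == 0) stop("empty sequence set")
  idx <- aa_indices(paste(residues, collapse = ""))
  tabulate(idx, 20) / length(idx)
}

#' Amino-acid composition distance between two sequence sets
#'
#' Residues are pooled per set; the distance is the Euclidean norm of the
#' difference of the two 20-dimensional frequency vectors.
#'
#' @param set_a,set_b `amp_records` tibbles or character vectors.
#' @return Non-negative distance; 0 iff the frequency vectors are equal.
#' @export
composition_distance <- function(set_a, set_b) {
  sqrt(sum((pooled_frequencies(set_a) - pooled_frequencies(set_b))^2))
}

mad0 <- function(x) stats::median(abs(x - stats::median(x)))

#' Ratio of between-group to within-group median absolute deviation
#'
#' Between-group MAD is the MAD of the group medians; within-group MAD is
#' the median of the per-group MADs (both unscaled).  A zero within-group
#' MAD yields `Inf` (pure between-group dispersion) and fully constant
#' values yield `NaN` (undefined).
#'
#' @param values Numeric vector (e.g. AUCs).
#' @param groups Group labels, same length.
#' @return The MAD ratio (possibly `Inf` or `NaN`).
#' @export
mad_ratio <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  split_vals <- split(values, groups)
  if (length(split_vals) < 2) stop("need at least 2 groups")
  between <- mad0(vapply(split_vals, stats::median, numeric(1)))
  within <- stats::median(vapply(split_vals, mad0, numeric(1)))
  if (within == 0) {
    if (between == 0) NaN else Inf
  } else {
    between / within
  }
}

#' Dataset distances for every (TSM, BSM, replicate) cell
#'
#' For each cell, the amino-acid composition distance and absolute median
#' length difference between the full training set (positives plus TSM
#' negatives) and the full benchmark set (positives plus BSM negatives),
#' plus the signed difference between the median lengths of the benchmark
#' negatives and the benchmark positives.
#'
#' @param datasets Named list: method -> list of `replicated_dataset`s.
#' @param n_replicates Number of replicates to use.
#' @return Tibble with one row per (tsm, bsm, replicate).
#' @export
compute_distances <- function(datasets,
                              n_replicates = length(datasets[[1]])) {
  methods <- names(datasets)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    train_sets <- lapply(methods, function(m) {
      ds <- datasets[[m]][[r]]
      c(ds$pos_train$residues, ds$neg_train$residues)
    })
    bench_sets <- lapply(methods, function(m) {
      ds <- datasets[[m]][[r]]
      c(ds$pos_bench$residues, ds$neg_bench$residues)
    })
    names(train_sets) <- names(bench_sets) <- methods
    train_freq <- lapply(train_sets, pooled_frequencies)
    bench_freq <- lapply(bench_sets, pooled_frequencies)
    train_med <- vapply(train_sets, function(s) stats::median(nchar(s)),
                        numeric(1))
    bench_med <- vapply(bench_sets, function(s) stats::median(nchar(s)),
                        numeric(1))
    pos_bench_med <- stats::median(
      nchar(datasets[[1]][[r]]$pos_bench$residues))
    for (tsm in methods) {
      for (bsm in methods) {
        neg_bench_med <- stats::median(
          nchar(datasets[[bsm]][[r]]$neg_bench$residues))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          tsm = tsm, bsm = bsm, replicate = r,
          composition_distance =
            sqrt(sum((train_freq[[tsm]] - bench_freq[[bsm]])^2)),
          median_length_abs_diff = abs(train_med[[tsm]] - bench_med[[bsm]]),
          bench_neg_vs_pos_median_length_diff =
            neg_bench_med - pos_bench_med)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Diagonal vs off-diagonal AUC summary
#'
#' For each architecture, the mean AUC over cells where training and
#' benchmark negatives come from the same sampling method (the diagonal)
#' and over cells where they differ, with the percentage improvement
#' `100 * (same - diff) / diff`; plus the per-cell replicate standard
#' deviations and the AUC distributions grouped by architecture, TSM and
#' BSM.
#'
#' @param grid A [run_grid()] result.
#' @return A list of class `bias_summary` with elements
#'   `per_architecture`, `overall`, `replicate_sd`, `auc_distributions`.
#' @export
bias_summary <- function(grid) {
  stopifnot(all(c("architecture", "train_method", "bench_method",
                  "replicate", "auc") %in% names(grid)))
  grid$same <- grid$train_method == grid$bench_method
  if (!any(grid$same) || !any(!grid$same)) {
    stop("grid must contain both diagonal and off-diagonal cells")
  }
  miss <- setdiff(unique(grid$architecture),
                  unique(grid$architecture[grid$same]))
  if (length(miss)) {
    stop("missing diagonal cells for: ", paste(miss, collapse = ", "))
  }
  per_arch <- dplyr::summarise(
    dplyr::group_by(grid, .data$architecture),
    mean_auc_same = mean(.data$auc[.data$same]),
    mean_auc_diff = mean(.data$auc[!.data$same]),
    .groups = "drop")
  per_arch$improvement_pct <- ifelse(
    per_arch$mean_auc_diff > 0,
    100 * (per_arch$mean_auc_same - per_arch$mean_auc_diff) /
      per_arch$mean_auc_diff,
    NA_real_)
  overall <- c(mean_auc_same = mean(grid$auc[grid$same]),
               mean_auc_diff = mean(grid$auc[!grid$same]))
  replicate_sd <- dplyr::summarise(
    dplyr::group_by(grid, .data$architecture, .data$train_method,
                    .data$bench_method),
    sd_auc = stats::sd(.data$auc), n = dplyr::n(), .groups = "drop")
  structure(
    list(per_architecture = per_arch, overall = overall,
         replicate_sd = replicate_sd,
         auc_distributions = list(
           architecture = split(grid$auc, grid$architecture),
           tsm = split(grid$auc, grid$train_method),
           bsm = split(grid$auc, grid$bench_method))),
    class = "bias_summary")
}

spearman_test <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 joined points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, flagged = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = length(x) < 10))
  list(rho = unname(ct$estimate), p_value = ct$p.value, flagged = FALSE)
}

#' Correlations of AUC with dataset distances
#'
#' Cells are joined at (TSM, BSM, replicate) granularity, averaging AUC
#' over architectures, then Spearman correlations are computed for (i) AUC
#' vs train/bench composition distance, (ii) AUC vs absolute train/bench
#' median length difference, (iii) AUC vs the signed difference between
#' benchmark negative and positive median lengths.
#'
#' @param grid A [run_grid()] result.
#' @param distances A [compute_distances()] result.
#' @return Tibble with columns analysis, rho, p_value, n, flagged.
#' @export
correlation_analyses <- function(grid, distances) {
  cell <- dplyr::summarise(
    dplyr::group_by(grid, .data$train_method, .data$bench_method,
                    .data$replicate),
    mean_auc = mean(.data$auc), .groups = "drop")
  joined <- dplyr::inner_join(
    cell, distances,
    by = c(train_method = "tsm", bench_method = "bsm", "replicate"))
  if (nrow(joined) < 3) stop("fewer than 3 joined points")
  tests <- list(
    composition_distance =
      spearman_test(joined$mean_auc, joined$composition_distance),
    median_length_abs_diff =
      spearman_test(joined$mean_auc, joined$median_length_abs_diff),
    bench_neg_vs_pos_median_length_diff =
      spearman_test(joined$mean_auc,
                    joined$bench_neg_vs_pos_median_length_diff))
  tibble::tibble(
    analysis = names(tests),
    rho = unname(vapply(tests, function(t) t$rho, numeric(1))),
    p_value = unname(vapply(tests, function(t) t$p_value, numeric(1))),
    n = nrow(joined),
    flagged = unname(vapply(tests, function(t) t$flagged, logical(1))))
}

paired_wilcoxon_family <- function(grid, group_col, key_cols) {
  levels <- sort(unique(grid[[group_col]]))
  out <- list()
  for (i in seq_along(levels)) {
    for (j in seq_along(levels)) {
      if (j <= i) next
      a <- grid[grid[[group_col]] == levels[i], c(key_cols, "auc")]
      b <- grid[grid[[group_col]] == levels[j], c(key_cols, "auc")]
      joined <- dplyr::inner_join(a, b, by = key_cols,
                                  suffix = c("_a", "_b"))
      if (nrow(joined) < nrow(a) || nrow(joined) < nrow(b)) {
        miss <- c(dplyr::anti_join(a, b, by = key_cols),
                  dplyr::anti_join(b, a, by = key_cols))
        stop("unpaired cells between ", levels[i], " and ", levels[j])
      }
      p <- tryCatch(
        suppressWarnings(stats::wilcox.test(joined$auc_a, joined$auc_b,
                                            paired = TRUE)$p.value),
        error = function(e) 1)
      out[[length(out) + 1L]] <- tibble::tibble(
        group_a = levels[i], group_b = levels[j], p_value = p,
        n_pairs = nrow(joined))
    }
  }
  fam <- dplyr::bind_rows(out)
  fam$p_adjusted <- stats::p.adjust(fam$p_value, method = "bonferroni")
  fam
}

#' Grouped hypothesis tests on the grid
#'
#' Per-architecture Kruskal-Wallis tests comparing same-method vs
#' different-method AUC (Bonferroni-corrected across architectures), and
#' pairwise paired Wilcoxon tests within three families (architectures,
#' TSMs, BSMs; pairing cells by the complementary keys,
#' Bonferroni-corrected within each family) with the fraction of
#' significant comparisons per family.
#'
#' @param grid A [run_grid()] result.
#' @param alpha Significance level for the reported fractions.
#' @return List with `kruskal`, `pairwise` (list of three tibbles) and
#'   `fraction_significant`.
#' @export
group_tests <- function(grid, alpha = 0.05) {
  grid$same <- grid$train_method == grid$bench_method
  archs <- sort(unique(grid$architecture))
  if (length(archs) < 1) stop("empty grid")
  kw <- dplyr::bind_rows(lapply(archs, function(a) {
    g <- grid[grid$architecture == a, ]
    p <- tryCatch(stats::kruskal.test(g$auc, factor(g$same))$p.value,
                  error = function(e) 1)
    if (is.na(p)) p <- 1   # fully tied AUCs: no evidence of a difference
    tibble::tibble(architecture = a, p_value = p)
  }))
  kw$p_adjusted <- stats::p.adjust(kw$p_value, method = "bonferroni")

  fams <- list(
    architecture = paired_wilcoxon_family(
      grid, "architecture", c("train_method", "bench_method", "replicate")),
    tsm = paired_wilcoxon_family(
      grid, "train_method", c("architecture", "bench_method", "replicate")),
    bsm = paired_wilcoxon_family(
      grid, "bench_method", c("architecture", "train_method", "replicate")))
  frac <- vapply(fams, function(f) mean(f$p_adjusted < alpha), numeric(1))
  list(kruskal = kw, pairwise = fams, fraction_significant = frac)
}

#' Bonferroni adjustment of a vector of p-values
#'
#' Thin wrapper over [stats::p.adjust()] (`min(1, p * m)`), exposed for
#' the diagnostic tables.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p) stats::p.adjust(p, method = "bonferroni")
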