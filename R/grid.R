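# The cross-benchmark experiment: train every architecture on every
# training sampling method (TSM) x replicate, evaluate every model on
# every benchmark sampling method (BSM).

#' Plan the architecture x sampling-method x replicate grid
#'
#' @param architectures Ordered character vector of architecture names.
#' @param sampling_methods Ordered character vector of sampling-method
#'   names.
#' @param n_replicates Replicates per (architecture, method) pair.
#' @param pairing_rule `"paired_replicate"` (train replicate r is evaluated
#'   on bench replicate r of every method) or `"full_cross"` (every bench
#'   replicate).
#' @return A `grid_plan` with `n_models` and `n_evaluations`.
#' @export
plan_grid <- function(architectures, sampling_methods, n_replicates = 5L,
                      pairing_rule = c("paired_replicate", "full_cross")) {
  pairing_rule <- match.arg(pairing_rule)
  stopifnot(length(architectures) > 0, length(sampling_methods) > 0,
            n_replicates >= 1)
  n_models <- length(architectures) * length(sampling_methods) *
    n_replicates
  n_eval <- n_models * length(sampling_methods) *
    if (pairing_rule == "full_cross") n_replicates else 1L
  structure(list(architectures = architectures,
                 sampling_methods = sampling_methods,
                 n_replicates = as.integer(n_replicates),
                 pairing_rule = pairing_rule,
                 n_models = n_models, n_evaluations = n_eval),
            class = "grid_plan")
}

#' Area under the ROC curve
#'
#' Mann-Whitney U statistic scaled by `n_pos * n_neg`, with half credit for
#' ties (equivalent to trapezoidal ROC integration).
#'
#' @param scores_pos Scores of the positive class.
#' @param scores_neg Scores of the negative class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores_pos, scores_neg) {
  np <- length(scores_pos)
  nn <- length(scores_neg)
  if (np == 0 || nn == 0) stop("both score vectors must be non-empty")
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Run the cross-benchmark grid
#'
#' For each (architecture, TSM, replicate) a model is trained on the shared
#' positive training sample plus that TSM replicate's negative training
#' sample, then evaluated on the shared positive benchmark sample against
#' every BSM's negative benchmark sample (same replicate index under
#' `paired_replicate`).  Feature matrices of extractors without
#' train-fitted state are computed once per architecture and reused across
#' cells.  With `cache_dir`, completed models are skipped on rerun.
#'
#' @param plan A [plan_grid()] result.
#' @param datasets Named list: method name -> list of `replicated_dataset`
#'   objects (from [assemble_negative_sample()]).
#' @param specs Named list of [architecture_spec()]s covering
#'   `plan$architectures`.
#' @param seed Master seed; each model derives its own seed.
#' @param cache_dir Optional directory for per-model result caching.
#' @param verbose Log one line per model?
#' @return Tidy tibble: architecture, train_method, bench_method,
#'   replicate, auc, n_pos_bench, n_neg_bench.
#' @export
run_grid <- function(plan, datasets, specs, seed = 1L, cache_dir = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(plan, "grid_plan"))
  for (m in plan$sampling_methods) {
    if (is.null(datasets[[m]]) || length(datasets[[m]]) < plan$n_replicates) {
      stop("missing datasets for sampling method ", m)
    }
  }
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  }
  first <- datasets[[plan$sampling_methods[1]]][[1]]
  pos_train <- first$pos_train
  pos_bench <- first$pos_bench

  rows <- list()
  for (arch in plan$architectures) {
    spec <- specs[[arch]]
    if (is.null(spec)) stop("no architecture spec named ", arch)
    if (!spec$trainable) next
    static <- !(spec$extractor %in% c("ngram", "lz"))
    fx <- function(recs) extract_features(spec, recs$residues)$X
    Xpt <- if (static) fx(pos_train) else NULL
    Xpb <- if (static) fx(pos_bench) else NULL
    Xnt <- list()
    Xnb <- list()
    if (static) {
      for (m in plan$sampling_methods) {
        Xnt[[m]] <- lapply(seq_len(plan$n_replicates),
                           function(r) fx(datasets[[m]][[r]]$neg_train))
        Xnb[[m]] <- lapply(seq_len(plan$n_replicates),
                           function(r) fx(datasets[[m]][[r]]$neg_bench))
      }
    }

    for (tsm in plan$sampling_methods) {
      for (r in seq_len(plan$n_replicates)) {
        key <- sprintf("%s__%s__r%d__s%d", gsub("[^A-Za-z0-9-]", "_", arch),
                       gsub("[^A-Za-z0-9-]", "_", tsm), r, seed)
        cache_file <- if (!is.null(cache_dir)) {
          file.path(cache_dir, paste0(key, ".tsv"))
        }
        if (!is.null(cache_file) && file.exists(cache_file)) {
          rows[[key]] <- tibble::as_tibble(
            utils::read.delim(cache_file, colClasses = c(
              architecture = "character", train_method = "character",
              bench_method = "character", replicate = "integer",
              bench_replicate = "integer",
              auc = "numeric", n_pos_bench = "integer",
              n_neg_bench = "integer")))
          next
        }
        ds <- datasets[[tsm]][[r]]
        spec_r <- spec
        spec_r$seed <- derive_seed(seed, arch, tsm, r)
        pre_train <- if (static) rbind(Xpt, Xnt[[tsm]][[r]]) else NULL
        model <- train(spec_r, ds$pos_train, ds$neg_train,
                       precomputed = pre_train)
        sp <- predict_scores(model, pos_bench, precomputed = Xpb)
        bench_reps <- if (plan$pairing_rule == "full_cross") {
          seq_len(plan$n_replicates)
        } else {
          r
        }
        cell <- lapply(plan$sampling_methods, function(bsm) {
          dplyr::bind_rows(lapply(bench_reps, function(br) {
            bench <- datasets[[bsm]][[br]]$neg_bench
            sn <- predict_scores(model, bench,
                                 precomputed = if (static) Xnb[[bsm]][[br]])
            tibble::tibble(architecture = arch, train_method = tsm,
                           bench_method = bsm, replicate = r,
                           bench_replicate = br,
                           auc = roc_auc(sp, sn),
                           n_pos_bench = nrow(pos_bench),
                           n_neg_bench = nrow(bench))
          }))
        })
        cell <- dplyr::bind_rows(cell)
        if (verbose) {
          message(sprintf("[grid] %s / %s / rep %d: mean AUC %.3f",
                          arch, tsm, r, mean(cell$auc)))
        }
        if (!is.null(cache_file)) {
          utils::write.table(cell, cache_file, sep = "\t", quote = FALSE,
                             row.names = FALSE)
        }
        rows[[key]] <- cell
      }
    }
  }
  dplyr::bind_rows(rows)
}
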