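# End-to-end pipeline: simulate -> sample -> run grid -> diagnostics, with
# a serializable run configuration and seeded stage derivation.

#' Construct a pipeline run configuration
#'
#' @param synthetic A [synthetic_config()].
#' @param methods Sampling-method names to run (subset of
#'   [builtin_specs()]).
#' @param architectures Architecture names to run (subset of
#'   [registry()]).
#' @param n_replicates Replicates per sampling method.
#' @param master_seed Single master seed; every stage derives its own seed
#'   from it via [derive_seed()].
#' @param positive_redundancy_threshold Identity threshold for the
#'   positive-set redundancy reduction.
#' @param split_fraction Positive train fraction.
#' @param lz_reference_size SVM-LZ reference-panel size for this run (the
#'   architecture's nominal panel is 1000; the run default is the
#'   desk-scale setting discussed in the methods vignette).
#' @param quipt_max_features Cap on QuiPT-selected n-grams for this run
#'   (desk-scale default; the nominal cap is 5000).
#' @param outdir Output directory for the file-emitting commands.
#' @return A list of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       methods = names(builtin_specs()),
                       architectures = names(registry()),
                       n_replicates = 2L,
                       master_seed = 1L,
                       positive_redundancy_threshold = 0.9,
                       split_fraction = 0.8,
                       lz_reference_size = 200L,
                       quipt_max_features = 1000L,
                       outdir = "ampbench_run") {
  structure(list(synthetic = synthetic, methods = methods,
                 architectures = architectures,
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed),
                 positive_redundancy_threshold =
                   positive_redundancy_threshold,
                 split_fraction = split_fraction,
                 lz_reference_size = as.integer(lz_reference_size),
                 quipt_max_features = as.integer(quipt_max_features),
                 outdir = outdir),
            class = "run_config")
}

#' Hash of a run configuration
#'
#' Recorded in every output manifest so results can be traced to the exact
#' configuration that produced them.
#'
#' @param config A [run_config()].
#' @return An 8-hex-digit hash string.
#' @export
config_hash <- function(config) {
  light_hash(utils::capture.output(utils::str(config, digits.d = 12)))
}

#' Write a run configuration to a YAML file
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  ser <- unclass(config)
  ser$synthetic <- lapply(unclass(ser$synthetic), function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  })
  yaml::write_yaml(ser, path, precision = 15L)
  invisible(path)
}

#' Read a run configuration from a YAML file
#' @param path Path written by [write_run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  syn <- raw$synthetic
  for (nm in c("positive_composition", "background_composition",
               "keyword_prevalence", "localization_prevalence")) {
    syn[[nm]] <- unlist(syn[[nm]])
  }
  synthetic <- do.call(synthetic_config,
                       syn[setdiff(names(syn), character())])
  do.call(run_config, c(list(synthetic = synthetic),
                        raw[setdiff(names(raw), "synthetic")]))
}

#' Prepare the study data: positives, redundancy reduction, split,
#' background
#'
#' @param config A [run_config()].
#' @return List with `positives`, `split`, `background`.
#' @export
prepare_data <- function(config) {
  positives <- generate_positives(config$synthetic)
  positives <- reduce_redundancy_positive(
    positives, config$positive_redundancy_threshold)
  split <- split_positive(positives, config$split_fraction,
                          seed = derive_seed(config$master_seed, "split"))
  background <- generate_background(config$synthetic)
  list(positives = positives, split = split, background = background)
}

#' Assemble the replicated datasets for every configured sampling method
#'
#' @param config A [run_config()].
#' @param data A [prepare_data()] result.
#' @param verbose Log per-method progress?
#' @return Named list: method -> list of `replicated_dataset`s.
#' @export
sample_all_methods <- function(config, data, verbose = FALSE) {
  specs <- builtin_specs()[config$methods]
  out <- lapply(specs, function(spec) {
    if (verbose) message("[sample] ", spec$name)
    assemble_negative_sample(spec, data$background, data$split,
                             n_replicates = config$n_replicates,
                             seed = derive_seed(config$master_seed,
                                                "sampling"))
  })
  names(out) <- config$methods
  out
}

#' Run the configured experiment end to end, in memory
#'
#' Generates the synthetic study system, assembles every sampling method's
#' replicates, runs the cross-benchmark grid and computes all diagnostics.
#'
#' @param config A [run_config()].
#' @param verbose Log progress?
#' @param cache_dir Optional grid cache directory (resumable reruns).
#' @return List with `data`, `datasets`, `plan`, `grid`, `distances`,
#'   `summary`, `correlations`, `tests`, `config`.
#' @export
run_pipeline <- function(config, verbose = FALSE, cache_dir = NULL) {
  data <- prepare_data(config)
  datasets <- sample_all_methods(config, data, verbose = verbose)
  specs <- registry(lz_reference_size = config$lz_reference_size,
                    quipt_max_features = config$quipt_max_features)
  plan <- plan_grid(config$architectures, config$methods,
                    config$n_replicates)
  grid <- run_grid(plan, datasets, specs,
                   seed = derive_seed(config$master_seed, "train"),
                   cache_dir = cache_dir, verbose = verbose)
  distances <- compute_distances(datasets, config$n_replicates)
  list(data = data, datasets = datasets, plan = plan, grid = grid,
       distances = distances,
       summary = bias_summary(grid),
       correlations = correlation_analyses(grid, distances),
       tests = group_tests(grid),
       config = config)
}

write_manifest <- function(config, dir, stage) {
  utils::write.table(
    data.frame(key = c("stage", "config_hash", "master_seed"),
               value = c(stage, config_hash(config),
                         config$master_seed)),
    file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
}

#' Emit the synthetic study system to disk
#'
#' @param config A [run_config()].
#' @return The stage output directory, invisibly.
#' @export
cmd_simulate <- function(config) {
  dir <- file.path(config$outdir, "simulate")
  if (config$synthetic$n_background < 1 || config$synthetic$n_positive < 1) {
    stop("n_positive and n_background must be >= 1")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_synthetic(config$synthetic, dir)
  write_manifest(config, dir, "simulate")
  invisible(dir)
}

#' Emit every sampling method's replicated datasets to disk
#'
#' @param config A [run_config()].
#' @param verbose Log progress?
#' @return The stage output directory, invisibly.
#' @export
cmd_sample <- function(config, verbose = FALSE) {
  dir <- file.path(config$outdir, "sample")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data <- prepare_data(config)
  datasets <- sample_all_methods(config, data, verbose = verbose)
  for (m in names(datasets)) {
    for (r in seq_along(datasets[[m]])) {
      write_replicate(datasets[[m]][[r]],
                      file.path(dir, gsub("[^A-Za-z0-9-]", "_", m),
                                sprintf("replicate_%d", r)))
    }
  }
  write_manifest(config, dir, "sample")
  invisible(dir)
}

#' Run the grid and write the tidy result table
#'
#' @param config A [run_config()].
#' @param verbose Log progress?
#' @return The stage output directory, invisibly.
#' @export
cmd_run <- function(config, verbose = FALSE) {
  dir <- file.path(config$outdir, "grid")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_pipeline(config, verbose = verbose)
  utils::write.table(res$grid, file.path(dir, "grid_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$distances, file.path(dir, "distances.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config, dir, "run")
  invisible(dir)
}

#' Recompute the diagnostic tables from a persisted grid table
#'
#' @param config A [run_config()] whose `outdir` contains the `grid`
#'   stage.
#' @return The stage output directory, invisibly.
#' @export
cmd_stats <- function(config) {
  grid_file <- file.path(config$outdir, "grid", "grid_results.tsv")
  dist_file <- file.path(config$outdir, "grid", "distances.tsv")
  if (!file.exists(grid_file)) stop("run cmd_run first: no ", grid_file)
  grid <- tibble::as_tibble(utils::read.delim(grid_file))
  distances <- tibble::as_tibble(utils::read.delim(dist_file))
  dir <- file.path(config$outdir, "stats")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- bias_summary(grid)
  utils::write.table(s$per_architecture,
                     file.path(dir, "bias_per_architecture.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(s$replicate_sd, file.path(dir, "replicate_sd.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(correlation_analyses(grid, distances),
                     file.path(dir, "correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tests <- group_tests(grid)
  utils::write.table(tests$kruskal, file.path(dir, "kruskal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(family = names(tests$fraction_significant),
               fraction_significant = tests$fraction_significant),
    file.path(dir, "pairwise_fraction_significant.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config, dir, "stats")
  invisible(dir)
}
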