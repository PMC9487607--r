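#' Configuration of the synthetic sequence generator
#'
#' Describes the statistical structure of the synthetic study system: short
#' cationic/hydrophobic AMP-like positives, and a large annotated background
#' database with a broad length distribution, function keywords and
#' subcellular-localization labels.  Defaults are the package's desk-scale
#' study conditions; see the methods vignette for the rationale behind each
#' value.
#'
#' @param n_positive Number of positive (AMP-like) sequences.
#' @param n_background Number of background database records.
#' @param positive_length_law Shifted negative-binomial parameters for
#'   positive lengths (median ~18, truncated to `[min, max]`).
#' @param background_length_law Discretised log-normal mixture for
#'   background lengths: a main component near the database median and a
#'   short-protein/peptide component (fraction `short_frac`), truncated to
#'   `[min, max]`.
#' @param positive_composition 20-vector of residue probabilities enriched
#'   in K, R, L, W, I, F.
#' @param background_composition 20-vector near database-average residue
#'   frequencies.
#' @param keyword_prevalence Named probabilities that a background record
#'   carries each function keyword.
#' @param localization_prevalence Named probabilities for localization
#'   labels.
#' @param secreted_antimicrobial_or Odds ratio coupling the "secreted" and
#'   "antimicrobial" keywords.
#' @param planted_amp_fraction Fraction of antimicrobial-keyword records
#'   whose residues follow the positive composition (annotated AMPs in the
#'   background pool).
#' @param mislabeled_amp_rate Probability that a background record has
#'   positive-style composition without any AMP keyword (mislabelled AMPs
#'   that keyword screens cannot catch).
#' @param secreted_mix Mixing weight pulling secreted-keyword records
#'   toward the positive composition.
#' @param transmembrane_mix Mixing weight pulling transmembrane records
#'   toward a hydrophobic composition.
#' @param seed Integer seed; identical configs and seeds give byte-identical
#'   outputs.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_positive = 1000L,
                             n_background = 20000L,
                             positive_length_law = list(size = 2, mu = 16,
                                                        shift = 5, min = 5,
                                                        max = 190),
                             background_length_law = list(meanlog = 5.68,
                                                          sdlog = 0.75,
                                                          short_frac = 0.18,
                                                          short_meanlog = 3.3,
                                                          short_sdlog = 0.6,
                                                          min = 5,
                                                          max = 2000),
                             positive_composition = NULL,
                             background_composition = BACKGROUND_COMPOSITION,
                             keyword_prevalence = c(
                               antimicrobial = 0.010, antibiotic = 0.008,
                               antibacterial = 0.008, antiviral = 0.006,
                               fungicide = 0.004, defensin = 0.003,
                               bacteriocin = 0.002, defence = 0.010,
                               toxin = 0.010, transmembrane = 0.250,
                               "transit peptide" = 0.060, secreted = 0.150),
                             localization_prevalence = c(
                               cytoplasm = 0.35, secreted = 0.15,
                               mitochondria = 0.08,
                               "endoplasmic reticulum" = 0.05, golgi = 0.03),
                             secreted_antimicrobial_or = 4,
                             planted_amp_fraction = 0.5,
                             mislabeled_amp_rate = 0.005,
                             secreted_mix = 0.3,
                             transmembrane_mix = 0.4,
                             seed = 1L) {
  if (is.null(positive_composition)) {
    boost <- stats::setNames(rep(1, 20), AA_ORDER)
    boost[c("K", "R")] <- 3
    boost[c("L", "W", "I", "F")] <- 1.8
    positive_composition <- background_composition * boost
    positive_composition <- positive_composition / sum(positive_composition)
  }
  cfg <- list(n_positive = as.integer(n_positive),
              n_background = as.integer(n_background),
              positive_length_law = positive_length_law,
              background_length_law = background_length_law,
              positive_composition = positive_composition[AA_ORDER],
              background_composition = background_composition[AA_ORDER],
              keyword_prevalence = keyword_prevalence,
              localization_prevalence = localization_prevalence,
              secreted_antimicrobial_or = secreted_antimicrobial_or,
              planted_amp_fraction = planted_amp_fraction,
              mislabeled_amp_rate = mislabeled_amp_rate,
              secreted_mix = secreted_mix,
              transmembrane_mix = transmembrane_mix,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  for (nm in c("positive_composition", "background_composition")) {
    comp <- cfg[[nm]]
    if (length(comp) != 20 || any(comp < 0)) {
      stop(nm, " must be a non-negative 20-vector")
    }
    if (sum(comp) == 0) stop(nm, " is degenerate (all zero)")
    if (abs(sum(comp) - 1) > 1e-9) stop(nm, " must sum to 1")
  }
  prev <- c(cfg$keyword_prevalence, cfg$localization_prevalence)
  if (any(prev < 0 | prev > 1)) stop("prevalences must lie in [0, 1]")
  invisible(cfg)
}

sample_composition <- function(n, lengths, composition) {
  # one bulk draw, then split into per-record strings
  total <- sum(lengths)
  chars <- sample(AA_ORDER, total, replace = TRUE, prob = composition)
  f <- rep.int(seq_len(n), lengths)
  unname(vapply(split(chars, f), paste, "", collapse = ""))
}

sample_truncated <- function(n, rfun, lo, hi) {
  out <- rfun(n)
  bad <- which(out < lo | out > hi)
  guard <- 0L
  while (length(bad) > 0 && guard < 1000L) {
    out[bad] <- rfun(length(bad))
    bad <- bad[out[bad] < lo | out[bad] > hi]
    guard <- guard + 1L
  }
  out[out < lo] <- lo
  out[out > hi] <- hi
  out
}

#' Generate the synthetic positive (AMP-like) set
#'
#' Sequences are i.i.d.: lengths from a shifted negative-binomial law
#' truncated to the configured range, residues i.i.d. from the positive
#' composition.
#'
#' @param config A [synthetic_config()].
#' @return An `amp_records` tibble with `source = "positive"` and a logical
#'   `oracle_amp` column (all `TRUE`).
#' @export
generate_positives <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  if (config$n_positive < 1) stop("n_positive must be >= 1")
  law <- config$positive_length_law
  withr::with_seed(derive_seed(config$seed, "positives"), {
    lens <- sample_truncated(
      config$n_positive,
      function(k) law$shift + stats::rnbinom(k, size = law$size, mu = law$mu),
      law$min, law$max)
    residues <- sample_composition(config$n_positive, lens,
                                   config$positive_composition)
  })
  out <- amp_records(sprintf("AMP%05d", seq_len(config$n_positive)),
                     residues, source = "positive")
  out$oracle_amp <- TRUE
  out
}

#' Generate the synthetic annotated background database
#'
#' Records carry independent keyword and localization annotations at the
#' configured prevalences, except that "secreted" and "antimicrobial" are
#' positively associated (configurable odds ratio).  Composition is
#' heterogeneous: transmembrane records lean hydrophobic, secreted records
#' lean toward the positive composition, a configurable fraction of
#' antimicrobial-keyword records are fully AMP-like (planted annotated
#' AMPs), and a small rate of records are AMP-like without any AMP keyword
#' (mislabelled AMPs).  The latent AMP-likeness is recorded in the
#' `oracle_amp` column.
#'
#' @param config A [synthetic_config()].
#' @return An `amp_records` tibble with `source = "negative_pool"`.
#' @export
generate_background <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  n <- config$n_background
  if (n < 1) stop("n_background must be >= 1")
  law <- config$background_length_law
  kp <- config$keyword_prevalence
  lp <- config$localization_prevalence

  rlen <- function(k) {
    short <- stats::runif(k) < (law$short_frac %||% 0)
    ml <- ifelse(short, law$short_meanlog, law$meanlog)
    sl <- ifelse(short, law$short_sdlog, law$sdlog)
    round(stats::rlnorm(k, ml, sl))
  }
  withr::with_seed(derive_seed(config$seed, "background"), {
    lens <- sample_truncated(n, rlen, law$min, law$max)

    # keywords: secreted first, antimicrobial conditionally (odds ratio),
    # everything else independent
    has <- list()
    p_sec <- if ("secreted" %in% names(kp)) kp[["secreted"]] else 0
    has$secreted <- stats::runif(n) < p_sec
    p_amp <- if ("antimicrobial" %in% names(kp)) kp[["antimicrobial"]] else 0
    cond <- conditional_probs(p_amp, p_sec, config$secreted_antimicrobial_or)
    has$antimicrobial <- stats::runif(n) <
      ifelse(has$secreted, cond$p1, cond$p0)
    for (kw in setdiff(names(kp), c("secreted", "antimicrobial"))) {
      has[[kw]] <- stats::runif(n) < kp[[kw]]
    }
    keywords <- transpose_flags(has, n)

    locs <- list()
    for (lc in names(lp)) locs[[lc]] <- stats::runif(n) < lp[[lc]]
    localization <- transpose_flags(locs, n)

    # latent composition classes, in priority order
    planted <- has$antimicrobial &
      stats::runif(n) < config$planted_amp_fraction
    mislabeled <- !has$antimicrobial &
      stats::runif(n) < config$mislabeled_amp_rate
    amp_like <- planted | mislabeled
    tm <- !amp_like & isTRUE_vec(has$transmembrane, n)
    secr <- !amp_like & !tm & has$secreted
    cyto <- !amp_like & !tm & !secr & isTRUE_vec(locs$cytoplasm, n)

    comp_bg <- config$background_composition
    comp_pos <- config$positive_composition
    comp_tm_target <- stats::setNames(rep(0.02, 20), AA_ORDER)
    hydro <- c("L", "I", "V", "F", "A", "G", "M", "W")
    comp_tm_target[hydro] <- (1 - 0.02 * (20 - length(hydro))) / length(hydro)
    mix <- function(a, b, w) { x <- (1 - w) * a + w * b; x / sum(x) }
    comp_tm <- mix(comp_bg, comp_tm_target, config$transmembrane_mix)
    comp_secr <- mix(comp_bg, comp_pos, config$secreted_mix)
    comp_cyto <- comp_bg * ifelse(AA_ORDER %in% c("D", "E"), 1.3, 1)
    comp_cyto <- comp_cyto / sum(comp_cyto)

    class_of <- rep("base", n)
    class_of[cyto] <- "cyto"
    class_of[secr] <- "secr"
    class_of[tm] <- "tm"
    class_of[amp_like] <- "amp"
    comps <- list(base = comp_bg, cyto = comp_cyto, secr = comp_secr,
                  tm = comp_tm, amp = comp_pos)
    residues <- character(n)
    for (cl in c("base", "cyto", "secr", "tm", "amp")) {
      idx <- which(class_of == cl)
      if (length(idx)) {
        residues[idx] <- sample_composition(length(idx), lens[idx],
                                            comps[[cl]])
      }
    }
  })

  out <- amp_records(sprintf("BG%06d", seq_len(n)), residues,
                     keywords = keywords, localization = localization,
                     source = "negative_pool")
  out$oracle_amp <- amp_like
  out
}

isTRUE_vec <- function(x, n) if (is.null(x)) rep(FALSE, n) else x

# Solve for P(amp | secreted) and P(amp | not secreted) such that the
# marginal equals p_amp and the odds ratio equals `or`.
conditional_probs <- function(p_amp, p_sec, or) {
  if (p_amp <= 0 || p_sec <= 0 || or == 1) {
    return(list(p0 = p_amp, p1 = p_amp))
  }
  f <- function(p0) {
    odds1 <- or * p0 / (1 - p0)
    p1 <- odds1 / (1 + odds1)
    p_sec * p1 + (1 - p_sec) * p0 - p_amp
  }
  p0 <- stats::uniroot(f, c(1e-12, p_amp))$root
  odds1 <- or * p0 / (1 - p0)
  list(p0 = p0, p1 = odds1 / (1 + odds1))
}

transpose_flags <- function(flags, n) {
  nms <- names(flags)
  mat <- do.call(cbind, flags)
  lapply(seq_len(n), function(i) nms[mat[i, ]])
}

#' Write the synthetic study system to disk
#'
#' Emits the FASTA and annotation-TSV dialects that [read_fasta()] and
#' [read_annotations()] consume, plus the latent oracle labels.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_synthetic <- function(config, dir) {
  positives <- generate_positives(config)
  background <- generate_background(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(positives = file.path(dir, "positives.fasta"),
             background = file.path(dir, "background.fasta"),
             annotations = file.path(dir, "background_annotations.tsv"),
             oracle = file.path(dir, "oracle_labels.tsv"))
  write_fasta(positives, paths[["positives"]])
  write_fasta(background, paths[["background"]])
  write_annotations(background, paths[["annotations"]])
  oracle <- data.frame(id = c(positives$id, background$id),
                       oracle_amp = c(positives$oracle_amp,
                                      background$oracle_amp))
  utils::write.table(oracle, paths[["oracle"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
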