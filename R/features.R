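# Feature extractors of the classical AMP-prediction architectures.  Every
# extractor is a pure deterministic function from a residue string to a
# fixed-length named numeric vector.

check_peptide <- function(residues) {
  if (length(residues) != 1 || !nzchar(residues)) {
    stop("residues must be a single non-empty string")
  }
  idx <- aa_indices(residues)
  if (anyNA(idx)) stop("non-standard residue in peptide")
  idx
}

#' Amino-acid composition (AAC)
#'
#' Frequency of each of the 20 standard residues; sums to 1.
#'
#' @param residues Peptide string.
#' @return Named numeric vector of length 20.
#' @export
aac <- function(residues) {
  idx <- check_peptide(residues)
  stats::setNames(tabulate(idx, 20) / length(idx), AA_ORDER)
}

standardize_scale <- function(scale) {
  (scale - mean(scale)) / stats::sd(scale)
}

default_pseaac_scales <- function() {
  list(hydrophobicity = SCALE_EISENBERG,
       hydrophilicity = SCALE_HOPP,
       sidechain_mass = SCALE_SIDECHAIN_MASS)
}

#' Pseudo-amino-acid composition (PseAAC)
#'
#' Classic Chou form: 20 composition entries plus `lam` sequence-order
#' correlation factors.  Factor `theta_j` averages, over residue pairs `j`
#' positions apart, the squared differences of standardized property values
#' (mean over the configured scales); the full vector is normalized by
#' `1 + w * sum(theta)`.
#'
#' @param residues Peptide string, longer than `lam`.
#' @param lam Correlation depth (default 20).
#' @param weight Weight `w` of the order factors (default 0.05).
#' @param scales Named list of 20-residue property scales; defaults to
#'   hydrophobicity, hydrophilicity and side-chain mass.
#' @param cap_to_length If `TRUE`, peptides no longer than `lam` are
#'   handled by computing only the order factors that exist (`j < L`) and
#'   setting the rest to zero, keeping the output dimension fixed — the
#'   continuous extension used by the iAMP-2L-style architecture so that
#'   very short peptides can still be scored.  If `FALSE` (the default),
#'   such peptides are an error.
#' @return Named numeric vector of length `20 + lam`.
#' @export
pseaac <- function(residues, lam = 20L, weight = 0.05,
                   scales = default_pseaac_scales(),
                   cap_to_length = FALSE) {
  idx <- check_peptide(residues)
  L <- length(idx)
  if (L <= lam && !cap_to_length) stop("peptide length must exceed lam")
  lam_eff <- min(lam, L - 1L)
  smat <- vapply(scales, function(s) standardize_scale(s)[idx],
                 numeric(L))
  if (L == 1) smat <- matrix(smat, nrow = 1)
  theta <- numeric(lam)
  theta[seq_len(lam_eff)] <- vapply(seq_len(lam_eff), function(j) {
    d <- smat[seq_len(L - j), , drop = FALSE] -
      smat[seq_len(L - j) + j, , drop = FALSE]
    mean(rowMeans(d^2))
  }, numeric(1))
  f <- tabulate(idx, 20) / L
  denom <- 1 + weight * sum(theta)
  stats::setNames(c(f, weight * theta) / denom,
                  c(AA_ORDER, paste0("lambda", seq_len(lam))))
}

ctd_names <- local({
  qs <- c(0, 25, 50, 75, 100)
  unlist(lapply(names(CTD_ATTRIBUTES), function(a) {
    paste0(a, ".G", rep(1:3, each = 5), ".D", rep(qs, 3))
  }))
})

distribution_descriptors <- function(positions, L) {
  k <- length(positions)
  if (k == 0) return(rep(0, 5))
  at <- pmax(1L, ceiling(c(0, 0.25, 0.5, 0.75, 1) * k))
  positions[at] / L
}

#' CTD distribution descriptors
#'
#' For each of 7 physicochemical attributes, residues are mapped into 3
#' classes; for each class, 5 descriptors give the relative sequence
#' position (proportion of length) of the first occurrence and of the
#' occurrences at the 25/50/75/100% quantiles: 7 x 3 x 5 = 105 features.
#' Classes absent from the peptide contribute zeros.
#'
#' @param residues Peptide string.
#' @return Named numeric vector of length 105.
#' @export
ctd_distribution <- function(residues) {
  idx <- check_peptide(residues)
  L <- length(idx)
  out <- numeric(105)
  pos <- 0L
  for (a in seq_along(CTD_CLASS_MAP)) {
    cls <- CTD_CLASS_MAP[[a]][idx]
    for (g in 1:3) {
      out[pos + 1:5] <- distribution_descriptors(which(cls == g), L)
      pos <- pos + 5L
    }
  }
  stats::setNames(out, ctd_names)
}

#' Reduced CTD distribution subset (AmPEP-style, 23 descriptors)
#'
#' A fixed index subset of [ctd_distribution()]; the default subset is a
#' package configuration constant (see the methods vignette) and can be
#' overridden.
#'
#' @param residues Peptide string.
#' @param subset Character vector of 23 CTD descriptor names.
#' @return Named numeric vector of length `length(subset)`.
#' @export
ampep_subset <- function(residues, subset = AMPEP_SUBSET_DEFAULT) {
  full <- ctd_distribution(residues)
  if (!all(subset %in% names(full))) stop("unknown descriptor in subset")
  full[subset]
}

charge_at <- function(counts, pH) {
  pos <- 1 / (1 + 10^(pH - PKA_NTERM)) +
    sum(counts[names(PKA_SIDECHAIN_POS)] /
          (1 + 10^(pH - PKA_SIDECHAIN_POS)))
  neg <- 1 / (1 + 10^(PKA_CTERM - pH)) +
    sum(counts[names(PKA_SIDECHAIN_NEG)] /
          (1 + 10^(PKA_SIDECHAIN_NEG - pH)))
  pos - neg
}

#' Global physicochemical descriptor panel
#'
#' Net charge by Henderson-Hasselbalch over the ionizable groups at the
#' given pH; isoelectric point by bisection of the charge curve; Eisenberg
#' mean hydrophobicity and hydrophobic moment (helical angle 100 degrees,
#' per residue); normalized amphipathicity (moment divided by mean absolute
#' hydrophobicity); instability index from the dipeptide weight table;
#' aliphatic and Boman indices; mean flexibility and secondary-structure
#' propensities; molecular weight; and a binary solubility flag (soluble if
#' the mean hydrophobicity is negative or the net charge magnitude is at
#' least 2).
#'
#' @param residues Peptide string.
#' @param pH pH for the charge calculation (default 7.0).
#' @return Named numeric vector of 15 descriptors.
#' @export
physchem_panel <- function(residues, pH = 7.0) {
  idx <- check_peptide(residues)
  L <- length(idx)
  counts <- stats::setNames(tabulate(idx, 20), AA_ORDER)
  h <- SCALE_EISENBERG[idx]
  net_charge <- charge_at(counts, pH)
  pI <- stats::uniroot(function(p) charge_at(counts, p), c(0, 14),
                       tol = 1e-8)$root
  angles <- (seq_len(L) - 1) * 100 * pi / 180
  mu_vec <- c(sum(h * cos(angles)), sum(h * sin(angles)))
  mu <- sqrt(sum(mu_vec^2)) / L
  amph <- mu / mean(abs(SCALE_EISENBERG))
  instab <- if (L < 2) 0 else
    10 / L * sum(DIWV[cbind(idx[-L], idx[-1])])
  f <- counts / L
  c(net_charge = net_charge,
    isoelectric_point = pI,
    hydrophobicity_mean = mean(h),
    hydrophobic_moment = mu,
    amphipathicity = amph,
    instability_index = instab,
    aliphatic_index = 100 * (f[["A"]] + 2.9 * f[["V"]] +
                               3.9 * (f[["I"]] + f[["L"]])),
    boman_index = -mean(SCALE_BOMAN[idx]),
    flexibility = mean(SCALE_FLEXIBILITY[idx]),
    alpha_helix = mean(SCALE_CF_HELIX[idx]),
    alpha_propensity = mean(SCALE_LEVITT_HELIX[idx]),
    beta_propensity = mean(SCALE_CF_SHEET[idx]),
    loop_propensity = mean(SCALE_CF_TURN[idx]),
    molecular_weight = sum(SCALE_RESIDUE_MASS[idx]) + MASS_WATER,
    solubility_flag = as.numeric(mean(h) < 0 || abs(net_charge) >= 2))
}

#' Nine-descriptor structural/physicochemical panel (CS-AMPPred-style)
#'
#' Helix scale mean and helix propensity, sheet and loop propensities,
#' charge, hydrophobicity, flexibility, amphipathicity and hydrophobic
#' moment, all drawn from [physchem_panel()].
#'
#' @param residues Peptide string.
#' @return Named numeric vector of length 9.
#' @export
cs_amppred_features <- function(residues) {
  physchem_panel(residues)[c("alpha_helix", "alpha_propensity",
                             "beta_propensity", "loop_propensity",
                             "net_charge", "hydrophobicity_mean",
                             "flexibility", "amphipathicity",
                             "hydrophobic_moment")]
}

group_first_occurrence <- function(cls, L) {
  vapply(1:3, function(g) {
    w <- which(cls == g)
    if (length(w) == 0) 0 else w[1] / L
  }, numeric(1))
}

group_fractions <- function(cls) {
  vapply(1:3, function(g) mean(cls == g), numeric(1))
}

#' 22-descriptor panel (MACREL-style)
#'
#' First-occurrence distribution descriptors and composition fractions for
#' two 3-group alphabets (free energy of transition into a membrane helix,
#' and solvent accessibility), plus ten global descriptors (charge,
#' solubility flag, instability, aliphaticity, membrane-binding
#' amphipathicity, hydrophobicity, Boman index, isoelectric point,
#' hydrophobic moment, molecular weight).  The exact 22-slot layout is a
#' package configuration constant.
#'
#' @param residues Peptide string.
#' @return Named numeric vector of length 22.
#' @export
macrel_features <- function(residues) {
  idx <- check_peptide(residues)
  L <- length(idx)
  fet <- FET_CLASS_MAP[idx]
  sa <- SA_CLASS_MAP[idx]
  panel <- physchem_panel(residues)
  c(stats::setNames(group_first_occurrence(fet, L),
                    paste0("fet.G", 1:3, ".first")),
    stats::setNames(group_first_occurrence(sa, L),
                    paste0("sa.G", 1:3, ".first")),
    stats::setNames(group_fractions(fet), paste0("fet.G", 1:3, ".frac")),
    stats::setNames(group_fractions(sa), paste0("sa.G", 1:3, ".frac")),
    panel[c("net_charge", "solubility_flag", "instability_index",
            "aliphatic_index", "amphipathicity", "hydrophobicity_mean",
            "boman_index", "isoelectric_point", "hydrophobic_moment",
            "molecular_weight")])
}

#' 27-descriptor panel (ampir-style)
#'
#' PseAAC at correlation depth 2 (22 entries) concatenated with
#' amphipathicity, hydrophobicity, isoelectric point, molecular weight and
#' net charge.
#'
#' @param residues Peptide string (length > 2).
#' @return Named numeric vector of length 27.
#' @export
ampir_features <- function(residues) {
  panel <- physchem_panel(residues)
  c(pseaac(residues, lam = 2L),
    panel[c("amphipathicity", "hydrophobicity_mean", "isoelectric_point",
            "molecular_weight", "net_charge")])
}

# GM(1,1) grey model on a numeric series: least squares on the accumulated
# series via the closed-form 2x2 normal equations; returns c(a, b)
# (development coefficient, grey input).
gm11 <- function(x) gm11_fast(x)

default_mlamp_scales <- function() {
  list(hydrophobicity = SCALE_EISENBERG,
       hydrophilicity = SCALE_HOPP,
       sidechain_mass = SCALE_SIDECHAIN_MASS,
       pk1 = SCALE_PK1,
       pk2 = SCALE_PK2)
}

#' 30-descriptor PseAAC with grey-model coefficients (MLAMP-style)
#'
#' 20 composition entries plus, for each of 5 per-residue property series
#' along the sequence, the two GM(1,1) grey-model coefficients
#' (development coefficient and grey input) fitted by least squares on the
#' accumulated series.
#'
#' @param residues Peptide string of length >= 4.
#' @param scales Named list of 5 property scales.
#' @return Named numeric vector of length 30.
#' @export
mlamp_features <- function(residues, scales = default_mlamp_scales()) {
  idx <- check_peptide(residues)
  if (length(idx) < 4) stop("grey model needs peptide length >= 4")
  grey <- unlist(lapply(names(scales), function(nm) {
    co <- gm11(scales[[nm]][idx])
    stats::setNames(co, paste0(nm, c(".a", ".b")))
  }))
  c(aac(residues), grey)
}

#' Centred principal-component projection fitted on training data
#'
#' PCA is fitted on the training matrix only (centring and unit scaling of
#' non-constant columns); benchmark data must be projected with
#' [pca_project()] so no benchmark information reaches the fit.
#'
#' @param train_matrix Numeric matrix, observations in rows.
#' @param n_components Number of components; default keeps the smallest
#'   number explaining 95% of the variance.
#' @return List with `rotation`, `center`, `scale`, `n_components` and the
#'   projected training matrix `scores`.
#' @export
pca_transform <- function(train_matrix, n_components = NULL) {
  sds <- apply(train_matrix, 2, stats::sd)
  if (all(sds == 0)) stop("constant feature matrix")
  scale_vec <- ifelse(sds == 0, 1, sds)
  fit <- stats::prcomp(train_matrix, center = TRUE, scale. = scale_vec)
  if (is.null(n_components)) {
    v <- fit$sdev^2
    n_components <- which(cumsum(v) / sum(v) >= 0.95)[1]
  }
  n_components <- min(n_components, ncol(fit$rotation))
  list(rotation = fit$rotation[, seq_len(n_components), drop = FALSE],
       center = fit$center, scale = fit$scale,
       n_components = n_components,
       scores = fit$x[, seq_len(n_components), drop = FALSE])
}

#' Project new data with a fitted [pca_transform()]
#'
#' @param fit A [pca_transform()] result.
#' @param newdata Numeric matrix with the same columns as the training
#'   matrix.
#' @return The projected matrix.
#' @export
pca_project <- function(fit, newdata) {
  scale(newdata, center = fit$center, scale = fit$scale) %*% fit$rotation
}

#' Apply a per-peptide extractor to a set of records
#'
#' @param records An `amp_records` tibble or character vector of sequences.
#' @param fun A per-peptide extractor (e.g. [aac()]).
#' @param ... Passed to `fun`.
#' @return Numeric matrix, one row per peptide.
#' @export
feature_matrix <- function(records, fun, ...) {
  residues <- if (is.character(records)) records else records$residues
  first <- fun(residues[1], ...)
  out <- matrix(0, nrow = length(residues), ncol = length(first),
                dimnames = list(NULL, names(first)))
  out[1, ] <- first
  if (length(residues) > 1) {
    for (i in 2:length(residues)) out[i, ] <- fun(residues[i], ...)
  }
  out
}
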