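# Matrix-level feature extraction.  These produce, for a whole set of
# peptides at once, exactly the matrices that row-wise application of the
# per-peptide extractors would give (asserted by tests), but vectorized —
# the grid runner extracts features for tens of thousands of peptides.

residue_count_matrix <- function(residues) {
  n <- length(residues)
  out <- matrix(0L, n, 20, dimnames = list(NULL, AA_ORDER))
  idx_list <- lapply(residues, aa_indices)
  for (i in seq_len(n)) {
    out[i, ] <- tabulate(idx_list[[i]], 20)
  }
  attr(out, "idx_list") <- idx_list
  out
}

# indexed 0-based from C++, hence the + 1
ctd_codes <- local({
  codes <- integer(256)
  codes[utf8ToInt(AA_STRING) + 1L] <- seq_len(20)
  codes
})

ctd_class_matrix <- local({
  do.call(rbind, CTD_CLASS_MAP)
})

ctd_matrix <- function(residues) {
  out <- ctd_matrix_cpp(residues, ctd_class_matrix, ctd_codes)
  colnames(out) <- ctd_names
  out
}

# vectorized Henderson-Hasselbalch net charge for a count matrix
charge_matrix <- function(counts, pH) {
  pos <- 1 / (1 + 10^(pH - PKA_NTERM))
  for (r in names(PKA_SIDECHAIN_POS)) {
    pos <- pos + counts[, r] / (1 + 10^(pH - PKA_SIDECHAIN_POS[[r]]))
  }
  neg <- 1 / (1 + 10^(PKA_CTERM - pH))
  for (r in names(PKA_SIDECHAIN_NEG)) {
    neg <- neg + counts[, r] / (1 + 10^(PKA_SIDECHAIN_NEG[[r]] - pH))
  }
  pos - neg
}

# isoelectric point by vectorized bisection (charge is monotone in pH)
pi_bisect <- function(counts, iters = 60L) {
  lo <- rep(0, nrow(counts))
  hi <- rep(14, nrow(counts))
  for (it in seq_len(iters)) {
    mid <- (lo + hi) / 2
    pos_charge <- charge_matrix(counts, mid) > 0
    lo <- ifelse(pos_charge, mid, lo)
    hi <- ifelse(pos_charge, hi, mid)
  }
  (lo + hi) / 2
}

panel_matrix <- function(residues, pH = 7.0) {
  counts <- residue_count_matrix(residues)
  idx_list <- attr(counts, "idx_list")
  n <- length(residues)
  L <- lengths(idx_list)
  f <- counts / L
  scale_mean <- function(sc) as.numeric(f %*% sc)

  net_charge <- charge_matrix(counts, pH)
  pI <- pi_bisect(counts)
  hmean <- scale_mean(SCALE_EISENBERG)

  mu <- numeric(n)
  instab <- numeric(n)
  for (i in seq_len(n)) {
    idx <- idx_list[[i]]
    h <- SCALE_EISENBERG[idx]
    ang <- (seq_along(idx) - 1) * 100 * pi / 180
    mu[i] <- sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / L[i]
    instab[i] <- if (L[i] < 2) 0 else
      10 / L[i] * sum(DIWV[cbind(idx[-L[i]], idx[-1])])
  }

  out <- cbind(
    net_charge = net_charge,
    isoelectric_point = pI,
    hydrophobicity_mean = hmean,
    hydrophobic_moment = mu,
    amphipathicity = mu / mean(abs(SCALE_EISENBERG)),
    instability_index = instab,
    aliphatic_index = 100 * (f[, "A"] + 2.9 * f[, "V"] +
                               3.9 * (f[, "I"] + f[, "L"])),
    boman_index = -scale_mean(SCALE_BOMAN),
    flexibility = scale_mean(SCALE_FLEXIBILITY),
    alpha_helix = scale_mean(SCALE_CF_HELIX),
    alpha_propensity = scale_mean(SCALE_LEVITT_HELIX),
    beta_propensity = scale_mean(SCALE_CF_SHEET),
    loop_propensity = scale_mean(SCALE_CF_TURN),
    molecular_weight = as.numeric(counts %*% SCALE_RESIDUE_MASS) +
      MASS_WATER,
    solubility_flag = as.numeric(hmean < 0 | abs(net_charge) >= 2))
  attr(out, "counts") <- counts
  attr(out, "idx_list") <- idx_list
  out
}

CS_AMPPRED_COLS <- c("alpha_helix", "alpha_propensity", "beta_propensity",
                     "loop_propensity", "net_charge",
                     "hydrophobicity_mean", "flexibility", "amphipathicity",
                     "hydrophobic_moment")

macrel_matrix <- function(residues) {
  panel <- panel_matrix(residues)
  idx_list <- attr(panel, "idx_list")
  n <- length(residues)
  grp <- matrix(0, n, 12,
                dimnames = list(NULL, c(paste0("fet.G", 1:3, ".first"),
                                        paste0("sa.G", 1:3, ".first"),
                                        paste0("fet.G", 1:3, ".frac"),
                                        paste0("sa.G", 1:3, ".frac"))))
  for (i in seq_len(n)) {
    idx <- idx_list[[i]]
    L <- length(idx)
    fet <- FET_CLASS_MAP[idx]
    sa <- SA_CLASS_MAP[idx]
    grp[i, 1:3] <- group_first_occurrence(fet, L)
    grp[i, 4:6] <- group_first_occurrence(sa, L)
    grp[i, 7:9] <- group_fractions(fet)
    grp[i, 10:12] <- group_fractions(sa)
  }
  cbind(grp, panel[, c("net_charge", "solubility_flag",
                       "instability_index", "aliphatic_index",
                       "amphipathicity", "hydrophobicity_mean",
                       "boman_index", "isoelectric_point",
                       "hydrophobic_moment", "molecular_weight"),
                   drop = FALSE])
}

pseaac_matrix <- function(residues, lam, weight = 0.05,
                          scales = default_pseaac_scales(),
                          cap_to_length = FALSE) {
  out <- t(vapply(residues, pseaac, numeric(20 + lam), lam = lam,
                  weight = weight, scales = scales,
                  cap_to_length = cap_to_length, USE.NAMES = FALSE))
  colnames(out) <- c(AA_ORDER, paste0("lambda", seq_len(lam)))
  out
}

ampir_matrix <- function(residues) {
  panel <- panel_matrix(residues)
  cbind(pseaac_matrix(residues, lam = 2L),
        panel[, c("amphipathicity", "hydrophobicity_mean",
                  "isoelectric_point", "molecular_weight", "net_charge"),
              drop = FALSE])
}

# closed-form GM(1,1) least squares (2x2 normal equations)
gm11_fast <- function(x) {
  L <- length(x)
  x1 <- cumsum(x)
  z <- 0.5 * (x1[-1] + x1[-L])
  y <- x[-1]
  szz <- sum(z * z)
  sz <- sum(z)
  szy <- sum(z * y)
  sy <- sum(y)
  n <- L - 1
  det <- szz * n - sz * sz
  if (abs(det) < 1e-12 * max(1, szz * n)) {
    return(c(0, mean(y)))
  }
  a <- -(n * szy - sz * sy) / det
  b <- (szz * sy - sz * szy) / det
  c(a, b)
}

mlamp_matrix <- function(residues, scales = default_mlamp_scales()) {
  n <- length(residues)
  counts <- residue_count_matrix(residues)
  idx_list <- attr(counts, "idx_list")
  grey_names <- unlist(lapply(names(scales),
                              function(nm) paste0(nm, c(".a", ".b"))))
  out <- matrix(0, n, 30,
                dimnames = list(NULL, c(AA_ORDER, grey_names)))
  out[, 1:20] <- counts / lengths(idx_list)
  for (i in seq_len(n)) {
    idx <- idx_list[[i]]
    if (length(idx) < 4) stop("grey model needs peptide length >= 4")
    col <- 21L
    for (nm in names(scales)) {
      out[i, col + 0:1] <- gm11_fast(scales[[nm]][idx])
      col <- col + 2L
    }
  }
  out
}

aac_matrix <- function(residues) {
  counts <- residue_count_matrix(residues)
  out <- counts / lengths(attr(counts, "idx_list"))
  attr(out, "idx_list") <- NULL
  out
}
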