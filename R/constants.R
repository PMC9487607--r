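# Physicochemical constants used by the feature extractors.  All vectors are
# keyed by the 20 standard residues in the order AA_ORDER.

AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_STRING <- paste(AA_ORDER, collapse = "")

aa_vec <- function(...) {
  x <- c(...)
  stopifnot(setequal(names(x), AA_ORDER))
  x[AA_ORDER]
}

# Eisenberg consensus hydrophobicity (Eisenberg et al. 1984)
SCALE_EISENBERG <- aa_vec(
  A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29, Q = -0.85, E = -0.74,
  G = 0.48, H = -0.40, I = 1.38, L = 1.06, K = -1.50, M = 0.64, F = 1.19,
  P = 0.12, S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08)

# Hopp & Woods (1981) hydrophilicity
SCALE_HOPP <- aa_vec(
  A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0, Q = 0.2, E = 3.0,
  G = 0.0, H = -0.5, I = -1.8, L = -1.8, K = 3.0, M = -1.3, F = -2.5,
  P = 0.0, S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5)

# Side-chain masses (Da), glycine side chain = 1 H
SCALE_SIDECHAIN_MASS <- aa_vec(
  A = 15, R = 101, N = 58, D = 59, C = 47, Q = 72, E = 73, G = 1, H = 82,
  I = 57, L = 57, K = 73, M = 75, F = 91, P = 42, S = 31, T = 45, W = 130,
  Y = 107, V = 43)

# alpha-carboxyl and alpha-amino pK values of the free amino acids
SCALE_PK1 <- aa_vec(
  A = 2.34, R = 2.17, N = 2.02, D = 1.88, C = 1.96, Q = 2.17, E = 2.19,
  G = 2.34, H = 1.82, I = 2.36, L = 2.36, K = 2.18, M = 2.28, F = 1.83,
  P = 1.99, S = 2.21, T = 2.09, W = 2.83, Y = 2.20, V = 2.32)
SCALE_PK2 <- aa_vec(
  A = 9.69, R = 9.04, N = 8.80, D = 9.60, C = 10.28, Q = 9.13, E = 9.67,
  G = 9.60, H = 9.17, I = 9.60, L = 9.60, K = 8.95, M = 9.21, F = 9.13,
  P = 10.60, S = 9.15, T = 9.10, W = 9.39, Y = 9.11, V = 9.62)

# Radzicka & Wolfenden transfer free energies as used for the Boman index
SCALE_BOMAN <- aa_vec(
  A = 1.81, R = -14.92, N = -6.64, D = -8.72, C = 1.28, Q = -5.54,
  E = -6.81, G = 0.94, H = -4.66, I = 4.92, L = 4.92, K = -5.55, M = 2.35,
  F = 2.98, P = 0.0, S = -3.40, T = -2.57, W = 2.33, Y = -0.14, V = 4.04)

# Bhaskaran & Ponnuswamy (1988) average flexibility
SCALE_FLEXIBILITY <- aa_vec(
  A = 0.357, R = 0.529, N = 0.463, D = 0.511, C = 0.346, Q = 0.493,
  E = 0.497, G = 0.544, H = 0.323, I = 0.462, L = 0.365, K = 0.466,
  M = 0.295, F = 0.314, P = 0.509, S = 0.507, T = 0.444, W = 0.305,
  Y = 0.420, V = 0.386)

# Chou & Fasman (1978) conformational preferences
SCALE_CF_HELIX <- aa_vec(
  A = 1.42, R = 0.98, N = 0.67, D = 1.01, C = 0.70, Q = 1.11, E = 1.51,
  G = 0.57, H = 1.00, I = 1.08, L = 1.21, K = 1.16, M = 1.45, F = 1.13,
  P = 0.57, S = 0.77, T = 0.83, W = 1.08, Y = 0.69, V = 1.06)
SCALE_CF_SHEET <- aa_vec(
  A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19, Q = 1.10, E = 0.37,
  G = 0.75, H = 0.87, I = 1.60, L = 1.30, K = 0.74, M = 1.05, F = 1.38,
  P = 0.55, S = 0.75, T = 1.19, W = 1.37, Y = 1.47, V = 1.70)
SCALE_CF_TURN <- aa_vec(
  A = 0.66, R = 0.95, N = 1.56, D = 1.46, C = 1.19, Q = 0.98, E = 0.74,
  G = 1.56, H = 0.95, I = 0.47, L = 0.59, K = 1.01, M = 0.60, F = 0.60,
  P = 1.52, S = 1.43, T = 0.96, W = 0.96, Y = 1.14, V = 0.50)

# Levitt (1978) helix propensity
SCALE_LEVITT_HELIX <- aa_vec(
  A = 1.29, R = 0.96, N = 0.90, D = 1.04, C = 1.11, Q = 1.27, E = 1.44,
  G = 0.56, H = 1.22, I = 0.97, L = 1.30, K = 1.23, M = 1.47, F = 1.07,
  P = 0.52, S = 0.82, T = 0.71, W = 0.99, Y = 0.72, V = 0.91)

# Average residue masses (Da); add one water for a whole peptide
SCALE_RESIDUE_MASS <- aa_vec(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
MASS_WATER <- 18.01524

# Side-chain / terminal pK values for Henderson-Hasselbalch charge (EMBOSS
# defaults)
PKA_SIDECHAIN_POS <- c(K = 10.8, R = 12.5, H = 6.5)
PKA_SIDECHAIN_NEG <- c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
PKA_NTERM <- 8.6
PKA_CTERM <- 3.6

# Three-class alphabets for the seven CTD attributes (Dubchak et al. 1995
# grouping as propagated by PROFEAT/propy)
CTD_ATTRIBUTES <- list(
  hydrophobicity       = c(G1 = "RKEDQN", G2 = "GASTPHY", G3 = "CLVIMFW"),
  normalized_vdw       = c(G1 = "GASTPDC", G2 = "NVEQIL", G3 = "MHKFRYW"),
  polarity             = c(G1 = "LIFWCMVY", G2 = "PATGS", G3 = "HQRKNED"),
  polarizability       = c(G1 = "GASDT", G2 = "CPNVEQIL", G3 = "KMHFRYW"),
  charge               = c(G1 = "KR", G2 = "ANCQGHILMFPSTWYV", G3 = "DE"),
  secondary_structure  = c(G1 = "EALMQKRH", G2 = "VIYCWFT", G3 = "GNPSD"),
  solvent_accessibility = c(G1 = "ALFCGIVW", G2 = "RKQEND", G3 = "MPSTHY"))

# Three-group alphabet by free energy of transition from coil in water to
# helix in a lipid phase (configuration constant for the MACREL-style
# extractor): strongly transferring hydrophobics, small/neutral, charged
# and strongly polar.
FET_GROUPS <- c(G1 = "ILVFMWC", G2 = "AGPSTYH", G3 = "RKDENQ")

# Solvent-accessibility groups reused from the CTD alphabet
SA_GROUPS <- CTD_ATTRIBUTES$solvent_accessibility

# Default 23-descriptor subset of the 105 CTD distribution descriptors used
# by the reduced AmPEP-style architecture.  The exact published subset is a
# configuration constant; this default keeps all hydrophobicity
# descriptors, the cationic-charge class and part of the
# solvent-accessibility space, and can be overridden.
AMPEP_SUBSET_DEFAULT <- c(
  paste0("hydrophobicity.G", rep(1:3, each = 5), ".D", rep(c(0, 25, 50, 75, 100), 3)),
  paste0("charge.G1.D", c(0, 25, 50, 75, 100)),
  paste0("solvent_accessibility.G2.D", c(0, 25, 50)))

# Guruprasad, Reddy & Pandit (1990) dipeptide instability weight values
# (DIWV); rows = first residue, columns = second residue, AA_ORDER order.
DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34),
  nrow = 20, byrow = TRUE, dimnames = list(AA_ORDER, AA_ORDER))

# Average amino-acid frequencies of reviewed protein databases, used as the
# default background composition of the synthetic generator.
BACKGROUND_COMPOSITION <- aa_vec(
  A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137, Q = 0.0393,
  E = 0.0674, G = 0.0708, H = 0.0227, I = 0.0593, L = 0.0965, K = 0.0582,
  M = 0.0241, F = 0.0386, P = 0.0472, S = 0.0661, T = 0.0535, W = 0.0110,
  Y = 0.0292, V = 0.0687)
BACKGROUND_COMPOSITION <- BACKGROUND_COMPOSITION / sum(BACKGROUND_COMPOSITION)

# residue -> class index (1..3) lookups, one per grouped alphabet
group_class_map <- function(groups) {
  m <- integer(20)
  for (g in seq_along(groups)) {
    m[match(strsplit(groups[[g]], "")[[1]], AA_ORDER)] <- g
  }
  m
}
CTD_CLASS_MAP <- lapply(CTD_ATTRIBUTES, group_class_map)
FET_CLASS_MAP <- group_class_map(FET_GROUPS)
SA_CLASS_MAP <- group_class_map(SA_GROUPS)

# Map a residue string to integer codes 1..20 in AA_ORDER (NA for anything
# else).  Shared by validation and every extractor.
AA_CODE <- local({
  code <- rep(NA_integer_, 128)
  code[utf8ToInt(AA_STRING)] <- seq_len(20)
  code
})

aa_indices <- function(residues) {
  AA_CODE[utf8ToInt(residues)]
}
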