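test_that("feature dimensions match the architecture table", {
  p <- "GIGKFLHSAKKFGKAFVGEIMNS"
  dims <- list(aac = 20L, ctd_distribution = 105L, ampep_subset = 23L,
               cs_amppred_features = 9L, macrel_features = 22L,
               ampir_features = 27L, mlamp_features = 30L)
  for (nm in names(dims)) {
    expect_length(get(nm)(p), dims[[nm]])
  }
  expect_length(pseaac(p, lam = 20), 40L)
  expect_length(pseaac(p, lam = 2), 22L)
})

test_that("amino-acid composition counts frequencies", {
  v <- aac("ACDE")
  expect_equal(unname(v[c("A", "C", "D", "E")]), rep(0.25, 4))
  expect_equal(sum(v), 1)
  expect_equal(unname(aac("AAAA")["A"]), 1)
  expect_error(aac(""), "non-empty")
  # permutation invariance
  expect_equal(aac("KWKL"), aac("LKWK"))
})

test_that("PseAAC reduces to pure composition on homopolymers", {
  v <- pseaac(strrep("A", 30), lam = 5)
  expect_equal(unname(v["A"]), 1)
  expect_equal(unname(v[21:25]), rep(0, 5))
})

test_that("PseAAC matches a step-by-step hand computation", {
  # 12-mer, lam = 2, single scale (hydrophobicity), w = 0.05
  p <- "KWKAFLGLLAKV"
  scale <- ampbench:::SCALE_EISENBERG
  s <- (scale - mean(scale)) / stats::sd(scale)
  x <- s[strsplit(p, "")[[1]]]
  L <- 12
  theta1 <- mean((x[1:(L - 1)] - x[2:L])^2)
  theta2 <- mean((x[1:(L - 2)] - x[3:L])^2)
  f <- table(factor(strsplit(p, "")[[1]], ampbench:::AA_ORDER)) / L
  denom <- 1 + 0.05 * (theta1 + theta2)
  expected <- c(as.numeric(f), 0.05 * c(theta1, theta2)) / denom
  got <- pseaac(p, lam = 2, weight = 0.05,
                scales = list(h = scale))
  expect_equal(unname(got), expected, tolerance = 1e-12)
})

test_that("CTD distribution descriptors obey the homopolymer closed form", {
  L <- 17L
  v <- ctd_distribution(strrep("K", L))
  # K is in charge class G1; its five descriptors follow the closed form
  expect_equal(unname(v[paste0("charge.G1.D", c(0, 25, 50, 75, 100))]),
               c(1, ceiling(0.25 * L), ceiling(0.5 * L),
                 ceiling(0.75 * L), L) / L)
  expect_equal(unname(v["charge.G3.D50"]), 0)
  # order sensitivity, in contrast with aac
  a <- ctd_distribution("KKKKLLLLWWWW")
  b <- ctd_distribution("KLWKLWKLWKLW")
  expect_false(isTRUE(all.equal(a, b)))
  expect_equal(aac("KKKKLLLLWWWW"), aac("KLWKLWKLWKLW"))
})

test_that("the reduced CTD subset is a projection of the full vector", {
  p <- "KWKLFKKIEKVGQNIRDGIIK"
  full <- ctd_distribution(p)
  sub <- ampep_subset(p)
  expect_equal(sub, full[names(sub)])
  alt <- ampep_subset(p, subset = names(full)[1:23])
  expect_equal(alt, full[1:23])
})

test_that("physicochemical panel has the right signs and roots", {
  expect_gt(physchem_panel("KKKKK")[["net_charge"]], 0)
  expect_lt(physchem_panel("DDDDD")[["net_charge"]], 0)
  p <- "GIGKFLHSAKKFGKAFVGEIMNS"
  pan <- physchem_panel(p)
  counts <- stats::setNames(tabulate(ampbench:::aa_indices(p), 20),
                            ampbench:::AA_ORDER)
  expect_lt(abs(ampbench:::charge_at(counts, pan[["isoelectric_point"]])),
            1e-6)
  # homopolymer moment nearly cancels; ideal amphipathic LK repeat does not
  mono <- physchem_panel(strrep("L", 18))[["hydrophobic_moment"]]
  lk <- physchem_panel(strrep("LKKLLKL", 3))[["hydrophobic_moment"]]
  expect_lt(mono, lk)
})

test_that("composite panels are projections of their parts", {
  p <- "KWKLFKKIEKVGQNIRDGIIKAG"
  pan <- physchem_panel(p)
  cs <- cs_amppred_features(p)
  expect_equal(cs, pan[names(cs)])
  am <- ampir_features(p)
  expect_equal(unname(am[23:27]),
               unname(pan[c("amphipathicity", "hydrophobicity_mean",
                            "isoelectric_point", "molecular_weight",
                            "net_charge")]))
  expect_equal(am[1:22], pseaac(p, lam = 2))
  mac <- macrel_features(p)
  # first-occurrence closed form on a homopolymer
  mono <- macrel_features(strrep("L", 10))
  expect_equal(unname(mono["fet.G1.first"]), 1 / 10)
  expect_equal(unname(mono["fet.G2.first"]), 0)
})

test_that("grey-model coefficients vanish for constant series", {
  co <- ampbench:::gm11(rep(3.7, 12))
  expect_lt(abs(co[1]), 1e-9)
  v <- mlamp_features("KWKLFKKIEKVG")
  expect_identical(v, mlamp_features("KWKLFKKIEKVG"))
  expect_error(mlamp_features("KWK"), "length")
})

test_that("PCA transform is fitted on training data only", {
  withr::with_seed(4, {
    t_line <- cbind(1:50, (1:50) * 2 + rnorm(50, sd = 1e-4))
    fit <- pca_transform(t_line, 1)
    v <- fit$rotation
    expect_gt(stats::var(fit$scores[, 1]) /
                sum(apply(scale(t_line, center = fit$center,
                                scale = fit$scale), 2, stats::var)),
              0.999)
    X <- matrix(rnorm(200), 40, 5)
    full <- pca_transform(X, 5)
    centre_proj <- pca_project(full, matrix(colMeans(X), 1))
    expect_lt(max(abs(centre_proj)), 1e-9)
    rec <- pca_project(full, X) %*% t(full$rotation)
    orig <- scale(X, center = full$center, scale = full$scale)
    expect_lt(max(abs(rec - orig)), 1e-9)
    expect_error(pca_transform(matrix(1, 10, 3)), "constant")
  })
})

test_that("extractors are pure and deterministic", {
  p <- random_peptides(1, 40, seed = 99)
  for (fun in list(aac, ctd_distribution, macrel_features, ampir_features,
                   mlamp_features, cs_amppred_features)) {
    expect_identical(fun(p), fun(p))
  }
})
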