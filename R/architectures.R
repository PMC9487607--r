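# Architecture specs bind a feature extractor, an optional selector and a
# classifier into a named, trainable unit.

#' Construct an architecture specification
#'
#' @param name Architecture name.
#' @param extractor One of `"aac"`, `"pseaac"`, `"ctd"`, `"ampep_subset"`,
#'   `"cs_amppred"`, `"macrel"`, `"ampir"`, `"mlamp"`, `"ngram"`, `"lz"`.
#' @param extractor_params Named list of extractor parameters.
#' @param selector `"none"`, `"quipt"` or `"pca"`.
#' @param selector_params Named list (e.g. `alpha`, `max_features` for
#'   QuiPT; `n_components` for PCA).
#' @param classifier `"random_forest"`, `"svm"` or `"fknn"`.
#' @param classifier_params Named list (e.g. `num_trees`; `kernel`, `cost`;
#'   `k`, `m`).
#' @param seed Integer seed used for every stochastic step of training.
#' @param trainable `FALSE` marks roster-only entries (the deep-learning
#'   stand-ins) that are registered for grid planning but not trained.
#' @return A list of class `architecture_spec`.
#' @export
architecture_spec <- function(name, extractor,
                              extractor_params = list(),
                              selector = "none",
                              selector_params = list(),
                              classifier = "random_forest",
                              classifier_params = list(),
                              seed = 1L, trainable = TRUE) {
  stopifnot(selector %in% c("none", "quipt", "pca"),
            classifier %in% c("random_forest", "svm", "fknn", "none"))
  structure(list(name = name, extractor = extractor,
                 extractor_params = extractor_params,
                 selector = selector, selector_params = selector_params,
                 classifier = classifier,
                 classifier_params = classifier_params,
                 seed = as.integer(seed), trainable = trainable),
            class = "architecture_spec")
}

#' The classical architecture roster
#'
#' The ten non-deep architectures, each the (extractor, selector,
#' classifier) triple of its published counterpart.  With
#' `include_deep = TRUE`, the two deep-learning architectures are appended
#' as non-trainable roster entries so grid planning can count the full
#' 12-architecture design.
#'
#' @param include_deep Append the two deep roster entries?
#' @param lz_reference_size Size of the SVM-LZ reference panel.
#' @param quipt_max_features Cap on the number of QuiPT-selected n-grams.
#' @return Named list of [architecture_spec()] objects.
#' @export
registry <- function(include_deep = FALSE, lz_reference_size = 1000L,
                     quipt_max_features = 5000L) {
  specs <- list(
    architecture_spec("AMAP", "aac", classifier = "svm",
                      classifier_params = list(kernel = "linear")),
    architecture_spec("AmPEP", "ampep_subset",
                      classifier = "random_forest"),
    architecture_spec("AmPEPpy", "ctd", classifier = "random_forest"),
    architecture_spec("AmpGram", "ngram", selector = "quipt",
                      selector_params = list(alpha = 0.05,
                                             max_features =
                                               quipt_max_features),
                      classifier = "random_forest"),
    architecture_spec("ampir", "ampir", classifier = "svm"),
    architecture_spec("CS-AMPPred", "cs_amppred", selector = "pca",
                      classifier = "svm"),
    architecture_spec("iAMP-2L", "pseaac",
                      extractor_params = list(lam = 20L,
                                              cap_to_length = TRUE),
                      classifier = "fknn",
                      classifier_params = list(k = 5L, m = 2)),
    architecture_spec("MACREL", "macrel", classifier = "random_forest"),
    architecture_spec("MLAMP", "mlamp", classifier = "random_forest"),
    architecture_spec("SVM-LZ", "lz",
                      extractor_params = list(n_ref =
                                                as.integer(lz_reference_size)),
                      classifier = "svm"))
  if (include_deep) {
    specs <- c(specs, list(
      architecture_spec("AMPScannerV2", "aac", classifier = "none",
                        trainable = FALSE),
      architecture_spec("Deep-AmPEP30", "aac", classifier = "none",
                        trainable = FALSE)))
  }
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

extractor_fun <- function(extractor) {
  switch(extractor,
         aac = aac,
         pseaac = pseaac,
         ctd = ctd_distribution,
         ampep_subset = ampep_subset,
         cs_amppred = cs_amppred_features,
         macrel = macrel_features,
         ampir = ampir_features,
         mlamp = mlamp_features,
         stop("unknown extractor: ", extractor))
}

# Extract features; `state` carries train-fitted artefacts (n-gram
# vocabulary, LZ reference panel).  Returns list(X, state).
extract_features <- function(spec, residues, state = NULL, y = NULL) {
  if (spec$extractor == "ngram") {
    if (is.null(state)) state <- list(vocab = build_ngram_vocabulary(residues))
    return(list(X = ngram_features(residues, state$vocab), state = state))
  }
  if (spec$extractor == "lz") {
    n_ref <- spec$extractor_params$n_ref %||% 1000L
    if (is.null(state)) {
      if (is.null(y)) stop("LZ extractor needs labels to build its panel")
      half <- n_ref %/% 2
      pick <- function(pool, n) {
        pool[sample.int(length(pool), n, replace = length(pool) < n)]
      }
      refs <- withr::with_seed(spec$seed, {
        c(pick(residues[y == 1], half), pick(residues[y == 0], n_ref - half))
      })
      state <- list(refs = refs)
    }
    return(list(X = lz_similarity_profile(residues, state$refs),
                state = state))
  }
  fast <- fast_matrix_extractors[[spec$extractor]]
  X <- if (!is.null(fast)) {
    fast(residues, spec$extractor_params)
  } else {
    do.call(feature_matrix,
            c(list(records = residues, fun = extractor_fun(spec$extractor)),
              spec$extractor_params))
  }
  list(X = X, state = state %||% list())
}

# vectorized equivalents of the per-peptide extractors (see
# features-matrix.R); row-wise equality with the per-peptide functions is
# asserted by the test suite
fast_matrix_extractors <- list(
  aac = function(res, p) aac_matrix(res),
  ctd = function(res, p) ctd_matrix(res),
  ampep_subset = function(res, p) {
    ctd_matrix(res)[, p$subset %||% AMPEP_SUBSET_DEFAULT, drop = FALSE]
  },
  cs_amppred = function(res, p) {
    panel_matrix(res)[, CS_AMPPRED_COLS, drop = FALSE]
  },
  macrel = function(res, p) macrel_matrix(res),
  ampir = function(res, p) ampir_matrix(res),
  mlamp = function(res, p) mlamp_matrix(res),
  pseaac = function(res, p) do.call(pseaac_matrix, c(list(res), p)))

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(mu = mu, sd = sd)
}

apply_scaler <- function(scaler, X) {
  scale(X, center = scaler$mu, scale = scaler$sd)
}

#' Train one architecture on a positive and a negative training sample
#'
#' Features are extracted, the selector (QuiPT with Benjamini-Hochberg
#' control, or PCA) is fitted on the training data only, and the classifier
#' is fitted with the spec's seed.  The returned model carries every piece
#' of train-fitted state needed to score new peptides.
#'
#' @param spec An [architecture_spec()].
#' @param pos_train,neg_train `amp_records` tibbles (or character vectors
#'   of sequences); both classes must be non-empty.
#' @param precomputed Optional precomputed feature matrix for
#'   `c(pos_train, neg_train)` (a performance hook used by the grid runner;
#'   only valid for extractors without train-fitted state).
#' @return A `trained_model` object.
#' @export
train <- function(spec, pos_train, neg_train, precomputed = NULL) {
  if (!spec$trainable) {
    stop("architecture ", spec$name, " is a roster-only entry")
  }
  pos <- if (is.character(pos_train)) pos_train else pos_train$residues
  neg <- if (is.character(neg_train)) neg_train else neg_train$residues
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both classes must be non-empty")
  }
  residues <- c(pos, neg)
  y <- c(rep(1L, length(pos)), rep(0L, length(neg)))

  if (is.null(precomputed)) {
    ext <- extract_features(spec, residues, y = y)
  } else {
    ext <- list(X = precomputed, state = list())
  }
  X <- ext$X
  selector_state <- NULL
  if (spec$selector == "quipt") {
    alpha <- spec$selector_params$alpha %||% 0.05
    cap <- spec$selector_params$max_features %||% 5000L
    p <- quipt_pvalues(X, y)
    padj <- stats::p.adjust(p, method = "BH")
    keep <- which(padj < alpha)
    if (length(keep) == 0) keep <- order(p)[seq_len(min(50L, length(p)))]
    if (length(keep) > cap) keep <- keep[order(p[keep])[seq_len(cap)]]
    keep <- sort(keep)
    selector_state <- list(keep = keep)
    X <- as.matrix(X[, keep, drop = FALSE])
  } else {
    X <- as.matrix(X)
  }
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  if (spec$selector == "pca") {
    n_comp <- spec$selector_params$n_components %||% NULL
    if (!is.null(n_comp) && n_comp > ncol(Xs)) {
      stop("more PCA components than features")
    }
    selector_state <- pca_transform(Xs, n_comp)
    Xs <- selector_state$scores
  }

  fit <- switch(
    spec$classifier,
    random_forest = {
      nt <- spec$classifier_params$num_trees %||% 500L
      ranger::ranger(x = Xs, y = factor(y, levels = c(0, 1)),
                     num.trees = nt, probability = TRUE,
                     seed = spec$seed, num.threads = 1, verbose = FALSE)
    },
    svm = {
      kern <- spec$classifier_params$kernel %||% "radial"
      cost <- spec$classifier_params$cost %||% 1
      e1071::svm(x = Xs, y = factor(y, levels = c(0, 1)), kernel = kern,
                 cost = cost, gamma = 1 / ncol(Xs), scale = FALSE)
    },
    fknn = {
      list(X = Xs, y = y,
           k = spec$classifier_params$k %||% 5L,
           m = spec$classifier_params$m %||% 2)
    })

  calib <- NULL
  if (spec$classifier == "svm") {
    dv <- as.numeric(attr(stats::predict(fit, Xs, decision.values = TRUE),
                          "decision.values"))
    calib <- suppressWarnings(
      stats::glm.fit(cbind(1, dv), y, family = stats::binomial())$coefficients)
    if (anyNA(calib)) calib <- c(0, 1)
  }

  structure(
    list(spec = spec, extract_state = ext$state,
         selector_state = selector_state, scaler = scaler,
         classifier_fit = fit, calib = calib,
         fingerprint = light_hash(c(spec$name, spec$seed, length(residues),
                                    utils::head(residues, 3),
                                    utils::tail(residues, 3)))),
    class = "trained_model")
}

#' Score peptides with a trained model
#'
#' Higher scores mean more AMP-like.  Random forests report the class-vote
#' fraction, SVMs a train-fitted sigmoid of the decision value, and FKNN
#' the fuzzy AMP membership.
#'
#' @param model A `trained_model`.
#' @param peptides `amp_records` tibble or character vector.
#' @param precomputed Optional precomputed feature matrix for `peptides`
#'   (see [train()]).
#' @return Numeric scores in `[0, 1]`, one per peptide.
#' @export
predict_scores <- function(model, peptides, precomputed = NULL) {
  residues <- if (is.character(peptides)) peptides else peptides$residues
  if (length(residues) == 0) return(numeric(0))
  spec <- model$spec
  X <- precomputed %||%
    extract_features(spec, residues, state = model$extract_state)$X
  if (spec$selector == "quipt") {
    X <- as.matrix(X[, model$selector_state$keep, drop = FALSE])
  } else {
    X <- as.matrix(X)
  }
  Xs <- apply_scaler(model$scaler, X)
  if (spec$selector == "pca") {
    Xs <- Xs %*% model$selector_state$rotation
  }
  switch(
    spec$classifier,
    random_forest = {
      pr <- stats::predict(model$classifier_fit, Xs,
                           num.threads = 1)$predictions
      unname(pr[, "1"])
    },
    svm = {
      dv <- as.numeric(attr(stats::predict(model$classifier_fit, Xs,
                                           decision.values = TRUE),
                            "decision.values"))
      unname(stats::plogis(model$calib[1] + model$calib[2] * dv))
    },
    fknn = {
      fknn_classify(Xs, model$classifier_fit$X, model$classifier_fit$y,
                    k = model$classifier_fit$k, m = model$classifier_fit$m)
    })
}

#' Fuzzy k-nearest-neighbour membership
#'
#' `u(q) = sum_{j in kNN} y_j d_j^(-2/(m-1)) / sum_{j in kNN}
#' d_j^(-2/(m-1))` with Euclidean distances; a query identical to a
#' training point takes that point's label.
#'
#' @param query_features Numeric matrix (queries in rows) or vector.
#' @param train_features Numeric matrix of training points.
#' @param train_labels Binary labels (0/1).
#' @param k Number of neighbours (`0 < k <=` training size).
#' @param m Fuzzifier (> 1).
#' @return Memberships in `[0, 1]`, one per query.
#' @export
fknn_classify <- function(query_features, train_features, train_labels,
                          k = 5L, m = 2) {
  if (k <= 0) stop("k must be positive")
  if (m <= 1) stop("m must exceed 1")
  Q <- if (is.null(dim(query_features))) matrix(query_features, nrow = 1)
       else as.matrix(query_features)
  Tr <- as.matrix(train_features)
  if (k > nrow(Tr)) stop("k exceeds training size")
  y <- as.numeric(train_labels)
  out <- numeric(nrow(Q))
  block <- max(1L, floor(2e7 / nrow(Tr)))
  tn2 <- rowSums(Tr^2)
  for (s in seq(1, nrow(Q), by = block)) {
    e <- min(s + block - 1L, nrow(Q))
    D2 <- outer(rowSums(Q[s:e, , drop = FALSE]^2), tn2, "+") -
      2 * Q[s:e, , drop = FALSE] %*% t(Tr)
    D2[D2 < 0] <- 0
    for (i in seq_len(e - s + 1L)) {
      d2 <- D2[i, ]
      nn <- order(d2)[seq_len(k)]
      if (d2[nn[1]] < 1e-20) {
        out[s + i - 1L] <- y[nn[1]]
      } else {
        w <- d2[nn]^(-1 / (m - 1))
        out[s + i - 1L] <- sum(w * y[nn]) / sum(w)
      }
    }
  }
  out
}

# cheap deterministic string hash (data fingerprints, derived seeds)
light_hash <- function(parts) {
  key <- paste(parts, collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Derive a stage seed from a master seed
#'
#' A stable 32-bit hash of the master seed and any number of stage labels,
#' so every stochastic stage of the pipeline gets its own reproducible
#' stream.
#'
#' @param master Integer master seed.
#' @param ... Stage labels (coerced to character).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}
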