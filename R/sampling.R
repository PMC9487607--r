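#' Declarative description of one negative-sampling method
#'
#' A sampling spec captures everything a published AMP tool did to build its
#' non-AMP set from an annotated protein database: which function keywords
#' disqualify a record, how sequence lengths are constrained (a fixed range,
#' or fragments matching the positive length distribution exactly or
#' approximately), whether redundancy is removed by identity clustering,
#' localization whitelists, cysteine-free substring extraction, screens
#' against potential/unlabelled AMPs, and the class balance.
#'
#' @param name Method name.
#' @param excluded_keywords Character vector of disqualifying keywords
#'   (case-insensitive).
#' @param length_policy One of `"equal_to_positive"`,
#'   `"similar_to_positive"`, `"range"`.
#' @param length_range Integer `c(lo, hi)` when `length_policy = "range"`.
#' @param clustering_threshold Identity threshold in (0, 1] or `NULL`.
#' @param localization_whitelist Character vector of compartments or `NULL`.
#' @param cysteine_free_substrings Extract only cysteine-free fragments?
#' @param remove_potential_amps Apply the six-keyword potential-AMP screen?
#' @param amp_similarity_screen Remove candidates sharing an exact k-mer
#'   with any positive?
#' @param balanced If `TRUE`, negative sample sizes equal the positive ones.
#' @param imbalance_ratio Target `|neg| / |pos|` when not balanced.
#'
#' @return A list of class `sampling_spec`.
#' @export
sampling_spec <- function(name,
                          excluded_keywords,
                          length_policy = c("equal_to_positive",
                                            "similar_to_positive", "range"),
                          length_range = NULL,
                          clustering_threshold = NULL,
                          localization_whitelist = NULL,
                          cysteine_free_substrings = FALSE,
                          remove_potential_amps = FALSE,
                          amp_similarity_screen = FALSE,
                          balanced = FALSE,
                          imbalance_ratio = 1) {
  length_policy <- match.arg(length_policy)
  if (length_policy == "range") {
    stopifnot(length(length_range) == 2, length_range[1] >= 1,
              length_range[1] <= length_range[2])
  }
  if (!is.null(clustering_threshold)) {
    stopifnot(clustering_threshold > 0, clustering_threshold <= 1)
  }
  structure(
    list(name = name,
         excluded_keywords = tolower(excluded_keywords),
         length_policy = length_policy,
         length_range = length_range,
         clustering_threshold = clustering_threshold,
         localization_whitelist = if (is.null(localization_whitelist)) NULL
                                  else tolower(localization_whitelist),
         cysteine_free_substrings = cysteine_free_substrings,
         remove_potential_amps = remove_potential_amps,
         amp_similarity_screen = amp_similarity_screen,
         balanced = balanced,
         imbalance_ratio = imbalance_ratio),
    class = "sampling_spec")
}

#' The eleven built-in negative-sampling methods
#'
#' One spec per published AMP tool whose negative-set construction the
#' package reimplements.  Imbalance ratios for the unbalanced methods are
#' package defaults chosen to match their qualitative descriptions
#' (slightly / moderately / highly imbalanced; negatives in the minority
#' for ampir-mature) and are configurable on the returned objects.
#'
#' @return Named list of 11 [sampling_spec()] objects.
#' @export
builtin_specs <- function() {
  specs <- list(
    sampling_spec("Wang",
                  c("secreted", "antimicrobial"),
                  "similar_to_positive",
                  clustering_threshold = 0.7,
                  imbalance_ratio = 2),
    sampling_spec("CS-AMPPred",
                  "antimicrobial",
                  "range", length_range = c(16L, 90L),
                  clustering_threshold = 0.4,
                  balanced = TRUE),
    sampling_spec("iAMP-2L",
                  c("antimicrobial", "antibiotic", "fungicide", "defensin"),
                  "range", length_range = c(5L, 100L),
                  clustering_threshold = 0.4,
                  imbalance_ratio = 2),
    sampling_spec("Gabere&Noble",
                  "antimicrobial",
                  "equal_to_positive",
                  localization_whitelist = c("golgi", "cytoplasm",
                                             "endoplasmic reticulum",
                                             "mitochondria"),
                  imbalance_ratio = 10),
    sampling_spec("AMAP",
                  "antimicrobial",
                  "similar_to_positive",
                  clustering_threshold = 0.4,
                  imbalance_ratio = 1.2),
    sampling_spec("AMPScannerV2",
                  c("antimicrobial", "antibiotic", "antiviral", "fungicide",
                    "secreted"),
                  "equal_to_positive",
                  localization_whitelist = "cytoplasm",
                  amp_similarity_screen = TRUE,
                  balanced = TRUE),
    sampling_spec("dbAMP",
                  c("transmembrane", "toxin", "secreted", "defensin",
                    "antimicrobial", "antibiotic", "antiviral", "fungicide"),
                  "range", length_range = c(10L, 100L),
                  clustering_threshold = 0.4,
                  imbalance_ratio = 1.2),
    sampling_spec("Witten&Witten",
                  c("antimicrobial", "antibiotic", "antiviral", "fungicide",
                    "secreted"),
                  "equal_to_positive",
                  clustering_threshold = 0.4,
                  localization_whitelist = "cytoplasm",
                  cysteine_free_substrings = TRUE,
                  balanced = TRUE),
    sampling_spec("AmpGram",
                  c("antimicrobial", "antibacterial", "antiviral",
                    "fungicide", "secreted", "transit peptide"),
                  "equal_to_positive",
                  balanced = TRUE),
    sampling_spec("ampir-mature",
                  "antimicrobial",
                  "range", length_range = c(10L, 40L),
                  clustering_threshold = 0.9,
                  imbalance_ratio = 0.8),
    sampling_spec("AMPlify",
                  c("antimicrobial", "antibiotic", "defence", "defensin",
                    "bacteriocin", "fungicide"),
                  "equal_to_positive",
                  remove_potential_amps = TRUE,
                  balanced = TRUE))
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Keyword exclusion filter
#'
#' Retains records whose keyword set is disjoint from `excluded`
#' (case-insensitive).
#'
#' @param db An `amp_records` tibble.
#' @param excluded Character vector of disqualifying terms.
#' @return The retained records.
#' @export
filter_by_keywords <- function(db, excluded) {
  if (length(excluded) == 0) return(db)
  excluded <- tolower(excluded)
  hit <- vapply(db$keywords, function(kw) any(kw %in% excluded), logical(1))
  db[!hit, ]
}

#' Localization whitelist filter
#'
#' Retains records whose localization set intersects the whitelist.
#'
#' @param db An `amp_records` tibble.
#' @param whitelist Non-empty character vector of compartments.
#' @return The retained records.
#' @export
filter_by_localization <- function(db, whitelist) {
  stopifnot(length(whitelist) > 0)
  whitelist <- tolower(whitelist)
  hit <- vapply(db$localization, function(lc) any(lc %in% whitelist),
                logical(1))
  db[hit, ]
}

#' Length-range filter (inclusive on both ends)
#'
#' @param db An `amp_records` tibble.
#' @param lo,hi Integer bounds, `1 <= lo <= hi`.
#' @return The retained records.
#' @export
filter_by_length_range <- function(db, lo, hi) {
  stopifnot(lo >= 1, lo <= hi)
  len <- record_lengths(db)
  db[len >= lo & len <= hi, ]
}

#' Potential-AMP screen
#'
#' Removes records carrying any of the six keywords marking potentially
#' antimicrobial entries: antimicrobial, antibiotic, defence, defensin,
#' bacteriocin, fungicide.
#'
#' @param db An `amp_records` tibble.
#' @return The retained records.
#' @export
remove_potential_amps <- function(db) {
  filter_by_keywords(db, c("antimicrobial", "antibiotic", "defence",
                           "defensin", "bacteriocin", "fungicide"))
}

#' Greedy CD-HIT-style identity clustering
#'
#' Records are sorted by decreasing length; each record joins the first
#' existing cluster whose representative it matches at `>= threshold`
#' identity, else founds a new cluster.  Identity is the number of matched
#' positions on an optimal affine-gap global alignment divided by the
#' shorter sequence length.
#'
#' @param records An `amp_records` tibble.
#' @param threshold Identity threshold in (0, 1].
#' @return The cluster representatives, in order of cluster founding.
#' @export
greedy_identity_cluster <- function(records, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  if (nrow(records) <= 1) return(records)
  ord <- order(-record_lengths(records))
  rep_idx <- greedy_cluster_cpp(records$residues[ord], threshold)
  keep_sorted <- which(rep_idx == seq_along(rep_idx))
  records[ord[keep_sorted], ]
}

#' Pairwise sequence identity used by the clustering engine
#'
#' @param a,b Character vectors of equal length; identity is computed
#'   element-wise.
#' @return Numeric vector of identities in `[0, 1]`.
#' @export
sequence_identity <- function(a, b) {
  nw_identity_cpp(as.character(a), as.character(b))
}

#' Sample a cysteine-free fragment from one sequence
#'
#' Uniformly samples a start position among all contiguous substrings of
#' `target_length` containing no cysteine; returns `NULL` if none exists.
#'
#' @param residues A single sequence string.
#' @param target_length Fragment length (>= 1).
#' @param seed Integer seed.
#' @return `list(start, fragment)` with a 0-based start, or `NULL`.
#' @export
cysteine_free_substrings <- function(residues, target_length, seed = 1L) {
  stopifnot(target_length >= 1)
  starts <- eligible_starts(residues, target_length, cysteine_free = TRUE)
  if (length(starts) == 0) return(NULL)
  start <- withr::with_seed(seed, starts[sample.int(length(starts), 1)])
  list(start = start,
       fragment = substr(residues, start + 1, start + target_length))
}

# 0-based start positions of all windows of `len`, optionally C-free
eligible_starts <- function(residues, len, cysteine_free = FALSE) {
  n <- nchar(residues)
  if (len > n) return(integer())
  starts <- 0:(n - len)
  if (!cysteine_free) return(starts)
  isC <- as.integer(strsplit(residues, "")[[1]] == "C")
  cs <- c(0L, cumsum(isC))
  starts[cs[starts + 1 + len] - cs[starts + 1] == 0]
}

#' Screen candidates against the positive set by shared exact k-mers
#'
#' A deterministic stand-in for a BLAT similarity search: any candidate
#' sharing a contiguous k-mer (default k = 10) with a positive sequence, or
#' equal to one, is removed.
#'
#' @param candidates,positives `amp_records` tibbles.
#' @param k Shared k-mer length.
#' @return The surviving candidates.
#' @export
amp_similarity_screen <- function(candidates, positives, k = 10L) {
  if (nrow(candidates) == 0) return(candidates)
  hit <- shares_kmer_cpp(candidates$residues, positives$residues,
                         as.integer(k)) |
    candidates$residues %in% positives$residues
  candidates[!hit, ]
}

# --- fragment sampling -----------------------------------------------------

frag_key <- function(parent, start, end) paste(parent, start, end, sep = ":")

# Sample one fragment per requested length (with multiplicity).  For each
# length L a database record of length >= L is drawn uniformly, then a
# uniform eligible window.  Returns an amp_records tibble with provenance
# columns parent_id / frag_start / frag_end (0-based, half-open).  `used`
# is an environment collecting fragment keys so repeated calls never emit
# the same fragment twice.
sample_fragments <- function(db, lengths, seed, cysteine_free = FALSE,
                             used = new.env(), id_prefix = "NEG",
                             reject = NULL, max_tries = 200L) {
  n <- length(lengths)
  db_len <- record_lengths(db)
  ord <- order(db_len)
  sorted_len <- db_len[ord]
  out_parent <- character(n)
  out_start <- integer(n)
  out_res <- character(n)
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      L <- lengths[i]
      lo <- findInterval(L - 1L, sorted_len) + 1L   # first index with len >= L
      if (lo > length(sorted_len)) {
        stop("no database record of length >= ", L)
      }
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        j <- ord[lo + sample.int(length(sorted_len) - lo + 1L, 1L) - 1L]
        starts <- eligible_starts(db$residues[j], L, cysteine_free)
        if (length(starts) == 0) next
        start <- starts[sample.int(length(starts), 1L)]
        key <- frag_key(db$id[j], start, start + L)
        if (!is.null(used[[key]])) next
        frag <- substr(db$residues[j], start + 1, start + L)
        if (!is.null(reject) && reject(frag)) next
        used[[key]] <- TRUE
        out_parent[i] <- db$id[j]
        out_start[i] <- start
        out_res[i] <- frag
        ok <- TRUE
        break
      }
      if (!ok) {
        stop("could not sample an admissible fragment of length ", L,
             " after ", max_tries, " tries")
      }
    }
  })
  out <- amp_records(sprintf("%s_%05d", id_prefix, seq_len(n)), out_res,
                     source = "negative_pool")
  out$parent_id <- out_parent
  out$frag_start <- out_start
  out$frag_end <- out_start + lengths
  out
}

#' Sample negative fragments matching the positive length multiset exactly
#'
#' For each positive length L (with multiplicity) one contiguous fragment
#' of length exactly L is cut from a uniformly chosen database record of
#' sufficient length, at a uniform start.  Fragment provenance (parent id,
#' 0-based half-open coordinates) is recorded.
#'
#' @param db An `amp_records` tibble (already filtered).
#' @param positive_lengths Integer multiset of required lengths.
#' @param seed Integer seed.
#' @param cysteine_free Restrict to cysteine-free windows?
#' @return An `amp_records` tibble with provenance columns; its length
#'   multiset equals `positive_lengths`.
#' @export
sample_lengths_equal <- function(db, positive_lengths, seed,
                                 cysteine_free = FALSE) {
  sample_fragments(db, positive_lengths, seed, cysteine_free = cysteine_free)
}

#' Sample negative fragments with approximately the positive length law
#'
#' Equal-length fragment sampling followed by greedy identity clustering;
#' the clustering may remove members, so only an approximate distribution
#' match is guaranteed (this is exactly how the "similar" methods end up
#' slightly imbalanced).
#'
#' @inheritParams sample_lengths_equal
#' @param threshold Identity threshold, or `NULL` to skip clustering (in
#'   which case the call degenerates to [sample_lengths_equal()]).
#' @return An `amp_records` tibble with provenance columns.
#' @export
sample_lengths_similar <- function(db, positive_lengths, seed,
                                   threshold = NULL) {
  frags <- sample_lengths_equal(db, positive_lengths, seed)
  if (is.null(threshold)) return(frags)
  greedy_identity_cluster(frags, threshold)
}

# Expand a positive length multiset to ratio * n lengths (seeded)
expand_lengths <- function(lengths, ratio, seed) {
  n_target <- round(ratio * length(lengths))
  base <- rep(lengths, floor(ratio))
  extra <- n_target - length(base)
  if (extra > 0) {
    base <- c(base, withr::with_seed(seed, sample(lengths, extra,
                                                  replace = TRUE)))
  } else if (extra < 0) {
    base <- withr::with_seed(seed, sample(base, n_target))
  }
  base
}

#' Assemble replicated negative samples for one sampling method
#'
#' Applies the spec's stages in a fixed order: keyword filter, localization
#' filter, potential-AMP screen, length policy (range filter or fragment
#' sampling against the positive train/bench length multisets), cysteine
#' rule, identity clustering, positive-similarity screen, positive-overlap
#' removal, size targeting and the train/bench partition.  Train negatives
#' are sampled against the positive training lengths and bench negatives
#' against the positive benchmark lengths, so the two are disjoint by
#' construction; every stage's record count is logged on the result.
#'
#' @param spec A [sampling_spec()].
#' @param db The annotated background database (`amp_records`).
#' @param split A [split_positive()] result.
#' @param n_replicates Number of independent replicates (default 5).
#' @param seed Master seed; each replicate derives its own seed.
#' @param oversample Safety factor for stages that discard candidates.
#' @return List of `replicated_dataset` objects (length `n_replicates`),
#'   each with `neg_train`, `neg_bench`, `pos_train`, `pos_bench`,
#'   `spec_name`, `replicate`, `stage_counts`.
#' @export
assemble_negative_sample <- function(spec, db, split, n_replicates = 5L,
                                     seed = 1L, oversample = 1.3) {
  stopifnot(inherits(spec, "sampling_spec"), inherits(split, "positive_split"))
  lapply(seq_len(n_replicates), function(r) {
    assemble_one_replicate(spec, db, split, r,
                           derive_seed(seed, spec$name, r), oversample)
  })
}

assemble_one_replicate <- function(spec, db, split, replicate, seed,
                                   oversample = 1.3) {
  counts <- c(input = nrow(db))
  pool <- filter_by_keywords(db, spec$excluded_keywords)
  counts["keyword_filter"] <- nrow(pool)
  if (nrow(pool) == 0) stop(spec$name, ": empty after keyword filter")
  if (!is.null(spec$localization_whitelist)) {
    pool <- filter_by_localization(pool, spec$localization_whitelist)
    counts["localization_filter"] <- nrow(pool)
    if (nrow(pool) == 0) stop(spec$name, ": empty after localization filter")
  }
  if (spec$remove_potential_amps) {
    pool <- remove_potential_amps(pool)
    counts["potential_amp_screen"] <- nrow(pool)
    if (nrow(pool) == 0) stop(spec$name, ": empty after potential-AMP screen")
  }

  positives_all <- dplyr::bind_rows(split$train, split$bench)
  ratio <- if (spec$balanced) 1 else spec$imbalance_ratio

  if (spec$length_policy == "range") {
    sets <- assemble_range(spec, pool, split, ratio, seed, oversample,
                           positives_all)
  } else {
    sets <- assemble_fragments(spec, pool, split, ratio, seed,
                               positives_all)
  }
  counts <- c(counts, sets$counts)

  structure(
    list(spec_name = spec$name, replicate = replicate,
         neg_train = sets$train, neg_bench = sets$bench,
         pos_train = split$train, pos_bench = split$bench,
         stage_counts = counts, seed = seed),
    class = "replicated_dataset")
}

# Range length policy: whole records, clustered on a seeded pre-subsample
# of the filtered pool, then sized and partitioned 80/20-style by the
# positive train/bench sizes.
assemble_range <- function(spec, pool, split, ratio, seed, oversample,
                           positives_all) {
  counts <- integer()
  pool <- filter_by_length_range(pool, spec$length_range[1],
                                 spec$length_range[2])
  counts["length_filter"] <- nrow(pool)
  if (nrow(pool) == 0) stop(spec$name, ": empty after length filter")

  n_train <- round(ratio * nrow(split$train))
  n_bench <- round(ratio * nrow(split$bench))
  target <- n_train + n_bench

  take <- min(nrow(pool), ceiling(oversample * target))
  repeat {
    idx <- withr::with_seed(seed, sample.int(nrow(pool), take))
    cand <- pool[idx, ]
    if (!is.null(spec$clustering_threshold)) {
      cand <- greedy_identity_cluster(cand, spec$clustering_threshold)
    }
    if (spec$amp_similarity_screen) {
      cand <- amp_similarity_screen(cand, positives_all)
    }
    cand <- cand[!(cand$residues %in% positives_all$residues), ]
    if (nrow(cand) >= target || take == nrow(pool)) break
    take <- min(nrow(pool), take * 2L)
  }
  counts["after_clustering"] <- nrow(cand)
  if (nrow(cand) < target) {
    stop(spec$name, ": target negative sample of ", target,
         " unreachable; at most ", nrow(cand), " records available")
  }
  pick <- withr::with_seed(offset_seed(seed, 1L),
                           sample.int(nrow(cand), target))
  counts["sized"] <- target
  list(train = cand[pick[seq_len(n_train)], ],
       bench = cand[pick[n_train + seq_len(n_bench)], ],
       counts = counts)
}

# Positive-driven length policies: fragments against the positive train and
# bench length multisets (hence disjoint by construction), with screening,
# optional clustering, and refilling so "equal" specs match the length
# multiset exactly.
assemble_fragments <- function(spec, pool, split, ratio, seed,
                               positives_all) {
  counts <- integer()
  cfree <- spec$cysteine_free_substrings
  used <- new.env()
  pos_res <- positives_all$residues
  pos_kmers <- if (spec$amp_similarity_screen) all_kmers(pos_res, 10L)
               else character()
  reject <- function(frag) {
    if (frag %in% pos_res) return(TRUE)
    if (spec$amp_similarity_screen &&
        any(all_kmers(frag, 10L) %in% pos_kmers)) {
      return(TRUE)
    }
    FALSE
  }

  make_set <- function(pos_records, which, seed_offset) {
    lengths <- expand_lengths(record_lengths(pos_records), ratio,
                              offset_seed(seed, seed_offset))
    if (spec$length_policy == "similar_to_positive") {
      lengths <- expand_lengths(lengths, 1.5,
                                offset_seed(seed, seed_offset + 1L))
    }
    frags <- sample_fragments(pool, lengths,
                              offset_seed(seed, seed_offset + 2L),
                              cysteine_free = cfree, used = used,
                              id_prefix = paste0("NEG_", which),
                              reject = reject)
    if (spec$length_policy == "similar_to_positive") {
      if (!is.null(spec$clustering_threshold)) {
        frags <- greedy_identity_cluster(frags, spec$clustering_threshold)
      }
      n_target <- round(ratio * nrow(pos_records))
      if (nrow(frags) > n_target) {
        keep <- withr::with_seed(offset_seed(seed, seed_offset + 3L),
                                 sample.int(nrow(frags), n_target))
        frags <- frags[sort(keep), ]
      }
      frags$id <- sprintf("NEG_%s_%05d", which, seq_len(nrow(frags)))
      return(frags)
    }
    # equal policy: enforce the exact multiset under clustering by
    # refilling removed slots with fragments that stay below the threshold
    if (!is.null(spec$clustering_threshold)) {
      kept <- greedy_identity_cluster(frags, spec$clustering_threshold)
      missing <- table_diff(lengths, record_lengths(kept))
      round_i <- 0L
      while (length(missing) > 0 && round_i < 60L) {
        round_i <- round_i + 1L
        fresh <- sample_fragments(pool, missing,
                                  offset_seed(seed,
                                              seed_offset + 10L + round_i),
                                  cysteine_free = cfree, used = used,
                                  id_prefix = paste0("NEG_", which, "_f",
                                                     round_i),
                                  reject = reject)
        ok <- !identity_vs_set_cpp(fresh$residues, kept$residues,
                                   spec$clustering_threshold)
        kept <- rbind(kept, fresh[ok, ])
        missing <- table_diff(lengths, record_lengths(kept))
      }
      if (length(missing) > 0) {
        stop(spec$name, ": could not refill ", length(missing),
             " fragments below the identity threshold")
      }
      frags <- kept
    }
    frags$id <- sprintf("NEG_%s_%05d", which, seq_len(nrow(frags)))
    frags
  }

  train <- make_set(split$train, "train", 0L)
  bench <- make_set(split$bench, "bench", 1000L)
  counts["neg_train"] <- nrow(train)
  counts["neg_bench"] <- nrow(bench)
  list(train = train, bench = bench, counts = counts)
}

# keep derived seeds inside the 32-bit integer range
offset_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + as.numeric(k)) %% 2147483647)
}

# all contiguous k-mers of a character vector of sequences
all_kmers <- function(seqs, k) {
  out <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1), k:n)
  })
  unique(unlist(out))
}

# multiset difference: elements of `want` not covered by `have`
table_diff <- function(want, have) {
  tw <- table(want)
  th <- table(have)
  out <- integer()
  for (nm in names(tw)) {
    deficit <- tw[[nm]] - if (nm %in% names(th)) th[[nm]] else 0L
    if (deficit > 0) out <- c(out, rep(as.integer(nm), deficit))
  }
  out
}

#' Write one replicated dataset to disk
#'
#' Emits per-replicate FASTA pairs (train/bench x pos/neg) plus a
#' provenance TSV (fragment parent and coordinates where applicable) and a
#' stage-count table.
#'
#' @param dataset A `replicated_dataset`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_replicate <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$pos_train, file.path(dir, "pos_train.fasta"))
  write_fasta(dataset$pos_bench, file.path(dir, "pos_bench.fasta"))
  write_fasta(dataset$neg_train, file.path(dir, "neg_train.fasta"))
  write_fasta(dataset$neg_bench, file.path(dir, "neg_bench.fasta"))
  prov <- function(x, set) {
    if (is.null(x$parent_id)) {
      data.frame(id = x$id, set = set, parent_id = NA, start = NA, end = NA)
    } else {
      data.frame(id = x$id, set = set, parent_id = x$parent_id,
                 start = x$frag_start, end = x$frag_end)
    }
  }
  utils::write.table(rbind(prov(dataset$neg_train, "train"),
                           prov(dataset$neg_bench, "bench")),
                     file.path(dir, "provenance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(stage = names(dataset$stage_counts),
                                count = as.integer(dataset$stage_counts)),
                     file.path(dir, "stage_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
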