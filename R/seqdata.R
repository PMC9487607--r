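#' Construct a table of annotated sequence records
#'
#' The central data container of the package: one row per peptide/protein
#' with its identifier, residues (upper-case, 20-letter alphabet), keyword
#' and subcellular-localization annotation sets, and its origin
#' (`"positive"` for AMPs, `"negative_pool"` for background database
#' entries).
#'
#' @param id Character vector of unique identifiers.
#' @param residues Character vector of sequences over the standard 20
#'   amino-acid alphabet (upper-cased on construction).
#' @param keywords Optional list of character vectors of annotation terms
#'   (lower-cased; empty sets allowed).
#' @param localization Optional list of character vectors of compartment
#'   terms (lower-cased; empty sets allowed).
#' @param source `"positive"` or `"negative_pool"`.
#'
#' @return A tibble of class `amp_records` with columns `id`, `residues`,
#'   `keywords`, `localization`, `source`.
#' @export
amp_records <- function(id, residues, keywords = NULL, localization = NULL,
                        source = "negative_pool") {
  n <- length(id)
  stopifnot(length(residues) == n)
  if (is.null(keywords)) keywords <- rep(list(character()), n)
  if (is.null(localization)) localization <- rep(list(character()), n)
  source <- rep_len(source, n)
  if (!all(source %in% c("positive", "negative_pool"))) {
    stop("source must be 'positive' or 'negative_pool'")
  }
  if (anyDuplicated(id)) stop("record ids must be unique")
  residues <- toupper(residues)
  bad <- !valid_residues(residues)
  if (any(bad)) {
    stop("records with empty or non-standard residues: ",
         paste(utils::head(id[bad], 5), collapse = ", "))
  }
  tibble::new_tibble(
    list(id = as.character(id), residues = residues,
         keywords = lapply(keywords, function(x) tolower(as.character(x))),
         localization = lapply(localization,
                               function(x) tolower(as.character(x))),
         source = source),
    class = "amp_records")
}

valid_residues <- function(residues) {
  nzchar(residues) & !grepl(paste0("[^", AA_STRING, "]"), residues)
}

record_lengths <- function(records) nchar(records$residues)

#' Read sequence records from a FASTA file
#'
#' Identifiers are taken from the header up to the first whitespace and
#' residues are upper-cased.  Records containing characters outside the
#' standard 20-letter alphabet are dropped with a warning; the number of
#' dropped records is attached as attribute `n_dropped`.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @param source Origin label for the records (see [amp_records()]).
#' @return An `amp_records` tibble, in file order.
#' @export
read_fasta <- function(path, source = "negative_pool") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  meaningful <- which(nzchar(trimws(lines)))
  if (length(meaningful) == 0) {
    out <- amp_records(character(), character(), source = character())
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  first <- meaningful[1]
  if (!startsWith(lines[first], ">")) {
    stop("malformed FASTA header at line ", first, ": expected '>'")
  }
  empty_header <- meaningful[startsWith(lines[meaningful], ">") &
                               !nzchar(sub("^>\\s*", "", lines[meaningful]))]
  if (length(empty_header)) {
    stop("malformed FASTA header at line ", empty_header[1], ": empty id")
  }
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicated FASTA ids: ",
         paste(unique(ids[duplicated(ids)])[1:3], collapse = ", "))
  }
  residues <- unname(toupper(as.character(seqs)))
  keep <- valid_residues(residues)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warning(n_dropped, " record(s) with non-standard residues dropped")
  }
  out <- amp_records(ids[keep], residues[keep], source = source)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write sequence records to a FASTA file
#'
#' @param records An `amp_records` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = 20001L)
  invisible(path)
}

#' Attach keyword/localization annotations from a TSV table
#'
#' The table must have a header `id<TAB>keywords<TAB>localization`, with
#' multi-valued fields joined by semicolons.  Records whose id is absent
#' from the table keep empty annotation sets.
#'
#' @param path Path to the annotation TSV.
#' @param records An `amp_records` tibble.
#' @return `records` with `keywords` and `localization` filled in.
#' @export
read_annotations <- function(path, records) {
  tab <- utils::read.delim(path, colClasses = "character",
                           na.strings = NULL, quote = "")
  if (!all(c("id", "keywords", "localization") %in% names(tab))) {
    stop("annotation table must have columns id, keywords, localization")
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicated id rows in annotation table: ",
         tab$id[duplicated(tab$id)][1])
  }
  unknown <- setdiff(tab$id, records$id)
  if (length(unknown)) {
    warning(length(unknown), " annotation id(s) not present in records")
  }
  split_terms <- function(x) {
    parts <- strsplit(x, ";", fixed = TRUE)[[1]]
    tolower(trimws(parts[nzchar(trimws(parts))]))
  }
  idx <- match(records$id, tab$id)
  records$keywords <- lapply(seq_along(idx), function(i) {
    if (is.na(idx[i])) character() else split_terms(tab$keywords[idx[i]])
  })
  records$localization <- lapply(seq_along(idx), function(i) {
    if (is.na(idx[i])) character() else split_terms(tab$localization[idx[i]])
  })
  records
}

#' Write the annotation table read by [read_annotations()]
#'
#' @param records An `amp_records` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path) {
  join <- function(x) vapply(x, paste, "", collapse = ";")
  tab <- data.frame(id = records$id,
                    keywords = join(records$keywords),
                    localization = join(records$localization))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Split the positive set into training and benchmark samples
#'
#' A uniform random partition without replacement, made before any negative
#' sampling so that no benchmark information can reach training.  The
#' training size is `floor(fraction * n + 0.5)`.
#'
#' @param records Positive `amp_records` (at least 2 rows).
#' @param fraction Training proportion in (0, 1); default 0.8.
#' @param seed Integer seed; the same seed always yields the same split.
#' @return A list of class `positive_split` with elements `train`, `bench`,
#'   `split_fraction`, `seed`.
#' @export
split_positive <- function(records, fraction = 0.8, seed = 1L) {
  n <- nrow(records)
  if (n < 2) stop("need at least 2 records to split")
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  n_train <- floor(fraction * n + 0.5)
  n_train <- max(1L, min(n - 1L, as.integer(n_train)))
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  structure(
    list(train = records[sort(idx), ], bench = records[-sort(idx), ],
         split_fraction = fraction, seed = as.integer(seed)),
    class = "positive_split")
}

#' Remove redundant positives by greedy identity clustering
#'
#' Delegates to [greedy_identity_cluster()] (the shared CD-HIT-style
#' implementation) and keeps one representative per cluster.
#'
#' @param records An `amp_records` tibble.
#' @param threshold Identity threshold in (0, 1]; default 0.9.
#' @return The surviving representatives, an `amp_records` tibble.
#' @export
reduce_redundancy_positive <- function(records, threshold = 0.9) {
  greedy_identity_cluster(records, threshold)
}
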