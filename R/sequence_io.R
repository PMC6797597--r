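#' Read a FASTA file of DNA sequences
#'
#' Reads a multi-record FASTA file into a data frame of sequence records.
#' Sequences are uppercased; the text after each \code{">"} becomes the record
#' id. Records are returned in file order.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with character columns \code{id} and \code{seq}, one
#'   row per FASTA record.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "gtatAT", ">s2", "GCCTAA"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop_validation("'path' must be a single file path")
  }
  if (!file.exists(path)) {
    stop_validation(sprintf("FASTA file not found: '%s'", path))
  }
  # Biostrings accepts some malformed layouts silently and reports others
  # without positions; pre-scan for the one hard error we promise to locate.
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    stop_validation(sprintf("FASTA file '%s' is empty", path))
  }
  first <- nonempty[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop_validation(sprintf(
      "malformed FASTA in '%s': sequence data before any header at line %d", path, first))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop_validation(sprintf("FASTA file '%s' contains no records", path))
  }
  ids <- names(set)
  if (is.null(ids)) ids <- rep("", length(set))
  data.frame(
    id = as.character(ids),
    seq = toupper(as.character(set)),
    stringsAsFactors = FALSE
  )
}

validate_records <- function(records, window_length, what = "sequence") {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  len_ok <- nchar(records$seq) == window_length
  alpha_ok <- !grepl("[^ACGT]", records$seq)
  bad <- !(len_ok & alpha_ok)
  if (any(bad)) {
    labels <- ifelse(nzchar(records$id), records$id, sprintf("record %d", seq_len(nrow(records))))
    why <- ifelse(!len_ok, sprintf("length %d != %d", nchar(records$seq), window_length),
                  "non-ACGT characters")
    stop_validation(sprintf(
      "%d invalid %s(s): %s", sum(bad), what,
      paste(sprintf("%s (%s)", labels[bad], why[bad]), collapse = "; ")))
  }
  invisible(records)
}

new_labeled_dataset <- function(id, seq, label, window_length) {
  structure(
    list(id = as.character(id), seq = as.character(seq),
         label = as.integer(label), window_length = as.integer(window_length)),
    class = "labeled_dataset")
}

#' Load a positive/negative benchmark FASTA pair
#'
#' Builds a labeled dataset from two FASTA files in the layout used by the
#' 6mA benchmark collections: one file of positive windows (the center base
#' is a methylated adenine, label 1) and one of negative windows (label 0).
#' Positives come first, in file order, then negatives. Every sequence must
#' have exactly \code{window_length} bases over \code{A,C,G,T}; ambiguity
#' codes such as \code{N} are rejected rather than imputed, because both
#' encodings are defined on the four-letter alphabet only.
#'
#' @param pos_path FASTA file of positive (6mA-centered) sequences.
#' @param neg_path FASTA file of negative sequences.
#' @param window_length Required sequence length in bp (default 41).
#' @return A \code{labeled_dataset}: a list with elements \code{id},
#'   \code{seq}, \code{label} (1 = positive) and \code{window_length}.
#' @seealso [read_fasta()], [load_manifest()], [write_benchmark_fixture()]
#' @export
load_benchmark <- function(pos_path, neg_path, window_length = 41) {
  window_length <- check_count(window_length, "window_length", min = 1)
  pos <- read_fasta(pos_path)
  neg <- read_fasta(neg_path)
  validate_records(pos, window_length, "positive sequence")
  validate_records(neg, window_length, "negative sequence")
  new_labeled_dataset(
    id = c(pos$id, neg$id),
    seq = c(pos$seq, neg$seq),
    label = c(rep(1L, nrow(pos)), rep(0L, nrow(neg))),
    window_length = window_length)
}

#' Load a dataset from a two-column manifest
#'
#' Alternative to [load_benchmark()]: a tab-separated manifest with columns
#' \code{path} and \code{label} lists any number of FASTA files, each
#' contributing all of its records with the given label (1 = positive,
#' 0 = negative). Files are read in manifest order.
#'
#' @param manifest_path Path to a TSV file with columns \code{path, label}.
#'   Relative paths are resolved against the manifest's directory.
#' @param window_length Required sequence length in bp (default 41).
#' @return A \code{labeled_dataset}.
#' @export
load_manifest <- function(manifest_path, window_length = 41) {
  window_length <- check_count(window_length, "window_length", min = 1)
  if (!file.exists(manifest_path)) {
    stop_validation(sprintf("manifest not found: '%s'", manifest_path))
  }
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(man))) {
    stop_validation("manifest must have columns 'path' and 'label'")
  }
  if (!all(man$label %in% c(0L, 1L))) {
    stop_validation("manifest labels must be 0 or 1")
  }
  base <- dirname(manifest_path)
  ids <- character(0); seqs <- character(0); labels <- integer(0)
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    rec <- read_fasta(p)
    validate_records(rec, window_length)
    ids <- c(ids, rec$id); seqs <- c(seqs, rec$seq)
    labels <- c(labels, rep(as.integer(man$label[i]), nrow(rec)))
  }
  new_labeled_dataset(ids, seqs, labels, window_length)
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labeled DNA dataset: %d sequences of %d bp (%d positive, %d negative)\n",
              length(x$seq), x$window_length, sum(x$label == 1L), sum(x$label == 0L)))
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) length(x$seq)

#' Subset a labeled dataset by index
#'
#' @param x A \code{labeled_dataset}.
#' @param i Integer or logical index over records.
#' @param ... Ignored.
#' @return A \code{labeled_dataset} with the selected records.
#' @export
`[.labeled_dataset` <- function(x, i, ...) {
  new_labeled_dataset(x$id[i], x$seq[i], x$label[i], x$window_length)
}

#' Write a labeled dataset as a positive/negative FASTA pair
#'
#' Emits the same two-file benchmark layout that [load_benchmark()] consumes,
#' so generated fixtures round-trip exactly.
#'
#' @param dataset A \code{labeled_dataset} containing both classes.
#' @param dir Output directory (created if missing).
#' @param basename Stem for the two files, written as
#'   \code{<basename>_pos.fa} and \code{<basename>_neg.fa}.
#' @return Invisibly, a named character vector with elements \code{pos} and
#'   \code{neg} giving the written paths.
#' @export
write_benchmark_fixture <- function(dataset, dir, basename = "benchmark") {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (!any(dataset$label == 1L) || !any(dataset$label == 0L)) {
    stop_validation("benchmark fixture requires at least one positive and one negative sequence")
  }
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory '%s'", dir))
  }
  paths <- c(pos = file.path(dir, paste0(basename, "_pos.fa")),
             neg = file.path(dir, paste0(basename, "_neg.fa")))
  for (cls in c("pos", "neg")) {
    keep <- dataset$label == (if (cls == "pos") 1L else 0L)
    set <- Biostrings::DNAStringSet(dataset$seq[keep])
    names(set) <- dataset$id[keep]
    Biostrings::writeXStringSet(set, filepath = paths[[cls]], width = 80L)
  }
  invisible(paths)
}
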