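# Both encodings map a sequence to a 4-row x L-column matrix, one column per
# position, rows ordered (A, T, C, G) for the one-hot scheme and
# (purine, weak-bond, amino, cumulative frequency) for the feature scheme.

BASES <- c("A", "T", "C", "G")

# one-hot indicator columns: A=(1,0,0,0), T=(0,1,0,0), C=(0,0,1,0), G=(0,0,0,1)
ONEHOT_TABLE <- diag(4)
dimnames(ONEHOT_TABLE) <- list(BASES, BASES)

# chemical-property triads, rows = (purine, weak hydrogen bond, amino group):
# A=(1,1,1), T=(0,1,0), C=(0,0,1), G=(1,0,0)
TRIAD_TABLE <- matrix(
  c(1, 1, 1,
    0, 1, 0,
    0, 0, 1,
    1, 0, 0),
  nrow = 3, dimnames = list(c("purine", "weak_bond", "amino"), BASES))

split_bases <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop_validation(sprintf("%s must be a single non-empty string", what))
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% BASES)
  if (length(bad) > 0L) {
    stop_validation(sprintf("%s contains non-ACGT character '%s' at position %d",
                            what, chars[bad[1L]], bad[1L]))
  }
  chars
}

#' One-hot encode a DNA sequence
#'
#' Encodes each base as a 4-element indicator vector with row order
#' \code{A, T, C, G}: A maps to (1,0,0,0), T to (0,1,0,0), C to (0,0,1,0)
#' and G to (0,0,0,1). A sequence of length L becomes a 4 x L matrix whose
#' column i describes position i.
#'
#' @param seq A DNA string over \code{A,C,G,T} (already uppercased).
#' @return A 4 x \code{nchar(seq)} numeric matrix; every column sums to 1.
#' @examples
#' one_hot_encode("ACGT")
#' @export
one_hot_encode <- function(seq) {
  chars <- split_bases(seq)
  m <- ONEHOT_TABLE[, chars, drop = FALSE]
  dimnames(m) <- list(BASES, NULL)
  m
}

#' Chemical-property triad of a DNA base
#'
#' Encodes a base by three binary chemical properties: ring structure
#' (1 = purine: A, G), hydrogen-bond strength (1 = weak pairing: A, T) and
#' functional group (1 = amino: A, C). Thus A = (1,1,1), T = (0,1,0),
#' C = (0,0,1), G = (1,0,0).
#'
#' @param base A single base, one of \code{"A"}, \code{"T"}, \code{"C"},
#'   \code{"G"}.
#' @return A named numeric vector of length 3
#'   (\code{purine}, \code{weak_bond}, \code{amino}).
#' @export
chemical_triad <- function(base) {
  if (!is.character(base) || length(base) != 1L || !base %in% BASES) {
    stop_validation(sprintf("'base' must be one of A, T, C, G (got %s)", deparse(base)))
  }
  TRIAD_TABLE[, base]
}

#' Cumulative nucleotide frequency profile
#'
#' For each position i, the fraction of positions 1..i that carry the same
#' base as position i (the cumulative nucleotide density of Chen et al.'s
#' feature encoding). Element 1 is always 1 and every element lies in (0, 1].
#'
#' @param seq A DNA string over \code{A,C,G,T}.
#' @return A numeric vector of length \code{nchar(seq)}.
#' @examples
#' cumulative_frequency("TATA")  # 1, 1/2, 2/3, 2/4
#' @export
cumulative_frequency <- function(seq) {
  chars <- split_bases(seq)
  counts <- sapply(BASES, function(b) cumsum(chars == b))
  if (length(chars) == 1L) counts <- matrix(counts, nrow = 1, dimnames = list(NULL, BASES))
  counts[cbind(seq_along(chars), match(chars, BASES))] / seq_along(chars)
}

#' Feature-encode a DNA sequence (chemical properties + frequency)
#'
#' Column i is the chemical-property triad of the base at position i
#' (see [chemical_triad()]) with the cumulative nucleotide frequency at i
#' (see [cumulative_frequency()]) appended as the fourth row. The result has
#' the same 4 x L shape as the one-hot encoding, so the same network
#' architecture consumes either scheme.
#'
#' @param seq A DNA string over \code{A,C,G,T}.
#' @return A 4 x \code{nchar(seq)} numeric matrix with rows
#'   \code{purine, weak_bond, amino, frequency}.
#' @examples
#' feature_encode("AT")  # columns (1,1,1,1) and (0,1,0,0.5)
#' @export
feature_encode <- function(seq) {
  chars <- split_bases(seq)
  m <- rbind(TRIAD_TABLE[, chars, drop = FALSE],
             frequency = cumulative_frequency(seq))
  dimnames(m) <- list(c("purine", "weak_bond", "amino", "frequency"), NULL)
  m
}

#' Encode every sequence of a labeled dataset
#'
#' Applies the chosen encoding scheme to each record, preserving order, and
#' stacks the per-sequence 4 x L matrices into a 3-D array.
#'
#' @param dataset A \code{labeled_dataset} (see [load_benchmark()]).
#' @param scheme \code{"onehot"} or \code{"feature"}.
#' @return A list with elements \code{x} (array of dim
#'   \code{c(4, window_length, n)}), \code{labels} (integer vector of length
#'   n) and \code{scheme}.
#' @export
encode_batch <- function(dataset, scheme = c("onehot", "feature")) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  scheme <- match.arg(scheme)
  n <- length(dataset$seq)
  L <- dataset$window_length
  x <- array(0, dim = c(4L, L, n))
  enc <- if (scheme == "onehot") one_hot_encode else feature_encode
  for (i in seq_len(n)) x[, , i] <- enc(dataset$seq[i])
  list(x = x, labels = dataset$label, scheme = scheme)
}

#' Export an encoded sequence as a TSV table for inspection
#'
#' Writes one row per position: the position, the base, and the four encoded
#' values under the chosen scheme.
#'
#' @param seq A DNA string over \code{A,C,G,T}.
#' @param path Output TSV path.
#' @param scheme \code{"onehot"} or \code{"feature"}.
#' @return Invisibly, the data frame that was written.
#' @export
write_encoding_tsv <- function(seq, path, scheme = c("onehot", "feature")) {
  scheme <- match.arg(scheme)
  m <- if (scheme == "onehot") one_hot_encode(seq) else feature_encode(seq)
  df <- data.frame(position = seq_len(ncol(m)),
                   base = strsplit(seq, "", fixed = TRUE)[[1L]],
                   t(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
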