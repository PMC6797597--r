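#' Generate a benchmark-shaped synthetic 6mA dataset
#'
#' Produces a balanced-by-construction labeled dataset with the geometry of
#' the rice 6mA benchmarks: fixed-length windows (default 41 bp) over
#' \code{A,C,G,T}, a positive and a negative class, and — when
#' \code{center_base_rule} is on — an adenine at the central position of
#' every window in \emph{both} classes, mirroring the real benchmarks whose
#' negatives are unmethylated adenine-centered windows. Class structure is
#' purely statistical: positives carry a short motif planted at a fixed
#' offset near the center with probability \code{planting_probability};
#' \code{planting_probability = 0} makes the two class distributions
#' identical (a null dataset).
#'
#' @param n_pos,n_neg Number of positive and negative windows.
#' @param window_length Window length in bp (default 41; must be odd so a
#'   central base exists when \code{center_base_rule} is on).
#' @param motif Short DNA string planted in positives (default
#'   \code{"GAGG"}).
#' @param motif_offset 1-based start position of the planted motif, or
#'   \code{"near_center"} for the default placement two positions right of
#'   the central base (so the classifier must learn local context, not just
#'   the center).
#' @param planting_probability Probability that a positive window receives
#'   the motif (default 1); the class-separability knob.
#' @param background Per-base probabilities for \code{A,T,C,G} (default
#'   uniform), or a 4 x 4 first-order Markov transition matrix (rows/cols in
#'   \code{A,T,C,G} order) for a correlated background.
#' @param center_base_rule Force an adenine at the central position of every
#'   window (default TRUE).
#' @param seed Integer seed; the same seed reproduces the dataset
#'   byte-for-byte.
#' @return A \code{labeled_dataset} with ids \code{pos_i} / \code{neg_i};
#'   positives first.
#' @examples
#' d <- generate_dataset(n_pos = 5, n_neg = 5, seed = 1)
#' d$seq[1]
#' @export
generate_dataset <- function(n_pos, n_neg, window_length = 41,
                             motif = "GAGG", motif_offset = "near_center",
                             planting_probability = 1,
                             background = c(A = 0.25, T = 0.25, C = 0.25, G = 0.25),
                             center_base_rule = TRUE, seed = 1) {
  n_pos <- check_count(n_pos, "n_pos")
  n_neg <- check_count(n_neg, "n_neg")
  window_length <- check_count(window_length, "window_length", min = 2)
  planting_probability <- check_fraction(planting_probability, "planting_probability")
  motif_chars <- split_bases(motif, "motif")
  if (length(motif_chars) >= window_length) {
    stop_validation("motif must be shorter than the window")
  }
  center <- (window_length + 1L) %/% 2L
  if (identical(motif_offset, "near_center")) {
    motif_offset <- min(center + 2L, window_length - length(motif_chars) + 1L)
  }
  motif_offset <- check_count(motif_offset, "motif_offset")
  if (motif_offset + length(motif_chars) - 1L > window_length) {
    stop_validation("motif does not fit in the window at the given offset")
  }

  markov <- is.matrix(background)
  if (markov) {
    if (!all(dim(background) == c(4L, 4L)) || any(background < 0) ||
        any(abs(rowSums(background) - 1) > 1e-8)) {
      stop_validation("a Markov background must be a 4 x 4 row-stochastic matrix")
    }
  } else {
    if (length(background) != 4L || any(background < 0) || abs(sum(background) - 1) > 1e-8) {
      stop_validation("background must be 4 probabilities (A, T, C, G) summing to 1")
    }
  }

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  set.seed(check_count(seed, "seed", min = 0))

  draw_window <- function() {
    if (markov) {
      s <- character(window_length)
      s[1L] <- sample(BASES, 1L)
      for (j in 2:window_length) s[j] <- sample(BASES, 1L, prob = background[s[j - 1L], ])
      s
    } else {
      sample(BASES, window_length, replace = TRUE, prob = background)
    }
  }
  make_class <- function(n, positive) {
    vapply(seq_len(n), function(i) {
      s <- draw_window()
      if (center_base_rule) s[center] <- "A"
      if (positive && stats::runif(1) < planting_probability) {
        s[motif_offset:(motif_offset + length(motif_chars) - 1L)] <- motif_chars
        if (center_base_rule) s[center] <- "A"
      }
      paste(s, collapse = "")
    }, character(1))
  }
  pos <- make_class(n_pos, TRUE)
  neg <- make_class(n_neg, FALSE)
  new_labeled_dataset(
    id = c(sprintf("pos_%d", seq_len(n_pos)), sprintf("neg_%d", seq_len(n_neg))),
    seq = c(pos, neg),
    label = c(rep(1L, n_pos), rep(0L, n_neg)),
    window_length = window_length)
}
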