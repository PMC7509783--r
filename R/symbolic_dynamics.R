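#' Binary symbolic encodings of the RR difference series
#'
#' Two coarse-grainings of \eqn{\Delta RR_i} into \{0, 1\}:
#'
#' * **sign encoding** - `0` where \eqn{\Delta RR_i \ge 0} (deceleration of
#'   heart rate, RR lengthening or equal), `1` where \eqn{\Delta RR_i < 0}
#'   (acceleration). Parameter-free.
#' * **threshold encoding** - `0` where \eqn{|\Delta RR_i| < \tau} (small
#'   change), `1` where \eqn{|\Delta RR_i| \ge \tau} (large change). The
#'   default \eqn{\tau = 35} ms is roughly 5% of a typical grand-average RR
#'   interval; [tau_from_rr()] computes that adaptive variant per subject.
#'
#' Ties follow the inequalities exactly: a zero difference codes 0 under the
#' sign rule, and a difference of exactly `tau` codes 1 under the threshold
#' rule.
#'
#' @param d a [rr_diff()] difference series.
#' @return A list of class `symbolic_sequence` with fields `symbols` (integer
#'   0/1), `encoding` and, for the threshold rule, `tau`.
#' @examples
#' d <- rr_diff(rr_series(c(800, 810, 805, 805)))
#' encode_sign(d)$symbols        # 0 1 0
#' encode_threshold(d, 8)$symbols # 1 0 0
#' @export
encode_sign <- function(d) {
  stopifnot(inherits(d, "diff_series"))
  if (length(d$drr) < 1L) stop("encode_sign: empty difference series")
  structure(list(symbols = ifelse(d$drr >= 0, 0L, 1L),
                 encoding = "sign", tau = NULL),
            class = "symbolic_sequence")
}

#' @rdname encode_sign
#' @param tau threshold in ms, > 0 (default 35).
#' @export
encode_threshold <- function(d, tau = 35) {
  stopifnot(inherits(d, "diff_series"))
  if (length(d$drr) < 1L) stop("encode_threshold: empty difference series")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("encode_threshold: tau must be a single positive number")
  structure(list(symbols = ifelse(abs(d$drr) >= tau, 1L, 0L),
                 encoding = "threshold", tau = tau),
            class = "symbolic_sequence")
}

#' @rdname encode_sign
#' @param rr an [rr_series()]; returns 5% of its mean RR as an adaptive
#'   threshold.
#' @export
tau_from_rr <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  0.05 * mean(rr$rr)
}

#' Classify a length-3 binary word into its variation category
#'
#' Categories count the symbol changes between successive positions:
#' `0V` - none (`000`, `111`); `1V` - one (`001`, `100`, `110`, `011`);
#' `2V` - two (`101`, `010`). Over the 8 binary words the multiplicities are
#' 2, 4 and 2.
#'
#' @param word integer or character vector of exactly 3 symbols over \{0, 1\},
#'   or a 3-character string such as `"010"`.
#' @return `"0V"`, `"1V"` or `"2V"`.
#' @examples
#' classify_word("101")  # "2V"
#' classify_word(c(0, 0, 1))  # "1V"
#' @export
classify_word <- function(word) {
  if (is.character(word) && length(word) == 1L)
    word <- strsplit(word, "")[[1]]
  word <- as.integer(word)
  if (length(word) != 3L || anyNA(word) || !all(word %in% c(0L, 1L)))
    stop("classify_word: word must be 3 symbols over {0,1}")
  v <- (word[1] != word[2]) + (word[2] != word[3])
  c("0V", "1V", "2V")[v + 1L]
}

#' Pattern-category distribution of a symbolic sequence
#'
#' Slides an overlapping window of length 3 (step 1) over the sequence and
#' tallies the variation categories; percentages are relative frequencies of
#' the `n - 2` words and always sum to 100.
#'
#' @param s a `symbolic_sequence` of length >= 3.
#' @return A list of class `pattern_distribution` with counts `n0v`, `n1v`,
#'   `n2v`, percentages `p0v_pct`, `p1v_pct`, `p2v_pct`, `n_words`, and the
#'   provenance fields `encoding` / `tau`.
#' @export
pattern_distribution <- function(s) {
  stopifnot(inherits(s, "symbolic_sequence"))
  y <- s$symbols
  n <- length(y)
  if (n < 3L) stop("pattern_distribution: need at least 3 symbols")
  v <- (y[1:(n - 2)] != y[2:(n - 1)]) + (y[2:(n - 1)] != y[3:n])
  counts <- tabulate(v + 1L, nbins = 3L)
  n_words <- n - 2L
  structure(list(n0v = counts[1], n1v = counts[2], n2v = counts[3],
                 p0v_pct = 100 * counts[1] / n_words,
                 p1v_pct = 100 * counts[2] / n_words,
                 p2v_pct = 100 * counts[3] / n_words,
                 n_words = n_words, encoding = s$encoding, tau = s$tau),
            class = "pattern_distribution")
}

#' Both symbolic pattern distributions of one window
#'
#' Convenience wrapper computing the sign-encoded and threshold-encoded
#' pattern percentages of an RR window in one call.
#'
#' @param rr an [rr_series()] with at least 4 intervals.
#' @param tau threshold in ms for the second encoding.
#' @return Named list with elements `sign` and `threshold`, each a
#'   `pattern_distribution`.
#' @export
symbolic_analysis <- function(rr, tau = 35) {
  d <- rr_diff(rr)
  list(sign = pattern_distribution(encode_sign(d)),
       threshold = pattern_distribution(encode_threshold(d, tau)))
}
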