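## Positional nucleotide composition (sequence-logo data) and biogenesis
## bias statistics: primary-pathway piRNAs show a 5'-U bias and no
## position-10 A enrichment (the ping-pong signature they lack).

#' Positional nucleotide composition
#'
#' Per-position base fractions from the 5' end, optionally weighted by
#' expression. Shorter sequences simply stop contributing, so coverage is
#' non-increasing with position. Per-position information content
#' (2 + sum f*log2 f, in bits) is included for logo rendering.
#'
#' @param sequences character vector of sequences (A/C/G/T).
#' @param weights optional nonnegative weights, one per sequence
#'   (default 1: an unweighted logo of the distinct repertoire).
#' @param max_pos truncate at this position (default: longest sequence).
#' @return object of class \code{positional_composition}: data.frame with
#'   position, A/C/G/T fractions, n (weight contributing), bits; the
#'   weighted base counts are attached as attribute \code{counts}.
#' @export
positional_composition <- function(sequences, weights = NULL,
                                   max_pos = NULL) {
  if (length(sequences) == 0L) stop("no sequences given")
  if (is.null(weights)) weights <- rep(1, length(sequences))
  stopifnot(length(weights) == length(sequences), all(weights >= 0))
  lens <- nchar(sequences)
  max_pos <- max_pos %||% max(lens)
  counts <- matrix(0, max_pos, 4L,
                   dimnames = list(NULL, BASES))
  for (p in seq_len(max_pos)) {
    b <- substring(sequences, p, p)
    covered <- b != ""
    for (base in BASES) {
      counts[p, base] <- sum(weights[covered & b == base])
    }
  }
  n <- rowSums(counts)
  frac <- counts / ifelse(n > 0, n, 1)
  bits <- apply(frac, 1, function(f) {
    f <- f[f > 0]
    if (length(f) == 0) return(NA_real_)
    2 + sum(f * log2(f))
  })
  out <- data.frame(position = seq_len(max_pos), frac, n = n, bits = bits,
                    check.names = FALSE)
  attr(out, "counts") <- counts
  class(out) <- c("positional_composition", "data.frame")
  out
}

#' Test positional base enrichment against a background
#'
#' Two-sided exact binomial test of the observed base fraction at a
#' position against a background probability. The "biased" call requires
#' both p <= 0.01 and an observed fraction at least twice the background.
#' Weighted compositions are rounded to integer pseudo-counts for the
#' test.
#'
#' @param composition a [positional_composition()].
#' @param position 1-based position from the 5' end.
#' @param base one of A, C, G, T.
#' @param background background probability (default 0.25).
#' @return list: position, base, n, fraction, p_value, biased.
#' @export
bias_test <- function(composition, position, base, background = 0.25) {
  counts <- attr(composition, "counts")
  if (position > nrow(counts)) {
    stop("position ", position, " beyond the longest sequence")
  }
  n <- round(sum(counts[position, ]))
  if (n <= 0) stop("no sequence covers position ", position)
  k <- round(counts[position, base])
  fraction <- counts[position, base] / sum(counts[position, ])
  p <- binom.test(k, n, p = background,
                  alternative = "two.sided")$p.value
  list(position = position, base = base, n = n,
       fraction = unname(fraction), p_value = p,
       biased = p <= 0.01 && fraction >= 2 * background)
}

#' Biogenesis-signature report
#'
#' The two diagnostic positions of the primary piRNA pathway: position-1 T
#' (the 5'-U bias of the RNA) and position-10 A (the ping-pong signature,
#' expected absent in somatic tissue).
#'
#' @param sequences character vector of piRNA / piRNA-like sequences.
#' @param weights optional expression weights.
#' @return data.frame with one row per diagnostic test.
#' @export
biogenesis_signature <- function(sequences, weights = NULL) {
  comp <- positional_composition(sequences, weights)
  t1 <- bias_test(comp, 1L, "T")
  a10 <- bias_test(comp, 10L, "A")
  data.frame(test = c("5prime_U", "position10_A"),
             position = c(1L, 10L), base = c("T", "A"),
             fraction = c(t1$fraction, a10$fraction),
             p_value = c(t1$p_value, a10$p_value),
             biased = c(t1$biased, a10$biased),
             stringsAsFactors = FALSE)
}
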