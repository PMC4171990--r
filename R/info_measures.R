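#' Information content of an event
#'
#' `IC(x) = -log2 p(x)`: the surprisal, in bits, of pitch `x` under the
#' predictive distribution. Always finite because predictive distributions
#' carry strictly positive probabilities.
#'
#' @param d A [pred_dist()].
#' @param x A pitch in `d`'s alphabet (vectorized).
#' @return Information content in bits.
#' @examples
#' d <- pred_dist(c(60, 62), c(0.5, 0.5))
#' information_content(d, 60) # 1 bit
#' @export
information_content <- function(d, x) {
  idx <- match(as.integer(x), d$pitch)
  if (anyNA(idx)) stop("pitch not in the distribution's alphabet", call. = FALSE)
  -log2(d$p[idx])
}

#' Shannon entropy of a predictive distribution
#'
#' `H = -sum(p * log2 p)`, in bits: the expected information content, i.e.
#' the model's predictive uncertainty before the event.
#'
#' @param d A [pred_dist()], or any data frame with a `p` column, or a
#'   bare probability vector.
#' @return Entropy in bits, in `[0, log2(n)]`.
#' @export
entropy_bits <- function(d) {
  p <- dist_p(d)
  -sum(p * log2(p))
}

#' Maximum entropy for an alphabet size
#'
#' `H_max = log2(n)`, attained by the uniform distribution.
#'
#' @param n Alphabet size, at least 1.
#' @return Bits.
#' @export
max_entropy <- function(n) {
  if (any(n < 1)) stop("alphabet size must be at least 1", call. = FALSE)
  log2(n)
}

#' Normalized entropy
#'
#' `H / H_max`, dimensionless in `[0, 1]`; comparable across alphabet
#' sizes. Undefined for a single-symbol alphabet.
#'
#' @inheritParams entropy_bits
#' @return A value in `[0, 1]`.
#' @export
normalized_entropy <- function(d) {
  p <- dist_p(d)
  n <- length(p)
  if (n < 2) stop("normalized entropy is undefined for alphabet size 1", call. = FALSE)
  entropy_bits(p) / log2(n)
}

#' Restrict and renormalize a distribution to a pitch subset
#'
#' Used to turn a full-alphabet distribution into the distribution over
#' the nine probe tones ("9-tone entropy"): the probabilities of the
#' subset are rescaled to sum to one; the output follows the subset's
#' order.
#'
#' @param d A [pred_dist()].
#' @param subset Non-empty vector of pitches, all within `d`'s alphabet.
#' @return A [pred_dist()] over `subset`.
#' @export
renormalize_subset <- function(d, subset) {
  subset <- as.integer(subset)
  if (length(subset) == 0) stop("subset must be non-empty", call. = FALSE)
  idx <- match(subset, d$pitch)
  if (anyNA(idx)) stop("subset contains pitches outside the alphabet", call. = FALSE)
  p <- d$p[idx]
  pred_dist(subset, p / sum(p), provenance = attr(d, "provenance"))
}

#' Schmuckler difference score
#'
#' A non-entropy summary of predictive uncertainty: the difference between
#' the average and the minimum information content over the distribution
#' (`variant = "ic"`), or between the average and the minimum probability
#' (`variant = "probability"`). Both are zero for a uniform distribution.
#'
#' @param d A [pred_dist()].
#' @param variant `"ic"` or `"probability"`.
#' @return A non-negative score.
#' @export
schmuckler_score <- function(d, variant = c("ic", "probability")) {
  variant <- match.arg(variant)
  p <- dist_p(d)
  if (variant == "ic") {
    ic <- -log2(p)
    mean(ic) - min(ic)
  } else {
    mean(p) - min(p)
  }
}
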