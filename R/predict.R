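#' Predictive distribution over a pitch alphabet
#'
#' @param pitch Ordered integer pitch alphabet.
#' @param p Probabilities (strictly positive, summing to one).
#' @param provenance Optional list describing how the distribution arose.
#' @return A tibble of class `"pred_dist"` with columns `pitch`, `p`.
#' @export
pred_dist <- function(pitch, p, provenance = NULL) {
  if (length(pitch) != length(p)) stop("pitch and p lengths differ", call. = FALSE)
  if (any(p <= 0)) stop("all probabilities must be strictly positive", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1", call. = FALSE)
  structure(
    tibble::tibble(pitch = as.integer(pitch), p = as.numeric(p)),
    class = c("pred_dist", class(tibble::tibble())),
    provenance = provenance
  )
}

dist_p <- function(d) {
  if (is.data.frame(d)) d$p else as.numeric(d)
}

#' Combine two predictive distributions by weighted geometric mean
#'
#' The combined probability is proportional to
#' `(p1^w1 * p2^w2)^(1/(w1+w2))`, with each weight the distribution's
#' normalized entropy raised to the power `-b`, so that for `b > 0` the
#' less uncertain (lower-entropy) sub-model dominates; `b = 0` gives equal
#' weights.
#'
#' @param d1,d2 [pred_dist()] objects over the same ordered alphabet.
#' @param b Non-negative bias exponent.
#' @return A [pred_dist()].
#' @export
combine_distributions <- function(d1, d2, b = 1) {
  if (!identical(d1$pitch, d2$pitch)) {
    stop("distributions are over different alphabets", call. = FALSE)
  }
  stopifnot(b >= 0)
  # floor keeps the weight finite for a near-point-mass sub-model
  h1 <- max(normalized_entropy(d1), 1e-6)
  h2 <- max(normalized_entropy(d2), 1e-6)
  w1 <- h1^(-b)
  w2 <- h2^(-b)
  lp <- (w1 * log(d1$p) + w2 * log(d2$p)) / (w1 + w2)
  p <- exp(lp - max(lp))
  pred_dist(d1$pitch, p / sum(p),
    provenance = list(combined = TRUE, bias = b, weights = c(w1, w2))
  )
}

# distribution over candidate pitches from one sub-model
submodel_pitch_dist <- function(store, context_syms, cand_syms, pitches,
                                config) {
  uniq <- unique(cand_syms)
  ps <- ppm_distribution(store, context_syms, uniq, config)
  mult <- table(cand_syms)
  p <- ps[cand_syms] / as.numeric(mult[cand_syms])
  p <- p / sum(p)
  stats::setNames(as.numeric(p), pitches)
}

#' Predict the next pitch after a melodic context
#'
#' For each candidate pitch in the alphabet the linked viewpoint symbol it
#' would produce is formed with [symbol_for_candidate()], each active
#' sub-model's PPM probability is evaluated, the sub-model distributions
#' are combined with [combine_distributions()] when both are active, and
#' the result is renormalized over the pitch alphabet. An empty context
#' (predicting the first note) backs off to scale-degree-only symbols;
#' pitches sharing a degree split that degree's probability equally.
#'
#' @param context A [melody()] prefix, possibly with zero rows.
#' @param key The [key()] used for scale degrees.
#' @param alphabet Integer vector of candidate pitches.
#' @param ltm,stm Trained [ngram_store()] objects; which are consulted is
#'   set by `config$configuration`.
#' @param config A [model_config()].
#' @param candidate_onset Onset assumed for the candidate note when the
#'   IOI-contour component is active; defaults to the context's last
#'   offset (an immediate continuation).
#' @return A [pred_dist()] over `alphabet`.
#' @export
predict_next <- function(context, key, alphabet, ltm = NULL, stm = NULL,
                         config = model_config(), candidate_onset = NULL) {
  stopifnot(inherits(key, "key"))
  if (length(alphabet) == 0) stop("alphabet must be non-empty", call. = FALSE)
  alphabet <- as.integer(alphabet)
  use_ltm <- config$configuration %in% c("ltm", "both")
  use_stm <- config$configuration %in% c("stm", "both")
  if (use_ltm && is.null(ltm)) stop("configuration needs an LTM store", call. = FALSE)
  if (use_stm && is.null(stm)) stop("configuration needs an STM store", call. = FALSE)

  n_ctx <- nrow(context)
  if (is.null(n_ctx) || n_ctx == 0) {
    ctx_syms <- character(0)
    cand_syms <- symbol_for_first(alphabet, key)
  } else {
    ctx_syms <- derive_viewpoints(context, key, config$include_ioi_contour)$symbol
    contour <- NA_integer_
    if (config$include_ioi_contour && n_ctx >= 2) {
      if (is.null(candidate_onset)) {
        candidate_onset <- context$onset[n_ctx] + context$duration[n_ctx]
      }
      ioi_prev <- context$onset[n_ctx] - context$onset[n_ctx - 1]
      contour <- as.integer(sign((candidate_onset - context$onset[n_ctx]) - ioi_prev))
    }
    cand_syms <- symbol_for_candidate(
      context$pitch[n_ctx], alphabet, key,
      ioi_contour = contour,
      include_ioi_contour = config$include_ioi_contour
    )
  }

  dists <- list()
  if (use_ltm) {
    dists$ltm <- submodel_pitch_dist(ltm, ctx_syms, cand_syms, alphabet, config)
  }
  if (use_stm) {
    dists$stm <- submodel_pitch_dist(stm, ctx_syms, cand_syms, alphabet, config)
  }
  prov <- list(
    configuration = config$configuration,
    order_bound = config$order_bound, escape = config$escape_method,
    context_length = length(ctx_syms)
  )
  if (length(dists) == 1) {
    return(pred_dist(alphabet, dists[[1]] / sum(dists[[1]]), provenance = prov))
  }
  combine_distributions(
    pred_dist(alphabet, dists$ltm, provenance = prov),
    pred_dist(alphabet, dists$stm, provenance = prov),
    b = config$bias
  )
}

#' Per-note predictive distributions for a whole melody
#'
#' Walks the melody note by note. The short-term sub-model starts empty
#' and is updated with each observed note after that note has been
#' predicted, so every prediction uses only the preceding context.
#'
#' @param m A [melody()].
#' @param key A [key()]; defaults to the melody's notated key, else
#'   [estimate_key()].
#' @param alphabet Candidate pitch alphabet.
#' @param ltm Trained long-term store (required unless the configuration
#'   is STM-only).
#' @param config A [model_config()].
#' @return A list of [pred_dist()], one per note, in note order.
#' @export
sequence_predictions <- function(m, alphabet, ltm = NULL, key = NULL,
                                 config = model_config()) {
  validate_melody(m)
  key <- key %||% melody_key(m) %||% estimate_key(m)
  use_stm <- config$configuration %in% c("stm", "both")
  stm <- if (use_stm) ngram_store(config$order_bound)
  obs_syms <- derive_viewpoints(m, key, config$include_ioi_contour)$symbol
  n <- nrow(m)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ctx <- m[seq_len(i - 1), , drop = FALSE]
    out[[i]] <- predict_next(ctx, key, alphabet,
      ltm = ltm, stm = stm, config = config,
      candidate_onset = m$onset[i]
    )
    if (use_stm) {
      stm <- store_add_event(stm, obs_syms[seq_len(i)], config$update_exclusion)
    }
  }
  out
}

#' Tidy per-note trace of a prediction sequence
#'
#' @param preds List of [pred_dist()] from [sequence_predictions()].
#' @param m The melody that was predicted.
#' @return A tibble with one row per note: the probability and information
#'   content of the heard pitch and the entropy / normalized entropy of
#'   the full distribution.
#' @export
prediction_trace <- function(preds, m) {
  validate_melody(m)
  stopifnot(length(preds) == nrow(m))
  purrr::imap_dfr(preds, function(d, i) {
    tibble::tibble(
      note_index = i,
      pitch = m$pitch[i],
      p = d$p[match(m$pitch[i], d$pitch)],
      ic = information_content(d, m$pitch[i]),
      entropy = entropy_bits(d),
      h_norm = normalized_entropy(d)
    )
  })
}
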