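#' Implication-Realization predictor constants
#'
#' The exact numeric codings of the rule-based predictors, collected in
#' one overridable list. Defaults follow Schellenberg's (1997) simplified
#' two-predictor quantification of the Implication-Realization model plus
#' the Krumhansl (1990) tonal-hierarchy predictor:
#' * proximity: `12 - min(|probe - last|, 12)`, linear in distance;
#' * pitch reversal: a direction component in `{+1, 0, -1}` that is 0 for
#'   implicative intervals of at most `small_interval` semitones, `+1`
#'   when a large implicative interval is followed by a direction change
#'   (a unison counts as a change) and `-1` otherwise, plus a returning
#'   proximity component of `reversal_return` when the realized tone lands
#'   within `return_window` semitones of the first tone of the implicative
#'   interval;
#' * tonal hierarchy: the key-profile value of the probe's scale degree.
#'
#' @param proximity_max Score at distance 0.
#' @param proximity_cap Distance at which the linear decrease stops.
#' @param small_interval Largest "small" implicative interval (semitones).
#' @param reversal_return Returning-proximity bonus.
#' @param return_window Half-width of the return window (semitones).
#' @param profile_set Profile set for the tonal-hierarchy predictor.
#' @return A named list of constants.
#' @export
ir_constants <- function(proximity_max = 12, proximity_cap = 12,
                         small_interval = 6, reversal_return = 1.5,
                         return_window = 2,
                         profile_set = "krumhansl_kessler") {
  list(
    proximity_max = proximity_max, proximity_cap = proximity_cap,
    small_interval = small_interval, reversal_return = reversal_return,
    return_window = return_window, profile_set = profile_set
  )
}

#' Pitch-proximity predictor
#'
#' Decreases linearly with the absolute semitone distance between the
#' probe and the last context pitch; maximal at distance zero.
#'
#' @param context_last_pitch Last pitch of the context.
#' @param probe Probe pitch (vectorized).
#' @param constants See [ir_constants()].
#' @return Numeric score(s).
#' @export
proximity_score <- function(context_last_pitch, probe,
                            constants = ir_constants()) {
  d <- abs(as.numeric(probe) - as.numeric(context_last_pitch))
  constants$proximity_max - pmin(d, constants$proximity_cap)
}

#' Pitch-reversal predictor
#'
#' Composite of a direction component (gated by the size of the
#' implicative interval) and a returning-proximity component; see
#' [ir_constants()] for the coding. Undefined (returns `NA`) when the
#' context is too short to define an implicative interval.
#'
#' @param implicative_interval Signed semitone interval formed by the last
#'   two context notes.
#' @param probe_interval Signed semitone interval from the last context
#'   note to the probe (vectorized).
#' @param constants See [ir_constants()].
#' @return Numeric score(s), `NA` if `implicative_interval` is `NA`.
#' @export
pitch_reversal_score <- function(implicative_interval, probe_interval,
                                 constants = ir_constants()) {
  if (is.na(implicative_interval)) {
    return(rep(NA_real_, length(probe_interval)))
  }
  imp <- as.numeric(implicative_interval)
  real <- as.numeric(probe_interval)
  direction <- if (abs(imp) <= constants$small_interval) {
    rep(0, length(real))
  } else {
    ifelse(sign(real) == sign(imp) & real != 0, -1, 1)
  }
  # realized tone within the return window of the implicative origin
  returning <- abs(real + imp) <= constants$return_window
  direction + constants$reversal_return * returning
}

#' Tonal-hierarchy predictor
#'
#' The key-profile value of the probe's scale degree in the given key.
#'
#' @param probe Probe pitch (vectorized).
#' @param key A [key()].
#' @param constants See [ir_constants()].
#' @return Profile values.
#' @export
tonal_hierarchy_score <- function(probe, key, constants = ir_constants()) {
  stopifnot(inherits(key, "key"))
  prof <- key_profiles(constants$profile_set)[[key$mode]]
  prof[((as.integer(probe) - key$tonic) %% 12L) + 1L]
}

#' Predictor table for a stimulus set
#'
#' Computes the three Implication-Realization predictors for every
#' (stimulus, probe) pair, aligned with probe trials.
#'
#' @param stimuli A `stimulus_set`.
#' @param constants See [ir_constants()].
#' @return A tibble with columns `stimulus_id`, `probe_pitch`,
#'   `proximity`, `pitch_reversal`, `tonal_hierarchy`.
#' @export
ir_predictor_table <- function(stimuli, constants = ir_constants()) {
  purrr::map_dfr(seq_len(nrow(stimuli)), function(i) {
    row <- stimuli[i, ]
    prefix <- row$prefix[[1]]
    n <- nrow(prefix)
    last <- prefix$pitch[n]
    imp <- if (n >= 2) prefix$pitch[n] - prefix$pitch[n - 1] else NA_integer_
    probes <- row$probes[[1]]
    k <- key(row$key_tonic, row$key_mode)
    tibble::tibble(
      stimulus_id = row$stimulus_id,
      probe_pitch = probes,
      proximity = proximity_score(last, probes, constants),
      pitch_reversal = pitch_reversal_score(imp, probes - last, constants),
      tonal_hierarchy = tonal_hierarchy_score(probes, k, constants)
    )
  })
}

#' Fit the Implication-Realization multiple regression
#'
#' Ordinary least squares of participant-averaged ratings on the three
#' rule-based predictors.
#'
#' @param predictor_table Data frame of predictor columns (any numeric
#'   columns other than `stimulus_id`/`probe_pitch` are used).
#' @param mean_ratings Numeric response, one value per row.
#' @return An object of class `"ir_fit"`: list with `coefficients`,
#'   `fitted`, `residuals`, `R` (multiple correlation), `n`.
#' @export
fit_ir_regression <- function(predictor_table, mean_ratings) {
  pred <- dplyr::select(
    as.data.frame(predictor_table),
    dplyr::where(is.numeric), -dplyr::any_of("probe_pitch")
  )
  stopifnot(length(mean_ratings) == nrow(pred))
  keep <- stats::complete.cases(pred) & !is.na(mean_ratings)
  pred <- pred[keep, , drop = FALSE]
  y <- mean_ratings[keep]
  if (nrow(pred) < ncol(pred) + 2) {
    stop("too few rows to fit the regression", call. = FALSE)
  }
  x <- as.matrix(pred)
  if (qr(cbind(1, x))$rank < ncol(x) + 1) {
    stop("rank-deficient design: predictors are collinear", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # a perfect fit is legitimate here (constructed designs); the summary
  # warning about it is noise
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(
      coefficients = stats::setNames(
        stats::coef(fit), c("(Intercept)", colnames(x))
      ),
      fitted = stats::fitted(fit), residuals = stats::resid(fit),
      R = sqrt(r2), n = nrow(pred)
    ),
    class = "ir_fit"
  )
}

#' @export
print.ir_fit <- function(x, ...) {
  cat("<ir_fit> multiple R =", format(x$R, digits = 4), "on", x$n, "trials\n")
  invisible(x)
}
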