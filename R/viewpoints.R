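#' Musical key
#'
#' @param tonic Pitch class of the tonal center, 0-11 (0 = C).
#' @param mode `"major"` or `"minor"`.
#' @return An object of class `"key"`.
#' @examples
#' key(0, "major") # C major
#' @export
key <- function(tonic, mode = c("major", "minor")) {
  mode <- match.arg(mode)
  tonic <- as.integer(tonic)
  if (is.na(tonic) || tonic < 0 || tonic > 11) {
    stop("tonic must be a pitch class in [0, 11]", call. = FALSE)
  }
  structure(list(tonic = tonic, mode = mode), class = "key")
}

#' @export
print.key <- function(x, ...) {
  nm <- c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "A#", "B")
  cat("<key> ", nm[x$tonic + 1], " ", x$mode, "\n", sep = "")
  invisible(x)
}

#' Derive linked viewpoint symbols from a melody
#'
#' Each note is represented by a linked viewpoint symbol combining pitch
#' interval (signed semitones from the previous note; undefined at the
#' first note), scale degree (semitones above the tonic, modulo 12) and,
#' optionally, the contour of inter-onset intervals (sign of the change in
#' IOI; undefined for the first two notes, ties coded 0). The first note
#' carries its scale degree only.
#'
#' @param m A [melody()].
#' @param key The [key()] fixing the tonal center for scale degrees.
#' @param include_ioi_contour Include the IOI-contour component (used for
#'   melodies that carry rhythm).
#' @return A tibble with columns `note_index`, `pitch_interval`,
#'   `scale_degree`, `ioi_contour` (`NA` where undefined) and the encoded
#'   `symbol` string used by the n-gram model.
#' @export
derive_viewpoints <- function(m, key, include_ioi_contour = FALSE) {
  validate_melody(m)
  stopifnot(inherits(key, "key"))
  n <- nrow(m)
  interval <- c(NA_integer_, diff(m$pitch))
  degree <- (m$pitch - key$tonic) %% 12L
  contour <- rep(NA_integer_, n)
  if (include_ioi_contour && n >= 3) {
    ioi <- diff(m$onset) # IOI_i = onset_i - onset_{i-1}, defined from note 2
    contour[3:n] <- sign(ioi[-1] - ioi[-(n - 1)])
  }
  tibble::tibble(
    note_index = seq_len(n),
    pitch_interval = interval,
    scale_degree = as.integer(degree),
    ioi_contour = as.integer(contour),
    symbol = encode_symbol(interval, degree, contour, include_ioi_contour)
  )
}

# Symbol string encoding. First-note symbols ("S<deg>") live in a distinct
# namespace from full linked symbols ("i<int>.d<deg>[.c<ctr>]") so the two
# never collide inside one n-gram store.
encode_symbol <- function(interval, degree, contour, include_ioi_contour) {
  full <- paste0("i", interval, ".d", degree)
  if (include_ioi_contour) {
    full <- paste0(full, ".c", ifelse(is.na(contour), "x", contour))
  }
  ifelse(is.na(interval), paste0("S", degree), full)
}

#' Viewpoint symbol for a candidate continuation
#'
#' Maps a candidate pitch to the linked symbol it would produce after a
#' given context. The mapping is injective in the candidate pitch for a
#' fixed previous pitch and key, which is what lets a predictive
#' distribution over derived symbols be read back as a distribution over
#' pitches.
#'
#' @param prev_pitch Last pitch of the context.
#' @param candidate_pitch Candidate continuation pitch (vectorized).
#' @param key A [key()].
#' @param ioi_contour Optional IOI contour value for the candidate
#'   (-1/0/1), or `NA` when rhythm is not represented.
#' @param include_ioi_contour Include the contour component in the symbol.
#' @return Character vector of encoded symbols.
#' @export
symbol_for_candidate <- function(prev_pitch, candidate_pitch, key,
                                 ioi_contour = NA_integer_,
                                 include_ioi_contour = FALSE) {
  stopifnot(inherits(key, "key"))
  interval <- as.integer(candidate_pitch) - as.integer(prev_pitch)
  degree <- (as.integer(candidate_pitch) - key$tonic) %% 12L
  encode_symbol(interval, degree,
    rep(as.integer(ioi_contour), length(interval)),
    include_ioi_contour
  )
}

# degree-only symbols for first-event prediction
symbol_for_first <- function(candidate_pitch, key) {
  paste0("S", (as.integer(candidate_pitch) - key$tonic) %% 12L)
}
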