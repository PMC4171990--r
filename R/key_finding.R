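the_profiles <- new.env(parent = emptyenv())

#' Key-profile data
#'
#' Returns the shipped key-profile sets used for key finding and the
#' tonal-hierarchy predictor: the Krumhansl-Kessler probe-tone profiles and
#' Temperley's modified profiles. Each set holds a `major` and a `minor`
#' 12-vector indexed by scale degree (0 = tonic) plus a provenance string.
#'
#' @param profile_set `"krumhansl_kessler"` or `"temperley"`.
#' @return A list with elements `major`, `minor`, `provenance`.
#' @export
key_profiles <- function(profile_set = c("krumhansl_kessler", "temperley")) {
  profile_set <- match.arg(profile_set)
  if (is.null(the_profiles$data)) {
    path <- system.file("extdata", "key_profiles.json", package = "melent")
    the_profiles$data <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  the_profiles$data[[profile_set]]
}

#' Estimate the key of a melody by profile correlation
#'
#' Krumhansl-Schmuckler key finding: the duration-weighted pitch-class
#' distribution of the melody is correlated (Pearson) with each of the 24
#' rotated key profiles and the best-matching key is returned. With
#' `weighting = "count"` every note counts equally instead. Ties are broken
#' deterministically: lowest tonic number first, major before minor.
#'
#' @param m A [melody()].
#' @param profile_set Profile values to use; `"temperley"` (default)
#'   mirrors the enhanced implementation used for stimulus selection.
#' @param weighting `"duration"` (default) or `"count"`.
#' @return A [key()].
#' @examples
#' estimate_key(melody(c(60, 62, 64, 65, 67, 69, 71, 72)))
#' @export
estimate_key <- function(m, profile_set = c("temperley", "krumhansl_kessler"),
                         weighting = c("duration", "count")) {
  validate_melody(m)
  profile_set <- match.arg(profile_set)
  weighting <- match.arg(weighting)
  prof <- key_profiles(profile_set)
  w <- if (weighting == "duration") m$duration else rep(1, nrow(m))
  pc_weight <- vapply(0:11, function(pc) sum(w[m$pitch %% 12 == pc]), 0)
  best <- NULL
  best_r <- -Inf
  for (tonic in 0:11) {
    for (mode in c("major", "minor")) {
      rotated <- prof[[mode]][(((0:11) - tonic) %% 12) + 1]
      r <- suppressWarnings(stats::cor(pc_weight, rotated))
      if (is.na(r)) r <- 0 # flat input: all keys tie
      if (r > best_r + 1e-12) {
        best_r <- r
        best <- key(tonic, mode)
      }
    }
  }
  best
}
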