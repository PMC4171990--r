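#' First-order melodic grammar specification
#'
#' A known first-order Markov chain over a pitch alphabet, with phrase
#' structure and a rhythmic style, used to generate synthetic corpora
#' whose statistical structure the expectation model should recover.
#'
#' @param alphabet Integer pitch alphabet.
#' @param transition Row-stochastic transition matrix
#'   (`length(alphabet)` square; rows sum to 1 within 1e-12).
#' @param initial Initial distribution; defaults to uniform.
#' @param phrase_range Inclusive range of phrase lengths in notes.
#' @param style `"isochronous"` (all durations 1 beat) or `"rhythmic"`
#'   (durations drawn from {0.5, 1, 2} beats).
#' @param style_label Melody style label for generated melodies; defaults
#'   to `"simple"` for isochronous and `"complex"` for rhythmic grammars.
#' @param key Notated [key()] attached to generated melodies.
#' @param seed Integer seed making generation reproducible.
#' @return A list of class `"grammar_spec"`.
#' @export
grammar_spec <- function(alphabet, transition,
                         initial = NULL,
                         phrase_range = c(6, 10),
                         style = c("isochronous", "rhythmic"),
                         style_label = NULL,
                         key = NULL, seed = 1) {
  style <- match.arg(style)
  key <- key %||% key(0, "major")
  alphabet <- as.integer(alphabet)
  transition <- as.matrix(transition)
  n <- length(alphabet)
  if (!all(dim(transition) == c(n, n))) {
    stop("transition matrix must be square on the alphabet", call. = FALSE)
  }
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-12)) {
    stop("transition matrix rows must be non-negative and sum to 1",
      call. = FALSE
    )
  }
  initial <- initial %||% rep(1 / n, n)
  if (abs(sum(initial) - 1) > 1e-12 || any(initial < 0)) {
    stop("initial distribution must be a probability vector", call. = FALSE)
  }
  structure(
    list(
      alphabet = alphabet, transition = transition, initial = initial,
      phrase_range = as.integer(phrase_range), style = style,
      style_label = style_label %||%
        if (style == "isochronous") "simple" else "complex",
      key = key, seed = as.integer(seed)
    ),
    class = "grammar_spec"
  )
}

#' Proximity- and tonality-biased grammar
#'
#' Builds a realistic melodic grammar over a chromatic pitch range: from
#' each pitch, transition weight decays exponentially with semitone
#' distance and is scaled by the key-profile value of the destination's
#' scale degree, then mixed with a uniform component. Smaller
#' `uniform_mix` and larger `proximity_scale` give lower conditional
#' entropy.
#'
#' @param pitch_range Inclusive pitch range, e.g. `c(60, 77)` (C4-F5).
#' @param key A [key()].
#' @param proximity_scale Semitone scale of the proximity decay.
#' @param uniform_mix Weight of the uniform component, in `[0, 1]`.
#' @param profile_set Profile set for the tonality bias.
#' @inheritParams grammar_spec
#' @return A `grammar_spec`.
#' @export
tonal_grammar <- function(pitch_range, key = NULL,
                          proximity_scale = 2.5, uniform_mix = 0.05,
                          style = "isochronous", phrase_range = c(6, 10),
                          seed = 1, profile_set = "krumhansl_kessler") {
  key <- key %||% key(0, "major")
  alphabet <- seq(pitch_range[1], pitch_range[2])
  n <- length(alphabet)
  prof <- key_profiles(profile_set)[[key$mode]]
  tonality <- prof[((alphabet - key$tonic) %% 12) + 1]
  trans <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- exp(-abs(alphabet - alphabet[i]) / proximity_scale) * tonality
    w[i] <- w[i] * 0.5 # discourage repetition
    w <- w / sum(w)
    trans[i, ] <- (1 - uniform_mix) * w + uniform_mix / n
  }
  init <- tonality / sum(tonality)
  grammar_spec(alphabet, trans,
    initial = init, phrase_range = phrase_range,
    style = style, key = key, seed = seed
  )
}

#' Sample a corpus from a melodic grammar
#'
#' Melodies are sampled from the chain; phrase lengths are drawn uniformly
#' from the grammar's phrase range and marked with `phrase_start` flags;
#' isochronous grammars give unit durations, rhythmic grammars draw
#' durations from {0.5, 1, 2} beats. Reproducible for a fixed
#' `spec$seed`.
#'
#' @param spec A [grammar_spec()].
#' @param n_melodies Number of melodies.
#' @param notes_per_melody Notes in each melody.
#' @param id_prefix Prefix for melody ids.
#' @return A [corpus()].
#' @export
generate_markov_corpus <- function(spec, n_melodies = 20,
                                   notes_per_melody = 30,
                                   id_prefix = spec$style_label) {
  stopifnot(inherits(spec, "grammar_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- length(spec$alphabet)
  mels <- purrr::map(seq_len(n_melodies), function(mi) {
    idx <- integer(notes_per_melody)
    idx[1] <- sample.int(n, 1, prob = spec$initial)
    for (j in 2:notes_per_melody) {
      idx[j] <- sample.int(n, 1, prob = spec$transition[idx[j - 1], ])
    }
    pitches <- spec$alphabet[idx]
    flags <- rep(FALSE, notes_per_melody)
    pos <- 1
    while (pos <= notes_per_melody) {
      flags[pos] <- TRUE
      pos <- pos + sample(spec$phrase_range[1]:spec$phrase_range[2], 1)
    }
    durations <- if (spec$style == "isochronous") {
      rep(1, notes_per_melody)
    } else {
      sample(c(0.5, 1, 2), notes_per_melody,
        replace = TRUE, prob = c(0.25, 0.5, 0.25)
      )
    }
    onsets <- cumsum(c(0, durations[-notes_per_melody]))
    melody(pitches, onsets, durations, flags,
      id = sprintf("%s_%03d", id_prefix, mi),
      style = spec$style_label, key = spec$key, source = "synthetic grammar"
    )
  })
  corpus(mels)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Analytic conditional entropy of a grammar
#'
#' The stationary-averaged conditional entropy of the chain,
#' `sum_s pi(s) H(row_s)` in bits, with `pi` the stationary distribution.
#' This is the value an ideal first-order model should converge to.
#'
#' @param spec A [grammar_spec()].
#' @return Bits.
#' @export
analytic_chain_entropy <- function(spec) {
  stopifnot(inherits(spec, "grammar_spec"))
  p <- spec$transition
  n <- nrow(p)
  reach <- (p > 0) | diag(n) > 0
  for (i in seq_len(ceiling(log2(n)) + 1)) reach <- (reach %*% reach) > 0
  if (!all(reach)) stop("chain is reducible", call. = FALSE)
  ev <- eigen(t(p))
  i <- which.min(abs(ev$values - 1))
  pi_s <- Re(ev$vectors[, i])
  pi_s <- pi_s / sum(pi_s)
  row_h <- apply(p, 1, function(r) {
    r <- r[r > 0]
    -sum(r * log2(r))
  })
  sum(pi_s * row_h)
}

#' Simulated listener specification
#'
#' Expertise is operationalized as rating noise: simulated musicians
#' carry lower `noise_sd` than non-musicians, reflecting a more accurate
#' internal model.
#'
#' @param group Group label, e.g. `"musician"`.
#' @param noise_sd Gaussian rating noise, expressed on the information
#'   content scale (bits), added before mapping to the 9-point scale.
#' @param lapse_rate Probability of replacing a rating with a uniform
#'   random one.
#' @return A list of class `"listener_spec"`.
#' @export
listener_spec <- function(group, noise_sd, lapse_rate = 0.02) {
  stopifnot(noise_sd >= 0, lapse_rate >= 0, lapse_rate <= 1)
  structure(
    list(group = group, noise_sd = noise_sd, lapse_rate = lapse_rate),
    class = "listener_spec"
  )
}

#' Default simulated listener panel
#'
#' Two groups mirroring the behavioral design: musicians with low rating
#' noise and non-musicians with high rating noise.
#'
#' @param musician_sd,nonmusician_sd Noise levels in bits.
#' @param lapse_rate Shared lapse rate.
#' @return List of two [listener_spec()] objects.
#' @export
default_listeners <- function(musician_sd = 1, nonmusician_sd = 2.5,
                              lapse_rate = 0.02) {
  list(
    listener_spec("musician", musician_sd, lapse_rate),
    listener_spec("nonmusician", nonmusician_sd, lapse_rate)
  )
}

# affine map calibrated so the 5th/95th percentiles of the pool land on
# the ends of the 9-point scale
likert_mapping <- function(pool) {
  q <- stats::quantile(pool, c(0.05, 0.95), names = FALSE)
  if (q[2] - q[1] < 1e-9) q[2] <- q[1] + 1 # degenerate pool: unit slope
  a <- 8 / (q[2] - q[1])
  function(x) 1 + a * (x - q[1])
}

clip_round <- function(x) pmin(9L, pmax(1L, as.integer(round(x))))

#' Simulate probe-tone ratings for a stimulus set
#'
#' Unexpectedness ratings are a noisy monotone function of the model's
#' per-probe information content; explicit uncertainty ratings are the
#' same for per-context entropy. The affine IC-to-Likert mapping is
#' calibrated so the 5th/95th percentiles of the stimulus set's IC values
#' map to the ends of the 9-point scale, then Gaussian noise (the listener
#' spec's `noise_sd`, on the IC scale) is added before mapping, and the
#' result is clipped and rounded; lapses replace a rating with a uniform
#' draw. Familiarity is false throughout (the synthetic melodies are novel
#' by construction).
#'
#' @param stimuli A `stimulus_set`.
#' @param model_eval Output of [evaluate_model_on_stimuli()] for the
#'   generating model.
#' @param listeners List of [listener_spec()]; see [default_listeners()].
#' @param n_per_group Participants per group.
#' @param seed Integer seed.
#' @return A list of class `"rating_dataset"` with tibbles
#'   `unexpectedness` (`participant`, `group`, `stimulus_id`,
#'   `probe_pitch`, `rating`), `explicit` (`participant`, `group`,
#'   `stimulus_id`, `rating`, `familiar`) and `participants`.
#' @export
simulate_listener_ratings <- function(stimuli, model_eval, listeners =
                                        default_listeners(),
                                      n_per_group = 17, seed = 1) {
  per_probe <- model_eval$per_probe
  per_stim <- model_eval$per_stimulus
  if (!setequal(per_stim$stimulus_id, stimuli$stimulus_id)) {
    stop("model outputs are not aligned with the stimulus set", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  map_ic <- likert_mapping(per_probe$ic)
  map_h <- likert_mapping(per_stim$entropy_full)

  res <- purrr::map(listeners, function(ls) {
    purrr::map(seq_len(n_per_group), function(pi) {
      pid <- sprintf("%s_%02d", ls$group, pi)
      u_raw <- map_ic(per_probe$ic + stats::rnorm(nrow(per_probe), 0, ls$noise_sd))
      u <- clip_round(u_raw)
      lapse <- stats::runif(length(u)) < ls$lapse_rate
      u[lapse] <- sample(1:9, sum(lapse), replace = TRUE)
      e_raw <- map_h(per_stim$entropy_full +
        stats::rnorm(nrow(per_stim), 0, ls$noise_sd))
      e <- clip_round(e_raw)
      lapse_e <- stats::runif(length(e)) < ls$lapse_rate
      e[lapse_e] <- sample(1:9, sum(lapse_e), replace = TRUE)
      gmsi <- if (ls$group == "musician") {
        sample(36:62, 1)
      } else {
        sample(9:20, 1)
      }
      list(
        unexpectedness = tibble::tibble(
          participant = pid, group = ls$group,
          stimulus_id = per_probe$stimulus_id,
          probe_pitch = per_probe$probe_pitch, rating = u
        ),
        explicit = tibble::tibble(
          participant = pid, group = ls$group,
          stimulus_id = per_stim$stimulus_id, rating = e, familiar = FALSE
        ),
        profile = tibble::tibble(
          participant = pid, group = ls$group,
          age = sample(19:48, 1),
          gender = sample(c("female", "male"), 1),
          gmsi_training = gmsi,
          gmsi_importance = sample(20:60, 1),
          gmsi_emotion = sample(20:60, 1)
        )
      )
    })
  })
  flat <- purrr::flatten(res)
  structure(
    list(
      unexpectedness = purrr::map_dfr(flat, "unexpectedness"),
      explicit = purrr::map_dfr(flat, "explicit"),
      participants = purrr::map_dfr(flat, "profile")
    ),
    class = "rating_dataset"
  )
}

#' Write a rating dataset as tidy CSVs
#'
#' @param ratings A `rating_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_rating_dataset <- function(ratings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(ratings$unexpectedness),
    file.path(dir, "unexpectedness.csv"),
    row.names = FALSE
  )
  utils::write.csv(as.data.frame(ratings$explicit),
    file.path(dir, "explicit.csv"),
    row.names = FALSE
  )
  utils::write.csv(as.data.frame(ratings$participants),
    file.path(dir, "participants.csv"),
    row.names = FALSE
  )
  invisible(dir)
}

#' @rdname write_rating_dataset
#' @export
read_rating_dataset <- function(dir) {
  structure(
    list(
      unexpectedness = tibble::as_tibble(
        utils::read.csv(file.path(dir, "unexpectedness.csv"))
      ),
      explicit = tibble::as_tibble(
        utils::read.csv(file.path(dir, "explicit.csv"))
      ),
      participants = tibble::as_tibble(
        utils::read.csv(file.path(dir, "participants.csv"))
      )
    ),
    class = "rating_dataset"
  )
}
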