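#' Per-note entropy over a corpus
#'
#' Runs the expectation model over every note of every melody and records
#' the entropy of the full-alphabet predictive distribution at each
#' position ("37-tone entropy" when the chromatic-span alphabet spans 37
#' pitches). This is the first stage of the stimulus-selection pipeline.
#'
#' @param corpus A [corpus()].
#' @param ltm Trained long-term store (unless the configuration is
#'   STM-only).
#' @param config A [model_config()].
#' @param key_source `"stored"` uses each melody's notated key, falling
#'   back to [estimate_key()]; `"estimated"` always estimates.
#' @return A tibble with columns `melody_id`, `style`, `note_index`,
#'   `pitch`, `entropy`.
#' @export
score_corpus_notes <- function(corpus, ltm = NULL, config = model_config(),
                               key_source = c("stored", "estimated")) {
  stopifnot(inherits(corpus, "melody_corpus"))
  key_source <- match.arg(key_source)
  alphabet <- corpus_alphabet(corpus, config$alphabet_policy)
  purrr::map_dfr(corpus$melodies, function(m) {
    k <- if (key_source == "stored") melody_key(m) %||% estimate_key(m) else estimate_key(m)
    preds <- sequence_predictions(m, alphabet, ltm = ltm, key = k, config = config)
    tibble::tibble(
      melody_id = melody_id(m), style = melody_style(m),
      note_index = seq_len(nrow(m)), pitch = m$pitch,
      entropy = purrr::map_dbl(preds, entropy_bits)
    )
  })
}

#' Select extreme-entropy candidate notes
#'
#' Per style, the `k_per_extreme` highest- and lowest-entropy notes are
#' selected. Ties are broken by melody id then note index, ascending, so
#' selection is fully deterministic.
#'
#' @param scores Output of [score_corpus_notes()].
#' @param k_per_extreme Notes to take per extreme per style.
#' @return `scores` rows for the selected notes with an added
#'   `entropy_class` column (`"high"`/`"low"`).
#' @export
select_candidate_notes <- function(scores, k_per_extreme = 18) {
  stopifnot(nrow(scores) > 0)
  per_style <- dplyr::count(scores, .data$style)
  if (any(per_style$n < k_per_extreme)) {
    stop("k_per_extreme exceeds the number of scored notes in a style",
      call. = FALSE
    )
  }
  pick <- function(df, class) {
    df <- if (class == "high") {
      dplyr::arrange(df, dplyr::desc(.data$entropy), .data$melody_id, .data$note_index)
    } else {
      dplyr::arrange(df, .data$entropy, .data$melody_id, .data$note_index)
    }
    dplyr::mutate(utils::head(df, k_per_extreme), entropy_class = class)
  }
  scores |>
    dplyr::group_by(.data$style) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      pick(.x, "high"), pick(.x, "low")
    )) |>
    dplyr::ungroup()
}

#' Extract the melodic context preceding a candidate note
#'
#' The context prefix runs from a phrase-starting note up to but excluding
#' the target note, and is the shortest such prefix containing at least
#' one complete phrase, at least eight notes, and at least four distinct
#' pitches. A phrase counts as complete when the following phrase begins
#' within the prefix or at the target itself. When no qualifying prefix
#' exists a rejection value (not an error) is returned with the reason.
#'
#' @param corpus A [corpus()].
#' @param melody_id Id of the melody holding the target note.
#' @param note_index Position of the target note.
#' @param min_notes,min_pitches,min_phrases Context constraints.
#' @return A list of class `"stimulus_context"` (fields `prefix`,
#'   `target_pitch`, `target_index`, `start_index`, `melody_id`, `style`)
#'   or of class `"context_rejection"` (field `reason`).
#' @export
extract_candidate_context <- function(corpus, melody_id, note_index,
                                      min_notes = 8, min_pitches = 4,
                                      min_phrases = 1) {
  m <- corpus$melodies[[melody_id]]
  if (is.null(m)) stop("unknown melody id: ", melody_id, call. = FALSE)
  t_idx <- as.integer(note_index)
  if (t_idx < 2 || t_idx > nrow(m)) {
    return(context_rejection("target has no preceding context"))
  }
  phrase_starts <- which(m$phrase_start)
  starts <- rev(phrase_starts[phrase_starts <= t_idx - 1])
  if (length(starts) == 0) {
    return(context_rejection("no phrase start precedes the target"))
  }
  reason <- "context too short"
  for (s in starts) {
    prefix <- m[s:(t_idx - 1), , drop = FALSE]
    n_complete <- sum(vapply(
      intersect(phrase_starts, s:(t_idx - 1)),
      function(p) any(phrase_starts > p & phrase_starts <= t_idx),
      logical(1)
    ))
    ok_notes <- nrow(prefix) >= min_notes
    ok_pitch <- length(unique(prefix$pitch)) >= min_pitches
    ok_phrase <- n_complete >= min_phrases
    if (ok_notes && ok_pitch && ok_phrase) {
      return(structure(
        list(
          prefix = melody(prefix$pitch, prefix$onset, prefix$duration,
            prefix$phrase_start,
            id = paste0(melody_id, "@", t_idx),
            style = melody_style(m), key = melody_key(m),
            source = melody_id
          ),
          target_pitch = m$pitch[t_idx], target_index = t_idx,
          start_index = s, melody_id = melody_id, style = melody_style(m)
        ),
        class = "stimulus_context"
      ))
    }
    reason <- paste(c(
      if (!ok_notes) sprintf("fewer than %d notes", min_notes),
      if (!ok_pitch) sprintf("fewer than %d distinct pitches", min_pitches),
      if (!ok_phrase) "no complete phrase"
    ), collapse = "; ")
  }
  context_rejection(reason)
}

context_rejection <- function(reason) {
  structure(list(reason = reason), class = "context_rejection")
}

#' Assign the nine probe tones for a context
#'
#' Nine chromatically consecutive pitches centered on the context's median
#' pitch (an even-length median is rounded half down to a semitone),
#' displaced by the minimal number of semitones needed to include the
#' actual continuation pitch.
#'
#' @param prefix The context [melody()] (or any data frame with a `pitch`
#'   column).
#' @param target_pitch The actual continuation pitch.
#' @return Integer vector of 9 consecutive pitches containing
#'   `target_pitch`.
#' @export
assign_probe_tones <- function(prefix, target_pitch) {
  stopifnot(nrow(prefix) > 0)
  med <- ceiling(stats::median(prefix$pitch) - 0.5) # round half down
  lo <- med - 4L
  hi <- med + 4L
  shift <- 0L
  if (target_pitch < lo) shift <- target_pitch - lo
  if (target_pitch > hi) shift <- target_pitch - hi
  as.integer((lo:hi) + shift)
}

#' Final entropy-based stimulus selection
#'
#' Recomputes each candidate context's predictive distribution with the
#' key estimated from the context itself ([estimate_key()]), derives its
#' full-alphabet entropy and its 9-tone entropy (the distribution
#' renormalized over the probe tones), then picks, per cell of style by
#' entropy class, the `per_cell` candidates with the most extreme 9-tone
#' entropy (highest for "high" cells, lowest for "low"), skipping
#' candidates whose note span overlaps an already-selected stimulus from
#' the same melody.
#'
#' @param candidates List of `stimulus_context` objects carrying an
#'   `entropy_class` attribute, e.g. from [build_stimulus_set()]'s
#'   internals.
#' @param classes Character vector giving each candidate's entropy class
#'   (`"high"`/`"low"`), recycled against `candidates`.
#' @param alphabet Full pitch alphabet for prediction; probe tones outside
#'   it are unioned in per candidate.
#' @param ltm,config Model to evaluate the candidates with.
#' @param per_cell Stimuli per (style, entropy class) cell.
#' @return A tibble of class `"stimulus_set"`, one row per stimulus, with
#'   list-columns `prefix` and `probes`.
#' @export
select_stimulus_set <- function(candidates, classes, alphabet, ltm = NULL,
                                config = model_config(), per_cell = 6) {
  stopifnot(length(candidates) > 0)
  classes <- rep_len(classes, length(candidates))
  scored <- purrr::imap_dfr(candidates, function(cand, i) {
    stopifnot(inherits(cand, "stimulus_context"))
    probes <- assign_probe_tones(cand$prefix, cand$target_pitch)
    k_est <- estimate_key(cand$prefix, "temperley")
    alph <- sort(unique(c(alphabet, probes)))
    d <- predict_next(cand$prefix, k_est, alph,
      ltm = ltm, stm = stm_for_prefix(cand$prefix, k_est, config),
      config = config
    )
    h_full <- entropy_bits(d)
    h_9 <- entropy_bits(renormalize_subset(d, probes))
    tibble::tibble(
      cand_index = i, melody_id = cand$melody_id, style = cand$style,
      entropy_class = classes[i],
      start_index = cand$start_index, target_index = cand$target_index,
      target_pitch = cand$target_pitch,
      probes = list(probes),
      entropy_full = h_full,
      entropy_9 = h_9,
      key_tonic = k_est$tonic, key_mode = k_est$mode,
      key_source = "estimated",
      prefix = list(cand$prefix)
    )
  })
  cells <- tidyr::expand_grid(
    style = unique(scored$style), entropy_class = c("high", "low")
  )
  chosen <- purrr::pmap_dfr(cells, function(style, entropy_class) {
    pool <- scored[scored$style == style & scored$entropy_class == entropy_class, ]
    pool <- if (entropy_class == "high") {
      dplyr::arrange(pool, dplyr::desc(.data$entropy_9), .data$melody_id, .data$target_index)
    } else {
      dplyr::arrange(pool, .data$entropy_9, .data$melody_id, .data$target_index)
    }
    taken <- pool[0, ]
    for (j in seq_len(nrow(pool))) {
      row <- pool[j, ]
      overlap <- any(
        taken$melody_id == row$melody_id &
          taken$start_index <= row$target_index &
          taken$target_index >= row$start_index
      )
      if (!overlap) taken <- dplyr::bind_rows(taken, row)
      if (nrow(taken) == per_cell) break
    }
    if (nrow(taken) < per_cell) {
      stop("insufficient candidates in cell ", style, "/", entropy_class,
        call. = FALSE
      )
    }
    taken
  })
  chosen$stimulus_id <- sprintf(
    "%s_%s_%02d", substr(chosen$style, 1, 4), chosen$entropy_class,
    seq_len(nrow(chosen))
  )
  structure(
    dplyr::select(chosen, "stimulus_id", dplyr::everything(), -"cand_index"),
    class = c("stimulus_set", class(tibble::tibble()))
  )
}

# the STM component of a context prediction: expose the model to the
# prefix itself, then predict the continuation
stm_for_prefix <- function(prefix, key, config) {
  if (!(config$configuration %in% c("stm", "both"))) {
    return(NULL)
  }
  stm <- ngram_store(config$order_bound)
  syms <- derive_viewpoints(prefix, key, config$include_ioi_contour)$symbol
  store_add_sequence(stm, syms, config$update_exclusion)
}

#' Run the full two-stage stimulus-selection pipeline
#'
#' Scores every corpus note ([score_corpus_notes()]), takes the
#' `k_per_extreme` highest- and lowest-entropy notes per style
#' ([select_candidate_notes()]), extracts qualifying candidate contexts
#' ([extract_candidate_context()]), assigns probe tones and performs the
#' final 9-tone-entropy selection ([select_stimulus_set()]).
#'
#' @inheritParams score_corpus_notes
#' @param k_per_extreme Candidate notes per extreme per style.
#' @param per_cell Final stimuli per (style, entropy class) cell.
#' @param min_context_notes Notes that must precede a target for it to be
#'   a candidate (segmentation cannot produce a qualifying context
#'   otherwise).
#' @return A `stimulus_set` tibble; the per-note score table and rejection
#'   reasons are attached as attributes `scores` and `rejections`.
#' @export
build_stimulus_set <- function(corpus, ltm = NULL, config = model_config(),
                               k_per_extreme = 18, per_cell = 6,
                               key_source = "stored",
                               min_context_notes = 8) {
  scores <- score_corpus_notes(corpus, ltm, config, key_source = key_source)
  eligible <- dplyr::filter(scores, .data$note_index > min_context_notes)
  cand_notes <- select_candidate_notes(eligible, k_per_extreme)
  extracted <- purrr::pmap(
    list(cand_notes$melody_id, cand_notes$note_index, cand_notes$entropy_class),
    function(mid, idx, cls) {
      ctx <- extract_candidate_context(corpus, mid, idx)
      list(ctx = ctx, class = cls, melody_id = mid, note_index = idx)
    }
  )
  keep <- purrr::map_lgl(extracted, ~ inherits(.x$ctx, "stimulus_context"))
  rejections <- purrr::map_dfr(extracted[!keep], ~ tibble::tibble(
    melody_id = .x$melody_id, note_index = .x$note_index,
    reason = .x$ctx$reason
  ))
  alphabet <- corpus_alphabet(corpus, config$alphabet_policy)
  set <- select_stimulus_set(
    purrr::map(extracted[keep], "ctx"),
    purrr::map_chr(extracted[keep], "class"),
    alphabet, ltm, config, per_cell
  )
  attr(set, "scores") <- scores
  attr(set, "rejections") <- rejections
  set
}

#' Serialize / restore a stimulus set as JSON
#'
#' Context note tables are inlined so the file is self-contained.
#'
#' @param set A `stimulus_set`.
#' @param path JSON path.
#' @return `path` invisibly / the restored `stimulus_set`.
#' @export
write_stimulus_set <- function(set, path) {
  entries <- purrr::map(seq_len(nrow(set)), function(i) {
    row <- set[i, ]
    list(
      stimulus_id = row$stimulus_id, melody_id = row$melody_id,
      style = row$style, entropy_class = row$entropy_class,
      start_index = row$start_index, target_index = row$target_index,
      target_pitch = row$target_pitch, probes = row$probes[[1]],
      entropy_full = row$entropy_full, entropy_9 = row$entropy_9,
      key = list(
        tonic = row$key_tonic, mode = row$key_mode,
        source = row$key_source
      ),
      prefix = as.data.frame(row$prefix[[1]])
    )
  })
  jsonlite::write_json(list(format = "melent-stimuli-1", stimuli = entries),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_stimulus_set
#' @export
read_stimulus_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!identical(obj$format, "melent-stimuli-1")) {
    stop("not a melent stimulus set: ", path, call. = FALSE)
  }
  s <- obj$stimuli
  structure(
    tibble::tibble(
      stimulus_id = s$stimulus_id, melody_id = s$melody_id, style = s$style,
      entropy_class = s$entropy_class, start_index = s$start_index,
      target_index = s$target_index, target_pitch = s$target_pitch,
      probes = purrr::map(s$probes, as.integer),
      entropy_full = s$entropy_full, entropy_9 = s$entropy_9,
      key_tonic = s$key$tonic, key_mode = s$key$mode,
      key_source = s$key$source,
      prefix = purrr::map(s$prefix, function(df) {
        melody(df$pitch, df$onset, df$duration, df$phrase_start)
      })
    ),
    class = c("stimulus_set", class(tibble::tibble()))
  )
}
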