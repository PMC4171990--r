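#' Construct a melody
#'
#' A melody is a tibble of ordered note events with columns `pitch`
#' (chromatic pitch number, middle C = 60), `onset` (beats, quarter note =
#' 1), `duration` (beats, > 0) and `phrase_start` (logical). Time is kept in
#' abstract beat units throughout; performance tempo is presentational and
#' out of scope.
#'
#' @param pitch Integer vector of chromatic pitch numbers.
#' @param onset Numeric vector of onsets in beats, non-decreasing.
#' @param duration Positive numeric vector of durations in beats.
#' @param phrase_start Logical vector; the first event must start a phrase.
#'   Defaults to `TRUE` for the first event only.
#' @param id,style,source Provenance fields stored as attributes. `style`
#'   is one of `"simple"`, `"complex"`, `"synthetic"`.
#' @param key Optional [key()] attached as the notated key.
#' @param pitch_range Permitted pitch range (inclusive) for validation.
#' @return A tibble of class `"melody"`.
#' @examples
#' melody(c(60, 62, 64), 0:2, rep(1, 3))
#' @export
melody <- function(pitch, onset = seq_along(pitch) - 1,
                   duration = rep(1, length(pitch)),
                   phrase_start = NULL,
                   id = "melody", style = "synthetic", key = NULL,
                   source = "constructed", pitch_range = c(21L, 108L)) {
  n <- length(pitch)
  if (n < 1) stop("a melody must contain at least one event", call. = FALSE)
  if (is.null(phrase_start)) phrase_start <- c(TRUE, rep(FALSE, n - 1))
  m <- tibble::tibble(
    pitch = as.integer(pitch),
    onset = as.numeric(onset),
    duration = as.numeric(duration),
    phrase_start = as.logical(phrase_start)
  )
  validate_melody(m, pitch_range = pitch_range)
  if (!m$phrase_start[1]) stop("the first event must start a phrase", call. = FALSE)
  structure(m,
    class = c("melody", class(m)),
    id = id, style = style, key = key, source = source
  )
}

validate_melody <- function(m, pitch_range = c(21L, 108L)) {
  req <- c("pitch", "onset", "duration", "phrase_start")
  missing_cols <- setdiff(req, names(m))
  if (length(missing_cols) > 0) {
    stop("melody format error: missing column(s) ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(m) == 0) stop("a melody must contain at least one event", call. = FALSE)
  bad <- which(!(m$duration > 0))
  if (length(bad) > 0) {
    stop("non-positive duration at row ", bad[1], call. = FALSE)
  }
  if (is.unsorted(m$onset)) stop("onsets must be non-decreasing", call. = FALSE)
  out_of_range <- which(m$pitch < pitch_range[1] | m$pitch > pitch_range[2])
  if (length(out_of_range) > 0) {
    stop("pitch out of range [", pitch_range[1], ", ", pitch_range[2],
      "] at row ", out_of_range[1],
      call. = FALSE
    )
  }
  invisible(m)
}

melody_id <- function(m) attr(m, "id") %||% "melody"
melody_style <- function(m) attr(m, "style") %||% "synthetic"
melody_key <- function(m) attr(m, "key")

#' Read a melody from a plain-text note table
#'
#' The note-table format is a UTF-8 CSV with a header row and columns
#' `pitch`, `onset`, `duration`, `phrase_start`; chosen so fixtures diff
#' cleanly under version control.
#'
#' @param path Path to the CSV file.
#' @param id,style,key Passed to [melody()].
#' @return A [melody()].
#' @seealso [write_note_table()]
#' @export
read_note_table <- function(path, id = basename(path), style = "synthetic",
                            key = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("pitch", "onset", "duration", "phrase_start")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("note table format error: missing column(s) ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(df) == 0) stop("note table is empty: ", path, call. = FALSE)
  melody(df$pitch, df$onset, df$duration, as.logical(df$phrase_start),
    id = id, style = style, key = key, source = path
  )
}

#' Write a melody as a plain-text note table
#'
#' @param m A [melody()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_note_table <- function(m, path) {
  validate_melody(m)
  utils::write.csv(
    as.data.frame(m[, c("pitch", "onset", "duration", "phrase_start")]),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Infer phrase boundaries from rests
#'
#' Sets `phrase_start` to `TRUE` for the first event and for every event
#' whose gap since the previous event's offset (onset + duration) is at
#' least `gap_threshold` beats; all other flags are cleared. The source
#' encodings this rule stands in for mark phrases explicitly; a rest-gap
#' rule is used when flags are absent (hymn-style encodings separate
#' phrases with rests).
#'
#' @param m A [melody()].
#' @param gap_threshold Minimum silent gap in beats (> 0); default 1 beat.
#' @return The melody with recomputed `phrase_start`.
#' @export
infer_phrases <- function(m, gap_threshold = 1) {
  validate_melody(m)
  stopifnot(gap_threshold > 0)
  n <- nrow(m)
  flags <- rep(FALSE, n)
  flags[1] <- TRUE
  if (n > 1) {
    gap <- m$onset[-1] - (m$onset[-n] + m$duration[-n])
    flags[-1] <- gap >= gap_threshold
  }
  m$phrase_start <- flags
  m
}

#' Assemble a corpus of melodies
#'
#' A corpus holds a list of melodies together with its pitch alphabet, the
#' sorted set of distinct pitches occurring anywhere in the corpus. The
#' alphabet size is the `n` entering maximum entropy `log2(n)`.
#'
#' @param melodies A list of [melody()] objects.
#' @return An object of class `"melody_corpus"`.
#' @export
corpus <- function(melodies) {
  if (!is.list(melodies) || length(melodies) == 0) {
    stop("a corpus needs at least one melody", call. = FALSE)
  }
  melodies <- purrr::imap(melodies, function(m, i) {
    validate_melody(m)
    if (is.null(attr(m, "id"))) attr(m, "id") <- paste0("mel", i)
    m
  })
  ids <- purrr::map_chr(melodies, melody_id)
  if (anyDuplicated(ids)) stop("melody ids must be unique", call. = FALSE)
  names(melodies) <- ids
  structure(
    list(
      melodies = melodies,
      alphabet = sort(unique(unlist(purrr::map(melodies, "pitch"))))
    ),
    class = "melody_corpus"
  )
}

#' @export
print.melody_corpus <- function(x, ...) {
  cat(
    "<melody_corpus> ", length(x$melodies), " melodies, ",
    sum(purrr::map_int(x$melodies, nrow)), " notes, alphabet of ",
    length(x$alphabet), " pitches [", pitch_name(min(x$alphabet)), "-",
    pitch_name(max(x$alphabet)), "]\n",
    sep = ""
  )
  invisible(x)
}

#' Corpus notes as one tidy table
#'
#' @param corpus A [corpus()].
#' @return A tibble with columns `melody_id`, `style`, `note_index` and the
#'   note-event columns.
#' @export
corpus_notes <- function(corpus) {
  stopifnot(inherits(corpus, "melody_corpus"))
  purrr::map_dfr(corpus$melodies, function(m) {
    tibble::tibble(
      melody_id = melody_id(m), style = melody_style(m),
      note_index = seq_len(nrow(m)),
      pitch = m$pitch, onset = m$onset, duration = m$duration,
      phrase_start = m$phrase_start
    )
  })
}

#' Pitch alphabet under a policy
#'
#' The `"corpus"` policy uses exactly the pitches observed; the
#' `"chromatic_span"` policy fills the corpus range chromatically so that,
#' e.g., a corpus spanning B2-B5 yields the full 37-pitch chromatic span.
#'
#' @param corpus A [corpus()].
#' @param policy `"corpus"` or `"chromatic_span"`.
#' @param include Extra pitches (e.g. stimulus continuations) unioned in
#'   before the policy is applied.
#' @return Sorted integer vector of pitches.
#' @export
corpus_alphabet <- function(corpus, policy = c("corpus", "chromatic_span"),
                            include = integer(0)) {
  policy <- match.arg(policy)
  pitches <- sort(unique(c(corpus$alphabet, as.integer(include))))
  if (policy == "chromatic_span") pitches <- seq(min(pitches), max(pitches))
  pitches
}

#' Read / write a corpus manifest
#'
#' A corpus manifest is a JSON file listing note-table files with style
#' labels and optional notated keys, relative to the manifest's directory.
#'
#' @param path Manifest path.
#' @return [read_corpus_manifest()] returns a [corpus()];
#'   [write_corpus_manifest()] returns `path` invisibly after writing the
#'   melodies as note tables next to the manifest.
#' @export
read_corpus_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  man <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(path)
  mels <- purrr::map(man$melodies, function(e) {
    k <- if (!is.null(e$key)) key(e$key$tonic, e$key$mode)
    read_note_table(file.path(base, e$file),
      id = e$id %||% basename(e$file),
      style = e$style %||% "synthetic", key = k
    )
  })
  corpus(mels)
}

#' @rdname read_corpus_manifest
#' @param corpus A [corpus()] to serialize.
#' @export
write_corpus_manifest <- function(corpus, path) {
  stopifnot(inherits(corpus, "melody_corpus"))
  base <- dirname(path)
  entries <- purrr::map(corpus$melodies, function(m) {
    f <- paste0(melody_id(m), ".csv")
    write_note_table(m, file.path(base, f))
    e <- list(id = melody_id(m), file = f, style = melody_style(m))
    k <- melody_key(m)
    if (!is.null(k)) e$key <- list(tonic = k$tonic, mode = k$mode)
    e
  })
  jsonlite::write_json(list(melodies = unname(entries)), path,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Scientific pitch names
#'
#' Display helpers mapping chromatic pitch numbers to scientific pitch
#' notation (B2 = 47, middle C = C4 = 60, B5 = 83).
#'
#' @param pitch Integer vector of chromatic pitch numbers.
#' @return Character vector of names like `"C4"`, `"F#5"`.
#' @examples
#' pitch_name(c(47, 60, 83)) # "B2" "C4" "B5"
#' @export
pitch_name <- function(pitch) {
  nm <- c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "A#", "B")
  paste0(nm[pitch %% 12 + 1], pitch %/% 12 - 1)
}
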