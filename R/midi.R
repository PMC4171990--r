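# Minimal Standard MIDI File (SMF type 0/1) support for monophonic
# melodies. Times are converted to beats via the file's ticks-per-quarter
# resolution; tempo meta events are presentation-only and ignored.

midi_vlq_encode <- function(x) {
  stopifnot(x >= 0)
  bytes <- as.raw(x %% 128L)
  x <- x %/% 128L
  while (x > 0) {
    bytes <- c(as.raw(bitwOr(x %% 128L, 128L)), bytes)
    x <- x %/% 128L
  }
  bytes
}

midi_vlq_decode <- function(bytes, pos) {
  val <- 0
  repeat {
    b <- as.integer(bytes[pos])
    pos <- pos + 1L
    val <- val * 128 + bitwAnd(b, 127L)
    if (b < 128L) break
  }
  list(value = val, pos = pos)
}

midi_uint <- function(bytes, pos, n) {
  sum(as.integer(bytes[pos:(pos + n - 1L)]) * 256^((n - 1L):0))
}

#' Write a melody as a MIDI file
#'
#' Emits a single-track (type 0) file with one note-on/note-off pair per
#' event on channel 1, at the given tick resolution.
#'
#' @param m A [melody()].
#' @param path Output path.
#' @param division Ticks per quarter note.
#' @param velocity Note-on velocity (1-127).
#' @return `path`, invisibly.
#' @export
write_midi_melody <- function(m, path, division = 480L, velocity = 64L) {
  validate_melody(m)
  ticks_on <- round(m$onset * division)
  ticks_off <- round((m$onset + m$duration) * division)
  ev <- rbind(
    data.frame(tick = ticks_on, on = TRUE, pitch = m$pitch),
    data.frame(tick = ticks_off, on = FALSE, pitch = m$pitch)
  )
  # offs sort before ons at the same tick so repeated pitches re-articulate
  ev <- ev[order(ev$tick, ev$on), ]
  track <- raw(0)
  last <- 0
  for (i in seq_len(nrow(ev))) {
    delta <- ev$tick[i] - last
    last <- ev$tick[i]
    status <- if (ev$on[i]) 0x90L else 0x80L
    vel <- if (ev$on[i]) velocity else 0L
    track <- c(
      track, midi_vlq_encode(delta),
      as.raw(c(status, ev$pitch[i], vel))
    )
  }
  track <- c(track, as.raw(c(0x00, 0xFF, 0x2F, 0x00))) # end of track
  int_bytes <- function(x, n) as.raw((x %/% 256^((n - 1L):0)) %% 256L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("MThd"), con)
  writeBin(int_bytes(6L, 4L), con)
  writeBin(int_bytes(0L, 2L), con) # format 0
  writeBin(int_bytes(1L, 2L), con) # one track
  writeBin(int_bytes(division, 2L), con)
  writeBin(charToRaw("MTrk"), con)
  writeBin(int_bytes(length(track), 4L), con)
  writeBin(track, con)
  invisible(path)
}

#' Read a monophonic melody from a MIDI file
#'
#' Parses SMF type 0 or 1, selects one track, pairs note-on/note-off
#' events into note events, converts ticks to beats via the header
#' resolution, and infers phrase boundaries from rest gaps with
#' [infer_phrases()].
#'
#' @param path Path to a `.mid` file.
#' @param track_policy `"first_with_notes"` or a 1-based track index.
#' @param gap_threshold Passed to [infer_phrases()].
#' @param id,style Provenance for the returned [melody()].
#' @return A [melody()].
#' @export
read_midi_melody <- function(path, track_policy = "first_with_notes",
                             gap_threshold = 1, id = basename(path),
                             style = "synthetic") {
  if (!file.exists(path)) stop("cannot read MIDI file: ", path, call. = FALSE)
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 14 || rawToChar(bytes[1:4]) != "MThd") {
    stop("cannot read MIDI file: ", path, " (bad header)", call. = FALSE)
  }
  n_tracks <- midi_uint(bytes, 11L, 2L)
  division <- midi_uint(bytes, 13L, 2L)
  if (division >= 32768) {
    stop("SMPTE time division is not supported", call. = FALSE)
  }
  pos <- 15L
  tracks <- vector("list", n_tracks)
  for (tr in seq_len(n_tracks)) {
    if (rawToChar(bytes[pos:(pos + 3L)]) != "MTrk") {
      stop("cannot read MIDI file: malformed track chunk", call. = FALSE)
    }
    len <- midi_uint(bytes, pos + 4L, 4L)
    tracks[[tr]] <- parse_midi_track(bytes, pos + 8L, len)
    pos <- pos + 8L + len
  }
  notes_per_track <- purrr::map_int(tracks, nrow)
  tr_idx <- if (identical(track_policy, "first_with_notes")) {
    idx <- which(notes_per_track > 0)
    if (length(idx) == 0) stop("MIDI file contains no notes", call. = FALSE)
    idx[1]
  } else {
    as.integer(track_policy)
  }
  notes <- tracks[[tr_idx]]
  if (nrow(notes) == 0) stop("selected track contains no notes", call. = FALSE)
  notes <- notes[order(notes$on_tick, notes$pitch), ]
  if (any(notes$on_tick[-1] < notes$off_tick[-nrow(notes)])) {
    stop("unsupported content: polyphony in selected track", call. = FALSE)
  }
  m <- melody(notes$pitch,
    onset = notes$on_tick / division,
    duration = pmax(notes$off_tick - notes$on_tick, 1) / division,
    id = id, style = style, source = path
  )
  infer_phrases(m, gap_threshold = gap_threshold)
}

parse_midi_track <- function(bytes, start, len) {
  pos <- start
  end <- start + len
  tick <- 0
  status <- 0L
  active <- list() # pitch -> on tick
  notes <- list()
  while (pos < end) {
    d <- midi_vlq_decode(bytes, pos)
    tick <- tick + d$value
    pos <- d$pos
    b <- as.integer(bytes[pos])
    if (b >= 128L) {
      status <- b
      pos <- pos + 1L
    }
    hi <- bitwAnd(status, 0xF0L)
    if (status == 0xFFL) { # meta
      meta_len <- midi_vlq_decode(bytes, pos + 1L)
      pos <- meta_len$pos + meta_len$value
    } else if (status == 0xF0L || status == 0xF7L) { # sysex
      sl <- midi_vlq_decode(bytes, pos)
      pos <- sl$pos + sl$value
    } else if (hi == 0x90L || hi == 0x80L) {
      pitch <- as.integer(bytes[pos])
      vel <- as.integer(bytes[pos + 1L])
      pos <- pos + 2L
      keyc <- as.character(pitch)
      if (hi == 0x90L && vel > 0L) {
        if (!is.null(active[[keyc]])) {
          stop("unsupported content: overlapping notes of equal pitch",
            call. = FALSE
          )
        }
        active[[keyc]] <- tick
      } else {
        if (!is.null(active[[keyc]])) {
          notes[[length(notes) + 1L]] <- data.frame(
            pitch = pitch, on_tick = active[[keyc]], off_tick = tick
          )
          active[[keyc]] <- NULL
        }
      }
    } else if (hi %in% c(0xA0L, 0xB0L, 0xE0L)) {
      pos <- pos + 2L
    } else if (hi %in% c(0xC0L, 0xD0L)) {
      pos <- pos + 1L
    } else {
      stop("cannot read MIDI file: unknown status byte", call. = FALSE)
    }
  }
  if (length(notes) == 0) {
    return(data.frame(
      pitch = integer(0), on_tick = numeric(0),
      off_tick = numeric(0)
    ))
  }
  do.call(rbind, notes)
}
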