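#' Build a single-side movement-event track
#'
#' An event track holds every scored movement of one mantle-lure flap as a
#' frame interval: `start_frame` is the first frame where contraction of the
#' mantle tissue is visible, `end_frame` the frame where the lure is back at
#' rest. Frames are 0-based and the interval is closed, so a movement occupies
#' `[start_frame, end_frame]` inclusive.
#'
#' Start frames must be strictly increasing (two movements of one flap cannot
#' begin on the same frame); event bodies may overlap the next start, which is
#' accepted with a warning because annotators do score re-contractions before
#' the lure has fully relaxed.
#'
#' @param side `"left"` or `"right"`.
#' @param start_frame,end_frame integer vectors of equal length, non-negative,
#'   with `end_frame >= start_frame` elementwise.
#' @param warn_overlap emit a warning when an event's body overlaps the next
#'   event's start.
#' @return an object of class `event_track`: a list with `side` and `events`
#'   (a data.frame with columns `start_frame`, `end_frame`, sorted by start).
#' @export
event_track <- function(side, start_frame = integer(), end_frame = integer(),
                        warn_overlap = TRUE) {
  side <- match.arg(side, c("left", "right"))
  if (length(start_frame) != length(end_frame)) {
    stop("start_frame and end_frame must have equal length")
  }
  start_frame <- as.numeric(start_frame)
  end_frame <- as.numeric(end_frame)
  if (length(start_frame)) {
    bad <- which(
      is.na(start_frame) | is.na(end_frame) |
        start_frame < 0 | end_frame < 0 |
        start_frame != trunc(start_frame) | end_frame != trunc(end_frame)
    )
    if (length(bad)) {
      stop("frames must be non-negative integers (event ", bad[1L], " on the ",
           side, " side)")
    }
    bad <- which(end_frame < start_frame)
    if (length(bad)) {
      stop("end_frame < start_frame for event ", bad[1L], " on the ", side,
           " side (start ", start_frame[bad[1L]], ", end ", end_frame[bad[1L]], ")")
    }
    ord <- order(start_frame)
    start_frame <- start_frame[ord]
    end_frame <- end_frame[ord]
    if (anyDuplicated(start_frame)) {
      dup <- start_frame[duplicated(start_frame)][1L]
      stop("duplicate start_frame ", dup, " on the ", side, " side")
    }
    n <- length(start_frame)
    if (warn_overlap && n > 1L && any(start_frame[-1L] <= end_frame[-n])) {
      warning("overlapping events on the ", side,
              " side (next start <= previous end); accepted", call. = FALSE)
    }
  }
  structure(
    list(side = side,
         events = data.frame(start_frame = start_frame, end_frame = end_frame)),
    class = "event_track"
  )
}

#' @export
length.event_track <- function(x) nrow(x$events)

#' @export
print.event_track <- function(x, ...) {
  cat("<event_track> side =", x$side, "with", nrow(x$events), "events\n")
  invisible(x)
}

#' Build a display recording
#'
#' One individual's annotated display: left and right event tracks plus the
#' recording metadata. All events must fall inside the analysis window
#' `[analysis_start_frame, analysis_start_frame + analysis_length_frames)`.
#'
#' @param recording_id recording identifier.
#' @param left,right `event_track` objects for the two flaps.
#' @param species species label, e.g. `"L. fasciola"`.
#' @param morph lure morph: `"darter"`, `"leech"`, or `"none"` (for the
#'   monomorphic congener).
#' @param site,date free-text site and ISO-8601 date.
#' @param water_temp_c water temperature in degrees Celsius, or `NA`.
#' @param fps recording frame rate (frames/s), default 120.
#' @param analysis_start_frame first frame of the scored window (default 5000,
#'   skipping camera set-up shake).
#' @param analysis_length_frames length of the scored window in frames
#'   (default 20000, i.e. 2.8 min at 120 fps).
#' @return an object of class `display_recording`.
#' @export
display_recording <- function(recording_id, left, right,
                              species = "L. fasciola",
                              morph = c("darter", "leech", "none"),
                              site = NA_character_, date = NA_character_,
                              water_temp_c = NA_real_, fps = 120,
                              analysis_start_frame = 5000,
                              analysis_length_frames = 20000) {
  morph <- match.arg(morph)
  stopifnot(inherits(left, "event_track"), inherits(right, "event_track"))
  if (left$side != "left" || right$side != "right") {
    stop("`left` must be a left-side track and `right` a right-side track")
  }
  if (!is.numeric(fps) || fps <= 0) stop("fps must be > 0")
  if (analysis_length_frames <= 0) stop("analysis_length_frames must be > 0")
  lo <- analysis_start_frame
  hi <- analysis_start_frame + analysis_length_frames
  for (tr in list(left, right)) {
    ev <- tr$events
    bad <- which(ev$start_frame < lo | ev$end_frame >= hi)
    if (length(bad)) {
      stop("recording ", recording_id, ": ", tr$side, " event starting at frame ",
           ev$start_frame[bad[1L]], " lies outside the analysis window [",
           lo, ", ", hi, ")")
    }
  }
  structure(
    list(recording_id = as.character(recording_id), species = species,
         morph = morph, site = site, date = date,
         water_temp_c = as.numeric(water_temp_c), fps = fps,
         analysis_start_frame = analysis_start_frame,
         analysis_length_frames = analysis_length_frames,
         left = left, right = right),
    class = "display_recording"
  )
}

#' @export
print.display_recording <- function(x, ...) {
  cat("<display_recording>", x$recording_id, "-", x$species,
      paste0("(", x$morph, " morph)"), "\n")
  cat("  left:", nrow(x$left$events), "events; right:",
      nrow(x$right$events), "events;", x$fps, "fps; window [",
      x$analysis_start_frame, ",",
      x$analysis_start_frame + x$analysis_length_frames, ")\n")
  invisible(x)
}

.metadata_cols <- c("recording_id", "species", "morph", "site", "date",
                    "water_temp_c", "fps", "analysis_start_frame",
                    "analysis_length_frames")

#' Read movement-event tables into display recordings
#'
#' Reads a delimited events table (columns `recording_id`, `side`,
#' `start_frame`, `end_frame`; one row per movement) and, optionally, a
#' metadata table keyed by `recording_id`, and assembles validated
#' [display_recording()] objects. Events are sorted by start frame within each
#' side; parsing never reorders them otherwise.
#'
#' @param path events file path.
#' @param metadata optional metadata file path (columns `recording_id`,
#'   `species`, `morph`, `site`, `date`, `water_temp_c`, `fps`,
#'   `analysis_start_frame`, `analysis_length_frames`).
#' @param sep field separator; `","` (default) or `"\t"`.
#' @return a named list of `display_recording` objects (empty list for an
#'   empty file).
#' @export
read_events <- function(path, metadata = NULL, sep = ",") {
  if (!file.exists(path)) stop("events file not found: ", path)
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) return(list())
  ev <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("recording_id", "side", "start_frame", "end_frame")
  if (nrow(ev) == 0 && ncol(ev) == 0) return(list())
  miss <- setdiff(need, names(ev))
  if (length(miss)) {
    stop("events file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  for (col in c("start_frame", "end_frame")) {
    v <- suppressWarnings(as.numeric(ev[[col]]))
    bad <- which(is.na(v) & !is.na(ev[[col]]) | is.na(ev[[col]]))
    if (length(bad)) {
      stop("malformed ", col, " in ", path, " at line ", bad[1L] + 1L,
           " (value: ", ev[[col]][bad[1L]], ")")
    }
    ev[[col]] <- v
  }
  bad <- which(!ev$side %in% c("left", "right"))
  if (length(bad)) {
    stop("malformed side in ", path, " at line ", bad[1L] + 1L,
         " (value: ", ev$side[bad[1L]], ")")
  }
  bad <- which(ev$end_frame < ev$start_frame)
  if (length(bad)) {
    stop("end_frame < start_frame in ", path, " at line ", bad[1L] + 1L,
         " (recording ", ev$recording_id[bad[1L]], ")")
  }
  dup <- duplicated(ev[c("recording_id", "side", "start_frame")])
  if (any(dup)) {
    i <- which(dup)[1L]
    stop("duplicate (recording_id, side, start_frame) in ", path, " at line ",
         i + 1L, " (recording ", ev$recording_id[i], ", side ", ev$side[i],
         ", start ", ev$start_frame[i], ")")
  }

  md <- NULL
  if (!is.null(metadata)) {
    md <- utils::read.table(metadata, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    miss <- setdiff(c("recording_id"), names(md))
    if (length(miss)) stop("metadata file is missing column recording_id")
    if (anyDuplicated(md$recording_id)) {
      stop("metadata file has duplicate recording_id")
    }
  }

  ids <- unique(ev$recording_id)
  if (!is.null(md)) ids <- unique(c(ids, md$recording_id))
  recs <- lapply(ids, function(id) {
    sub <- ev[ev$recording_id == id, , drop = FALSE]
    tr <- lapply(c("left", "right"), function(s) {
      ss <- sub[sub$side == s, , drop = FALSE]
      event_track(s, ss$start_frame, ss$end_frame)
    })
    args <- list(recording_id = id, left = tr[[1L]], right = tr[[2L]])
    if (!is.null(md) && id %in% md$recording_id) {
      row <- md[md$recording_id == id, , drop = FALSE]
      for (f in setdiff(.metadata_cols, "recording_id")) {
        if (f %in% names(row) && !is.na(row[[f]])) args[[f]] <- row[[f]]
      }
    }
    do.call(display_recording, args)
  })
  names(recs) <- ids
  recs
}

#' Write display recordings back to delimited text
#'
#' Inverse of [read_events()]: emits the events table and (optionally) the
#' metadata table in the package's interchange schema, so that
#' `read_events(write_events(x))` round-trips.
#'
#' @param recordings a list of `display_recording` objects.
#' @param path events file path to write.
#' @param metadata optional metadata file path to write.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_events <- function(recordings, path, metadata = NULL, sep = ",") {
  if (inherits(recordings, "display_recording")) recordings <- list(recordings)
  rows <- lapply(recordings, function(r) {
    do.call(rbind, lapply(list(r$left, r$right), function(tr) {
      if (!nrow(tr$events)) return(NULL)
      data.frame(recording_id = r$recording_id, side = tr$side,
                 start_frame = tr$events$start_frame,
                 end_frame = tr$events$end_frame)
    }))
  })
  ev <- do.call(rbind, rows)
  if (is.null(ev)) {
    ev <- data.frame(recording_id = character(), side = character(),
                     start_frame = numeric(), end_frame = numeric())
  }
  utils::write.table(ev, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(metadata)) {
    md <- do.call(rbind, lapply(recordings, function(r) {
      data.frame(recording_id = r$recording_id, species = r$species,
                 morph = r$morph, site = r$site, date = r$date,
                 water_temp_c = r$water_temp_c, fps = r$fps,
                 analysis_start_frame = r$analysis_start_frame,
                 analysis_length_frames = r$analysis_length_frames)
    }))
    utils::write.table(md, metadata, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
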