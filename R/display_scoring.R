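#' Classify left-right synchronization of lure movements
#'
#' Two movements are synchronized when their start frames differ by at most
#' `tolerance_frames` (inclusive; 4 frames at 120 fps is 1/30 s). Matching is
#' greedy and chronological: left events are swept in start order and each is
#' paired with the earliest not-yet-matched right event within tolerance; each
#' event participates in at most one pair. Unmatched events are counted as
#' one-sided. The proportion synchronized is
#' `n_sync / (n_sync + n_left_only + n_right_only)`, and is `NA` when a
#' recording has no movements at all (no display, rather than a display that
#' never synchronized).
#'
#' @param left,right `event_track` objects for the two sides.
#' @param tolerance_frames non-negative integer matching tolerance (default 4).
#' @return an object of class `sync_score`: list with `pairs` (two-column
#'   matrix of left/right event indices), `n_sync`, `n_left_only`,
#'   `n_right_only`, `proportion_sync`, `tolerance_frames`.
#' @export
classify_synchrony <- function(left, right, tolerance_frames = 4) {
  stopifnot(inherits(left, "event_track"), inherits(right, "event_track"))
  if (left$side == right$side) {
    stop("both tracks are '", left$side, "' tracks; need one left and one right")
  }
  if (left$side == "right") { tmp <- left; left <- right; right <- tmp }
  if (tolerance_frames < 0) stop("tolerance_frames must be >= 0")
  ls <- left$events$start_frame
  rs <- right$events$start_frame
  used <- logical(length(rs))
  pl <- integer(0)
  pr <- integer(0)
  for (i in seq_along(ls)) {
    cand <- which(!used & abs(rs - ls[i]) <= tolerance_frames)
    if (length(cand)) {
      j <- cand[1L] # right starts are strictly increasing: first = earliest
      used[j] <- TRUE
      pl <- c(pl, i)
      pr <- c(pr, j)
    }
  }
  n_sync <- length(pl)
  n_left_only <- length(ls) - n_sync
  n_right_only <- length(rs) - n_sync
  denom <- n_sync + n_left_only + n_right_only
  structure(
    list(pairs = cbind(left = pl, right = pr),
         n_sync = n_sync, n_left_only = n_left_only,
         n_right_only = n_right_only,
         proportion_sync = if (denom > 0) n_sync / denom else NA_real_,
         tolerance_frames = tolerance_frames),
    class = "sync_score"
  )
}

#' @export
print.sync_score <- function(x, ...) {
  cat("<sync_score> sync:", x$n_sync, " left-only:", x$n_left_only,
      " right-only:", x$n_right_only, "\n")
  cat("  proportion synchronized:",
      if (is.na(x$proportion_sync)) "NA (no movements)"
      else sprintf("%.3f", x$proportion_sync),
      " (tolerance", x$tolerance_frames, "frames)\n")
  invisible(x)
}

#' Start-to-start intervals between consecutive movements of one flap
#'
#' @param track an `event_track`.
#' @param fps frames per second.
#' @return numeric vector of `(start[i+1] - start[i]) / fps`, in seconds;
#'   empty when the track has fewer than two events.
#' @export
movement_intervals <- function(track, fps) {
  stopifnot(inherits(track, "event_track"))
  s <- track$events$start_frame
  if (length(s) < 2L) return(numeric(0))
  frames_to_seconds(diff(s), fps)
}

#' Start-to-end durations of each movement of one flap
#'
#' @inheritParams movement_intervals
#' @return numeric vector of `(end - start) / fps` per event, in seconds.
#' @export
movement_durations <- function(track, fps) {
  stopifnot(inherits(track, "event_track"))
  frames_to_seconds(track$events$end_frame - track$events$start_frame, fps)
}

#' Per-individual display summary
#'
#' Per side: movement count, mean and SD of the start-to-start intervals, and
#' mean movement duration; plus the proportion of movements synchronized at
#' the given tolerance. A side with fewer than two intervals gets `NA` (not
#' zero) for the interval SD, with a message.
#'
#' @param recording a `display_recording`.
#' @param tolerance_frames synchrony tolerance passed to
#'   [classify_synchrony()].
#' @return a one-row data.frame (class `display_summary`) with columns
#'   `recording_id`, `species`, `morph`, `water_temp_c`,
#'   `n_left`, `n_right`, `mean_interval_left/right`, `sd_interval_left/right`,
#'   `mean_duration_left/right`, `proportion_sync`.
#' @export
summarize_display <- function(recording, tolerance_frames = 4) {
  stopifnot(inherits(recording, "display_recording"))
  fps <- recording$fps
  side_stats <- lapply(list(recording$left, recording$right), function(tr) {
    iv <- movement_intervals(tr, fps)
    if (length(iv) < 2L) {
      message("recording ", recording$recording_id, ": ", tr$side,
              " side has ", length(iv), " interval(s); SD not defined")
    }
    list(n = nrow(tr$events),
         mean_interval = if (length(iv)) mean(iv) else NA_real_,
         sd_interval = if (length(iv) >= 2L) stats::sd(iv) else NA_real_,
         mean_duration = if (nrow(tr$events))
           mean(movement_durations(tr, fps)) else NA_real_)
  })
  sc <- classify_synchrony(recording$left, recording$right, tolerance_frames)
  out <- data.frame(
    recording_id = recording$recording_id,
    species = recording$species,
    morph = recording$morph,
    water_temp_c = recording$water_temp_c,
    n_left = side_stats[[1L]]$n,
    n_right = side_stats[[2L]]$n,
    mean_interval_left = side_stats[[1L]]$mean_interval,
    sd_interval_left = side_stats[[1L]]$sd_interval,
    mean_duration_left = side_stats[[1L]]$mean_duration,
    mean_interval_right = side_stats[[2L]]$mean_interval,
    sd_interval_right = side_stats[[2L]]$sd_interval,
    mean_duration_right = side_stats[[2L]]$mean_duration,
    proportion_sync = sc$proportion_sync,
    stringsAsFactors = FALSE
  )
  class(out) <- c("display_summary", class(out))
  out
}

#' Summarize a collection of recordings into one table
#'
#' @param recordings list of `display_recording` objects.
#' @inheritParams summarize_display
#' @return a data.frame with one [summarize_display()] row per recording.
#' @export
summarize_displays <- function(recordings, tolerance_frames = 4) {
  out <- do.call(rbind, lapply(recordings, summarize_display,
                               tolerance_frames = tolerance_frames))
  rownames(out) <- NULL
  out
}

#' Build a gait diagram of one display
#'
#' Ethological gait-diagram layout: synchronized movement pairs are drawn on
#' the center line (spanning the union of the two paired events), left-only
#' movements above it and right-only movements below it, all on a time axis in
#' seconds (with the frame number at the recording's fps as a secondary axis).
#'
#' @param recording a `display_recording`.
#' @param tolerance_frames synchrony tolerance.
#' @return object of class `gait_diagram`: list with `segments` (data.frame
#'   with `line` in `{"left_only","sync","right_only"}`, `start_s`, `end_s`,
#'   `start_frame`, `end_frame`), `recording_id`, `fps`, and the analysis
#'   window. Use `plot()` / [plot.gait_diagram()] to render.
#' @export
gait_diagram <- function(recording, tolerance_frames = 4) {
  stopifnot(inherits(recording, "display_recording"))
  sc <- classify_synchrony(recording$left, recording$right, tolerance_frames)
  le <- recording$left$events
  re <- recording$right$events
  fps <- recording$fps
  seg <- list()
  if (sc$n_sync > 0) {
    li <- sc$pairs[, "left"]
    ri <- sc$pairs[, "right"]
    seg$sync <- data.frame(
      line = "sync",
      start_frame = pmin(le$start_frame[li], re$start_frame[ri]),
      end_frame = pmax(le$end_frame[li], re$end_frame[ri])
    )
  }
  lo <- setdiff(seq_len(nrow(le)), if (sc$n_sync) sc$pairs[, "left"] else integer())
  ro <- setdiff(seq_len(nrow(re)), if (sc$n_sync) sc$pairs[, "right"] else integer())
  if (length(lo)) {
    seg$left <- data.frame(line = "left_only",
                           start_frame = le$start_frame[lo],
                           end_frame = le$end_frame[lo])
  }
  if (length(ro)) {
    seg$right <- data.frame(line = "right_only",
                            start_frame = re$start_frame[ro],
                            end_frame = re$end_frame[ro])
  }
  segments <- if (length(seg)) do.call(rbind, seg) else {
    data.frame(line = character(), start_frame = numeric(), end_frame = numeric())
  }
  rownames(segments) <- NULL
  segments$start_s <- frames_to_seconds(segments$start_frame, fps)
  segments$end_s <- frames_to_seconds(segments$end_frame, fps)
  structure(
    list(segments = segments, recording_id = recording$recording_id, fps = fps,
         analysis_start_frame = recording$analysis_start_frame,
         analysis_length_frames = recording$analysis_length_frames,
         sync_score = sc),
    class = "gait_diagram"
  )
}

#' Plot a gait diagram
#'
#' @param x a `gait_diagram`.
#' @param ... unused.
#' @return a ggplot object: red center-line segments for synchronized
#'   movements, black segments above (left-only) and below (right-only).
#' @export
plot.gait_diagram <- function(x, ...) {
  lev <- c(left_only = 1, sync = 0, right_only = -1)
  seg <- x$segments
  seg$y <- unname(lev[seg$line])
  fps <- x$fps
  p <- ggplot2::ggplot(seg) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start_s, xend = .data$end_s,
                   y = .data$y, yend = .data$y, colour = .data$line),
      linewidth = 3, lineend = "butt"
    ) +
    ggplot2::scale_colour_manual(
      values = c(sync = "red", left_only = "black", right_only = "black"),
      guide = "none"
    ) +
    ggplot2::scale_y_continuous(
      breaks = c(-1, 0, 1), limits = c(-1.5, 1.5),
      labels = c("right only", "synchronized", "left only")
    ) +
    ggplot2::scale_x_continuous(
      name = "time (s)",
      limits = frames_to_seconds(
        c(x$analysis_start_frame,
          x$analysis_start_frame + x$analysis_length_frames), fps),
      sec.axis = ggplot2::sec_axis(~ . * fps, name = "frame")
    ) +
    ggplot2::labs(title = x$recording_id, y = NULL) +
    ggplot2::theme_minimal()
  p
}

#' Render gait diagrams for a set of recordings to image files
#'
#' Writes `<recording_id>_gait.svg` and/or `<recording_id>_gait.png` per
#' recording into `out_dir`.
#'
#' @param recordings list of `display_recording` objects.
#' @param out_dir output directory (created if needed).
#' @param formats subset of `c("svg", "png")`.
#' @param tolerance_frames synchrony tolerance.
#' @return invisible character vector of the files written.
#' @export
render_gait_diagrams <- function(recordings, out_dir,
                                 formats = c("svg", "png"),
                                 tolerance_frames = 4) {
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (rec in recordings) {
    gd <- gait_diagram(rec, tolerance_frames)
    p <- plot(gd)
    for (fmt in formats) {
      f <- file.path(out_dir, paste0(rec$recording_id, "_gait.", fmt))
      suppressMessages(ggplot2::ggsave(f, p, width = 9, height = 2.5,
                                       device = fmt, dpi = 96))
      files <- c(files, f)
    }
  }
  invisible(files)
}
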