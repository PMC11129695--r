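# In-code fixtures shared across test files.

# A random single-side track: distinct integer starts in [lo, hi), short
# positive durations. Caller is responsible for the RNG state.
random_track <- function(side, n, lo = 5000, hi = 25000, max_dur = 60) {
  starts <- sort(sample(seq(lo, hi - max_dur - 1L), n))
  ends <- starts + sample(0:max_dur, n, replace = TRUE)
  event_track(side, starts, ends, warn_overlap = FALSE)
}

# A small hand-built recording: two synchronized pairs, one left-only and
# one right-only movement (at tolerance 4).
fixture_recording <- function() {
  left <- event_track("left", c(5000, 5100, 5200), c(5040, 5140, 5240))
  right <- event_track("right", c(5003, 5150, 5204), c(5043, 5190, 5244))
  display_recording("fix1", left, right, species = "L. fasciola",
                    morph = "darter", fps = 120)
}

write_fixture_csvs <- function(dir) {
  ev <- data.frame(
    recording_id = c("r1", "r1", "r1"),
    side = c("left", "left", "right"),
    start_frame = c(5000, 5120, 5002),
    end_frame = c(5050, 5170, 5052)
  )
  md <- data.frame(
    recording_id = "r1", species = "L. fasciola", morph = "darter",
    site = "raisin", date = "2018-07-01", water_temp_c = 21.5, fps = 120,
    analysis_start_frame = 5000, analysis_length_frames = 20000
  )
  evp <- file.path(dir, "events.csv")
  mdp <- file.path(dir, "metadata.csv")
  utils::write.csv(ev, evp, row.names = FALSE, quote = FALSE)
  utils::write.csv(md, mdp, row.names = FALSE, quote = FALSE)
  list(events = evp, metadata = mdp)
}
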