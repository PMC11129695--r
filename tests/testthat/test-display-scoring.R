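test_that("synchrony classifier matches the worked small cases", {
  # fully synchronized: identical starts on both sides
  l <- event_track("left", c(0, 100, 200, 300, 400) + 5000,
                   c(0, 100, 200, 300, 400) + 5020)
  r <- event_track("right", c(0, 100, 200, 300, 400) + 5000,
                   c(0, 100, 200, 300, 400) + 5020)
  sc <- classify_synchrony(l, r)
  expect_identical(sc$n_sync, 5L)
  expect_identical(sc$proportion_sync, 1)

  # mixed case: pairs (0,3) and (200,204) at tolerance 4; brute-force
  # maximum matching agrees
  l <- event_track("left", c(0, 100, 200), c(10, 110, 210))
  r <- event_track("right", c(3, 150, 204), c(13, 160, 214))
  sc <- classify_synchrony(l, r, tolerance_frames = 4)
  expect_equal(unname(sc$pairs), cbind(c(1L, 3L), c(1L, 3L)))
  expect_identical(sc$n_sync, 2L)
  expect_identical(sc$n_left_only, 1L)
  expect_identical(sc$n_right_only, 1L)
  expect_identical(sc$proportion_sync, 0.5)
  expect_identical(max_matching_oracle(c(0, 100, 200), c(3, 150, 204), 4), 2L)

  # argument order does not matter
  sc2 <- classify_synchrony(r, l, tolerance_frames = 4)
  expect_identical(sc2$n_sync, sc$n_sync)
  expect_identical(sc2$n_left_only, sc$n_left_only)

  # empty tracks
  sc3 <- classify_synchrony(event_track("left"), r)
  expect_identical(sc3$n_sync, 0L)
  expect_identical(sc3$proportion_sync, 0)
  sc4 <- classify_synchrony(event_track("left"), event_track("right"))
  expect_true(is.na(sc4$proportion_sync))

  expect_error(classify_synchrony(l, l), "left")
})

test_that("conservation holds and greedy never beats exhaustive matching", {
  set.seed(101)
  n_cases <- 300
  n_agree <- 0
  for (i in seq_len(n_cases)) {
    nl <- sample(0:12, 1)
    nr <- sample(0:12, 1)
    tol <- sample(0:8, 1)
    l <- random_track("left", max(nl, 0), lo = 5000, hi = 6000)
    r <- random_track("right", max(nr, 0), lo = 5000, hi = 6000)
    sc <- classify_synchrony(l, r, tol)
    expect_identical(sc$n_sync + sc$n_left_only, nrow(l$events))
    expect_identical(sc$n_sync + sc$n_right_only, nrow(r$events))
    opt <- max_matching_oracle(l$events$start_frame, r$events$start_frame, tol)
    expect_lte(sc$n_sync, opt)
    if (sc$n_sync == opt) n_agree <- n_agree + 1
  }
  expect_gte(n_agree / n_cases, 0.99)
})

test_that("n_sync is non-decreasing in the tolerance", {
  set.seed(7)
  for (i in 1:20) {
    l <- random_track("left", 10, lo = 5000, hi = 5500)
    r <- random_track("right", 10, lo = 5000, hi = 5500)
    ns <- vapply(0:12, function(tol) classify_synchrony(l, r, tol)$n_sync,
                 integer(1))
    expect_true(all(diff(ns) >= 0))
  }
})

test_that("intervals and durations follow their frame definitions", {
  tr <- event_track("left", c(0, 120, 360), c(60, 180, 400))
  expect_equal(movement_intervals(tr, 120), c(1, 2))
  expect_equal(movement_durations(tr, 120), c(0.5, 0.5, 1 / 3))
  expect_identical(movement_intervals(event_track("left", 5, 10), 120),
                   numeric(0))
  expect_identical(movement_intervals(event_track("left"), 120), numeric(0))
  # zero-length event has duration 0; equal durations have SD 0
  tr2 <- event_track("left", c(0, 100, 200), c(0, 100, 200))
  expect_equal(movement_durations(tr2, 120), c(0, 0, 0))
  expect_equal(sd(movement_durations(tr2, 120)), 0)
})

test_that("second-valued outputs are invariant to frame/fps rescaling", {
  set.seed(11)
  l <- random_track("left", 8, lo = 5000, hi = 6000)
  r <- random_track("right", 8, lo = 5000, hi = 6000)
  double_track <- function(tr) {
    event_track(tr$side, tr$events$start_frame * 2, tr$events$end_frame * 2,
                warn_overlap = FALSE)
  }
  expect_equal(movement_intervals(double_track(l), 240),
               movement_intervals(l, 120))
  expect_equal(movement_durations(double_track(l), 240),
               movement_durations(l, 120))
  sc <- classify_synchrony(l, r, 4)
  sc2 <- classify_synchrony(double_track(l), double_track(r), 8)
  expect_identical(sc2$n_sync, sc$n_sync)
  expect_identical(sc2$proportion_sync, sc$proportion_sync)
})

test_that("display summaries report per-side statistics and synchrony", {
  starts <- seq(5000, 6200, by = 120)
  l <- event_track("left", starts, starts + 48)
  r <- event_track("right", starts, starts + 48)
  rec <- display_recording("s1", l, r, morph = "darter", water_temp_c = 20)
  s <- summarize_display(rec)
  expect_equal(s$mean_interval_left, 1)
  expect_equal(s$mean_interval_right, 1)
  expect_equal(s$sd_interval_left, 0)
  expect_equal(s$mean_duration_left, 0.4)
  expect_identical(s$proportion_sync, 1)
  expect_identical(s$n_left, length(starts))

  # a side with < 2 intervals yields NA SD, with a note
  l1 <- event_track("left", c(5000, 5100), c(5010, 5110))
  rec2 <- display_recording("s2", l1, event_track("right"))
  expect_message(s2 <- summarize_display(rec2), "SD not defined")
  expect_true(is.na(s2$sd_interval_left))
  expect_true(is.na(s2$mean_interval_right))
})

test_that("gait diagrams place every movement on the correct line", {
  gd <- gait_diagram(fixture_recording())
  seg <- gd$segments
  sc <- gd$sync_score
  expect_identical(nrow(seg), sc$n_sync + sc$n_left_only + sc$n_right_only)
  expect_identical(sum(seg$line == "sync"), sc$n_sync)
  expect_identical(sum(seg$line == "left_only"), sc$n_left_only)
  expect_identical(sum(seg$line == "right_only"), sc$n_right_only)
  # sync segments span the union of the paired events
  sy <- seg[seg$line == "sync", ][1L, ]
  expect_equal(sy$start_frame, 5000)
  expect_equal(sy$end_frame, 5043)
  expect_equal(sy$start_s, 5000 / 120)
  # fully synchronized recording: all segments on the center line
  starts <- seq(5000, 5480, by = 120)
  rec <- display_recording("c", event_track("left", starts, starts + 10),
                           event_track("right", starts, starts + 10),
                           species = "L. cardium", morph = "none")
  expect_true(all(gait_diagram(rec)$segments$line == "sync"))
  # empty recording: empty diagram, no error
  gd0 <- gait_diagram(display_recording("e", event_track("left"),
                                        event_track("right")))
  expect_identical(nrow(gd0$segments), 0L)
  expect_s3_class(plot(gd0), "ggplot")
  expect_s3_class(plot(gd), "ggplot")
})
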