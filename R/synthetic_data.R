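#' Parameters for a synthetic display recording
#'
#' The generator emulates the statistical structure of an annotated lure
#' display: a driving renewal process of movement times, partial left-right
#' coupling with a small start-time jitter, and independent movement
#' durations, all inside the standard 20,000-frame analysis window at
#' 120 fps.
#'
#' Interval draws (in seconds) are converted to frames and clamped below at
#' `max(1, 2 * jitter_frames + 2)` frames so that generated tracks always
#' satisfy the strictly-increasing-start invariant.
#'
#' @param interval_mean,interval_sd mean and SD (seconds, > 0) of the
#'   inter-movement interval distribution.
#' @param interval_family `"gamma"` (default: non-negative and right-skewed,
#'   like erratic displays) or `"lognormal"`.
#' @param duration_mean,duration_sd mean and SD (seconds, > 0) of the
#'   movement-duration distribution (defaults 0.4 / 0.1 s; no field estimate
#'   of durations exists, so these are invented, plausible values).
#' @param duration_family `"gamma"` or `"lognormal"`.
#' @param p_sync probability in [0, 1] that a driving movement is mirrored on
#'   both sides as a synchronized pair.
#' @param jitter_frames non-negative integer; a synchronized partner's start
#'   is offset by a uniform integer in `[-jitter_frames, jitter_frames]`.
#' @param fps frames per second (default 120).
#' @param analysis_start_frame,analysis_length_frames the analysis window
#'   (defaults 5000 and 20000).
#' @param seed default seed used when the simulator is called without one.
#' @return object of class `display_sim_params`.
#' @export
display_sim_params <- function(interval_mean, interval_sd,
                               interval_family = c("gamma", "lognormal"),
                               duration_mean = 0.4, duration_sd = 0.1,
                               duration_family = c("gamma", "lognormal"),
                               p_sync = 1, jitter_frames = 2, fps = 120,
                               analysis_start_frame = 5000,
                               analysis_length_frames = 20000,
                               seed = 1L) {
  interval_family <- match.arg(interval_family)
  duration_family <- match.arg(duration_family)
  if (interval_mean <= 0 || interval_sd <= 0 ||
      duration_mean <= 0 || duration_sd <= 0) {
    stop("distribution means and SDs must be > 0")
  }
  if (p_sync < 0 || p_sync > 1) stop("p_sync must be in [0, 1]")
  if (jitter_frames < 0 || jitter_frames != trunc(jitter_frames)) {
    stop("jitter_frames must be a non-negative integer")
  }
  if (fps <= 0 || analysis_length_frames <= 0) {
    stop("fps and analysis_length_frames must be > 0")
  }
  structure(
    list(interval_mean = interval_mean, interval_sd = interval_sd,
         interval_family = interval_family,
         duration_mean = duration_mean, duration_sd = duration_sd,
         duration_family = duration_family,
         p_sync = p_sync, jitter_frames = as.integer(jitter_frames),
         fps = fps, analysis_start_frame = analysis_start_frame,
         analysis_length_frames = analysis_length_frames,
         seed = as.integer(seed)),
    class = "display_sim_params"
  )
}

# Draw n values from a gamma or lognormal distribution parameterized by
# mean and SD.
draw_positive <- function(n, mean, sd, family) {
  if (family == "gamma") {
    shape <- (mean / sd)^2
    stats::rgamma(n, shape = shape, rate = shape / mean)
  } else {
    sdlog2 <- log(1 + (sd / mean)^2)
    stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
  }
}

#' Species/morph presets for the display simulator
#'
#' Loosely calibrated to the field estimates for the three lure groups: the
#' congener (*L. cardium*) displays fast (mean interval 0.21 s), regular and
#' fully synchronized movements; the polymorphic morphs display slower
#' (darter 3.2 s, leech 1.0 s), much more variable and only partly coupled
#' movements. Interval SDs and coupling probabilities for the morphs are free
#' parameters of the generator (no field dispersion estimates exist); they
#' are chosen to reproduce the qualitative contrast (regular + synchronized
#' vs erratic + partly independent).
#'
#' @param name `"congener"`, `"darter_morph"` or `"leech_morph"`.
#' @return a [display_sim_params()] object.
#' @export
species_preset <- function(name = c("congener", "darter_morph", "leech_morph")) {
  name <- match.arg(name)
  switch(name,
    congener = display_sim_params(
      interval_mean = 0.21, interval_sd = 0.05,
      duration_mean = 0.10, duration_sd = 0.03,
      p_sync = 1, jitter_frames = 2
    ),
    darter_morph = display_sim_params(
      interval_mean = 3.2, interval_sd = 2.0,
      duration_mean = 0.4, duration_sd = 0.1,
      p_sync = 0.6, jitter_frames = 2
    ),
    leech_morph = display_sim_params(
      interval_mean = 1.0, interval_sd = 0.7,
      duration_mean = 0.4, duration_sd = 0.1,
      p_sync = 0.6, jitter_frames = 2
    )
  )
}

#' Write / read simulator parameters as a YAML config
#'
#' @param params a `display_sim_params` object.
#' @param path config file path.
#' @return `read_sim_config` returns a `display_sim_params`; the writer
#'   returns `path` invisibly. Round-trips exactly.
#' @export
write_sim_config <- function(params, path) {
  stopifnot(inherits(params, "display_sim_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(display_sim_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown simulation config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(display_sim_params, vals)
}

#' Simulate one bilateral display recording
#'
#' A driving renewal process generates candidate movement times. With
#' probability `p_sync` a driving movement is expressed on both sides as a
#' synchronized pair, the right start offset by a uniform integer jitter in
#' `[-jitter_frames, +jitter_frames]`. Otherwise the movement is expressed on
#' one side only at the driving time (fair coin), and its missed partner on
#' the other side occurs out of register, displaced to the midpoint of the
#' gap to the next driving movement — so each uncoupled draw contributes one
#' left-only and one right-only movement. With jitter no larger than the
#' classifier tolerance and intervals well above it, the expected proportion
#' synchronized is therefore `p_sync / (2 - p_sync)`.
#'
#' Movement durations are drawn independently per event and truncated so
#' every event stays inside the analysis window and ends before the next
#' movement of the same flap.
#'
#' @param params a [display_sim_params()].
#' @param recording_id id for the generated recording.
#' @param seed integer seed (defaults to `params$seed`); same seed, same
#'   recording, bit for bit.
#' @param species,morph,site,date,water_temp_c metadata passed through to
#'   [display_recording()].
#' @return a validated `display_recording`.
#' @export
simulate_display <- function(params, recording_id = "sim",
                             seed = params$seed,
                             species = "L. fasciola",
                             morph = "darter", site = "simulated",
                             date = NA_character_,
                             water_temp_c = NA_real_) {
  stopifnot(inherits(params, "display_sim_params"))
  fps <- params$fps
  jit <- params$jitter_frames
  min_gap <- max(1L, 2L * jit + 2L)
  win_lo <- params$analysis_start_frame
  win_hi <- params$analysis_start_frame + params$analysis_length_frames
  margin <- jit + 1L

  sim <- with_seed(seed, {
    # driving renewal times, in frames
    times <- numeric(0)
    gaps <- numeric(0)
    t <- win_lo
    repeat {
      gap <- max(min_gap,
                 round(draw_positive(1L, params$interval_mean,
                                     params$interval_sd,
                                     params$interval_family) * fps))
      t <- t + gap
      if (t >= win_hi - margin) break
      times <- c(times, t)
      gaps <- c(gaps, gap)
    }
    n <- length(times)
    gaps <- if (n) c(gaps[-1L], max(min_gap,
                                    round(draw_positive(1L, params$interval_mean,
                                                        params$interval_sd,
                                                        params$interval_family) * fps)))
            else numeric(0)
    left_starts <- numeric(0)
    right_starts <- numeric(0)
    if (n) {
      coupled <- stats::runif(n) < params$p_sync
      jitter <- if (jit > 0) sample(seq(-jit, jit), n, replace = TRUE)
                else rep(0L, n)
      anchor_left <- stats::runif(n) < 0.5
      for (i in seq_len(n)) {
        if (coupled[i]) {
          left_starts <- c(left_starts, times[i])
          right_starts <- c(right_starts, times[i] + jitter[i])
        } else {
          disp <- max(jit + 1L, floor(gaps[i] / 2))
          if (anchor_left[i]) {
            left_starts <- c(left_starts, times[i])
            right_starts <- c(right_starts, times[i] + disp)
          } else {
            right_starts <- c(right_starts, times[i])
            left_starts <- c(left_starts, times[i] + disp)
          }
        }
      }
    }
    make_side <- function(starts, side) {
      starts <- starts[starts >= win_lo & starts < win_hi]
      if (!length(starts)) return(event_track(side))
      dur <- round(draw_positive(length(starts), params$duration_mean,
                                 params$duration_sd,
                                 params$duration_family) * fps)
      dur <- pmax(dur, 0)
      ends <- starts + dur
      # end before the next movement of the same flap, and inside the window
      ends <- pmin(ends, c(starts[-1L] - 1, Inf), win_hi - 1)
      ends <- pmax(ends, starts)
      event_track(side, starts, ends, warn_overlap = FALSE)
    }
    list(left = make_side(left_starts, "left"),
         right = make_side(right_starts, "right"))
  })

  display_recording(
    recording_id = recording_id, left = sim$left, right = sim$right,
    species = species, morph = morph, site = site, date = date,
    water_temp_c = water_temp_c, fps = fps,
    analysis_start_frame = win_lo,
    analysis_length_frames = params$analysis_length_frames
  )
}

#' Simulate a three-group display study
#'
#' Generates a study of synthetic recordings from the three
#' [species_preset()] groups, mirroring a field campaign on the polymorphic
#' mussel and its monomorphic congener. Default group sizes are 4 congener,
#' 15 darter-morph and 12 leech-morph recordings. Water temperatures are
#' drawn uniformly on 17-24 degrees C and attached as metadata.
#'
#' @param n_per_group named integer vector with entries `congener`,
#'   `darter_morph`, `leech_morph`.
#' @param seed master seed; every recording derives its own seed from it.
#' @return named list of `display_recording` objects.
#' @export
simulate_study <- function(n_per_group = c(congener = 4, darter_morph = 15,
                                           leech_morph = 12),
                           seed = 1L) {
  meta <- list(
    congener = list(species = "L. cardium", morph = "none", prefix = "cardium"),
    darter_morph = list(species = "L. fasciola", morph = "darter",
                        prefix = "darter"),
    leech_morph = list(species = "L. fasciola", morph = "leech",
                       prefix = "leech")
  )
  recs <- list()
  k <- 0L
  for (grp in names(n_per_group)) {
    if (!grp %in% names(meta)) stop("unknown group: ", grp)
    params <- species_preset(grp)
    for (i in seq_len(n_per_group[[grp]])) {
      k <- k + 1L
      id <- sprintf("%s_%02d", meta[[grp]]$prefix, i)
      temp <- with_seed(derive_seed(seed, 1000L + k),
                        round(stats::runif(1, 17, 24), 1))
      recs[[id]] <- simulate_display(
        params, recording_id = id, seed = derive_seed(seed, k),
        species = meta[[grp]]$species, morph = meta[[grp]]$morph,
        site = "simulated", date = "2018-07-01", water_temp_c = temp
      )
    }
  }
  recs
}

#' Simulate a captive brood under a single-locus model
#'
#' Each offspring receives a maternal allele from the dam's genotype and a
#' paternal allele that is dominant with the model's sire allele frequency
#' (random union of gametes; multiple unknown sires are absorbed into that
#' frequency). Phenotype follows complete dominance.
#'
#' @param n_offspring brood size (>= 0).
#' @param model a [genetic_model()].
#' @param seed integer seed.
#' @return a [brood_counts()] with the dam's morph implied by the model.
#' @export
simulate_brood <- function(n_offspring, model, seed = 1L) {
  stopifnot(inherits(model, "genetic_model"))
  if (n_offspring < 0) stop("n_offspring must be >= 0")
  counts <- with_seed(seed, {
    if (n_offspring == 0) {
      c(dominant = 0L, recessive = 0L)
    } else {
      dam_dom <- stats::runif(n_offspring) < dam_dominant_transmission(model)
      sire_dom <- stats::runif(n_offspring) < model$sire_dominant_freq
      dominant_pheno <- dam_dom | sire_dom
      c(dominant = sum(dominant_pheno),
        recessive = sum(!dominant_pheno))
    }
  })
  n_dom <- counts[["dominant"]]
  n_rec <- counts[["recessive"]]
  if (model$dominant_morph == "darter") {
    brood_counts(n_darter = n_dom, n_leech = n_rec,
                 dam_morph = model_dam_morph(model))
  } else {
    brood_counts(n_darter = n_rec, n_leech = n_dom,
                 dam_morph = model_dam_morph(model))
  }
}
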