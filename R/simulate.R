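#' Default transition bias between motor states
#'
#' Row-stochastic 5-state matrix over AT, BW, FW, PT, QS used by the
#' generator: backward waves are followed mostly by anterior bursts and
#' forward waves mostly by posterior bursts, the dominant couplings of the
#' larval repertoire, with quiescence interleaved. The diagonal is zero:
#' the generator is semi-Markov (dwell, then switch).
#'
#' @return 5 x 5 numeric matrix with dimnames.
#' @export
default_transitions <- function() {
  st <- c("AT", "BW", "FW", "PT", "QS")
  m <- rbind(
    AT = c(0.00, 0.30, 0.15, 0.05, 0.50),
    BW = c(0.60, 0.00, 0.05, 0.05, 0.30),
    FW = c(0.05, 0.05, 0.00, 0.60, 0.30),
    PT = c(0.05, 0.05, 0.55, 0.00, 0.35),
    QS = c(0.20, 0.20, 0.35, 0.25, 0.00))
  dimnames(m) <- list(from = st, to = st)
  m
}

#' Simulation configuration
#'
#' Study conditions for the synthetic fictive-locomotion generator. The
#' defaults emulate a typical motoneuron recording: 2048 volumes at 0.2 s
#' per volume (the faster end of the usual 0.18-0.42 s volume intervals,
#' so that an 8-frame window sits comfortably inside a single pattern), per-class dwell times lognormal around the observed mean
#' durations (AT 2.2, BW 2.8, FW 2.3, PT 1.5 s), heavy-tailed quiescent
#' gaps of 10 s on average (inter-bout quiescence is much longer than the
#' short QS runs a frame classifier reports), waves spanning
#' the whole cord over the event, anterior bursts over T2-A4 with
#' left-right asymmetry, posterior bursts over A4-A7, slow exponential
#' bleaching and Gaussian shot-like noise.
#'
#' @param n_frames Number of volumes.
#' @param frame_interval_s Seconds per volume.
#' @param transitions Row-stochastic transition matrix over the five
#'   states (zero diagonal).
#' @param dwell_mean_s Named per-class mean dwell in seconds.
#' @param dwell_sdlog Lognormal sdlog of dwell times (scalar or named
#'   per class).
#' @param lead_in_s Quiescent lead-in so the running baseline settles
#'   before the first event.
#' @param amplitude Peak activity as a fraction of baseline fluorescence.
#' @param wave_speed Wave speed in segments per frame, or `NULL`
#'   (default) to span the 9 segments over each event's duration.
#' @param wave_sigma_seg Spatial width (s.d., in segments) of the
#'   traveling bump.
#' @param at_segments,pt_segments Segment indices (1 = T2 anterior) of the
#'   anterior / posterior burst plateaus.
#' @param at_asym_range Range of the weak/strong side amplitude ratio for
#'   anterior bursts (uniform; the strong side is chosen at random).
#' @param baseline_f0 Baseline fluorescence (arbitrary units).
#' @param noise_sd Gaussian noise s.d. as a fraction of `baseline_f0`.
#' @param decay_tau_s Optional calcium-indicator decay time constant:
#'   activity rises instantaneously and relaxes exponentially, leaving
#'   trailing streaks as in GCaMP x-t images. Default 0 (off): the
#'   rectified running-baseline dF/F transform already absorbs most of
#'   the falling phase, and tails smear pattern boundaries.
#' @param bleach_tau_s Exponential bleaching time constant.
#' @param movie_dims Movie lattice `c(z, y, x)`.
#' @param movie_background Background fluorescence of the movie.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_frames = 2048L,
                       frame_interval_s = 0.2,
                       transitions = default_transitions(),
                       dwell_mean_s = c(AT = 2.2, BW = 2.8, FW = 2.3,
                                        PT = 1.5, QS = 10),
                       dwell_sdlog = c(AT = 0.25, BW = 0.25, FW = 0.25,
                                       PT = 0.25, QS = 0.8),
                       lead_in_s = 6,
                       amplitude = 1,
                       wave_speed = NULL,
                       wave_sigma_seg = 0.8,
                       at_segments = 1:6,
                       pt_segments = 6:9,
                       at_asym_range = c(0.2, 0.6),
                       baseline_f0 = 100,
                       noise_sd = 0.02,
                       decay_tau_s = 0,
                       bleach_tau_s = 600,
                       movie_dims = c(z = 2L, y = 32L, x = 64L),
                       movie_background = 30) {
  stopifnot(n_frames > 0, frame_interval_s > 0,
            all(abs(rowSums(transitions) - 1) < 1e-9),
            all(dwell_mean_s > 0), all(dwell_sdlog > 0), amplitude > 0,
            noise_sd >= 0, decay_tau_s >= 0, bleach_tau_s > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a ground-truth event sequence
#'
#' Semi-Markov state process: states follow the transition bias matrix,
#' dwell times are lognormal per class (mean on the natural scale equals
#' `dwell_mean_s`), converted to frames with a 2-frame floor. The sequence
#' starts with a quiescent lead-in and is truncated at `n_frames`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return An [event_table()] (intensity/asymmetry `NA`) covering
#'   `[0, n_frames)` without gaps.
#' @export
simulate_events <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    dt <- config$frame_interval_s
    states <- rownames(config$transitions)
    sdl <- rep(config$dwell_sdlog, length.out = length(states))
    if (!is.null(names(config$dwell_sdlog)))
      sdl <- config$dwell_sdlog[states]
    names(sdl) <- states
    mu <- log(config$dwell_mean_s[states]) - sdl^2 / 2
    cls <- "QS"
    t0 <- 0L
    len <- max(2L, as.integer(round(config$lead_in_s / dt)))
    out_cls <- character(); out_s <- integer(); out_e <- integer()
    repeat {
      t1 <- min(t0 + len, config$n_frames)
      if (t1 > t0) {
        out_cls <- c(out_cls, cls); out_s <- c(out_s, t0); out_e <- c(out_e, t1)
      }
      t0 <- t1
      if (t0 >= config$n_frames) break
      cls <- sample(states, 1L, prob = config$transitions[cls, ])
      len <- max(2L, as.integer(round(
        stats::rlnorm(1, mu[cls], sdl[cls]) / dt)))
    }
    event_table(class = out_cls, start_frame = out_s, end_frame = out_e,
                duration_s = (out_e - out_s) * dt)
  })
}

# activity templates on the [18 x n_frames] hemisegment grid; rows are
# (T2_L, T2_R, T3_L, ...) as in roi_traces ordering
render_activity <- function(events, config) {
  A <- matrix(0, 18L, config$n_frames)
  sigma <- config$wave_sigma_seg
  for (i in seq_len(nrow(events))) {
    cls <- events$class[i]
    if (cls == "QS") next
    f <- events$start_frame[i]:(events$end_frame[i] - 1L)
    n <- length(f)
    amp <- config$amplitude * stats::runif(1, 0.85, 1.15)
    if (cls %in% c("FW", "BW")) {
      u <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0.5
      if (!is.null(config$wave_speed))
        u <- pmin(1, (seq_len(n) - 1) * config$wave_speed / 8)
      pos <- if (cls == "FW") 9 - 8 * u else 1 + 8 * u
      bump <- outer(1:9, pos, function(s, p) exp(-(s - p)^2 / (2 * sigma^2)))
      both <- bump[rep(1:9, each = 2), , drop = FALSE]
      A[, f + 1L] <- A[, f + 1L] + amp * both
    } else {
      segs <- if (cls == "AT") config$at_segments else config$pt_segments
      gain <- rep(0, 18L)
      gain[2L * segs - 1L] <- 1; gain[2L * segs] <- 1
      if (cls == "AT") {
        ratio <- stats::runif(1, config$at_asym_range[1],
                              config$at_asym_range[2])
        weak <- sample(c("L", "R"), 1L)
        idx <- if (weak == "L") 2L * segs - 1L else 2L * segs
        gain[idx] <- ratio
      }
      env <- rep(1, n)
      if (n >= 4) { env[1] <- 0.5; env[n] <- 0.5 }  # soft onset/offset
      A[, f + 1L] <- A[, f + 1L] + amp * outer(gain, env)
    }
  }
  # indicator kinetics: instantaneous rise, exponential decay
  if (config$decay_tau_s > 0) {
    k <- exp(-config$frame_interval_s / config$decay_tau_s)
    for (t in 2:ncol(A)) A[, t] <- pmax(A[, t], A[, t - 1L] * k)
  }
  A
}

#' Render synthetic 18-ROI fluorescence traces
#'
#' Builds raw fluorescence from a ground-truth event sequence: a bleaching
#' baseline `f0 * exp(-t / tau)` modulated by class-specific activity
#' templates (traveling Gaussian bump across the segment axis for FW/BW,
#' static plateaus for AT/PT with one-sided attenuation for AT), plus
#' Gaussian noise, floored to stay positive.
#'
#' @param events Event table from [simulate_events()].
#' @param config The same [sim_config()].
#' @param seed Integer seed.
#' @return List with `traces` (a [roi_traces()]) and `truth` (the event
#'   table).
#' @export
render_roi_traces <- function(events, config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed * 1000L + 1L, {
    A <- render_activity(events, config)
    t_s <- (seq_len(config$n_frames) - 1) * config$frame_interval_s
    bleach <- exp(-t_s / config$bleach_tau_s)
    F <- config$baseline_f0 * sweep(1 + A, 2, bleach, `*`)
    F <- F + matrix(stats::rnorm(length(F),
                                 sd = config$noise_sd * config$baseline_f0),
                    nrow(F))
    F <- pmax(F, config$baseline_f0 * 1e-3)
    ids <- data.frame(segment = rep(SEGMENTS, each = 2),
                      side = rep(c("L", "R"), 9))
    list(traces = roi_traces(F, ids, config$frame_interval_s),
         truth = events)
  })
}

# disjoint ellipsoid masks on the [z, y, x] lattice: 18 hemisegmental
# units along x (L row / R row in y) plus one midline unit that is active
# only during backward waves
movie_unit_masks <- function(dims) {
  z <- dims[1]; y <- dims[2]; x <- dims[3]
  masks <- array(0L, dim = c(z, y, x))
  xc <- seq(4, x - 3, length.out = 9)
  yl <- round(y * 0.3); yr <- round(y * 0.7)
  put <- function(id, cy, cx, ry, rx) {
    for (yy in seq_len(y)) for (xx in seq_len(x))
      if (((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1 &&
          masks[1, yy, xx] == 0L)
        masks[, yy, xx] <<- id
  }
  for (s in 1:9) {
    put(2L * s - 1L, yl, xc[s], 2.2, 2.2)  # left
    put(2L * s, yr, xc[s], 2.2, 2.2)       # right
  }
  put(19L, round(y / 2), xc[2], 2.0, 2.0)  # planted BW-specific unit
  masks
}

#' Render a synthetic volumetric movie
#'
#' A small registered lattice carrying the hemisegmental traces in
#' ellipsoidal units, one planted midline unit active only during backward
#' waves (an analogue of a BW-specific interneuron), and noisy background.
#'
#' @param events Event table from [simulate_events()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `movie` (a [volume_movie()]), `masks` (integer
#'   `[z, y, x]`, 0 = background, 1..18 = hemisegment units anterior to
#'   posterior L/R-interleaved, 19 = planted BW unit) and `truth`.
#' @export
render_volume_movie <- function(events, config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  rendered <- render_roi_traces(events, config, seed)
  with_seed(seed * 1000L + 2L, {
    dims <- as.integer(config$movie_dims)
    masks <- movie_unit_masks(dims)
    n_t <- config$n_frames
    t_s <- (seq_len(n_t) - 1) * config$frame_interval_s
    bleach <- exp(-t_s / config$bleach_tau_s)
    bw_ind <- as.numeric(events_to_series(events, n_t) == "BW")
    if (config$decay_tau_s > 0) {
      k <- exp(-config$frame_interval_s / config$decay_tau_s)
      for (t in 2:n_t) bw_ind[t] <- max(bw_ind[t], bw_ind[t - 1L] * k)
    }
    planted <- config$baseline_f0 *
      bleach * (1 + config$amplitude * bw_ind)
    vox <- array(0, dim = c(n_t, dims))
    flat <- matrix(config$movie_background * bleach, n_t,
                   prod(dims))
    ids <- as.vector(masks)
    Ftr <- rendered$traces$values  # [18 x t]
    for (u in 1:18) if (any(ids == u)) flat[, ids == u] <- Ftr[u, ]
    if (any(ids == 19L)) flat[, ids == 19L] <- planted
    flat <- flat + matrix(stats::rnorm(length(flat),
                                       sd = config$noise_sd *
                                            config$baseline_f0),
                          n_t)
    flat <- pmax(flat, config$baseline_f0 * 1e-3)
    vox <- array(flat, dim = c(n_t, dims))
    list(movie = volume_movie(vox, config$frame_interval_s),
         masks = masks, truth = events)
  })
}
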