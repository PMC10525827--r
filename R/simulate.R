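#' Simulation parameters
#'
#' Parameters of the synthetic pose-track generator. Defaults emulate the
#' study conditions the pipeline was designed for: cohorts of 16 embryos
#' filmed at 50 fps, a 2-min (ED15-18) or 3-min (ED9-14) baseline before
#' each of two stimuli applied in randomized order, and a 3-min
#' observation after each stimulus of which the first 120 s are analyzed.
#' The noxious Pinch evokes swift beak-opening events — trapezoidal
#' pulses in the beak gap — whose rate is highest in the first 30 s after
#' clamp release and decays geometrically across the four post intervals;
#' the control Touch evokes none by default. Tracking imperfections are
#' emulated by per-frame Gaussian landmark jitter, likelihood dropouts
#' (isolated and bursty), and occasional gross outlier frames.
#'
#' @param n_embryos cohort size (default 16).
#' @param embryonic_day ED of the simulated cohort (default 16).
#' @param frame_rate frames per second (default 50).
#' @param baseline_duration baseline length in s; default per ED (120 for
#'   ED15-18, 180 for ED9-14).
#' @param observation_duration post-stimulus observation length in s
#'   (default 180; the analysis uses the first `post_duration` seconds).
#' @param post_duration analyzed post window in s (default 120).
#' @param stim_contact_s clamp contact time in s (default 1).
#' @param resting_gap resting beak gap in px (default 10).
#' @param fulcrum_offset beak-fulcrum position relative to the upper-beak
#'   landmark, px.
#' @param noise_sd per-frame landmark jitter SD in px (default 0.5).
#' @param embryo_sd SD of the embryo-level resting-gap offset in px
#'   (default 1), the source of the random-intercept structure.
#' @param bout_rate spontaneous motility bouts per minute affecting the
#'   eye corner, elbow and leg (default 2).
#' @param bout_amp bout displacement amplitude in px (default 3).
#' @param bout_dur_s range of bout durations in s.
#' @param event_rate Pinch-evoked beak-opening events per 30-s interval
#'   in the first post interval (default 8).
#' @param event_amplitude added beak gap at pulse plateau, px (default 8).
#' @param event_decay per-interval multiplier on the event rate across
#'   the four post intervals, in (0, 1\] (default 0.5).
#' @param event_rise_frames,event_hold_frames pulse shape: linear rise
#'   and fall of `event_rise_frames` frames around a plateau of
#'   `event_hold_frames` frames (defaults 5 and 30; one event then keeps
#'   the beak open for 0.7 s at 50 fps).
#' @param touch_event_rate beak-opening rate after Touch (default 0).
#' @param dropout_rate per-frame probability of an isolated likelihood
#'   dropout per body part (default 0.01).
#' @param burst_rate dropout bursts per minute per part (default 0.5).
#' @param burst_mean_len mean burst length in frames (default 10).
#' @param outlier_rate per-frame probability of a gross outlier frame
#'   (default 5e-4).
#' @param outlier_magnitude outlier displacement in px (default 300).
#' @param parts which landmarks to emit; any subset of the default set
#'   (the three beak parts are required for beak kinematics).
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(n_embryos = 16, embryonic_day = 16, frame_rate = 50,
                       baseline_duration = NULL, observation_duration = 180,
                       post_duration = 120, stim_contact_s = 1,
                       resting_gap = 10, fulcrum_offset = c(-12, 5),
                       noise_sd = 0.5, embryo_sd = 1,
                       bout_rate = 2, bout_amp = 3, bout_dur_s = c(0.5, 2),
                       event_rate = 8, event_amplitude = 8, event_decay = 0.5,
                       event_rise_frames = 5, event_hold_frames = 30,
                       touch_event_rate = 0,
                       dropout_rate = 0.01, burst_rate = 0.5, burst_mean_len = 10,
                       outlier_rate = 5e-4, outlier_magnitude = 300,
                       parts = c("beak_upper", "beak_lower", "beak_fulcrum",
                                 "eye_corner", "elbow", "leg", "egg_reference")) {
  if (is.null(baseline_duration))
    baseline_duration <- if (embryonic_day >= 15) 120 else 180
  p <- as.list(environment())
  rates <- c(p$bout_rate, p$event_rate, p$touch_event_rate, p$dropout_rate,
             p$burst_rate, p$outlier_rate)
  if (any(rates < 0)) stop("sim_params: rates must be >= 0")
  if (!(p$event_decay > 0 && p$event_decay <= 1))
    stop("sim_params: event_decay must lie in (0, 1]")
  if (p$noise_sd < 0 || p$embryo_sd < 0) stop("sim_params: SDs must be >= 0")
  if (!all(c("beak_upper", "beak_lower", "beak_fulcrum") %in% p$parts))
    stop("sim_params: the three beak parts are required")
  structure(p, class = "sim_params")
}

# fixed resting skeleton (px, y-down image coordinates)
sim_skeleton <- function(params) {
  list(beak_upper = c(100, 100),
       beak_lower = c(100, 100 + params$resting_gap),  # gap opens downward
       beak_fulcrum = c(100, 100) + params$fulcrum_offset,
       eye_corner = c(130, 80), elbow = c(160, 140), leg = c(190, 190),
       egg_reference = c(40, 40))
}

#' Build the trial design implied by the simulation timeline
#'
#' Timeline: baseline, stimulus 1 (contact, then release), observation,
#' second baseline, stimulus 2, observation.
#'
#' @param params a [sim_params].
#' @param embryo_id trial identifier.
#' @param order stimulus order, e.g. `c("Pinch", "Touch")`.
#' @param group group tag.
#' @return a [trial_design].
#' @export
sim_trial_design <- function(params, embryo_id, order = c("Pinch", "Touch"),
                             group = "plain") {
  fr <- params$frame_rate
  B <- round(params$baseline_duration * fr)
  C <- round(params$stim_contact_s * fr)
  O <- round(params$observation_duration * fr)
  onset1 <- B; release1 <- onset1 + C
  onset2 <- release1 + O + B; release2 <- onset2 + C
  trial_design(embryo_id, params$embryonic_day,
               data.frame(kind = order,
                          onset_frame = c(onset1, onset2),
                          release_frame = c(release1, release2)),
               group = group,
               baseline_duration = params$baseline_duration,
               post_duration = params$post_duration)
}

#' Total frames of a simulated recording
#'
#' @param params a [sim_params].
#' @param design a [trial_design] from [sim_trial_design].
#' @return integer frame count covering both observation windows.
#' @export
sim_n_frames <- function(params, design) {
  max(design$stimuli$release_frame) +
    round(params$observation_duration * params$frame_rate) + 1L
}

# trapezoidal opening pulse: linear rise, plateau, linear fall
opening_pulse <- function(amplitude, rise, hold) {
  amplitude * c(seq_len(rise) / rise, rep(1, hold), rev(seq_len(rise)) / rise)
}

#' Simulate one pose-track trial
#'
#' Generates a [pose_track] for one trial under `params` and `design`,
#' together with the ground truth of everything injected: beak-opening
#' events (stimulus, start frame, amplitude, duration), dropout and
#' outlier frames per part, and the true (noise-free) beak-gap interval
#' sums over the analysis grid. On a noise-free, dropout-free
#' parameterization the pipeline reproduces the true interval sums
#' exactly.
#'
#' @param params a [sim_params]. The extra field `embryo_offset` (px,
#'   default 0) shifts the resting gap, giving embryo-level structure
#'   when set by [simulate_cohort].
#' @param design a [trial_design], typically from [sim_trial_design].
#' @param seed integer seed; the same seed reproduces the track
#'   byte-for-byte.
#' @return list with elements `track` ([pose_track]) and `truth` (list:
#'   `events`, `dropouts`, `outliers`, `true_interval_sums`,
#'   `resting_gap`).
#' @export
simulate_trial <- function(params, design, seed) {
  stopifnot(inherits(params, "sim_params"), inherits(design, "trial_design"))
  set.seed(as.integer(seed))
  fr <- params$frame_rate
  nf <- sim_n_frames(params, design)
  L <- round(30 * fr)
  offset <- params$embryo_offset %||% 0
  resting <- params$resting_gap + offset
  skel <- sim_skeleton(params)

  # --- beak gap signal: resting gap + evoked opening pulses ---------------
  gap <- rep(resting, nf)
  dur <- 2L * params$event_rise_frames + params$event_hold_frames
  events <- list()
  for (i in seq_len(nrow(design$stimuli))) {
    kind <- design$stimuli$kind[i]
    release <- design$stimuli$release_frame[i]
    base_rate <- if (kind == "Pinch") params$event_rate else params$touch_event_rate
    if (base_rate <= 0) next
    n_iv <- as.integer(floor(params$post_duration / 30))
    for (j in seq_len(n_iv)) {
      lambda <- base_rate * params$event_decay^(j - 1)
      n_ev <- stats::rpois(1, lambda)
      if (n_ev == 0) next
      slot <- L %/% n_ev
      starts <- release + (j - 1L) * L + (seq_len(n_ev) - 1L) * slot +
        floor(stats::runif(n_ev) * max(1L, slot - dur))
      for (s in starts) {
        w <- opening_pulse(params$event_amplitude, params$event_rise_frames,
                           params$event_hold_frames)
        idx <- s + seq_along(w)  # pulse starts the frame after s
        keep <- idx <= nf
        gap[idx[keep]] <- gap[idx[keep]] + w[keep]
      }
      events[[length(events) + 1]] <-
        data.frame(stimulus = kind, start_frame = as.integer(starts),
                   amplitude = params$event_amplitude, duration_frames = dur)
    }
  }
  events <- if (length(events)) do.call(rbind, events)
  else data.frame(stimulus = character(), start_frame = integer(),
                  amplitude = numeric(), duration_frames = integer())

  # --- spontaneous motility bouts (eye corner, elbow, leg) ----------------
  minutes <- nf / fr / 60
  bout_parts <- intersect(c("eye_corner", "elbow", "leg"), params$parts)
  bout_disp <- list()
  for (p in bout_parts) {
    dx <- numeric(nf); dy <- numeric(nf)
    n_b <- stats::rpois(1, params$bout_rate * minutes)
    if (n_b > 0) {
      for (b in seq_len(n_b)) {
        d <- round(stats::runif(1, params$bout_dur_s[1], params$bout_dur_s[2]) * fr)
        s <- sample.int(max(1L, nf - d), 1)
        th <- stats::runif(1, 0, 2 * pi)
        prof <- params$bout_amp * sin(pi * seq_len(d) / d)^2
        idx <- s + seq_len(d) - 1L
        dx[idx] <- dx[idx] + prof * cos(th)
        dy[idx] <- dy[idx] + prof * sin(th)
      }
    }
    bout_disp[[p]] <- list(x = dx, y = dy)
  }

  # --- assemble landmarks + jitter ---------------------------------------
  x <- y <- lik <- matrix(NA_real_, nf, length(params$parts),
                          dimnames = list(NULL, params$parts))
  for (p in params$parts) {
    base <- skel[[p]]
    sx <- rep(base[1], nf); sy <- rep(base[2], nf)
    if (p == "beak_lower") sy <- sy + (gap - params$resting_gap)
    if (p %in% names(bout_disp)) {
      sx <- sx + bout_disp[[p]]$x; sy <- sy + bout_disp[[p]]$y
    }
    x[, p] <- sx + stats::rnorm(nf, 0, params$noise_sd)
    y[, p] <- sy + stats::rnorm(nf, 0, params$noise_sd)
    lik[, p] <- stats::runif(nf, 0.8, 1)
  }

  # --- dropouts (isolated + bursts) and outliers -------------------------
  dropouts <- outliers <- list()
  for (p in params$parts) {
    drop <- stats::runif(nf) < params$dropout_rate
    n_b <- stats::rpois(1, params$burst_rate * minutes)
    if (n_b > 0) for (b in seq_len(n_b)) {
      len <- 1L + stats::rgeom(1, 1 / params$burst_mean_len)
      s <- sample.int(nf, 1)
      drop[s:min(nf, s + len - 1L)] <- TRUE
    }
    if (any(drop)) {
      lik[drop, p] <- stats::runif(sum(drop), 0, 0.5)
      dropouts[[p]] <- data.frame(label = p, frame = which(drop) - 1L)
    }
    out <- which(stats::runif(nf) < params$outlier_rate & !drop)
    if (length(out)) {
      th <- stats::runif(length(out), 0, 2 * pi)
      x[out, p] <- x[out, p] + params$outlier_magnitude * cos(th)
      y[out, p] <- y[out, p] + params$outlier_magnitude * sin(th)
      outliers[[p]] <- data.frame(label = p, frame = out - 1L)
    }
  }
  bind0 <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  proto <- data.frame(label = character(), frame = integer())

  # coordinates rounded to 1e-6 px so that CSV output is byte-stable
  x <- round(x, 6); y <- round(y, 6); lik <- round(lik, 6)
  track <- pose_track(design$embryo_id, x, y, lik, frame_rate = fr)

  seg <- segment_intervals(design, fr, nf)
  seg$true_sum <- vapply(seq_len(nrow(seg)), function(i)
    sum(gap[(seg$start_frame[i] + 1L):seg$end_frame[i]]), 0)
  truth <- list(events = events,
                dropouts = bind0(dropouts, proto),
                outliers = bind0(outliers, proto),
                true_interval_sums = seg[c("stimulus", "window", "interval", "true_sum")],
                resting_gap = resting)
  list(track = track, truth = truth)
}

#' Simulate a cohort of trials
#'
#' Generates `n_embryos` trials with randomized stimulus order and
#' embryo-level resting-gap offsets drawn from N(0, `embryo_sd`), the
#' structure the random-intercept model recovers. Each trial gets its own
#' sub-seed derived from `seed`, so the whole cohort is reproducible
#' byte-for-byte. With `dir` set, the cohort is written to disk: one pose
#' CSV per embryo, a YAML design file, a ground-truth event CSV and a
#' manifest.
#'
#' @param params a [sim_params].
#' @param seed integer master seed.
#' @param dir optional output directory (created; must not already
#'   contain a manifest).
#' @param n number of embryos; defaults to `params$n_embryos`.
#' @return list with `tracks`, `designs`, `truths` (all named by embryo),
#'   the `scheme` used, `params`, and `manifest` (data.frame: embryo,
#'   order, offset, sub-seed, file name).
#' @export
simulate_cohort <- function(params, seed, dir = NULL, n = params$n_embryos) {
  stopifnot(inherits(params, "sim_params"), n >= 1)
  set.seed(as.integer(seed))
  offsets <- stats::rnorm(n, 0, params$embryo_sd)
  orders <- lapply(seq_len(n), function(i) sample(c("Pinch", "Touch")))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("e%02d", seq_len(n))
  tracks <- designs <- truths <- stats::setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    p_i <- params; p_i$embryo_offset <- offsets[i]
    designs[[i]] <- sim_trial_design(params, ids[i], order = orders[[i]])
    sim <- simulate_trial(p_i, designs[[i]], sub_seeds[i])
    tracks[[i]] <- sim$track
    truths[[i]] <- sim$truth
  }
  manifest <- data.frame(embryo_id = ids,
                         stimulus_1 = vapply(orders, `[`, "", 1),
                         embryo_offset = offsets,
                         sub_seed = sub_seeds,
                         pose_file = paste0(ids, ".csv"))
  scheme <- sim_scheme(params)
  if (!is.null(dir)) {
    if (file.exists(file.path(dir, "manifest.yaml")))
      stop("simulate_cohort: '", dir, "' already holds a cohort; refusing to overwrite")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n))
      write_pose_csv(tracks[[i]], file.path(dir, manifest$pose_file[i]))
    write_trial_designs(designs, file.path(dir, "designs.yaml"))
    ev <- do.call(rbind, lapply(ids, function(id) {
      e <- truths[[id]]$events
      if (nrow(e)) cbind(trial_id = id, e) else NULL
    }))
    if (is.null(ev))
      ev <- data.frame(trial_id = character(), stimulus = character(),
                       start_frame = integer(), amplitude = numeric(),
                       duration_frames = integer())
    utils::write.csv(ev, file.path(dir, "truth_events.csv"), row.names = FALSE)
    yaml::write_yaml(list(seed = as.integer(seed), n_embryos = n,
                          manifest = manifest, params = unclass(params)),
                     file.path(dir, "manifest.yaml"))
  }
  list(tracks = tracks, designs = designs, truths = truths,
       scheme = scheme, params = params, manifest = manifest)
}

#' Body-part scheme matching the simulator's labels
#'
#' @param params a [sim_params] (determines which optional parts are
#'   mapped and the leg site: tarsus on ED9, metatarsus otherwise).
#' @return a [bodypart_scheme].
#' @export
sim_scheme <- function(params) {
  has <- function(p) if (p %in% params$parts) p else NULL
  bodypart_scheme(beak_upper = "beak_upper", beak_lower = "beak_lower",
                  beak_fulcrum = "beak_fulcrum",
                  eye_corner = has("eye_corner"), elbow = has("elbow"),
                  leg = has("leg"),
                  reference_points = intersect("egg_reference", params$parts),
                  leg_site = if (params$embryonic_day == 9) "tarsus" else "metatarsus")
}
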