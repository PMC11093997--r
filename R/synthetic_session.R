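#' Synthetic session generator with ground truth
#'
#' Emulates the statistical structure the analyses assume: foraging
#' alternates between body translations (smooth 3D paths between reward
#' ports, head aligned to heading) and stationary epochs peppered with
#' ballistic head-gaze shifts whose peak velocity follows a Naka-Rushton
#' main sequence; spike trains are inhomogeneous Poisson with log-additive
#' place/view/head-direction (pyramidal) or AHV/TS (interneuron) tuning and
#' optional burst doublets; LFP is 1/f background plus a theta oscillation
#' phase-reset at head-movement peaks. Every generated quantity is recorded
#' in a ground-truth manifest for recovery tests.
#'
#' @name synthetic_session
NULL

#' Generator parameters
#'
#' Defaults describe a full recording session: ~40 min, 204 putative pyramidal
#' and 127 putative interneuron units, 80% of head movements during body
#' stops, marmoset main-sequence parameters (R_max = 795 deg/s), theta at
#' 7 Hz reset at head-movement peaks. Tests pass smaller sizes explicitly.
#'
#' @param duration_s session length [s].
#' @param maze a `maze_model`.
#' @param stop_mean_s mean stop-epoch duration [s].
#' @param locomotion_speed_range peak body speed range [cm/s].
#' @param head_event_rate_during_stops head-gaze shift rate in stops [Hz].
#' @param amplitude_meanlog,amplitude_sdlog log-normal amplitude parameters,
#'   truncated to `amplitude_range` [deg].
#' @param amplitude_range truncation range [deg].
#' @param main_sequence list (r_max, n, k, b) of the generating
#'   Naka-Rushton curve [deg/s].
#' @param main_sequence_noise multiplicative (log-normal) noise SD on peak
#'   velocity.
#' @param fraction_head_moves_during_stops target fraction of head events
#'   inside stop epochs.
#' @param n_pyr,n_int unit counts by type.
#' @param lfp_fs LFP rate [Hz].
#' @param aperiodic_exponent power-spectrum 1/f^a exponent of the background.
#' @param theta_freq theta frequency [Hz].
#' @param theta_amp theta amplitude relative to background SD.
#' @param reset_gain amplitude gain at resets (0 = no resetting).
#' @param reset_decay_s reset envelope decay [s].
#' @param reset_phase phase value events reset to [rad].
#' @param phase_diffusion theta phase-diffusion rate [rad/sqrt(s)]; sets how
#'   fast phase coherence decays away from resets.
#' @param seed RNG seed; fixed seed gives bit-identical sessions.
#' @return list of class `generator_params`.
#' @export
generator_params <- function(duration_s = 2400, maze = maze_model(),
                             stop_mean_s = 6,
                             locomotion_speed_range = c(16, 60),
                             head_event_rate_during_stops = 2,
                             amplitude_meanlog = log(25), amplitude_sdlog = 0.5,
                             amplitude_range = c(10, 90),
                             main_sequence = list(r_max = 795, n = 2, k = 20, b = 50),
                             main_sequence_noise = 0.1,
                             fraction_head_moves_during_stops = 0.8,
                             n_pyr = 204, n_int = 127,
                             lfp_fs = 1000, aperiodic_exponent = 2,
                             theta_freq = 7, theta_amp = 1,
                             reset_gain = 2, reset_decay_s = 0.15,
                             reset_phase = 0, phase_diffusion = 3, seed = 1) {
  stopifnot(duration_s > 0, head_event_rate_during_stops >= 0,
            fraction_head_moves_during_stops >= 0,
            fraction_head_moves_during_stops <= 1,
            theta_freq > 0)
  p <- as.list(environment())
  class(p) <- "generator_params"
  p
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2 * n, meanlog, sdlog)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Unit-quaternion for rotation of angle theta_deg about world axis u.
quat_axis <- function(u, theta_deg) {
  u <- u / sqrt(sum(u^2))
  h <- theta_deg * pi / 360
  cbind(cos(h), sin(h) * u[1], sin(h) * u[2], sin(h) * u[3])
}

#' Generate behavior: pose plus ground-truth movement events
#'
#' @param params a `generator_params`.
#' @return list: `pose` (a `pose_series`), `events` (ground-truth head and
#'   body event table), `stop_epochs` (data frame t_on, t_off).
#' @export
gen_behavior <- function(params) {
  p <- params
  fs <- 60
  n <- floor(p$duration_s * fs)
  tgrid <- (seq_len(n) - 1) / fs
  ports <- p$maze$reward_ports
  if (nrow(ports) < 2) stop("degenerate maze: need at least 2 reward ports")
  local_seed(child_seed(p$seed, "behavior"), {
    pos <- matrix(0, n, 3)
    yaw <- numeric(n); pitch <- numeric(n)
    segs <- list()       # (type, i0, i1, port or targets)
    cur <- 1L            # current sample
    here <- ports[sample(nrow(ports), 1), ]
    ext <- p$maze$extent
    # next stop target: a reward port or a random interior waypoint (50/50),
    # so stopping places (hence place occupancy) are not confined to ports
    draw_target <- function(from) {
      repeat {
        b <- if (stats::runif(1) < 0.5) ports[sample(nrow(ports), 1), ]
        else c(stats::runif(1, 5, ext[1] - 5), stats::runif(1, 5, ext[2] - 5),
               sample(p$maze$floor_heights, 1) + 5)
        if (sqrt(sum((b - from)^2)) > 30) return(b)
      }
    }
    stop_rows <- list(); body_rows <- list()
    state <- "stop"
    while (cur <= n) {
      if (state == "stop") {
        dur <- min(max(stats::rexp(1, 1 / p$stop_mean_s), 1.5), 4 * p$stop_mean_s)
        i1 <- min(n, cur + round(dur * fs) - 1L)
        pos[cur:i1, ] <- matrix(here, i1 - cur + 1L, 3, byrow = TRUE)
        stop_rows[[length(stop_rows) + 1L]] <- c(tgrid[cur], tgrid[i1] + 1 / fs)
        segs[[length(segs) + 1L]] <- list(type = "stop", i0 = cur, i1 = i1)
        cur <- i1 + 1L
        state <- "move"
      } else {
        a <- here; b <- draw_target(here)
        D <- sqrt(sum((b - a)^2))
        vpk <- stats::runif(1, p$locomotion_speed_range[1], p$locomotion_speed_range[2])
        Tm <- 2 * D / vpk
        i1 <- min(n, cur + round(Tm * fs) - 1L)
        if (i1 > cur) {
          tt <- (seq(cur, i1) - cur) / (i1 - cur)            # 0..1
          frac <- tt - sin(2 * pi * tt) / (2 * pi)
          pos[cur:i1, ] <- cbind(a[1] + (b[1] - a[1]) * frac,
                                 a[2] + (b[2] - a[2]) * frac,
                                 a[3] + (b[3] - a[3]) * frac)
          d <- (b - a) / D
          yaw[cur:i1] <- atan2(d[2], d[1]) * 180 / pi
          pitch[cur:i1] <- asin(pmin(pmax(d[3], -1), 1)) * 180 / pi
          body_rows[[length(body_rows) + 1L]] <-
            data.frame(kind = "body", t_on = tgrid[cur],
                       t_peak = tgrid[cur + round((i1 - cur) / 2)],
                       t_off = tgrid[i1] + 1 / fs,
                       peak_velocity = vpk, amplitude = D)
          segs[[length(segs) + 1L]] <- list(type = "move", i0 = cur, i1 = i1)
        }
        here <- b
        cur <- i1 + 1L
        state <- "stop"
      }
    }
    # carry heading into stops (head holds last orientation between shifts)
    for (i in 2:n) {
      if (pos[i, 1] == pos[i - 1, 1] && pos[i, 2] == pos[i - 1, 2] &&
          pos[i, 3] == pos[i - 1, 3]) {
        yaw[i] <- yaw[i - 1]; pitch[i] <- pitch[i - 1]
      }
    }
    # schedule head-gaze shifts
    stop_ep <- do.call(rbind, lapply(stop_rows, function(r)
      data.frame(t_on = r[1], t_off = r[2])))
    move_segs <- Filter(function(s) s$type == "move", segs)
    stop_segs <- Filter(function(s) s$type == "stop", segs)
    sched <- list()
    if (p$head_event_rate_during_stops > 0) {
      for (s in stop_segs) {
        t0 <- tgrid[s$i0]; t1 <- tgrid[s$i1]
        # clear the re-orientation ramp at stop onset before the first shift
        tcur <- t0 + 0.6 + stats::rexp(1, p$head_event_rate_during_stops)
        while (tcur < t1 - 0.3) {
          sched[[length(sched) + 1L]] <- c(tcur, 0)
          tcur <- tcur + 0.3 + stats::rexp(1, p$head_event_rate_during_stops)
        }
      }
    }
    n_stop_ev <- length(sched)
    f <- p$fraction_head_moves_during_stops
    n_loc_ev <- if (f >= 1) 0L
    else if (f <= 0) round(p$head_event_rate_during_stops *
                             sum(vapply(move_segs, function(s) (s$i1 - s$i0) / fs, 1)))
    else round(n_stop_ev * (1 - f) / f)
    if (n_loc_ev > 0 && length(move_segs)) {
      lens <- vapply(move_segs, function(s) (s$i1 - s$i0) / fs, 1)
      # the re-orientation ramp at segment onset can last up to ~1.2 s
      # (180 deg at 150 deg/s); keep in-translation shifts clear of it
      ok_segs <- which(lens > 1.8)
      if (length(ok_segs)) {
        for (k in seq_len(n_loc_ev)) {
          s <- move_segs[[sample(ok_segs, 1)]]
          t0s <- tgrid[s$i0]; t1s <- tgrid[s$i1]
          lo <- t0s + max(0.4 * (t1s - t0s), 1.3)
          if (lo >= t1s - 0.25) next
          tcur <- stats::runif(1, lo, t1s - 0.2)
          sched[[length(sched) + 1L]] <- c(tcur, 1)
        }
      }
    }
    # realize each scheduled shift as a ballistic yaw rotation (sin^2
    # velocity profile). At constant pitch the quaternion geodesic between
    # consecutive samples equals the yaw increment exactly, so injected
    # amplitudes and peak velocities are recovered without bias. The yaw
    # offset persists until the next locomotion onset re-imposes heading
    # (the smoothing pass below turns that jump into a sub-threshold ramp).
    ev_rows <- list()
    delta_yaw <- numeric(n)
    move_starts <- vapply(move_segs, function(s) as.integer(s$i0), 1L)
    if (length(sched)) {
      ord <- order(vapply(sched, `[[`, 1, 1))
      sched <- sched[ord]
      last_end <- -Inf
      for (k in seq_along(sched)) {
        t_on <- sched[[k]][1]
        A <- rtrunc_lnorm(1, p$amplitude_meanlog, p$amplitude_sdlog,
                          p$amplitude_range[1], p$amplitude_range[2])
        ms <- p$main_sequence
        vpk <- naka_rushton(A, ms$r_max, ms$n, ms$k, ms$b) *
          stats::rlnorm(1, 0, p$main_sequence_noise)
        Tm <- 2 * A / vpk
        if (t_on < last_end + 0.1) next
        t_off <- t_on + Tm
        if (t_off > p$duration_s - 0.1) next
        last_end <- t_off
        i0 <- max(1L, ceiling(t_on * fs) + 1L)
        i1 <- min(n, floor(t_off * fs) + 1L)
        if (i1 <= i0 + 1L) next
        dir <- sample(c(-1, 1), 1)
        tt <- (tgrid[i0:i1] - t_on) / Tm
        theta <- A * (tt - sin(2 * pi * tt) / (2 * pi))
        nm <- move_starts[move_starts > i1]
        range_end <- if (length(nm)) nm[1] - 1L else n
        delta_yaw[i0:i1] <- delta_yaw[i0:i1] + dir * theta
        if (range_end > i1)
          delta_yaw[(i1 + 1L):range_end] <- delta_yaw[(i1 + 1L):range_end] + dir * A
        ev_rows[[length(ev_rows) + 1L]] <-
          data.frame(kind = "head", t_on = t_on, t_peak = t_on + Tm / 2,
                     t_off = t_off, peak_velocity = vpk, amplitude = A,
                     during_translation = sched[[k]][2] == 1)
      }
    }
    yaw <- yaw + delta_yaw
    # smooth residual discontinuities (heading re-imposition at locomotion
    # onsets, return ramps after in-translation shifts) at 150 deg/s, below
    # the 200 deg/s detection threshold; injected events are protected
    protected <- rep(FALSE, n)
    for (r in ev_rows) {
      i0 <- max(1L, ceiling(r$t_on * fs))
      i1 <- min(n, floor(r$t_off * fs) + 2L)
      protected[i0:i1] <- TRUE
    }
    max_step <- 150 / fs
    i <- 2L
    while (i <= n) {
      if (protected[i]) { i <- i + 1L; next }
      dy <- ((yaw[i] - yaw[i - 1] + 180) %% 360) - 180
      dp <- pitch[i] - pitch[i - 1]
      jump <- max(abs(dy), abs(dp))
      if (jump > max_step * 1.5) {
        k <- ceiling(jump / max_step)
        j1 <- min(n, i + k - 1L)
        pp <- which(protected[i:j1])
        if (length(pp)) j1 <- i + pp[1] - 2L
        if (j1 < i) { i <- i + 1L; next }
        frac2 <- seq_len(j1 - i + 1L) / (j1 - i + 1L)
        yaw[i:j1] <- yaw[i - 1] + dy * frac2
        pitch[i:j1] <- pitch[i - 1] + dp * frac2
        i <- j1 + 1L
      } else i <- i + 1L
    }
    base_q <- quat_from_euler(yaw, pitch, 0)
    head_ev <- if (length(ev_rows)) do.call(rbind, ev_rows) else
      data.frame(kind = character(), t_on = numeric(), t_peak = numeric(),
                 t_off = numeric(), peak_velocity = numeric(),
                 amplitude = numeric(), during_translation = logical())
    body_ev <- if (length(body_rows)) do.call(rbind, body_rows) else NULL
    if (!is.null(body_ev)) body_ev$during_translation <- NA
    pose <- pose_series(tgrid, pos, quat_normalize(base_q))
    list(pose = pose, events = rbind(head_ev, body_ev), stop_epochs = stop_ep)
  })
}

#' Default per-unit tuning specifications
#'
#' Pyramidal units draw tuning from \{place, view, hd\} (each with its own
#' probability), low base rates and burst doublets; interneurons draw from
#' \{ahv, ts\}, high base rates, no bursts. Some units of each type are
#' untuned.
#'
#' @param n_pyr,n_int unit counts.
#' @param maze a `maze_model` (place fields are seeded near its ports).
#' @param seed RNG seed.
#' @param p_place,p_view,p_hd,p_ahv,p_ts per-variable inclusion probabilities.
#' @return list of per-unit spec lists (fields: unit_id, type, base_rate,
#'   doublet_p, and a `terms` list of active tuning terms).
#' @export
make_unit_specs <- function(n_pyr, n_int, maze = maze_model(), seed = 1,
                            p_place = 0.6, p_view = 0.4, p_hd = 0.3,
                            p_ahv = 0.5, p_ts = 0.5) {
  local_seed(child_seed(seed, "unitspec"), {
    specs <- list()
    for (i in seq_len(n_pyr)) {
      terms <- list()
      if (stats::runif(1) < p_place) {
        # fields near reward ports so the field support is well sampled
        port <- maze$reward_ports[sample(nrow(maze$reward_ports), 1), ]
        terms$place <- list(center = port + stats::rnorm(3, 0, 8),
                            sigma = stats::runif(1, 10, 20),
                            gain = stats::runif(1, 4, 10))
      }
      if (stats::runif(1) < p_view)
        terms$view <- list(face = sample(c("x0", "x1", "y0", "y1"), 1),
                           center = c(stats::runif(1, 5, 45), stats::runif(1, 10, 110)),
                           sigma = stats::runif(1, 10, 25),
                           gain = stats::runif(1, 4, 10))
      if (stats::runif(1) < p_hd)
        terms$hd <- list(mu = stats::runif(1, -180, 180),
                         kappa = stats::runif(1, 1, 3),
                         gain = stats::runif(1, 3, 6))
      specs[[length(specs) + 1L]] <-
        list(unit_id = sprintf("pyr%03d", i), type = "pyramidal",
             base_rate = stats::runif(1, 0.5, 2),
             doublet_p = stats::runif(1, 0.25, 0.45), terms = terms)
    }
    for (i in seq_len(n_int)) {
      terms <- list()
      if (stats::runif(1) < p_ahv)
        terms$ahv <- list(v_sat = stats::runif(1, 150, 300),
                          gain = stats::runif(1, 2, 4))
      if (stats::runif(1) < p_ts)
        terms$ts <- list(v_sat = stats::runif(1, 20, 50),
                         gain = stats::runif(1, 2, 4))
      specs[[length(specs) + 1L]] <-
        list(unit_id = sprintf("int%03d", i), type = "interneuron",
             base_rate = stats::runif(1, 12, 25),
             doublet_p = 0, terms = terms)
    }
    specs
  })
}

#' Generate spike trains from pose and tuning specs
#'
#' Inhomogeneous Poisson spiking with log-additive tuning terms evaluated
#' on the 60 Hz pose grid; optional burst doublets (extra spike 2-20 ms
#' after a parent spike). Errors if any instantaneous rate exceeds 500 Hz.
#'
#' @param pose a `pose_series`.
#' @param specs list from [make_unit_specs()] (or hand-built).
#' @param maze a `maze_model` (for view tuning).
#' @param seed RNG seed.
#' @param kin,view optional precomputed kinematics/view frames.
#' @return list: `units` (list of `unit_profile`s), `truth` (per-unit list
#'   of generating terms and labels).
#' @export
gen_spikes <- function(pose, specs, maze = maze_model(), seed = 1,
                       kin = NULL, view = NULL) {
  fs <- pose$fs
  dt <- 1 / fs
  duration <- max(pose$t) + dt
  kin <- kin %||% compute_kinematics(pose, analysis_config())
  view <- view %||% project_view(pose, maze)
  yaw <- atan2(2 * (pose$quat[, 1] * pose$quat[, 4] + pose$quat[, 2] * pose$quat[, 3]),
               1 - 2 * (pose$quat[, 3]^2 + pose$quat[, 4]^2)) * 180 / pi
  n <- length(pose$t)
  ahv_s <- c(kin$ahv, 0); ts_s <- c(kin$ts, 0)
  ahv_s[!is.finite(ahv_s)] <- 0; ts_s[!is.finite(ts_s)] <- 0
  units <- list(); truth <- list()
  local_seed(child_seed(seed, "spikes"), {
    for (sp in specs) {
      lograte <- rep(log(sp$base_rate), n)
      tm <- sp$terms
      if (!is.null(tm$place)) {
        # additive per-dimension bumps: the log-rate is a sum of smooth
        # one-dimensional terms, the model family the encoding GAM assumes
        g <- 0
        for (j in 1:3)
          g <- g + exp(-(pose$pos[, j] - tm$place$center[j])^2 /
                         (2 * tm$place$sigma^2))
        lograte <- lograte + log(tm$place$gain) * g / 3
      }
      if (!is.null(tm$view)) {
        gc <- view_global_coords(maze, tm$view$face,
                                 tm$view$center[1], tm$view$center[2])
        gs <- view_global_coords(maze, view$face, view$u, view$v)
        bu <- exp(-(gs$gu - gc$gu)^2 / (2 * tm$view$sigma^2))
        bv <- exp(-(gs$gv - gc$gv)^2 / (2 * tm$view$sigma^2))
        bump <- (bu + bv) / 2
        bump[is.na(bump)] <- 0
        lograte <- lograte + log(tm$view$gain) * bump
      }
      if (!is.null(tm$hd)) {
        ang <- (yaw - tm$hd$mu) * pi / 180
        lograte <- lograte + log(tm$hd$gain) *
          exp(tm$hd$kappa * (cos(ang) - 1))
      }
      if (!is.null(tm$ahv))
        lograte <- lograte + log(tm$ahv$gain) * pmin(ahv_s / tm$ahv$v_sat, 1)
      if (!is.null(tm$ts))
        lograte <- lograte + log(tm$ts$gain) * pmin(ts_s / tm$ts$v_sat, 1)
      rate <- exp(lograte)
      if (any(rate > 500)) stop("tuning too strong: rate exceeds 500 Hz")
      counts <- stats::rpois(n, rate * dt)
      times <- rep(pose$t, counts) + stats::runif(sum(counts), 0, dt)
      if (sp$doublet_p > 0 && length(times)) {
        parents <- times[stats::runif(length(times)) < sp$doublet_p]
        extra <- parents + stats::runif(length(parents), 0.002, 0.008)
        times <- c(times, extra)
      }
      times <- sort(times[times < duration])
      units[[length(units) + 1L]] <- unit_profile(sp$unit_id, times)
      truth[[sp$unit_id]] <- list(type = sp$type,
                                  variables = if (length(tm)) names(tm) else character(0),
                                  label = if (length(tm) == 0) "none"
                                  else if (length(tm) == 1) "single" else "mixed",
                                  base_rate = sp$base_rate,
                                  doublet_p = sp$doublet_p,
                                  terms = tm)
    }
  })
  list(units = units, truth = truth)
}

#' Generate an LFP channel with theta phase resetting
#'
#' signal = 1/f^a background + theta whose phase jumps to `reset_phase` at
#' each event time and whose amplitude gains `reset_gain` (decaying with
#' time constant `reset_decay_s`) after each event.
#'
#' @param event_times head-movement peak-velocity times [s].
#' @param params a `generator_params`.
#' @return an `lfp_series`; the injected reset phase is in
#'   `attr(, "reset_phase")`.
#' @export
gen_lfp <- function(event_times, params) {
  p <- params
  fs <- p$lfp_fs
  if (fs < 40) stop("fs too low for theta")
  n <- floor(p$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  local_seed(child_seed(p$seed, "lfp"), {
    # 1/f^a background via FFT amplitude shaping
    w <- stats::rnorm(n)
    W <- stats::fft(w)
    fax <- seq(0, n - 1) / n * fs
    fax <- pmin(fax, fs - fax)
    shape <- ifelse(fax > 0, fax^(-p$aperiodic_exponent / 2), 0)
    bg <- Re(stats::fft(W * shape, inverse = TRUE)) / n
    bg <- bg / stats::sd(bg)
    sig <- bg
    if (p$theta_amp > 0) {
      # theta with phase diffusion so coherence decays between resets
      inc <- 2 * pi * p$theta_freq / fs +
        stats::rnorm(n, 0, p$phase_diffusion / sqrt(fs))
      phase <- cumsum(inc) + stats::runif(1, 0, 2 * pi)
      amp <- rep(p$theta_amp, n)
      if (p$reset_gain > 0) {
        ev <- sort(event_times[event_times > 0 & event_times < p$duration_s])
        for (e in ev) {
          i0 <- floor(e * fs) + 1L
          if (i0 > n) next
          idx <- i0:n
          rel <- t[idx] - e
          # phase jumps to the reset value, then evolves (with diffusion)
          phase[idx] <- p$reset_phase + (phase[idx] - phase[i0])
          amp[idx] <- p$theta_amp *
            (1 + p$reset_gain * exp(-rel / p$reset_decay_s))
        }
      }
      sig <- sig + amp * cos(phase)
    }
    out <- lfp_series(sig, fs, "lfp1")
    attr(out, "reset_phase") <- p$reset_phase
    out
  })
}

#' Generate a complete synthetic session bundle
#'
#' Composes [gen_behavior()], [gen_spikes()] and [gen_lfp()]; a fixed seed
#' gives bit-identical output.
#'
#' @param params a `generator_params`.
#' @param specs optional unit specs (default [make_unit_specs()] at the
#'   configured counts).
#' @return list: `bundle` (a `session_bundle`), `truth` (class
#'   `session_ground_truth`: per-unit generating models, the true event
#'   list, stop epochs, and the LFP reset phase).
#' @export
gen_session <- function(params = generator_params(), specs = NULL) {
  beh <- gen_behavior(params)
  specs <- specs %||% make_unit_specs(params$n_pyr, params$n_int, params$maze,
                                      params$seed)
  spk <- gen_spikes(beh$pose, specs, params$maze, params$seed)
  head_peaks <- beh$events$t_peak[beh$events$kind == "head"]
  lfp <- gen_lfp(head_peaks, params)
  bundle <- session_bundle(sprintf("synthetic-seed%d", as.integer(params$seed)),
                           beh$pose, spk$units, list(lfp), params$maze,
                           meta = list(species = "synthetic_marmoset",
                                       tracking_fs = 60, lfp_fs = params$lfp_fs,
                                       seed = params$seed))
  truth <- structure(list(units = spk$truth, events = beh$events,
                          stop_epochs = beh$stop_epochs,
                          reset_phase = params$reset_phase,
                          params = params),
                     class = "session_ground_truth")
  list(bundle = bundle, truth = truth)
}
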