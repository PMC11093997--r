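#' Head-gaze and body kinematics
#'
#' Translation speed (TS) is the Euclidean step length of the low-pass
#' filtered 3D position per unit time. Angular head velocity (AHV) is the
#' geodesic quaternion distance between consecutive samples per unit time.
#' Rapid head movements and body translations are detected as
#' supra-threshold epochs of these series, and the amplitude/peak-velocity
#' relation (main sequence) is summarized with a Naka-Rushton fit.
#'
#' @name kinematics
NULL

#' Translation speed (cm/s)
#'
#' Position is zero-phase low-pass filtered (default 4 Hz) before
#' differencing; speed for interval i is assigned to the interval midpoint.
#'
#' @param pose a `pose_series`.
#' @param lowpass_hz low-pass cutoff in Hz; `NA` or `Inf` bypasses the filter.
#' @return data frame `t`, `ts` with n-1 rows (NA across tracking gaps).
#' @export
translation_speed <- function(pose, lowpass_hz = 4) {
  n <- length(pose$t)
  if (sum(pose$valid) < 2) stop("need at least 2 valid samples")
  dt <- diff(pose$t)
  if (max(abs(dt - stats::median(dt))) > 0.25 * stats::median(dt))
    stop("resample required: non-uniform time axis")
  pos <- pose$pos
  if (is.finite(lowpass_hz)) {
    # filter each contiguous valid run independently; gaps are never bridged
    runs <- valid_runs(pose$valid)
    for (r in seq_len(nrow(runs))) {
      idx <- runs[r, 1]:runs[r, 2]
      if (length(idx) >= 8)
        for (j in 1:3)
          pos[idx, j] <- filtfilt_butter(pos[idx, j], pose$fs, order = 4,
                                         high = lowpass_hz)
    }
  }
  step <- sqrt(rowSums(diff(pos)^2))
  ts <- step / dt
  ok <- pose$valid[-n] & pose$valid[-1]
  ts[!ok] <- NA_real_
  data.frame(t = pose$t[-n] + dt / 2, ts = ts)
}

valid_runs <- function(valid) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

#' Angular head velocity (deg/s)
#'
#' omega_i = angular_distance(q_i, q_{i+1}) / dt, assigned to the interval
#' midpoint. Gaps propagate as missing values.
#'
#' @param pose a `pose_series`.
#' @return data frame `t`, `ahv`, `ang_dist` (deg), `dt` with n-1 rows.
#' @export
angular_head_velocity <- function(pose) {
  n <- length(pose$t)
  dt <- diff(pose$t)
  theta <- angular_distance(pose$quat[-n, , drop = FALSE],
                            pose$quat[-1, , drop = FALSE])
  ok <- pose$valid[-n] & pose$valid[-1]
  theta[!ok] <- NA_real_
  data.frame(t = pose$t[-n] + dt / 2, ahv = theta / dt, ang_dist = theta, dt = dt)
}

#' Combined kinematic series
#'
#' Convenience wrapper returning TS and AHV on the shared midpoint grid.
#'
#' @inheritParams translation_speed
#' @param cfg an [analysis_config()].
#' @return data frame `t`, `ts`, `ahv`.
#' @export
compute_kinematics <- function(pose, cfg = analysis_config()) {
  ts <- translation_speed(pose, cfg$ts_lowpass_hz)
  av <- angular_head_velocity(pose)
  data.frame(t = ts$t, ts = ts$ts, ahv = av$ahv)
}

# Epochs above `thresh`, extended outward to the nearest local minimum below
# half-threshold; returns event rows with path-integrated amplitude.
detect_one_kind <- function(t, v, thresh, amp_min, vel_artifact, dt) {
  above <- !is.na(v) & v > thresh
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ev_s <- starts[r$values]; ev_e <- ends[r$values]
  half <- thresh / 2
  n <- length(v)
  out <- vector("list", length(ev_s))
  for (k in seq_along(ev_s)) {
    s <- ev_s[k]; e <- ev_e[k]
    # extend outward to the nearest local minima below half-threshold
    while (s > 1L) {
      prev <- v[s - 1L]
      if (is.na(prev) || (v[s] < half && prev >= v[s])) break
      s <- s - 1L
    }
    while (e < n) {
      nxt <- v[e + 1L]
      if (is.na(nxt) || (v[e] < half && nxt >= v[e])) break
      e <- e + 1L
    }
    idx <- s:e
    pk <- idx[which.max(v[idx])]           # earliest sample on plateaus
    amp <- sum(v[idx] * dt[idx], na.rm = TRUE)
    out[[k]] <- data.frame(t_on = t[s], t_peak = t[pk], t_off = t[e] + dt[e],
                           peak_velocity = v[pk], amplitude = amp)
  }
  ev <- do.call(rbind, out)
  # merge events sharing extended boundaries (overlapping windows)
  keep <- c(TRUE, ev$t_on[-1] >= ev$t_off[-nrow(ev)] - 1e-9)
  ev <- ev[keep, , drop = FALSE]
  ev$artifact <- ev$peak_velocity > vel_artifact
  ev[ev$amplitude >= amp_min | ev$artifact, , drop = FALSE]
}

#' Detect rapid head movements and body translations
#'
#' Head events: AHV above `head_vel_thresh` (200 deg/s) with path-integrated
#' amplitude >= `head_amp_min` (10 deg); peaks above 2000 deg/s are
#' artifactual and excluded (returned flagged). Body events: TS above
#' 16 cm/s, amplitude >= 30 cm, artifact ceiling 300 cm/s. Epochs extend to
#' the nearest local minima below half-threshold on each side.
#'
#' @param kin data frame from [compute_kinematics()].
#' @param cfg an [analysis_config()].
#' @return data frame of events:
#'   `kind,t_on,t_peak,t_off,peak_velocity,amplitude,during_translation,artifact`.
#' @export
detect_movements <- function(kin, cfg = analysis_config()) {
  dt <- c(diff(kin$t), stats::median(diff(kin$t)))
  head <- detect_one_kind(kin$t, kin$ahv, cfg$head_vel_thresh,
                          cfg$head_amp_min, cfg$head_vel_artifact, dt)
  body <- detect_one_kind(kin$t, kin$ts, cfg$body_vel_thresh,
                          cfg$body_amp_min, cfg$body_vel_artifact, dt)
  empty <- data.frame(t_on = numeric(), t_peak = numeric(), t_off = numeric(),
                      peak_velocity = numeric(), amplitude = numeric(),
                      artifact = logical())
  head <- head %||% empty; body <- body %||% empty
  head$kind <- rep("head", nrow(head)); body$kind <- rep("body", nrow(body))
  ev <- rbind(head, body)
  ev <- ev[order(ev$t_on), , drop = FALSE]
  bd <- ev[ev$kind == "body" & !ev$artifact, , drop = FALSE]
  ev$during_translation <- ev$kind == "head" &
    vapply(ev$t_peak, function(tp)
      any(tp >= bd$t_on & tp < bd$t_off), logical(1))
  rownames(ev) <- NULL
  ev[, c("kind", "t_on", "t_peak", "t_off", "peak_velocity", "amplitude",
         "during_translation", "artifact")]
}

#' Fraction of head movements during body stops vs translations
#'
#' A head event counts as "during translation" if its peak-velocity time
#' falls inside any body event's half-open interval. Bootstrap CI resamples
#' head events.
#'
#' @param events data frame from [detect_movements()] (artifacts excluded
#'   internally).
#' @param cfg an [analysis_config()].
#' @return list with `frac_during_stops`, `frac_during_translation`, `ci`
#'   (for the stop fraction), and `n_head`.
#' @export
movement_concurrency <- function(events, cfg = analysis_config()) {
  he <- events[events$kind == "head" & !events$artifact, , drop = FALSE]
  if (nrow(he) == 0)
    return(list(frac_during_stops = NA_real_, frac_during_translation = NA_real_,
                ci = c(NA_real_, NA_real_), n_head = 0L))
  during <- he$during_translation
  f_tr <- mean(during)
  boot <- local_seed(cfg$seed, replicate(cfg$concurrency_n_boot,
                                         mean(sample(during, replace = TRUE))))
  a <- (1 - cfg$concurrency_ci) / 2
  ci_tr_stop <- stats::quantile(1 - boot, c(a, 1 - a), names = FALSE)
  list(frac_during_stops = 1 - f_tr, frac_during_translation = f_tr,
       ci = ci_tr_stop, n_head = nrow(he))
}

#' Main sequence of head movements
#'
#' Events binned by amplitude; per-bin mean peak velocity with a 95% normal
#' CI. Bins with fewer than `min_count` events are dropped.
#'
#' @param events head-event data frame (non-artifact rows are used).
#' @param bin_edges amplitude bin edges [deg].
#' @param min_count minimum events per retained bin.
#' @return data frame `amp_lo, amp_hi, amp_mid, mean_peak_vel, ci_lo, ci_hi, n`.
#' @export
main_sequence <- function(events, bin_edges = seq(10, 90, by = 5), min_count = 1) {
  he <- events[events$kind == "head" & !events$artifact, , drop = FALSE]
  bin <- cut(he$amplitude, bin_edges, right = FALSE, labels = FALSE)
  rows <- lapply(seq_len(length(bin_edges) - 1L), function(b) {
    v <- he$peak_velocity[!is.na(bin) & bin == b]
    if (length(v) < min_count) return(NULL)
    se <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
    data.frame(amp_lo = bin_edges[b], amp_hi = bin_edges[b + 1],
               amp_mid = (bin_edges[b] + bin_edges[b + 1]) / 2,
               mean_peak_vel = mean(v),
               ci_lo = mean(v) - 1.96 * se, ci_hi = mean(v) + 1.96 * se,
               n = length(v))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("all amplitude bins empty")
  out
}

#' Naka-Rushton function
#'
#' R(x) = R_max * x^n / (x^n + K^n) + b: a saturating curve with peak
#' response `r_max`, exponent `n`, half-saturation `k`, and additive
#' constant `b`.
#'
#' @param x predictor (amplitude, ensemble size, ...).
#' @param r_max,n,k,b parameters.
#' @export
naka_rushton <- function(x, r_max, n, k, b) r_max * x^n / (x^n + k^n) + b

#' Fit a Naka-Rushton curve by multi-start non-linear least squares
#'
#' Initialization: R_max0 = max(r) - min(r), b0 = min(r), K0 = median(x),
#' n0 = 2, plus jittered restarts; the best residual wins. Positivity is
#' enforced on r_max, k and n.
#'
#' @param x predictor values.
#' @param r responses.
#' @param n_starts number of jittered restarts.
#' @param seed RNG seed for the jitter.
#' @return list of class `naka_rushton_fit`: `par` (r_max, n, k, b),
#'   `residual_norm`, `fitted`, `convergence`.
#' @export
fit_naka_rushton <- function(x, r, n_starts = 10, seed = 1) {
  stopifnot(length(x) == length(r), length(x) >= 4)
  obj <- function(p) {
    pr <- naka_rushton(x, exp(p[1]), exp(p[2]), exp(p[3]), p[4])
    sum((pr - r)^2)
  }
  base <- c(log(max(max(r) - min(r), 1e-3)), log(2),
            log(max(stats::median(x), 1e-3)), min(r))
  best <- NULL
  local_seed(seed, {
    for (s in seq_len(n_starts)) {
      p0 <- base
      if (s > 1) p0 <- p0 + c(stats::rnorm(3, 0, 0.4), stats::rnorm(1, 0, 0.2 * stats::sd(r)))
      fit <- tryCatch(stats::optim(p0, obj, method = "BFGS",
                                   control = list(maxit = 500, reltol = 1e-12)),
                      error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
  })
  if (is.null(best)) stop("fit failed: no start converged")
  par <- c(r_max = exp(best$par[1]), n = exp(best$par[2]),
           k = exp(best$par[3]), b = best$par[4])
  structure(list(par = par, residual_norm = sqrt(best$value),
                 fitted = naka_rushton(x, par[1], par[2], par[3], par[4]),
                 convergence = best$convergence == 0),
            class = "naka_rushton_fit")
}

#' Build a 2D pose series from front/back LED tracks
#'
#' For two-LED (rat-style) tracking: position is the LED midpoint, yaw the
#' atan2 of the front-minus-back vector (east = +x = 0 deg); pitch and roll
#' are undefined and the quaternion encodes yaw only. Lets the full
#' kinematics stack run on planar pose data.
#'
#' @param front_xy,back_xy n x 2 matrices [cm].
#' @param fs sampling rate [Hz].
#' @return a `pose_series` with z = 0.
#' @export
led_pair_to_pose <- function(front_xy, back_xy, fs) {
  front_xy <- as.matrix(front_xy); back_xy <- as.matrix(back_xy)
  stopifnot(nrow(front_xy) == nrow(back_xy))
  d <- front_xy - back_xy
  coincident <- rowSums(d^2) < 1e-12
  yaw <- atan2(d[, 2], d[, 1]) * 180 / pi
  q <- quat_from_euler(yaw, 0, 0)
  mid <- (front_xy + back_xy) / 2
  t <- seq(0, by = 1 / fs, length.out = nrow(front_xy))
  pose_series(t, cbind(mid, 0), q, valid = !coincident)
}
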