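# Shared fixtures, memoized so expensive synthetic sessions are generated
# once per test run. Durations and permutation counts are scaled down from
# the session-scale defaults purely for run time; every generator setting
# that the analyses make claims about (thresholds, main-sequence parameters,
# stop fraction, tuning forms) is left at its default.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fix)) assign(key, force(expr), envir = .fix)
  get(key, envir = .fix)
}

# Mid-size mixed session for unit metrics / tuning tests.
ms_session <- function() memo("ms", {
  gen_session(generator_params(duration_s = 600, n_pyr = 8, n_int = 5, seed = 3))
})

ms_kin <- function() memo("ms_kin", {
  compute_kinematics(ms_session()$bundle$tracking)
})

# Larger pyramidal-only session for place decoding.
decode_session <- function() memo("dec", {
  gen_session(generator_params(duration_s = 900, n_pyr = 20, n_int = 0, seed = 7))
})

decode_trials <- function() memo("dec_trials", {
  s <- decode_session()
  kin <- compute_kinematics(s$bundle$tracking)
  extract_trials(s$bundle, kin, analysis_config())
})

# Single-variable tuned units for GAM selection recovery.
gam_specs <- function() list(
  list(unit_id = "u_pl1", type = "pyramidal", base_rate = 1, doublet_p = 0,
       terms = list(place = list(center = c(5, 5, 5), sigma = 15, gain = 8))),
  list(unit_id = "u_pl2", type = "pyramidal", base_rate = 1.5, doublet_p = 0,
       terms = list(place = list(center = c(95, 45, 85), sigma = 12, gain = 8))),
  list(unit_id = "u_vw1", type = "pyramidal", base_rate = 1, doublet_p = 0,
       terms = list(view = list(face = "y0", center = c(30, 60), sigma = 20, gain = 8))),
  list(unit_id = "u_vw2", type = "pyramidal", base_rate = 1.5, doublet_p = 0,
       terms = list(view = list(face = "x1", center = c(25, 40), sigma = 18, gain = 8))),
  list(unit_id = "u_hd1", type = "pyramidal", base_rate = 1, doublet_p = 0,
       terms = list(hd = list(mu = 45, kappa = 2, gain = 5))),
  list(unit_id = "u_hd2", type = "pyramidal", base_rate = 1.5, doublet_p = 0,
       terms = list(hd = list(mu = -120, kappa = 2, gain = 5))),
  list(unit_id = "u_ahv", type = "interneuron", base_rate = 15, doublet_p = 0,
       terms = list(ahv = list(v_sat = 250, gain = 3))),
  list(unit_id = "u_ts", type = "interneuron", base_rate = 15, doublet_p = 0,
       terms = list(ts = list(v_sat = 30, gain = 3))),
  list(unit_id = "u_null", type = "pyramidal", base_rate = 2, doublet_p = 0,
       terms = list())
)

gam_fixture <- function() memo("gamfix", {
  p <- generator_params(duration_s = 400, seed = 21)
  beh <- gen_behavior(p)
  spk <- gen_spikes(beh$pose, gam_specs(), p$maze, seed = 21)
  b <- session_bundle("gamfix", beh$pose, spk$units, list(), p$maze)
  list(bundle = b, truth = spk$truth,
       kin = compute_kinematics(b$tracking),
       view = project_view(b$tracking, b$maze))
})

# A pose rotating about +z at a constant rate (deg/s), identity start.
rotating_pose <- function(rate_dps, duration = 2, fs = 60) {
  t <- seq(0, duration, by = 1 / fs)
  yaw <- rate_dps * t
  pose_series(t, matrix(0, length(t), 3), quat_from_euler(yaw, 0, 0))
}

# Kinematic frame with a single triangular AHV pulse of given peak (deg/s)
# and width (s) on an otherwise-quiet trace.
pulse_kin <- function(peak, width = 0.3, fs = 60, duration = 10, at = 5) {
  t <- seq(0, duration, by = 1 / fs)
  v <- rep(0, length(t))
  half <- width / 2
  inside <- abs(t - at) < half
  v[inside] <- peak * (1 - abs(t[inside] - at) / half)
  data.frame(t = t, ts = rep(0, length(t)), ahv = v)
}

# Independent rotation-matrix oracle for the angle between two quaternions.
angle_matrix_oracle <- function(q1, q2) {
  R <- t(marmonav:::quat_to_matrix(q1)) %*% marmonav:::quat_to_matrix(q2)
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}

random_unit_quat <- function(n) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}
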