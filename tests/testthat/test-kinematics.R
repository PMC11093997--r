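test_that("translation speed: stationary, 3-4-5 step, and finite-difference oracle", {
  t <- seq(0, 2, by = 1 / 60)
  n <- length(t)
  still <- pose_series(t, matrix(5, n, 3), quat_from_euler(rep(0, n), 0, 0))
  expect_true(all(abs(translation_speed(still, lowpass_hz = Inf)$ts) < 1e-12))

  # (3,4,0) cm over 1 s sampled at 1 Hz, filter bypassed -> 5 cm/s
  t2 <- 0:3
  pos <- cbind(3 * t2, 4 * t2, 0)
  p <- pose_series(t2, pos, quat_from_euler(rep(0, 4), 0, 0))
  expect_equal(translation_speed(p, lowpass_hz = Inf)$ts, rep(5, 3))

  # random walk vs an independent finite-difference oracle on the same input
  set.seed(11)
  pos3 <- apply(matrix(rnorm(3 * n, sd = 0.5), n, 3), 2, cumsum)
  p3 <- pose_series(t, pos3, quat_from_euler(rep(0, n), 0, 0))
  got <- translation_speed(p3, lowpass_hz = Inf)$ts
  oracle <- sqrt(rowSums((pos3[-1, ] - pos3[-n, ])^2)) / diff(t)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("angular distance matches the rotation-matrix oracle and double cover", {
  q <- quat_from_euler(30, 10, 5)
  expect_equal(angular_distance(q, q), 0)
  expect_equal(angular_distance(q, -q), 0)
  set.seed(12)
  q1 <- random_unit_quat(50); q2 <- random_unit_quat(50)
  got <- angular_distance(q1, q2)
  oracle <- vapply(1:50, function(i) angle_matrix_oracle(q1[i, ], q2[i, ]),
                   numeric(1))
  expect_equal(got, oracle, tolerance = 1e-8)
  expect_error(angular_distance(c(0, 0, 0, 0), q), "zero-norm")
})

test_that("AHV recovers constant rotation rate and is invariant to global rotation", {
  pose <- rotating_pose(90)
  av <- angular_head_velocity(pose)
  expect_true(all(abs(av$ahv - 90) < 0.1))

  ident <- pose_series(pose$t, pose$pos,
                       quat_from_euler(rep(0, length(pose$t)), 0, 0))
  expect_true(all(angular_head_velocity(ident)$ahv == 0))

  # composite yaw+pitch rotation against the rotation-matrix oracle
  t <- seq(0, 1, by = 1 / 60)
  q <- quat_from_euler(40 * t, 25 * t, 0)
  posec <- pose_series(t, matrix(0, length(t), 3), q)
  got <- angular_head_velocity(posec)$ahv
  oracle <- vapply(seq_len(length(t) - 1), function(i)
    angle_matrix_oracle(q[i, ], q[i + 1, ]), numeric(1)) * 60
  expect_equal(got, oracle, tolerance = 1e-6)

  # left-multiply all quaternions by one fixed rotation: AHV unchanged
  g <- quat_from_euler(77, -20, 31)
  qg <- marmonav:::quat_multiply(matrix(g, length(t), 4, byrow = TRUE), q)
  poseg <- pose_series(t, matrix(0, length(t), 3), qg)
  expect_equal(angular_head_velocity(poseg)$ahv, got, tolerance = 1e-8)
})

test_that("movement detection applies velocity, amplitude and artifact rules", {
  cfg <- analysis_config()
  # pulse peaking 300 deg/s, integral = 0.5*300*0.3 = 45 deg -> one event
  ev <- detect_movements(pulse_kin(300, width = 0.3), cfg)
  expect_equal(sum(ev$kind == "head" & !ev$artifact), 1)
  expect_equal(ev$t_peak[1], 5, tolerance = 0.02)
  expect_equal(ev$amplitude[1], 45, tolerance = 2)

  # below the 200 deg/s threshold -> nothing
  expect_equal(nrow(detect_movements(pulse_kin(150), cfg)), 0)

  # above 2000 deg/s -> no usable event, one artifact record
  eva <- detect_movements(pulse_kin(2500), cfg)
  expect_equal(sum(!eva$artifact), 0)
  expect_equal(sum(eva$artifact), 1)

  # sub-threshold amplitude: 250 deg/s peak, 0.06 s width -> ~7.5 deg < 10
  expect_equal(nrow(detect_movements(pulse_kin(250, width = 0.06), cfg)), 0)
})

test_that("raising the velocity threshold never adds events", {
  s <- ms_session()
  kin <- ms_kin()
  n1 <- sum(detect_movements(kin, analysis_config())$kind == "head")
  n2 <- sum(detect_movements(kin, analysis_config(head_vel_thresh = 300))$kind == "head")
  n3 <- sum(detect_movements(kin, analysis_config(head_vel_thresh = 450))$kind == "head")
  expect_true(n2 <= n1 && n3 <= n2)
  # idempotent under re-run
  expect_identical(detect_movements(kin, analysis_config()),
                   detect_movements(kin, analysis_config()))
})

test_that("concurrency uses half-open body intervals and bootstraps a CI", {
  he <- data.frame(kind = "head", t_on = c(0.9, 4.9), t_peak = c(1, 5),
                   t_off = c(1.1, 5.1), peak_velocity = 300, amplitude = 20,
                   during_translation = NA, artifact = FALSE)
  bd <- data.frame(kind = "body", t_on = 4, t_peak = 4.5, t_off = 5,
                   peak_velocity = 30, amplitude = 40,
                   during_translation = NA, artifact = FALSE)
  ev <- rbind(he, bd)
  ev$during_translation <- ev$kind == "head" &
    vapply(ev$t_peak, function(tp) tp >= bd$t_on & tp < bd$t_off, logical(1))
  cc <- movement_concurrency(ev, analysis_config())
  # peak at exactly t_off = 5 counts as during stop (half-open interval)
  expect_equal(cc$frac_during_stops, 1)
  expect_true(is.na(movement_concurrency(ev[ev$kind == "body", ],
                                         analysis_config())$frac_during_stops))
})

test_that("main sequence bins events and degenerate input collapses its CI", {
  one <- data.frame(kind = "head", t_on = 1:5, t_peak = 1:5 + 0.05,
                    t_off = 1:5 + 0.1, peak_velocity = 400, amplitude = 22,
                    during_translation = FALSE, artifact = FALSE)
  ms <- main_sequence(one)
  expect_equal(nrow(ms), 1)
  expect_equal(ms$ci_hi - ms$ci_lo, 0)

  # noiseless events on the generating curve -> bin means on the curve
  set.seed(13)
  amp <- runif(400, 10, 88)
  ev <- data.frame(kind = "head", t_on = seq_along(amp), t_peak = seq_along(amp),
                   t_off = seq_along(amp) + 0.1,
                   peak_velocity = naka_rushton(amp, 795, 2, 20, 50),
                   amplitude = amp, during_translation = FALSE, artifact = FALSE)
  ms2 <- main_sequence(ev, bin_edges = seq(10, 90, 10))
  curve_at_mid <- naka_rushton(ms2$amp_mid, 795, 2, 20, 50)
  expect_true(all(abs(ms2$mean_peak_vel - curve_at_mid) / curve_at_mid < 0.05))
})

test_that("Naka-Rushton fit: identities and noiseless parameter recovery", {
  par0 <- c(r_max = 795, n = 2, k = 20, b = 50)
  # R(K) = R_max/2 + b and R(0) = b
  expect_equal(naka_rushton(20, 795, 2, 20, 50), 795 / 2 + 50)
  expect_equal(naka_rushton(0, 795, 2, 20, 50), 50)

  set.seed(14)
  x <- seq(5, 90, length.out = 40)
  r <- naka_rushton(x, par0[1], par0[2], par0[3], par0[4])
  fit <- fit_naka_rushton(x, r, seed = 2)
  expect_true(all(abs(fit$par - par0) / par0 < 1e-3))
  expect_true(fit$convergence)
})

test_that("LED-pair poses give the stated yaw convention and AHV", {
  # front east of back -> yaw 0; front north of back -> yaw 90
  p1 <- led_pair_to_pose(cbind(2, 0), cbind(0, 0), fs = 60)
  expect_equal(angular_distance(p1$quat, quat_from_euler(0, 0, 0)), 0,
               tolerance = 1e-8)
  p2 <- led_pair_to_pose(cbind(0, 2), cbind(0, 0), fs = 60)
  expect_equal(angular_distance(p2$quat, quat_from_euler(90, 0, 0)), 0,
               tolerance = 1e-8)

  t <- seq(0, 2, by = 1 / 60)
  ang <- 50 * t * pi / 180
  front <- cbind(cos(ang), sin(ang)); back <- -front
  pr <- led_pair_to_pose(front, back, fs = 60)
  expect_true(all(abs(angular_head_velocity(pr)$ahv - 50) < 0.1))

  pc <- led_pair_to_pose(cbind(c(1, 1), c(0, 0)), cbind(c(0, 1), c(0, 0)), fs = 60)
  expect_false(pc$valid[2])  # coincident LEDs -> missing sample
})
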