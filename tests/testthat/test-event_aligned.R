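test_that("LFP preprocessing preserves theta, removes DC, masks HF bursts", {
  fs <- 1000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 8 * t)
  pp <- preprocess_lfp(x + 3, fs)   # DC offset on a clean theta sinusoid
  mid <- 2000:18000
  expect_lt(abs(mean(pp$samples[mid])), 0.02)
  amp_ratio <- stats::sd(pp$samples[mid]) / stats::sd(x[mid])
  expect_lt(abs(amp_ratio - 1), 0.05)
  expect_false(any(pp$artifact_mask))

  # 150 Hz burst at 10x background amplitude -> masked with +-100 ms padding
  set.seed(51)
  noise <- rnorm(length(t), 0, 0.2)
  burst <- ifelse(t > 10 & t < 10.2, 10 * sin(2 * pi * 150 * t), 0)
  pp2 <- preprocess_lfp(x + noise + burst, fs)
  burst_idx <- which(t > 10 & t < 10.2)
  expect_true(all(pp2$artifact_mask[burst_idx]))
  expect_true(pp2$artifact_mask[min(burst_idx) - 90])
  expect_false(any(pp2$artifact_mask[t < 9.5]))
})

test_that("theta phase tracks an analytic oscillation including sign flips", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  lfp <- lfp_series(cos(2 * pi * 6 * t), fs)
  ph <- theta_phase(lfp, c(4, 10))
  mid <- 2000:8000
  # phase advances at 6 cycles/s
  slope <- stats::lm(unwrap ~ t, data.frame(unwrap = cumsum(c(ph[mid][1],
    (diff(ph[mid]) + pi) %% (2 * pi) - pi)), t = t[mid]))$coefficients[2]
  expect_equal(unname(slope), 2 * pi * 6, tolerance = 0.01)
  # cos peaks -> phase 0 (mod 2pi)
  pk <- which.min(abs(t - 1))  # t=1 s: cos(12 pi) = 1
  expect_lt(abs(ph[pk]), 0.05)
  # -cos is offset by pi
  ph2 <- theta_phase(lfp_series(-cos(2 * pi * 6 * t), fs), c(4, 10))
  d <- abs(abs(ph2[pk] - ph[pk]) - pi)
  expect_lt(d, 0.05)
})

test_that("Rayleigh statistics: identity at perfect locking, null near 1", {
  r <- rayleigh_test(rep(1.3, 40))
  expect_equal(r$z, 40)
  expect_equal(r$r_bar, 1)
  expect_lt(r$p, 1e-10)

  set.seed(52)
  zs <- replicate(400, rayleigh_test(runif(50, -pi, pi))$z)
  expect_lt(abs(mean(zs) - 1), 0.15)
  crit <- marmonav:::rayleigh_crit(50, 0.01)
  expect_lt(abs(mean(zs > crit) - 0.01), 0.015)
})

test_that("event-aligned Rayleigh window localizes an injected phase reset", {
  p <- generator_params(duration_s = 400, seed = 9, reset_gain = 2)
  beh <- memo("beh9", gen_behavior(p))
  evt <- beh$events$t_peak[beh$events$kind == "head"]
  lfp <- gen_lfp(evt, p)
  ph <- theta_phase(lfp, c(4, 10))
  rs <- rayleigh_over_window(ph, lfp$fs, evt)
  expect_lt(abs(rs$times[which.max(rs$z)]), 0.025)  # Z peak within +-25 ms
  expect_true(rs$z[which.min(abs(rs$times))] > rs$crit_z)
  expect_true(all(rs$r_bar >= 0 & rs$r_bar <= 1))

  # global phase rotation leaves Z unchanged
  rs2 <- rayleigh_over_window((ph + 1) %% (2 * pi) - pi, lfp$fs, evt)
  expect_equal(rs2$z, rs$z, tolerance = 1e-6)

  expect_error(rayleigh_over_window(ph, lfp$fs, evt[1:5]), "at least 10")
})

test_that("event-averaged TFR flags theta power against the fractal baseline", {
  fs <- 1000
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  set.seed(53)
  # white-ish background with a strong continuous 8 Hz rhythm
  x <- 0.3 * rnorm(length(t)) + sin(2 * pi * 8 * t)
  lfp <- lfp_series(x, fs)
  evt <- seq(2, 58, by = 2)
  tfr <- morlet_tfr(lfp, evt, window = c(-0.5, 0.5), cfg = analysis_config())
  prof <- rowMeans(tfr$db)
  expect_equal(tfr$freqs[which.max(prof)], 8, tolerance = 1)

  # scaling the signal leaves the dB map unchanged (baseline scales too)
  tfr2 <- morlet_tfr(lfp_series(3 * x, fs), evt, window = c(-0.5, 0.5),
                     cfg = analysis_config())
  expect_equal(tfr2$db, tfr$db, tolerance = 0.05)

  # pure noise -> flat map
  lfp0 <- lfp_series(rnorm(length(t)), fs)
  tfr0 <- morlet_tfr(lfp0, evt, window = c(-0.5, 0.5), cfg = analysis_config())
  expect_lt(max(abs(rowMeans(tfr0$db))), 1)
  expect_error(morlet_tfr(lfp, evt[1:4], cfg = analysis_config()), "10 usable")
})

test_that("peri-movement modulation classes are recovered", {
  set.seed(54)
  dur <- 600
  evt <- sort(runif(150, 10, dur - 10))
  cfg <- analysis_config(mod_n_shuffle = 300)
  base <- sort(runif(3000, 0, dur))

  m0 <- classify_modulation(base, evt, dur, cfg, seed = 2)
  expect_equal(m0$label, "unmodulated")

  up <- sort(c(base, unlist(lapply(evt, function(e) e + runif(8, 0, 0.1)))))
  m1 <- classify_modulation(up, evt, dur, cfg, seed = 2)
  expect_equal(m1$label, "up")
  expect_true(m1$peak_ms > 0 && m1$peak_ms < 100)

  down <- base[!vapply(base, function(s) any(s > evt & s < evt + 0.1), logical(1))]
  m2 <- classify_modulation(down, evt, dur, cfg, seed = 2)
  expect_equal(m2$label, "down")

  both <- sort(c(down, unlist(lapply(evt, function(e) e + runif(6, 0.1, 0.2)))))
  m3 <- classify_modulation(both, evt, dur, cfg, seed = 2)
  expect_equal(m3$label, "down_up")

  expect_error(align_firing(base, numeric(0), dur), "empty event list")
})
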