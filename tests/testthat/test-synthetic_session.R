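test_that("fixed seeds give bit-identical sessions", {
  p <- generator_params(duration_s = 60, n_pyr = 2, n_int = 1, seed = 17)
  s1 <- gen_session(p)
  s2 <- gen_session(p)
  expect_identical(s1$bundle$tracking$quat, s2$bundle$tracking$quat)
  expect_identical(s1$bundle$tracking$pos, s2$bundle$tracking$pos)
  expect_identical(lapply(s1$bundle$units, `[[`, "times"),
                   lapply(s2$bundle$units, `[[`, "times"))
  expect_identical(s1$bundle$lfp[[1]]$samples, s2$bundle$lfp[[1]]$samples)
  expect_identical(s1$truth$events, s2$truth$events)
})

test_that("behavioral edge cases honor the event-placement parameters", {
  b0 <- gen_behavior(generator_params(duration_s = 120,
                                      head_event_rate_during_stops = 0,
                                      fraction_head_moves_during_stops = 1,
                                      seed = 2))
  expect_equal(sum(b0$events$kind == "head"), 0)

  b1 <- gen_behavior(generator_params(duration_s = 300,
                                      fraction_head_moves_during_stops = 1,
                                      seed = 2))
  he <- b1$events[b1$events$kind == "head", ]
  in_stop <- vapply(he$t_peak, function(tp)
    any(tp >= b1$stop_epochs$t_on & tp < b1$stop_epochs$t_off), logical(1))
  expect_true(all(in_stop))
})

test_that("generated pose is physically valid", {
  s <- ms_session()
  tr <- s$bundle$tracking
  expect_true(all(abs(sqrt(rowSums(tr$quat^2)) - 1) < 1e-9))
  ahv <- angular_head_velocity(tr)$ahv
  expect_true(all(ahv < 2000, na.rm = TRUE))
  e <- s$bundle$maze$extent
  expect_true(all(tr$pos[, 1] >= 0 & tr$pos[, 1] <= e[1]))
  expect_true(all(tr$pos[, 3] >= 0 & tr$pos[, 3] <= e[3]))
})

test_that("movement detection recovers >=90% of injected head events", {
  beh <- gen_behavior(generator_params(duration_s = 600, seed = 5))
  kin <- compute_kinematics(beh$pose)
  ev <- detect_movements(kin)
  det <- ev[ev$kind == "head" & !ev$artifact, ]
  th <- beh$events[beh$events$kind == "head", ]
  hit <- vapply(seq_len(nrow(th)), function(i) {
    j <- which.min(abs(det$t_peak - th$t_peak[i]))
    abs(det$t_peak[j] - th$t_peak[i]) < 0.05 &&
      abs(det$amplitude[j] - th$amplitude[i]) < 2
  }, logical(1))
  expect_gte(mean(hit), 0.9)
  expect_equal(sum(ev$artifact), 0)
})

test_that("untuned units emit Poisson counts at the configured base rate", {
  p <- generator_params(duration_s = 600, seed = 8)
  beh <- memo("beh8", gen_behavior(p))
  spec <- list(list(unit_id = "flat", type = "pyramidal", base_rate = 5,
                    doublet_p = 0, terms = list()))
  spk <- gen_spikes(beh$pose, spec, p$maze, seed = 8)
  n <- length(spk$units[[1]]$times)
  expect_lt(abs(n - 3000), 3 * sqrt(3000))
  expect_equal(spk$truth$flat$label, "none")

  # rate cap: gain strong enough to exceed 500 Hz errors out
  spec_hot <- list(list(unit_id = "hot", type = "pyramidal", base_rate = 100,
                        doublet_p = 0,
                        terms = list(hd = list(mu = 0, kappa = 0.01, gain = 50))))
  expect_error(gen_spikes(beh$pose, spec_hot, p$maze, seed = 8),
               "tuning too strong")
})

test_that("doublet injection raises the burst index above a Poisson match", {
  p <- generator_params(duration_s = 600, seed = 8)
  beh <- memo("beh8", gen_behavior(p))
  specs <- list(
    list(unit_id = "bursty", type = "pyramidal", base_rate = 4,
         doublet_p = 0.5, terms = list()),
    list(unit_id = "poisson", type = "pyramidal", base_rate = 6,
         doublet_p = 0, terms = list()))
  spk <- gen_spikes(beh$pose, specs, p$maze, seed = 9)
  dur <- s_dur <- max(beh$pose$t) + 1 / 60
  bi_b <- burst_index(spk$units[[1]], dur)$burst_index
  bi_p <- burst_index(spk$units[[2]], dur)$burst_index
  expect_gt(bi_b, bi_p + 0.2)
})

test_that("unit counts and session scale pass through to the bundle", {
  s <- gen_session(generator_params(duration_s = 30, n_pyr = 204, n_int = 127,
                                    seed = 6))
  ids <- vapply(s$bundle$units, `[[`, "", "unit_id")
  expect_equal(sum(grepl("^pyr", ids)), 204)
  expect_equal(sum(grepl("^int", ids)), 127)
  expect_length(s$truth$units, 331)
  # default duration matches the session lengths the analyses assume (~40 min)
  expect_equal(generator_params()$duration_s, 2400)
})
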