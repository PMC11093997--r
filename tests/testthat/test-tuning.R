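test_that("view projection hits the geometrically required faces", {
  maze <- maze_model()
  ctr <- maze$extent / 2
  t <- c(0, 1 / 60)
  # facing +x horizontally from the center -> x1 face at head height
  p1 <- pose_series(t, rbind(ctr, ctr), quat_from_euler(c(0, 0), 0, 0))
  v1 <- project_view(p1, maze)
  expect_equal(v1$face[1], "x1")
  expect_equal(v1$x[1], maze$extent[1])
  expect_equal(v1$v[1], ctr[3])   # height preserved
  # facing straight up -> ceiling directly above
  p2 <- pose_series(t, rbind(ctr, ctr), quat_from_euler(c(0, 0), 90, 0))
  v2 <- project_view(p2, maze)
  expect_equal(v2$face[1], "z1")
  expect_equal(c(v2$x[1], v2$y[1]), c(ctr[1], ctr[2]), tolerance = 1e-9)
})

test_that("random rays land exactly on a face and inside its bounds", {
  set.seed(31)
  maze <- maze_model()
  n <- 2000
  pos <- cbind(runif(n, 1, 99), runif(n, 1, 49), runif(n, 1, 119))
  q <- random_unit_quat(n)
  pose <- pose_series(seq(0, by = 1 / 60, length.out = n), pos, q)
  vw <- project_view(pose, maze)
  e <- maze$extent
  on_face <- abs((vw$face == "x0") * vw$x +
                 (vw$face == "x1") * (vw$x - e[1]) +
                 (vw$face == "y0") * vw$y +
                 (vw$face == "y1") * (vw$y - e[2]) +
                 (vw$face == "z0") * vw$z +
                 (vw$face == "z1") * (vw$z - e[3]))
  expect_true(all(on_face < 1e-9))
  expect_true(all(vw$x >= -1e-9 & vw$x <= e[1] + 1e-9))
  expect_true(all(vw$y >= -1e-9 & vw$y <= e[2] + 1e-9))
  expect_true(all(vw$z >= -1e-9 & vw$z <= e[3] + 1e-9))
  bins <- view_bin_index(maze, vw$face, vw$u, vw$v)
  expect_true(all(bins >= 1 & bins <= n_view_bins(maze)))
})

test_that("rate maps exclude under-sampled bins and normalize occupancy", {
  cfg <- analysis_config()
  # 10 bins; bin k occupied in contiguous dwells
  fs <- 60
  bins_seq <- rep(c(1, 2, 1, 2, 1, 2, 1, 2, 3), times = c(60, 60, 60, 60, 60, 60, 60, 60, 9))
  t <- seq_along(bins_seq) / fs
  # bin 3: one visit of 150 ms -> excluded; bins 1,2: 4 visits, 4 s each
  m <- build_rate_map(numeric(0), t, bins_seq, 10, cfg)
  expect_true(m$included[1] && m$included[2])
  expect_false(m$included[3])
  expect_equal(sum(m$p_occ[m$included]), 1)
})

test_that("SIC identities and brute-force oracle agreement", {
  uniform <- structure(list(rate = rep(3, 4), p_occ = rep(0.25, 4),
                            included = rep(TRUE, 4), mean_rate = 3,
                            occupancy = rep(1, 4), empty = FALSE),
                       class = "rate_map")
  expect_equal(spatial_information(uniform), 0)

  twobin <- structure(list(rate = c(2, 0), p_occ = c(0.5, 0.5),
                           included = c(TRUE, TRUE), mean_rate = 1,
                           occupancy = c(1, 1), empty = FALSE),
                      class = "rate_map")
  expect_equal(spatial_information(twobin), 1)  # log2(2) case

  set.seed(32)
  L <- 84
  p <- runif(L); p <- p / sum(p)
  lam <- rgamma(L, 2, 1)
  lbar <- sum(p * lam)
  m <- structure(list(rate = lam, p_occ = p, included = rep(TRUE, L),
                      mean_rate = lbar, occupancy = p, empty = FALSE),
                 class = "rate_map")
  oracle <- 0
  for (i in 1:L) if (lam[i] > 0)
    oracle <- oracle + p[i] * (lam[i] / lbar) * log2(lam[i] / lbar)
  expect_equal(spatial_information(m), oracle, tolerance = 1e-12)

  # SIC = 0 iff rate is flat on included bins
  expect_gt(spatial_information(m), 0)
})

test_that("SIC permutation test flags tuned units, spares the untuned", {
  s <- ms_session(); b <- s$bundle
  db <- marmonav:::domain_bins(b, "place3d")
  cfg <- analysis_config(sic_n_perm = 300)
  truth <- s$truth$units
  tuned <- names(Filter(function(u) "place" %in% u$variables, truth))
  ids <- vapply(b$units, `[[`, "", "unit_id")
  u <- b$units[[match(tuned[1], ids)]]
  r <- sic_significance(u$times, b$tracking$t, db$bin, db$n_bins, b$duration,
                        cfg, seed = 2)
  expect_true(r$is_selective)
  expect_gt(length(r$significant_bins), 0)
  expect_length(r$null_sics, 300)
  # the dominant field bin is significant and lies near the generating
  # field center (the additive tuning spreads mass along axes, and the
  # exact center bin can be under-occupied, so proximity is the right check)
  rate_inc <- ifelse(r$map$included, r$map$rate, -Inf)
  peak_bin <- which.max(rate_inc)
  expect_true(peak_bin %in% r$significant_bins)
  bin_center <- function(bin, maze) {
    nx <- maze$place_grid[1]; ny <- maze$place_grid[2]
    fl <- (bin - 1) %/% (nx * ny)
    rem <- (bin - 1) %% (nx * ny)
    iy <- rem %/% nx; ix <- rem %% nx
    c((ix + 0.5) * maze$extent[1] / nx, (iy + 0.5) * maze$extent[2] / ny,
      maze$floor_heights[fl + 1] + 5)
  }
  ctr <- truth[[tuned[1]]]$terms$place$center
  expect_lt(sqrt(sum((bin_center(peak_bin, b$maze)[1:2] - ctr[1:2])^2)), 50)

  expect_error(sic_significance(u$times, b$tracking$t, db$bin, db$n_bins,
                                b$duration, analysis_config(sic_n_perm = 50)),
               "refuse")
})

test_that("speed score is exact for proportional series and affine-invariant", {
  set.seed(33)
  fs <- 60; dur <- 120
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  counts <- rpois(length(t), 2)
  spikes <- rep(t, counts)  # counts per frame reproduce `counts`
  kin <- data.frame(t = t, ts = counts * fs, ahv = rnorm(length(t), 100, 10))
  cfg <- analysis_config(speed_n_shift = 100)
  r <- speed_score(spikes, kin, "ts", cfg, seed = 3)
  expect_equal(r$score, 1, tolerance = 1e-9)
  expect_true(r$passes)

  # affine rescaling of the speed series leaves the score unchanged
  kin2 <- kin; kin2$ts <- 3 * kin$ts + 7
  r2 <- speed_score(spikes, kin2, "ts", cfg, seed = 3)
  expect_equal(r2$score, r$score, tolerance = 1e-9)

  # negatively proportional series: r = -1 and not classified
  kin3 <- kin; kin3$ts <- max(counts) * fs - kin$ts + 1
  r3 <- speed_score(spikes, kin3, "ts", cfg, seed = 3)
  expect_equal(r3$score, -1, tolerance = 1e-9)
  expect_false(r3$passes)
})

test_that("generator speed tuning yields the advertised labels", {
  s <- ms_session(); b <- s$bundle
  kin <- ms_kin()
  truth <- s$truth$units
  ids <- vapply(b$units, `[[`, "", "unit_id")
  ts_only <- names(Filter(function(u) identical(u$variables, "ts"), truth))
  if (length(ts_only)) {
    u <- b$units[[match(ts_only[1], ids)]]
    lab <- speed_cell_label(u$times, kin, analysis_config(speed_n_shift = 200),
                            seed = 4)
    expect_gt(lab$ts$score, 0.3)
    expect_true(lab$label %in% c("TS", "mixed"))
  }
  untuned <- names(Filter(function(u) length(u$variables) == 0, truth))
  if (length(untuned)) {
    u0 <- b$units[[match(untuned[1], ids)]]
    lab0 <- speed_cell_label(u0$times, kin, analysis_config(speed_n_shift = 200),
                             seed = 4)
    expect_lt(abs(lab0$ts$score), 0.3)
  }
})
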