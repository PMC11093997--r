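test_that("trial extraction respects the low-AHV rule and window spacing", {
  cfg <- analysis_config()
  s <- decode_session(); b <- s$bundle
  tr <- decode_trials()
  expect_gte(min(diff(sort(tr$t_center))), cfg$decoder_window_ms / 1000)
  expect_length(tr$classes, 4)
  expect_true(all(tr$class_counts >= cfg$decoder_min_trials))
  expect_equal(ncol(tr$rates), 20)

  # continuous high AHV -> zero trials
  t <- seq(0, 10, by = 1 / 60)
  kin_hi <- data.frame(t = t, ts = 0, ahv = 500)
  expect_warning(tr0 <- extract_trials(b, kin_hi, cfg), "insufficient")
  expect_equal(nrow(tr0$rates), 0)
})

test_that("decoder hits 1.0 on separable rates and chance on shuffled labels", {
  set.seed(41)
  n_per <- 60
  labels <- rep(1:4, each = n_per)
  means <- matrix(c(10, 0, 0, 0,
                    0, 10, 0, 0,
                    0, 0, 10, 0,
                    0, 0, 0, 10), 4, byrow = TRUE)
  rates <- means[labels, ] + matrix(rnorm(length(labels) * 4, 0, 0.1),
                                    ncol = 4)
  colnames(rates) <- paste0("u", 1:4)
  trials <- structure(list(rates = rates, labels = labels,
                           t_center = seq_along(labels), classes = 1:4,
                           class_counts = rep(n_per, 4)),
                      class = "trial_set")
  cfg <- analysis_config()
  d <- train_decoder(trials, cfg = cfg, seed = 1, repeats = 3)
  expect_equal(d$accuracy, 1.0)

  dsh <- train_decoder(trials, cfg = cfg, seed = 2, repeats = 5,
                       shuffle_labels = TRUE)
  expect_lt(abs(dsh$accuracy - 0.25), 0.08)

  # single uninformative unit ~ chance
  noise <- matrix(rnorm(length(labels)), ncol = 1, dimnames = list(NULL, "u1"))
  tn <- structure(list(rates = noise, labels = labels,
                       t_center = seq_along(labels), classes = 1:4,
                       class_counts = rep(n_per, 4)), class = "trial_set")
  dn <- train_decoder(tn, cfg = cfg, seed = 3, repeats = 5)
  expect_lt(abs(dn$accuracy - 0.25), 0.1)
})

test_that("greedy ensembles seed on the informative unit and beat random sets", {
  set.seed(42)
  n_per <- 60
  labels <- rep(1:4, each = n_per)
  informative <- labels * 2 + rnorm(length(labels), 0, 0.5)
  rates <- cbind(informative, matrix(rnorm(length(labels) * 5), ncol = 5))
  colnames(rates) <- paste0("u", 1:6)
  trials <- structure(list(rates = rates, labels = labels,
                           t_center = seq_along(labels), classes = 1:4,
                           class_counts = rep(n_per, 4)), class = "trial_set")
  cfg <- analysis_config()
  g <- build_greedy_ensemble(trials, cfg = cfg, max_size = 3, seed = 4,
                             repeats = 3)
  expect_equal(g$members[1], "u1")
  expect_true(all(diff(match(g$members, colnames(rates))) != 0))

  r <- random_ensembles(trials, colnames(rates), size = 3, n_combos = 10,
                        cfg = cfg, seed = 5, repeats = 3)
  expect_gte(g$accuracy[3], r$mean - 0.02)

  # untuned pool stays flat at chance
  tn <- trials; tn$rates <- matrix(rnorm(length(labels) * 6), ncol = 6,
                                   dimnames = list(NULL, paste0("u", 1:6)))
  g0 <- build_greedy_ensemble(tn, cfg = cfg, max_size = 3, seed = 6, repeats = 3)
  expect_lt(abs(g0$accuracy[3] - 0.25), 0.12)
})

test_that("random ensembles are unique, seeded, and degenerate to the full pool", {
  tr <- decode_trials()
  cfg <- analysis_config()
  pool <- colnames(tr$rates)[1:5]
  r1 <- random_ensembles(tr, pool, size = 3, n_combos = 8, cfg = cfg,
                         seed = 7, repeats = 2)
  r2 <- random_ensembles(tr, pool, size = 3, n_combos = 8, cfg = cfg,
                         seed = 7, repeats = 2)
  expect_identical(r1$combos, r2$combos)
  expect_equal(length(unique(vapply(r1$combos, paste, "", collapse = "|"))), 8)

  # pool == size -> the single combo equals the plain decoder
  rfull <- random_ensembles(tr, pool[1:3], size = 3, n_combos = 5, cfg = cfg,
                            seed = 8, repeats = 2)
  expect_length(rfull$combos, 1)
  expect_error(random_ensembles(tr, pool[1:2], size = 3), "pool smaller")
})

test_that("performance curves fit a saturating Naka-Rushton asymptote", {
  flat <- structure(list(members = paste0("u", 1:6),
                         accuracy = rep(0.25, 6), ci = NULL,
                         variant = "greedy"), class = "ensemble_curve")
  f <- curve_fit_performance(flat, seed = 1)
  expect_equal(unname(f$par["r_max"] + f$par["b"]), 0.25, tolerance = 0.02)

  sizes <- 1:12
  acc <- naka_rushton(sizes, 0.4, 1.5, 3, 0.25)
  cv <- structure(list(members = paste0("u", sizes), accuracy = acc, ci = NULL,
                       variant = "greedy"), class = "ensemble_curve")
  f2 <- curve_fit_performance(cv, seed = 2)
  expect_equal(unname(f2$par["r_max"] + f2$par["b"]), 0.65, tolerance = 0.02)
  expect_true(all(diff(f2$fitted) >= -1e-9))  # monotone on the observed range
  expect_error(curve_fit_performance(structure(list(accuracy = c(0.2, 0.3)),
                                               class = "ensemble_curve")),
               "at least 4")
})
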