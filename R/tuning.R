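#' Place/view tuning and spatial information content
#'
#' Spatial information content (SIC) in bits/spike:
#' I = sum_i P_i (lambda_i / lbar) log2(lambda_i / lbar), with P_i the
#' occupancy proportion of bin i, lambda_i its firing rate, and
#' lbar = sum_i P_i lambda_i. Nulls come from circularly shifting spike
#' times by uniform random offsets while occupancy stays fixed. "View" is
#' the facing location: the intersection of the head's forward ray with the
#' enclosure's inner faces.
#'
#' @name tuning
NULL

#' Project head pose to facing locations on the maze walls
#'
#' Casts the forward axis of the head quaternion from the 3D position and
#' returns the first intersection with the six inner faces in unwrapped
#' face coordinates.
#'
#' @param pose a `pose_series`.
#' @param maze a `maze_model`.
#' @return data frame `t, face, u, v, x, y, z` (NA rows at tracking gaps or
#'   degenerate poses). Face coordinate conventions: "x0"/"x1" faces map
#'   (u, v) = (y, z); "y0"/"y1" map (x, z); "z0"/"z1" (floor/ceiling) map
#'   (x, y).
#' @export
project_view <- function(pose, maze) {
  e <- maze$extent
  p <- pose$pos
  # clamp origins to the interior (tracking jitter can exit the box)
  p[, 1] <- pmin(pmax(p[, 1], 1e-9), e[1] - 1e-9)
  p[, 2] <- pmin(pmax(p[, 2], 1e-9), e[2] - 1e-9)
  p[, 3] <- pmin(pmax(p[, 3], 1e-9), e[3] - 1e-9)
  d <- quat_rotate(pose$quat, c(1, 0, 0))
  n <- nrow(p)
  tt <- matrix(Inf, n, 6)  # ray parameter to each face plane
  tt[, 1] <- ifelse(d[, 1] < 0, -p[, 1] / d[, 1], Inf)          # x0
  tt[, 2] <- ifelse(d[, 1] > 0, (e[1] - p[, 1]) / d[, 1], Inf)  # x1
  tt[, 3] <- ifelse(d[, 2] < 0, -p[, 2] / d[, 2], Inf)          # y0
  tt[, 4] <- ifelse(d[, 2] > 0, (e[2] - p[, 2]) / d[, 2], Inf)  # y1
  tt[, 5] <- ifelse(d[, 3] < 0, -p[, 3] / d[, 3], Inf)          # z0
  tt[, 6] <- ifelse(d[, 3] > 0, (e[3] - p[, 3]) / d[, 3], Inf)  # z1
  hit <- max.col(-tt, ties.method = "first")
  thit <- tt[cbind(seq_len(n), hit)]
  ok <- pose$valid & is.finite(thit)
  px <- p[, 1] + thit * d[, 1]
  py <- p[, 2] + thit * d[, 2]
  pz <- p[, 3] + thit * d[, 3]
  faces <- c("x0", "x1", "y0", "y1", "z0", "z1")
  face <- faces[hit]
  u <- ifelse(hit <= 2, py, px)
  v <- ifelse(hit <= 4, pz, py)
  face[!ok] <- NA; u[!ok] <- NA; v[!ok] <- NA
  px[!ok] <- NA; py[!ok] <- NA; pz[!ok] <- NA
  data.frame(t = pose$t, face = face, u = u, v = v, x = px, y = py, z = pz,
             stringsAsFactors = FALSE)
}

#' Global unwrapped coordinates for view samples
#'
#' Maps per-face (u, v) to a single 2D chart: the four walls unroll along a
#' perimeter coordinate (y0, x1, y1, x0 in sequence) with v = height; floor
#' and ceiling stack above the wall band. Disjoint by construction, so a
#' localized facing field stays localized in the chart (used by the GAM's
#' additive view smooths).
#'
#' @param maze a `maze_model`.
#' @param face,u,v columns from [project_view()].
#' @return data frame `gu`, `gv`.
#' @export
view_global_coords <- function(maze, face, u, v) {
  ex <- maze$extent[1]; ey <- maze$extent[2]; ez <- maze$extent[3]
  gu <- rep(NA_real_, length(face)); gv <- rep(NA_real_, length(face))
  i <- !is.na(face) & face == "y0"; gu[i] <- u[i];                 gv[i] <- v[i]
  i <- !is.na(face) & face == "x1"; gu[i] <- ex + u[i];            gv[i] <- v[i]
  i <- !is.na(face) & face == "y1"; gu[i] <- ex + ey + (ex - u[i]); gv[i] <- v[i]
  i <- !is.na(face) & face == "x0"; gu[i] <- 2 * ex + ey + (ey - u[i]); gv[i] <- v[i]
  i <- !is.na(face) & face == "z0"; gu[i] <- u[i];                 gv[i] <- ez + v[i]
  i <- !is.na(face) & face == "z1"; gu[i] <- u[i];                 gv[i] <- ez + ey + v[i]
  data.frame(gu = gu, gv = gv)
}

# Per-sample bin index for a domain; NA = unusable sample.
domain_bins <- function(bundle, domain, view = NULL) {
  pose <- bundle$tracking
  if (domain == "place3d") {
    b <- place_bin_index(bundle$maze, pose$pos)
    b[!pose$valid] <- NA_integer_
    list(bin = b, n_bins = n_place_bins(bundle$maze))
  } else if (domain == "view2d") {
    if (is.null(view)) view <- project_view(pose, bundle$maze)
    list(bin = view_bin_index(bundle$maze, view$face, view$u, view$v),
         n_bins = n_view_bins(bundle$maze))
  } else stop("unknown domain: ", domain)
}

#' Build an occupancy/rate map
#'
#' lambda_i = spikes in bin i / occupancy time in bin i. An "independent
#' visit" is a maximal contiguous dwell in a bin; bins visited 3 or fewer
#' independent times, or occupied under 200 ms, are excluded from the map
#' (and from the normalization of P_i).
#'
#' @param spike_times spike times [s].
#' @param t_grid tracking sample times.
#' @param bin_at_sample per-sample bin id (NA = gap).
#' @param n_bins total number of bins in the partition.
#' @param cfg an [analysis_config()].
#' @return list of class `rate_map`: `rate`, `occupancy`, `p_occ`, `visits`,
#'   `included`, `mean_rate` (lbar), `n_bins`, `spikes_per_bin`.
#' @export
build_rate_map <- function(spike_times, t_grid, bin_at_sample, n_bins,
                           cfg = analysis_config()) {
  dt <- stats::median(diff(t_grid))
  bb <- bin_at_sample
  occ <- tabulate(bb[!is.na(bb)], n_bins) * dt
  r <- rle(ifelse(is.na(bb), -1L, bb))
  vis_bins <- r$values[r$values > 0]
  visits <- tabulate(vis_bins, n_bins)
  si <- spike_sample_index(spike_times, t_grid, dt)
  sb <- bb[si]
  spikes <- tabulate(sb[!is.na(sb)], n_bins)
  included <- visits > cfg$min_bin_visits & occ >= cfg$min_bin_occupancy_s
  if (!any(included)) {
    return(structure(list(rate = rep(NA_real_, n_bins), occupancy = occ,
                          p_occ = rep(NA_real_, n_bins), visits = visits,
                          included = included, mean_rate = NA_real_,
                          n_bins = n_bins, spikes_per_bin = spikes,
                          empty = TRUE), class = "rate_map"))
  }
  rate <- ifelse(included, spikes / occ, NA_real_)
  p <- ifelse(included, occ / sum(occ[included]), NA_real_)
  lbar <- sum(p[included] * rate[included])
  structure(list(rate = rate, occupancy = occ, p_occ = p, visits = visits,
                 included = included, mean_rate = lbar, n_bins = n_bins,
                 spikes_per_bin = spikes, empty = FALSE),
            class = "rate_map")
}

spike_sample_index <- function(spike_times, t_grid, dt) {
  i <- findInterval(spike_times, c(t_grid, t_grid[length(t_grid)] + dt))
  i[i < 1L] <- 1L
  i[i > length(t_grid)] <- length(t_grid)
  i
}

#' Spatial information content of a rate map (bits/spike)
#'
#' @param map a `rate_map`.
#' @return SIC in bits/spike; errors if the mean rate is zero/undefined.
#' @export
spatial_information <- function(map) {
  if (map$empty || !is.finite(map$mean_rate) || map$mean_rate <= 0)
    stop("mean rate undefined or zero")
  inc <- map$included
  rel <- map$rate[inc] / map$mean_rate
  term <- ifelse(rel > 0, map$p_occ[inc] * rel * log2(rel), 0)
  sum(term)
}

#' SIC significance by circular-shift permutation
#'
#' The unit's spike times are circularly shifted by uniform random offsets
#' (minimum 1 s from either end), occupancy held fixed; the shuffle
#' preserves spike count exactly. Cell-level selectivity compares the real
#' SIC against the `sic_percentile` (default 95th) of the null; for
#' selective cells, per-bin fields are bins whose real rate exceeds the
#' Bonferroni-corrected per-bin null percentile (1 - alpha / L).
#'
#' @param spike_times spike times [s].
#' @param t_grid,bin_at_sample,n_bins as in [build_rate_map()].
#' @param duration session duration [s].
#' @param cfg an [analysis_config()]; `sic_n_perm` (default 5000) must be at
#'   least 100.
#' @param seed RNG seed.
#' @return list of class `selectivity_result`: `sic`, `null_sics`,
#'   `threshold`, `is_selective`, `significant_bins`, `map`.
#' @export
sic_significance <- function(spike_times, t_grid, bin_at_sample, n_bins,
                             duration, cfg = analysis_config(), seed = 1) {
  if (cfg$sic_n_perm < 100) stop("refuse: fewer than 100 permutations is unstable")
  map <- build_rate_map(spike_times, t_grid, bin_at_sample, n_bins, cfg)
  sic <- spatial_information(map)
  dt <- stats::median(diff(t_grid))
  inc <- map$included
  L <- sum(inc)
  occ_inc <- map$occupancy[inc]
  p_inc <- map$p_occ[inc]
  null_sics <- numeric(cfg$sic_n_perm)
  null_rates <- matrix(0, cfg$sic_n_perm, L)
  lo <- cfg$sic_min_shift_s
  offsets <- local_seed(seed, stats::runif(cfg$sic_n_perm, lo, duration - lo))
  for (k in seq_len(cfg$sic_n_perm)) {
    st <- (spike_times + offsets[k]) %% duration
    sb <- bin_at_sample[spike_sample_index(st, t_grid, dt)]
    spk <- tabulate(sb[!is.na(sb)], n_bins)[inc]
    rate <- spk / occ_inc
    lbar <- sum(p_inc * rate)
    rel <- rate / lbar
    null_sics[k] <- sum(ifelse(rel > 0, p_inc * rel * log2(rel), 0))
    null_rates[k, ] <- rate
  }
  thr <- stats::quantile(null_sics, cfg$sic_percentile, names = FALSE)
  is_sel <- sic > thr
  sig_bins <- integer(0)
  if (is_sel && L > 0) {
    q_bin <- 1 - (1 - cfg$sic_percentile) / L
    bin_thr <- apply(null_rates, 2, stats::quantile, probs = q_bin)
    sig_bins <- which(inc)[map$rate[inc] > bin_thr]
  }
  structure(list(sic = sic, null_sics = null_sics, threshold = thr,
                 percentile = cfg$sic_percentile, is_selective = is_sel,
                 significant_bins = sig_bins, map = map),
            class = "selectivity_result")
}

#' Frame-rate firing series aligned to the tracking grid
#'
#' Spike counts in tracking-locked frames divided by the frame length.
#'
#' @param spike_times spike times [s].
#' @param t_grid tracking sample times.
#' @return rate in Hz per frame.
#' @export
frame_rate_series <- function(spike_times, t_grid) {
  dt <- stats::median(diff(t_grid))
  idx <- spike_sample_index(spike_times, t_grid, dt)
  tabulate(idx, length(t_grid)) / dt
}

#' Speed score with dual significance criteria
#'
#' Pearson correlation between the Gaussian-smoothed (250 ms SD) firing-rate
#' and speed series at the tracking rate. A unit passes for a given speed
#' kind when r > 0.3 AND r exceeds the 95th percentile of a null built from
#' 1000 circular shifts of the rate series.
#'
#' @param spike_times spike times [s].
#' @param kin data frame from [compute_kinematics()].
#' @param which "ts" or "ahv".
#' @param cfg an [analysis_config()].
#' @param seed RNG seed for the shifts.
#' @return list: `score`, `null_scores`, `passes_threshold`,
#'   `passes_shuffle`, `passes`.
#' @export
speed_score <- function(spike_times, kin, which = c("ts", "ahv"),
                        cfg = analysis_config(), seed = 1) {
  which <- match.arg(which)
  speed <- kin[[which]]
  fs <- 1 / stats::median(diff(kin$t))
  rate <- frame_rate_series(spike_times, kin$t)
  sd_samp <- cfg$speed_smooth_sd_ms / 1000 * fs
  speed_s <- gauss_smooth(speed, sd_samp)
  rate_s <- gauss_smooth(rate, sd_samp)
  ok <- is.finite(speed_s) & is.finite(rate_s)
  if (stats::sd(speed_s[ok]) == 0 || stats::sd(rate_s[ok]) == 0)
    stop("undefined correlation: constant series")
  r <- stats::cor(speed_s[ok], rate_s[ok])
  n <- length(rate_s)
  min_shift <- max(1L, as.integer(fs * cfg$sic_min_shift_s))
  shifts <- local_seed(seed,
                       sample(seq(min_shift, n - min_shift), cfg$speed_n_shift,
                              replace = cfg$speed_n_shift > (n - 2 * min_shift)))
  null_scores <- vapply(shifts, function(k) {
    rs <- c(rate_s[(k + 1):n], rate_s[1:k])
    ok2 <- is.finite(speed_s) & is.finite(rs)
    stats::cor(speed_s[ok2], rs[ok2])
  }, numeric(1))
  pt <- r > cfg$speed_score_thresh
  ps <- r > stats::quantile(null_scores, cfg$speed_percentile, names = FALSE)
  list(score = r, null_scores = null_scores,
       passes_threshold = pt, passes_shuffle = ps, passes = pt && ps)
}

#' Joint TS/AHV speed-cell label
#'
#' @inheritParams speed_score
#' @return list with both score objects and `label` in
#'   \{"none", "TS", "AHV", "mixed"\}.
#' @export
speed_cell_label <- function(spike_times, kin, cfg = analysis_config(), seed = 1) {
  s_ts <- speed_score(spike_times, kin, "ts", cfg, seed)
  s_ahv <- speed_score(spike_times, kin, "ahv", cfg, child_seed(seed, "ahv"))
  label <- if (s_ts$passes && s_ahv$passes) "mixed"
  else if (s_ts$passes) "TS"
  else if (s_ahv$passes) "AHV"
  else "none"
  list(ts = s_ts, ahv = s_ahv, label = label)
}
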