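#' Analysis configuration
#'
#' Collects every threshold and tuning parameter used across the pipeline in
#' one validated list. Defaults are the values used throughout the analyses;
#' override any subset via `...`.
#'
#' Key entries (units in brackets):
#' \describe{
#'   \item{head_vel_thresh}{AHV threshold for rapid head movements [deg/s], 200.}
#'   \item{head_amp_min}{minimum head-movement amplitude [deg], 10.}
#'   \item{head_vel_artifact}{AHV above this is artifactual [deg/s], 2000.}
#'   \item{body_vel_thresh}{TS threshold for body translations [cm/s], 16.}
#'   \item{body_amp_min}{minimum body-translation amplitude [cm], 30.}
#'   \item{body_vel_artifact}{TS above this is artifactual [cm/s], 300.}
#'   \item{ts_lowpass_hz}{zero-phase low-pass on position before differencing, 4 Hz.}
#'   \item{min_spikes}{unit QC floor on spikes per session, 100.}
#'   \item{dup_overlap_frac}{duplicate-unit spike-time overlap fraction, 0.5.}
#'   \item{sic_n_perm}{circular-shift permutations for SIC nulls, 5000.}
#'   \item{sic_percentile}{cell-level selectivity percentile, 0.95.}
#'   \item{speed_n_shift}{circular shifts for the speed-score null, 1000.}
#'   \item{speed_score_thresh}{speed-cell Pearson threshold, 0.3.}
#'   \item{speed_smooth_sd_ms}{Gaussian smoothing SD for rate/speed series, 250 ms.}
#'   \item{gam_n_shuffle}{shuffles per forward-selection gate, 100.}
#'   \item{gam_alpha}{selection alpha (Bonferroni corrected per iteration), 0.05.}
#'   \item{ed_formula}{"conventional" (1 - Dfit/Dnull) or "printed".}
#'   \item{decoder_low_ahv}{AHV ceiling for fixation trials [deg/s], 200.}
#'   \item{decoder_window_ms}{trial integration window, 200 ms.}
#'   \item{decoder_min_trials}{minimum trials per class, 50.}
#'   \item{decoder_repeats}{balanced-subsample repeats, 10.}
#'   \item{decoder_folds}{cross-validation folds, 5.}
#'   \item{theta_band}{LFP theta band [Hz], c(4, 10).}
#'   \item{tfr_freqs}{Morlet center frequencies [Hz], 1:30.}
#'   \item{morlet_cycles}{Morlet oscillations per wavelet, 7.}
#'   \item{mod_n_shuffle}{spike-time permutations for modulation class, 1000.}
#'   \item{mod_window_ms}{peri-movement window, 400 ms in 8 x 50 ms bins.}
#' }
#'
#' @param ... named overrides of the defaults.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    tracking_fs = 60,
    lfp_fs = 1000,
    gap_fill_ms = 0,                 # 0 = never interpolate occlusions
    ts_lowpass_hz = 4,
    head_vel_thresh = 200, head_amp_min = 10, head_vel_artifact = 2000,
    body_vel_thresh = 16,  body_amp_min = 30, body_vel_artifact = 300,
    concurrency_ci = 0.99, concurrency_n_boot = 1000,
    nr_n_starts = 10,
    min_spikes = 100, dup_overlap_frac = 0.5,
    bi_range_ms = c(2, 40), bi_sum_ms = c(2, 20),
    bi_predicted = "integrated",     # or "center" (per-bin density at centers)
    min_bin_visits = 3, min_bin_occupancy_s = 0.2,
    sic_n_perm = 5000, sic_percentile = 0.95, sic_min_shift_s = 1,
    speed_n_shift = 1000, speed_score_thresh = 0.3,
    speed_percentile = 0.95, speed_smooth_sd_ms = 250,
    gam_n_shuffle = 100, gam_alpha = 0.05, gam_basis_k = 10,
    gam_frame_ms = 1000 / 60, ed_formula = "conventional",
    cv_folds = 5, cv_alpha = 0.05,
    decoder_low_ahv = 200, decoder_window_ms = 200, decoder_spacing_ms = 200,
    decoder_min_trials = 50, decoder_repeats = 10, decoder_folds = 5,
    decoder_C = 1, ensemble_max_size = 20, ensemble_tol = 0.005,
    random_n_combos = 100,
    lfp_highpass_hz = 1, lfp_antialias_hz = 250,
    lfp_preserve_printed_filter = FALSE,
    artifact_band = c(100, 250), artifact_z = 4, artifact_pad_ms = 100,
    theta_band = c(4, 10), tfr_freqs = 1:30, morlet_cycles = 7,
    tfr_smooth_ms = 25, rayleigh_alpha = 0.01,
    mod_n_shuffle = 1000, mod_window_ms = 400, mod_bin_ms = 50,
    mod_alpha = 0.05,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$tracking_fs > 0, cfg$lfp_fs > 0,
            cfg$sic_n_perm > 0, cfg$gam_n_shuffle > 0,
            cfg$theta_band[2] < cfg$lfp_fs / 2,
            max(cfg$tfr_freqs) < cfg$lfp_fs / 2)
  class(cfg) <- "analysis_config"
  cfg
}
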