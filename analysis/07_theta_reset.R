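# Head-movement-aligned LFP analyses: preprocessing with artifact masking,
# event-averaged Morlet time-frequency map normalized against the
# aperiodic (1/f) spectrum, theta phase resetting via the Rayleigh Z time
# course, and peri-movement firing-rate modulation classes.

source("analysis/00_common.R")
sess <- load_or_simulate()
b <- sess$bundle
cfg <- analysis_config(mod_n_shuffle = 300)

kin <- compute_kinematics(b$tracking, cfg)
events <- detect_movements(kin, cfg)
evt <- events$t_peak[events$kind == "head" & !events$artifact]

lfp <- preprocess_lfp(b$lfp[[1]]$samples, b$lfp[[1]]$fs, cfg)
cat(sprintf("LFP: %.1f%% masked as artifact\n", 100 * mean(lfp$artifact_mask)))

tfr <- morlet_tfr(lfp, evt, window = c(-0.5, 0.5), cfg)
write.csv(tfr$db, file.path(RESULTS, "tfr_db.csv"), row.names = FALSE)
jsonlite::write_json(list(times = tfr$times, freqs = tfr$freqs),
                     file.path(RESULTS, "tfr_axes.json"), digits = NA)

ph <- theta_phase(lfp, cfg$theta_band)
rs <- rayleigh_over_window(ph, lfp$fs, evt)
cat(sprintf("Rayleigh Z peak %.1f at %+.0f ms (critical %.2f at p=0.01); first significant at %+.0f ms\n",
            max(rs$z), 1000 * rs$times[which.max(rs$z)], rs$crit_z,
            1000 * rs$first_sig_time))

rows <- lapply(b$units, function(u) {
  m <- classify_modulation(u$times, evt, b$duration, cfg, seed = SEED)
  data.frame(unit_id = u$unit_id, label = m$label,
             first_sig_ms = m$first_sig_ms, peak_ms = m$peak_ms)
})
mod <- do.call(rbind, rows)
write.csv(mod, file.path(RESULTS, "modulation.csv"), row.names = FALSE)
cat("modulation classes:\n"); print(table(mod$label))
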