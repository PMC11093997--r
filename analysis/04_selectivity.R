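# Spatial information content for place (3D bins) and view (facing
# location on the maze walls) with circular-shift permutation nulls, and
# AHV/TS speed scores with the dual (r > 0.3 AND shuffle) criterion.
# Permutation counts are reduced from the 5000/1000 defaults for run time.

source("analysis/00_common.R")
sess <- load_or_simulate()
b <- sess$bundle
cfg <- analysis_config(sic_n_perm = 500, speed_n_shift = 300)
kin <- compute_kinematics(b$tracking, cfg)

rows <- list(); speed_rows <- list()
for (dom in c("place3d", "view2d")) {
  db <- marmonav:::domain_bins(b, dom)
  for (u in b$units) {
    r <- sic_significance(u$times, b$tracking$t, db$bin, db$n_bins,
                          b$duration, cfg, seed = SEED)
    rows[[paste(dom, u$unit_id)]] <-
      data.frame(unit_id = u$unit_id, domain = dom, sic_bits = r$sic,
                 null_p95 = r$threshold, is_selective = r$is_selective,
                 n_fields = length(r$significant_bins))
  }
}
sel <- do.call(rbind, rows)
write.csv(sel, file.path(RESULTS, "selectivity.csv"), row.names = FALSE)
cat(sprintf("selective units: %d/%d (place), %d/%d (view)\n",
            sum(sel$is_selective[sel$domain == "place3d"]), length(b$units),
            sum(sel$is_selective[sel$domain == "view2d"]), length(b$units)))

for (u in b$units) {
  lab <- speed_cell_label(u$times, kin, cfg, seed = SEED)
  speed_rows[[u$unit_id]] <-
    data.frame(unit_id = u$unit_id, score_ts = lab$ts$score,
               score_ahv = lab$ahv$score, label = lab$label)
}
sp <- do.call(rbind, speed_rows)
write.csv(sp, file.path(RESULTS, "speed_scores.csv"), row.names = FALSE)
cat("speed-cell labels:\n"); print(table(sp$label))
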