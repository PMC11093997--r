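# Simulate the reference session: foraging behavior alternating body
# translations and head-gaze shifts, tuned spike trains, and an LFP with
# theta phase resetting. Writes the session bundle plus the ground-truth
# manifest every later stage is checked against.

source("analysis/00_common.R")

sess <- gen_session(ref_params())
write_session(sess$bundle, SESSION_DIR)

truth <- sess$truth
jsonlite::write_json(
  list(units = truth$units,
       events = truth$events,
       stop_epochs = truth$stop_epochs,
       reset_phase = truth$reset_phase),
  file.path(RESULTS, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

he <- truth$events[truth$events$kind == "head", ]
cat(sprintf("session: %.0f s, %d units, %d injected head-gaze shifts (%.0f%% during stops)\n",
            sess$bundle$duration, length(sess$bundle$units), nrow(he),
            100 * mean(!he$during_translation)))
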