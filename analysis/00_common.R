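# Shared setup for the analysis drivers: one reference synthetic session,
# written once and reused by every numbered script. Source this first.

library(marmonav)

SEED <- as.integer(Sys.getenv("MARMONAV_SEED", "1"))
RESULTS <- "results"
SESSION_DIR <- file.path(RESULTS, "session")
dir.create(RESULTS, showWarnings = FALSE)

# Desk-scale session: 10 min, 12 pyramidal + 6 interneuron units. The
# generator defaults (40 min, 204 + 127 units) reproduce the session scale
# the analyses assume but take correspondingly longer.
ref_params <- function() generator_params(duration_s = 600, n_pyr = 12,
                                          n_int = 6, seed = SEED)

load_or_simulate <- function() {
  if (file.exists(file.path(SESSION_DIR, "manifest.json")) &&
      file.exists(file.path(RESULTS, "ground_truth.json"))) {
    bundle <- load_session(SESSION_DIR)
    truth <- jsonlite::read_json(file.path(RESULTS, "ground_truth.json"),
                                 simplifyVector = TRUE)
    list(bundle = bundle, truth = truth)
  } else {
    stop("run analysis/01_simulate.R first")
  }
}
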