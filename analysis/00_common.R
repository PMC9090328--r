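# Shared setup for the numbered analysis drivers: study geometry, cohort
# simulation and preprocessing. Everything is deterministic in MASTER_SEED,
# so each driver can rebuild exactly the objects it needs.

library(nirstopo)

MASTER_SEED <- 20211109L

study_geometry <- function() {
  mesh <- make_patch_mesh(13, 13, 90, 90, 120)
  mont <- default_montage(mesh)
  list(mesh = mesh, mont = mont, jac = synthetic_jacobian(mont, mesh))
}

# default physiological noise plus occasional motion artifacts
study_noise <- function() {
  noise_spec(motion_rate_per_min = 0.3)
}

simulate_cohort <- function(geo, seed = MASTER_SEED) {
  simulate_group(default_conditions(geo$mesh), geo$mont, geo$mesh, geo$jac,
                 noise = study_noise(), seed = seed)
}

# preprocess every subject of one condition; returns the per-subject
# averaged epochs plus bookkeeping
preprocess_condition <- function(subjects, cfg = analysis_config()) {
  out <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    out[[i]] <- preprocess_recording(subjects[[i]]$recording, cfg,
                                     subject = i)
  }
  out
}

epoch_averages <- function(preprocessed) {
  lapply(preprocessed, function(p) p$epochs$average)
}

results_path <- function(name) {
  dir.create("results", showWarnings = FALSE)
  file.path("results", name)
}
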