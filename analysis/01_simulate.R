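#!/usr/bin/env Rscript
# Step 1: simulate the synthetic cohort.
#
# Generates a cohort of dyads with full motion/gaze sessions and planted
# behaviour-questionnaire relationships, writes the dyad-level summary
# table, and exports one example session in the on-disk CSV layout so the
# registration step can demonstrate the reader.

source(file.path("analysis", "common.R"))

co <- analysis_cohort()

write_table(co$table, "cohort_table.csv")

# Export the first dyad's raw session (two participants x two sensors).
example_dir <- file.path(results_dir(), "example_session")
unlink(example_dir, recursive = TRUE)
write_session(co$sessions[[1]]$session, example_dir)
message("wrote ", example_dir)

# Record the generator truths the later steps compare against.
truths <- do.call(rbind, lapply(seq_along(co$sessions), function(i) {
  tr <- co$sessions[[i]]$truth
  data.frame(dyad_id = co$table$dyad_id[i],
             clock_offset_s = tr$clock_offset_s,
             coupling_lag_s = tr$coupling$lag_s,
             coupling_strength = tr$coupling$strength)
}))
write_table(truths, "simulation_truth.csv")

message("done: ", nrow(co$table), " dyads simulated")
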