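# Shared configuration for the numbered analysis drivers.
#
# The drivers regenerate the synthetic cohort deterministically from the
# constants below instead of passing large raw-stream files between steps;
# only the example session written by 01_simulate.R lives on disk.

library(dyadmotion)

COHORT_SEED <- 20260101L
N_DYADS <- 8L

# Shortened session protocol: opening conversation, practice, alternating
# cooperative/competitive games separated by pauses (roughly 15 min).
analysis_schedule <- function() {
  data.frame(
    condition = c("conversation", "pause", "practice", "cooperative",
                  "pause", "competitive", "cooperative", "pause",
                  "competitive"),
    duration_s = c(120, 30, 60, 150, 30, 150, 150, 30, 150))
}

analysis_cohort <- function(sessions = TRUE) {
  generate_cohort(cohort_config(n_dyads = N_DYADS, sessions = sessions,
                                session_schedule = analysis_schedule(),
                                seed = COHORT_SEED))
}

results_dir <- function() {
  d <- file.path("results")
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

write_table <- function(df, name) {
  path <- file.path(results_dir(), name)
  write.csv(df, path, row.names = FALSE)
  message("wrote ", path, " (", nrow(df), " rows)")
}
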