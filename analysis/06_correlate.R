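#!/usr/bin/env Rscript
# Step 6: behaviour-questionnaire correlations.
#
# Relates the dyad-level behavioural summaries to the questionnaire scores:
# partner agreement on the ratings, the planted behaviour-score
# correlations (with Bonferroni correction and permutation checks), and an
# outlier-controlled partial correlation for the distance-enjoyment link.

source(file.path("analysis", "common.R"))

co <- analysis_cohort(sessions = TRUE)
tab <- read.csv(file.path(results_dir(), "cohort_table.csv"))

# partner agreement on the per-participant ratings
sc1 <- do.call(rbind, lapply(co$sessions, function(g) g$session$scores[1, ]))
sc2 <- do.call(rbind, lapply(co$sessions, function(g) g$session$scores[2, ]))
agree <- partner_agreement(sc1, sc2,
                           columns = c("enjoyment", "effort", "age"))
write_table(agree, "partner_agreement.csv")

# the three planted links, Bonferroni-corrected as a family of three
tests <- list(
  list(behaviour = "mean_distance_m", score = "enjoyment",
       direction = "negative"),
  list(behaviour = "eye_contact_pct", score = "effort",
       direction = "positive"),
  list(behaviour = "synchrony_peak_r", score = "age",
       direction = "positive"))
rows <- lapply(tests, function(ts) {
  res <- correlate_behaviour_scores(tab[[ts$behaviour]], tab[[ts$score]],
                                    tails = "one", direction = ts$direction,
                                    bonferroni_m = length(tests))
  perm <- permutation_check(tab[[ts$behaviour]], tab[[ts$score]],
                            statistic = "correlation", n_perm = 2000,
                            seed = 21)
  cbind(data.frame(behaviour = ts$behaviour, score = ts$score), res,
        p_permutation = perm$p_permutation)
})
correlations <- do.call(rbind, rows)
write_table(correlations, "behaviour_score_correlations.csv")

# distance-enjoyment again with 3-SD outlier control on distance
pc <- partial_correlation_outlier_control(tab$mean_distance_m, tab$enjoyment,
                                          control = tab$mean_distance_m,
                                          tails = "one",
                                          direction = "negative")
write_table(pc, "distance_enjoyment_outlier_controlled.csv")

message(paste(sprintf("%s ~ %s: r = %.2f (p = %.3f, perm p = %.3f)",
                      correlations$behaviour, correlations$score,
                      correlations$r, correlations$p,
                      correlations$p_permutation),
              collapse = "\n"))
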