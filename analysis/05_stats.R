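#!/usr/bin/env Rscript
# Group statistics: assemble the cohort table (global metrics plus the
# 700 um local metrics) and run the comparison battery — first vs second
# time point on BV/TV, VV/TV, V.Th and Me.V/TV, and the second-time-point
# treatment arms on local VV/TV and local V.Th — each preceded by
# Lilliefors normality and Bartlett variance checks.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_cohort.R"))

samples <- generate_cohort(study_cohort_spec())
tab <- cohort_table(samples, local_threshold_um = 700)
write.csv(tab, file.path(results_dir(), "05_cohort_table.csv"),
          row.names = FALSE)

tests <- run_study_comparisons(tab, timepoints = c("T1", "T2"), seed = 99)
out <- file.path(results_dir(), "05_stats.csv")
write.csv(tests, out, row.names = FALSE)

message("group comparisons:")
for (i in seq_len(nrow(tests))) {
  message(sprintf("  [%s] %-12s F = %6.2f (df %d,%d)  p = %.2g  %s%s",
                  tests$family[i], tests$metric[i], tests$statistic[i],
                  tests$df1[i], tests$df2[i], tests$p_value[i],
                  tests$tier[i],
                  ifelse(tests$assumptions_ok[i], "", "  [assumptions flagged]")))
}
message("tests -> ", out)
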