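#!/usr/bin/env Rscript
# Global morphometry per sample: TV from the closed outer bone contour,
# compartment volumes and fractions (BV/TV, VV/TV, Me.V/TV), mean local
# vessel thickness (V.Th) and vascular-metastasis interdistance (VMI).

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_cohort.R"))

samples <- generate_cohort(study_cohort_spec())
reports <- do.call(rbind, lapply(samples, function(s) {
  cbind(sample_id = s$sample_id, group = s$group, timepoint = s$timepoint,
        as.data.frame(morphometry_report(s$labels)))
}))
out <- file.path(results_dir(), "03_morphometry.csv")
write.csv(reports, out, row.names = FALSE)

for (tp in unique(reports$timepoint)) {
  sub <- reports[reports$timepoint == tp, ]
  message(sprintf(
    "%s (n=%d): BV/TV %.3f | VV/TV %.3f | Me.V/TV %.3f | V.Th %.1f um | VMI %.0f um",
    tp, nrow(sub), mean(sub$bvtv), mean(sub$vvtv), mean(sub$mevtv),
    mean(sub$vth_um, na.rm = TRUE), mean(sub$vmi_um, na.rm = TRUE)))
}
message("global morphometry -> ", out)
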