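# Shared study design for the analysis scripts: a synthetic two-time-point
# cohort mirroring the in-vivo design — a baseline group (T1, early after
# tumour-cell injection, fewer lesions) and four second-time-point
# treatment arms of seven samples each (P placebo, B and V single
# anti-angiogenics, C their combination). The combination arm carries a
# 0.6x vessel-radius shrinkage within 700 um of the metastases, the effect
# the local analysis is designed to detect. Phantoms are 64^3 voxels of
# 3.5 um.

library(osteovasc)

study_cohort_spec <- function(seed = 20260925L) {
  cohort_spec(groups = list(
    list(label = "T1", n = 8, timepoint = "T1", lesion_offset = -1L),
    list(label = "T2P", n = 7, timepoint = "T2"),
    list(label = "T2B", n = 7, timepoint = "T2"),
    list(label = "T2V", n = 7, timepoint = "T2"),
    list(label = "T2C", n = 7, timepoint = "T2", radius_factor = 0.6,
         effect_distance_um = 700)),
    base = phantom_spec(), seed = seed)
}

results_dir <- function() {
  d <- file.path("results")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}
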