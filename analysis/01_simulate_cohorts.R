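#!/usr/bin/env Rscript
# Stage 1 - simulate every cohort the downstream analyses consume.
#
# Produces, with known ground truth: a balanced FACS learning dataset, PT and
# LN cell cohorts (PT biased to CAF-S2/S3, LN to CAF-S1/S4, the shift seen
# between primary tumors and invaded nodes), paired IHC H-score cohorts, and
# a survival cohort with higher hazard for high-stromal / CAF-S4 patients.

library(caflnmap)

seed <- 20260929L
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ref <- simulate_reference_cells(4000, seed = seed + 1L)
pt <- simulate_facs_cohort(2000, c(0.15, 0.30, 0.35, 0.20), tissue = "PT",
                           seed = seed + 2L)
ln <- simulate_facs_cohort(2000, c(0.40, 0.05, 0.05, 0.50), tissue = "LN",
                           seed = seed + 3L)
href <- simulate_reference_hscores(400, seed = seed + 4L)
ihc_pt <- simulate_ihc_cohort(120, c(0.15, 0.30, 0.35, 0.20), seed = seed + 5L)
ihc_ln <- simulate_ihc_cohort(120, c(0.40, 0.05, 0.05, 0.50), seed = seed + 6L)
surv <- simulate_survival_cohort(240, c(stromal_high = log(2),
                                        "CAF-S4" = log(1.8)),
                                 seed = seed + 7L)

write.csv(ref, file.path(out, "facs_reference.csv"), row.names = FALSE)
write.csv(rbind(pt, ln), file.path(out, "facs_cohort.csv"), row.names = FALSE)
write.csv(href, file.path(out, "hscore_reference.csv"), row.names = FALSE)
write.csv(ihc_pt, file.path(out, "ihc_pt.csv"), row.names = FALSE)
write.csv(ihc_ln, file.path(out, "ihc_ln.csv"), row.names = FALSE)
write.csv(surv, file.path(out, "survival_cohort.csv"), row.names = FALSE)

message("simulated: ", nrow(pt) + nrow(ln), " cells, ",
        nrow(ihc_pt) + nrow(ihc_ln), " IHC samples, ",
        nrow(surv), " patients (", sum(surv$event), " events)")
message("true LN CAF-S1+S4 fraction: ",
        round(mean(ln$true_subset %in% c("CAF-S1", "CAF-S4")), 3))
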