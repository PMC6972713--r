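#!/usr/bin/env Rscript
# Stage 2 - learn quartile thresholds on the FACS learning dataset, classify
# the PT/LN cell cohorts, transpose the thresholds to the IHC modality and
# call per-sample enrichment; cross-tabulate PT vs LN enrichment.
#
# Expects the tables written by 01_simulate_cohorts.R.

library(caflnmap)

out <- "results/analysis"
ref <- read.csv(file.path(out, "facs_reference.csv"))
cells <- read.csv(file.path(out, "facs_cohort.csv"))
href <- read.csv(file.path(out, "hscore_reference.csv"))
ihc_pt <- read.csv(file.path(out, "ihc_pt.csv"))
ihc_ln <- read.csv(file.path(out, "ihc_ln.csv"))

th <- learn_thresholds(ref, markers = caf_panel("FACS"))
write.csv(data.frame(th), file.path(out, "thresholds_facs.csv"),
          row.names = FALSE)
calls <- classify_cells(cells, th, caf_profiles("FACS"))
cells$called_subset <- calls$label
write.csv(cells, file.path(out, "facs_cohort_classified.csv"),
          row.names = FALSE)
acc <- mean(cells$called_subset == cells$true_subset)
message("per-cell classification accuracy vs ground truth: ", round(acc, 4))

prop <- prop.table(table(cells$tissue, cells$called_subset), 1)
print(round(prop, 3))
write.csv(as.data.frame.matrix(prop), file.path(out, "subset_proportions.csv"))

th_ihc <- transpose_thresholds(href, markers = caf_panel("IHC"),
                               marker_map = c())
write.csv(data.frame(th_ihc), file.path(out, "thresholds_ihc.csv"),
          row.names = FALSE)
cp <- call_sample_enrichment(ihc_pt, th_ihc)
cl <- call_sample_enrichment(ihc_ln, th_ihc)
rec <- mean(c(cp$label == ihc_pt$true_enrichment,
              cl$label == ihc_ln$true_enrichment))
message("IHC enrichment recovery: ", round(rec, 4))

cont <- table(PT = cp$label, LN = cl$label)
print(cont)
write.csv(as.data.frame.matrix(cont), file.path(out, "contingency_pt_ln.csv"))
message("LN samples called CAF-S1/S4-enriched: ",
        round(mean(cl$label %in% c("CAF-S1", "CAF-S4")), 3),
        " (imposed mix 0.90)")
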