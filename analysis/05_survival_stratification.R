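#!/usr/bin/env Rscript
# Stage 5 - outcome stratification on the simulated cohort: median split of
# stromal content, Kaplan-Meier curves with log-rank p-values, and
# univariate plus multivariate (additive) Cox models.
#
# Expects results/analysis/survival_cohort.csv from 01_simulate_cohorts.R.

library(caflnmap)

out <- "results/analysis"
sv <- read.csv(file.path(out, "survival_cohort.csv"))

sv$stromal_group <- stratify_by_median(sv$stromal_percent)
sv$s4_enriched <- factor(ifelse(sv$enrichment == "CAF-S4", "CAF-S4", "other"),
                         levels = c("other", "CAF-S4"))

lr_stromal <- logrank_test(sv$time, sv$event, sv$stromal_group)
lr_s4 <- logrank_test(sv$time, sv$event, sv$s4_enriched)
message(sprintf("log-rank stromal low/high: chi2=%.2f p=%.2e",
                lr_stromal$statistic, lr_stromal$p_value))
message(sprintf("log-rank CAF-S4 vs other:  chi2=%.2f p=%.2e",
                lr_s4$statistic, lr_s4$p_value))

km <- do.call(rbind, lapply(levels(sv$stromal_group), function(g) {
  f <- km_estimator(sv$time[sv$stromal_group == g],
                    sv$event[sv$stromal_group == g])
  cbind(group = g, as.data.frame(f))
}))
write.csv(km, file.path(out, "km_stromal.csv"), row.names = FALSE)

uni <- lapply(list(stromal = data.frame(high_stromal =
                                          as.numeric(sv$stromal_group == "high")),
                   s4 = data.frame(caf_s4 =
                                     as.numeric(sv$s4_enriched == "CAF-S4"))),
              function(d) cox_fit(sv$time, sv$event, d))
multi <- cox_fit(sv$time, sv$event,
                 data.frame(high_stromal = as.numeric(sv$stromal_group == "high"),
                            caf_s4 = as.numeric(sv$s4_enriched == "CAF-S4"),
                            n_stage = sv$n_stage, subtype = sv$subtype))

fmt <- function(f, model) data.frame(
  model = model, term = names(f$coef), hr = f$hr, ci_lower = f$ci_lower,
  ci_upper = f$ci_upper, p_value = f$p_value, row.names = NULL)
tab <- rbind(fmt(uni$stromal, "univariate"), fmt(uni$s4, "univariate"),
             fmt(multi, "multivariate"))
print(tab, row.names = FALSE, digits = 3)
write.csv(tab, file.path(out, "cox_models.csv"), row.names = FALSE)
message("generating log-HRs were log(2) for high stromal and log(1.8) for CAF-S4")
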