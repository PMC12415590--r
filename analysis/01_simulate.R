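#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Emulates the study design the package targets: 65 controls and 55
# patients with 116 regional gray-matter density values, four covariates
# (sex, age, education, TIV), and two planted patient subtypes (19 and 36
# patients) whose covariance structure is perturbed in opposite directions
# (|delta| = 0.3) on a shared 40-edge set. Clinical variables (headache
# frequency, headache occurrence) are tied to the subtype label.

suppressPackageStartupMessages(library(idscn))
seed <- 1

cohort <- simulate_cohort(sim_config(seed = seed))
print(cohort)

out <- file.path("results", "cohort")
paths <- write_cohort(cohort, out)
cat("cohort written to", out, "\n")
cat("  subtype sizes:", paste(table(cohort$truth$subtype), collapse = "/"), "\n")
cat("  planted edges per subtype:",
    nrow(cohort$truth$subtype_spec[[1]]$edges), "\n")
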