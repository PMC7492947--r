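#!/usr/bin/env Rscript
# Stage 1: draw the synthetic trial cohort.
#
# The shipped configuration encodes the arm-level summaries of the
# two-arm randomized balloon-deflation trial (105 rapid / 106 slow):
# baseline covariates, angiographic features, frame counts at four
# timepoints, peak cardiac enzymes and 30-day event proportions.  One
# seeded patient-level realization is written under results/cohort/.

suppressPackageStartupMessages(library(stentflow))
seed <- 20150801  # trial enrolment opened August 2015

specs <- default_arm_specs()
cohort <- generate_cohort(specs$rapid, specs$slow, seed = seed)
paths <- write_cohort(cohort, file.path("results", "cohort"))

p <- cohort$patients
cat(sprintf("Drew %d patients (%d rapid, %d slow), seed %d\n",
            nrow(p), sum(p$arm == "rapid"), sum(p$arm == "slow"), seed))
cat(sprintf("Occluded at baseline: %d rapid / %d slow\n",
            sum(p$occluded_at_baseline & p$arm == "rapid"),
            sum(p$occluded_at_baseline & p$arm == "slow")))
cc <- ctfc(p$tfc_post2_raw, p$infarct_artery, p$occl_post2)
cat(sprintf("cTFC at end of PCI: rapid %.1f +/- %.1f, slow %.1f +/- %.1f frames\n",
            mean(cc[p$arm == "rapid"]), sd(cc[p$arm == "rapid"]),
            mean(cc[p$arm == "slow"]), sd(cc[p$arm == "slow"])))
cat("Wrote:", paste(paths, collapse = ", "), "\n")
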