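#!/usr/bin/env Rscript
# Step 4 — cross-validate the deterministic cohort engine against the
# independent individual-level microsimulation.
#
# For representative cohorts and both arms, simulates 20,000 individuals
# and compares expected fractures, deaths, life-years and costs with the
# cohort engine (z-scores of the difference against the Monte-Carlo SE).

suppressPackageStartupMessages(library(osteocea))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

sc <- make_reference_scenario(seed)
dir.create("results", showWarnings = FALSE)

cases <- list(list(sex = "women", age = 70, stratum = "general", arm = "control"),
              list(sex = "women", age = 70, stratum = "general", arm = "intervention"),
              list(sex = "men", age = 60, stratum = "osteoporosis", arm = "control"),
              list(sex = "women", age = 80, stratum = "prevalent_fracture",
                   arm = "intervention"))
out <- list()
for (cs in cases) {
  chk <- oracle_check(cs[c("sex", "age", "stratum")], cs$arm, sc,
                      n = 20000L, seed = seed)
  out[[length(out) + 1L]] <- data.frame(sex = cs$sex, age = cs$age,
                                        stratum = cs$stratum, arm = cs$arm, chk)
  message(sprintf("%s %d %s (%s): max |z| = %.2f over %d metrics",
                  cs$sex, cs$age, cs$stratum, cs$arm, max(abs(chk$z)), nrow(chk)))
}
out <- do.call(rbind, out)
write.table(out, "results/microsim_validation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("All metrics within 4 SE: ", all(abs(out$z) <= 4))
message("Details in results/microsim_validation.tsv")
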