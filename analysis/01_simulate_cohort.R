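#!/usr/bin/env Rscript
# Simulate the two experiment variants with heterogeneous hybrid agents and
# write the raw trial logs, ground-truth parameter tables and consumption
# records under results/.

library(habitlearn)

seed <- 20260921L
dir.create("results/cohorts", recursive = TRUE, showWarnings = FALSE)

for (exp in c("exp1", "exp2")) {
  cfg <- task_config(exp)
  co <- generate_cohort(90, cfg, seed = child_seed(seed, match(exp, c("exp1", "exp2"))))
  out <- file.path("results/cohorts", exp)
  dir.create(out, showWarnings = FALSE)
  write_trials(co$trials, file.path(out, "trials.csv"))
  write.csv(co$truth, file.path(out, "truth.csv"), row.names = FALSE)
  write.csv(co$consumption, file.path(out, "consumption.csv"),
            row.names = FALSE)
  write_config(cfg, file.path(out, "config.json"))
  cat(sprintf("%s: %d subjects, %d trial records, devalued split %s\n",
              exp, nrow(co$truth), nrow(co$trials),
              paste(table(co$truth$devalued), collapse = "/")))
}

cat("Cohorts written to results/cohorts/\n")
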