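#!/usr/bin/env Rscript
# Parameter-recovery benchmark: ten synthetic maps at the study conditions,
# each analysed with the 20-restart anchored global fit; across-seed means
# of the recovered time constants and the excitation fraction.
#
# This is the computation behind scripts/acceptance.R.
# Writes: results/benchmark/per_seed.tsv, results/benchmark/summary.txt

library(trxkin)
dir.create("results/benchmark", recursive = TRUE, showWarnings = FALSE)

rr <- run_recovery(seeds = 1:10, config = scenario_config(),
                   fitcfg = fit_config(restarts = 20L, seed = 101L))

per <- rr$per_seed
write.table(format(per, digits = 6), "results/benchmark/per_seed.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

truth <- rr$truth
tc <- function(k, unit) if (unit == "fs") 1000 / k else 1 / k
sum_lines <- c(
  sprintf("1/k1: %6.1f fs  (generating %.0f fs, %+.1f%%)",
          mean(tc(per$k1, "fs")), 1000 / truth[["k1"]],
          100 * (mean(tc(per$k1, "fs")) / (1000 / truth[["k1"]]) - 1)),
  sprintf("1/k2: %6.2f ps  (generating %.2f ps, %+.1f%%)",
          mean(1 / per$k2), 1 / truth[["k2"]],
          100 * (mean(1 / per$k2) * truth[["k2"]] - 1)),
  sprintf("1/k5: %6.1f ps  (generating %.1f ps, %+.1f%%)",
          mean(1 / per$k5), 1 / truth[["k5"]],
          100 * (mean(1 / per$k5) * truth[["k5"]] - 1)),
  sprintf("gamma: %5.2f %%  (generating %.1f %%, %+.1f%%)",
          100 * rr$gamma_mean, 4.5, 100 * (rr$gamma_mean / 0.045 - 1)),
  sprintf("restarts kept per seed: %s", paste(per$n_kept, collapse = " ")))
writeLines(sum_lines, "results/benchmark/summary.txt")
message(paste(sum_lines, collapse = "\n"))
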