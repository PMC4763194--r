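#!/usr/bin/env Rscript
# Stage 4 — the locus-elimination analysis.
#
# Self-contained end-to-end run (same master seed as stages 1-3, so the
# simulated cohort and estimates coincide): for every population, the
# baseline 8/8 and 7/8 likelihoods and the 6/6 and 5/6 likelihoods after
# removing each locus from matching consideration, with the directional
# properties of the matching model verified before anything is written.
# Exit status: 0 success, 3 property violation.

suppressPackageStartupMessages(library(hlamatchr))

seed <- 1L
out <- "results/locus_elimination"

res <- tryCatch(
  run_locus_elimination_study(seed = seed, out_dir = out,
                              make_plot = requireNamespace("ggplot2", quietly = TRUE)),
  error = function(e) {
    message("locus-elimination study failed: ", conditionMessage(e))
    quit(status = 3L)
  })

cat("Locus-elimination report (from EM-estimated tables):\n")
print(res$report, digits = 4, row.names = FALSE)
cat(sprintf("\nLargest |estimated - ground truth| likelihood difference: %.4f\n",
            res$max_abs_error))

gains <- unlist(res$report[grep("^gain_6of6_", names(res$report))])
cat(sprintf("6/6 gains range from %.4f to %.4f; the minority population's largest gain comes from dropping %s.\n",
            min(gains), max(gains),
            { g <- sapply(hla_loci(), function(l)
                res$report[res$report$population == "minority",
                           sprintf("gain_6of6_drop%s", l)])
              names(which.max(g)) }))
cat(sprintf("Reports and metadata written to %s/\n", out))
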