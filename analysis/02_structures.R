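#!/usr/bin/env Rscript
# Step 2: geometry benchmark.
#
# For every compound x method pair: superpose the computed structure onto
# the reference (hydrogens excluded) and evaluate the RMSE, then measure
# the metal-ligand bond errors (MUE, MSE) over the coordination sphere
# detected on the reference. Writes results/structures.tsv.

library(uvvisbench)

res <- run_benchmark("results/synthetic_benchmark/manifest.yaml",
                     out_dir = "results")

str_tab <- res$structures
cat("Structure metrics for", nrow(str_tab), "compound x method pairs\n\n")
print(str_tab, row.names = FALSE, digits = 4)

cat("\nPer-method aggregates (Angstrom; methods with larger perturbations",
    "\nshould show larger errors):\n\n")
print(res$aggregates$mue, row.names = FALSE, digits = 4)

truth <- read.delim("results/synthetic_benchmark/ground_truth.tsv")
m <- merge(str_tab, truth, by = c("compound", "method"))
cat("\nMax |MUE - MUE_true| =", format(max(abs(m$mue - m$mue_true))),
    "Angstrom (zero-jitter scenarios: exact bookkeeping)\n")
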