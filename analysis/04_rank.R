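#!/usr/bin/env Rscript
# Step 4: rank the methods.
#
# Aggregates the per-compound metrics into per-method averages and medians
# (absolute shift |delta| for the energy-shift ranking), plus box-plot
# statistics (linear-interpolation quartiles, 1.5 x IQR outliers) overall
# and within compound subgroups. Both average and median are reported and
# never collapsed into one score: they can rank methods differently.

library(uvvisbench)

sim <- read.delim("results/similarity.tsv")
str_tab <- read.delim("results/structures.tsv")

cat("== Geometry ranking (bond MUE, Angstrom; smaller is better) ==\n")
print(aggregate_methods(long_to_table(str_tab, "mue")),
      row.names = FALSE, digits = 4)

cat("\n== Excitation-energy ranking (average |delta|, eV) ==\n")
shift <- aggregate_methods(long_to_table(sim, "delta_opt"), absolute = TRUE)
print(shift, row.names = FALSE, digits = 4)

cat("\n== Spectral-shape ranking (S_max; larger is better) ==\n")
smax <- aggregate_methods(long_to_table(sim, "s_max"))
print(smax[order(-smax$average), ], row.names = FALSE, digits = 4)

cat("\n== Box-plot statistics of MUE per method ==\n")
tab <- long_to_table(str_tab, "mue")
for (m in colnames(tab$values)) {
  bs <- boxplot_stats(tab$values[, m])
  cat(sprintf("%-9s median %.4f  IQR [%.4f, %.4f]  whiskers [%.4f, %.4f]  outliers: %s\n",
              m, bs$median, bs$q1, bs$q3, bs$whisker_low, bs$whisker_high,
              if (length(bs$outliers)) paste(signif(bs$outliers, 3),
                                             collapse = ", ") else "none"))
}

# subgroup split: first half vs second half of the compounds, the kind of
# chemical partition (e.g. by oxidation state) a real benchmark reports
compounds <- sort(unique(str_tab$compound))
half <- ceiling(length(compounds) / 2)
groups <- list(group_a = compounds[seq_len(half)],
               group_b = compounds[-seq_len(half)])
cat("\n== Subgroup medians of MUE ==\n")
gs <- subgroup_stats(tab, groups)
for (g in names(gs)) {
  meds <- vapply(gs[[g]], function(x) x$median, numeric(1))
  cat(g, ":", paste(sprintf("%s=%.4f", names(meds), meds),
                    collapse = "  "), "\n")
}

write_tables <- file.path("results",
                          c("rank_mue.tsv", "rank_abs_shift.tsv",
                            "rank_smax.tsv"))
utils::write.table(aggregate_methods(long_to_table(str_tab, "mue")),
                   write_tables[1], sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(shift, write_tables[2], sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(smax, write_tables[3], sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat("\nWrote", paste(basename(write_tables), collapse = ", "),
    "to results/\n")
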