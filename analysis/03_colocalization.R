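#!/usr/bin/env Rscript
# Per-cell two-channel pixel co-localization: nuclei whose channels share
# one punctate signal (co-condensing factors) vs nuclei with independent
# patterns (a chromatin factor unrelated to the condensate), the
# histogram-ready per-cell Pearson r table, and the group contrast.

suppressMessages(library(condquant))
dir.create("results", showWarnings = FALSE)

shared <- simulate_coloc_population(93, target_r = 0.75, seed = 301L)
indep <- simulate_coloc_population(149, target_r = 0.75, seed = 302L,
                                   mode = "independent")

r_of <- function(pop, label) data.frame(
  condition = label,
  cell = seq_along(pop),
  n_pixels = vapply(pop, function(x) x$n, 0L),
  pearson_r = vapply(pop, function(x)
    pixel_colocalization(x$ch1, x$ch2)$pearson_r, 0))

tab <- rbind(r_of(shared, "shared_signal"), r_of(indep, "independent_signal"))
write_results(tab, "results/03_per_cell_pearson.csv")

g <- compare_groups(tab$pearson_r[tab$condition == "shared_signal"],
                    tab$pearson_r[tab$condition == "independent_signal"])
cat(sprintf("mean per-cell r: shared %.3f (n=%d) vs independent %.3f (n=%d); p = %.3g %s\n",
            g$means[["a"]], g$n[["a"]], g$means[["b"]], g$n[["b"]],
            g$p, g$stars))
cat("per-cell values in results/03_per_cell_pearson.csv (histogram-ready)\n")
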