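#!/usr/bin/env Rscript
# Per-nucleus dispersion statistics across conditions: CV, Fano number and
# the reference-normalized Fano, with two-sided Student's t-tests of every
# punctate condition against the free-fluorophore control.

suppressMessages(library(condquant))
dir.create("results", showWarnings = FALSE)
seed <- 20260929L

conditions <- list(
  free_fluorophore = scene_config(n_puncta = 0L, puncta_fraction = 0,
                                  noise = "poisson"),
  puncta_f20 = scene_config(puncta_fraction = 0.2, noise = "poisson"),
  puncta_f40 = scene_config(puncta_fraction = 0.4, noise = "poisson"),
  puncta_f60 = scene_config(puncta_fraction = 0.6, noise = "poisson"))

per_cell <- list()
for (nm in names(conditions)) {
  pop <- simulate_population(conditions[[nm]], 50, seed = seed)
  stats <- do.call(rbind, lapply(seq_along(pop), function(i) {
    st <- nucleus_pixel_stats(pop[[i]]$stack, channel = "gfp")
    if (nrow(st) == 0) return(NULL)
    st$cell <- i
    st[1, ]
  }))
  stats$condition <- nm
  per_cell[[nm]] <- stats
  seed <- seed + 1L
}
all_cells <- do.call(rbind, per_cell)
write_results(all_cells[, c("condition", "cell", "n_pixels", "sub_mean",
                            "variance", "cv", "fano", "undefined")],
              "results/02_per_cell_stats.csv")

ref <- per_cell$free_fluorophore$fano
summary_rows <- lapply(names(conditions), function(nm) {
  f <- per_cell[[nm]]$fano
  nf <- normalize_fano(f, ref)
  g <- if (nm == "free_fluorophore") NULL else compare_groups(f, ref)
  data.frame(condition = nm, n = nf$n,
             mean_cv = mean(per_cell[[nm]]$cv, na.rm = TRUE),
             mean_fano = mean(f, na.rm = TRUE),
             norm_fano = nf$mean, norm_fano_sem = nf$sem,
             p_vs_reference = if (is.null(g)) NA_real_ else g$p,
             stars = if (is.null(g)) "" else g$stars)
})
summary <- do.call(rbind, summary_rows)
write_results(summary, "results/02_condition_summary.csv")

cat("condition summary (normalized Fano is 1 for the reference by construction):\n")
print(summary, row.names = FALSE, digits = 3)
cat(sprintf("\nmean Fano rises monotonically with puncta load: %s\n",
            ifelse(all(diff(summary$mean_fano) > 0), "yes", "NO")))
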