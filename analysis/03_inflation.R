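#!/usr/bin/env Rscript
# The pooled-sample vs meta-analysis label-permutation experiment: permute
# tumor/normal labels within each study of a batch-structured null cohort,
# then compare the two analysis paths. Pooling inflates dramatically with
# the batch shift SD; the meta path stays calibrated. Writes QQ data, a QQ
# figure and a JSON report under results/inflation/.

library(lungmeta)

dir.create("results/inflation", showWarnings = FALSE, recursive = TRUE)
grid <- c(0, 0.5, 1.0)
reports <- lapply(grid, function(bs) {
  co <- generate_cohort(synthetic_config(n_studies = 10, genes = 5000,
                                         seed = 2026L, batch_shift_sd = bs))
  inflation_experiment(co$studies, seed = 7L)
})
names(reports) <- paste0("shift_", grid)

summ <- data.frame(
  batch_shift_sd = grid,
  pooled_bonf_sig = vapply(reports, function(r) r$sig_fraction[["pooled"]], 0),
  meta_bonf_sig = vapply(reports, function(r) r$sig_fraction[["meta"]], 0),
  pooled_ks = vapply(reports, function(r) r$ks[["pooled"]], 0),
  meta_ks = vapply(reports, function(r) r$ks[["meta"]], 0),
  meta_anticons_ks = vapply(reports, function(r) r$ks_anticons[["meta"]], 0))
write.table(summ, "results/inflation/summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(summ, digits = 3)
cat("\nAt shift SD 1.0 the pooled path keeps",
    sprintf("%.0f%%", 100 * summ$pooled_bonf_sig[3]),
    "of genes Bonferroni-significant under a label permutation;",
    "the meta path keeps",
    sprintf("%.2f%%.\n", 100 * summ$meta_bonf_sig[3]))

qq <- reports$shift_1$qq
write.table(qq, "results/inflation/qq_shift1.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(summ, "results/inflation/report.json",
                     auto_unbox = TRUE, digits = NA)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(qq, aes(expected, observed, colour = path)) +
    geom_point(size = 0.4) +
    geom_abline(linetype = 2) +
    labs(x = expression(Expected ~ -log[10](p)),
         y = expression(Observed ~ -log[10](p)),
         title = "Label-permuted null, batch shift SD = 1",
         colour = NULL) +
    theme_bw()
  ggsave("results/inflation/qq_shift1.png", p, width = 5, height = 4, dpi = 150)
}
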