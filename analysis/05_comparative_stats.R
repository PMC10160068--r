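#!/usr/bin/env Rscript
# Stage 5: the comparative statistics layer — per-sample quantities with
# Student's t between conditions, a Pearson correlation panel with BH-FDR,
# and Mantel tests of community dissimilarity against each water-quality
# covariate.

source("analysis/00_config.R")

com <- study_community()
rep <- run_pipeline(com, n_perm = 999)

save_table(rep$per_sample, "per_sample_quantities.tsv")
save_table(rep$tests, "condition_t_tests.tsv")
cat("condition contrasts (Student's t):\n")
for (i in seq_len(nrow(rep$tests))) {
  cat(sprintf("  %-18s t = %6.2f  p = %.3g\n", rep$tests$quantity[i],
              rep$tests$statistic[i], rep$tests$p_value[i]))
}

mant <- data.frame(
  covariate = names(rep$mantel),
  rho = vapply(rep$mantel, function(m) m$statistic, numeric(1)),
  p = vapply(rep$mantel, function(m) m$p_value, numeric(1)),
  n_perm = vapply(rep$mantel, function(m) m$n_perm, integer(1)))
save_table(mant, "mantel_tests.tsv")
cat(sprintf("Mantel vs chlorine: rho = %.2f, p = %.3g\n",
            mant$rho[mant$covariate == "chlorine"],
            mant$p[mant$covariate == "chlorine"]))

# Pearson panel: viral load vs defense carrier share and burden, BH-adjusted
ps <- rep$per_sample
panel <- list(
  c("viral_share", "carrier_fraction"),
  c("viral_share", "M"),
  c("lysogenic_share", "carrier_fraction"))
pear <- do.call(rbind, lapply(panel, function(pair) {
  pr <- pearson_test(ps[[pair[1]]], ps[[pair[2]]])
  data.frame(x = pair[1], y = pair[2], r = pr$statistic, p = pr$p_value)
}))
pear$p_adj <- adjust_fdr(pear$p)
save_table(pear, "pearson_panel.tsv")
cat("Pearson panel:\n")
for (i in seq_len(nrow(pear))) {
  cat(sprintf("  %s ~ %s: r = %.2f, p = %.3g (BH %.3g)\n", pear$x[i], pear$y[i],
              pear$r[i], pear$p[i], pear$p_adj[i]))
}
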