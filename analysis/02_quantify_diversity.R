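#!/usr/bin/env Rscript
# Stage 2: simulate read mappings, apply the >= 30 bp aligned-length filter,
# quantify contigs as TPM, and summarize alpha/beta diversity (Shannon,
# Bray-Curtis PCoA) of the viral and prokaryotic fractions.

source("analysis/00_config.R")

com <- study_community()
lengths <- setNames(com$contigs$length, com$contigs$contig_id)
aln <- simulate_alignments(com, seed = child_seed(STUDY_SEED, "reads"))
ab <- abundance_table(aln, lengths, min_aligned = 30L)

viral <- com$contigs$contig_id[com$contigs$category != "prokaryotic"]
prok <- setdiff(rownames(ab), viral)
cond <- setNames(com$tables$samples$condition, com$tables$samples$sample_id)

summary <- data.frame(
  sample_id = colnames(ab),
  condition = cond[colnames(ab)],
  shannon_viral = apply(ab[viral, ], 2, shannon),
  shannon_prok = apply(ab[prok, ], 2, shannon),
  viral_pct = 100 * colSums(ab[viral, ]) / 1e6)
save_table(summary, "abundance_summary.tsv")

D <- bray_curtis_matrix(ab[prok, ])
ord <- pcoa(D, k = 2)
coords <- data.frame(sample_id = rownames(ord$coordinates),
                     condition = cond[rownames(ord$coordinates)],
                     ord$coordinates)
save_table(coords, "pcoa_coordinates.tsv")

cat(sprintf("mean viral Shannon: %.2f (disinfected) vs %.2f (non-disinfected)\n",
            mean(summary$shannon_viral[summary$condition == "disinfected"]),
            mean(summary$shannon_viral[summary$condition == "non_disinfected"])))
cat(sprintf("mean viral share: %.2f%% vs %.2f%%\n",
            mean(summary$viral_pct[summary$condition == "disinfected"]),
            mean(summary$viral_pct[summary$condition == "non_disinfected"])))
cat(sprintf("PCoA: PCo1 %.1f%%, PCo2 %.1f%% of positive-eigenvalue variance\n",
            100 * ord$variance_explained[1], 100 * ord$variance_explained[2]))
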