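#!/usr/bin/env Rscript
# Stage 3: profile the antiviral arsenal — carrier fractions, per-family
# abundance/proportions, RM subtype shares, lysogen-restricted and
# phage-carried profiles — and compare conditions with Student's t.

source("analysis/00_config.R")

com <- study_community()
lengths <- setNames(com$contigs$length, com$contigs$contig_id)
aln <- simulate_alignments(com, seed = child_seed(STUDY_SEED, "reads"))
ab <- abundance_table(aln, lengths)
cond <- setNames(com$tables$samples$condition, com$tables$samples$sample_id)
dis <- names(cond)[cond == "disinfected"]
non <- names(cond)[cond == "non_disinfected"]

ann <- com$tables$defense[com$tables$defense$carrier_category == "prokaryotic", ]
cf <- carrier_fraction(ann, ab, rownames(ab))
tt <- t_test(cf[dis], cf[non])
cat(sprintf("defense-carrier TPM share: %.2f%% vs %.2f%% (t = %.2f, p = %.2g)\n",
            100 * mean(cf[dis]), 100 * mean(cf[non]), tt$statistic, tt$p_value))

prof <- profile_families(ann, ab, cond)
save_table(prof, "defense_profile.tsv")
top <- prof[prof$group == "disinfected", ][1, ]
cat(sprintf("top family under disinfection: %s (%.0f%% of defense TPM)\n",
            top$family, 100 * top$proportion))

if ("RM" %in% ann$family) {
  sh <- subtype_shares(ann, ab, "RM")
  save_table(data.frame(subtype = names(sh), share = as.numeric(sh)),
             "rm_subtype_shares.tsv")
  cat("RM subtype shares:",
      paste(sprintf("%s=%.0f%%", names(sh), 100 * sh), collapse = ", "), "\n")
}

lysogens <- unique(com$tables$prophages$host_contig_id)
lys_prof <- restricted_profile(ann, ab, lysogens, cond)
save_table(lys_prof, "lysogen_defense_profile.tsv")
cat(sprintf("lysogenized prokaryotes carry %d defense famil(ies) in profile\n",
            length(unique(lys_prof$family))))
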