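#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study community and emit its input file
# set (contigs, prophage coordinates, tRNAs, defense annotations, lifestyle
# labels, viral gene hits, sample metadata) plus the planted ground truth.

source("analysis/00_config.R")

com <- study_community()
write_community(com, DATA_DIR)

cat(sprintf("community: %d contigs (%d prokaryotic, %d free viral, %d prophage)\n",
            nrow(com$contigs), sum(com$contigs$category == "prokaryotic"),
            sum(com$contigs$category == "free_viral"),
            sum(com$contigs$category == "prophage")))
cat(sprintf("planted: %d host links (%s), %d CRISPR arrays, %d defense annotations\n",
            nrow(com$truth$true_host_links),
            paste(names(table(com$truth$true_host_links$channel)),
                  table(com$truth$true_host_links$channel),
                  sep = "=", collapse = ", "),
            nrow(com$truth$true_arrays), nrow(com$tables$defense)))
cat(sprintf("samples: %d per condition; inputs written under %s\n",
            com$config$n_samples_per_condition, DATA_DIR))
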