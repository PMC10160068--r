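Package: aquaphage
Title: Antiviral Systems and Phage-Host Interactions in Water Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community-level analysis of prokaryotic antiviral defense
    systems and prokaryote-phage interactions in (drinking-)water
    metagenomes. Provides TPM abundance quantification with an
    aligned-length filter, greedy sequence dereplication at
    identity/coverage thresholds, majority-vote viral contig taxonomy,
    CRISPR repeat-spacer array detection and the length- and
    abundance-normalized spacer burden statistic, three-channel in-situ
    phage-host linkage (CRISPR spacer, tRNA, prophage) with
    polyvalent-phage classification, defense-system community profiling,
    and the comparative statistics layer (Shannon diversity, Bray-Curtis,
    PCoA, Mantel permutation test, Pearson, Student's t). Includes a
    seeded synthetic metagenome generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
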