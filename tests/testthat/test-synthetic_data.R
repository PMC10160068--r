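test_that("generation is deterministic given the seed", {
  cfg <- small_config(seed = 5L)
  com1 <- generate_community(cfg)
  com2 <- generate_community(cfg)
  expect_identical(com1$contigs, com2$contigs)
  expect_identical(com1$tables, com2$tables)
  expect_identical(com1$truth, com2$truth)
  # and the emitted file set is byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_community(com1, d1); write_community(com2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the data
  expect_false(identical(generate_community(small_config(seed = 6L))$contigs$sequence,
                         com1$contigs$sequence))
})

test_that("config invariants are validated before generation", {
  expect_error(small_config(prophage_rate = 1.2), "probabilities")
  expect_error(small_config(spacers_per_array_range = c(1L, 3L)), "spacers_per_array")
  expect_error(small_config(contig_length_range = c(2000L, 2000L)), "non-degenerate")
  expect_error(small_config(defense_family_weights = c(RM = 0)), "weights")
  expect_error(small_config(viral_length_range = c(800L, 1200L)), "1500")
  expect_error(small_config(reads_per_sample = 0L), "reads_per_sample")
})

test_that("prophage_rate 0 plants no prophage links or contigs", {
  com <- generate_community(small_config(seed = 8L, prophage_rate = 0))
  expect_equal(sum(com$contigs$category == "prophage"), 0L)
  expect_equal(nrow(com$tables$prophages), 0L)
  expect_false("prophage" %in% com$truth$true_host_links$channel)
})

test_that("with source rate 1 every planted spacer is a viral substring", {
  com <- generate_community(small_config(seed = 9L, crispr_rate = 1,
                                         spacer_source_rate = 1))
  prov <- com$truth$spacer_provenance
  expect_gt(nrow(prov), 0)
  expect_false(any(is.na(prov$source)))
  viral <- com$contigs[com$contigs$category != "prokaryotic", ]
  found <- oracle_match_spacers(
    data.frame(contig_id = prov$contig_id, spacer = prov$spacer,
               stringsAsFactors = FALSE), viral)
  # every planted spacer is found by the naive scan in its recorded source
  for (i in seq_len(nrow(prov))) {
    expect_true(any(found$phage_id == prov$source[i] &
                      found$host_contig_id == prov$contig_id[i]),
                info = sprintf("spacer %d from %s", i, prov$source[i]))
  }
  # truth links point at real contigs
  expect_true(all(com$truth$true_host_links$phage_id %in% com$contigs$contig_id))
  expect_true(all(com$truth$true_host_links$host_contig_id %in% com$contigs$contig_id))
})

test_that("prophages are verbatim copies at their recorded intervals", {
  com <- generate_community(small_config(seed = 10L, prophage_rate = 0.6))
  pp <- com$tables$prophages
  expect_gt(nrow(pp), 0)
  seqs <- stats::setNames(com$contigs$sequence, com$contigs$contig_id)
  for (i in seq_len(nrow(pp))) {
    host <- seqs[[pp$host_contig_id[i]]]
    embedded <- substr(host, pp$start[i] + 1, pp$end[i])
    expect_identical(embedded, seqs[[pp$prophage_id[i]]])
  }
})

test_that("simulated reads recover expected abundance through TPM", {
  com <- generate_community(small_config(seed = 11L))
  lengths <- stats::setNames(com$contigs$length, com$contigs$contig_id)
  ids <- com$contigs$contig_id

  # single contig carries everything -> post-filter TPM = 1e6
  ab1 <- matrix(0, length(ids), 1, dimnames = list(ids, "s1"))
  ab1[1, 1] <- 1
  aln <- simulate_alignments(com, seed = 3L, abundance = ab1)
  tpm <- compute_tpm(suppressMessages(filter_alignments(aln$s1)), lengths)
  expect_equal(unname(tpm[ids[1]]), 1e6)
  expect_equal(sum(tpm[-1]), 0)

  # two contigs of different length at equal expected relative abundance:
  # length-normalized counts give ~equal TPM within multinomial error
  com2 <- generate_community(small_config(seed = 11L, reads_per_sample = 100000L))
  ab2 <- matrix(0, length(ids), 1, dimnames = list(ids, "s1"))
  ab2[c(1, 5), 1] <- 0.5
  aln2 <- simulate_alignments(com2, seed = 4L, abundance = ab2)
  tpm2 <- compute_tpm(suppressMessages(filter_alignments(aln2$s1)), lengths)
  expect_equal(unname(tpm2[ids[1]]), 5e5, tolerance = 0.02)
  expect_equal(unname(tpm2[ids[5]]), 5e5, tolerance = 0.02)

  # all reads short -> nothing survives the filter
  com3 <- generate_community(small_config(seed = 11L, short_read_rate = 1))
  aln3 <- simulate_alignments(com3, seed = 5L)
  expect_equal(nrow(suppressMessages(filter_alignments(aln3[[1]]))), 0L)

  # count-level simulation agrees with record-level in expectation
  cnt <- simulate_counts(com, seed = 6L)
  expect_equal(dim(cnt), dim(com$truth$true_abundance))
  expect_true(all(cnt >= 0))
})

test_that("condition effects tilt lysogenic and carrier abundance as configured", {
  cfg <- small_config(seed = 12L, n_samples_per_condition = 8L)
  com <- generate_community(cfg)
  ab <- com$truth$true_abundance
  lys <- names(com$truth$true_lifestyles)[com$truth$true_lifestyles == "lysogenic"]
  viral <- com$contigs$contig_id[com$contigs$category != "prokaryotic"]
  cond <- stats::setNames(com$tables$samples$condition, com$tables$samples$sample_id)
  share <- colSums(ab[intersect(lys, viral), , drop = FALSE]) /
    colSums(ab[viral, , drop = FALSE])
  m_dis <- mean(share[cond[names(share)] == "disinfected"])
  m_non <- mean(share[cond[names(share)] == "non_disinfected"])
  expect_gt(m_dis, m_non)
  expect_equal(m_dis, 0.3, tolerance = 0.35)
  expect_equal(m_non, 0.1, tolerance = 0.35)
})
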