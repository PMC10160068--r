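mk_ann <- function(ids, family, subtype = NA_character_) {
  data.frame(contig_id = ids, family = family,
             subtype = rep_len(subtype, length(ids)),
             carrier_category = rep_len("prokaryotic", length(ids)),
             stringsAsFactors = FALSE)
}

test_that("carrier fraction is the TPM share of distinct carrier contigs", {
  ab <- c(c1 = 8800, c2 = 491200, c3 = 500000)
  expect_equal(carrier_fraction(mk_ann("c1", "RM"), ab, names(ab)), 0.0088)
  # every contig annotated -> 1
  expect_equal(carrier_fraction(mk_ann(names(ab), "RM"), ab, names(ab)), 1)
  # a contig with 3 annotations counts its TPM once
  tri <- rbind(mk_ann("c1", "RM"), mk_ann("c1", "BREX"), mk_ann("c1", "Abi"))
  expect_equal(carrier_fraction(tri, ab, names(ab)), 0.0088)
  # monotone non-decreasing under adding annotations
  expect_gte(carrier_fraction(rbind(tri, mk_ann("c2", "RM")), ab, names(ab)),
             carrier_fraction(tri, ab, names(ab)))
  expect_error(carrier_fraction(tri, ab, character(0)), "empty universe")
})

test_that("family profiles normalize to proportions that sum to one", {
  ab <- matrix(c(510, 150, 340, 999000), ncol = 1,
               dimnames = list(c("r", "c", "o", "bg"), "s1"))
  ann <- rbind(mk_ann("r", "RM"), mk_ann("c", "CRISPR-Cas"), mk_ann("o", "Abi"))
  prof <- profile_families(ann, ab)
  expect_equal(prof$proportion[prof$family == "RM"], 0.51)
  expect_equal(prof$proportion[prof$family == "CRISPR-Cas"], 0.15)
  expect_equal(prof$proportion[prof$family == "Abi"], 0.34)
  expect_equal(sum(prof$proportion), 1, tolerance = 1e-9)
  # ordering is TPM-descending
  expect_equal(prof$family, c("RM", "Abi", "CRISPR-Cas"))

  one <- profile_families(mk_ann("r", "RM"), ab)
  expect_equal(one$proportion, 1)

  expect_message(zero <- profile_families(mk_ann(character(0), character(0)), ab),
                 "no annotations")
  expect_equal(nrow(zero), 0L)
})

test_that("subtype shares normalize within a family", {
  ab <- c(g1 = 30, g2 = 30, g3 = 14, g4 = 11, g5 = 15, bg = 999900)
  ann <- mk_ann(paste0("g", 1:5), "RM",
                c("Type_IIG", "Type_II", "Type_I", "Type_III", "Type_IV"))
  sh <- subtype_shares(ann, ab, "RM")
  expect_equal(unname(sh["Type_IIG"]), 0.30)
  expect_equal(unname(sh["Type_II"]), 0.30)
  expect_equal(unname(sh["Type_I"]), 0.14)
  expect_equal(unname(sh["Type_III"]), 0.11)
  expect_equal(unname(sh["Type_IV"]), 0.15)
  expect_equal(sum(sh), 1, tolerance = 1e-9)

  all_iig <- subtype_shares(mk_ann("g1", "RM", "Type_IIG"), ab, "RM")
  expect_equal(unname(all_iig), 1)

  # missing subtype mass is reported under "unknown"
  sh2 <- subtype_shares(rbind(ann[1, ], mk_ann("g2", "RM")), ab, "RM")
  expect_true("unknown" %in% names(sh2))
  expect_equal(sum(sh2), 1)

  expect_error(subtype_shares(ann, ab, "NotAFamily"), "unknown defense family")
  expect_warning(
    empty <- subtype_shares(ann, ab, "BREX", vocabulary = c("RM", "BREX")),
    "absent")
  expect_equal(length(empty), 0L)
})

test_that("restricted profile equals the full profile under an always-true predicate", {
  com <- generate_community(small_config(
    seed = 13L,
    defense_rate_by_condition = c(disinfected = 0.6, non_disinfected = 0.5)))
  aln <- simulate_alignments(com, seed = 2L)
  ab <- suppressMessages(abundance_table(
    aln, stats::setNames(com$contigs$length, com$contigs$contig_id)))
  ann <- com$tables$defense[com$tables$defense$carrier_category == "prokaryotic", ]
  expect_gt(nrow(ann), 0)
  full <- profile_families(ann, ab)
  always <- restricted_profile(ann, ab, unique(ann$contig_id))
  expect_equal(always, full)

  # predicate as a logical vector must cover all annotated contigs
  flag <- stats::setNames(rep(TRUE, length(unique(ann$contig_id))),
                          unique(ann$contig_id))
  expect_equal(restricted_profile(ann, ab, flag), full)
  bad <- flag[-1]
  expect_error(restricted_profile(ann, ab, bad), "undecidable")

  # restriction satisfied by nothing -> zero profile, flagged
  expect_message(none <- restricted_profile(ann, ab, character(0)), "no annotations")
  expect_equal(nrow(none), 0L)
})

test_that("lysogen-restricted and lifestyle-split profiles partition defense TPM", {
  ab <- matrix(c(400, 300, 300, 999000), ncol = 1,
               dimnames = list(c("ly1", "ly2", "lt1", "bg"), "s1"))
  ann <- rbind(mk_ann("ly1", "RM"), mk_ann("ly2", "BREX"), mk_ann("lt1", "RM"))
  lys <- restricted_profile(ann, ab, c("ly1", "ly2"))
  lyt <- restricted_profile(ann, ab, "lt1")
  tot_lys <- sum(lys$tpm)
  tot_lyt <- sum(lyt$tpm)
  expect_equal(tot_lys / (tot_lys + tot_lyt), 0.7)
  expect_equal(tot_lyt / (tot_lys + tot_lyt), 0.3)
})
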