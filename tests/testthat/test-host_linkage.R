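mk_spacers <- function(spacer, contig = "p1") {
  data.frame(contig_id = contig, spacer_index = seq_along(spacer) - 1L,
             spacer = spacer, duplicate = FALSE, stringsAsFactors = FALSE)
}

test_that("spacer matching finds protospacers on either strand, exact only", {
  withr::local_seed(51)
  v <- rand_seq(1500)
  viral <- contig_table("v1", v, category = "free_viral")
  sp_fwd <- substr(v, 101, 132)
  sp_rev <- revcomp(substr(v, 501, 532))
  sp_absent <- rand_seq(32)

  links <- match_spacers(mk_spacers(c(sp_fwd, sp_rev, sp_absent)), viral)
  expect_equal(nrow(links), 1L)  # deduplicated on (phage, host, channel)
  expect_equal(links$phage_id, "v1")
  expect_equal(links$host_contig_id, "p1")
  expect_equal(links$channel, "crispr")

  # strands produce links independently
  expect_equal(nrow(match_spacers(mk_spacers(sp_rev), viral)), 1L)
  expect_equal(nrow(match_spacers(mk_spacers(sp_absent), viral)), 0L)

  # one mismatch blocks a match at max_mismatch = 0 but not at 1
  sp_mm <- sp_fwd
  substr(sp_mm, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(sp_mm, 5, 5))[1]
  expect_equal(nrow(match_spacers(mk_spacers(sp_mm), viral)), 0L)
  expect_equal(nrow(match_spacers(mk_spacers(sp_mm), viral, max_mismatch = 1L)), 1L)

  # short spacers rejected with a warning
  expect_warning(out <- match_spacers(mk_spacers(substr(sp_fwd, 1, 17)), viral),
                 "< 18 bp")
  expect_equal(nrow(out), 0L)
})

test_that("spacer matcher equals the naive substring-scan oracle", {
  withr::local_seed(52)
  viral <- contig_table(sprintf("v%d", 1:6),
                        vapply(rep(1500, 6), rand_seq, character(1)),
                        category = "free_viral")
  sps <- list()
  for (i in 1:12) {
    host <- sprintf("p%d", sample(1:5, 1))
    if (runif(1) < 0.6) {
      vi <- sample(1:6, 1)
      at <- sample(1:1400, 1)
      s <- substr(viral$sequence[vi], at, at + 31)
      if (runif(1) < 0.5) s <- revcomp(s)
    } else {
      s <- rand_seq(32)
    }
    sps[[i]] <- data.frame(contig_id = host, spacer_index = 0L, spacer = s,
                           duplicate = FALSE, stringsAsFactors = FALSE)
  }
  spacers <- do.call(rbind, sps)
  got <- match_spacers(spacers, viral)
  want <- oracle_match_spacers(spacers, viral)
  key <- function(d) sort(unique(paste(d$phage_id, d$host_contig_id)))
  expect_equal(key(got), key(want))
})

test_that("tRNA links require full-length perfect matches on either strand", {
  withr::local_seed(53)
  t1 <- rand_seq(72)
  vt <- data.frame(contig_id = "v1", trna_id = "vt1", trna_seq = t1,
                   stringsAsFactors = FALSE)
  pt <- data.frame(contig_id = "p1", trna_id = "pt1", trna_seq = t1,
                   stringsAsFactors = FALSE)
  links <- match_trnas(vt, pt)
  expect_equal(nrow(links), 1L)
  expect_equal(links$channel, "trna")

  # reverse-complement counts as a perfect match
  pt_rc <- pt; pt_rc$trna_seq <- revcomp(t1)
  expect_equal(nrow(match_trnas(vt, pt_rc)), 1L)

  # a single mismatch breaks it
  pt_mm <- pt; pt_mm$trna_seq <- mutate_seq(t1, 1)
  expect_equal(nrow(match_trnas(vt, pt_mm)), 0L)

  expect_equal(nrow(match_trnas(vt[0, ], pt)), 0L)
  expect_warning(match_trnas(data.frame(contig_id = "v1", trna_id = "x",
                                        trna_seq = rand_seq(30)), pt),
                 "outside 60-120")
})

test_that("prophage localization links hosts and validates intervals", {
  tab <- data.frame(prophage_id = "pp1", host_contig_id = "p7",
                    start = 1000L, end = 36000L, stringsAsFactors = FALSE)
  links <- link_prophages(tab, c(p7 = 40000))
  expect_equal(links$phage_id, "pp1")
  expect_equal(links$host_contig_id, "p7")
  expect_equal(links$channel, "prophage")
  expect_error(link_prophages(tab, c(p7 = 30000)), "out of bounds")
  expect_equal(nrow(link_prophages(tab[0, ], c(p7 = 1))), 0L)
})

test_that("merging keeps channel-distinct rows and counts multi-channel phages", {
  l1 <- data.frame(phage_id = "v1", host_contig_id = "p1", channel = "crispr",
                   detail = "", stringsAsFactors = FALSE)
  l2 <- data.frame(phage_id = "v1", host_contig_id = "p1", channel = "trna",
                   detail = "", stringsAsFactors = FALSE)
  m <- merge_links(l1, l2, l1, host_genus = c(p1 = "Polaromonas"))
  expect_equal(nrow(m$links), 2L)  # duplicate crispr row collapsed
  expect_equal(m$multi_channel_phages, "v1")
  expect_equal(m$links$genus, rep("Polaromonas", 2))

  e <- merge_links(host_genus = c(p1 = "G"))
  expect_equal(nrow(e$links), 0L)
  expect_equal(length(e$multi_channel_phages), 0L)
})

test_that("channel counts are additive over a large synthetic link table", {
  # counts shaped like an in-situ three-channel survey: 1837 tRNA links,
  # 71 CRISPR links, 289 prophage links -> 2197 rows in total
  mk <- function(n, channel, off) {
    data.frame(phage_id = sprintf("v%04d", off + seq_len(n)),
               host_contig_id = sprintf("h%04d", seq_len(n)),
               channel = channel, detail = "", stringsAsFactors = FALSE)
  }
  m <- merge_links(mk(1837, "trna", 0), mk(71, "crispr", 2000),
                   mk(289, "prophage", 3000))
  expect_equal(nrow(m$links), 2197L)
  expect_equal(unname(m$channel_counts[c("trna", "crispr", "prophage")]),
               c(1837L, 71L, 289L))
})

test_that("polyvalent classification counts distinct genera", {
  links <- data.frame(
    phage_id = c("v1", "v1", "v2", "v2", "v3"),
    host_contig_id = c("h1", "h2", "h3", "h4", "h5"),
    channel = "crispr", detail = "",
    genus = c("A", "B", "A", "A", NA), stringsAsFactors = FALSE)
  res <- classify_polyvalent(links)
  expect_equal(res$summary$polyvalent[res$summary$phage_id == "v1"], TRUE)
  expect_equal(res$summary$polyvalent[res$summary$phage_id == "v2"], FALSE)
  expect_false("v3" %in% res$summary$phage_id)  # genus-less links excluded
  expect_equal(res$fraction_count, 0.5)

  # duplicating a link row changes nothing
  res2 <- classify_polyvalent(rbind(links, links[1, ]))
  expect_equal(res2$fraction_count, res$fraction_count)

  # abundance basis weighs phages by TPM
  res3 <- classify_polyvalent(links, abundance = c(v1 = 900, v2 = 100))
  expect_equal(res3$fraction_abundance, 0.9)

  none <- classify_polyvalent(links[0, ])
  expect_true(is.na(none$fraction_count))
})

test_that("host population summary reports the three per-genus shares", {
  links <- data.frame(
    phage_id = sprintf("v%d", 1:7),
    host_contig_id = c("h1", "h1", "h2", "h3", "h3", "h3", "h4"),
    channel = c("prophage", "crispr", "trna", "prophage", "trna", "trna", "trna"),
    detail = "", genus = c("A", "A", "A", "B", "B", "B", "B"),
    stringsAsFactors = FALSE)
  ab <- c(h1 = 3000, h2 = 1000, h3 = 5000, h4 = 1000, h5 = 90000)
  cg <- c(h1 = "A", h2 = "A", h3 = "B", h4 = "B", h5 = "C")
  out <- host_population_summary(links, ab, cg, top_k = 2)
  a <- out[out$genus == "A", ]
  b <- out[out$genus == "B", ]
  expect_equal(a$host_tpm, 4000)
  expect_equal(b$host_tpm, 6000)
  expect_equal(a$share_hosts, 0.4)
  expect_equal(b$share_hosts, 0.6)
  expect_equal(a$share_community, 4000 / 100000)
  # 1 of 3 genus-A links and 1 of 4 genus-B links came via prophage channel
  expect_equal(a$prophage_link_share, 1 / 3)
  expect_equal(b$prophage_link_share, 1 / 4)
  # top-2 host genera are A,B; top-2 community genera are C plus one of A/B
  expect_equal(sum(out$matched), 1L)

  single <- host_population_summary(links[links$genus == "A", ],
                                    ab[c("h1", "h2")], cg[c("h1", "h2")])
  expect_equal(single$share_hosts, 1)
  expect_equal(single$share_community, 1)
  expect_error(host_population_summary(links, ab, cg, top_k = 0), "top_k")
})
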