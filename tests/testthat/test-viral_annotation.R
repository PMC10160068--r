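mk_hits <- function(lineages, evalue = 1e-10) {
  if (!length(lineages)) {
    return(data.frame(contig_id = character(0), gene_index = integer(0),
                      lineage = character(0), evalue = numeric(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(contig_id = "v", gene_index = seq_along(lineages) - 1L,
             lineage = lineages, evalue = evalue, stringsAsFactors = FALSE)
}

test_that("voting rule boundaries: 20% hit fraction and 60% consensus are eligible", {
  # 10 genes, 2 hits of the same family: exactly at both boundaries
  res <- assign_contig_taxonomy(mk_hits(rep("order=O1;family=F1", 2)), n_genes = 10)
  expect_equal(res$rank_assigned, "family")
  expect_equal(res$assigned_lineage, "order=O1;family=F1")
  expect_equal(res$hit_fraction, 0.2)
  expect_equal(res$consensus_fraction, 1)

  # 0 hits -> unassigned
  expect_true(is.na(assign_contig_taxonomy(mk_hits(character(0)), 10)$assigned_lineage))

  # 12 genes, 3 hits (25%), consensus 2/3 >= 0.6 -> majority family wins
  res <- assign_contig_taxonomy(
    mk_hits(c("order=O1;family=A", "order=O1;family=A", "order=O1;family=B")), 12)
  expect_equal(res$assigned_lineage, "order=O1;family=A")
  expect_equal(res$consensus_fraction, 2 / 3)

  # consensus exactly 3/5 = 0.6 qualifies ("at least")
  res <- assign_contig_taxonomy(
    mk_hits(c(rep("order=O1;family=A", 3), rep("order=O1;family=B", 2))), 20)
  expect_equal(res$assigned_lineage, "order=O1;family=A")

  # short contig (<10 genes), 2 hits to different families sharing an order:
  # assignment falls back to the order rank
  res <- assign_contig_taxonomy(
    mk_hits(c("order=O1;family=A", "order=O1;family=B")), 8)
  expect_equal(res$rank_assigned, "order")
  expect_equal(res$assigned_lineage, "order=O1")
  expect_equal(res$consensus_fraction, 1)

  # 19% hit fraction on a long contig is not eligible
  res <- assign_contig_taxonomy(mk_hits(rep("order=O1;family=A", 19)), 100)
  expect_true(is.na(res$assigned_lineage))

  expect_error(assign_contig_taxonomy(mk_hits("order=O1;family=A"), 0), "n_genes")
})

test_that("vote matches exhaustive rule enumeration over all small hit tables", {
  # taxa: t1=(O1,F1) t2=(O1,F2) t3=(O2,F3); genes are exchangeable, so
  # enumerate hit-count compositions (n_none, n1, n2, n3) for every n_genes
  lins <- c("order=O1;family=F1", "order=O1;family=F2", "order=O2;family=F3")
  n_checked <- 0
  for (n_genes in 1:6) {
    comps <- expand.grid(n1 = 0:n_genes, n2 = 0:n_genes, n3 = 0:n_genes)
    comps <- comps[rowSums(comps) <= n_genes, , drop = FALSE]
    for (i in seq_len(nrow(comps))) {
      lineages <- rep(lins, times = unlist(comps[i, ]))
      hits <- mk_hits(lineages)
      got <- assign_contig_taxonomy(hits, n_genes)
      want <- oracle_taxonomy(hits, n_genes)
      label <- if (is.na(got$assigned_lineage)) NA_character_ else
        paste0(got$rank_assigned, "=",
               sub("^.*=", "", got$assigned_lineage))
      expect_equal(label, want,
                   info = sprintf("n_genes=%d comp=%s", n_genes,
                                  paste(comps[i, ], collapse = ",")))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 200)
})

test_that("adding a hit agreeing with the assignment never removes it", {
  withr::local_seed(31)
  lins <- c("order=O1;family=F1", "order=O1;family=F2", "order=O2;family=F3")
  for (rep_i in 1:50) {
    n_genes <- sample(3:12, 1)
    n_hits <- sample(0:n_genes, 1)
    hits <- mk_hits(sample(lins, n_hits, replace = TRUE))
    res <- assign_contig_taxonomy(hits, n_genes)
    if (is.na(res$assigned_lineage) || n_hits == n_genes) next
    agree <- mk_hits(c(hits$lineage, res$assigned_lineage))
    res2 <- assign_contig_taxonomy(agree, n_genes)
    expect_false(is.na(res2$assigned_lineage))
    expect_equal(res2$assigned_lineage, res$assigned_lineage)
  }
})

test_that("only the lowest-evalue hit per gene votes", {
  hits <- data.frame(contig_id = "v", gene_index = c(0L, 0L, 1L),
                     lineage = c("order=O1;family=A", "order=O1;family=B",
                                 "order=O1;family=A"),
                     evalue = c(1e-20, 1e-8, 1e-12), stringsAsFactors = FALSE)
  res <- assign_contig_taxonomy(hits, 8)
  expect_equal(res$assigned_lineage, "order=O1;family=A")
  expect_equal(res$consensus_fraction, 1)  # 2 genes, both vote A
})

test_that("lifestyle labels attach, prophages are forced lysogenic", {
  ct <- contig_table(c("p1", "v1", "v2", "pp1"), rep("ACGT", 4),
                     category = c("prokaryotic", "free_viral", "free_viral", "prophage"))
  out <- attach_lifestyles(ct, c(v1 = "lysogenic"))
  expect_equal(out$lifestyle, c(NA, "lysogenic", "unknown", "lysogenic"))
  expect_warning(out2 <- attach_lifestyles(ct, c(pp1 = "lytic")), "forced to lysogenic")
  expect_equal(out2$lifestyle[out2$contig_id == "pp1"], "lysogenic")
  expect_warning(attach_lifestyles(ct, c(p1 = "lytic")), "non-viral")
})
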