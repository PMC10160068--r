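#' Taxonomy voting parameters
#'
#' A contig is eligible for assignment when at least `min_hit_fraction` of
#' its genes have a database hit, or — for contigs with fewer than
#' `short_gene_count` genes — when at least `min_hits_short` genes have hits.
#' An eligible contig is assigned at the deepest rank where a single taxon is
#' shared by at least `min_consensus` of the hit genes. Both boundaries are
#' inclusive ("at least").
#'
#' @param min_hit_fraction default 0.2.
#' @param min_hits_short default 2.
#' @param short_gene_count default 10.
#' @param min_consensus default 0.6.
#' @return validated parameter list.
#' @export
taxonomy_params <- function(min_hit_fraction = 0.2, min_hits_short = 2L,
                            short_gene_count = 10L, min_consensus = 0.6) {
  stopifnot(min_hit_fraction > 0, min_hit_fraction <= 1,
            min_hits_short >= 1, short_gene_count >= 1,
            min_consensus > 0, min_consensus <= 1)
  list(min_hit_fraction = min_hit_fraction, min_hits_short = as.integer(min_hits_short),
       short_gene_count = as.integer(short_gene_count), min_consensus = min_consensus)
}

# Parse "rank=taxon;rank=taxon" (least -> most specific) into a two-column
# matrix (rank, taxon).
parse_lineage <- function(lineage) {
  if (is.na(lineage) || !nzchar(lineage)) {
    return(matrix(character(0), ncol = 2, dimnames = list(NULL, c("rank", "taxon"))))
  }
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  kv <- do.call(rbind, strsplit(parts, "=", fixed = TRUE))
  colnames(kv) <- c("rank", "taxon")
  kv
}

join_lineage <- function(mat) {
  if (!nrow(mat)) return(NA_character_)
  paste(paste(mat[, "rank"], mat[, "taxon"], sep = "="), collapse = ";")
}

#' Assign contig-level viral taxonomy by two-criterion majority vote
#'
#' Gene hits are first reduced to the single lowest-evalue hit per gene
#' (the rule counts genes, not hits). Eligibility: `hits/n_genes >= 0.2`, or
#' `n_genes < 10` with at least 2 hit genes. If eligible, ranks are walked
#' from most specific to least and the contig is assigned at the deepest
#' rank where one taxon is shared by >= 60% of the hit genes (denominator =
#' genes with any hit). Otherwise the contig stays unassigned.
#'
#' @param hits data.frame for one contig: gene_index, lineage, evalue.
#' @param n_genes total gene count of the contig (> 0).
#' @param params see [taxonomy_params()].
#' @param max_evalue hits above this are dropped (default 1e-5).
#' @return list: contig eligibility/assignment with fields `assigned_lineage`
#'   (NA if unassigned), `rank_assigned`, `hit_fraction`,
#'   `consensus_fraction`.
#' @export
assign_contig_taxonomy <- function(hits, n_genes, params = taxonomy_params(),
                                   max_evalue = 1e-5) {
  if (n_genes <= 0) abort_validation("n_genes must be > 0")
  unassigned <- list(assigned_lineage = NA_character_, rank_assigned = NA_character_,
                     hit_fraction = 0, consensus_fraction = NA_real_)
  if (is.null(hits) || !nrow(hits)) return(unassigned)
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (!nrow(hits)) return(unassigned)
  # one best hit per gene
  hits <- hits[order(hits$gene_index, hits$evalue), , drop = FALSE]
  hits <- hits[!duplicated(hits$gene_index), , drop = FALSE]
  n_hits <- nrow(hits)
  hit_fraction <- n_hits / n_genes
  unassigned$hit_fraction <- hit_fraction
  eligible <- hit_fraction >= params$min_hit_fraction ||
    (n_genes < params$short_gene_count && n_hits >= params$min_hits_short)
  if (!eligible) return(unassigned)
  lineages <- lapply(hits$lineage, parse_lineage)
  ranks <- unique(unlist(lapply(lineages, function(m) m[, "rank"])))
  if (!length(ranks)) return(unassigned)
  # ranks appear least -> most specific within each lineage; walk deepest first
  for (rk in rev(ranks)) {
    taxa <- vapply(lineages, function(m) {
      hit <- m[m[, "rank"] == rk, "taxon"]
      if (length(hit)) hit[[1]] else NA_character_
    }, character(1))
    tab <- table(taxa[!is.na(taxa)])
    if (!length(tab)) next
    best <- names(tab)[which.max(tab)]
    consensus <- max(tab) / n_hits
    if (consensus >= params$min_consensus) {
      # truncate the winning lineage at the assigned rank
      win <- lineages[[which(!is.na(taxa) & taxa == best)[1]]]
      cut <- which(win[, "rank"] == rk)
      return(list(assigned_lineage = join_lineage(win[seq_len(cut), , drop = FALSE]),
                  rank_assigned = rk, hit_fraction = hit_fraction,
                  consensus_fraction = as.numeric(consensus)))
    }
  }
  unassigned
}

#' Assign taxonomy for a whole gene-hit table
#'
#' @param hits data.frame: contig_id, gene_index, lineage, evalue.
#' @param gene_counts named vector contig_id -> total gene count.
#' @param params see [taxonomy_params()].
#' @return data.frame, one row per contig in `gene_counts`.
#' @export
assign_taxonomy <- function(hits, gene_counts, params = taxonomy_params()) {
  rows <- lapply(names(gene_counts), function(cid) {
    h <- hits[hits$contig_id == cid, , drop = FALSE]
    res <- assign_contig_taxonomy(h, gene_counts[[cid]], params)
    data.frame(contig_id = cid, assigned_lineage = res$assigned_lineage,
               rank_assigned = res$rank_assigned, hit_fraction = res$hit_fraction,
               consensus_fraction = res$consensus_fraction, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Attach lifestyle labels to viral contigs
#'
#' Labels (lytic / lysogenic) are consumed from an upstream classifier table.
#' Unlabeled viral contigs are marked `unknown`; prophage-category contigs
#' are forced to `lysogenic` (with a note) since they are by construction
#' integrated. Labels for non-viral contigs are ignored with a warning.
#'
#' @param contigs a `contig_table`.
#' @param labels named character vector phage_id -> "lytic"/"lysogenic".
#' @return the contig table with a `lifestyle` column.
#' @export
attach_lifestyles <- function(contigs, labels) {
  viral <- contigs$category %in% c("free_viral", "prophage")
  stray <- setdiff(names(labels), contigs$contig_id[viral])
  if (length(stray)) {
    warning(sprintf("lifestyle labels for non-viral contig(s) ignored: %s",
                    paste(utils::head(stray, 5), collapse = ", ")), call. = FALSE)
    labels <- labels[setdiff(names(labels), stray)]
  }
  lifestyle <- rep(NA_character_, nrow(contigs))
  lifestyle[viral] <- "unknown"
  idx <- match(names(labels), contigs$contig_id)
  lifestyle[idx] <- unname(labels)
  forced <- which(contigs$category == "prophage" & !is.na(lifestyle) & lifestyle == "lytic")
  if (length(forced)) {
    warning(sprintf("attach_lifestyles: %d prophage contig(s) labelled lytic forced to lysogenic",
                    length(forced)), call. = FALSE)
  }
  lifestyle[contigs$category == "prophage"] <- "lysogenic"
  contigs$lifestyle <- lifestyle
  contigs
}
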