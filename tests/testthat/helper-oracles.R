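# Independent oracle implementations used to cross-check the package's
# algorithms on small inputs. These deliberately use different code paths
# (naive scans, exhaustive enumeration) from the implementations they check.

# Naive substring scan for protospacer matching: loop over spacers, contigs
# and strands with fixed-string grepl.
oracle_match_spacers <- function(spacers, viral_contigs) {
  out <- list()
  for (i in seq_len(nrow(spacers))) {
    sp <- spacers$spacer[i]
    if (nchar(sp) < 18 || grepl("N", sp, fixed = TRUE)) next
    rc <- revcomp(sp)
    for (j in seq_len(nrow(viral_contigs))) {
      vs <- viral_contigs$sequence[j]
      if (grepl(sp, vs, fixed = TRUE) || grepl(rc, vs, fixed = TRUE)) {
        out[[length(out) + 1L]] <- data.frame(
          phage_id = viral_contigs$contig_id[j],
          host_contig_id = spacers$contig_id[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(phage_id = character(0), host_contig_id = character(0)))
  }
  unique(do.call(rbind, out))
}

# Brute-force application of the two-criterion taxonomy vote.
oracle_taxonomy <- function(hits, n_genes, params = taxonomy_params()) {
  if (is.null(hits) || !nrow(hits)) return(NA_character_)
  hits <- hits[hits$evalue <= 1e-5, , drop = FALSE]
  hits <- hits[order(hits$gene_index, hits$evalue), , drop = FALSE]
  hits <- hits[!duplicated(hits$gene_index), , drop = FALSE]
  n_hits <- nrow(hits)
  if (n_hits == 0) return(NA_character_)
  eligible <- (n_hits / n_genes) >= params$min_hit_fraction ||
    (n_genes < params$short_gene_count && n_hits >= params$min_hits_short)
  if (!eligible) return(NA_character_)
  split_lin <- strsplit(hits$lineage, ";", fixed = TRUE)
  rank_of <- function(entry) sub("=.*$", "", entry)
  taxon_of <- function(entry) sub("^.*=", "", entry)
  all_ranks <- unique(unlist(lapply(split_lin, rank_of)))
  for (rk in rev(all_ranks)) {
    taxa <- vapply(split_lin, function(lin) {
      m <- lin[rank_of(lin) == rk]
      if (length(m)) taxon_of(m[1]) else NA_character_
    }, character(1))
    counts <- table(taxa[!is.na(taxa)])
    if (!length(counts)) next
    if (max(counts) / n_hits >= params$min_consensus) {
      return(paste0(rk, "=", names(counts)[which.max(counts)]))
    }
  }
  NA_character_
}

# Exhaustive chain enumeration for CRISPR arrays: every (repeat length,
# start) pair is considered as a chain start; chains extend greedily over
# all exact occurrences; the same longest-repeat-first greedy selection is
# then applied. Suitable for contigs up to a few kb.
oracle_detect_crispr <- function(seq, params = crispr_params()) {
  n <- nchar(seq)
  cands <- list()
  for (L in params$repeat_len_range[2]:params$repeat_len_range[1]) {
    if (n < L) next
    subs <- substring(seq, 1:(n - L + 1), L:n)
    for (p in seq_along(subs)) {
      word <- subs[p]
      occ <- which(subs == word)
      if (length(occ) < params$min_repeats) next
      gap_in <- (p - (occ + L)) >= params$spacer_len_range[1] &
        (p - (occ + L)) <= params$spacer_len_range[2]
      if (any(gap_in)) next  # a chain continues into p; not a maximal start
      chain <- p
      last <- p
      repeat {
        gaps <- occ - (last + L)
        nxt <- occ[gaps >= params$spacer_len_range[1] & gaps <= params$spacer_len_range[2]]
        if (!length(nxt)) break
        last <- nxt[1]
        chain <- c(chain, last)
      }
      if (length(chain) >= params$min_repeats) {
        cands[[length(cands) + 1L]] <- list(word = word, chain = chain - 1L, L = L)
      }
    }
  }
  if (!length(cands)) {
    return(data.frame(repeat_seq = character(0), spacers = character(0),
                      n_spacers = integer(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  ord <- order(-vapply(cands, function(x) x$L, numeric(1)),
               vapply(cands, function(x) x$chain[1], numeric(1)))
  cands <- cands[ord]
  occupied <- logical(n)
  out <- list()
  for (cd in cands) {
    a_start <- cd$chain[1]
    a_end <- cd$chain[length(cd$chain)] + cd$L
    if (any(occupied[(a_start + 1):a_end])) next
    spacers <- substring(seq, head(cd$chain, -1) + cd$L + 1, cd$chain[-1])
    out[[length(out) + 1L]] <- data.frame(
      repeat_seq = cd$word, spacers = paste(spacers, collapse = ","),
      n_spacers = length(spacers), start = a_start, end = a_end,
      stringsAsFactors = FALSE)
    occupied[(a_start + 1):a_end] <- TRUE
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

# Greedy dereplication using unconditional all-pairs alignment (no k-mer
# prefilter). Returns the cluster map.
oracle_dereplicate <- function(contigs, params = derep_params()) {
  ord <- order(-contigs$length, contigs$contig_id)
  contigs <- contigs[ord, , drop = FALSE]
  reps <- integer(0)
  assign <- character(nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    placed <- FALSE
    for (r in reps) {
      pid <- pairwise_identity(contigs$sequence[i], contigs$sequence[r], params)
      if (pid[["identity"]] >= params$min_identity &&
          pid[["short_coverage"]] >= params$min_short_coverage) {
        assign[i] <- contigs$contig_id[r]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- contigs$contig_id[i]
    }
  }
  stats::setNames(assign, contigs$contig_id)
}

# Mantel p-value by direct enumeration over all label permutations of D2.
oracle_mantel_exhaustive <- function(D1, D2, method = "spearman") {
  n <- nrow(D1)
  v1 <- D1[upper.tri(D1)]
  perms <- do.call(rbind, combinat_perms(seq_len(n)))
  stats_all <- apply(perms, 1, function(p) {
    cor(v1, D2[p, p][upper.tri(D1)], method = method)
  })
  obs <- cor(v1, D2[upper.tri(D2)], method = method)
  sum(stats_all >= obs - 1e-12) / nrow(perms)
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Random DNA helper for fixtures.
rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                                collapse = "")

# Mutate a sequence at k positions (guaranteed substitutions).
mutate_seq <- function(seq, k) {
  pos <- sample.int(nchar(seq), k)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}
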