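#' Synthetic community configuration
#'
#' Parameters of the seeded synthetic drinking-water-like metagenome. The
#' defaults describe the study conditions the generator emulates: two sample
#' groups (disinfected / non-disinfected), genus-structured prokaryotic
#' contigs with lognormal rank-abundance skew, uniform-random viral contigs
#' of at least 1.5 kb (so 32-mer spacer collisions are vanishingly rare),
#' prophages embedded verbatim in host contigs, exact-repeat CRISPR arrays
#' whose spacers are copied from viral contigs, shared tRNA genes, and
#' condition effects realized on the abundance of defense carriers,
#' lysogenic phages and total viral load.
#'
#' @param n_genera number of prokaryotic genera.
#' @param contigs_per_genus prokaryotic contigs per genus.
#' @param contig_length_range prokaryotic contig length bounds (bp).
#' @param n_viral_contigs number of free viral contigs.
#' @param viral_length_range viral contig length bounds (bp, min >= 1500).
#' @param prophage_rate probability a viral contig is also embedded as a
#'   prophage in a host contig.
#' @param crispr_rate probability a prokaryotic contig carries an array.
#' @param spacers_per_array_range spacer count bounds per array (min >= 2).
#' @param spacer_source_rate probability a spacer is copied from a viral
#'   contig (vs random).
#' @param trna_share_rate probability a viral contig shares a tRNA with a
#'   host.
#' @param defense_rate_by_condition named probabilities (disinfected,
#'   non_disinfected) that a prokaryotic contig's abundance behaves as a
#'   defense carrier; carrier identity is drawn at the non-disinfected rate
#'   and the disinfected effect is applied to carrier abundance.
#' @param defense_family_weights named non-negative sampling weights.
#' @param lysogeny_rate_by_condition named expected lysogenic TPM share
#'   among viral contigs per condition.
#' @param viral_share_by_condition named expected viral TPM share of the
#'   whole community per condition.
#' @param base_lysogeny_rate probability a free viral contig is labelled
#'   lysogenic.
#' @param phage_defense_rate probability a viral contig carries a defense
#'   annotation.
#' @param taxonomy_annotation_rate fraction of viral contigs with gene hits
#'   supporting a taxonomy call.
#' @param n_samples_per_condition samples per condition.
#' @param reads_per_sample reads simulated per sample.
#' @param abundance_lognormal_sigma sdlog of the genus abundance lognormal.
#' @param short_read_rate fraction of simulated reads with aligned length
#'   below 30 bp (exercising the length filter).
#' @param repeat_length,spacer_length planted repeat/spacer lengths (bp).
#' @param trna_length planted tRNA length (bp).
#' @param seed master seed; per-stage child seeds are derived from it.
#' @return validated config list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genera = 8L,
                             contigs_per_genus = 5L,
                             contig_length_range = c(3000L, 8000L),
                             n_viral_contigs = 30L,
                             viral_length_range = c(1500L, 4000L),
                             prophage_rate = 0.3,
                             crispr_rate = 0.4,
                             spacers_per_array_range = c(2L, 6L),
                             spacer_source_rate = 0.8,
                             trna_share_rate = 0.2,
                             defense_rate_by_condition = c(disinfected = 0.25,
                                                           non_disinfected = 0.10),
                             defense_family_weights = c(RM = 0.45, "CRISPR-Cas" = 0.20,
                                                        BREX = 0.12, Abi = 0.12,
                                                        CBASS = 0.11),
                             lysogeny_rate_by_condition = c(disinfected = 0.3,
                                                            non_disinfected = 0.1),
                             viral_share_by_condition = c(disinfected = 0.014,
                                                          non_disinfected = 0.003),
                             base_lysogeny_rate = 0.4,
                             phage_defense_rate = 0.08,
                             taxonomy_annotation_rate = 0.6,
                             n_samples_per_condition = 6L,
                             reads_per_sample = 20000L,
                             abundance_lognormal_sigma = 1,
                             short_read_rate = 0.1,
                             repeat_length = 28L,
                             spacer_length = 32L,
                             trna_length = 72L,
                             seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(prophage_rate, crispr_rate, spacer_source_rate, trna_share_rate,
             defense_rate_by_condition, lysogeny_rate_by_condition,
             viral_share_by_condition, base_lysogeny_rate, phage_defense_rate,
             taxonomy_annotation_rate, short_read_rate)
  if (any(probs < 0 | probs > 1)) abort_validation("all probabilities must be in [0,1]")
  for (nm in c("defense_rate_by_condition", "lysogeny_rate_by_condition",
               "viral_share_by_condition")) {
    if (!all(c("disinfected", "non_disinfected") %in% names(cfg[[nm]]))) {
      abort_validation("%s must name both conditions", nm)
    }
  }
  if (contig_length_range[1] >= contig_length_range[2] ||
      viral_length_range[1] >= viral_length_range[2] ||
      spacers_per_array_range[1] > spacers_per_array_range[2]) {
    abort_validation("ranges must be non-degenerate")
  }
  if (spacers_per_array_range[1] < 2) {
    abort_validation("spacers_per_array_range minimum must be >= 2")
  }
  if (viral_length_range[1] < 1500) abort_validation("viral contigs must be >= 1500 bp")
  if (any(defense_family_weights < 0) || sum(defense_family_weights) == 0) {
    abort_validation("defense_family_weights must be non-negative, not all zero")
  }
  if (n_genera < 1 || contigs_per_genus < 1 || n_viral_contigs < 1 ||
      n_samples_per_condition < 1) {
    abort_validation("counts must be >= 1")
  }
  if (reads_per_sample <= 0) abort_validation("reads_per_sample must be > 0")
  class(cfg) <- "synthetic_config"
  cfg
}

# Draw a spacer; constrained spacers must differ from `other` in first and
# last character so the planted repeat chain cannot be extended by one base.
draw_spacer <- function(len, viral_seqs, source_rate, other = NULL) {
  for (try in 1:200) {
    if (length(viral_seqs) && runif(1) < source_rate) {
      vid <- sample(names(viral_seqs), 1)
      vlen <- nchar(viral_seqs[[vid]])
      pos <- sample.int(vlen - len + 1, 1)
      sp <- substr(viral_seqs[[vid]], pos, pos + len - 1)
      if (runif(1) < 0.5) sp <- revcomp(sp)
      src <- vid
    } else {
      sp <- random_dna(len)
      src <- NA_character_
    }
    ok <- is.null(other) ||
      (substr(sp, 1, 1) != substr(other, 1, 1) &&
         substr(sp, len, len) != substr(other, len, len))
    if (ok) return(list(spacer = sp, source = src))
  }
  abort_validation("could not draw a chain-terminal spacer (pathological config)")
}

#' Generate a synthetic metagenomic community with planted ground truth
#'
#' Deterministic given `config$seed`. Returns the contig table, every
#' feature table the pipeline consumes (prophage coordinates, tRNA genes,
#' defense annotations, lifestyle labels, viral gene hits, sample metadata)
#' and the planted ground truth (host links per channel, CRISPR arrays,
#' lifestyles, expected per-sample relative abundance).
#'
#' @param config a [synthetic_config()].
#' @return list with elements `contigs`, `tables` and `truth`.
#' @export
generate_community <- function(config) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  n_prok <- config$n_genera * config$contigs_per_genus

  ## prokaryotic and viral base sequences
  base <- withr::with_seed(child_seed(config$seed, "contigs"), {
    genera <- sprintf("Genus_%02d", seq_len(config$n_genera))
    phyla <- sprintf("Phylum_%02d", ((seq_len(config$n_genera) - 1) %% 3) + 1)
    prok_genus <- rep(genera, each = config$contigs_per_genus)
    prok_phylum <- rep(phyla, each = config$contigs_per_genus)
    prok_len <- sample(config$contig_length_range[1]:config$contig_length_range[2],
                       n_prok, replace = TRUE)
    viral_len <- sample(config$viral_length_range[1]:config$viral_length_range[2],
                        config$n_viral_contigs, replace = TRUE)
    list(genera = genera,
         prok_ids = sprintf("prok_%03d", seq_len(n_prok)),
         prok_genus = prok_genus,
         prok_lineage = sprintf("domain=Bacteria;phylum=%s;genus=%s",
                                prok_phylum, prok_genus),
         prok_seq = random_dna(prok_len),
         viral_ids = sprintf("vir_%03d", seq_len(config$n_viral_contigs)),
         viral_seq = random_dna(viral_len))
  })
  prok_seq <- stats::setNames(base$prok_seq, base$prok_ids)
  viral_seq <- stats::setNames(base$viral_seq, base$viral_ids)

  ## lifestyles of free viral contigs
  lifestyles <- withr::with_seed(child_seed(config$seed, "lifestyles"), {
    stats::setNames(ifelse(runif(config$n_viral_contigs) < config$base_lysogeny_rate,
                           "lysogenic", "lytic"), base$viral_ids)
  })

  ## prophages: verbatim copies embedded in hosts; a prophage-category contig
  ## mirrors each embedded genome (CheckV-style provirus record)
  prophage <- withr::with_seed(child_seed(config$seed, "prophage"), {
    sel <- base$viral_ids[runif(config$n_viral_contigs) < config$prophage_rate]
    rows <- list()
    for (vid in sel) {
      hid <- sample(base$prok_ids, 1)
      vlen <- nchar(viral_seq[[vid]])
      hlen <- nchar(prok_seq[[hid]])
      # keep the insertion point outside earlier prophages on this host, and
      # shift their recorded intervals when inserting upstream of them
      prev <- which(vapply(rows, function(r) r$host_contig_id == hid, logical(1)))
      repeat {
        at <- sample.int(hlen + 1, 1) - 1L    # 0-based insertion point
        inside <- length(prev) && any(
          at > vapply(rows[prev], function(r) r$start, numeric(1)) &
            at < vapply(rows[prev], function(r) r$end, numeric(1)))
        if (!inside) break
      }
      prok_seq[[hid]] <- paste0(substr(prok_seq[[hid]], 1, at),
                                viral_seq[[vid]],
                                substr(prok_seq[[hid]], at + 1, hlen))
      for (p in prev) {
        if (rows[[p]]$start >= at) {
          rows[[p]]$start <- rows[[p]]$start + vlen
          rows[[p]]$end <- rows[[p]]$end + vlen
        }
      }
      rows[[vid]] <- data.frame(prophage_id = sub("^vir_", "pp_", vid),
                                source_viral_id = vid, host_contig_id = hid,
                                start = at, end = at + vlen,
                                stringsAsFactors = FALSE)
    }
    list(table = if (length(rows)) do.call(rbind, rows) else
      data.frame(prophage_id = character(0), source_viral_id = character(0),
                 host_contig_id = character(0), start = integer(0), end = integer(0),
                 stringsAsFactors = FALSE),
      prok_seq = prok_seq)
  })
  prok_seq <- prophage$prok_seq
  prophage_tab <- prophage$table
  rownames(prophage_tab) <- NULL

  ## CRISPR arrays planted after prophage insertion; prophage intervals are
  ## shifted when an array lands upstream of them
  crispr <- withr::with_seed(child_seed(config$seed, "crispr"), {
    arrays <- list()
    spacer_rows <- list()
    for (cid in base$prok_ids) {
      if (runif(1) >= config$crispr_rate) next
      k <- sample(config$spacers_per_array_range[1]:config$spacers_per_array_range[2], 1)
      rep_seq <- random_dna(config$repeat_length)
      # every consecutive spacer pair differs in first and last character, so
      # no sub-chain of repeat copies can be read with a longer repeat
      sps <- list(draw_spacer(config$spacer_length, viral_seq, config$spacer_source_rate))
      for (j in seq_len(k - 1)) {
        sps[[j + 1]] <- draw_spacer(config$spacer_length, viral_seq,
                                    config$spacer_source_rate, other = sps[[j]]$spacer)
      }
      arr_seq <- paste0(rep_seq,
                        paste(vapply(sps, function(s) paste0(s$spacer, rep_seq),
                                     character(1)), collapse = ""))
      hlen <- nchar(prok_seq[[cid]])
      pp_here <- which(prophage_tab$host_contig_id == cid)
      ok_at <- function(at) {
        !length(pp_here) ||
          all(at <= prophage_tab$start[pp_here] | at >= prophage_tab$end[pp_here])
      }
      repeat {
        at <- sample.int(hlen + 1, 1) - 1L
        if (ok_at(at)) break
      }
      prok_seq[[cid]] <- paste0(substr(prok_seq[[cid]], 1, at), arr_seq,
                                substr(prok_seq[[cid]], at + 1, hlen))
      shift <- pp_here[prophage_tab$start[pp_here] >= at]
      if (length(shift)) {
        prophage_tab$start[shift] <- prophage_tab$start[shift] + nchar(arr_seq)
        prophage_tab$end[shift] <- prophage_tab$end[shift] + nchar(arr_seq)
      }
      arrays[[cid]] <- data.frame(
        contig_id = cid, repeat_seq = rep_seq,
        spacers = paste(vapply(sps, function(s) s$spacer, character(1)), collapse = ","),
        n_spacers = k, start = at, end = at + nchar(arr_seq),
        stringsAsFactors = FALSE)
      for (j in seq_len(k)) {
        spacer_rows[[length(spacer_rows) + 1L]] <- data.frame(
          contig_id = cid, spacer = sps[[j]]$spacer, source = sps[[j]]$source,
          stringsAsFactors = FALSE)
      }
    }
    list(arrays = if (length(arrays)) do.call(rbind, arrays) else
      data.frame(contig_id = character(0), repeat_seq = character(0),
                 spacers = character(0), n_spacers = integer(0),
                 start = integer(0), end = integer(0), stringsAsFactors = FALSE),
      spacers = if (length(spacer_rows)) do.call(rbind, spacer_rows) else
        data.frame(contig_id = character(0), spacer = character(0),
                   source = character(0), stringsAsFactors = FALSE),
      prok_seq = prok_seq)
  })
  prok_seq <- crispr$prok_seq
  truth_arrays <- crispr$arrays
  rownames(truth_arrays) <- NULL

  ## shared tRNA genes (table-level features)
  trna <- withr::with_seed(child_seed(config$seed, "trna"), {
    rows <- list()
    for (vid in base$viral_ids) {
      if (runif(1) >= config$trna_share_rate) next
      hid <- sample(base$prok_ids, 1)
      seq <- random_dna(config$trna_length)
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = c(vid, hid),
        trna_id = paste0("trna_", vid, c("_v", "_h")),
        trna_seq = seq, stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(contig_id = character(0), trna_id = character(0),
                 trna_seq = character(0), stringsAsFactors = FALSE)
  })

  ## assemble the contig table (prophage contigs mirror their free genome)
  pp_ids <- prophage_tab$prophage_id
  contigs <- contig_table(
    contig_id = c(base$prok_ids, base$viral_ids, pp_ids),
    sequence = c(unname(prok_seq), unname(viral_seq),
                 unname(viral_seq[prophage_tab$source_viral_id])),
    category = c(rep("prokaryotic", n_prok),
                 rep("free_viral", config$n_viral_contigs),
                 rep("prophage", length(pp_ids))),
    genus = c(base$prok_genus, rep(NA_character_, config$n_viral_contigs + length(pp_ids))),
    lineage = c(base$prok_lineage,
                rep(NA_character_, config$n_viral_contigs + length(pp_ids))))
  all_viral_ids <- c(base$viral_ids, pp_ids)
  viral_seq_all <- stats::setNames(contigs$sequence[match(all_viral_ids, contigs$contig_id)],
                                   all_viral_ids)
  lifestyles_all <- c(lifestyles, stats::setNames(rep("lysogenic", length(pp_ids)), pp_ids))

  ## defense annotations (carriers at the base rate; condition effect is on
  ## carrier abundance, see draw_sample_abundance)
  fams <- names(config$defense_family_weights)
  rm_subtypes <- c(Type_I = 0.14, Type_II = 0.30, Type_IIG = 0.30,
                   Type_III = 0.11, Type_IV = 0.15)
  cas_subtypes <- c(Type_I = 0.40, Type_II = 0.40, Type_III = 0.10,
                    Type_IV = 0.05, Type_V = 0.05)
  defense <- withr::with_seed(child_seed(config$seed, "defense"), {
    rows <- list()
    annotate <- function(cid, category) {
      fam <- sample(fams, 1, prob = config$defense_family_weights)
      sub <- if (fam == "RM") sample(names(rm_subtypes), 1, prob = rm_subtypes)
        else if (fam == "CRISPR-Cas") sample(names(cas_subtypes), 1, prob = cas_subtypes)
        else NA_character_
      data.frame(contig_id = cid, family = fam, subtype = sub,
                 carrier_category = category, stringsAsFactors = FALSE)
    }
    base_rate <- config$defense_rate_by_condition[["non_disinfected"]]
    for (cid in base$prok_ids) {
      if (runif(1) < base_rate) rows[[length(rows) + 1L]] <- annotate(cid, "prokaryotic")
    }
    for (vid in all_viral_ids) {
      if (runif(1) < config$phage_defense_rate) {
        rows[[length(rows) + 1L]] <- annotate(
          vid, contigs$category[match(vid, contigs$contig_id)])
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(contig_id = character(0), family = character(0),
                 subtype = character(0), carrier_category = character(0),
                 stringsAsFactors = FALSE)
  })

  ## viral gene hits supporting the taxonomy vote
  taxa <- data.frame(family = c("Fam_A", "Fam_B", "Fam_C", "Fam_D"),
                     order = c("Ord_1", "Ord_1", "Ord_2", "Ord_2"),
                     stringsAsFactors = FALSE)
  genehits <- withr::with_seed(child_seed(config$seed, "genehits"), {
    hit_rows <- list()
    gene_counts <- stats::setNames(sample(5:20, config$n_viral_contigs, replace = TRUE),
                                   base$viral_ids)
    true_family <- stats::setNames(rep(NA_character_, config$n_viral_contigs),
                                   base$viral_ids)
    for (vid in base$viral_ids) {
      if (runif(1) >= config$taxonomy_annotation_rate) next
      ti <- sample(nrow(taxa), 1)
      true_family[[vid]] <- taxa$family[ti]
      ng <- gene_counts[[vid]]
      nh <- max(2L, round(0.3 * ng))
      lineage <- sprintf("order=%s;family=%s", taxa$order[ti], taxa$family[ti])
      hit_rows[[vid]] <- data.frame(
        contig_id = vid, gene_index = sort(sample.int(ng, nh)) - 1L,
        lineage = lineage, evalue = 10^-runif(nh, 6, 20),
        stringsAsFactors = FALSE)
    }
    list(hits = if (length(hit_rows)) do.call(rbind, hit_rows) else
      data.frame(contig_id = character(0), gene_index = integer(0),
                 lineage = character(0), evalue = numeric(0), stringsAsFactors = FALSE),
      gene_counts = gene_counts, true_family = true_family)
  })

  ## sample metadata
  samples <- withr::with_seed(child_seed(config$seed, "stats"), {
    nsc <- config$n_samples_per_condition
    data.frame(
      sample_id = c(sprintf("dis_%02d", seq_len(nsc)),
                    sprintf("non_%02d", seq_len(nsc))),
      condition = rep(c("disinfected", "non_disinfected"), each = nsc),
      chlorine = c(runif(nsc, 0.3, 0.8), runif(nsc, 0, 0.05)),
      phosphate = c(runif(nsc, 0.05, 0.3), runif(nsc, 0.01, 0.1)),
      stringsAsFactors = FALSE)
  })

  ## planted ground-truth host links
  truth_links <- local({
    rows <- list()
    sp <- crispr$spacers
    sp <- sp[!is.na(sp$source), , drop = FALSE]
    for (i in seq_len(nrow(sp))) {
      s <- sp$spacer[i]
      rc <- revcomp(s)
      hit <- vapply(viral_seq_all, function(vs) {
        grepl(s, vs, fixed = TRUE) || grepl(rc, vs, fixed = TRUE)
      }, logical(1))
      for (vid in names(viral_seq_all)[hit]) {
        rows[[length(rows) + 1L]] <- data.frame(
          phage_id = vid, host_contig_id = sp$contig_id[i], channel = "crispr",
          stringsAsFactors = FALSE)
      }
    }
    if (nrow(trna)) {
      vmask <- trna$contig_id %in% all_viral_ids
      vt <- trna[vmask, , drop = FALSE]
      ht <- trna[!vmask, , drop = FALSE]
      for (i in seq_len(nrow(vt))) {
        hits <- ht$contig_id[ht$trna_seq == vt$trna_seq[i]]
        for (hid in hits) {
          rows[[length(rows) + 1L]] <- data.frame(
            phage_id = vt$contig_id[i], host_contig_id = hid, channel = "trna",
            stringsAsFactors = FALSE)
        }
      }
    }
    for (i in seq_len(nrow(prophage_tab))) {
      rows[[length(rows) + 1L]] <- data.frame(
        phage_id = prophage_tab$prophage_id[i],
        host_contig_id = prophage_tab$host_contig_id[i], channel = "prophage",
        stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(phage_id = character(0), host_contig_id = character(0),
                 channel = character(0), stringsAsFactors = FALSE)
    out <- out[!duplicated(out), , drop = FALSE]
    out$genus <- contigs$genus[match(out$host_contig_id, contigs$contig_id)]
    rownames(out) <- NULL
    out
  })

  community <- list(
    config = config,
    contigs = contigs,
    tables = list(
      prophages = prophage_tab[, c("prophage_id", "host_contig_id", "start", "end")],
      trna = trna,
      defense = defense,
      lifestyles = data.frame(phage_id = names(lifestyles),
                              lifestyle = unname(lifestyles), stringsAsFactors = FALSE),
      gene_hits = genehits$hits,
      gene_counts = data.frame(contig_id = names(genehits$gene_counts),
                               n_genes = unname(genehits$gene_counts),
                               stringsAsFactors = FALSE),
      samples = samples),
    truth = list(
      true_host_links = truth_links,
      true_lifestyles = lifestyles_all,
      true_arrays = truth_arrays,
      true_defense = defense,
      true_family = genehits$true_family,
      spacer_provenance = crispr$spacers))
  community$truth$true_abundance <- draw_sample_abundance(
    community, child_seed(config$seed, "abundance"))
  community
}

#' Draw expected per-sample relative abundance for a community
#'
#' Lognormal genus abundances with per-contig lognormal scatter; condition
#' effects scale defense-carrier weights, lysogenic viral weights and the
#' total viral share to their configured expected values. Exposed so
#' replicate power/calibration studies can redraw abundance without
#' regenerating sequences.
#'
#' @param community output of [generate_community()].
#' @param seed RNG seed for this draw.
#' @return contig x sample matrix of expected relative abundance (columns
#'   sum to 1).
#' @export
draw_sample_abundance <- function(community, seed) {
  config <- community$config
  contigs <- community$contigs
  samples <- community$tables$samples
  prok_ids <- contigs$contig_id[contigs$category == "prokaryotic"]
  viral_ids <- contigs$contig_id[contigs$category != "prokaryotic"]
  genus <- stats::setNames(contigs$genus, contigs$contig_id)
  carriers <- intersect(unique(community$truth$true_defense$contig_id[
    community$truth$true_defense$carrier_category == "prokaryotic"]), prok_ids)
  lys_ids <- names(community$truth$true_lifestyles)[
    community$truth$true_lifestyles == "lysogenic"]
  lys_ids <- intersect(lys_ids, viral_ids)
  lyt_ids <- setdiff(viral_ids, lys_ids)
  r_base <- length(carriers) / length(prok_ids)
  withr::with_seed(seed, {
    ab <- matrix(0, nrow(contigs), nrow(samples),
                 dimnames = list(contigs$contig_id, samples$sample_id))
    for (s in seq_len(nrow(samples))) {
      cond <- samples$condition[s]
      gweights <- stats::setNames(
        rlnorm(config$n_genera, 0, config$abundance_lognormal_sigma),
        sprintf("Genus_%02d", seq_len(config$n_genera)))
      w_prok <- gweights[genus[prok_ids]] *
        rlnorm(length(prok_ids), 0, config$abundance_lognormal_sigma / 2)
      names(w_prok) <- prok_ids
      # condition effect on defense carriers (expected carrier share -> rate)
      r_target <- config$defense_rate_by_condition[[cond]]
      if (length(carriers) && r_base > 0 && r_base < 1 && r_target > 0 && r_target < 1) {
        f <- (r_target / (1 - r_target)) / (r_base / (1 - r_base))
        w_prok[carriers] <- w_prok[carriers] * f
      }
      w_vir <- stats::setNames(
        rlnorm(length(viral_ids), 0, config$abundance_lognormal_sigma), viral_ids)
      # condition effect on lysogenic share among viral TPM
      r_lys <- config$lysogeny_rate_by_condition[[cond]]
      if (length(lys_ids) && length(lyt_ids) && r_lys > 0 && r_lys < 1) {
        a <- (r_lys / (1 - r_lys)) * (length(lyt_ids) / length(lys_ids))
        w_vir[lys_ids] <- w_vir[lys_ids] * a
      }
      # viral share of the whole community
      vs <- config$viral_share_by_condition[[cond]]
      w_vir <- w_vir * (vs / (1 - vs)) * (sum(w_prok) / sum(w_vir))
      w <- c(w_prok, w_vir)[contigs$contig_id]
      ab[, s] <- w / sum(w)
    }
    ab
  })
}

#' Simulate per-sample alignment records
#'
#' Read counts per contig are multinomial with probability proportional to
#' expected abundance x contig length (so TPM recovers the expected
#' relative abundance). A `short_read_rate` fraction of reads gets an
#' aligned length of 10-29 bp and is removed by the standard >= 30 bp
#' filter; the rest draw 30-150 bp.
#'
#' @param community output of [generate_community()].
#' @param seed RNG seed.
#' @param abundance optional abundance matrix (defaults to the community's
#'   planted truth).
#' @return named list of alignment record data.frames, one per sample.
#' @export
simulate_alignments <- function(community, seed = community$config$seed + 1L,
                                abundance = community$truth$true_abundance) {
  config <- community$config
  if (config$reads_per_sample <= 0) abort_validation("reads_per_sample must be > 0")
  lengths <- stats::setNames(community$contigs$length, community$contigs$contig_id)
  withr::with_seed(seed, {
    out <- list()
    for (s in colnames(abundance)) {
      prob <- abundance[, s] * lengths[rownames(abundance)]
      counts <- as.integer(rmultinom(1, config$reads_per_sample, prob))
      names(counts) <- rownames(abundance)
      cid <- rep(names(counts), counts)
      n <- length(cid)
      is_short <- runif(n) < config$short_read_rate
      alen <- integer(n)
      alen[is_short] <- sample(10:29, sum(is_short), replace = TRUE)
      alen[!is_short] <- sample(30:150, sum(!is_short), replace = TRUE)
      out[[s]] <- data.frame(
        read_id = sprintf("%s_r%06d", s, seq_len(n)),
        contig_id = cid, aligned_length = alen, stringsAsFactors = FALSE)
    }
    out
  })
}

#' Simulate filtered per-contig read counts (no per-read records)
#'
#' Count-level equivalent of [simulate_alignments()] followed by the 30 bp
#' filter: multinomial counts thinned binomially at `1 - short_read_rate`.
#' Used by replicate-heavy simulation studies.
#'
#' @param community output of [generate_community()].
#' @param seed RNG seed.
#' @param abundance optional abundance matrix.
#' @return contig x sample matrix of surviving read counts.
#' @export
simulate_counts <- function(community, seed = community$config$seed + 1L,
                            abundance = community$truth$true_abundance) {
  config <- community$config
  lengths <- stats::setNames(community$contigs$length, community$contigs$contig_id)
  withr::with_seed(seed, {
    out <- matrix(0L, nrow(abundance), ncol(abundance), dimnames = dimnames(abundance))
    for (s in colnames(abundance)) {
      prob <- abundance[, s] * lengths[rownames(abundance)]
      counts <- as.integer(rmultinom(1, config$reads_per_sample, prob))
      out[, s] <- rbinom(length(counts), counts, 1 - config$short_read_rate)
    }
    out
  })
}

#' Write all community inputs as plain-text files
#'
#' Emits the file set the pipeline reads: contigs.fasta, prophages.tsv,
#' trna.tsv, defense.tsv, lifestyles.tsv, gene_hits.tsv, gene_counts.tsv,
#' samples.tsv, prok_taxonomy.tsv, plus truth tables (truth_links.tsv,
#' truth_arrays.tsv, truth_abundance.tsv). Prophage coordinates are 0-based
#' half-open.
#'
#' @param community output of [generate_community()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_fasta(community$contigs, file.path(dir, "contigs.fasta"))
  wt(community$tables$prophages, "prophages.tsv")
  wt(community$tables$trna, "trna.tsv")
  wt(community$tables$defense, "defense.tsv")
  wt(community$tables$lifestyles, "lifestyles.tsv")
  wt(community$tables$gene_hits, "gene_hits.tsv")
  wt(community$tables$gene_counts, "gene_counts.tsv")
  wt(community$tables$samples, "samples.tsv")
  prok <- community$contigs[community$contigs$category == "prokaryotic", ]
  wt(prok[, c("contig_id", "genus", "lineage")], "prok_taxonomy.tsv")
  wt(community$truth$true_host_links, "truth_links.tsv")
  wt(community$truth$true_arrays, "truth_arrays.tsv")
  ab <- data.frame(contig_id = rownames(community$truth$true_abundance),
                   community$truth$true_abundance, check.names = FALSE)
  wt(ab, "truth_abundance.tsv")
  invisible(dir)
}
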