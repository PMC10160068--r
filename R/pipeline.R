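#' Run the community analysis pipeline end to end
#'
#' Orchestrates the stage order quantify -> annotate -> detect arrays ->
#' link -> profile -> test on a synthetic community (or any community-shaped
#' input list). Stage toggles switch individual analyses off. Rerunning with
#' the same community and seed reproduces identical results; when `outdir`
#' is given every table is also written as TSV along with a manifest of
#' parameters and seeds.
#'
#' @param community output of [generate_community()] (or a list with the
#'   same `contigs`/`tables` shape).
#' @param seed seed for read simulation and permutation tests.
#' @param min_aligned aligned-length filter (bp).
#' @param channels linkage evidence channels to use.
#' @param stages character vector of stages to run; any of "derep",
#'   "abundance", "taxonomy", "crispr", "linkage", "defense", "stats".
#'   Later stages that need a disabled stage are skipped. Dereplication is
#'   applied within each contig category (a prophage record is a verbatim
#'   copy of its free genome, so pooling categories would collapse the
#'   prophage channel) and downstream stages use the representatives.
#' @param n_perm Mantel permutations.
#' @param outdir optional output directory for TSV results.
#' @return report list (see details in the individual stage functions).
#' @export
run_pipeline <- function(community, seed = community$config$seed,
                         min_aligned = 30L,
                         channels = c("crispr", "trna", "prophage"),
                         stages = c("derep", "abundance", "taxonomy", "crispr",
                                    "linkage", "defense", "stats"),
                         n_perm = 999L, outdir = NULL) {
  contigs <- community$contigs
  tables <- community$tables
  samples <- tables$samples
  report <- list(seed = seed, stages = stages, channels = channels)

  ## dereplication, within category
  if ("derep" %in% stages) {
    cluster_maps <- list()
    keep <- character(0)
    for (cat in unique(contigs$category)) {
      dr <- dereplicate(contigs[contigs$category == cat, , drop = FALSE])
      keep <- c(keep, dr$representatives$contig_id)
      cluster_maps[[cat]] <- dr$cluster_map
    }
    report$cluster_map <- do.call(c, unname(cluster_maps))
    n_before <- nrow(contigs)
    # reads are still simulated from the full community; downstream stages
    # quantify and analyse the representatives only
    contigs <- contigs[contigs$contig_id %in% keep, , drop = FALSE]
    message(sprintf("pipeline: dereplication kept %d of %d contigs",
                    nrow(contigs), n_before))
  }
  lengths <- stats::setNames(contigs$length, contigs$contig_id)

  ## abundance
  if ("abundance" %in% stages) {
    alignments <- simulate_alignments(community, seed = child_seed(seed, "reads"))
    # reads on contigs dropped by dereplication (if any) are discarded
    alignments <- lapply(alignments, function(d) {
      d[d$contig_id %in% names(lengths), , drop = FALSE]
    })
    report$abundance <- abundance_table(alignments, lengths, min_aligned = min_aligned)
    message(sprintf("pipeline: %d contigs quantified over %d samples",
                    nrow(report$abundance), ncol(report$abundance)))
  }

  ## viral taxonomy + lifestyles
  if ("taxonomy" %in% stages) {
    gc <- stats::setNames(tables$gene_counts$n_genes, tables$gene_counts$contig_id)
    report$taxonomy <- assign_taxonomy(tables$gene_hits, gc)
    labels <- stats::setNames(tables$lifestyles$lifestyle, tables$lifestyles$phage_id)
    contigs <- attach_lifestyles(contigs, labels)
    report$contigs <- contigs
  }

  ## CRISPR arrays + spacer burden
  if ("crispr" %in% stages) {
    prok <- contigs[contigs$category == "prokaryotic", , drop = FALSE]
    report$arrays <- detect_crispr_all(prok)
    report$spacers <- extract_spacers(report$arrays)
    if (!is.null(report$abundance)) {
      report$burden <- data.frame(
        sample_id = colnames(report$abundance),
        M = vapply(colnames(report$abundance), function(s) {
          spacer_burden(report$arrays, lengths, report$abundance[, s])$M
        }, numeric(1)), stringsAsFactors = FALSE)
    }
    message(sprintf("pipeline: %d CRISPR arrays on %d contigs",
                    nrow(report$arrays), length(unique(report$arrays$contig_id))))
  }

  ## host linkage
  if ("linkage" %in% stages && "crispr" %in% stages) {
    viral <- contigs[contigs$category != "prokaryotic", , drop = FALSE]
    host_genus <- stats::setNames(contigs$genus, contigs$contig_id)
    link_parts <- list()
    if ("crispr" %in% channels) {
      link_parts$crispr <- match_spacers(report$spacers, viral)
    }
    if ("trna" %in% channels && nrow(tables$trna)) {
      vmask <- tables$trna$contig_id %in% viral$contig_id
      link_parts$trna <- match_trnas(tables$trna[vmask, , drop = FALSE],
                                     tables$trna[!vmask, , drop = FALSE])
    }
    if ("prophage" %in% channels) {
      link_parts$prophage <- link_prophages(tables$prophages, lengths)
    }
    merged <- do.call(merge_links, c(unname(link_parts), list(host_genus = host_genus)))
    report$links <- merged$links
    report$channel_counts <- merged$channel_counts
    report$multi_channel_phages <- merged$multi_channel_phages
    viral_ab <- if (!is.null(report$abundance)) {
      rowMeans(report$abundance[viral$contig_id, , drop = FALSE])
    } else NULL
    poly <- classify_polyvalent(report$links, viral_ab)
    report$host_range <- poly$summary
    report$polyvalent_fraction_count <- poly$fraction_count
    report$polyvalent_fraction_abundance <- poly$fraction_abundance
    if (!is.null(report$abundance)) {
      prok_ids <- contigs$contig_id[contigs$category == "prokaryotic"]
      prok_ab <- rowMeans(report$abundance[prok_ids, , drop = FALSE])
      cg <- stats::setNames(contigs$genus[match(prok_ids, contigs$contig_id)], prok_ids)
      report$host_population <- host_population_summary(report$links, prok_ab, cg)
    }
    message(sprintf("pipeline: %d host links (%s); %d multi-channel phages",
                    nrow(report$links),
                    paste(names(report$channel_counts), report$channel_counts,
                          sep = "=", collapse = ", "),
                    length(report$multi_channel_phages)))
  }

  ## defense profiling
  if ("defense" %in% stages && !is.null(report$abundance)) {
    ab <- report$abundance
    grouping <- stats::setNames(samples$condition, samples$sample_id)
    prok_ids <- contigs$contig_id[contigs$category == "prokaryotic"]
    prok_ann <- tables$defense[tables$defense$carrier_category == "prokaryotic", ,
                               drop = FALSE]
    report$carrier_fraction <- carrier_fraction(prok_ann, ab, rownames(ab))
    report$defense_profile <- profile_families(prok_ann, ab, grouping)
    report$rm_subtypes <- if ("RM" %in% prok_ann$family) {
      subtype_shares(prok_ann, ab, "RM")
    } else stats::setNames(numeric(0), character(0))
    lysogen_ids <- unique(tables$prophages$host_contig_id)
    report$lysogen_profile <- restricted_profile(prok_ann, ab, lysogen_ids, grouping)
    phage_ann <- tables$defense[tables$defense$carrier_category != "prokaryotic", ,
                                drop = FALSE]
    if (nrow(phage_ann) && !is.null(report$contigs)) {
      lf <- stats::setNames(report$contigs$lifestyle, report$contigs$contig_id)
      split_ids <- list(
        lytic = names(lf)[!is.na(lf) & lf == "lytic"],
        lysogenic_or_prophage = names(lf)[!is.na(lf) & lf == "lysogenic"])
      report$phage_carried <- lapply(split_ids, function(ids) {
        restricted_profile(phage_ann, ab, ids, grouping)
      })
    }
  }

  ## comparative statistics
  if ("stats" %in% stages && !is.null(report$abundance)) {
    ab <- report$abundance
    cond <- stats::setNames(samples$condition, samples$sample_id)
    dis <- names(cond)[cond == "disinfected"]
    non <- names(cond)[cond == "non_disinfected"]
    viral_ids <- contigs$contig_id[contigs$category != "prokaryotic"]
    prok_ids <- contigs$contig_id[contigs$category == "prokaryotic"]
    per_sample <- data.frame(
      sample_id = colnames(ab),
      condition = cond[colnames(ab)],
      shannon_viral = apply(ab[viral_ids, , drop = FALSE] + 0, 2, function(x) {
        if (sum(x) > 0) shannon(x) else NA_real_
      }),
      viral_share = colSums(ab[viral_ids, , drop = FALSE]) / 1e6,
      stringsAsFactors = FALSE)
    if (!is.null(report$contigs)) {
      lf <- stats::setNames(report$contigs$lifestyle, report$contigs$contig_id)
      lys <- viral_ids[!is.na(lf[viral_ids]) & lf[viral_ids] == "lysogenic"]
      per_sample$lysogenic_share <- colSums(ab[lys, , drop = FALSE]) /
        pmax(colSums(ab[viral_ids, , drop = FALSE]), .Machine$double.eps)
    }
    prok_ann <- tables$defense[tables$defense$carrier_category == "prokaryotic", ,
                               drop = FALSE]
    per_sample$carrier_fraction <- carrier_fraction(prok_ann, ab, rownames(ab))
    if (!is.null(report$burden)) {
      per_sample$M <- report$burden$M[match(per_sample$sample_id,
                                            report$burden$sample_id)]
    }
    report$per_sample <- per_sample
    tests <- list()
    for (v in setdiff(names(per_sample), c("sample_id", "condition"))) {
      x <- per_sample[[v]][per_sample$sample_id %in% dis]
      y <- per_sample[[v]][per_sample$sample_id %in% non]
      if (sum(!is.na(x)) >= 2 && sum(!is.na(y)) >= 2) {
        tt <- t_test(x[!is.na(x)], y[!is.na(y)])
        tests[[v]] <- data.frame(quantity = v, statistic = tt$statistic,
                                 p_value = tt$p_value, method = "student_t",
                                 stringsAsFactors = FALSE)
      }
    }
    report$tests <- do.call(rbind, tests)
    # community ordination + environmental driver
    prok_ab <- ab[prok_ids, , drop = FALSE]
    D <- bray_curtis_matrix(prok_ab)
    report$pcoa <- pcoa(D, k = 2)
    covs <- samples[, setdiff(names(samples), c("sample_id", "condition")),
                    drop = FALSE]
    rownames(covs) <- samples$sample_id
    report$mantel <- lapply(names(covs), function(cv) {
      Dc <- covariate_distance(covs[colnames(ab), cv, drop = FALSE])
      mantel_test(D, Dc, n_perm = n_perm, seed = child_seed(seed, "stats"))
    })
    names(report$mantel) <- names(covs)
  }

  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' Compare pipeline links against planted ground truth
#'
#' @param links merged link table (phage_id, host_contig_id, channel).
#' @param truth_links truth table with the same columns.
#' @return list with precision, recall, n_predicted, n_true.
#' @export
link_accuracy <- function(links, truth_links) {
  key <- function(d) paste(d$phage_id, d$host_contig_id, d$channel, sep = "|")
  pred <- unique(key(links))
  true <- unique(key(truth_links))
  tp <- length(intersect(pred, true))
  list(precision = if (length(pred)) tp / length(pred) else NA_real_,
       recall = if (length(true)) tp / length(true) else NA_real_,
       n_predicted = length(pred), n_true = length(true))
}

#' Write a pipeline report as TSV files plus a manifest
#'
#' @param report output of [run_pipeline()].
#' @param outdir output directory.
#' @return invisibly, the directory.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name) {
    write.table(x, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(report$abundance)) {
    wt(data.frame(contig_id = rownames(report$abundance), report$abundance,
                  check.names = FALSE), "abundance.tsv")
  }
  if (!is.null(report$taxonomy)) wt(report$taxonomy, "taxonomy.tsv")
  if (!is.null(report$arrays)) wt(report$arrays, "arrays.tsv")
  if (!is.null(report$burden)) wt(report$burden, "burden.tsv")
  if (!is.null(report$links)) wt(report$links, "links.tsv")
  if (!is.null(report$host_range)) wt(report$host_range, "hostrange.tsv")
  if (!is.null(report$host_population)) wt(report$host_population, "host_population.tsv")
  if (!is.null(report$defense_profile)) wt(report$defense_profile, "defense_profile.tsv")
  if (!is.null(report$lysogen_profile)) wt(report$lysogen_profile, "lysogen_profile.tsv")
  if (!is.null(report$per_sample)) wt(report$per_sample, "per_sample.tsv")
  if (!is.null(report$tests)) wt(report$tests, "tests.tsv")
  manifest <- c(
    sprintf("package: aquaphage %s", as.character(utils::packageVersion("aquaphage"))),
    sprintf("seed: %s", report$seed),
    sprintf("stages: %s", paste(report$stages, collapse = ",")),
    sprintf("channels: %s", paste(report$channels, collapse = ",")))
  writeLines(manifest, file.path(outdir, "manifest.txt"))
  invisible(outdir)
}
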