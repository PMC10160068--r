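#' Link phages to hosts by CRISPR spacer (protospacer) matching
#'
#' A link is emitted when a spacer occurs in a viral contig on either strand
#' with at most `max_mismatch` mismatches (no indels). The spacer's contig is
#' the host. Spacers shorter than 18 bp are rejected with a warning;
#' spacers containing N never match (N is conservative in exact matching).
#'
#' @param spacers data.frame: contig_id, spacer (from [extract_spacers()]).
#' @param viral_contigs `contig_table` of viral-category contigs.
#' @param max_mismatch mismatches tolerated (default 0).
#' @return link data.frame: phage_id, host_contig_id, channel ("crispr"),
#'   detail.
#' @export
match_spacers <- function(spacers, viral_contigs, max_mismatch = 0L) {
  empty <- data.frame(phage_id = character(0), host_contig_id = character(0),
                      channel = character(0), detail = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(spacers) || !nrow(spacers) || !nrow(viral_contigs)) return(empty)
  short <- nchar(spacers$spacer) < 18
  if (any(short)) {
    warning(sprintf("match_spacers: %d spacer(s) < 18 bp rejected", sum(short)),
            call. = FALSE)
    spacers <- spacers[!short, , drop = FALSE]
  }
  has_n <- grepl("N", spacers$spacer, fixed = TRUE)
  spacers <- spacers[!has_n, , drop = FALSE]
  if (!nrow(spacers)) return(empty)
  subj <- Biostrings::DNAStringSet(viral_contigs$sequence)
  names(subj) <- viral_contigs$contig_id
  links <- list()
  for (i in seq_len(nrow(spacers))) {
    sp <- spacers$spacer[i]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") sp else revcomp(sp)
      n_hit <- Biostrings::vcountPattern(pat, subj, max.mismatch = max_mismatch,
                                         fixed = TRUE)
      hit_ids <- names(subj)[n_hit > 0]
      for (vid in hit_ids) {
        pos <- Biostrings::start(Biostrings::matchPattern(
          pat, subj[[vid]], max.mismatch = max_mismatch, fixed = TRUE))[1]
        links[[length(links) + 1L]] <- data.frame(
          phage_id = vid, host_contig_id = spacers$contig_id[i],
          channel = "crispr",
          detail = sprintf("spacer=%s;strand=%s;pos=%d", sp, strand, pos - 1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(links)) return(empty)
  out <- do.call(rbind, links)
  out[!duplicated(out[, c("phage_id", "host_contig_id", "channel")]), , drop = FALSE]
}

#' Link phages to hosts by perfect tRNA matching
#'
#' A link requires a full-length, 100%-identity match (either strand)
#' between a viral tRNA and a prokaryotic tRNA; one link per (phage, host
#' contig) pair. tRNA sequences outside 60-120 bp are rejected with a
#' warning.
#'
#' @param viral_trnas data.frame: contig_id, trna_id, trna_seq.
#' @param prok_trnas same schema for prokaryotic contigs.
#' @return link data.frame (channel "trna").
#' @export
match_trnas <- function(viral_trnas, prok_trnas) {
  empty <- data.frame(phage_id = character(0), host_contig_id = character(0),
                      channel = character(0), detail = character(0),
                      stringsAsFactors = FALSE)
  check_len <- function(df, label) {
    if (is.null(df) || !nrow(df)) return(df)
    bad <- nchar(df$trna_seq) < 60 | nchar(df$trna_seq) > 120
    if (any(bad)) {
      warning(sprintf("match_trnas: %d %s tRNA(s) outside 60-120 bp rejected",
                      sum(bad), label), call. = FALSE)
      df <- df[!bad, , drop = FALSE]
    }
    df
  }
  viral_trnas <- check_len(viral_trnas, "viral")
  prok_trnas <- check_len(prok_trnas, "prokaryotic")
  if (is.null(viral_trnas) || !nrow(viral_trnas) ||
      is.null(prok_trnas) || !nrow(prok_trnas)) return(empty)
  prok_fwd <- toupper(prok_trnas$trna_seq)
  prok_rev <- revcomp(prok_fwd)
  links <- list()
  for (i in seq_len(nrow(viral_trnas))) {
    vseq <- toupper(viral_trnas$trna_seq[i])
    hit <- prok_fwd == vseq | prok_rev == vseq
    for (j in which(hit)) {
      links[[length(links) + 1L]] <- data.frame(
        phage_id = viral_trnas$contig_id[i],
        host_contig_id = prok_trnas$contig_id[j],
        channel = "trna",
        detail = sprintf("trna=%s~%s", viral_trnas$trna_id[i], prok_trnas$trna_id[j]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(links)) return(empty)
  out <- do.call(rbind, links)
  out[!duplicated(out[, c("phage_id", "host_contig_id")]), , drop = FALSE]
}

#' Link prophages to their integration hosts
#'
#' One link per prophage row: the prokaryotic contig carrying the
#' integrated prophage is its host. Intervals are 0-based half-open and
#' must lie within the host contig.
#'
#' @param prophage_table data.frame: prophage_id, host_contig_id, start, end.
#' @param host_lengths named vector contig_id -> length (bp), used for
#'   bounds checking.
#' @return link data.frame (channel "prophage").
#' @export
link_prophages <- function(prophage_table, host_lengths) {
  empty <- data.frame(phage_id = character(0), host_contig_id = character(0),
                      channel = character(0), detail = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(prophage_table) || !nrow(prophage_table)) return(empty)
  for (i in seq_len(nrow(prophage_table))) {
    hid <- prophage_table$host_contig_id[i]
    hlen <- host_lengths[[hid]]
    if (is.null(hlen)) abort_validation("prophage host contig unknown: %s", hid)
    if (prophage_table$start[i] < 0 || prophage_table$end[i] > hlen ||
        prophage_table$start[i] >= prophage_table$end[i]) {
      abort_validation("prophage %s interval [%d,%d) out of bounds for %s (length %d)",
                       prophage_table$prophage_id[i], prophage_table$start[i],
                       prophage_table$end[i], hid, hlen)
    }
  }
  data.frame(phage_id = prophage_table$prophage_id,
             host_contig_id = prophage_table$host_contig_id,
             channel = "prophage",
             detail = sprintf("interval=[%d,%d)", prophage_table$start,
                              prophage_table$end),
             stringsAsFactors = FALSE)
}

#' Merge link channels and attach host genus
#'
#' Exact duplicates on (phage, host contig, channel) are removed; the same
#' phage-host pair supported by two channels keeps both rows. Genus comes
#' from the host contig's taxonomy; links without genus are retained but
#' excluded from genus-level summaries downstream.
#'
#' @param ... link data.frames from the channel operations.
#' @param host_genus named vector host_contig_id -> genus (NA allowed).
#' @return list: `links` (deduplicated table with `genus`),
#'   `channel_counts` (named integer vector),
#'   `multi_channel_phages` (ids linked by >= 2 distinct channels).
#' @export
merge_links <- function(..., host_genus = NULL) {
  parts <- Filter(function(d) !is.null(d) && nrow(d) > 0, list(...))
  if (!length(parts)) {
    links <- data.frame(phage_id = character(0), host_contig_id = character(0),
                        channel = character(0), detail = character(0),
                        genus = character(0), stringsAsFactors = FALSE)
    return(list(links = links, channel_counts = integer(0),
                multi_channel_phages = character(0)))
  }
  links <- do.call(rbind, parts)
  links <- links[!duplicated(links[, c("phage_id", "host_contig_id", "channel")]), ,
                 drop = FALSE]
  links$genus <- if (is.null(host_genus)) NA_character_ else
    as.character(host_genus[links$host_contig_id])
  rownames(links) <- NULL
  channel_counts <- vapply(split(links, links$channel), nrow, integer(1))
  per_phage <- tapply(links$channel, links$phage_id, function(ch) length(unique(ch)))
  multi <- names(per_phage)[per_phage >= 2]
  list(links = links, channel_counts = channel_counts, multi_channel_phages = multi)
}

#' Classify polyvalent phages and host-range summaries
#'
#' A phage is polyvalent when it links to two or more distinct host genera.
#' Links without genus are ignored for genus counting; phages whose links
#' all lack genus are excluded entirely. The count-basis fraction is
#' polyvalent phages over genus-linked phages; the abundance-basis fraction
#' weighs each phage by its TPM in the supplied abundance column.
#'
#' @param links merged link table (with `genus`).
#' @param abundance optional named TPM vector over phage ids.
#' @return list: `summary` (phage_id, n_genera, genera, polyvalent),
#'   `fraction_count`, `fraction_abundance` (NA when not computable).
#' @export
classify_polyvalent <- function(links, abundance = NULL) {
  gl <- links[!is.na(links$genus), , drop = FALSE]
  if (!nrow(gl)) {
    return(list(summary = data.frame(phage_id = character(0), n_genera = integer(0),
                                     genera = character(0), polyvalent = logical(0),
                                     stringsAsFactors = FALSE),
                fraction_count = NA_real_, fraction_abundance = NA_real_))
  }
  per <- split(gl$genus, gl$phage_id)
  summary <- data.frame(
    phage_id = names(per),
    n_genera = vapply(per, function(g) length(unique(g)), integer(1)),
    genera = vapply(per, function(g) paste(sort(unique(g)), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  summary$polyvalent <- summary$n_genera >= 2
  fraction_count <- mean(summary$polyvalent)
  fraction_abundance <- NA_real_
  if (!is.null(abundance)) {
    a <- abundance[summary$phage_id]
    a[is.na(a)] <- 0
    tot <- sum(a)
    if (tot > 0) fraction_abundance <- sum(a[summary$polyvalent]) / tot
  }
  rownames(summary) <- NULL
  list(summary = summary, fraction_count = fraction_count,
       fraction_abundance = fraction_abundance)
}

#' Per-genus host population summary
#'
#' Genera are ranked by the summed TPM of their distinct predicted-host
#' contigs. For each genus the table reports: share among all predicted
#' hosts, share among all prokaryotes, and the fraction of the genus's links
#' that came through the prophage channel. Genera in the top-k of both the
#' predicted-host and the whole-community ranking are flagged as `matched`.
#'
#' @param links merged link table with genus.
#' @param prok_abundance named TPM vector over prokaryotic contigs.
#' @param contig_genus named vector contig_id -> genus for all prokaryotic
#'   contigs.
#' @param top_k number of top genera to report (default 20).
#' @return data.frame ordered by predicted-host abundance.
#' @export
host_population_summary <- function(links, prok_abundance, contig_genus, top_k = 20L) {
  if (top_k < 1) abort_validation("top_k must be >= 1")
  gl <- links[!is.na(links$genus), , drop = FALSE]
  if (!nrow(gl)) {
    return(data.frame(genus = character(0), host_tpm = numeric(0),
                      share_hosts = numeric(0), share_community = numeric(0),
                      prophage_link_share = numeric(0), matched = logical(0),
                      stringsAsFactors = FALSE))
  }
  host_contigs <- unique(gl[, c("host_contig_id", "genus")])
  host_contigs$tpm <- as.numeric(prok_abundance[host_contigs$host_contig_id])
  host_contigs$tpm[is.na(host_contigs$tpm)] <- 0
  host_tpm <- tapply(host_contigs$tpm, host_contigs$genus, sum)
  total_host <- sum(host_tpm)
  comm <- tapply(as.numeric(prok_abundance[names(contig_genus)]),
                 as.character(contig_genus), sum)
  comm[is.na(comm)] <- 0
  prophage_share <- vapply(names(host_tpm), function(g) {
    d <- gl[gl$genus == g, , drop = FALSE]
    mean(d$channel == "prophage")
  }, numeric(1))
  out <- data.frame(
    genus = names(host_tpm),
    host_tpm = as.numeric(host_tpm),
    share_hosts = if (total_host > 0) as.numeric(host_tpm) / total_host else 0,
    share_community = as.numeric(comm[names(host_tpm)]) / sum(comm),
    prophage_link_share = prophage_share,
    stringsAsFactors = FALSE)
  out <- out[order(-out$host_tpm, out$genus), , drop = FALSE]
  top_hosts <- utils::head(out$genus, top_k)
  top_comm <- utils::head(names(sort(comm, decreasing = TRUE)), top_k)
  out$matched <- out$genus %in% intersect(top_hosts, top_comm)
  out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}
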