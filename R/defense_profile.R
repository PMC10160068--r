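#' TPM share of defense-carrying contigs
#'
#' The carrier fraction is the summed TPM of distinct annotation-carrying
#' contigs within a chosen universe of contigs, divided by the universe's
#' total TPM. Each contig counts once regardless of how many systems it
#' carries.
#'
#' @param annotations data.frame: contig_id, family, subtype.
#' @param abundance named TPM vector (one sample) or matrix (contigs x
#'   samples).
#' @param universe character vector of contig ids defining the denominator.
#' @return fraction in 0..1 (vector over samples when a matrix is given).
#' @export
carrier_fraction <- function(annotations, abundance, universe) {
  if (!length(universe)) abort_validation("empty universe")
  carriers <- intersect(unique(annotations$contig_id), universe)
  if (is.matrix(abundance)) {
    tot <- colSums(abundance[intersect(universe, rownames(abundance)), , drop = FALSE])
    car <- colSums(abundance[intersect(carriers, rownames(abundance)), , drop = FALSE])
    return(ifelse(tot > 0, car / tot, NA_real_))
  }
  tot <- sum(abundance[intersect(universe, names(abundance))], na.rm = TRUE)
  if (tot <= 0) return(NA_real_)
  sum(abundance[intersect(carriers, names(abundance))], na.rm = TRUE) / tot
}

#' Per-family defense profile by grouping
#'
#' For each sample, a family's TPM is the summed TPM of contigs carrying at
#' least one system of that family (a contig with systems of two families
#' contributes its TPM to both; repeated systems of one family count once).
#' Group-level values are means over the group's samples; proportions
#' normalize the group means by total defense TPM. Ordering is stable (TPM
#' descending, then family name).
#'
#' @param annotations data.frame: contig_id, family, subtype.
#' @param abundance TPM matrix (contigs x samples).
#' @param grouping named vector sample_id -> group label (e.g. condition);
#'   defaults to one group per sample.
#' @return data.frame: group, family, tpm, proportion.
#' @export
profile_families <- function(annotations, abundance, grouping = NULL) {
  samples <- colnames(abundance)
  if (is.null(grouping)) grouping <- stats::setNames(samples, samples)
  fams <- sort(unique(annotations$family))
  if (!length(fams)) {
    message("profile_families: no annotations; zero profile")
    return(data.frame(group = character(0), family = character(0),
                      tpm = numeric(0), proportion = numeric(0),
                      stringsAsFactors = FALSE))
  }
  # per-sample family TPM (distinct carrier contigs per family)
  fam_tpm <- sapply(fams, function(f) {
    ids <- intersect(unique(annotations$contig_id[annotations$family == f]),
                     rownames(abundance))
    colSums(abundance[ids, , drop = FALSE])
  })
  fam_tpm <- matrix(fam_tpm, nrow = length(samples),
                    dimnames = list(samples, fams))
  rows <- lapply(unique(grouping), function(g) {
    gs <- names(grouping)[grouping == g]
    m <- colMeans(fam_tpm[gs, , drop = FALSE])
    tot <- sum(m)
    d <- data.frame(group = g, family = fams, tpm = as.numeric(m),
                    proportion = if (tot > 0) as.numeric(m) / tot else 0,
                    stringsAsFactors = FALSE)
    d[order(-d$tpm, d$family), , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Subtype shares within one defense family
#'
#' Shares over the family's total TPM; annotations of the family without a
#' subtype are reported as `unknown`. Shares sum to 1 when the family has
#' positive TPM.
#'
#' @param annotations data.frame: contig_id, family, subtype.
#' @param abundance named TPM vector (one sample) or matrix (shares then use
#'   the per-sample mean TPM).
#' @param family family name; must be present in the vocabulary.
#' @param vocabulary controlled family vocabulary; requesting a family
#'   outside it is a validation error (default: families seen in
#'   `annotations`).
#' @return named numeric vector of shares (possibly empty, with a warning).
#' @export
subtype_shares <- function(annotations, abundance, family,
                           vocabulary = unique(annotations$family)) {
  if (!family %in% vocabulary) {
    abort_validation("unknown defense family '%s'", family)
  }
  if (!family %in% annotations$family) {
    warning(sprintf("subtype_shares: family '%s' absent from annotations", family),
            call. = FALSE)
    return(stats::setNames(numeric(0), character(0)))
  }
  ann <- annotations[annotations$family == family, , drop = FALSE]
  ann$subtype[is.na(ann$subtype) | !nzchar(ann$subtype)] <- "unknown"
  ab <- if (is.matrix(abundance)) rowMeans(abundance) else abundance
  per_contig <- unique(ann[, c("contig_id", "subtype")])
  tpm <- tapply(as.numeric(ab[per_contig$contig_id]), per_contig$subtype, sum)
  tpm[is.na(tpm)] <- 0
  tot <- sum(tpm)
  if (tot <= 0) {
    warning("subtype_shares: family has zero abundance", call. = FALSE)
    return(stats::setNames(numeric(0), character(0)))
  }
  shares <- tpm / tot
  stats::setNames(as.numeric(shares), names(shares))
}

#' Defense profile restricted to a contig predicate
#'
#' Same computation as [profile_families()] restricted to contigs satisfying
#' a predicate (e.g. lysogenized prokaryotes = contigs hosting a prophage;
#' phage-carried systems split by lifestyle). The predicate must be
#' decidable (non-NA) for every annotated contig.
#'
#' @param annotations data.frame: contig_id, family, subtype.
#' @param abundance TPM matrix.
#' @param restrict either a character vector of contig ids, or a named
#'   logical vector over contig ids.
#' @param grouping optional sample -> group mapping.
#' @return data.frame as in [profile_families()]; zero profile (with a
#'   message) when nothing satisfies the restriction.
#' @export
restricted_profile <- function(annotations, abundance, restrict, grouping = NULL) {
  if (is.logical(restrict)) {
    ann_ids <- unique(annotations$contig_id)
    und <- setdiff(ann_ids, names(restrict))
    if (length(und)) {
      abort_validation("restriction undecidable for contig(s): %s",
                       paste(utils::head(und, 5), collapse = ", "))
    }
    keep_ids <- names(restrict)[restrict]
  } else {
    keep_ids <- restrict
  }
  ann <- annotations[annotations$contig_id %in% keep_ids, , drop = FALSE]
  profile_families(ann, abundance, grouping)
}
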