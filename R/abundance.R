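#' Filter alignment records on aligned length
#'
#' Keeps records whose aligned block length is at least `min_aligned` (the
#' inclusive reading of the "more than 30 bp" mapping-length rule, matching
#' the aligner's 30 bp seed). Order is preserved; the number dropped is
#' reported via `message()`.
#'
#' @param records data.frame with read_id, contig_id, aligned_length.
#' @param min_aligned minimum aligned length in bp (default 30).
#' @return filtered data.frame.
#' @export
filter_alignments <- function(records, min_aligned = 30L) {
  if (min_aligned < 0) abort_validation("min_aligned must be >= 0")
  keep <- records$aligned_length >= min_aligned
  n_drop <- sum(!keep)
  if (n_drop > 0) message(sprintf("filter_alignments: dropped %d of %d records below %d bp",
                                  n_drop, nrow(records), min_aligned))
  records[keep, , drop = FALSE]
}

#' TPM from filtered alignment records
#'
#' TPM_i = (count_i / length_i) / sum_j(count_j / length_j) * 1e6. Each
#' alignment record counts once (no fractional multi-mapping weights).
#' Contigs present in `lengths` but with no reads get 0. When no reads
#' survive, the all-zero column is flagged via `message()`.
#'
#' @param records filtered alignment records.
#' @param lengths named numeric vector, contig_id -> length in bp (all > 0).
#' @param sample_id label used in messages only.
#' @return named numeric vector of TPM values over `names(lengths)`.
#' @export
compute_tpm <- function(records, lengths, sample_id = "sample") {
  if (any(lengths <= 0)) abort_validation("all contig lengths must be > 0")
  unknown <- setdiff(unique(records$contig_id), names(lengths))
  if (length(unknown)) {
    abort_validation("alignment references unknown contig(s): %s",
                     paste(utils::head(unknown, 5), collapse = ", "))
  }
  counts <- table(factor(records$contig_id, levels = names(lengths)))
  tpm_from_counts(as.numeric(counts), lengths, sample_id = sample_id)
}

#' TPM from a per-contig read-count vector or matrix
#'
#' Count-level entry point to the same TPM computation; used by the
#' replicate-heavy simulation studies where materialising per-read records
#' adds nothing.
#'
#' @param counts numeric vector (one sample) or matrix (contigs x samples)
#'   aligned with `names(lengths)` / `rownames`.
#' @param lengths named numeric vector of contig lengths (bp).
#' @param sample_id label used in messages.
#' @return TPM vector or matrix matching `counts`.
#' @export
tpm_from_counts <- function(counts, lengths, sample_id = "sample") {
  if (is.matrix(counts)) {
    out <- apply(counts, 2, tpm_from_counts, lengths = lengths)
    dimnames(out) <- dimnames(counts)
    if (is.null(rownames(out))) rownames(out) <- names(lengths)
    return(out)
  }
  rate <- counts / as.numeric(lengths)
  tot <- sum(rate)
  if (tot == 0) {
    message(sprintf("compute_tpm: sample '%s' has no surviving reads (all-zero column)",
                    sample_id))
    return(stats::setNames(numeric(length(lengths)), names(lengths)))
  }
  stats::setNames(rate / tot * 1e6, names(lengths))
}

#' Build a contig x sample abundance table
#'
#' @param alignments named list of alignment record data.frames, one per
#'   sample (names are sample ids).
#' @param lengths named numeric vector of contig lengths.
#' @param min_aligned aligned-length filter threshold (bp).
#' @return numeric matrix, rows contigs, columns samples; every column with
#'   surviving reads sums to 1e6.
#' @export
abundance_table <- function(alignments, lengths, min_aligned = 30L) {
  stopifnot(!is.null(names(alignments)))
  cols <- lapply(names(alignments), function(s) {
    compute_tpm(filter_alignments(alignments[[s]], min_aligned), lengths, sample_id = s)
  })
  out <- do.call(cbind, cols)
  colnames(out) <- names(alignments)
  out
}

#' Aggregate contig abundance into groups
#'
#' Group value is the summed TPM of member contigs per sample; `share` is the
#' group's fraction of the 1e6 column total. Contigs absent from `membership`
#' are ignored.
#'
#' @param table abundance matrix (contigs x samples).
#' @param membership named character vector, contig_id -> group label.
#' @return list with `tpm` (group x sample matrix) and `share` (same shape,
#'   values in 0..1).
#' @export
aggregate_abundance <- function(table, membership) {
  if (length(membership) && any(!nzchar(membership))) {
    abort_validation("empty group label in membership")
  }
  ids <- intersect(names(membership), rownames(table))
  groups <- sort(unique(as.character(membership)))
  tpm <- matrix(0, nrow = length(groups), ncol = ncol(table),
                dimnames = list(groups, colnames(table)))
  for (g in groups) {
    g_ids <- ids[membership[ids] == g]
    tpm[g, ] <- colSums(table[g_ids, , drop = FALSE])
  }
  list(tpm = tpm, share = tpm / 1e6)
}
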