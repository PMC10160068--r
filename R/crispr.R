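#' CRISPR array detection parameters
#'
#' Exact-repeat chain detection: a CRISPR array is a chain of at least
#' `min_repeats` identical copies of a direct repeat (length within
#' `repeat_len_range`) separated by gaps (spacers) within
#' `spacer_len_range`. Exact matching (`max_repeat_mismatches = 0`) is the
#' default.
#'
#' @param repeat_len_range repeat length bounds in bp (default 23-55).
#' @param spacer_len_range spacer length bounds in bp (default 20-60).
#' @param min_repeats minimum repeat copies per array (default 3, i.e. two
#'   spacers).
#' @param max_repeat_mismatches tolerated mismatches between repeat copies
#'   (only 0 is implemented; the parameter records the convention).
#' @return validated parameter list.
#' @export
crispr_params <- function(repeat_len_range = c(23L, 55L),
                          spacer_len_range = c(20L, 60L),
                          min_repeats = 3L, max_repeat_mismatches = 0L) {
  stopifnot(length(repeat_len_range) == 2, repeat_len_range[1] < repeat_len_range[2],
            length(spacer_len_range) == 2, spacer_len_range[1] < spacer_len_range[2],
            min_repeats >= 2)
  if (max_repeat_mismatches != 0) {
    abort_validation("only exact repeat matching (max_repeat_mismatches = 0) is implemented")
  }
  list(repeat_len_range = as.integer(repeat_len_range),
       spacer_len_range = as.integer(spacer_len_range),
       min_repeats = as.integer(min_repeats),
       max_repeat_mismatches = as.integer(max_repeat_mismatches))
}

# Greedy maximal chains from sorted start positions of one repeat word.
# Returns a list of integer vectors (start positions, 0-based).
chain_positions <- function(pos, L, gap_range) {
  chains <- list()
  used <- rep(FALSE, length(pos))
  for (i in seq_along(pos)) {
    if (used[i]) next
    chain <- pos[i]
    used[i] <- TRUE
    last <- pos[i]
    repeat {
      gaps <- pos - (last + L)
      nxt <- which(!used & gaps >= gap_range[1] & gaps <= gap_range[2])
      if (!length(nxt)) break
      j <- nxt[1]
      chain <- c(chain, pos[j])
      used[j] <- TRUE
      last <- pos[j]
    }
    chains[[length(chains) + 1L]] <- chain
  }
  chains
}

#' Detect repeat-spacer arrays on one contig
#'
#' Scans repeat lengths from longest to shortest; for each length, repeated
#' words occurring at chain-compatible spacings form candidate arrays.
#' Arrays are accepted greedily (longest repeat first, then leftmost) and
#' never overlap. Intervals are 0-based half-open on the contig.
#'
#' @param contig single-row `contig_table` (or list with contig_id,
#'   sequence).
#' @param params see [crispr_params()].
#' @return data.frame with one row per array: contig_id, repeat_seq,
#'   spacers (comma-joined), n_spacers, start, end.
#' @export
detect_crispr_arrays <- function(contig, params = crispr_params()) {
  seq <- contig$sequence
  cid <- contig$contig_id
  n <- nchar(seq)
  empty <- data.frame(contig_id = character(0), repeat_seq = character(0),
                      spacers = character(0), n_spacers = integer(0),
                      start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  Lmin <- params$repeat_len_range[1]
  Lmax <- params$repeat_len_range[2]
  if (n < params$min_repeats * Lmin + (params$min_repeats - 1) * params$spacer_len_range[1]) {
    return(empty)
  }
  # fast precheck: any array implies some Lmin-mer occurring >= min_repeats
  subs_min <- substring(seq, 1:(n - Lmin + 1), Lmin:n)
  tab <- table(subs_min)
  if (!any(tab >= params$min_repeats)) return(empty)
  # restrict the heavy per-length scan to the hull of candidate word positions
  cand_pos <- which(subs_min %in% names(tab)[tab >= params$min_repeats])
  lo <- max(1L, min(cand_pos) - (Lmax - Lmin))
  hi <- min(n, max(cand_pos) + Lmax + params$spacer_len_range[2])
  arrays <- list()
  occupied <- logical(n)
  for (L in Lmax:Lmin) {
    if (hi - lo + 1 < L) next
    starts <- lo:(hi - L + 1)
    subs <- substring(seq, starts, starts + L - 1)
    grp <- split(starts, subs)
    grp <- grp[lengths(grp) >= params$min_repeats]
    if (!length(grp)) next
    cands <- list()
    for (word in names(grp)) {
      for (chain in chain_positions(sort(grp[[word]]) - 1L, L, params$spacer_len_range)) {
        if (length(chain) >= params$min_repeats) {
          cands[[length(cands) + 1L]] <- list(word = word, chain = chain, L = L)
        }
      }
    }
    if (!length(cands)) next
    cands <- cands[order(vapply(cands, function(x) x$chain[1], numeric(1)))]
    for (cd in cands) {
      a_start <- cd$chain[1]                       # 0-based
      a_end <- cd$chain[length(cd$chain)] + cd$L   # half-open
      if (any(occupied[(a_start + 1):a_end])) next
      spacers <- substring(seq, utils::head(cd$chain, -1) + cd$L + 1, cd$chain[-1])
      arrays[[length(arrays) + 1L]] <- data.frame(
        contig_id = cid, repeat_seq = cd$word,
        spacers = paste(spacers, collapse = ","),
        n_spacers = length(spacers),
        start = a_start, end = a_end, stringsAsFactors = FALSE)
      occupied[(a_start + 1):a_end] <- TRUE
    }
  }
  if (!length(arrays)) return(empty)
  out <- do.call(rbind, arrays)
  out[order(out$start), , drop = FALSE]
}

#' Detect arrays across a contig table
#'
#' @param contigs a `contig_table`.
#' @param params see [crispr_params()].
#' @return row-bound array table over all contigs.
#' @export
detect_crispr_all <- function(contigs, params = crispr_params()) {
  res <- lapply(seq_len(nrow(contigs)), function(i) {
    detect_crispr_arrays(contigs[i, , drop = FALSE], params)
  })
  do.call(rbind, res)
}

#' Extract spacers from detected arrays
#'
#' Spacers are emitted in genomic order per contig; byte-identical spacers
#' within a contig are flagged as duplicates (all occurrences kept).
#'
#' @param arrays array table from [detect_crispr_arrays()].
#' @return data.frame: contig_id, spacer_index, spacer, duplicate.
#' @export
extract_spacers <- function(arrays) {
  if (is.null(arrays) || !nrow(arrays)) {
    return(data.frame(contig_id = character(0), spacer_index = integer(0),
                      spacer = character(0), duplicate = logical(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(arrays)), function(i) {
    sp <- strsplit(arrays$spacers[i], ",", fixed = TRUE)[[1]]
    data.frame(contig_id = arrays$contig_id[i], spacer = sp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(out, out$contig_id), function(d) {
    d$spacer_index <- seq_len(nrow(d)) - 1L
    d$duplicate <- duplicated(d$spacer) | duplicated(d$spacer, fromLast = TRUE)
    d
  }))
  rownames(out) <- NULL
  out[, c("contig_id", "spacer_index", "spacer", "duplicate")]
}

#' Spacer burden statistic M = sum(N/L * A)
#'
#' For each CRISPR-carrying contig, N is its total spacer count (over all
#' arrays), L its length in bp and A its relative abundance (TPM) in the
#' given sample; M sums N/L * A over carrying contigs.
#'
#' @param arrays array table.
#' @param lengths named vector contig_id -> length (bp).
#' @param abundance named TPM vector for one sample.
#' @return list with `M` (scalar) and `contributions` (per-contig data.frame
#'   with N, L, A and the term N/L*A).
#' @export
spacer_burden <- function(arrays, lengths, abundance) {
  if (is.null(arrays) || !nrow(arrays)) {
    return(list(M = 0, contributions = data.frame(
      contig_id = character(0), N = integer(0), L = numeric(0), A = numeric(0),
      term = numeric(0), stringsAsFactors = FALSE)))
  }
  N <- tapply(arrays$n_spacers, arrays$contig_id, sum)
  ids <- names(N)
  missing_len <- ids[!ids %in% names(lengths)]
  if (length(missing_len)) abort_validation("no length for CRISPR contig(s): %s",
                                            paste(missing_len, collapse = ", "))
  missing_ab <- ids[!ids %in% names(abundance)]
  if (length(missing_ab)) abort_validation("no abundance for CRISPR contig(s): %s",
                                           paste(missing_ab, collapse = ", "))
  L <- as.numeric(lengths[ids])
  A <- as.numeric(abundance[ids])
  term <- as.numeric(N) / L * A
  list(M = sum(term),
       contributions = data.frame(contig_id = ids, N = as.integer(N), L = L, A = A,
                                  term = term, stringsAsFactors = FALSE))
}
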