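#' Dereplication parameters
#'
#' Defaults mirror the CD-HIT setting `-c 0.95 -aS 0.8`: cluster when the
#' best local alignment reaches 95% identity over its columns and covers at
#' least 80% of the shorter sequence.
#'
#' @param min_identity minimum alignment identity (matches / aligned columns,
#'   gaps included), in (0, 1].
#' @param min_short_coverage minimum aligned span on the shorter sequence as
#'   a fraction of its length, in (0, 1].
#' @param word_size k-mer length for the shared-word prefilter (>= 4).
#' @param match,mismatch,gap alignment scoring constants.
#' @return list of validated parameters.
#' @export
derep_params <- function(min_identity = 0.95, min_short_coverage = 0.8,
                         word_size = 16L, match = 1, mismatch = -1, gap = -2) {
  if (!(min_identity > 0 && min_identity <= 1)) abort_validation("min_identity must be in (0,1]")
  if (!(min_short_coverage > 0 && min_short_coverage <= 1)) {
    abort_validation("min_short_coverage must be in (0,1]")
  }
  if (word_size < 4) abort_validation("word_size must be >= 4")
  list(min_identity = min_identity, min_short_coverage = min_short_coverage,
       word_size = as.integer(word_size), match = match, mismatch = mismatch, gap = gap)
}

#' Pairwise identity and short-sequence coverage
#'
#' Best local alignment (match +1, mismatch -1, gap -2 by default); identity
#' is matches over aligned columns including gap columns, coverage is the
#' aligned span on the shorter sequence over its length. Symmetric in its
#' arguments (inputs are canonically ordered before aligning).
#'
#' @param a,b DNA sequences (character scalars) or single-row contig tables.
#' @param params see [derep_params()].
#' @return named numeric vector c(identity=, short_coverage=).
#' @export
pairwise_identity <- function(a, b, params = derep_params()) {
  seq_a <- if (is.character(a)) a else a$sequence
  seq_b <- if (is.character(b)) b else b$sequence
  stopifnot(nzchar(seq_a), nzchar(seq_b))
  # canonical order (longer first; ties lexicographic) makes the result
  # symmetric even when several alignments share the optimal score
  if (nchar(seq_b) > nchar(seq_a) || (nchar(seq_b) == nchar(seq_a) && seq_b < seq_a)) {
    tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                                  mismatch = params$mismatch)
  aln <- Biostrings::pairwiseAlignment(seq_b, seq_a, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = -params$gap)
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  if (cols == 0) return(c(identity = 0, short_coverage = 0))
  identity <- Biostrings::nmatch(aln) / cols
  short_len <- nchar(seq_b)  # seq_b is the shorter after canonical ordering
  span <- Biostrings::end(Biostrings::pattern(aln)) -
    Biostrings::start(Biostrings::pattern(aln)) + 1
  c(identity = identity, short_coverage = span / short_len)
}

# Smallest gap-free exact run guaranteed by the identity/coverage thresholds
# for a shorter-sequence length m (pigeonhole over admissible column counts).
# The k-mer prefilter is only sound when this run is >= word_size.
guaranteed_word <- function(m_short, m_long, params) {
  c0 <- ceiling(params$min_short_coverage * m_short)
  # the bound grows with the column count apart from floor jitter, so the
  # minimum sits near c0; a capped window keeps this O(1) per pair
  cs <- c0:min(m_short + m_long, c0 + 500L)
  errs <- floor((1 - params$min_identity) * cs)
  min(ceiling((cs - errs) / (errs + 1)))
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Greedy dereplication at identity/coverage thresholds
#'
#' CD-HIT-style greedy longest-first clustering: contigs are visited in
#' decreasing length order (ties broken by lexicographic contig_id); each
#' joins the first existing representative meeting both thresholds, else
#' founds a new cluster. A shared-k-mer prefilter skips alignments only when
#' the thresholds provably imply a shared exact word of `word_size`.
#'
#' @param contigs a `contig_table`.
#' @param params see [derep_params()].
#' @return list with `representatives` (contig_table subset) and
#'   `cluster_map` (named character vector contig_id -> representative_id;
#'   representatives map to themselves).
#' @export
dereplicate <- function(contigs, params = derep_params()) {
  if (anyDuplicated(contigs$contig_id)) abort_validation("duplicate contig ids")
  ord <- order(-contigs$length, contigs$contig_id)
  contigs <- contigs[ord, , drop = FALSE]
  reps <- integer(0)  # row indices of representatives
  assign <- character(nrow(contigs))
  rep_kmers <- list()
  for (i in seq_len(nrow(contigs))) {
    seq_i <- contigs$sequence[i]
    km_i <- NULL
    placed <- FALSE
    for (r in reps) {
      m_short <- contigs$length[i]  # visiting order ensures rep is >= length
      need <- guaranteed_word(m_short, contigs$length[r], params)
      if (need >= params$word_size) {
        if (is.null(km_i)) km_i <- kmer_set(seq_i, params$word_size)
        if (!any(km_i %in% rep_kmers[[as.character(r)]])) next
      }
      pid <- pairwise_identity(seq_i, contigs$sequence[r], params)
      if (pid[["identity"]] >= params$min_identity &&
          pid[["short_coverage"]] >= params$min_short_coverage) {
        assign[i] <- contigs$contig_id[r]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      rep_kmers[[as.character(i)]] <- kmer_set(seq_i, params$word_size)
      assign[i] <- contigs$contig_id[i]
    }
  }
  cluster_map <- stats::setNames(assign, contigs$contig_id)
  representatives <- contigs[reps, , drop = FALSE]
  list(representatives = representatives, cluster_map = cluster_map)
}
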