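#' @importFrom stats cor pt rbinom rlnorm rmultinom runif var
#' @importFrom utils read.delim write.table combn
NULL

# Internal validation helper: stop with a consistent error class so tests can
# distinguish validation failures from R-level errors.
abort_validation <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

#' Reverse-complement a DNA string
#'
#' @param x character vector of DNA sequences over A,C,G,T,N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Derive a stage-specific child seed from a master seed
#'
#' Fixed prime offsets keep the pipeline stages statistically independent
#' while remaining reproducible from one master seed; results stay below
#' the 32-bit integer limit.
#'
#' @param seed master seed (integer).
#' @param stage one of "contigs", "prophage", "crispr", "trna", "defense",
#'   "lifestyles", "genehits", "abundance", "reads", "stats".
#' @return integer child seed.
#' @export
child_seed <- function(seed, stage) {
  offsets <- c(
    contigs = 1L, prophage = 2L, crispr = 3L, trna = 4L, defense = 5L,
    lifestyles = 6L, genehits = 7L, abundance = 8L, reads = 9L, stats = 10L
  )
  if (!stage %in% names(offsets)) abort_validation("unknown seed stage '%s'", stage)
  as.integer((as.numeric(seed) * 31L + offsets[[stage]] * 10007) %% 2147483629)
}

# Uniform random DNA of given length (vectorised over n).
random_dna <- function(n) {
  vapply(n, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Upper-triangle vector of a square matrix (row-major pair order irrelevant,
# but must be consistent between two matrices of the same dimension).
upper_tri_vec <- function(m) m[upper.tri(m)]
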