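#' Contig table constructor
#'
#' Contigs are represented as a plain data.frame with one row per contig:
#' `contig_id`, `sequence` (uppercase DNA over A,C,G,T,N), `category`
#' (`prokaryotic`, `free_viral` or `prophage`), `length`, `genus` (NA when
#' unknown) and `lineage` (semicolon-joined `rank=taxon` pairs ordered from
#' least to most specific, NA when unknown).
#'
#' @param contig_id character vector of unique ids.
#' @param sequence character vector of DNA sequences.
#' @param category contig category, recycled.
#' @param genus optional genus labels.
#' @param lineage optional lineage strings.
#' @return data.frame of class `contig_table`.
#' @export
contig_table <- function(contig_id, sequence, category = "prokaryotic",
                         genus = NA_character_, lineage = NA_character_) {
  if (anyDuplicated(contig_id)) {
    abort_validation("duplicate contig_id: %s",
                     paste(unique(contig_id[duplicated(contig_id)]), collapse = ", "))
  }
  if (any(!nzchar(contig_id))) abort_validation("empty contig_id")
  category <- rep_len(category, length(contig_id))
  bad <- setdiff(unique(category), c("prokaryotic", "free_viral", "prophage"))
  if (length(bad)) abort_validation("unknown contig category: %s", paste(bad, collapse = ", "))
  sequence <- toupper(sequence)
  if (any(grepl("[^ACGTN]", sequence))) abort_validation("sequence contains non-ACGTN characters")
  df <- data.frame(
    contig_id = as.character(contig_id),
    sequence = sequence,
    category = category,
    length = nchar(sequence),
    genus = rep_len(as.character(genus), length(contig_id)),
    lineage = rep_len(as.character(lineage), length(contig_id)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("contig_table", "data.frame")
  df
}

#' Read a FASTA file into a contig table
#'
#' Sequences are uppercased and wrapped lines concatenated. IUPAC ambiguity
#' codes other than N are mapped to N with a warning; any other character is a
#' validation error reported with its line number. Duplicate header ids are an
#' error. Category defaults to `prokaryotic` until reclassified downstream.
#'
#' @param path path to a FASTA file.
#' @return a `contig_table`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (length(lines) && !hdr[1] && any(nzchar(trimws(lines)))) {
    abort_validation("line 1: expected FASTA header ('>')")
  }
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  buf <- character(0)
  iupac_extra <- "RYSWKMBDHV"
  flush <- function() {
    if (!is.null(cur)) {
      seqs[[length(seqs) + 1L]] <<- paste(buf, collapse = "")
      ids[[length(ids) + 1L]] <<- cur
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^>", ln)) {
      flush()
      cur <- sub("^>\\s*", "", ln)
      cur <- sub("\\s.*$", "", cur)
      if (!nzchar(cur)) abort_validation("line %d: empty FASTA header id", i)
      buf <- character(0)
    } else {
      s <- toupper(trimws(ln))
      if (!nzchar(s)) next
      bad <- gsub(sprintf("[ACGTN%s]", iupac_extra), "", s)
      if (nzchar(bad)) {
        abort_validation("line %d: non-IUPAC character(s) '%s' in sequence", i,
                         substr(bad, 1, 5))
      }
      if (grepl(sprintf("[%s]", iupac_extra), s)) {
        warning(sprintf("line %d: IUPAC ambiguity codes mapped to N", i), call. = FALSE)
        s <- gsub(sprintf("[%s]", iupac_extra), "N", s)
      }
      buf <- c(buf, s)
    }
  }
  flush()
  if (anyDuplicated(ids)) {
    abort_validation("duplicate FASTA id: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  contig_table(ids, seqs)
}

#' Write a contig table to FASTA
#'
#' @param contigs a `contig_table` (or data.frame with contig_id, sequence).
#' @param path output path.
#' @param width line width for sequence wrapping (>= 1).
#' @return invisibly, the path.
#' @export
write_fasta <- function(contigs, path, width = 70L) {
  if (width < 1) abort_validation("width must be >= 1")
  ss <- Biostrings::DNAStringSet(contigs$sequence)
  names(ss) <- contigs$contig_id
  Biostrings::writeXStringSet(ss, filepath = path, width = as.integer(width))
  invisible(path)
}

#' Read per-read alignment records
#'
#' The canonical dialect is a 3-column TSV with header
#' `read_id, contig_id, aligned_length`. The optional `sam` dialect parses
#' plain-text SAM: unmapped, secondary and supplementary records are skipped
#' and `aligned_length` is the summed M/=/X CIGAR length of the remaining
#' primary records.
#'
#' @param path input file.
#' @param dialect `"tsv"` (default) or `"sam"`.
#' @return data.frame with read_id, contig_id, aligned_length.
#' @export
read_alignments <- function(path, dialect = c("tsv", "sam")) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) abort_validation("unknown alignment dialect"))
  if (!file.exists(path)) stop(sprintf("alignment file not found: %s", path), call. = FALSE)
  if (dialect == "tsv") {
    df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                     colClasses = c("character", "character", "integer"))
    names(df) <- c("read_id", "contig_id", "aligned_length")
    if (nrow(df) && any(df$aligned_length < 0)) {
      abort_validation("negative aligned_length in %s", path)
    }
    return(df)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^@", lines)]
  if (!length(lines)) {
    return(data.frame(read_id = character(0), contig_id = character(0),
                      aligned_length = integer(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_total <- length(fields)
  recs <- lapply(fields, function(f) {
    flag <- as.integer(f[[2]])
    # skip unmapped (0x4), secondary (0x100), supplementary (0x800)
    if (bitwAnd(flag, 4L) != 0L || bitwAnd(flag, 256L) != 0L || bitwAnd(flag, 2048L) != 0L) {
      return(NULL)
    }
    data.frame(read_id = f[[1]], contig_id = f[[3]],
               aligned_length = cigar_aligned_length(f[[6]]),
               stringsAsFactors = FALSE)
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  message(sprintf("read_alignments(sam): kept %d of %d records", length(recs), n_total))
  if (!length(recs)) {
    return(data.frame(read_id = character(0), contig_id = character(0),
                      aligned_length = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, recs)
}

# Sum of M/=/X operation lengths in a CIGAR string.
cigar_aligned_length <- function(cigar) {
  if (cigar == "*") return(0L)
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  kinds <- sub("^[0-9]+", "", ops)
  sum(lens[kinds %in% c("M", "=", "X")])
}

#' Write alignment records as canonical TSV
#'
#' @param records data.frame with read_id, contig_id, aligned_length.
#' @param path output path.
#' @export
write_alignments <- function(records, path) {
  write.table(records[, c("read_id", "contig_id", "aligned_length")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `condition` (disinfected / non_disinfected)
#' and any number of numeric covariate columns (e.g. chlorine, phosphate).
#'
#' @param path input TSV.
#' @return data.frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) abort_validation("duplicate sample_id in %s", path)
  bad <- setdiff(unique(df$condition), c("disinfected", "non_disinfected"))
  if (length(bad)) abort_validation("unknown condition: %s", paste(bad, collapse = ", "))
  cov <- setdiff(names(df), c("sample_id", "condition"))
  for (cc in cov) {
    if (!all(is.finite(df[[cc]]))) abort_validation("non-finite covariate '%s'", cc)
  }
  df
}
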