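#' Genome sequence container
#'
#' Holds uppercase chromosome sequences over the alphabet A/C/G/T/N and
#' caches per-chromosome cumulative counts of unambiguous (non-N) bases so
#' that attributable-base totals over many intervals are cheap.
#'
#' @param seqs named character vector, one uppercase DNA string per
#'   chromosome. Names are the chromosome identifiers.
#' @return an object of class `GenomeSequence`.
#' @export
GenomeSequence <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    format_error("chromosome names must be present and unique")
  seqs <- toupper(unlist(seqs))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    format_error("non-IUPAC characters in chromosome(s): ",
                 paste(names(seqs)[bad], collapse = ", "))
  if (any(nchar(seqs) < 1L))
    format_error("every chromosome must have length >= 1")
  obj <- list(seqs = seqs,
              lengths = stats::setNames(nchar(seqs), names(seqs)),
              cache = new.env(parent = emptyenv()))
  class(obj) <- "GenomeSequence"
  obj
}

#' @export
print.GenomeSequence <- function(x, ...) {
  cat("GenomeSequence with", length(x$seqs), "chromosome(s):\n")
  print(x$lengths)
  invisible(x)
}

#' Chromosome names of a genome
#' @param genome a `GenomeSequence`.
#' @return character vector of chromosome identifiers.
#' @export
chrom_names <- function(genome) names(genome$seqs)

#' Chromosome lengths of a genome
#' @param genome a `GenomeSequence`.
#' @return named integer vector.
#' @export
chrom_lengths <- function(genome) genome$lengths

#' Extract genome sequence for 0-based half-open intervals
#'
#' @param genome a `GenomeSequence`.
#' @param chrom chromosome identifier (scalar or vector recycled with
#'   `start`/`end`).
#' @param start,end 0-based half-open interval bounds.
#' @return character vector of sequences.
#' @export
genome_seq <- function(genome, chrom, start, end) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n); end <- rep_len(end, n)
  bad_chrom <- !(chrom %in% names(genome$seqs))
  if (any(bad_chrom))
    input_error("unknown chromosome(s): ",
                paste(unique(chrom[bad_chrom]), collapse = ", "))
  len <- genome$lengths[chrom]
  if (any(start < 0L | end > len | start > end))
    input_error("interval outside chromosome bounds")
  out <- character(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    out[i] <- substring(genome$seqs[[ch]], start[i] + 1L, end[i])
  }
  out
}

# Cumulative count of attributable (non-N) bases, cached per chromosome.
attributable_cumsum <- function(genome, chrom) {
  key <- paste0("acgt_", chrom)
  if (!is.null(genome$cache[[key]])) return(genome$cache[[key]])
  s <- strsplit(genome$seqs[[chrom]], "", fixed = TRUE)[[1]]
  cs <- cumsum(s != "N")
  genome$cache[[key]] <- cs
  cs
}

#' Count attributable bases in intervals
#'
#' Attributable bases are A, C, G and T; ambiguous positions (N) are never
#' counted. Intervals are 0-based half-open.
#'
#' @param genome a `GenomeSequence`.
#' @param chrom chromosome identifiers (vectorised).
#' @param start,end 0-based half-open interval bounds.
#' @return integer vector of attributable-base counts per interval.
#' @export
attributable_bases <- function(genome, chrom, start, end) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n); end <- rep_len(end, n)
  out <- integer(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    cs <- attributable_cumsum(genome, ch)
    lo <- start[i]; hi <- end[i]
    if (any(lo < 0L | hi > length(cs) | lo > hi))
      input_error("interval outside chromosome bounds on ", ch)
    out[i] <- cs[pmax(hi, 1L)] * (hi > 0L) -
      ifelse(lo > 0L, cs[pmax(lo, 1L)], 0L)
    out[i][hi == 0L] <- 0L
  }
  as.integer(out)
}

#' Read a genome from a FASTA file
#'
#' Sequences are uppercased; duplicate headers and non-IUPAC characters are
#' format errors.
#'
#' @param path path to a FASTA file.
#' @return a `GenomeSequence`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) input_error("no such file: ", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) format_error("FASTA parse error: ",
                                                  conditionMessage(e)),
                 warning = function(w)
                   format_error("invalid sequence characters in ", path,
                                ": ", conditionMessage(w)))
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) format_error("duplicate FASTA headers in ", path)
  GenomeSequence(stats::setNames(as.character(ss), nm))
}

#' Write a genome to a FASTA file
#' @param genome a `GenomeSequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chrom_names(genome)) {
    writeLines(paste0(">", ch), con)
    s <- genome$seqs[[ch]]
    starts <- seq(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}
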