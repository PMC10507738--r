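#' Signal track container
#'
#' A per-chromosome step function: sorted, non-overlapping 0-based
#' half-open segments each carrying one numeric signal value. Queries
#' outside covered segments return the configured missing value (0 by
#' default), mirroring sparse genome-wide assay exports where absent
#' signal means no measured occupancy.
#'
#' @param df data frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open).
#' @param missing_value value returned for uncovered positions.
#' @return an object of class `signal_track`.
#' @export
signal_track <- function(df, missing_value = 0) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  if (any(df$start >= df$end)) format_error("segment with start >= end")
  by_chrom <- split(df[c("start", "end", "value")], df$chrom)
  for (ch in names(by_chrom)) {
    seg <- by_chrom[[ch]]
    if (is.unsorted(seg$start, strictly = TRUE) ||
        any(seg$start[-1L] < seg$end[-nrow(seg)]))
      format_error("unsorted or overlapping segments on ", ch)
    rownames(by_chrom[[ch]]) <- NULL
  }
  structure(list(segments = by_chrom, missing_value = missing_value,
                 cache = new.env(parent = emptyenv())),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  nseg <- vapply(x$segments, nrow, integer(1))
  cat("signal_track:", sum(nseg), "segments on", length(nseg),
      "chromosome(s)\n")
  invisible(x)
}

#' Segments of a signal track as one data frame
#' @param track a `signal_track`.
#' @return data frame with `chrom`, `start`, `end`, `value`.
#' @export
track_segments <- function(track) {
  out <- do.call(rbind, lapply(names(track$segments), function(ch) {
    cbind(data.frame(chrom = ch), track$segments[[ch]])
  }))
  rownames(out) <- NULL
  out
}

#' Query a signal track at single positions
#'
#' @param track a `signal_track`.
#' @param chrom chromosome identifiers (vectorised with `pos`).
#' @param pos 0-based positions.
#' @return numeric vector of signal values; uncovered positions yield the
#'   track's missing value. The number of uncovered queries is attached as
#'   attribute `n_gap`.
#' @export
track_values <- function(track, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out <- rep(track$missing_value, n)
  gaps <- 0L
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    seg <- track$segments[[ch]]
    if (is.null(seg)) { gaps <- gaps + length(i); next }
    j <- findInterval(pos[i], seg$start)
    hit <- j >= 1L & pos[i] < seg$end[pmax(j, 1L)]
    out[i][hit] <- seg$value[j[hit]]
    gaps <- gaps + sum(!hit)
  }
  attr(out, "n_gap") <- gaps
  out
}

#' Dense per-base signal vector for one chromosome
#'
#' Expands the step function into a numeric vector of length `len`
#' (position `i` of the vector is 0-based genome position `i - 1`), filling
#' gaps with the missing value. Used by the occupancy machinery, where many
#' overlapping windows make per-query lookups wasteful.
#'
#' @param track a `signal_track`.
#' @param chrom chromosome identifier.
#' @param len chromosome length in bases.
#' @return numeric vector of length `len`.
#' @export
track_base_vector <- function(track, chrom, len) {
  key <- paste0(chrom, "_", len)
  cached <- track$cache[[key]]
  if (!is.null(cached)) return(cached)
  out <- rep(track$missing_value, len)
  seg <- track$segments[[chrom]]
  if (!is.null(seg)) {
    seg <- seg[seg$start < len, , drop = FALSE]
    for (k in seq_len(nrow(seg))) {
      out[(seg$start[k] + 1L):min(seg$end[k], len)] <- seg$value[k]
    }
  }
  track$cache[[key]] <- out
  out
}

#' Read a signal track from wig or bedGraph
#'
#' Supported dialects are fixed-step wig, variable-step wig and bedGraph.
#' wig coordinates (1-based) are converted to the internal 0-based
#' half-open convention; bedGraph is already 0-based. Overlapping or
#' unsorted segments are a format error, never repaired.
#'
#' @param path input file.
#' @param dialect one of `"wig-fixedStep"`, `"wig-variableStep"`,
#'   `"bedGraph"`.
#' @param missing_value value for uncovered positions (default 0).
#' @return a `signal_track`.
#' @export
read_signal_track <- function(path,
                              dialect = c("wig-fixedStep",
                                          "wig-variableStep", "bedGraph"),
                              missing_value = 0) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) input_error("no such file: ", path)
  head_lines <- readLines(path, n = 50L)
  declared <- if (dialect == "wig-fixedStep") "fixedStep"
  else if (dialect == "wig-variableStep") "variableStep" else NULL
  if (!is.null(declared) && !any(grepl(declared, head_lines, fixed = TRUE)))
    format_error(path, " does not contain a ", declared, " declaration")
  fmt <- if (dialect == "bedGraph") "bedGraph" else "wig"
  gr <- tryCatch(rtracklayer::import(path, format = fmt),
                 error = function(e) format_error("track parse error: ",
                                                  conditionMessage(e)))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   value = gr$score)
  signal_track(df, missing_value = missing_value)
}

#' Read a BED3 file as an interval set
#'
#' BED is 0-based half-open; no coordinate conversion is applied.
#'
#' @param path BED file.
#' @return data frame with `chrom`, `start`, `end` (and `name` if present),
#'   sorted by (chrom, start).
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) input_error("no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) format_error("BED parse error: ",
                                                  conditionMessage(e)))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  if (!is.null(gr$name)) df$name <- gr$name
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Read protein-coding gene annotations from BED6
#'
#' Strand is mandatory: genes without a `+`/`-` strand are a format error.
#'
#' @param path BED6 file (name column carries the gene id).
#' @return data frame with `chrom`, `start`, `end`, `strand`, `gene_id`.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) input_error("no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) format_error("BED parse error: ",
                                                  conditionMessage(e)))
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    format_error("gene file ", path, " has records without strand")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = strand,
                   gene_id = if (!is.null(gr$name)) gr$name else
                     paste0("gene", seq_along(gr)))
  if (any(df$start >= df$end)) format_error("gene with start >= end")
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Write intervals as BED3
#' @param df data frame with `chrom`, `start`, `end` (0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(df, path) {
  utils::write.table(df[c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a signal track as fixed-step wig (step 1) or bedGraph
#' @param track a `signal_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path) {
  df <- track_segments(track)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
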