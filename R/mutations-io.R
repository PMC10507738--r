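# Mutation tables use 0-based positions internally. VCF input (1-based) is
# converted at the boundary; the TSV dialect written by this package is
# already 0-based. Indels are stored anchor-free: deletions carry the
# deleted sequence in `ref` and an empty `alt`; insertions the reverse,
# with `pos` the 0-based base before which the sequence is inserted.
# "-" stands for the empty side on disk.

mutation_frame <- function(sample = character(0), chrom = character(0),
                           pos = integer(0), ref = character(0),
                           alt = character(0)) {
  type <- mutation_type(ref, alt)
  data.frame(sample = sample, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, type = type)
}

mutation_type <- function(ref, alt) {
  n_ref <- nchar(ref); n_alt <- nchar(alt)
  ifelse(n_ref == 1L & n_alt == 1L, "SBS",
         ifelse(n_ref == 2L & n_alt == 2L, "DBS",
                ifelse(n_ref != n_alt, "ID", NA_character_)))
}

#' Read a somatic mutation catalog
#'
#' Two dialects are supported. `tsv` is the package's own five-column
#' table (`sample`, `chrom`, `pos`, `ref`, `alt`; 0-based positions, `-`
#' for the empty side of an indel). `vcf` is a minimal VCF subset: the
#' fixed columns are parsed, the 1-based POS is converted to 0-based, and
#' anchored indel records are normalised to the anchor-free
#' representation. Sample ids for VCF come from the file name unless an
#' explicit `sample` is given.
#'
#' Records whose alleles cannot be typed (equal-length multi-nucleotide
#' substitutions longer than 2, or non-prefix-anchored indels) are skipped;
#' the number skipped is attached as attribute `n_skipped`.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param sample sample id override for VCF input.
#' @return data frame with `sample`, `chrom`, `pos`, `ref`, `alt`, `type`,
#'   sorted by (chrom, pos).
#' @export
read_mutations <- function(path, dialect = c("tsv", "vcf"), sample = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) input_error("no such file: ", path)
  if (dialect == "tsv") {
    df <- tryCatch(utils::read.table(path, header = TRUE, sep = "\t",
                                     colClasses = c("character", "character",
                                                    "integer", "character",
                                                    "character")),
                   error = function(e) {
                     if (length(readLines(path, n = 2L)) <= 1L)
                       return(NULL)
                     format_error("mutation table parse error: ",
                                  conditionMessage(e))
                   })
    if (is.null(df) || nrow(df) == 0L) {
      warning("empty mutation file: ", path)
      out <- mutation_frame()
      attr(out, "n_skipped") <- 0L
      return(out)
    }
    names(df)[1:5] <- c("sample", "chrom", "pos", "ref", "alt")
    df$ref[df$ref == "-"] <- ""
    df$alt[df$alt == "-"] <- ""
    out <- mutation_frame(df$sample, df$chrom, df$pos, df$ref, df$alt)
    skipped <- sum(is.na(out$type))
    out <- out[!is.na(out$type), , drop = FALSE]
  } else {
    v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) format_error("VCF parse error: ",
                                                   conditionMessage(e)))
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    if (nrow(fix) == 0L) {
      warning("empty mutation file: ", path)
      out <- mutation_frame()
      attr(out, "n_skipped") <- 0L
      return(out)
    }
    sid <- if (is.null(sample))
      sub("\\.vcf(\\.gz)?$", "", basename(path)) else sample
    norm <- normalize_vcf_alleles(as.integer(fix[, "POS"]) - 1L,
                                  fix[, "REF"], fix[, "ALT"])
    skipped <- sum(!norm$ok)
    out <- mutation_frame(rep(sid, sum(norm$ok)),
                          fix[norm$ok, "CHROM"], norm$pos[norm$ok],
                          norm$ref[norm$ok], norm$alt[norm$ok])
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  if (skipped > 0L)
    warning(skipped, " unsupported record(s) skipped in ", path)
  attr(out, "n_skipped") <- skipped
  out
}

# Convert anchored VCF REF/ALT pairs into the internal representation.
normalize_vcf_alleles <- function(pos0, ref, alt) {
  n <- length(pos0)
  out_pos <- pos0; out_ref <- ref; out_alt <- alt
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]
    nr <- nchar(r); na <- nchar(a)
    if (nr == na) {
      if (nr == 1L && r != a) next
      if (nr == 2L && substr(r, 1, 1) != substr(a, 1, 1) &&
          substr(r, 2, 2) != substr(a, 2, 2)) next
      ok[i] <- FALSE
    } else if (nr > na && startsWith(r, a)) {
      out_pos[i] <- pos0[i] + na
      out_ref[i] <- substr(r, na + 1L, nr)
      out_alt[i] <- ""
    } else if (na > nr && startsWith(a, r)) {
      out_pos[i] <- pos0[i] + nr
      out_ref[i] <- ""
      out_alt[i] <- substr(a, nr + 1L, na)
    } else {
      ok[i] <- FALSE
    }
  }
  list(pos = out_pos, ref = out_ref, alt = out_alt, ok = ok)
}

#' Write a mutation catalog in the package TSV dialect
#' @param muts mutation data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(muts, path) {
  out <- muts[c("sample", "chrom", "pos", "ref", "alt")]
  out$ref[out$ref == ""] <- "-"
  out$alt[out$alt == ""] <- "-"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-mutation signature probability table
#'
#' A TSV keyed by (`sample`, `chrom`, `pos`) with one column per signature
#' holding the probability that the signature generated the mutation. Each
#' row must sum to 1 within 1e-6.
#'
#' @param path input TSV.
#' @return data frame with key columns and signature probability columns;
#'   signature column names are recorded in attribute `signatures`.
#' @export
read_probabilities <- function(path) {
  if (!file.exists(path)) input_error("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  key <- c("sample", "chrom", "pos")
  if (!all(key %in% names(df)))
    format_error("probability table must have sample/chrom/pos columns")
  sigs <- setdiff(names(df), key)
  if (length(sigs) == 0L) format_error("no signature columns in ", path)
  sums <- rowSums(df[sigs])
  if (any(abs(sums - 1) > 1e-6))
    format_error("probability rows must sum to 1 (max deviation ",
                 format(max(abs(sums - 1))), ")")
  attr(df, "signatures") <- sigs
  df
}

#' Write a result table as TSV
#'
#' Deterministic, header-carrying writer used for every result the
#' pipeline emits; `read_result_table()` round-trips it.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_result_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
}
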