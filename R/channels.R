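#' Mutational channel schemes
#'
#' Enumerations of the standard mutation classification schemas: the six
#' pyrimidine-oriented substitution classes (SBS-6), their trinucleotide
#' expansion (SBS-96), the doublet-base substitution catalogue (DBS-78) and
#' the small insertion/deletion catalogue (ID-83).
#'
#' @return character vector of channel labels, in canonical order.
#' @name channel_schemes
NULL

#' @rdname channel_schemes
#' @export
sbs6_channels <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' @rdname channel_schemes
#' @export
sbs96_channels <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (cls in sbs6_channels())
    for (p5 in bases)
      for (p3 in bases)
        out <- c(out, paste0(p5, "[", cls, "]", p3))
  out
}

# The canonical DBS-78 catalogue: ten reference doublets (maximum pyrimidine
# orientation) with the alternate doublets retained after reverse-complement
# collapse. This table is normative; classification maps onto it.
.dbs78 <- c(
  "AC>CA","AC>CG","AC>CT","AC>GA","AC>GG","AC>GT","AC>TA","AC>TG","AC>TT",
  "AT>CA","AT>CC","AT>CG","AT>GA","AT>GC","AT>TA",
  "CC>AA","CC>AG","CC>AT","CC>GA","CC>GG","CC>GT","CC>TA","CC>TG","CC>TT",
  "CG>AT","CG>GC","CG>GT","CG>TA","CG>TC","CG>TT",
  "CT>AA","CT>AC","CT>AG","CT>GA","CT>GC","CT>GG","CT>TA","CT>TC","CT>TG",
  "GC>AA","GC>AG","GC>AT","GC>CA","GC>CG","GC>TA",
  "TA>AT","TA>CG","TA>CT","TA>GC","TA>GG","TA>GT",
  "TC>AA","TC>AG","TC>AT","TC>CA","TC>CG","TC>CT","TC>GA","TC>GG","TC>GT",
  "TG>AA","TG>AC","TG>AT","TG>CA","TG>CC","TG>CT","TG>GA","TG>GC","TG>GT",
  "TT>AA","TT>AC","TT>AG","TT>CA","TT>CC","TT>CG","TT>GA","TT>GC","TT>GG")

#' @rdname channel_schemes
#' @export
dbs78_channels <- function() .dbs78

#' @rdname channel_schemes
#' @export
id83_channels <- function() {
  out <- character(0)
  for (b in c("C", "T")) out <- c(out, paste0("1:Del:", b, ":", 0:5))
  for (b in c("C", "T")) out <- c(out, paste0("1:Ins:", b, ":", 0:5))
  for (l in 2:5) out <- c(out, paste0(l, ":Del:R:", 0:5))
  for (l in 2:5) out <- c(out, paste0(l, ":Ins:R:", 0:5))
  out <- c(out, "2:Del:M:1", "3:Del:M:1", "3:Del:M:2",
           paste0("4:Del:M:", 1:3), paste0("5:Del:M:", 1:5))
  out
}

#' Channel scheme lookup
#'
#' @param name one of `"SBS6"`, `"SBS96"`, `"DBS78"`, `"ID83"`.
#' @return list with `name` and the ordered `channels` vector.
#' @export
channel_scheme <- function(name = c("SBS6", "SBS96", "DBS78", "ID83")) {
  name <- match.arg(name)
  channels <- switch(name,
                     SBS6 = sbs6_channels(), SBS96 = sbs96_channels(),
                     DBS78 = dbs78_channels(), ID83 = id83_channels())
  list(name = name, channels = channels)
}

#' Classify single-base substitutions into SBS-96 channels
#'
#' Each substitution is oriented on the pyrimidine strand: when the
#' reference base is a purine, the mutated base and both flanks are
#' reverse-complemented before labelling. The label has the form
#' `X[R>A]Y` with `R` in {C, T}.
#'
#' @param muts data frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`; rows must be single-base substitutions.
#' @param genome a `GenomeSequence`; `ref` must match the genome at `pos`.
#' @return character vector of SBS-96 labels; `NA` where the focal base or
#'   a flank is `N` (unclassifiable), or where a flank falls outside the
#'   chromosome.
#' @export
classify_sbs <- function(muts, genome) {
  if (nrow(muts) == 0L) return(character(0))
  stopifnot(all(nchar(muts$ref) == 1L), all(nchar(muts$alt) == 1L))
  len <- genome$lengths[muts$chrom]
  inb <- muts$pos >= 1L & muts$pos <= len - 2L
  out <- rep(NA_character_, nrow(muts))
  if (any(inb)) {
    tri <- genome_seq(genome, muts$chrom[inb], muts$pos[inb] - 1L,
                      muts$pos[inb] + 2L)
    focal <- substr(tri, 2L, 2L)
    if (any(focal != muts$ref[inb] & focal != "N"))
      input_error("ref allele does not match genome sequence")
    ok <- !grepl("N", tri, fixed = TRUE)
    ref <- muts$ref[inb]; alt <- muts$alt[inb]
    flip <- !is_pyrimidine(ref)
    tri[flip] <- revcomp(tri[flip])
    ref[flip] <- complement_base(ref[flip])
    alt[flip] <- complement_base(alt[flip])
    lab <- paste0(substr(tri, 1L, 1L), "[", ref, ">", alt, "]",
                  substr(tri, 3L, 3L))
    lab[!ok] <- NA_character_
    out[inb] <- lab
  }
  out
}

#' Six-class substitution channel of SBS mutations
#'
#' Pyrimidine-oriented `R>A` class, e.g. `"C>T"`; independent of flanks so
#' no genome is needed.
#'
#' @param ref,alt single-base reference and alternate alleles.
#' @return character vector of SBS-6 labels; `NA` for alleles containing N.
#' @export
classify_sbs6 <- function(ref, alt) {
  flip <- !is_pyrimidine(ref)
  ref[flip] <- complement_base(ref[flip])
  alt[flip] <- complement_base(alt[flip])
  lab <- paste0(ref, ">", alt)
  lab[!lab %in% sbs6_channels()] <- NA_character_
  lab
}

#' Pyrimidine reference strand of a mutation
#'
#' `"+"` when the canonical (pyrimidine-oriented) representation of the
#' reference allele already lies on the plus strand, `"-"` when the alleles
#' had to be reverse-complemented. For indels the first base of the
#' inserted/deleted sequence decides.
#'
#' @param ref,alt allele strings; empty string denotes the anchor-free side
#'   of an indel.
#' @return character vector of `"+"`/`"-"` (NA where undecidable).
#' @export
pyrimidine_strand <- function(ref, alt) {
  n_ref <- nchar(ref)
  n_alt <- nchar(alt)
  out <- rep(NA_character_, length(ref))
  sbs <- n_ref == 1L & n_alt == 1L
  out[sbs] <- ifelse(is_pyrimidine(ref[sbs]), "+", "-")
  dbs <- n_ref == 2L & n_alt == 2L
  if (any(dbs)) {
    canon_ref <- substr(.dbs78, 1L, 2L)
    out[dbs] <- ifelse(ref[dbs] %in% canon_ref, "+",
                       ifelse(revcomp(ref[dbs]) %in% canon_ref, "-", NA))
  }
  id <- n_ref != n_alt
  if (any(id)) {
    seqs <- ifelse(n_ref[id] > n_alt[id], ref[id], alt[id])
    b1 <- substr(seqs, 1L, 1L)
    out[id] <- ifelse(is_pyrimidine(b1), "+",
                      ifelse(b1 %in% c("A", "G"), "-", NA))
  }
  out
}

#' Classify doublet-base substitutions into DBS-78 channels
#'
#' Collapses each doublet substitution and its reverse complement onto the
#' canonical member of the 78-channel catalogue.
#'
#' @param ref,alt two-base reference and alternate alleles differing at
#'   both positions.
#' @return character vector of DBS-78 labels; `NA` for alleles containing N.
#' @export
classify_dbs <- function(ref, alt) {
  stopifnot(all(nchar(ref) == 2L), all(nchar(alt) == 2L))
  cand1 <- paste0(ref, ">", alt)
  cand2 <- paste0(revcomp(ref), ">", revcomp(alt))
  out <- ifelse(cand1 %in% .dbs78, cand1,
                ifelse(cand2 %in% .dbs78, cand2, NA_character_))
  out
}

# Number of whole copies of `unit` repeated immediately from `from`
# (0-based) moving right (dir = +1) or whose last copy ends at `from`
# moving left (dir = -1), within sequence s (character scalar).
count_unit_copies <- function(s, unit, from, dir) {
  k <- nchar(unit)
  n <- nchar(s)
  copies <- 0L
  pos <- from
  repeat {
    if (dir > 0) {
      if (pos + k > n) break
      if (substr(s, pos + 1L, pos + k) != unit) break
      copies <- copies + 1L
      pos <- pos + k
    } else {
      if (pos - k < 0L) break
      if (substr(s, pos - k + 1L, pos) != unit) break
      copies <- copies + 1L
      pos <- pos - k
    }
  }
  copies
}

# Longest microhomology between a deleted sequence and its flanks: either a
# prefix of the deletion repeated immediately 3' of it, or a suffix
# repeated immediately 5'. Both directions checked, maximum returned.
microhomology_length <- function(s, del_seq, start) {
  L <- nchar(del_seq)
  n <- nchar(s)
  best <- 0L
  for (m in seq_len(L - 1L)) {
    if (start + L + m <= n &&
        substr(s, start + L + 1L, start + L + m) == substr(del_seq, 1L, m))
      best <- max(best, m)
    if (start - m >= 0L &&
        substr(s, start - m + 1L, start) ==
          substr(del_seq, L - m + 1L, L))
      best <- max(best, m)
  }
  best
}

id83_label_one <- function(chrom_seq, pos, ref, alt) {
  is_del <- nchar(ref) > nchar(alt)
  seqv <- if (is_del) ref else alt
  L <- nchar(seqv)
  if (L == 0L || grepl("N", seqv, fixed = TRUE)) return(NA_character_)
  n <- nchar(chrom_seq)
  if (is_del && (pos < 0L || pos + L > n)) return(NA_character_)
  if (!is_del && (pos < 0L || pos > n)) return(NA_character_)
  if (is_del && substr(chrom_seq, pos + 1L, pos + L) != seqv)
    input_error("deleted sequence does not match genome")
  size_cls <- min(L, 5L)
  if (L == 1L) {
    base <- seqv
    pyr <- if (is_pyrimidine(base)) base else complement_base(base)
    if (is_del) {
      run <- 1L + count_unit_copies(chrom_seq, base, pos + 1L, +1L) +
        count_unit_copies(chrom_seq, base, pos, -1L)
      return(paste0("1:Del:", pyr, ":", min(run - 1L, 5L)))
    }
    run <- count_unit_copies(chrom_seq, base, pos, +1L) +
      count_unit_copies(chrom_seq, base, pos, -1L)
    return(paste0("1:Ins:", pyr, ":", min(run, 5L)))
  }
  if (is_del) {
    copies <- 1L + count_unit_copies(chrom_seq, seqv, pos + L, +1L) +
      count_unit_copies(chrom_seq, seqv, pos, -1L)
    if (copies >= 2L)
      return(paste0(size_cls, ":Del:R:", min(copies - 1L, 5L)))
    mh <- microhomology_length(chrom_seq, seqv, pos)
    if (mh >= 1L)
      return(paste0(size_cls, ":Del:M:", min(mh, size_cls - 1L, 5L)))
    return(paste0(size_cls, ":Del:R:0"))
  }
  copies <- count_unit_copies(chrom_seq, seqv, pos, +1L) +
    count_unit_copies(chrom_seq, seqv, pos, -1L)
  paste0(size_cls, ":Ins:R:", min(copies, 5L))
}

#' Classify small insertions and deletions into ID-83 channels
#'
#' Indels are represented anchor-free: a deletion has `ref` equal to the
#' deleted sequence and empty `alt`; an insertion has empty `ref` and `alt`
#' equal to the inserted sequence, placed before `pos`. Labels follow the
#' standard 83-channel scheme: single-base events are typed by the
#' pyrimidine of the affected base and its homopolymer run, longer events
#' by their size, flanking tandem-repeat copy number, or deletion
#' microhomology.
#'
#' @param muts data frame with `chrom`, `pos` (0-based), `ref`, `alt`.
#' @param genome a `GenomeSequence`.
#' @return character vector of ID-83 labels; `NA` where the needed context
#'   overruns the chromosome or contains N.
#' @export
classify_id <- function(muts, genome) {
  if (nrow(muts) == 0L) return(character(0))
  out <- character(nrow(muts))
  for (i in seq_len(nrow(muts))) {
    out[i] <- id83_label_one(genome$seqs[[muts$chrom[i]]], muts$pos[i],
                             muts$ref[i], muts$alt[i])
  }
  out
}

#' Channel labels for a mixed mutation table
#'
#' Dispatches on mutation type: SBS rows get SBS-96 labels, DBS rows
#' DBS-78 labels, ID rows ID-83 labels.
#'
#' @param muts mutation data frame with `type` in {SBS, DBS, ID}.
#' @param genome a `GenomeSequence`.
#' @return character vector of channel labels (NA = unclassifiable).
#' @export
classify_mutations <- function(muts, genome) {
  out <- rep(NA_character_, nrow(muts))
  i <- which(muts$type == "SBS")
  if (length(i)) out[i] <- classify_sbs(muts[i, , drop = FALSE], genome)
  i <- which(muts$type == "DBS")
  if (length(i)) out[i] <- classify_dbs(muts$ref[i], muts$alt[i])
  i <- which(muts$type == "ID")
  if (length(i)) out[i] <- classify_id(muts[i, , drop = FALSE], genome)
  out
}
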