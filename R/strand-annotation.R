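# Transcription- and replication-strand annotation. Both annotations are
# driven by where the mutation's pyrimidine base lies: mutations are called
# on the + strand of the reference and oriented by their pyrimidine
# context, so a mutation whose canonical representation required
# reverse-complementing has its pyrimidine on the - strand.

#' Transcription-strand labels for mutations
#'
#' A mutation inside a protein-coding gene is `TRANSCRIBED` when its
#' pyrimidine base lies on the gene's template (transcribed) strand and
#' `UNTRANSCRIBED` when it lies on the coding strand. Mutations covered by
#' genes annotated on both strands are `EXCLUDED_BIDIRECTIONAL` and
#' ignored by the asymmetry tests; mutations outside all genes are
#' `NONTRANSCRIBED`.
#'
#' @param muts mutation data frame with `chrom`, `pos` and a `pyr_strand`
#'   column (see [pyrimidine_strand()]); `attribute_mutations()` adds it.
#' @param genes gene annotation data frame (`chrom`, `start`, `end`,
#'   `strand`), 0-based half-open.
#' @return character vector of labels, one per mutation.
#' @export
annotate_transcription <- function(muts, genes) {
  n <- nrow(muts)
  out <- rep("NONTRANSCRIBED", n)
  if (n == 0L) return(out)
  if (is.null(muts$pyr_strand))
    muts$pyr_strand <- pyrimidine_strand(muts$ref, muts$alt)
  for (ch in unique(muts$chrom)) {
    mi <- which(muts$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) next
    q <- IRanges::IRanges(start = muts$pos[mi] + 1L, width = 1L)
    s <- IRanges::IRanges(start = g$start + 1L, end = g$end)
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) == 0L) next
    hit_q <- S4Vectors::queryHits(ov)
    hit_s <- S4Vectors::subjectHits(ov)
    plus <- tapply(g$strand[hit_s] == "+", hit_q, any)
    minus <- tapply(g$strand[hit_s] == "-", hit_q, any)
    qi <- as.integer(names(plus))
    lab <- character(length(qi))
    both <- plus & minus
    lab[both] <- "EXCLUDED_BIDIRECTIONAL"
    gene_strand <- ifelse(plus, "+", "-")
    pyr <- muts$pyr_strand[mi][qi]
    # template strand is the opposite of the gene's annotated strand
    lab[!both] <- ifelse(pyr[!both] == gene_strand[!both],
                         "UNTRANSCRIBED", "TRANSCRIBED")
    lab[is.na(pyr) & !both] <- "NONTRANSCRIBED"
    out[mi[qi]] <- lab
  }
  out
}

#' Derive leading/lagging strand regions from a Repli-seq profile
#'
#' Between consecutive replication initiation zones (peaks of the
#' wavelet-smoothed timing signal) and termination zones (valleys),
#' monotone stretches with positive slope are leading-strand regions on
#' the + strand, negative slope lagging-strand regions. Stretches shorter
#' than `min_len` are dropped, and the last-replicated `term_trim` bases
#' on each side of every valley midpoint are removed for stringency.
#'
#' @param profile list with `signal` (a `signal_track`), `peaks` and
#'   `valleys` (interval data frames with `chrom`, `start`, `end`).
#' @param min_len minimum monotone stretch length in bases (default
#'   10,000).
#' @param term_trim bases trimmed on each flank of a valley midpoint
#'   (default 25,000).
#' @param trim_both trim both flanks of the valley (default) or only the
#'   approach side of each stretch.
#' @return data frame with `chrom`, `start`, `end`, `label` where label is
#'   `LEADING_PLUS` or `LAGGING_PLUS`; chromosomes lacking peaks or
#'   valleys are skipped with a warning.
#' @export
derive_replication_strand_map <- function(profile, min_len = 10000,
                                          term_trim = 25000,
                                          trim_both = TRUE) {
  out <- list()
  chroms <- union(unique(profile$peaks$chrom), unique(profile$valleys$chrom))
  for (ch in chroms) {
    pk <- profile$peaks[profile$peaks$chrom == ch, , drop = FALSE]
    vl <- profile$valleys[profile$valleys$chrom == ch, , drop = FALSE]
    if (nrow(pk) == 0L || nrow(vl) == 0L) {
      warning("chromosome ", ch, " lacks peaks or valleys; unannotated")
      next
    }
    anchors <- rbind(data.frame(mid = floor((pk$start + pk$end) / 2),
                                type = "P"),
                     data.frame(mid = floor((vl$start + vl$end) / 2),
                                type = "V"))
    anchors <- anchors[order(anchors$mid), , drop = FALSE]
    if (any(anchors$type[-1L] == anchors$type[-nrow(anchors)]))
      format_error("peaks and valleys do not alternate on ", ch)
    vals <- track_values(profile$signal, ch, anchors$mid)
    segs <- list()
    for (k in seq_len(nrow(anchors) - 1L)) {
      a <- anchors$mid[k]; b <- anchors$mid[k + 1L]
      if (b - a < min_len) next
      slope <- vals[k + 1L] - vals[k]
      if (slope == 0) next
      label <- if (slope > 0) "LEADING_PLUS" else "LAGGING_PLUS"
      s <- a; e <- b
      # last-replicated DNA flanks the valley midpoint; trim it away
      if (anchors$type[k + 1L] == "V") e <- b - term_trim
      if (trim_both && anchors$type[k] == "V") s <- a + term_trim
      if (e - s <= 0) next
      segs[[length(segs) + 1L]] <- data.frame(chrom = ch, start = s,
                                              end = e, label = label)
    }
    if (length(segs)) out[[ch]] <- do.call(rbind, segs)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), label = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Replication-strand labels for mutations
#'
#' A mutation whose pyrimidine lies on the + strand inside a
#' `LEADING_PLUS` region is on the leading strand; the pyrimidine on the
#' - strand flips the call, and `LAGGING_PLUS` regions are symmetric.
#' Mutations outside the map (including trimmed termination zones) are
#' `UNASSIGNED`.
#'
#' @param muts mutation data frame with `chrom`, `pos`, `pyr_strand`.
#' @param map replication strand map from
#'   [derive_replication_strand_map()].
#' @return character vector with values `LEADING`, `LAGGING`,
#'   `UNASSIGNED`.
#' @export
annotate_replication <- function(muts, map) {
  n <- nrow(muts)
  out <- rep("UNASSIGNED", n)
  if (n == 0L || nrow(map) == 0L) return(out)
  if (is.null(muts$pyr_strand))
    muts$pyr_strand <- pyrimidine_strand(muts$ref, muts$alt)
  for (ch in unique(muts$chrom)) {
    mi <- which(muts$chrom == ch)
    m <- map[map$chrom == ch, , drop = FALSE]
    if (nrow(m) == 0L) next
    m <- m[order(m$start), , drop = FALSE]
    j <- findInterval(muts$pos[mi], m$start)
    hit <- j >= 1L & muts$pos[mi] < m$end[pmax(j, 1L)]
    region <- m$label[j[hit]]
    pyr <- muts$pyr_strand[mi][hit]
    lab <- ifelse(is.na(pyr), "UNASSIGNED",
                  ifelse((region == "LEADING_PLUS") == (pyr == "+"),
                         "LEADING", "LAGGING"))
    out[mi[hit]] <- lab
  }
  out
}

#' Genic/intergenic region of mutations
#'
#' Genic means covered by any annotated gene (including bidirectional
#' regions); intergenic is everything else. Reuses the transcription
#' labels.
#'
#' @param tx_labels labels from [annotate_transcription()].
#' @return character vector with values `GENIC`/`INTERGENIC`.
#' @export
genic_label <- function(tx_labels) {
  ifelse(tx_labels == "NONTRANSCRIBED", "INTERGENIC", "GENIC")
}
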