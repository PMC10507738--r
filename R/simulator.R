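# Context-preserving background simulator. Each replicate keeps, per
# (sample, chromosome, channel), exactly the real catalog's mutation
# count, but redraws positions uniformly among same-chromosome loci whose
# reference context reproduces the channel. Positions are drawn with
# replacement; replicates are seeded independently from (seed, replicate)
# so they are reproducible and order-insensitive.

# Canonical 3-mer contexts for SBS resampling: 16 flank pairs x {C, T}.
sbs_contexts32 <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (mid in c("C", "T"))
    for (p5 in bases)
      for (p3 in bases)
        out <- c(out, paste0(p5, mid, p3))
  out
}

canonical_context3 <- function(tri) {
  mid <- substr(tri, 2L, 2L)
  flip <- !is_pyrimidine(mid)
  tri[flip] <- revcomp(tri[flip])
  tri
}

canonical_doublet <- function(dd) {
  canon <- unique(substr(dbs78_channels(), 1L, 2L))
  ifelse(dd %in% canon, dd,
         ifelse(revcomp(dd) %in% canon, revcomp(dd), NA_character_))
}

match_positions <- function(subject, pattern) {
  if (is.character(subject)) subject <- Biostrings::DNAString(subject)
  m <- Biostrings::matchPattern(pattern, subject)
  Biostrings::start(m) - 1L
}

#' Index genome positions by canonical mutational context
#'
#' For SBS, central positions of every occurrence of each of the 32
#' canonical pyrimidine 3-mer contexts (both strands); for DBS, start
#' positions of each of the 10 canonical reference doublets. The index is
#' cached on the genome object, so repeated simulations are cheap.
#'
#' @param genome a `GenomeSequence`.
#' @return invisibly, a list with `sbs[[chrom]][[context]]` and
#'   `dbs[[chrom]][[doublet]]` position vectors (0-based).
#' @export
index_context_positions <- function(genome) {
  if (!is.null(genome$cache$context_index))
    return(invisible(genome$cache$context_index))
  sbs <- list(); dbs <- list()
  canon_dd <- unique(substr(dbs78_channels(), 1L, 2L))
  for (ch in chrom_names(genome)) {
    s <- Biostrings::DNAString(genome$seqs[[ch]])
    sbs[[ch]] <- lapply(stats::setNames(nm = sbs_contexts32()), function(ctx) {
      pos <- c(match_positions(s, ctx), match_positions(s, revcomp(ctx)))
      sort(pos) + 1L  # central base of the 3-mer
    })
    dbs[[ch]] <- lapply(stats::setNames(nm = canon_dd), function(dd) {
      rc <- revcomp(dd)
      pos <- match_positions(s, dd)
      if (rc != dd) pos <- c(pos, match_positions(s, rc))
      sort(pos)
    })
  }
  idx <- list(sbs = sbs, dbs = dbs)
  genome$cache$context_index <- idx
  invisible(idx)
}

# Candidate anchors on one chromosome where placing the given indel yields
# the same ID-83 channel, in either orientation. Returns a data frame of
# pos/ref/alt. Sampling-based with a full deletion scan as fallback.
id_candidate_positions <- function(genome, chrom, ref, alt, channel,
                                   max_candidates = 5000L) {
  s <- genome$seqs[[chrom]]
  n <- nchar(s)
  is_del <- nchar(ref) > nchar(alt)
  seqs <- unique(c(if (is_del) ref else alt,
                   revcomp(if (is_del) ref else alt)))
  cand <- list()
  for (sq in seqs) {
    r <- if (is_del) sq else ""
    a <- if (is_del) "" else sq
    if (is_del) {
      anchors <- match_positions(s, sq)
    } else {
      anchors <- seq(10L, n - 10L)
    }
    if (length(anchors) == 0L) next
    if (length(anchors) > max_candidates)
      anchors <- anchors[round(seq(1L, length(anchors),
                                   length.out = max_candidates))]
    lab <- vapply(anchors, function(p) id83_label_one(s, p, r, a),
                  character(1))
    hit <- !is.na(lab) & lab == channel
    if (any(hit))
      cand[[length(cand) + 1L]] <- data.frame(pos = anchors[hit],
                                              ref = r, alt = a)
  }
  if (length(cand) == 0L)
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0)))
  do.call(rbind, cand)
}

simulate_one_replicate <- function(groups, genome, idx, rep_seed) {
  set.seed(rep_seed)
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    k <- nrow(g)
    ch <- g$chrom[1]
    sig <- if ("signature" %in% names(g)) g$signature[1] else NULL
    if (g$type[1] == "SBS") {
      ctx <- canonical_context3(genome_seq(genome, ch, g$pos - 1L,
                                           g$pos + 2L))[1]
      pool <- idx$sbs[[ch]][[ctx]]
      if (length(pool) == 0L)
        stop("no loci with context ", ctx, " on ", ch)
      pos <- pool[sample.int(length(pool), k, replace = TRUE)]
      base <- genome_seq(genome, ch, pos, pos + 1L)
      plus <- is_pyrimidine(base)
      # channel's pyrimidine-oriented alleles
      alt_p <- sub("^.*>", "", classify_sbs6(g$ref[1], g$alt[1]))
      ref_p <- sub(">.*$", "", classify_sbs6(g$ref[1], g$alt[1]))
      ref_new <- ifelse(plus, ref_p, complement_base(ref_p))
      alt_new <- ifelse(plus, alt_p, complement_base(alt_p))
      out[[gi]] <- data.frame(sample = g$sample[1], chrom = ch, pos = pos,
                              ref = ref_new, alt = alt_new, type = "SBS")
    } else if (g$type[1] == "DBS") {
      dd <- canonical_doublet(g$ref[1])
      pool <- idx$dbs[[ch]][[dd]]
      if (length(pool) == 0L)
        stop("no loci with doublet ", dd, " on ", ch)
      pos <- pool[sample.int(length(pool), k, replace = TRUE)]
      here <- genome_seq(genome, ch, pos, pos + 2L)
      plus <- here == dd
      # orient alleles to the strand the canonical doublet sits on
      ref_c <- dd
      alt_c <- if (g$ref[1] == dd) g$alt[1] else revcomp(g$alt[1])
      ref_new <- ifelse(plus, ref_c, revcomp(ref_c))
      alt_new <- ifelse(plus, alt_c, revcomp(alt_c))
      out[[gi]] <- data.frame(sample = g$sample[1], chrom = ch, pos = pos,
                              ref = ref_new, alt = alt_new, type = "DBS")
    } else {
      key <- paste0("idcand_", ch, "_", g$ref[1], "_", g$alt[1])
      cand <- genome$cache[[key]]
      if (is.null(cand)) {
        chan <- id83_label_one(genome$seqs[[ch]], g$pos[1], g$ref[1],
                               g$alt[1])
        cand <- id_candidate_positions(genome, ch, g$ref[1], g$alt[1], chan)
        genome$cache[[key]] <- cand
      }
      if (nrow(cand) == 0L)
        stop("no loci reproducing indel context of ", g$ref[1], ">",
             g$alt[1], " on ", ch)
      j <- sample.int(nrow(cand), k, replace = TRUE)
      out[[gi]] <- data.frame(sample = g$sample[1], chrom = ch,
                              pos = cand$pos[j], ref = cand$ref[j],
                              alt = cand$alt[j], type = "ID")
    }
    if (!is.null(sig)) out[[gi]]$signature <- sig
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sample, res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Simulate context-preserving background catalogs
#'
#' Generates `n_reps` replicate catalogs (default 100). For every real
#' mutation, each replicate draws a position uniformly among
#' same-chromosome loci whose reference context reproduces the mutation's
#' channel, and carries the alternate allele over (reverse-complemented
#' when the drawn locus holds the context on the opposite strand). The
#' per-(sample, chromosome, channel) mutational burden is therefore
#' conserved exactly while positions are randomised.
#'
#' @param real mutation data frame (`sample`, `chrom`, `pos`, `ref`,
#'   `alt`, `type`). An optional `signature` column is carried through to
#'   the replicates, conserving per-signature burdens too.
#' @param genome a `GenomeSequence`.
#' @param n_reps number of replicates.
#' @param seed master seed; replicate r is reproducible from (seed, r).
#' @return list with `replicates` (list of mutation data frames),
#'   `n_reps` and `seed`.
#' @export
simulate_catalog <- function(real, genome, n_reps = 100, seed = 1) {
  if (nrow(real) == 0L) input_error("empty real catalog")
  idx <- index_context_positions(genome)
  gkey <- ifelse(real$type == "SBS",
                 canonical_context3(genome_seq(genome, real$chrom,
                                               real$pos - 1L,
                                               real$pos + 2L)),
                 paste(real$ref, real$alt, sep = ">"))
  # SBS groups also need the alt allele (channel), not just context
  gkey <- paste(real$sample, real$chrom, real$type, gkey,
                classify_sbs6(real$ref, real$alt), sep = "\r")
  # an optional signature column partitions the groups further, so each
  # replicate conserves the per-signature burden as well
  if ("signature" %in% names(real))
    gkey <- paste(gkey, real$signature, sep = "\r")
  groups <- split(real, gkey)
  reps <- lapply(seq_len(n_reps), function(r) {
    simulate_one_replicate(groups, genome, idx, derive_seed(seed, r))
  })
  list(replicates = reps, n_reps = n_reps, seed = seed)
}
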