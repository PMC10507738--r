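# Shared fixture components, built lazily once per test run. The small
# fixture (2 x 300 kb) backs unit tests; the standard fixture (3 x 2 Mb,
# the generator's defaults) backs the parameter-recovery suites, where
# catalogs vary by seed over one shared genome and context index.

.fx <- new.env(parent = emptyenv())

small_spec <- function(seed = 101) {
  fixture_spec(seed = seed, n_chrom = 2, chrom_len = 3e5,
               gene_len = 10000, gene_spacing = 30000,
               sawtooth_period = 100000)
}

small_fixture <- function() {
  if (is.null(.fx$small)) {
    spec <- small_spec()
    genome <- make_genome(spec)
    index_context_positions(genome)
    repli <- make_repliseq(spec)
    .fx$small <- list(spec = spec, genome = genome,
                      genes = make_genes(spec), repli = repli,
                      rep_map = derive_replication_strand_map(repli),
                      deciles = split_deciles(repli$signal))
  }
  .fx$small
}

std_fixture <- function() {
  if (is.null(.fx$std)) {
    spec <- fixture_spec(seed = 2024)
    genome <- make_genome(spec)
    index_context_positions(genome)
    repli <- make_repliseq(spec)
    .fx$std <- list(spec = spec, genome = genome,
                    genes = make_genes(spec), repli = repli,
                    rep_map = derive_replication_strand_map(repli),
                    deciles = split_deciles(repli$signal))
  }
  .fx$std
}

# Annotate a simulated replicate with the columns the strand analyses use.
annotate_replicate <- function(s, genes = NULL, rep_map = NULL) {
  s$channel6 <- NA_character_
  sbs <- s$type == "SBS"
  s$channel6[sbs] <- classify_sbs6(s$ref[sbs], s$alt[sbs])
  s$pyr_strand <- pyrimidine_strand(s$ref, s$alt)
  s$probability <- 1
  if (!is.null(genes)) s$tx_label <- annotate_transcription(s, genes)
  if (!is.null(rep_map)) s$rep_label <- annotate_replication(s, rep_map)
  s
}

# Catalog of n substitutions of one six-class channel drawn uniformly
# from a genome (no planted effect), as a quick null.
uniform_catalog <- function(genome, n, channel6 = "C>T", seed = 1,
                            sample_id = "S1") {
  spec_like <- list(seed = seed)
  set.seed(seed)
  ref_pyr <- substr(channel6, 1, 1)
  alt_pyr <- substr(channel6, 3, 3)
  out <- list()
  chroms <- chrom_names(genome)
  per <- table(factor(sample(chroms, n, replace = TRUE), chroms))
  for (ch in chroms) {
    k <- per[[ch]]
    if (k == 0) next
    len <- chrom_lengths(genome)[[ch]]
    pos <- integer(0)
    while (length(pos) < k) {
      cand <- sample.int(len - 4000L, 2L * (k - length(pos)) + 10L) + 1999L
      base <- genome_seq(genome, ch, cand, cand + 1L)
      cand <- cand[base %in% c(ref_pyr, complement_base_pub(ref_pyr))]
      pos <- c(pos, utils::head(cand, k - length(pos)))
    }
    base <- genome_seq(genome, ch, pos, pos + 1L)
    alt <- ifelse(base == ref_pyr, alt_pyr, complement_base_pub(alt_pyr))
    out[[ch]] <- data.frame(sample = sample_id, chrom = ch, pos = pos,
                            ref = base, alt = alt, type = "SBS")
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

complement_base_pub <- function(x) chartr("ACGT", "TGCA", x)

# O(n^2) oracle: try to extend every maximal run by brute force.
scm_oracle <- function(m, imd = 10000) {
  m <- m[m$type == "SBS" & m$signature != "UNASSIGNED" &
           m$probability >= 0.5, , drop = FALSE]
  m <- m[order(m$sample, m$chrom, m$pos), , drop = FALSE]
  groups <- list()
  i <- 1
  while (i <= nrow(m)) {
    j <- i
    while (j + 1 <= nrow(m) &&
           m$sample[j + 1] == m$sample[j] &&
           m$chrom[j + 1] == m$chrom[j] &&
           m$signature[j + 1] == m$signature[j] &&
           m$channel6[j + 1] == m$channel6[j] &&
           m$pyr_strand[j + 1] == m$pyr_strand[j] &&
           m$pos[j + 1] - m$pos[j] < imd) j <- j + 1
    if (j > i)
      groups[[length(groups) + 1]] <-
        data.frame(sample = m$sample[i], signature = m$signature[i],
                   channel = m$channel6[i], strand = m$pyr_strand[i],
                   chrom = m$chrom[i], start = m$pos[i], end = m$pos[j],
                   length = j - i + 1L)
    i <- j + 1
  }
  if (length(groups) == 0)
    return(data.frame(sample = character(0), signature = character(0),
                      channel = character(0), strand = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0)))
  do.call(rbind, groups)
}
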