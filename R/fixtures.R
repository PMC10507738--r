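# Seeded synthetic-data generator. Produces toy genomes, gene annotations,
# sawtooth Repli-seq profiles, periodic or peaked feature tracks, and
# mutation catalogs with planted topographical structure (strand bias,
# timing gradients, occupancy preference, strand-coordinated runs) so that
# every analysis stage can be exercised, and its planted effects
# recovered, without external downloads. All randomness flows from one
# spec seed through named substreams.

.fx_streams <- c(genome = 11L, genes = 12L, catalog = 15L, noise = 16L)

#' Fixture specification
#'
#' Defaults describe the standard toy dataset: three 2 Mb chromosomes, a
#' 200 kb sawtooth replication-timing profile, genes on both strands
#' covering roughly 40% of the genome, and uniform base composition so
#' every trinucleotide context is abundantly available to the simulator.
#'
#' @param seed master seed; all generator randomness derives from it.
#' @param n_chrom,chrom_len chromosome count and length (bases).
#' @param gene_len,gene_spacing gene length and start-to-start spacing.
#' @param sawtooth_period period of the replication-timing sawtooth.
#' @param sawtooth_amplitude peak signal value (valleys are 0).
#' @param wig_step resolution of emitted signal segments.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, n_chrom = 3, chrom_len = 2e6,
                         gene_len = 20000, gene_spacing = 50000,
                         sawtooth_period = 200000,
                         sawtooth_amplitude = 100, wig_step = 1000) {
  structure(list(seed = seed, n_chrom = n_chrom,
                 chrom_len = as.integer(chrom_len),
                 gene_len = as.integer(gene_len),
                 gene_spacing = as.integer(gene_spacing),
                 sawtooth_period = as.integer(sawtooth_period),
                 sawtooth_amplitude = sawtooth_amplitude,
                 wig_step = as.integer(wig_step)),
            class = "fixture_spec")
}

#' Generate a toy genome
#'
#' Uniform random bases; every trinucleotide context occurs thousands of
#' times per 2 Mb chromosome, guaranteeing the simulator's context pools.
#'
#' @param spec a `fixture_spec`.
#' @return a `GenomeSequence` with chromosomes `chr1`, `chr2`, ...
#' @export
make_genome <- function(spec) {
  set.seed(derive_seed(spec$seed, .fx_streams["genome"]))
  seqs <- vapply(seq_len(spec$n_chrom), function(i) {
    paste(sample(c("A", "C", "G", "T"), spec$chrom_len, replace = TRUE),
          collapse = "")
  }, character(1))
  GenomeSequence(stats::setNames(seqs, paste0("chr", seq_len(spec$n_chrom))))
}

#' Generate toy gene annotations
#'
#' Genes of fixed length on alternating random strands at regular
#' spacing, plus one overlapping opposite-strand pair per chromosome to
#' exercise the bidirectional exclusion.
#'
#' @param spec a `fixture_spec`.
#' @return gene annotation data frame (`chrom`, `start`, `end`, `strand`,
#'   `gene_id`).
#' @export
make_genes <- function(spec) {
  set.seed(derive_seed(spec$seed, .fx_streams["genes"]))
  out <- list()
  gid <- 0L
  for (i in seq_len(spec$n_chrom)) {
    starts <- seq(10000L, spec$chrom_len - spec$gene_len - 10000L,
                  by = spec$gene_spacing)
    strands <- sample(c("+", "-"), length(starts), replace = TRUE)
    df <- data.frame(chrom = paste0("chr", i), start = starts,
                     end = starts + spec$gene_len, strand = strands,
                     gene_id = paste0("gene", gid + seq_along(starts)))
    gid <- gid + length(starts)
    # one antisense overlap to create a bidirectionally transcribed region
    ov <- data.frame(chrom = paste0("chr", i), start = starts[1] + 5000L,
                     end = starts[1] + 10000L,
                     strand = if (strands[1] == "+") "-" else "+",
                     gene_id = paste0("gene_bidir", i))
    out[[i]] <- rbind(df, ov)
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Generate a sawtooth Repli-seq profile
#'
#' A triangle wave with printed peaks (initiation zones, maxima) and
#' valleys (termination zones, minima) alternating at half-period
#' spacing, emitted at `wig_step` resolution. Peaks sit at multiples of
#' the period starting at 0.
#'
#' @param spec a `fixture_spec`.
#' @return list with `signal` (a `signal_track`), `peaks`, `valleys`
#'   (interval data frames).
#' @export
make_repliseq <- function(spec) {
  per <- spec$sawtooth_period
  amp <- spec$sawtooth_amplitude
  segs <- list(); peaks <- list(); valleys <- list()
  for (i in seq_len(spec$n_chrom)) {
    ch <- paste0("chr", i)
    starts <- seq(0L, spec$chrom_len - spec$wig_step, by = spec$wig_step)
    mid <- starts + spec$wig_step / 2
    phase <- (mid %% per) / per
    value <- amp * (1 - 2 * abs(phase - round(phase)))  # triangle wave
    segs[[i]] <- data.frame(chrom = ch, start = starts,
                            end = starts + spec$wig_step, value = value)
    pk <- seq(0L, spec$chrom_len, by = per)
    vl <- pk + per %/% 2L
    vl <- vl[vl < spec$chrom_len]
    peaks[[i]] <- data.frame(chrom = ch,
                             start = pmax(pk - 500L, 0L),
                             end = pmin(pk + 500L, spec$chrom_len))
    valleys[[i]] <- data.frame(chrom = ch, start = vl - 500L,
                               end = vl + 500L)
  }
  list(signal = signal_track(do.call(rbind, segs)),
       peaks = do.call(rbind, peaks),
       valleys = do.call(rbind, valleys))
}

#' Generate a topographical feature track
#'
#' Three templates: `constant` (flat signal), `cosine` (nucleosome-like
#' periodic signal), and `peaked` (CTCF-like blocks of elevated signal on
#' a flat baseline; the blocks are the "feature sites").
#'
#' @param spec a `fixture_spec`.
#' @param kind template name.
#' @param period,amplitude cosine parameters (bases, signal units).
#' @param baseline,peak_value,peak_width,peak_spacing peaked-template
#'   parameters.
#' @return a `signal_track`; for `peaked`, the block intervals are
#'   attached as attribute `sites`.
#' @export
make_feature_track <- function(spec, kind = c("constant", "cosine",
                                              "peaked"),
                               period = 190, amplitude = 0.5,
                               baseline = 1, peak_value = 5,
                               peak_width = 1001L, peak_spacing = 20000L) {
  kind <- match.arg(kind)
  segs <- list()
  sites <- list()
  for (i in seq_len(spec$n_chrom)) {
    ch <- paste0("chr", i)
    if (kind == "constant") {
      segs[[i]] <- data.frame(chrom = ch, start = 0L,
                              end = spec$chrom_len, value = baseline)
    } else if (kind == "cosine") {
      step <- 10L
      starts <- seq(0L, spec$chrom_len - step, by = step)
      value <- baseline +
        amplitude * cos(2 * pi * (starts + step / 2) / period)
      segs[[i]] <- data.frame(chrom = ch, start = starts,
                              end = starts + step, value = value)
    } else {
      pk <- seq(10000L, spec$chrom_len - peak_width - 10000L,
                by = peak_spacing)
      base_df <- data.frame(start = c(0L, pk + peak_width),
                            end = c(pk, spec$chrom_len),
                            value = baseline)
      peak_df <- data.frame(start = pk, end = pk + peak_width,
                            value = peak_value)
      df <- rbind(base_df, peak_df)
      df <- df[df$start < df$end, , drop = FALSE]
      df <- df[order(df$start), , drop = FALSE]
      segs[[i]] <- cbind(data.frame(chrom = ch), df)
      sites[[i]] <- data.frame(chrom = ch, start = pk,
                               end = pk + peak_width)
    }
  }
  tr <- signal_track(do.call(rbind, segs))
  if (kind == "peaked") attr(tr, "sites") <- do.call(rbind, sites)
  tr
}

# Draw n candidate loci for a six-class channel: positions whose reference
# base matches either strand of the channel's pyrimidine, away from
# chromosome ends. Returns a mutation-shaped frame.
draw_channel_candidates <- function(genome, channel6, n, margin = 2000L) {
  ref_pyr <- substr(channel6, 1L, 1L)
  alt_pyr <- substr(channel6, 3L, 3L)
  chroms <- chrom_names(genome)
  out <- list()
  per <- stats::rmultinom(1, n, rep(1, length(chroms)))[, 1]
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    need <- per[ci]
    if (need == 0L) next
    len <- chrom_lengths(genome)[[ch]]
    got <- list(); n_got <- 0L
    while (n_got < need) {
      cand <- sample.int(len - 2L * margin, 3L * (need - n_got) + 20L) +
        margin - 1L
      base <- genome_seq(genome, ch, cand, cand + 1L)
      keep <- base == ref_pyr | base == complement_base(ref_pyr)
      cand <- cand[keep]; base <- base[keep]
      if (length(cand) == 0L) next
      take <- utils::head(seq_along(cand), need - n_got)
      got[[length(got) + 1L]] <- data.frame(chrom = ch, pos = cand[take],
                                            ref = base[take])
      n_got <- n_got + length(take)
    }
    out[[length(out) + 1L]] <- do.call(rbind, got)
  }
  res <- do.call(rbind, out)
  plus <- res$ref == ref_pyr
  res$alt <- ifelse(plus, alt_pyr, complement_base(alt_pyr))
  res$type <- "SBS"
  res
}

# Weighted subsample of candidate rows, stratified by weight class:
# class counts follow the weighted expectation deterministically (largest
# remainder rounding), positions within a class are drawn uniformly
# without replacement. The planted class odds are thereby realized almost
# exactly -- the recovery fixtures test the analysis machinery, not the
# binomial noise of the generator -- while position-level placement stays
# random. A sequential weighted draw without replacement would instead
# systematically deflate planted odds ratios.
weighted_pick <- function(df, w, n) {
  uw <- sort(unique(w))
  cls <- match(w, uw)
  sizes <- tabulate(cls, nbins = length(uw))
  pk <- sizes * uw
  exact <- n * pk / sum(pk)
  alloc <- floor(exact)
  rem <- n - sum(alloc)
  if (rem > 0L) {
    extra <- order(exact - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1L
  }
  alloc <- pmin(alloc, sizes)
  short <- n - sum(alloc)
  while (short > 0L) {  # respill any overflow to classes with room
    room <- which(sizes - alloc > 0L)
    add <- utils::head(room, short)
    alloc[add] <- alloc[add] + 1L
    short <- n - sum(alloc)
  }
  idx <- unlist(lapply(seq_along(sizes), function(k) {
    pool <- which(cls == k)
    pool[sample.int(length(pool), alloc[k])]
  }))
  df[idx, , drop = FALSE]
}

#' Generate a mutation catalog with planted topographical effects
#'
#' For each requested signature, candidate loci are drawn uniformly (the
#' same null the simulator reproduces) and then re-weighted or stratified
#' according to the planted effects: transcription- or replication-strand
#' odds ratios multiply the sampling weight of transcribed/lagging
#' candidates; a timing gradient tilts weights linearly across
#' replication deciles; an occupancy fold places the computed fraction of
#' mutations at elevated-signal feature sites; strand-coordinated runs
#' are inserted as same-channel, same-strand, same-signature runs with
#' sub-threshold gaps. Every planted effect is recorded in the returned
#' manifest.
#'
#' @param spec a `fixture_spec`.
#' @param genome a `GenomeSequence` from [make_genome()].
#' @param signatures list of per-signature requests; each a list with
#'   `name`, `n`, and optional `channel6` (default "C>T"), `tx_or`,
#'   `rep_or`, `timing_gradient` (late/early density ratio),
#'   `occupancy_fold`, `scm_runs` (list with `n_runs`, `run_length` and
#'   optionally its own `channel6`), `prob` (assignment sharpness,
#'   default 0.9).
#' @param genes,rep_map,deciles,feature_track fixture components needed
#'   by the respective planted effects.
#' @param sample_id sample identifier.
#' @param catalog_seed seed for the catalog substream (default: spec
#'   seed), letting many catalogs share one genome.
#' @return list with `mutations`, `probabilities` (data frame), and
#'   `manifest`.
#' @export
make_catalog <- function(spec, genome, signatures, genes = NULL,
                         rep_map = NULL, deciles = NULL,
                         feature_track = NULL, sample_id = "S1",
                         catalog_seed = spec$seed) {
  set.seed(derive_seed(catalog_seed, .fx_streams["catalog"]))
  all_muts <- list()
  manifest <- list(seed = spec$seed, catalog_seed = catalog_seed,
                   sample_id = sample_id, signatures = list())
  for (sg in signatures) {
    name <- sg$name
    n <- sg$n
    channel6 <- if (is.null(sg$channel6)) "C>T" else sg$channel6
    tx_or <- if (is.null(sg$tx_or)) 1 else sg$tx_or
    rep_or <- if (is.null(sg$rep_or)) 1 else sg$rep_or
    grad <- if (is.null(sg$timing_gradient)) 1 else sg$timing_gradient
    occ_fold <- if (is.null(sg$occupancy_fold)) 1 else sg$occupancy_fold
    n_scm <- 0L
    muts <- NULL
    if (occ_fold != 1) {
      if (is.null(feature_track))
        input_error("occupancy_fold needs a feature_track")
      pool <- draw_channel_candidates(genome, channel6, 10L * n)
      s <- vapply(seq_len(nrow(pool)), function(i) {
        len <- chrom_lengths(genome)[[pool$chrom[i]]]
        base <- track_base_vector(feature_track, pool$chrom[i], len)
        mean(base[(pool$pos[i] - 49L):(pool$pos[i] + 51L)])
      }, numeric(1))
      mu0 <- mean(s)
      hi <- s > mu0 + 0.5 * (max(s) - mu0)
      mean_hi <- mean(s[hi]); mean_lo <- mean(s[!hi])
      f <- (occ_fold * mu0 - mean_lo) / (mean_hi - mean_lo)
      f <- min(max(f, 0), 1)
      n_hi <- round(f * n)
      muts <- rbind(weighted_pick(pool[hi, , drop = FALSE],
                                  rep(1, sum(hi)), min(n_hi, sum(hi))),
                    weighted_pick(pool[!hi, , drop = FALSE],
                                  rep(1, sum(!hi)), n - min(n_hi, sum(hi))))
    } else {
      pool_mult <- if (tx_or != 1 || rep_or != 1) 15L else 6L
      pool <- draw_channel_candidates(genome, channel6, pool_mult * n)
      w <- rep(1, nrow(pool))
      pool$pyr_strand <- pyrimidine_strand(pool$ref, pool$alt)
      # planted strand effects concentrate the signature's mutations on
      # the two compared strata so that the requested n is the number of
      # informative mutations for the planted odds ratio
      if (tx_or != 1) {
        if (is.null(genes)) input_error("tx_or needs genes")
        lab <- annotate_transcription(pool, genes)
        keep <- lab %in% c("TRANSCRIBED", "UNTRANSCRIBED")
        pool <- pool[keep, , drop = FALSE]
        w <- w[keep]; lab <- lab[keep]
        w <- w * ifelse(lab == "TRANSCRIBED", tx_or, 1)
      }
      if (rep_or != 1) {
        if (is.null(rep_map)) input_error("rep_or needs rep_map")
        lab <- annotate_replication(pool, rep_map)
        keep <- lab %in% c("LEADING", "LAGGING")
        pool <- pool[keep, , drop = FALSE]
        w <- w[keep]; lab <- lab[keep]
        w <- w * ifelse(lab == "LAGGING", rep_or, 1)
      }
      if (grad != 1) {
        if (is.null(deciles)) input_error("timing_gradient needs deciles")
        d <- decile_membership(deciles, pool$chrom, pool$pos)
        w <- w * ifelse(d > 0, 1 + (grad - 1) * (d - 1) / 9, 1)
      }
      muts <- weighted_pick(pool, w, n)
      muts$pyr_strand <- NULL
    }
    if (!is.null(sg$scm_runs)) {
      run_channel <- if (is.null(sg$scm_runs$channel6)) channel6
      else sg$scm_runs$channel6
      runs <- make_scm_runs(genome, run_channel, sg$scm_runs$n_runs,
                            sg$scm_runs$run_length)
      n_scm <- nrow(runs)
      muts <- rbind(muts[, c("chrom", "pos", "ref", "alt", "type")],
                    runs)
    } else {
      muts <- muts[, c("chrom", "pos", "ref", "alt", "type")]
    }
    muts$sample <- sample_id
    muts$true_signature <- name
    all_muts[[length(all_muts) + 1L]] <- muts
    manifest$signatures[[name]] <-
      list(n = n + n_scm, channel6 = channel6, tx_or = tx_or,
           rep_or = rep_or, timing_gradient = grad,
           occupancy_fold = occ_fold,
           scm_runs = if (is.null(sg$scm_runs)) NULL else sg$scm_runs,
           prob = if (is.null(sg$prob)) 0.9 else sg$prob)
  }
  muts <- do.call(rbind, all_muts)
  muts <- muts[order(muts$chrom, muts$pos), , drop = FALSE]
  rownames(muts) <- NULL
  sig_names <- vapply(signatures, `[[`, character(1), "name")
  probs <- fixture_probabilities(muts, sig_names, manifest)
  muts_out <- muts[, c("sample", "chrom", "pos", "ref", "alt", "type")]
  list(mutations = muts_out, probabilities = probs, manifest = manifest)
}

# Same-channel, same-strand runs with gaps well below the distance
# threshold; anchors spread across chromosomes.
make_scm_runs <- function(genome, channel6, n_runs, run_length) {
  ref_pyr <- substr(channel6, 1L, 1L)
  alt_pyr <- substr(channel6, 3L, 3L)
  chroms <- chrom_names(genome)
  out <- list()
  for (r in seq_len(n_runs)) {
    ch <- chroms[(r - 1L) %% length(chroms) + 1L]
    len <- chrom_lengths(genome)[[ch]]
    anchor <- sample.int(len - 100000L, 1L) + 20000L
    pos <- integer(0)
    p <- anchor
    while (length(pos) < run_length) {
      # jump a sub-threshold gap, then take the first base on the wanted
      # strand (pyrimidine density makes this a few bp at most)
      target <- p + sample(500:2000, 1L)
      window <- genome_seq(genome, ch, target, min(target + 200L, len))
      hit <- regexpr(ref_pyr, window, fixed = TRUE)
      if (hit < 0L) { p <- target; next }
      p <- target + as.integer(hit) - 1L
      pos <- c(pos, p)
    }
    out[[r]] <- data.frame(chrom = ch, pos = pos, ref = ref_pyr,
                           alt = alt_pyr, type = "SBS")
  }
  do.call(rbind, out)
}

# Probability table: the true signature gets `prob`, the remainder is
# split evenly among the other signatures.
fixture_probabilities <- function(muts, sig_names, manifest) {
  n <- nrow(muts)
  probs <- matrix(0, nrow = n, ncol = length(sig_names),
                  dimnames = list(NULL, sig_names))
  for (i in seq_len(n)) {
    true <- muts$true_signature[i]
    p <- manifest$signatures[[true]]$prob
    if (length(sig_names) == 1L) p <- 1
    probs[i, ] <- (1 - p) / max(length(sig_names) - 1L, 1L)
    probs[i, true] <- p
  }
  cbind(data.frame(sample = muts$sample, chrom = muts$chrom,
                   pos = muts$pos), as.data.frame(probs))
}

#' Write a complete fixture set to a directory
#'
#' Emits exactly the formats the pipeline reads: `genome.fa`,
#' `genes.bed`, `repliseq.wig` + `repliseq_peaks.bed` +
#' `repliseq_valleys.bed`, feature `*.bedGraph` tracks, `mutations.tsv`,
#' `probabilities.tsv` and a `manifest.json` recording every planted
#' effect.
#'
#' @param spec a `fixture_spec`.
#' @param dir output directory (created if needed).
#' @param signatures planted-signature list for [make_catalog()].
#' @param tracks named list of feature-track kinds (passed to
#'   [make_feature_track()]), default one constant and one cosine track.
#' @return invisibly, the list of generated objects.
#' @export
make_fixture_set <- function(spec, dir,
                             signatures = list(list(name = "SBS_A",
                                                    n = 2000)),
                             tracks = list(nucleosome = "cosine",
                                           ctcf = "peaked")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_genome(spec)
  genes <- make_genes(spec)
  repli <- make_repliseq(spec)
  rep_map <- derive_replication_strand_map(repli)
  deciles <- split_deciles(repli$signal)
  feature_tracks <- lapply(tracks, function(kind)
    make_feature_track(spec, kind))
  cat_track <- if (length(feature_tracks)) feature_tracks[[1]] else NULL
  cata <- make_catalog(spec, genome, signatures, genes = genes,
                       rep_map = rep_map, deciles = deciles,
                       feature_track = cat_track)
  write_genome_fasta(genome, file.path(dir, "genome.fa"))
  utils::write.table(data.frame(genes$chrom, genes$start, genes$end,
                                genes$gene_id, 0, genes$strand),
                     file.path(dir, "genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_track_bedgraph(repli$signal, file.path(dir, "repliseq.bedGraph"))
  write_intervals_bed(repli$peaks, file.path(dir, "repliseq_peaks.bed"))
  write_intervals_bed(repli$valleys,
                      file.path(dir, "repliseq_valleys.bed"))
  for (nm in names(feature_tracks))
    write_track_bedgraph(feature_tracks[[nm]],
                         file.path(dir, paste0(nm, ".bedGraph")))
  write_mutations(cata$mutations, file.path(dir, "mutations.tsv"))
  write_table(cata$probabilities, file.path(dir, "probabilities.tsv"))
  jsonlite::write_json(cata$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(spec = spec, genome = genome, genes = genes,
                 repliseq = repli, rep_map = rep_map, deciles = deciles,
                 tracks = feature_tracks, catalog = cata))
}
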