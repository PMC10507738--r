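# End-to-end orchestration. A run configuration carries every input path
# and every threshold the analyses use; defaults are the method's standard
# values. The resolved configuration is written next to the outputs so a
# run can be reproduced from its own echo.

#' Default run configuration
#'
#' Thresholds default to the standard values of the method: odds ratios
#' above 1.10 at corrected p <= 0.05, inter-mutational distance 10 kb,
#' signature assignment probability cutoff 0.5, at least 1,000 attributed
#' mutations per signature, 2,001/1,001/101 bp occupancy windows, 100
#' simulation replicates, 25 kb termination-zone trim and 10 kb minimum
#' monotone stretch.
#'
#' @param paths named list of input paths (see [run_topography()]).
#' @param seed master seed.
#' @return configuration list.
#' @export
default_config <- function(paths = list(), seed = 1) {
  list(paths = paths,
       thresholds = list(or_min = 1.10, q_max = 0.05, imd = 10000,
                         prob_cutoff = 0.5, min_mutations = 1000,
                         occupancy_half = 1000, similarity_half = 500,
                         abundance_half = 50, n_reps = 100,
                         term_trim = 25000, min_stretch = 10000,
                         abundance_fold = 0.05),
       seed = seed)
}

# Channel and strand columns for a simulated replicate.
annotate_sim_catalog <- function(s) {
  s$channel6 <- NA_character_
  sbs <- s$type == "SBS"
  s$channel6[sbs] <- classify_sbs6(s$ref[sbs], s$alt[sbs])
  s$pyr_strand <- pyrimidine_strand(s$ref, s$alt)
  s$probability <- 1
  s
}

#' Run the topography pipeline
#'
#' Executes the stages in dependency order: read inputs, attribute
#' mutations to signatures, simulate background catalogs (per-signature
#' burdens conserved), annotate transcription/replication strand, test
#' strand and genic/intergenic asymmetries, replication-timing deciles
#' and trend, strand-coordinated mutagenesis, and (when feature tracks
#' are configured) abundance. Results are written as TSV files under
#' `out_dir` together with the resolved configuration.
#'
#' @param config list from [default_config()]; `config$paths` must name
#'   `genome`, `mutations`, `probabilities`, and may name `genes`,
#'   `repliseq_signal`/`repliseq_peaks`/`repliseq_valleys`, and
#'   `features` (named list of track path vectors).
#' @param out_dir output directory.
#' @param stages character vector of stages to run (default all
#'   applicable).
#' @return invisibly, a list of the in-memory results.
#' @export
run_topography <- function(config, out_dir,
                           stages = c("asymmetry", "timing", "scm",
                                      "occupancy")) {
  th <- config$thresholds
  paths <- config$paths
  for (p in c("genome", "mutations", "probabilities"))
    if (is.null(paths[[p]]) || !file.exists(paths[[p]]))
      input_error("missing required input path: ", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_genome_fasta(paths$genome)
  muts <- read_mutations(paths$mutations, "tsv")
  probs <- read_probabilities(paths$probabilities)
  att <- attribute_mutations(muts, probs, genome,
                             cutoff = th$prob_cutoff)
  sims <- simulate_catalog(att, genome, n_reps = th$n_reps,
                           seed = config$seed)
  att_sims <- lapply(sims$replicates, annotate_sim_catalog)
  results <- list(attributed = att, config = config)
  sig_pass <- signature_mutation_counts(att, th$min_mutations)

  genes <- if (!is.null(paths$genes)) read_genes(paths$genes) else NULL
  repli <- NULL
  if (!is.null(paths$repliseq_signal)) {
    repli <- list(signal = read_signal_track(paths$repliseq_signal,
                                             "bedGraph"),
                  peaks = read_intervals(paths$repliseq_peaks),
                  valleys = read_intervals(paths$repliseq_valleys))
  }

  if ("asymmetry" %in% stages && !is.null(genes)) {
    att$tx_label <- annotate_transcription(att, genes)
    for (i in seq_along(att_sims))
      att_sims[[i]]$tx_label <- annotate_transcription(att_sims[[i]],
                                                       genes)
    tx_tab <- strand_count_table(att, att_sims, "tx_label",
                                 "TRANSCRIBED", "UNTRANSCRIBED",
                                 sig_pass$signature)
    results$transcription <- detect_asymmetries(tx_tab, th$or_min,
                                                th$q_max)
    write_table(results$transcription,
                file.path(out_dir, "asymmetry_transcription.tsv"))
    att$region <- genic_label(att$tx_label)
    for (i in seq_along(att_sims))
      att_sims[[i]]$region <- genic_label(att_sims[[i]]$tx_label)
    gi_tab <- strand_count_table(att, att_sims, "region",
                                 "GENIC", "INTERGENIC",
                                 sig_pass$signature)
    results$genic_intergenic <- detect_asymmetries(gi_tab, th$or_min,
                                                   th$q_max)
    write_table(results$genic_intergenic,
                file.path(out_dir, "asymmetry_genic_intergenic.tsv"))
  }
  if (!is.null(repli)) {
    rep_map <- derive_replication_strand_map(repli, th$min_stretch,
                                             th$term_trim)
    if ("asymmetry" %in% stages) {
      att$rep_label <- annotate_replication(att, rep_map)
      for (i in seq_along(att_sims))
        att_sims[[i]]$rep_label <- annotate_replication(att_sims[[i]],
                                                        rep_map)
      rp_tab <- strand_count_table(att, att_sims, "rep_label",
                                   "LAGGING", "LEADING",
                                   sig_pass$signature)
      results$replication <- detect_asymmetries(rp_tab, th$or_min,
                                                th$q_max)
      write_table(results$replication,
                  file.path(out_dir, "asymmetry_replication.tsv"))
    }
    if ("timing" %in% stages) {
      deciles <- split_deciles(repli$signal)
      timing <- lapply(sig_pass$signature, function(sig) {
        real_x <- decile_density(att[att$signature == sig, ], deciles,
                                 genome)
        sim_x <- lapply(att_sims, function(s)
          decile_density(s[s$signature == sig, ], deciles, genome)$x)
        ens <- ensemble_stats(sim_x)
        tr <- classify_trend(real_x$x)
        data.frame(signature = sig, decile = 1:10, x_real = real_x$x,
                   sim_mean = ens$mean, sim_sd = ens$sd,
                   ci_lower = ens$ci_lower, ci_upper = ens$ci_upper,
                   slope = tr$slope, slope_p = tr$p, trend = tr$trend)
      })
      results$timing <- do.call(rbind, timing)
      write_table(results$timing, file.path(out_dir, "timing.tsv"))
    }
  }
  if ("scm" %in% stages) {
    real_groups <- find_scm_groups(att, th$imd, th$prob_cutoff)
    sim_groups <- lapply(att_sims, find_scm_groups, imd = th$imd,
                         prob_cutoff = th$prob_cutoff)
    results$scm <- test_scm_lengths(real_groups, sim_groups, th$q_max)
    write_table(results$scm, file.path(out_dir, "scm.tsv"))
  }
  if ("occupancy" %in% stages && !is.null(paths$features)) {
    lens <- chrom_lengths(genome)
    occ_all <- list()
    for (feat in names(paths$features)) {
      tracks <- lapply(paths$features[[feat]], read_signal_track,
                       dialect = "bedGraph")
      names(tracks) <- basename(unlist(paths$features[[feat]]))
      for (sig in sig_pass$signature) {
        m <- att[att$signature == sig, ]
        sim_m <- lapply(att_sims, function(s) s[s$signature == sig, ])
        ab <- abundance_test(m, sim_m, tracks, lens, th$abundance_half)
        occ_all[[paste(feat, sig)]] <-
          data.frame(feature = feat, signature = sig,
                     fold_change = ab$fold_change, p = ab$p_combined)
      }
    }
    occ <- do.call(rbind, occ_all)
    occ$q <- bh_adjust(occ$p)
    occ$call <- mapply(abundance_call, occ$fold_change, occ$q,
                       MoreArgs = list(q_max = th$q_max,
                                       fold_margin = th$abundance_fold))
    results$abundance <- occ
    write_table(occ, file.path(out_dir, "abundance.tsv"))
  }
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(results)
}
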