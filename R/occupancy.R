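# Occupancy and abundance analysis around mutations. Occupancy averages a
# topographical signal in a 2,001 bp window centered on each mutation
# (offsets -1000..+1000), in two rounds: over mutations per dataset
# (K vectors), then unweighted over datasets/cohorts (M vectors).
# Abundance compares the mean +/-50 bp signal of real mutations with the
# simulated ensemble through a z test, combining datasets with Fisher's
# method.

#' Signal vector in a window centered on one mutation
#'
#' @param track a `signal_track`.
#' @param chrom chromosome identifier.
#' @param pos 0-based mutation position (window center, offset 0).
#' @param half half-window in bases (default 1,000, giving 2,001
#'   positions).
#' @param chrom_len chromosome length; windows overrunning the chromosome
#'   return `NULL` (the mutation is skipped and counted by callers).
#' @return numeric vector of length `2 * half + 1`, or `NULL`.
#' @export
window_signal <- function(track, chrom, pos, half = 1000,
                          chrom_len = Inf) {
  if (pos - half < 0 || pos + half >= chrom_len) return(NULL)
  offs <- (pos - half):(pos + half)
  v <- track_values(track, chrom, offs)
  attributes(v) <- NULL
  v
}

# Mean window vector over mutations for one dataset, using dense per-base
# track vectors for speed. Returns list(vec, n_used, n_skipped).
mean_window_vector <- function(muts, track, chrom_lens, half = 1000) {
  total <- numeric(2L * half + 1L)
  n_used <- 0L; n_skipped <- 0L
  for (ch in unique(muts$chrom)) {
    len <- chrom_lens[[ch]]
    pos <- muts$pos[muts$chrom == ch]
    ok <- pos - half >= 0L & pos + half < len
    n_skipped <- n_skipped + sum(!ok)
    pos <- pos[ok]
    if (length(pos) == 0L) next
    base <- track_base_vector(track, ch, len)
    idx <- outer(pos + 1L, (-half):half, `+`)
    total <- total + colSums(matrix(base[idx], nrow = length(pos)))
    n_used <- n_used + length(pos)
  }
  list(vec = if (n_used > 0L) total / n_used else rep(NA_real_,
                                                      2L * half + 1L),
       n_used = n_used, n_skipped = n_skipped)
}

#' Two-round average occupancy profile
#'
#' Round one averages the window signal over all mutations for each
#' dataset, giving one K vector per dataset; round two averages the K
#' vectors unweighted across datasets, giving the M vector. The same
#' procedure applied per simulated replicate and averaged over replicates
#' gives the simulated counterparts.
#'
#' @param muts real mutation data frame.
#' @param tracks named list of `signal_track` objects (the datasets of one
#'   topographical feature).
#' @param chrom_lens named chromosome lengths.
#' @param sims optional list of simulated mutation data frames.
#' @param half half-window (default 1,000).
#' @return list with `K_real` (matrix, datasets x offsets), `M_real`
#'   (vector), `K_sims`, `M_sims` (or NULL without sims), `n_mutations`.
#' @export
average_occupancy <- function(muts, tracks, chrom_lens, sims = NULL,
                              half = 1000) {
  if (nrow(muts) == 0L) input_error("no usable mutations for occupancy")
  K_real <- t(vapply(tracks, function(tr) {
    mean_window_vector(muts, tr, chrom_lens, half)$vec
  }, numeric(2L * half + 1L)))
  M_real <- colMeans(K_real)
  K_sims <- NULL; M_sims <- NULL
  if (!is.null(sims)) {
    acc <- matrix(0, nrow = length(tracks), ncol = 2L * half + 1L)
    for (s in sims) {
      acc <- acc + t(vapply(tracks, function(tr) {
        mean_window_vector(s, tr, chrom_lens, half)$vec
      }, numeric(2L * half + 1L)))
    }
    K_sims <- acc / length(sims)
    M_sims <- colMeans(K_sims)
  }
  list(K_real = K_real, M_real = M_real, K_sims = K_sims, M_sims = M_sims,
       n_mutations = nrow(muts))
}

#' Similarity of a cancer-type profile to the global profile
#'
#' Pearson correlation between the K and M vectors over offsets within
#' `half` (default 500) of the mutation, with a p value from the Fisher
#' z transform. A profile is similar when r >= 0.5 and the (corrected)
#' p value is at most 0.05; with a single test the raw p is used.
#'
#' @param K_real,M_real occupancy vectors of length 2,001 (offset 0 at
#'   position 1001).
#' @param half correlation half-window (default 500).
#' @param q optional precomputed corrected p value.
#' @return list with `r`, `p`, `q`, `similar`, `flagged` (zero-variance
#'   input).
#' @export
occupancy_similarity <- function(K_real, M_real, half = 500, q = NULL) {
  stopifnot(length(K_real) == length(M_real))
  center <- (length(K_real) + 1L) / 2L
  i <- (center - half):(center + half)
  a <- K_real[i]; b <- M_real[i]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_, q = NA_real_,
                similar = FALSE, flagged = TRUE))
  r <- stats::cor(a, b)
  nn <- length(i)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15)) * sqrt(nn - 3)
  p <- 2 * stats::pnorm(-abs(z))
  if (is.null(q)) q <- p
  list(r = r, p = p, q = q, similar = (r >= 0.5 && q <= 0.05),
       flagged = FALSE)
}

# Mean +/-half signal around each catalog's mutations for one dataset.
window_mean_value <- function(muts, track, chrom_lens, half = 50) {
  mean_window_vector(muts, track, chrom_lens, half)$vec |> mean()
}

#' Abundance test of a signature against a topographical feature
#'
#' For each dataset, the observed mean signal in the +/-50 bp window
#' around real mutations (101 positions including the mutated base) is
#' compared with the per-replicate simulated means by a z test; fold
#' change is observed over simulated mean. Datasets of one cohort are
#' combined with Fisher's method on the p values and the fold changes are
#' averaged.
#'
#' @param muts real mutations.
#' @param sims list of simulated replicate catalogs.
#' @param tracks named list of `signal_track` datasets.
#' @param chrom_lens named chromosome lengths.
#' @param half abundance half-window (default 50).
#' @return list with per-dataset `s_real`, `sim_mean`, `sim_sd`, `fold`,
#'   `z`, `p`, `degenerate`, plus combined `fold_change` and `p_combined`.
#' @export
abundance_test <- function(muts, sims, tracks, chrom_lens, half = 50) {
  if (length(sims) < 2L) input_error("at least 2 replicates required")
  per <- lapply(tracks, function(tr) {
    s_real <- window_mean_value(muts, tr, chrom_lens, half)
    s_sims <- vapply(sims, function(s)
      window_mean_value(s, tr, chrom_lens, half), numeric(1))
    abundance_cell(s_real, s_sims)
  })
  folds <- vapply(per, `[[`, numeric(1), "fold")
  ps <- vapply(per, `[[`, numeric(1), "p")
  comb <- fisher_combine(ps[!is.na(ps)])
  list(datasets = per, fold_change = mean(folds, na.rm = TRUE),
       p_combined = comb)
}

#' Z test of one observed abundance value against simulated values
#'
#' @param s_real observed mean signal.
#' @param s_sims numeric vector of per-replicate simulated mean signals.
#' @return list with `s_real`, `sim_mean`, `sim_sd`, `fold`, `z`, `p`,
#'   `degenerate`.
#' @export
abundance_cell <- function(s_real, s_sims) {
  mu <- mean(s_sims)
  sdev <- stats::sd(s_sims)
  fold <- if (mu != 0) s_real / mu else NA_real_
  if (is.na(sdev) || sdev == 0) {
    degenerate <- TRUE
    z <- if (isTRUE(all.equal(s_real, mu))) 0 else
      Inf * sign(s_real - mu)
    p <- if (is.finite(z)) 1 else NA_real_
  } else {
    degenerate <- FALSE
    z <- (s_real - mu) / sdev
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(s_real = s_real, sim_mean = mu, sim_sd = sdev, fold = fold, z = z,
       p = p, degenerate = degenerate)
}

#' Combine p values with Fisher's method
#'
#' @param pvals vector of p values.
#' @return combined p from the chi-square distribution with `2 * length`
#'   degrees of freedom.
#' @export
fisher_combine <- function(pvals) {
  if (length(pvals) == 0L) return(NA_real_)
  pvals <- pmax(pvals, 1e-300)
  x2 <- -2 * sum(log(pvals))
  stats::pchisq(x2, df = 2 * length(pvals), lower.tail = FALSE)
}

#' Enrichment/depletion call from fold change and corrected p
#'
#' `ENRICHED` requires q <= `q_max` and fold at least `1 + fold_margin`
#' (default 5% enrichment); `DEPLETED` requires q <= `q_max` and fold at
#' most `1 - fold_margin`; anything else is `NONE`.
#'
#' @param fold_change averaged fold change.
#' @param q corrected p value.
#' @param q_max significance threshold (default 0.05).
#' @param fold_margin minimum relative departure from 1 (default 0.05).
#' @return one of `"ENRICHED"`, `"DEPLETED"`, `"NONE"`.
#' @export
abundance_call <- function(fold_change, q, q_max = 0.05,
                           fold_margin = 0.05) {
  if (is.na(fold_change) || is.na(q)) return("NONE")
  if (q <= q_max && fold_change >= 1 + fold_margin) return("ENRICHED")
  if (q <= q_max && fold_change <= 1 - fold_margin) return("DEPLETED")
  "NONE"
}
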