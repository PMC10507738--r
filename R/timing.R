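# Replication-timing decile analysis. The wavelet-smoothed timing signal
# (higher = earlier replication) is sorted in descending order and split
# into ten bins each holding as close to 10% of the total signal as whole
# segments allow; mutation densities per decile are corrected for
# attributable bases and normalised to the densest decile.

#' Split a replication-timing signal into deciles
#'
#' Segments are sorted by signal value descending (ties broken by genomic
#' order) and assigned greedily: the current decile accumulates segments
#' until it holds at least a tenth of the total signal mass, then the next
#' decile opens. Segments are atomic and never split across deciles, so
#' each decile holds approximately 10% of the signal. Decile 1 holds the
#' highest (earliest-replicating) values.
#'
#' @param signal a `signal_track` of wavelet-smoothed replication timing.
#' @return object of class `decile_set`: a list of 10 interval data frames
#'   (`chrom`, `start`, `end`), with per-decile signal shares in attribute
#'   `signal_share`.
#' @export
split_deciles <- function(signal) {
  seg <- track_segments(signal)
  if (nrow(seg) < 10L) input_error("need at least 10 segments for deciles")
  seg$mass <- seg$value * (seg$end - seg$start)
  ord <- order(-seg$value, seg$chrom, seg$start)
  seg <- seg[ord, , drop = FALSE]
  total <- sum(seg$mass)
  n <- nrow(seg)
  decile <- integer(n)
  cur <- 1L
  acc <- 0
  remaining <- total
  for (i in seq_len(n)) {
    decile[i] <- cur
    acc <- acc + seg$mass[i]
    remaining <- remaining - seg$mass[i]
    if (cur < 10L) {
      # remaining-aware target keeps every decile close to a tenth of the
      # signal while never splitting a segment or starving a late decile
      target <- (acc + remaining) / (10L - cur + 1L)
      if (acc >= target - 1e-9 || (n - i) <= (10L - cur)) {
        cur <- cur + 1L
        acc <- 0
      }
    }
  }
  out <- lapply(1:10, function(k) {
    d <- seg[decile == k, c("chrom", "start", "end"), drop = FALSE]
    d <- d[order(d$chrom, d$start), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  shares <- vapply(1:10, function(k) sum(seg$mass[decile == k]) / total,
                   numeric(1))
  structure(out, signal_share = shares, class = "decile_set")
}

#' @export
print.decile_set <- function(x, ...) {
  cat("decile_set: signal shares (%):",
      paste(sprintf("%.1f", 100 * attr(x, "signal_share")), collapse = " "),
      "\n")
  invisible(x)
}

# Which decile covers each (chrom, pos); 0 when uncovered.
decile_membership <- function(deciles, chrom, pos) {
  all_seg <- do.call(rbind, lapply(1:10, function(k) {
    d <- deciles[[k]]
    if (nrow(d) == 0L) return(NULL)
    d$decile <- k
    d
  }))
  out <- integer(length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    s <- all_seg[all_seg$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0L) next
    s <- s[order(s$start), , drop = FALSE]
    j <- findInterval(pos[i], s$start)
    hit <- j >= 1L & pos[i] < s$end[pmax(j, 1L)]
    out[i][hit] <- s$decile[j[hit]]
  }
  out
}

#' Normalised mutation density per replication-timing decile
#'
#' Counts mutations per decile, divides by the decile's attributable
#' (non-N) bases, and scales the resulting densities so the densest decile
#' equals 1. Mutations outside the covered genome are excluded and
#' counted in attribute `n_uncovered`.
#'
#' @param muts mutation data frame.
#' @param deciles a `decile_set`.
#' @param genome a `GenomeSequence` for attributable-base counting.
#' @return list with `x` (10 normalised densities), `raw_counts`,
#'   `attributable_bases`.
#' @export
decile_density <- function(muts, deciles, genome) {
  bases <- vapply(1:10, function(k) {
    d <- deciles[[k]]
    sum(attributable_bases(genome, d$chrom, d$start, d$end))
  }, numeric(1))
  if (any(bases == 0))
    input_error("decile with zero attributable bases; density undefined")
  memb <- decile_membership(deciles, muts$chrom, muts$pos)
  counts <- tabulate(memb[memb > 0L], nbins = 10L)
  dens <- counts / bases
  x <- if (max(dens) > 0) dens / max(dens) else dens
  out <- list(x = x, raw_counts = counts,
              attributable_bases = as.integer(bases))
  attr(out, "n_uncovered") <- sum(memb == 0L)
  out
}

#' Summary statistics of a simulated density ensemble
#'
#' @param replicate_vectors list of normalised density vectors (or a
#'   replicates-by-deciles matrix).
#' @return list with `mean`, `sd` (sample sd), `ci_lower`, `ci_upper`
#'   (normal-approximation 95% interval of the mean) and the stacked
#'   matrix `X`.
#' @export
ensemble_stats <- function(replicate_vectors) {
  X <- if (is.matrix(replicate_vectors)) replicate_vectors
  else do.call(rbind, replicate_vectors)
  if (nrow(X) < 2L) input_error("need at least 2 replicates")
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  half <- 1.96 * sdev / sqrt(nrow(X))
  list(mean = mu, sd = sdev, ci_lower = mu - half, ci_upper = mu + half,
       X = X)
}

#' Classify the replication-timing trend of a density vector
#'
#' An ordinary least-squares line is fitted to the ten normalised
#' densities against decile index. The trend is `INCREASING` when the
#' slope differs significantly from zero (two-sided t test at `alpha`)
#' and the densities are monotonically non-decreasing from early to late;
#' `DECREASING` symmetrically; otherwise `FLAT`.
#'
#' @param x numeric vector of 10 normalised densities
#'   (earliest to latest decile).
#' @param alpha significance level for the slope (default 0.05).
#' @return list with `trend`, `slope`, `p`.
#' @export
classify_trend <- function(x, alpha = 0.05) {
  stopifnot(length(x) == 10L, all(is.finite(x)))
  idx <- 1:10
  if (stats::sd(x) == 0)
    return(list(trend = "FLAT", slope = 0, p = 1))
  fit <- stats::lm(x ~ idx)
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm["idx", "Estimate"]
  p <- sm["idx", "Pr(>|t|)"]
  d <- diff(x)
  trend <- if (p <= alpha && all(d >= 0) && slope > 0) "INCREASING"
  else if (p <= alpha && all(d <= 0) && slope < 0) "DECREASING"
  else "FLAT"
  list(trend = trend, slope = slope, p = p)
}
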