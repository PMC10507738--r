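# Strand-asymmetry testing: real strand ratios are compared with simulated
# strand ratios through an odds ratio, with a two-sided Fisher exact test
# on the 2x2 count table and Benjamini-Hochberg correction across one
# analysis family.

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Closed-form hypergeometric computation (sum of all tables with the same
#' margins whose probability does not exceed the observed one, with the
#' customary small relative tolerance). Agrees with
#' `stats::fisher.test()`; implemented directly so large test families
#' remain cheap.
#'
#' @param a,b,c,d cell counts, rows = (real, simulated), columns = the two
#'   strata.
#' @return two-sided p value.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  m <- a + b  # row 1 total
  n <- c + d
  k <- a + c  # column 1 total
  if (m + n == 0) return(1)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  x <- lo:hi
  dens <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Odds ratio between real and simulated strand ratios
#'
#' OR = (real_a / real_b) / (sim_a / sim_b); p from the two-sided Fisher
#' exact test on the table `[[real_a, real_b], [sim_a, sim_b]]`. Zero
#' denominators yield an infinite or zero odds ratio with the p value
#' still defined by the exact test; an all-zero row makes the result
#' untestable.
#'
#' @param real_a,real_b real mutation counts on the two strata.
#' @param sim_a,sim_b simulated counts on the same strata.
#' @return list with `odds_ratio`, `p`, `testable`.
#' @export
strand_odds_ratio <- function(real_a, real_b, sim_a, sim_b) {
  testable <- (real_a + real_b) > 0 && (sim_a + sim_b) > 0
  or <- (real_a / real_b) / (sim_a / sim_b)
  if (is.nan(or)) or <- if (real_a > 0) Inf else 0
  p <- if (testable) fisher_exact_p(real_a, real_b, sim_a, sim_b) else NA_real_
  list(odds_ratio = or, p = p, testable = testable)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the
#' input.
#'
#' @param pvals numeric vector of p values in `[0, 1]`.
#' @return vector of q values.
#' @export
bh_adjust <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}

#' Build a strand count table from annotated catalogs
#'
#' Aggregates mutation counts per (signature, six-class channel) on two
#' strata (e.g. transcribed/untranscribed or lagging/leading) for the real
#' catalog and for each simulated replicate. Simulated counts entering the
#' table are the per-replicate mean rounded to the nearest integer;
#' `aggregate = "sum"` pools replicates instead.
#'
#' @param real annotated real catalog (needs `signature`, `channel6` and
#'   the `label` column named by `label_col`).
#' @param sims list of annotated simulated catalogs with the same columns.
#' @param label_col name of the label column.
#' @param stratum_a,stratum_b the two label values compared (a vs b).
#' @param signatures signatures to tabulate (default: those in `real`).
#' @param aggregate `"mean"` (default) or `"sum"` across replicates.
#' @return data frame with `signature`, `channel`, `real_a`, `real_b`,
#'   `sim_a`, `sim_b`.
#' @export
strand_count_table <- function(real, sims, label_col, stratum_a, stratum_b,
                               signatures = NULL,
                               aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (is.null(signatures))
    signatures <- sort(setdiff(unique(real$signature), "UNASSIGNED"))
  count_cells <- function(df) {
    keep <- df$signature %in% signatures & !is.na(df$channel6) &
      df[[label_col]] %in% c(stratum_a, stratum_b)
    df <- df[keep, , drop = FALSE]
    tab <- table(factor(df$signature, signatures),
                 factor(df$channel6, sbs6_channels()),
                 factor(df[[label_col]], c(stratum_a, stratum_b)))
    tab
  }
  rtab <- count_cells(real)
  stabs <- lapply(sims, count_cells)
  ssum <- Reduce(`+`, stabs)
  sagg <- if (aggregate == "mean") round(ssum / length(sims)) else ssum
  grid <- expand.grid(signature = signatures, channel = sbs6_channels(),
                      stringsAsFactors = FALSE)
  grid$real_a <- as.vector(rtab[cbind(grid$signature, grid$channel,
                                      stratum_a)])
  grid$real_b <- as.vector(rtab[cbind(grid$signature, grid$channel,
                                      stratum_b)])
  grid$sim_a <- as.vector(sagg[cbind(grid$signature, grid$channel,
                                     stratum_a)])
  grid$sim_b <- as.vector(sagg[cbind(grid$signature, grid$channel,
                                     stratum_b)])
  grid[order(grid$signature, grid$channel), , drop = FALSE]
}

#' Detect strand asymmetries against the simulated null
#'
#' Tests every (signature, channel) cell of a strand count table,
#' correcting across the whole family with Benjamini-Hochberg. A cell is
#' reported when its corrected p value is at most `q_max` and the odds
#' ratio departs from 1 by more than `or_min` in either direction (strict
#' inequality). Direction is the stratum whose real share exceeds its
#' simulated share.
#'
#' @param counts table from [strand_count_table()] (or any data frame with
#'   `real_a`, `real_b`, `sim_a`, `sim_b`).
#' @param or_min minimum odds ratio (default 1.10).
#' @param q_max maximum corrected p (default 0.05).
#' @return `counts` with `odds_ratio`, `p`, `q`, `direction`, `reported`.
#' @export
detect_asymmetries <- function(counts, or_min = 1.10, q_max = 0.05) {
  res <- mapply(strand_odds_ratio, counts$real_a, counts$real_b,
                counts$sim_a, counts$sim_b, SIMPLIFY = FALSE)
  counts$odds_ratio <- vapply(res, `[[`, numeric(1), "odds_ratio")
  counts$p <- vapply(res, function(x) {
    if (isTRUE(x$testable)) x$p else NA_real_
  }, numeric(1))
  counts$testable <- vapply(res, `[[`, logical(1), "testable")
  counts$q <- NA_real_
  ok <- !is.na(counts$p)
  counts$q[ok] <- bh_adjust(counts$p[ok])
  counts$direction <- ifelse(counts$odds_ratio > 1, "a",
                             ifelse(counts$odds_ratio < 1, "b", "none"))
  counts$reported <- ok & counts$q <= q_max &
    (counts$odds_ratio > or_min | counts$odds_ratio < 1 / or_min)
  counts$reported[is.na(counts$reported)] <- FALSE
  counts
}

#' Genic versus intergenic enrichment with optional asymmetry correction
#'
#' Same odds-ratio/Fisher machinery as the strand tests, on genic versus
#' intergenic counts. With `corrected = TRUE` the genic count is rebuilt
#' as twice the larger of the transcribed and untranscribed counts,
#' removing any contribution of transcription strand asymmetry to the
#' fold change.
#'
#' @param real_genic,real_intergenic real counts.
#' @param sim_genic,sim_intergenic simulated counts.
#' @param corrected apply the strand-asymmetry correction.
#' @param real_transcribed,real_untranscribed per-strand genic counts,
#'   required when `corrected = TRUE`.
#' @return list with `odds_ratio`, `p`, `genic_used`.
#' @export
genic_intergenic_fold <- function(real_genic, real_intergenic, sim_genic,
                                  sim_intergenic, corrected = FALSE,
                                  real_transcribed = NULL,
                                  real_untranscribed = NULL) {
  if (corrected) {
    if (is.null(real_transcribed) || is.null(real_untranscribed))
      input_error("corrected fold needs per-strand genic counts")
    real_genic <- 2 * max(real_transcribed, real_untranscribed)
  }
  res <- strand_odds_ratio(real_genic, real_intergenic, sim_genic,
                           sim_intergenic)
  list(odds_ratio = res$odds_ratio, p = res$p, genic_used = real_genic)
}
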