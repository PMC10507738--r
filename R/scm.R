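# Strand-coordinated mutagenesis: maximal runs of consecutive single base
# substitutions in one sample that share the six-class channel, the
# reference strand of their pyrimidine, and the attributed signature, with
# every inter-mutational distance below the threshold. Runs of length 1
# are discarded.

#' Find strand-coordinated mutation groups
#'
#' Only substitutions assigned to a signature with probability at least
#' `prob_cutoff` enter the scan; distances are measured between retained
#' mutations. Runs are maximal: a group ends where the sample, chromosome,
#' signature, channel or strand changes, or where the gap to the next
#' retained mutation reaches `imd`.
#'
#' @param muts attributed mutation data frame (needs `sample`, `chrom`,
#'   `pos`, `type`, `channel6`, `pyr_strand`, `signature`,
#'   `probability`).
#' @param imd inter-mutational distance threshold in bases (gap must be
#'   strictly below it; default 10,000).
#' @param prob_cutoff minimum assignment probability (default 0.5).
#' @return data frame with one row per group: `sample`, `signature`,
#'   `channel`, `strand`, `chrom`, `start`, `end`, `length`.
#' @export
find_scm_groups <- function(muts, imd = 10000, prob_cutoff = 0.5) {
  keep <- muts$type == "SBS" & muts$signature != "UNASSIGNED" &
    !is.na(muts$probability) & muts$probability >= prob_cutoff &
    !is.na(muts$channel6) & !is.na(muts$pyr_strand)
  m <- muts[keep, , drop = FALSE]
  empty <- data.frame(sample = character(0), signature = character(0),
                      channel = character(0), strand = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0))
  if (nrow(m) < 2L) return(empty)
  m <- m[order(m$sample, m$chrom, m$pos), , drop = FALSE]
  same_key <- m$sample[-1L] == m$sample[-nrow(m)] &
    m$chrom[-1L] == m$chrom[-nrow(m)] &
    m$signature[-1L] == m$signature[-nrow(m)] &
    m$channel6[-1L] == m$channel6[-nrow(m)] &
    m$pyr_strand[-1L] == m$pyr_strand[-nrow(m)]
  close_enough <- (m$pos[-1L] - m$pos[-nrow(m)]) < imd
  new_run <- c(TRUE, !(same_key & close_enough))
  run_id <- cumsum(new_run)
  len <- tabulate(run_id)
  keep_runs <- which(len >= 2L)
  if (length(keep_runs) == 0L) return(empty)
  first <- match(keep_runs, run_id)
  last <- length(run_id) - match(keep_runs, rev(run_id)) + 1L
  out <- data.frame(sample = m$sample[first], signature = m$signature[first],
                    channel = m$channel6[first],
                    strand = m$pyr_strand[first], chrom = m$chrom[first],
                    start = m$pos[first], end = m$pos[last],
                    length = len[keep_runs])
  rownames(out) <- NULL
  out
}

#' Histogram of group lengths per signature
#'
#' @param groups data frame from [find_scm_groups()].
#' @return data frame with `signature`, `length`, `count`.
#' @export
scm_length_histogram <- function(groups) {
  if (nrow(groups) == 0L)
    return(data.frame(signature = character(0), length = integer(0),
                      count = integer(0)))
  tab <- as.data.frame(table(signature = groups$signature,
                             length = groups$length),
                       stringsAsFactors = FALSE)
  tab$length <- as.integer(tab$length)
  names(tab)[3] <- "count"
  tab <- tab[tab$count > 0L, , drop = FALSE]
  tab[order(tab$signature, tab$length), , drop = FALSE]
}

#' Test observed group-length counts against simulated replicates
#'
#' For every (signature, length) cell seen in the real or simulated
#' catalogs, a z statistic compares the observed number of groups with the
#' mean and standard deviation of the per-replicate counts; two-sided
#' normal p values are Benjamini-Hochberg corrected across all cells.
#' Cells whose replicate counts have zero variance are flagged degenerate:
#' the p value is 1 when the observation equals the common simulated
#' value, else a zero sentinel (the observation lies outside anything the
#' null produced).
#'
#' @param real_groups groups found in the real catalog.
#' @param sim_groups_list list of group data frames, one per simulated
#'   replicate.
#' @param q_max reporting threshold on corrected p (default 0.05).
#' @return data frame with `signature`, `length`, `observed`, `sim_mean`,
#'   `sim_sd`, `z`, `p`, `q`, `degenerate`, `reported`.
#' @export
test_scm_lengths <- function(real_groups, sim_groups_list, q_max = 0.05) {
  if (length(sim_groups_list) < 2L)
    input_error("at least 2 simulated replicates required")
  real_h <- scm_length_histogram(real_groups)
  sim_h <- lapply(sim_groups_list, scm_length_histogram)
  cells <- unique(rbind(real_h[c("signature", "length")],
                        do.call(rbind,
                                lapply(sim_h, `[`,
                                       c("signature", "length")))))
  if (nrow(cells) == 0L)
    return(data.frame(signature = character(0), length = integer(0),
                      observed = integer(0), sim_mean = numeric(0),
                      sim_sd = numeric(0), z = numeric(0), p = numeric(0),
                      q = numeric(0), degenerate = logical(0),
                      reported = logical(0)))
  cells <- cells[order(cells$signature, cells$length), , drop = FALSE]
  lookup <- function(h, sig, len) {
    i <- which(h$signature == sig & h$length == len)
    if (length(i)) h$count[i] else 0L
  }
  n_cells <- nrow(cells)
  obs <- integer(n_cells); mu <- numeric(n_cells); sdev <- numeric(n_cells)
  z <- numeric(n_cells); p <- numeric(n_cells); degen <- logical(n_cells)
  for (i in seq_len(n_cells)) {
    sig <- cells$signature[i]; len <- cells$length[i]
    obs[i] <- lookup(real_h, sig, len)
    sims <- vapply(sim_h, lookup, numeric(1), sig, len)
    mu[i] <- mean(sims)
    sdev[i] <- stats::sd(sims)
    if (sdev[i] == 0) {
      degen[i] <- TRUE
      z[i] <- if (obs[i] == mu[i]) 0 else Inf * sign(obs[i] - mu[i])
      p[i] <- if (obs[i] == mu[i]) 1 else 0
    } else {
      z[i] <- (obs[i] - mu[i]) / sdev[i]
      p[i] <- 2 * stats::pnorm(-abs(z[i]))
    }
  }
  out <- data.frame(signature = cells$signature, length = cells$length,
                    observed = obs, sim_mean = mu, sim_sd = sdev,
                    z = z, p = p, q = bh_adjust(p), degenerate = degen)
  out$reported <- out$q <= q_max & out$observed != out$sim_mean
  rownames(out) <- NULL
  out
}
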