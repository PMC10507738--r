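# Cohort stratification: APOBEC3 presence classes from the log-ratio of
# APOBEC-attributed (SBS2/SBS13) to other mutations, and generic
# annotation-driven group comparisons.

#' APOBEC3 presence ratio of one sample
#'
#' `ln(n_apobec) / ln(n_other)`, where `n_apobec` counts mutations
#' attributed to SBS2 or SBS13 and `n_other` all remaining attributed
#' mutations. Samples with `n_apobec = 0` or `n_other < 2` (non-positive
#' log denominator) are unclassifiable.
#'
#' @param n_apobec count of SBS2/SBS13-attributed mutations.
#' @param n_other count of all other mutations.
#' @return the ratio, or `NA` when unclassifiable.
#' @export
apobec_ratio <- function(n_apobec, n_other) {
  ifelse(n_apobec >= 1 & n_other >= 2,
         log(n_apobec) / log(n_other), NA_real_)
}

#' Classify samples by APOBEC3 presence
#'
#' Ratios of at least 0.90 are `HIGH`; ratios strictly between 0.75 and
#' 0.90 are `MID` (excluded from downstream group re-analyses); ratios of
#' at most 0.75 are `LOW`. Unclassifiable samples get `NA`.
#'
#' @param attributed attributed mutation data frame (`sample`,
#'   `signature`).
#' @param apobec_signatures signature names counted as APOBEC3-associated
#'   (default SBS2 and SBS13).
#' @return data frame with `sample`, `n_apobec`, `n_other`, `ratio`,
#'   `class`.
#' @export
classify_apobec <- function(attributed,
                            apobec_signatures = c("SBS2", "SBS13")) {
  att <- attributed[attributed$signature != "UNASSIGNED", , drop = FALSE]
  samples <- sort(unique(attributed$sample))
  n_apo <- vapply(samples, function(s)
    sum(att$sample == s & att$signature %in% apobec_signatures),
    numeric(1))
  n_oth <- vapply(samples, function(s)
    sum(att$sample == s & !att$signature %in% apobec_signatures),
    numeric(1))
  ratio <- apobec_ratio(n_apo, n_oth)
  cls <- ifelse(is.na(ratio), NA_character_,
                ifelse(ratio >= 0.90, "HIGH",
                       ifelse(ratio > 0.75, "MID", "LOW")))
  data.frame(sample = samples, n_apobec = as.integer(n_apo),
             n_other = as.integer(n_oth), ratio = ratio, class = cls,
             row.names = NULL)
}

#' Compare per-sample mutation burdens between two groups
#'
#' Fold change of group medians with a two-sided Mann-Whitney U test.
#'
#' @param group_a,group_b numeric vectors of per-sample attributed
#'   mutation counts.
#' @return list with `fold` (median a over median b) and `p`.
#' @export
compare_group_burden <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    input_error("both groups must be non-empty")
  med_a <- stats::median(group_a)
  med_b <- stats::median(group_b)
  fold <- if (med_b != 0) med_a / med_b else NA_real_
  p <- suppressWarnings(stats::wilcox.test(group_a, group_b)$p.value)
  if (is.na(p)) p <- 1
  list(fold = fold, p = p)
}

#' Split samples by an annotation column
#'
#' @param annotations data frame with a `sample` column and grouping
#'   columns (e.g. drinker status, POLE genotype).
#' @param column grouping column name.
#' @return named list of sample-id vectors, one per group level.
#' @export
sample_groups <- function(annotations, column) {
  if (!column %in% names(annotations))
    input_error("no annotation column named ", column)
  split(annotations$sample, annotations[[column]])
}
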