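#' Assign each mutation to its most probable signature
#'
#' The argmax signature is taken when its probability reaches `cutoff`
#' (default 0.5, i.e. at least an even chance that the signature generated
#' the mutation); otherwise the mutation is `UNASSIGNED`. Ties are broken
#' by lexicographic signature name so that assignment is deterministic.
#'
#' @param probs matrix or data frame of probabilities, one column per
#'   signature, one row per mutation; rows sum to 1.
#' @param cutoff minimum probability for an assignment.
#' @return data frame with `signature` and `probability` per row.
#' @export
assign_signature <- function(probs, cutoff = 0.5) {
  probs <- as.matrix(probs)
  if (ncol(probs) == 0L || nrow(probs) == 0L)
    input_error("empty probability rows")
  ord <- order(colnames(probs))
  probs <- probs[, ord, drop = FALSE]
  best <- max.col(probs, ties.method = "first")
  p <- probs[cbind(seq_len(nrow(probs)), best)]
  sig <- colnames(probs)[best]
  sig[p < cutoff] <- "UNASSIGNED"
  data.frame(signature = sig, probability = p)
}

#' Attach signature assignments to a mutation catalog
#'
#' Joins a probability table onto mutations by (sample, chrom, pos),
#' applies [assign_signature()] and adds channel labels (SBS-96 / DBS-78 /
#' ID-83 by mutation type, plus the six-class channel and pyrimidine
#' strand for substitutions).
#'
#' @param muts mutation data frame.
#' @param probs probability table from [read_probabilities()] (or a data
#'   frame of the same shape).
#' @param genome a `GenomeSequence` for channel classification.
#' @param cutoff probability cutoff for assignment.
#' @return `muts` with `channel`, `channel6`, `pyr_strand`, `signature`,
#'   `probability` columns; mutations absent from the table are
#'   `UNASSIGNED` with probability `NA`.
#' @export
attribute_mutations <- function(muts, probs, genome, cutoff = 0.5) {
  sigs <- attr(probs, "signatures")
  if (is.null(sigs)) sigs <- setdiff(names(probs),
                                     c("sample", "chrom", "pos"))
  key_m <- paste(muts$sample, muts$chrom, muts$pos, sep = "\r")
  key_p <- paste(probs$sample, probs$chrom, probs$pos, sep = "\r")
  idx <- match(key_m, key_p)
  muts$channel <- classify_mutations(muts, genome)
  muts$channel6 <- NA_character_
  sbs <- muts$type == "SBS"
  muts$channel6[sbs] <- classify_sbs6(muts$ref[sbs], muts$alt[sbs])
  muts$pyr_strand <- pyrimidine_strand(muts$ref, muts$alt)
  muts$signature <- "UNASSIGNED"
  muts$probability <- NA_real_
  hit <- !is.na(idx)
  if (any(hit)) {
    asn <- assign_signature(probs[idx[hit], sigs, drop = FALSE], cutoff)
    muts$signature[hit] <- asn$signature
    muts$probability[hit] <- asn$probability
  }
  muts
}

#' Signatures passing the minimum-attribution filter
#'
#' Per-signature analyses only consider signatures with a minimum number
#' of unambiguously attributed mutations (default 1,000).
#'
#' @param attributed mutation data frame with a `signature` column.
#' @param min_count minimum attributed mutations per signature.
#' @return data frame with `signature` and `count` for signatures passing
#'   the filter (UNASSIGNED never passes).
#' @export
signature_mutation_counts <- function(attributed, min_count = 1000) {
  if (nrow(attributed) == 0L)
    return(data.frame(signature = character(0), count = integer(0)))
  tab <- table(attributed$signature[attributed$signature != "UNASSIGNED"])
  keep <- tab[tab >= min_count]
  out <- data.frame(signature = names(keep),
                    count = as.integer(keep))
  out[order(out$signature), , drop = FALSE]
}
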