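#' @keywords internal
"_PACKAGE"

# Complement map shared by all strand operations. N stays N.
.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement DNA strings
#'
#' Vectorised over `x`; strings may contain `N`. Used wherever mutations,
#' contexts or doublets are collapsed onto the pyrimidine strand.
#'
#' @param x character vector of DNA strings (A/C/G/T/N, uppercase).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACA", "TGC"))
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  n <- nchar(comp)
  out <- character(length(comp))
  w3 <- which(n == 3L)
  if (length(w3)) {
    out[w3] <- paste0(substr(comp[w3], 3L, 3L), substr(comp[w3], 2L, 2L),
                      substr(comp[w3], 1L, 1L))
  }
  w2 <- which(n == 2L)
  if (length(w2)) {
    out[w2] <- paste0(substr(comp[w2], 2L, 2L), substr(comp[w2], 1L, 1L))
  }
  w1 <- which(n == 1L)
  if (length(w1)) out[w1] <- comp[w1]
  rest <- which(n > 3L)
  if (length(rest)) {
    out[rest] <- vapply(strsplit(comp[rest], "", fixed = TRUE),
                        function(s) paste(rev(s), collapse = ""), character(1))
  }
  out[n == 0L] <- ""
  out
}

#' Complement of single bases (vectorised, no reversal)
#' @param x character vector of single bases.
#' @return complemented bases.
#' @keywords internal
complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

is_pyrimidine <- function(x) x %in% c("C", "T")

# Derive a per-replicate RNG seed from a master seed; keeps results
# reproducible per (seed, replicate) and below 2^31.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(stream)) %%
               2147483629)
}

# Stop with a consistent error class so callers/tests can distinguish
# format errors from programming errors.
format_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("topomut_format_error", "error")))
}

input_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("topomut_input_error", "error")))
}
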