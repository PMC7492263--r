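# Shared constants and small helpers.

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
# X is tolerated (unknown residue) but never matches any signal predicate.
AA_VALID <- c(AA_STANDARD, "X")
AA_BASIC <- c("K", "R")
AA_PHI <- c("L", "I", "V", "F", "M")      # hydrophobic NES anchor residues

TOOLS <- c("wolfpsort", "yloc", "cello", "nucpred")
CATEGORY_LEVELS <- c("non_nuclear", "cat1", "cat2", "cat3", "cat4")
LOC_CLASSES <- c("no_signal", "export_signal_only", "nuclear_resident", "shuttling")

#' Round half away from zero
#'
#' Plain half-up rounding (0.005 -> 0.01 at 2 digits), used for all reported
#' percentages instead of [base::round()]'s round-half-to-even rule.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage with half-up rounding
#'
#' @param k numerator count.
#' @param n denominator count; `NA` is returned when `n` is zero (a missing
#'   percentage, never silently 0).
#' @param digits decimal places (default 2).
#' @return percentage `100 * k / n`, rounded.
#' @export
percent <- function(k, n, digits = 2) {
  out <- round_half_up(100 * k / n, digits)
  out[rep_len(!(n > 0), length(out))] <- NA_real_
  out
}

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

# Sequence must be non-empty, uppercase, over the 20-letter alphabet plus X.
validate_sequence <- function(sequence, id = "<sequence>") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("empty sequence for ", id, call. = FALSE)
  bad <- gsub(paste0("[", paste(AA_VALID, collapse = ""), "]"), "", sequence)
  if (nzchar(bad))
    stop(sprintf("invalid amino-acid letter(s) '%s' in %s",
                 paste(unique(seq_chars(bad)), collapse = ""), id),
         call. = FALSE)
  invisible(TRUE)
}

empty_match_df <- function() {
  data.frame(kind = character(), start = integer(), length = integer(),
             match = character(), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
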