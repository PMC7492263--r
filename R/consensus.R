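# Binary nuclear calls per predictor and the five-category consensus vote.

NUCLEUS_TOKENS <- c("nucleus", "nuclear")

#' Normalize one predictor's output to a binary nuclear call
#'
#' For WoLF-PSORT, CELLO and YLoc the call is nuclear iff the nucleus
#' compartment's score is strictly greater than every other compartment's
#' score (argmax with a conservative tie rule: a tie involving the nucleus
#' is not nuclear). For NucPred the call is nuclear iff the score is
#' strictly above `config$nucpred_threshold`.
#'
#' @param tool one of `"wolfpsort"`, `"yloc"`, `"cello"`, `"nucpred"`.
#' @param scores for argmax tools a named numeric vector of compartment
#'   scores; for nucpred a single score in `[0, 1]`.
#' @param config a [pipeline_config()].
#' @return list with `nuclear`, `top_compartment`, `top_score`.
#' @export
normalize_call <- function(tool, scores, config = pipeline_config()) {
  tool <- match.arg(tolower(tool), TOOLS)
  if (tool == "nucpred") {
    stopifnot(length(scores) == 1L, is.numeric(scores))
    if (scores < 0 || scores > 1) stop("nucpred score must lie in [0, 1]")
    return(list(nuclear = unname(scores) > config$nucpred_threshold,
                top_compartment = "nuclear", top_score = unname(scores)))
  }
  if (length(scores) == 0L) stop("empty compartment score map for ", tool)
  if (is.null(names(scores)) || !all(nzchar(names(scores))))
    stop("compartment scores must be named")
  if (tool == "yloc" && any(scores < 0))
    stop("negative probability score for yloc")
  comp <- tolower(names(scores))
  is_nuc <- comp %in% NUCLEUS_TOKENS
  nuc <- if (any(is_nuc)) max(scores[is_nuc]) else -Inf
  other <- if (any(!is_nuc)) max(scores[!is_nuc]) else -Inf
  top <- which.max(scores)
  list(nuclear = nuc > other,
       top_compartment = comp[top], top_score = unname(scores[top]))
}

#' Normalize a whole prediction table to per-(protein, tool) nuclear calls
#'
#' Vectorized version of [normalize_call()] over a long-format prediction
#' table as read by [read_prediction_table()].
#'
#' @param predictions data frame with columns `protein_id`, `tool`,
#'   `compartment`, `score`.
#' @param config a [pipeline_config()].
#' @return data frame with one row per (protein, tool): `locus_id`, `tool`,
#'   `nuclear`, `top_compartment`, `top_score`.
#' @export
normalize_calls <- function(predictions, config = pipeline_config()) {
  p <- predictions
  stopifnot(all(c("protein_id", "tool", "compartment", "score") %in% names(p)))
  p$tool <- tolower(p$tool)
  bad <- setdiff(unique(p$tool), TOOLS)
  if (length(bad)) stop("unknown tool name(s): ", paste(bad, collapse = ", "))
  if (any(p$tool == "yloc" & p$score < 0))
    stop("negative probability score for yloc")
  p$compartment <- tolower(p$compartment)

  np <- p[p$tool == "nucpred", , drop = FALSE]
  if (nrow(np) && (any(np$score < 0) || any(np$score > 1)))
    stop("nucpred score must lie in [0, 1]")
  np_calls <- if (nrow(np)) {
    data.frame(locus_id = np$protein_id, tool = "nucpred",
               nuclear = np$score > config$nucpred_threshold,
               top_compartment = "nuclear", top_score = np$score,
               stringsAsFactors = FALSE)
  } else NULL

  am <- p[p$tool != "nucpred", , drop = FALSE]
  am_calls <- if (nrow(am)) {
    key <- paste(am$protein_id, am$tool, sep = "\r")
    is_nuc <- am$compartment %in% NUCLEUS_TOKENS
    nuc_score <- tapply(ifelse(is_nuc, am$score, -Inf), key, max)
    oth_score <- tapply(ifelse(is_nuc, -Inf, am$score), key, max)
    ord <- order(key, -am$score)
    top <- am[ord, ][!duplicated(key[ord]), ]
    tkey <- paste(top$protein_id, top$tool, sep = "\r")
    data.frame(locus_id = top$protein_id, tool = top$tool,
               nuclear = unname(nuc_score[tkey] > oth_score[tkey]),
               top_compartment = top$compartment, top_score = top$score,
               stringsAsFactors = FALSE)
  } else NULL

  out <- rbind(np_calls, am_calls)
  out <- out[order(out$locus_id, out$tool), , drop = FALSE]
  rownames(out) <- NULL
  out
}

category_label <- function(votes) {
  ifelse(votes == 0L, "non_nuclear", paste0("cat", votes))
}

#' Consensus category for one protein
#'
#' Counts the predictors calling the protein nuclear (0-4 votes) and maps
#' the count to the five-category label (`non_nuclear`, `cat1` ... `cat4`).
#' Tools without a call are counted as non-nuclear votes with a warning.
#'
#' @param calls data frame with columns `tool` and `nuclear` for a single
#'   protein (at most one row per tool).
#' @return list with `votes`, `category` and `tools_called` (the tools
#'   voting nuclear).
#' @export
assign_category <- function(calls) {
  stopifnot(nrow(calls) >= 1L, all(calls$tool %in% TOOLS))
  if (anyDuplicated(calls$tool))
    stop("two calls from the same tool: ",
         paste(unique(calls$tool[duplicated(calls$tool)]), collapse = ", "))
  missing <- setdiff(TOOLS, calls$tool)
  if (length(missing))
    warning("missing tool call(s) counted as non-nuclear: ",
            paste(missing, collapse = ", "), call. = FALSE)
  votes <- sum(calls$nuclear)
  list(votes = as.integer(votes), category = category_label(votes),
       tools_called = sort(calls$tool[calls$nuclear]))
}

#' Consensus categories for a whole call table
#'
#' @param calls data frame from [normalize_calls()] (columns `locus_id`,
#'   `tool`, `nuclear`).
#' @return data frame with one row per protein: `locus_id`, `votes`,
#'   `category` (factor over the five levels), `tools_called`
#'   (comma-separated).
#' @export
consensus_categories <- function(calls) {
  stopifnot(all(c("locus_id", "tool", "nuclear") %in% names(calls)))
  if (nrow(calls) == 0L)
    return(data.frame(locus_id = character(), votes = integer(),
                      category = factor(character(), levels = CATEGORY_LEVELS),
                      tools_called = character(), stringsAsFactors = FALSE))
  key <- paste(calls$locus_id, calls$tool, sep = "\r")
  if (anyDuplicated(key))
    stop("two calls from the same tool for protein(s): ",
         paste(utils::head(unique(calls$locus_id[duplicated(key)]), 5),
               collapse = ", "))
  n_tools <- tapply(calls$tool, calls$locus_id, length)
  if (any(n_tools < length(TOOLS)))
    warning(sum(n_tools < length(TOOLS)),
            " protein(s) with missing tool calls; missing tools counted as ",
            "non-nuclear", call. = FALSE)
  votes <- tapply(calls$nuclear, calls$locus_id, sum)
  called <- tapply(ifelse(calls$nuclear, calls$tool, NA_character_),
                   calls$locus_id,
                   function(x) paste(sort(x[!is.na(x)]), collapse = ","))
  ids <- names(votes)
  data.frame(locus_id = ids, votes = as.integer(votes),
             category = factor(category_label(as.integer(votes)),
                               levels = CATEGORY_LEVELS),
             tools_called = unname(called[ids]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Category counts and headline fractions
#'
#' Reporting layer shared by [categorize_dataset()]: given counts per
#' category it derives the totals and percentages the analysis reports,
#' including the "category >= 2" higher-assertion aggregate.
#'
#' @param counts named numeric vector of per-category protein counts
#'   (missing categories default to 0).
#' @param digits decimal places for percentages.
#' @return list with `counts` (all five categories), `n_total`,
#'   `n_cat2_plus`, `percent_by_category`, `percent_non_nuclear` and
#'   `percent_nuclear_any` (category >= 1).
#' @export
category_summary <- function(counts, digits = 2) {
  full <- stats::setNames(numeric(length(CATEGORY_LEVELS)), CATEGORY_LEVELS)
  bad <- setdiff(names(counts), CATEGORY_LEVELS)
  if (length(bad)) stop("unknown category label(s): ", paste(bad, collapse = ", "))
  full[names(counts)] <- counts
  n <- sum(full)
  list(counts = full,
       n_total = n,
       n_cat2_plus = unname(sum(full[c("cat2", "cat3", "cat4")])),
       percent_by_category = percent(full, n, digits),
       percent_non_nuclear = unname(percent(full[["non_nuclear"]], n, digits)),
       percent_nuclear_any = unname(percent(n - full[["non_nuclear"]], n, digits)))
}

#' Category count table for a consensus data frame
#'
#' @param consensus data frame from [consensus_categories()].
#' @param digits decimal places for percentages.
#' @return a [category_summary()] list.
#' @export
categorize_dataset <- function(consensus, digits = 2) {
  counts <- table(factor(consensus$category, levels = CATEGORY_LEVELS))
  category_summary(stats::setNames(as.numeric(counts), names(counts)), digits)
}
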