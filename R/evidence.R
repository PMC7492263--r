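# Benchmarking consensus categories and individual tools against
# experimentally observed localizations.

#' Merge evidence records per protein
#'
#' Multiple sources for one protein are merged by set union of their
#' compartments; a protein counts as nuclear-evidenced when any source saw
#' the nucleus (conditional nuclear movers count as nuclear).
#'
#' @param evidence data frame from [read_evidence_table()].
#' @return data frame with one row per protein: `locus_id`, `compartments`
#'   (sorted, semicolon-joined), `nuclear`, `nucleus_only`.
#' @export
merge_evidence <- function(evidence) {
  toks <- strsplit(tolower(evidence$compartments), ";", fixed = TRUE)
  long <- data.frame(locus_id = rep(evidence$protein_id, lengths(toks)),
                     comp = trimws(unlist(toks)), stringsAsFactors = FALSE)
  long <- long[nzchar(long$comp), , drop = FALSE]
  sets <- lapply(split(long$comp, long$locus_id), function(x) sort(unique(x)))
  data.frame(locus_id = names(sets),
             compartments = vapply(sets, paste, "", collapse = ";"),
             nuclear = vapply(sets, function(s) "nucleus" %in% s, logical(1)),
             nucleus_only = vapply(sets, function(s) identical(s, "nucleus"),
                                   logical(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Agreement between consensus categories and localization evidence
#'
#' For each category, the percentage of evidenced proteins whose merged
#' evidence includes the nucleus; categories without evidenced proteins
#' report a missing (NA) percentage, never 0. The pooled "category >= 3"
#' set gives the combined accuracy of the two high-confidence categories.
#'
#' @param consensus data frame from [consensus_categories()].
#' @param evidence data frame from [read_evidence_table()] (deduplicated
#'   internally via [merge_evidence()]).
#' @param digits decimal places for percentages.
#' @return list with `by_category` (data frame: `category`, `n_evidenced`,
#'   `n_nuclear`, `percent_nuclear`) and `pooled_cat3plus` (list with `n`,
#'   `n_nuclear`, `percent_nuclear`).
#' @export
agreement_by_category <- function(consensus, evidence, digits = 2) {
  ev <- merge_evidence(evidence)
  m <- merge(consensus[c("locus_id", "category")], ev, by = "locus_id")
  cat_f <- factor(m$category, levels = CATEGORY_LEVELS)
  n_ev <- as.integer(table(cat_f))
  n_nuc <- as.integer(tapply(m$nuclear, cat_f, sum, default = 0L))
  by_cat <- data.frame(category = CATEGORY_LEVELS,
                       n_evidenced = n_ev, n_nuclear = n_nuc,
                       percent_nuclear = percent(n_nuc, n_ev, digits),
                       stringsAsFactors = FALSE)
  hi <- m$category %in% c("cat3", "cat4")
  pooled <- list(n = sum(hi), n_nuclear = sum(m$nuclear[hi]),
                 percent_nuclear = percent(sum(m$nuclear[hi]), sum(hi), digits))
  list(by_category = by_cat, pooled_cat3plus = pooled)
}

#' Per-tool accuracy on evidenced-nuclear proteins
#'
#' Sensitivity of each predictor measured on the proteins with nuclear
#' localization evidence: the percentage of evidenced-nuclear proteins the
#' tool itself called nuclear. Specificity on evidenced non-nuclear
#' proteins is reported alongside.
#'
#' @param calls data frame from [normalize_calls()].
#' @param evidence data frame from [read_evidence_table()].
#' @param digits decimal places for percentages.
#' @return data frame with one row per tool: `tool`, `n_nuclear_evidenced`,
#'   `n_called_nuclear`, `sensitivity_percent`, `n_nonnuclear_evidenced`,
#'   `specificity_percent`.
#' @export
tool_accuracy <- function(calls, evidence, digits = 2) {
  ev <- merge_evidence(evidence)
  nuc_ids <- ev$locus_id[ev$nuclear]
  non_ids <- ev$locus_id[!ev$nuclear]
  if (length(nuc_ids) == 0L)
    stop("no evidenced-nuclear proteins: tool accuracy undefined")
  rows <- lapply(sort(unique(calls$tool)), function(t) {
    tc <- calls[calls$tool == t, , drop = FALSE]
    pos <- tc$locus_id %in% nuc_ids
    neg <- tc$locus_id %in% non_ids
    data.frame(tool = t,
               n_nuclear_evidenced = sum(pos),
               n_called_nuclear = sum(tc$nuclear[pos]),
               sensitivity_percent = percent(sum(tc$nuclear[pos]), sum(pos),
                                             digits),
               n_nonnuclear_evidenced = sum(neg),
               specificity_percent = percent(sum(!tc$nuclear[neg]), sum(neg),
                                             digits),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exclusive-nuclear fraction of a category
#'
#' Among the nuclear-evidenced proteins of one consensus category, the
#' percentage whose merged evidence is restricted to the nucleus alone
#' (no other compartment ever observed).
#'
#' @param consensus data frame from [consensus_categories()].
#' @param evidence data frame from [read_evidence_table()].
#' @param category one of the five category labels.
#' @param digits decimal places.
#' @return list with `n_nuclear_evidenced`, `n_nucleus_only` and `percent`
#'   (NA when the category has no nuclear-evidenced protein).
#' @export
exclusive_nuclear_fraction <- function(consensus, evidence, category,
                                       digits = 2) {
  stopifnot(category %in% CATEGORY_LEVELS)
  ev <- merge_evidence(evidence)
  ids <- consensus$locus_id[consensus$category == category]
  sub <- ev[ev$locus_id %in% ids & ev$nuclear, , drop = FALSE]
  list(n_nuclear_evidenced = nrow(sub),
       n_nucleus_only = sum(sub$nucleus_only),
       percent = percent(sum(sub$nucleus_only), nrow(sub), digits))
}
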