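# Concordance of predicted nuclear localization across splice variants.

#' Concordance class of one splice group
#'
#' @param variant_nuclear logical vector of per-variant nuclear calls for
#'   one gene; at least two variants are required (a single-variant gene is
#'   not a splice group).
#' @return `"all_nuclear"`, `"mixed"` or `"none_nuclear"`.
#' @export
classify_gene <- function(variant_nuclear) {
  if (length(variant_nuclear) < 2L)
    stop("a splice group needs at least two variants")
  if (all(variant_nuclear)) "all_nuclear"
  else if (!any(variant_nuclear)) "none_nuclear"
  else "mixed"
}

#' Build splice groups from a variant table and normalized calls
#'
#' Variant nuclear calls come from a single designated predictor's
#' normalized call (the tool used for all gene models); variants without a
#' call from that tool are counted as non-nuclear with a warning.
#'
#' @param splice data frame with columns `gene_id`, `variant_id`.
#' @param calls data frame from [normalize_calls()] at variant level.
#' @param tool predictor supplying the per-variant call.
#' @return data frame with one row per multi-variant gene: `gene_id`,
#'   `n_variants`, `n_nuclear`, `concordance`.
#' @export
splice_groups <- function(splice, calls, tool = "wolfpsort") {
  stopifnot(tool %in% TOOLS)
  tc <- calls[calls$tool == tool, , drop = FALSE]
  call_map <- stats::setNames(tc$nuclear, tc$locus_id)
  multi <- splice$gene_id %in% names(which(table(splice$gene_id) >= 2L))
  sp <- splice[multi, , drop = FALSE]
  known <- sp$variant_id %in% names(call_map)
  if (any(!known))
    warning(sum(!known), " splice variant(s) without a ", tool,
            " call counted as non-nuclear", call. = FALSE)
  nuc <- ifelse(known, unname(call_map[sp$variant_id]), FALSE)
  genes <- split(nuc, sp$gene_id)
  data.frame(gene_id = names(genes),
             n_variants = lengths(genes),
             n_nuclear = vapply(genes, sum, integer(1)),
             concordance = vapply(genes, classify_gene, character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize splice-group concordance
#'
#' @param groups data frame from [splice_groups()], or a character vector
#'   of concordance labels.
#' @return list of counts: `n_groups`, `n_all_nuclear`, `n_mixed`,
#'   `n_none_nuclear`, `n_any_nuclear` (= all + mixed: genes with at least
#'   one nuclear-localized splice form).
#' @export
summarize_splicing <- function(groups) {
  conc <- if (is.data.frame(groups)) groups$concordance else groups
  n_all <- sum(conc == "all_nuclear")
  n_mix <- sum(conc == "mixed")
  n_none <- sum(conc == "none_nuclear")
  list(n_groups = length(conc),
       n_all_nuclear = n_all, n_mixed = n_mix, n_none_nuclear = n_none,
       n_any_nuclear = n_all + n_mix)
}
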