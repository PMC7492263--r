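# End-to-end orchestration: consensus + signals + evidence + splicing,
# with TSV/JSON writers.

as_input <- function(x, reader) {
  if (is.null(x) || is.data.frame(x) || is.list(x) && !is.character(x)) return(x)
  if (is.character(x) && length(x) == 1L) return(reader(x))
  x
}

#' Run the full nuclear-localization pipeline
#'
#' Normalizes predictor scores to binary nuclear calls, assigns the
#' five-category consensus, scans every protein for NLS/NES signals,
#' classifies resident vs shuttling proteins, and (when the corresponding
#' inputs are supplied) benchmarks the categories against localization
#' evidence, summarizes TF composition and splice-variant concordance.
#' The result is deterministic given the configuration and inputs.
#'
#' Proteins present in the prediction table but absent from the FASTA are
#' excluded with a warning; proteins without any prediction row are
#' excluded from the category tables rather than silently binned as
#' non-nuclear.
#'
#' @param fasta FASTA path or data frame from [read_fasta()].
#' @param predictions prediction-table path or data frame.
#' @param config a [pipeline_config()].
#' @param residue_scores optional per-residue NES track path or list from
#'   [read_residue_scores()]; proteins without a track use the surrogate
#'   scorer.
#' @param evidence optional evidence CSV path or data frame.
#' @param tf optional TF table path or data frame (`locus_id`, `family`).
#' @param splice optional splice table path or data frame.
#' @param out_dir optional directory; when given, writes `report.tsv` and
#'   `summary.json` there.
#' @return invisibly, a list with `report` (one row per protein present in
#'   both FASTA and prediction table) and `summary` (category counts,
#'   signal composition and optional evidence/splicing blocks).
#' @export
run_pipeline <- function(fasta, predictions, config = pipeline_config(),
                         residue_scores = NULL, evidence = NULL, tf = NULL,
                         splice = NULL, out_dir = NULL) {
  records <- as_input(fasta, read_fasta)
  predictions <- as_input(predictions, read_prediction_table)
  evidence <- as_input(evidence, read_evidence_table)
  splice <- as_input(splice, read_splice_table)
  if (is.character(tf) && length(tf) == 1L)
    tf <- read_annotation_tables(tf_path = tf)$tf
  if (is.character(residue_scores) && length(residue_scores) == 1L)
    residue_scores <- read_residue_scores(residue_scores, records)

  calls <- normalize_calls(predictions, config)
  unknown <- setdiff(calls$locus_id, records$locus_id)
  if (length(unknown)) {
    warning(length(unknown), " protein(s) in prediction table absent from ",
            "FASTA; excluded: ",
            paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    calls <- calls[!calls$locus_id %in% unknown, , drop = FALSE]
  }
  consensus <- consensus_categories(calls)
  keep <- records$locus_id %in% consensus$locus_id
  profiles <- signal_profiles(records[keep, , drop = FALSE], config,
                              residue_scores)
  report <- merge(consensus, profiles, by = "locus_id")
  report <- report[order(report$locus_id), , drop = FALSE]
  rownames(report) <- NULL
  d <- config$rounding
  report$basic_percent <- round_half_up(report$basic_percent, d)

  ev_merged <- if (!is.null(evidence)) merge_evidence(evidence) else NULL
  if (!is.null(ev_merged)) {
    report$evidence_nuclear <- ev_merged$nuclear[
      match(report$locus_id, ev_merged$locus_id)]
  }

  cats <- categorize_dataset(consensus, d)
  sig_by_cat <- lapply(stats::setNames(nm = CATEGORY_LEVELS), function(cat) {
    sub <- report[report$category == cat, , drop = FALSE]
    list(n = nrow(sub),
         percent_nls = percent(sum(sub$nls_positive), nrow(sub), d),
         percent_nes = percent(sum(sub$nes_positive), nrow(sub), d),
         percent_both = percent(sum(sub$nls_positive & sub$nes_positive),
                                nrow(sub), d),
         percent_nes_only = percent(sum(!sub$nls_positive & sub$nes_positive),
                                    nrow(sub), d))
  })
  summary <- list(
    n_proteins = nrow(report),
    categories = cats,
    signals = list(
      n_nls_positive = sum(report$nls_positive),
      n_nes_positive = sum(report$nes_positive),
      percent_nls = percent(sum(report$nls_positive), nrow(report), d),
      percent_nes = percent(sum(report$nes_positive), nrow(report), d),
      by_category = sig_by_cat))
  if (!is.null(evidence)) {
    summary$evidence <- agreement_by_category(consensus, evidence, d)
    any_nuclear_ev <- any(merge_evidence(evidence)$nuclear)
    summary$evidence$tool_accuracy <-
      if (any_nuclear_ev) tool_accuracy(calls, evidence, d) else NULL
    summary$evidence$exclusive_nuclear_cat4 <-
      exclusive_nuclear_fraction(consensus, evidence, "cat4", d)
  }
  if (!is.null(tf)) summary$tf <- tf_composition(consensus, tf, d)
  if (!is.null(splice)) {
    groups <- splice_groups(splice, calls, config$splice_tool)
    summary$splicing <- summarize_splicing(groups)
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_report_tsv(report, file.path(out_dir, "report.tsv"))
    write_summary_json(summary, file.path(out_dir, "summary.json"))
  }
  invisible(list(report = report, summary = summary))
}

#' Write the per-protein report as TSV
#'
#' Tab-delimited, UTF-8, header row, `.` decimals.
#'
#' @param report data frame from [run_pipeline()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the pipeline summary as JSON
#'
#' Key order follows the summary list (stable across runs).
#'
#' @param summary summary list from [run_pipeline()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
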