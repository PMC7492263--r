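#' Pipeline configuration
#'
#' Central container for every tunable of the analysis. Defaults follow the
#' conventions of the underlying predictors: NucPred calls are nuclear when
#' the score is strictly above 0.8; a nuclear export signal (NES) call needs
#' at least three contributing residues within a stretch of 15 amino acids;
#' external per-residue NES tracks use 0.5 as the per-residue decision
#' threshold (the built-in surrogate scorer emits 0/1 scores and uses > 0).
#' NLS weights are chosen so that any single bipartite or monopartite match
#' makes the cumulative NLS score positive.
#'
#' @param nucpred_threshold NucPred nuclear-call threshold in `[0, 1]`;
#'   a protein is nuclear when its score is strictly greater.
#' @param nes_window window length (residues) for the NES call.
#' @param nes_min_residues minimum number of contributing residues within
#'   one window for an NES-positive call.
#' @param nes_residue_threshold per-residue score above which a residue
#'   "contributes" to the NES call (applied to external tracks; the
#'   surrogate track uses 0, i.e. any anchored residue contributes).
#' @param nls_weights named numeric vector `c(pat4, pat7, bipartite, base)`
#'   of cumulative NLS score weights.
#' @param splice_tool predictor whose normalized call classifies splice
#'   variants (default `"wolfpsort"`).
#' @param rng_seed integer seed for any randomized step.
#' @param rounding decimal places for reported percentages.
#' @return a list of class `"nucvote_config"`.
#' @export
pipeline_config <- function(nucpred_threshold = 0.8,
                            nes_window = 15L,
                            nes_min_residues = 3L,
                            nes_residue_threshold = 0.5,
                            nls_weights = c(pat4 = 1, pat7 = 1,
                                            bipartite = 2, base = -1),
                            splice_tool = "wolfpsort",
                            rng_seed = 1L,
                            rounding = 2L) {
  stopifnot(nucpred_threshold >= 0, nucpred_threshold <= 1,
            nes_window >= 1, nes_min_residues >= 1,
            rounding >= 0)
  if (!all(c("pat4", "pat7", "bipartite", "base") %in% names(nls_weights)))
    stop("nls_weights must name pat4, pat7, bipartite and base")
  if (!splice_tool %in% TOOLS)
    stop("splice_tool must be one of: ", paste(TOOLS, collapse = ", "))
  structure(
    list(nucpred_threshold = nucpred_threshold,
         nes_window = as.integer(nes_window),
         nes_min_residues = as.integer(nes_min_residues),
         nes_residue_threshold = nes_residue_threshold,
         nls_weights = nls_weights,
         splice_tool = splice_tool,
         rng_seed = as.integer(rng_seed),
         rounding = as.integer(rounding)),
    class = "nucvote_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys present in the file override the [pipeline_config()] defaults;
#' unknown keys raise an error so typos do not pass silently.
#'
#' @param path YAML file.
#' @return a `"nucvote_config"` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  if (!is.null(raw$nls_weights)) raw$nls_weights <- unlist(raw$nls_weights)
  do.call(pipeline_config, raw)
}
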