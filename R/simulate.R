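# Synthetic proteome generator with known ground truth: sequences with
# planted NLS/NES motifs, predictor tables with controlled error rates,
# evidence tables and annotation tables, emitting exactly the file formats
# the rest of the pipeline consumes.
#
# Determinism: every stage seeds its own RNG from rng_seed plus a fixed
# stage offset (0 proteome, 1 predictions, 2 evidence, 3 annotations), so
# each stage is independently reproducible and the full dataset is
# byte-identical across runs with the same configuration.

MOTIF_LITERALS <- c(pat4 = "KKKR",
                    pat7 = "PKKKRKV",
                    bipartite = "KRAAAAAAAAAAKKKKK",   # 2 basic + 10 spacer + 5 basic
                    nes = "LAALAALAL")

#' Simulation configuration
#'
#' Defaults describe a rice-seed-proteome-like study: 19,441 proteins, half
#' of them truly nuclear, tool sensitivities ranked cello > yloc >
#' wolfpsort > nucpred (0.79 / 0.72 / 0.60 / 0.16), specificities 0.99,
#' literature-evidence coverage 7% with a 5% observation error, 70% of
#' nuclear evidence restricted to the nucleus alone, transcription factors
#' strongly enriched among nuclear-truth proteins, and 29% of proteins
#' grouped into multi-variant splice genes.
#'
#' @param n_proteins number of proteins to generate.
#' @param length_range min/max sequence length (uniform).
#' @param fraction_nuclear fraction of proteins with nuclear ground truth.
#' @param plant_prob named per-class planting probabilities for
#'   nuclear-truth proteins (`pat4`, `pat7`, `bipartite`, `nes`).
#' @param plant_prob_non_nuclear same for non-nuclear-truth proteins
#'   (NLS classes default to 0 so the no-leak property is exact).
#' @param tool_sensitivity,tool_specificity named per-tool probabilities of
#'   calling a true-nuclear (resp. not calling a true-non-nuclear) protein
#'   nuclear.
#' @param evidence_coverage fraction of proteins receiving an evidence
#'   record.
#' @param evidence_error probability an evidence record contradicts truth.
#' @param evidence_nucleus_only among nuclear evidence, fraction restricted
#'   to the nucleus (the rest also reports the cytoplasm).
#' @param tf_prob named TF-label probabilities for `nuclear` and
#'   `non_nuclear` truth classes.
#' @param go_nucleus_prob named probabilities of carrying the `nucleus` GO
#'   term per truth class.
#' @param splice_fraction fraction of proteins grouped into multi-variant
#'   genes (groups of 2-3).
#' @param background one of `"basic_free"` (the 18 letters excluding K and
#'   R, so un-planted sequences contain no NLS pattern and planted-motif
#'   recall is exact) or `"uniform"` (all 20 letters, for purely
#'   statistical tests).
#' @param rng_seed integer master seed.
#' @return list of class `"nucvote_sim_config"`.
#' @export
sim_config <- function(n_proteins = 19441L,
                       length_range = c(100L, 600L),
                       fraction_nuclear = 0.5,
                       plant_prob = c(pat4 = 0.7, pat7 = 0.5,
                                      bipartite = 0.4, nes = 0.19),
                       plant_prob_non_nuclear = c(pat4 = 0, pat7 = 0,
                                                  bipartite = 0, nes = 0.075),
                       tool_sensitivity = c(wolfpsort = 0.60, yloc = 0.72,
                                            cello = 0.79, nucpred = 0.16),
                       tool_specificity = c(wolfpsort = 0.99, yloc = 0.99,
                                            cello = 0.99, nucpred = 0.99),
                       evidence_coverage = 0.07,
                       evidence_error = 0.05,
                       evidence_nucleus_only = 0.7,
                       tf_prob = c(nuclear = 0.15, non_nuclear = 0.011),
                       go_nucleus_prob = c(nuclear = 0.35, non_nuclear = 0.15),
                       splice_fraction = 0.29,
                       background = c("basic_free", "uniform"),
                       rng_seed = 1L) {
  background <- match.arg(background)
  probs <- c(fraction_nuclear, plant_prob, plant_prob_non_nuclear,
             tool_sensitivity, tool_specificity, evidence_coverage,
             evidence_error, evidence_nucleus_only, tf_prob,
             go_nucleus_prob, splice_fraction)
  stopifnot(n_proteins >= 1, all(probs >= 0), all(probs <= 1),
            length(length_range) == 2L, length_range[1] >= 20,
            length_range[1] <= length_range[2],
            all(TOOLS %in% names(tool_sensitivity)),
            all(TOOLS %in% names(tool_specificity)))
  structure(
    list(n_proteins = as.integer(n_proteins),
         length_range = as.integer(length_range),
         fraction_nuclear = fraction_nuclear,
         plant_prob = plant_prob,
         plant_prob_non_nuclear = plant_prob_non_nuclear,
         tool_sensitivity = tool_sensitivity[TOOLS],
         tool_specificity = tool_specificity[TOOLS],
         evidence_coverage = evidence_coverage,
         evidence_error = evidence_error,
         evidence_nucleus_only = evidence_nucleus_only,
         tf_prob = tf_prob, go_nucleus_prob = go_nucleus_prob,
         splice_fraction = splice_fraction,
         background = background,
         rng_seed = as.integer(rng_seed)),
    class = "nucvote_sim_config")
}

# Plant motifs at random non-overlapping positions, overwriting the
# background; errors out when the sequence cannot hold them.
plant_motifs <- function(chars, motifs) {
  n <- length(chars)
  occupied <- logical(n)
  planted <- character(0)
  for (m in motifs) {
    lit <- seq_chars(MOTIF_LITERALS[[m]])
    L <- length(lit)
    if (L > n) stop("sequence of length ", n, " cannot hold motif ", m)
    s <- NA_integer_
    for (try in 1:50) {
      cand <- sample.int(n - L + 1L, 1L)
      if (!any(occupied[cand:(cand + L - 1L)])) { s <- cand; break }
    }
    if (is.na(s)) {   # deterministic fallback: first free slot
      free <- !occupied
      for (cand in seq_len(n - L + 1L))
        if (all(free[cand:(cand + L - 1L)])) { s <- cand; break }
      if (is.na(s)) stop("no room left to plant motif ", m)
    }
    chars[s:(s + L - 1L)] <- lit
    occupied[s:(s + L - 1L)] <- TRUE
    planted <- c(planted, paste0(m, "@", s))
  }
  list(chars = chars, planted = paste(planted, collapse = ";"))
}

#' Generate a synthetic proteome with planted motifs
#'
#' Background residues are drawn from a basic-depleted alphabet (K/R
#' excluded) so that un-planted sequences contain no NLS pattern;
#' nuclear-truth proteins receive planted motif literals per the
#' configured probabilities. Proteins are grouped into splice genes, a
#' fraction of which carry 2-3 variants.
#'
#' @param cfg a [sim_config()].
#' @return list with `records` (data frame `locus_id`, `sequence`),
#'   `truth` (data frame `locus_id`, `gene_id`, `true_nuclear`,
#'   `planted_motifs`) and `splice` (data frame `gene_id`, `variant_id`
#'   restricted to multi-variant genes).
#' @export
generate_proteome <- function(cfg = sim_config()) {
  set.seed(cfg$rng_seed)
  n <- cfg$n_proteins
  alphabet <- if (cfg$background == "basic_free")
    setdiff(AA_STANDARD, AA_BASIC) else AA_STANDARD

  # gene/variant structure: multi-variant genes hold 2-3 consecutive proteins
  n_multi_prot <- floor(cfg$splice_fraction * n)
  sizes <- integer(0)
  while (sum(sizes) < n_multi_prot)
    sizes <- c(sizes, sample(2:3, 1L))
  if (sum(sizes) > n) sizes <- sizes[cumsum(sizes) <= n]
  n_single <- n - sum(sizes)
  gene_sizes <- c(sizes, rep(1L, n_single))
  n_genes <- length(gene_sizes)
  gene_names <- sprintf("LOC_Os%02dg%05d",
                        (seq_len(n_genes) - 1L) %% 12L + 1L,
                        seq_len(n_genes) * 10L)
  gene_id <- rep(gene_names, gene_sizes)
  variant_no <- sequence(gene_sizes)
  locus_id <- ifelse(rep(gene_sizes, gene_sizes) > 1L,
                     paste0(gene_id, ".", variant_no), gene_id)

  true_nuclear <- stats::runif(n) < cfg$fraction_nuclear
  lens <- cfg$length_range[1] - 1L +
    sample.int(cfg$length_range[2] - cfg$length_range[1] + 1L, n,
               replace = TRUE)

  sequences <- character(n)
  planted <- character(n)
  motif_names <- names(cfg$plant_prob)
  for (i in seq_len(n)) {
    probs <- if (true_nuclear[i]) cfg$plant_prob else cfg$plant_prob_non_nuclear
    motifs <- motif_names[stats::runif(length(probs)) < probs]
    chars <- sample(alphabet, lens[i], replace = TRUE)
    if (length(motifs)) {
      res <- plant_motifs(chars, motifs)
      chars <- res$chars
      planted[i] <- res$planted
    }
    sequences[i] <- paste(chars, collapse = "")
  }

  records <- data.frame(locus_id = locus_id, sequence = sequences,
                        stringsAsFactors = FALSE)
  truth <- data.frame(locus_id = locus_id, gene_id = gene_id,
                      true_nuclear = true_nuclear, planted_motifs = planted,
                      stringsAsFactors = FALSE)
  multi <- rep(gene_sizes, gene_sizes) > 1L
  splice <- data.frame(gene_id = gene_id[multi], variant_id = locus_id[multi],
                       stringsAsFactors = FALSE)
  list(records = records, truth = truth, splice = splice)
}

#' Simulate predictor output tables from ground truth
#'
#' Each tool calls a nuclear-truth protein nuclear with probability equal
#' to its sensitivity and a non-nuclear-truth protein nuclear with
#' probability one minus its specificity, independently across tools and
#' proteins. Calls are emitted as a long-format prediction table whose
#' scores are consistent with the normalization rules: for the argmax
#' tools the nucleus compartment scores strictly highest iff the call is
#' nuclear; for NucPred the score falls strictly above/below the 0.8
#' threshold.
#'
#' @param truth data frame from [generate_proteome()].
#' @param cfg a [sim_config()].
#' @return data frame with columns `protein_id`, `tool`, `compartment`,
#'   `score`.
#' @export
simulate_tool_predictions <- function(truth, cfg = sim_config()) {
  set.seed(cfg$rng_seed + 1L)
  n <- nrow(truth)
  rows <- lapply(TOOLS, function(t) {
    p_call <- ifelse(truth$true_nuclear, cfg$tool_sensitivity[[t]],
                     1 - cfg$tool_specificity[[t]])
    call <- stats::runif(n) < p_call
    if (t == "nucpred") {
      score <- ifelse(call, 0.801 + 0.198 * stats::runif(n),
                      0.799 * stats::runif(n))
      data.frame(protein_id = truth$locus_id, tool = t,
                 compartment = "nuclear", score = round(score, 4),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(protein_id = rep(truth$locus_id, each = 2L), tool = t,
                 compartment = rep(c("nucleus", "cytoplasm"), n),
                 score = as.numeric(rbind(ifelse(call, 2, 1),
                                          ifelse(call, 1, 2))),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Simulate a localization-evidence table from ground truth
#'
#' A random subset of proteins (the coverage fraction) receives one
#' evidence record; the observed compartment matches truth with
#' probability `1 - evidence_error`. Nuclear observations are restricted
#' to the nucleus alone with probability `evidence_nucleus_only`,
#' otherwise the cytoplasm is seen as well.
#'
#' @inheritParams simulate_tool_predictions
#' @return data frame with columns `protein_id`, `source`, `cell_system`,
#'   `compartments`.
#' @export
simulate_evidence <- function(truth, cfg = sim_config()) {
  set.seed(cfg$rng_seed + 2L)
  n <- nrow(truth)
  covered <- stats::runif(n) < cfg$evidence_coverage
  flip <- stats::runif(n) < cfg$evidence_error
  obs_nuclear <- xor(truth$true_nuclear, flip)
  only <- stats::runif(n) < cfg$evidence_nucleus_only
  comp <- ifelse(obs_nuclear,
                 ifelse(only, "nucleus", "nucleus;cytoplasm"), "cytoplasm")
  idx <- which(covered)
  data.frame(protein_id = truth$locus_id[idx],
             source = sprintf("SIM%06d", idx),
             cell_system = "synthetic",
             compartments = comp[idx], stringsAsFactors = FALSE)
}

GO_NUCLEUS <- "GO:0005634"

#' Simulate GO and transcription-factor annotation tables
#'
#' TF labels and the `nucleus` cellular-component GO term are assigned
#' with higher probability to nuclear-truth proteins per the configured
#' class probabilities; every protein additionally draws a Poisson number
#' of neutral background GO terms.
#'
#' @inheritParams simulate_tool_predictions
#' @return list with `go` (data frame `locus_id`, `go_id`) and `tf` (data
#'   frame `locus_id`, `family`).
#' @export
simulate_annotations <- function(truth, cfg = sim_config()) {
  set.seed(cfg$rng_seed + 3L)
  n <- nrow(truth)
  p_tf <- ifelse(truth$true_nuclear, cfg$tf_prob[["nuclear"]],
                 cfg$tf_prob[["non_nuclear"]])
  is_tf <- stats::runif(n) < p_tf
  families <- c("MYB", "bZIP", "WRKY", "NAC", "MADS", "AP2", "C2H2", "bHLH")
  tf <- data.frame(locus_id = truth$locus_id[is_tf],
                   family = sample(families, sum(is_tf), replace = TRUE),
                   stringsAsFactors = FALSE)
  p_go <- ifelse(truth$true_nuclear, cfg$go_nucleus_prob[["nuclear"]],
                 cfg$go_nucleus_prob[["non_nuclear"]])
  has_nuc_go <- stats::runif(n) < p_go
  pool <- sprintf("GO:%07d", 1:20)
  extra_n <- stats::rpois(n, 2)
  go_long <- data.frame(
    locus_id = c(truth$locus_id[has_nuc_go],
                 rep(truth$locus_id, extra_n)),
    go_id = c(rep(GO_NUCLEUS, sum(has_nuc_go)),
              sample(pool, sum(extra_n), replace = TRUE)),
    stringsAsFactors = FALSE)
  list(go = unique(go_long), tf = tf)
}

#' Generate a complete synthetic dataset
#'
#' Runs all generator stages in their fixed order and returns every table
#' the pipeline consumes plus the ground truth.
#'
#' @param cfg a [sim_config()].
#' @return list with `records`, `truth`, `splice`, `predictions`,
#'   `evidence`, `go`, `tf`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  prot <- generate_proteome(cfg)
  ann <- simulate_annotations(prot$truth, cfg)
  list(records = prot$records, truth = prot$truth, splice = prot$splice,
       predictions = simulate_tool_predictions(prot$truth, cfg),
       evidence = simulate_evidence(prot$truth, cfg),
       go = ann$go, tf = ann$tf)
}

#' Closed-form consensus category distribution under independent errors
#'
#' Expected probability of each consensus category when the four tools err
#' independently: a mixture, over the nuclear-truth fraction, of
#' Poisson-binomial vote-count distributions with per-tool success
#' probabilities equal to the sensitivities (nuclear truth) or one minus
#' the specificities (non-nuclear truth).
#'
#' @param sensitivity,specificity named per-tool probabilities.
#' @param fraction_nuclear nuclear-truth mixing fraction.
#' @return named probability vector over the five categories (sums to 1).
#' @export
expected_category_probs <- function(sensitivity, specificity,
                                    fraction_nuclear) {
  pois_binom <- function(p) {
    d <- 1
    for (pi in p) d <- c(d * (1 - pi), 0) + c(0, d * pi)
    d
  }
  mix <- fraction_nuclear * pois_binom(sensitivity) +
    (1 - fraction_nuclear) * pois_binom(1 - specificity)
  stats::setNames(mix, CATEGORY_LEVELS)
}
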