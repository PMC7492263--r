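# Category composition statistics: TF fractions, GO fold enrichment with
# hypergeometric tests and BH-FDR, score-distribution tests, keyword
# screens and nuclear-proteome overlap tables.

#' Fold enrichment of a term in a category
#'
#' `(k/n) / (K/N)`: frequency of the term among category members relative
#' to its frequency in the reference universe.
#'
#' @param k term-positive proteins in the category.
#' @param n category size.
#' @param K term-positive proteins in the reference.
#' @param N reference size.
#' @return fold enrichment (vectorized); `NA` when `K` or `N` is 0.
#' @export
fold_enrichment <- function(k, n, K, N) {
  stopifnot(all(k <= n), all(k <= K), all(K <= N))
  ifelse(K > 0 & N > 0 & n > 0, (k / n) / (K / N), NA_real_)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= k)` when drawing `n` proteins from a universe of `N` containing
#' `K` term-positive ones.
#'
#' @inheritParams fold_enrichment
#' @return p-value (vectorized).
#' @export
hypergeom_p <- function(k, n, K, N) {
  stopifnot(all(k >= 0), all(k <= n), all(k <= K), all(K <= N), all(n <= N))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p vector of p-values forming one test family.
#' @return BH step-up adjusted q-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' GO-term enrichment of consensus categories
#'
#' For each requested category, tests every GO term annotated to at least
#' one category member for enrichment against the reference universe (by
#' default the whole supplied protein set). BH-FDR is applied across all
#' terms within one category.
#'
#' @param consensus data frame from [consensus_categories()].
#' @param go data frame with columns `locus_id`, `go_id`.
#' @param categories category labels to test (default all but non-nuclear).
#' @param universe protein IDs forming the reference (default every protein
#'   in `consensus`).
#' @return data frame with columns `category`, `term`, `k`, `n`, `K`, `N`,
#'   `fold`, `p_value`, `q_value`.
#' @export
go_enrichment <- function(consensus, go,
                          categories = c("cat1", "cat2", "cat3", "cat4"),
                          universe = consensus$locus_id) {
  go <- unique(go[go$locus_id %in% universe, c("locus_id", "go_id")])
  N <- length(unique(universe))
  K_tab <- table(go$go_id)
  res <- lapply(categories, function(cat) {
    ids <- consensus$locus_id[consensus$category == cat]
    n <- length(ids)
    sub <- go[go$locus_id %in% ids, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    k_tab <- table(sub$go_id)
    terms <- names(k_tab)
    k <- as.integer(k_tab)
    K <- as.integer(K_tab[terms])
    p <- hypergeom_p(k, n, K, N)
    data.frame(category = cat, term = terms, k = k, n = n, K = K, N = N,
               fold = fold_enrichment(k, n, K, N),
               p_value = p, q_value = bh_adjust(p),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, res)
}

#' Transcription-factor composition per category
#'
#' @param consensus data frame from [consensus_categories()].
#' @param tf data frame with columns `locus_id`, `family`, or `NULL`
#'   (yields zero counts).
#' @param digits decimal places for percentages.
#' @return list with `by_category` (data frame: `category`, `n_proteins`,
#'   `n_tf`, `tf_percent`, `percent_of_all_tf`) and `n_tf_total`.
#' @export
tf_composition <- function(consensus, tf, digits = 2) {
  tf_ids <- if (is.null(tf)) character() else unique(tf$locus_id)
  cat_f <- factor(consensus$category, levels = CATEGORY_LEVELS)
  n_prot <- as.integer(table(cat_f))
  is_tf <- consensus$locus_id %in% tf_ids
  n_tf <- as.integer(tapply(is_tf, cat_f, sum, default = 0L))
  total_tf <- sum(n_tf)
  by_cat <- data.frame(category = CATEGORY_LEVELS,
                       n_proteins = n_prot, n_tf = n_tf,
                       tf_percent = ifelse(n_prot > 0,
                                           percent(n_tf, n_prot, digits), 0),
                       percent_of_all_tf = percent(n_tf, total_tf, digits),
                       stringsAsFactors = FALSE)
  list(by_category = by_cat, n_tf_total = total_tf)
}

#' Welch two-sample t-test between score distributions
#'
#' Unequal-variance (Welch) t statistic with a two-sided p-value. Groups
#' with fewer than two values or zero variance yield a missing result.
#'
#' @param values_a,values_b numeric score vectors.
#' @return list with `t` and `p` (both `NA` when degenerate).
#' @export
score_distribution_test <- function(values_a, values_b) {
  degenerate <- length(values_a) < 2L || length(values_b) < 2L ||
    stats::var(values_a) == 0 || stats::var(values_b) == 0
  if (degenerate) {
    message("score_distribution_test: degenerate group, result reported missing")
    return(list(t = NA_real_, p = NA_real_))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Keyword screen over functional annotations
#'
#' Case-insensitive literal substring match of `keyword` against each
#' record's `annotation_text` (no stemming; pass a stem such as "ribosom"
#' to widen the match deliberately).
#'
#' @param records data frame with columns `locus_id`, `annotation_text`.
#' @param keyword non-empty search string.
#' @param digits decimal places.
#' @return list with `ids` (matching loci), `n_hits`, `n_universe` and
#'   `percent` of the searched universe.
#' @export
keyword_screen <- function(records, keyword, digits = 2) {
  if (!is.character(keyword) || length(keyword) != 1L || !nzchar(keyword))
    stop("keyword must be a non-empty string")
  hit <- grepl(tolower(keyword), tolower(records$annotation_text), fixed = TRUE)
  list(ids = records$locus_id[hit],
       n_hits = sum(hit), n_universe = nrow(records),
       percent = percent(sum(hit), nrow(records), digits))
}

#' Overlap of external nuclear-proteome locus lists with the consensus
#'
#' Deduplicates the union of one or more mass-spectrometry nuclear-proteome
#' locus lists, intersects it with the seed-expressed universe, and
#' cross-tabulates the intersection over the five consensus categories.
#'
#' @param consensus data frame from [consensus_categories()].
#' @param locus_lists list of character vectors of locus IDs.
#' @param universe seed-expressed locus IDs (default every protein in
#'   `consensus`).
#' @param digits decimal places.
#' @return list with `n_union`, `n_seed_expressed`, `category_counts` and
#'   `percent_predicted_nuclear` (category >= 1 among the seed-expressed
#'   overlap with a consensus call).
#' @export
proteome_overlap <- function(consensus, locus_lists,
                             universe = consensus$locus_id, digits = 2) {
  union_ids <- unique(unlist(locus_lists, use.names = FALSE))
  seed_ids <- intersect(union_ids, unique(universe))
  sub <- consensus[consensus$locus_id %in% seed_ids, , drop = FALSE]
  counts <- table(factor(sub$category, levels = CATEGORY_LEVELS))
  n_nuc <- nrow(sub) - as.integer(counts[["non_nuclear"]])
  list(n_union = length(union_ids),
       n_seed_expressed = length(seed_ids),
       category_counts = stats::setNames(as.integer(counts), names(counts)),
       percent_predicted_nuclear = percent(n_nuc, nrow(sub), digits))
}
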