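# Composition and enrichment statistics.

test_that("fold enrichment is the ratio of term frequencies", {
  expect_equal(fold_enrichment(2, 10, 10, 100), 2)
  expect_equal(fold_enrichment(0, 10, 10, 100), 0)
  expect_true(is.na(fold_enrichment(0, 10, 0, 100)))  # undefined reference
  # category and complement folds bracket 1 when frequencies differ
  k <- 8; n <- 20; K <- 20; N <- 100
  f_cat <- fold_enrichment(k, n, K, N)
  f_comp <- fold_enrichment(K - k, N - n, K, N)
  expect_true((f_cat - 1) * (f_comp - 1) < 0)
})

test_that("hypergeometric p matches closed cases", {
  expect_equal(hypergeom_p(3, 3, 3, 10), 1 / choose(10, 3))
  expect_equal(hypergeom_p(5, 5, 5, 5), 1)    # certain event
  expect_equal(hypergeom_p(0, 3, 3, 10), 1)   # P(X >= 0)
})

test_that("hypergeometric p agrees with exhaustive enumeration for N <= 12", {
  for (N in 1:12) for (n in 1:N) {
    for (K in 0:N) {
      for (k in 0:min(n, K)) {
        expect_equal(hypergeom_p(k, n, K, N),
                     oracle_hypergeom_upper(k, n, K, N),
                     tolerance = 1e-12,
                     info = sprintf("k=%d n=%d K=%d N=%d", k, n, K, N))
      }
    }
  }
})

test_that("BH adjustment matches the hand-written step-up and is rank-monotone", {
  set.seed(31)
  for (i in 1:20) {
    p <- stats::runif(sample(3:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p-rank
    # rejections at any alpha form a p-value prefix
    for (alpha in c(0.05, 0.2)) {
      rej <- q <= alpha
      if (any(rej) && any(!rej))
        expect_true(max(p[rej]) <= min(p[!rej]) + 1e-12)
    }
  }
})

test_that("GO enrichment recovers a planted enriched term", {
  ids <- sprintf("p%03d", 1:200)
  cons <- data.frame(locus_id = ids,
                     category = rep(c("cat4", "non_nuclear"), each = 100),
                     stringsAsFactors = FALSE)
  # term in 60/100 cat4 members but only 70/200 overall
  go <- data.frame(locus_id = c(ids[1:60], ids[101:110]),
                   go_id = "GO:0005634", stringsAsFactors = FALSE)
  res <- go_enrichment(cons, go, categories = "cat4")
  expect_equal(res$k, 60L)
  expect_equal(res$K, 70L)
  expect_equal(res$fold, (60 / 100) / (70 / 200))
  expect_lt(res$p_value, 1e-10)
})

test_that("TF composition reproduces the published category percentages", {
  counts <- c(non_nuclear = 9549, cat1 = 3776, cat2 = 2654,
              cat3 = 2617, cat4 = 845)
  tf_counts <- c(non_nuclear = 108, cat1 = 140, cat2 = 335,
                 cat3 = 766, cat4 = 140)
  ids <- sprintf("p%05d", seq_len(sum(counts)))
  cats <- rep(names(counts), counts)
  # TFs are the first tf_counts[i] proteins of each category
  is_tf <- unlist(lapply(names(counts), function(cat)
    seq_len(counts[[cat]]) <= tf_counts[[cat]]))
  cons <- data.frame(locus_id = ids, category = cats, stringsAsFactors = FALSE)
  tf <- data.frame(locus_id = ids[is_tf], family = "MYB",
                   stringsAsFactors = FALSE)
  comp <- tf_composition(cons, tf)
  by_cat <- comp$by_category
  getp <- function(cat) by_cat$tf_percent[by_cat$category == cat]
  expect_equal(getp("non_nuclear"), 1.13)
  expect_equal(getp("cat2"), 12.62)
  expect_equal(getp("cat3"), 29.27)
  expect_equal(comp$n_tf_total, sum(tf_counts))
  # percents recompute from their own counts at the configured rounding
  expect_equal(by_cat$tf_percent,
               round_half_up(100 * by_cat$n_tf / by_cat$n_proteins, 2))
  # no TF table at all
  comp0 <- tf_composition(cons, NULL)
  expect_equal(comp0$n_tf_total, 0L)
  expect_equal(comp0$by_category$tf_percent, rep(0, 5))
})

test_that("Welch t-test handles the worked example and degenerate groups", {
  res <- score_distribution_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(res$t), 3.674, tolerance = 1e-3)
  expect_equal(res$p, 0.0214, tolerance = 1e-2)
  same <- score_distribution_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_message(deg <- score_distribution_test(1, c(1, 2)), "degenerate")
  expect_true(is.na(deg$t))
  expect_message(flat <- score_distribution_test(c(1, 1), c(1, 2)), "degenerate")
  expect_true(is.na(flat$p))
})

test_that("keyword screen is case-insensitive literal substring matching", {
  recs <- data.frame(locus_id = c("a", "b", "c"),
                     annotation_text = c("40S ribosome protein",
                                         "RIBOSOME biogenesis", "kinase"),
                     stringsAsFactors = FALSE)
  res <- keyword_screen(recs, "ribosome")
  expect_equal(sort(res$ids), c("a", "b"))
  expect_equal(res$percent, 66.67)
  expect_equal(keyword_screen(recs, "RIBOSOME")$ids, res$ids)
  expect_equal(keyword_screen(recs, "proteasome")$n_hits, 0L)
  expect_error(keyword_screen(recs, ""), "non-empty")
})

test_that("proteome overlap deduplicates, intersects and cross-tabulates", {
  cons <- data.frame(locus_id = c("a", "b", "d"),
                     category = c("cat3", "non_nuclear", "cat1"),
                     stringsAsFactors = FALSE)
  res <- proteome_overlap(cons, list(c("a", "b"), c("b", "c")),
                          universe = c("a", "b"))
  expect_equal(res$n_union, 3L)
  expect_equal(res$n_seed_expressed, 2L)
  expect_equal(unname(res$category_counts[c("cat3", "non_nuclear")]), c(1L, 1L))
  expect_equal(res$percent_predicted_nuclear, 50)
  none <- proteome_overlap(cons[cons$category == "non_nuclear", ],
                           list("b"), universe = "b")
  expect_equal(none$percent_predicted_nuclear, 0)
})
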