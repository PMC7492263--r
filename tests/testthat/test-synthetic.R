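# Synthetic proteome generator: determinism, planted-motif recall and
# error-rate structure.

test_that("generation is deterministic for a fixed seed", {
  cfg <- sim_config(n_proteins = 40, rng_seed = 99)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a, b)
  fa <- tempfile(fileext = ".fa"); fb <- tempfile(fileext = ".fa")
  write_fasta(a$records, fa); write_fasta(b$records, fb)
  expect_identical(readLines(fa), readLines(fb))
  c <- simulate_dataset(sim_config(n_proteins = 40, rng_seed = 100))
  expect_false(identical(a$records$sequence, c$records$sequence))
})

test_that("forced planting gives perfect scanner recall on basic-free background", {
  cfg <- sim_config(n_proteins = 10, fraction_nuclear = 1,
                    plant_prob = c(pat4 = 1, pat7 = 1, bipartite = 1, nes = 1),
                    length_range = c(120L, 200L), rng_seed = 5)
  sim <- generate_proteome(cfg)
  prof <- signal_profiles(sim$records)
  expect_true(all(prof$n_pat4 >= 1))
  expect_true(all(prof$n_pat7 >= 1))
  expect_true(all(prof$n_bipartite >= 1))
  expect_true(all(prof$nls_positive))
  expect_true(all(prof$nes_positive))   # planted consensus has 4 anchors in 9
  # planted positions are consistent with the emitted sequences
  for (i in seq_len(10)) {
    for (pm in strsplit(sim$truth$planted_motifs[i], ";")[[1]]) {
      parts <- strsplit(pm, "@", fixed = TRUE)[[1]]
      lit <- c(pat4 = "KKKR", pat7 = "PKKKRKV",
               bipartite = "KRAAAAAAAAAAKKKKK", nes = "LAALAALAL")[[parts[1]]]
      s <- as.integer(parts[2])
      expect_equal(substring(sim$records$sequence[i], s, s + nchar(lit) - 1L),
                   lit)
    }
  }
})

test_that("plant-free basic-depleted sequences carry no NLS signal (no leak)", {
  cfg <- sim_config(n_proteins = 30, fraction_nuclear = 0,
                    plant_prob_non_nuclear = c(pat4 = 0, pat7 = 0,
                                               bipartite = 0, nes = 0),
                    rng_seed = 6)
  sim <- generate_proteome(cfg)
  prof <- signal_profiles(sim$records)
  expect_true(all(prof$n_pat4 == 0))
  expect_true(all(prof$n_pat7 == 0))
  expect_true(all(prof$n_bipartite == 0))
  expect_true(all(prof$basic_percent == 0))
})

test_that("planting a motif longer than the sequence errors", {
  cfg <- sim_config(n_proteins = 3, fraction_nuclear = 1,
                    plant_prob = c(pat4 = 0, pat7 = 0, bipartite = 1, nes = 0),
                    length_range = c(20L, 20L), rng_seed = 7)
  expect_silent(generate_proteome(cfg))   # 17-mer fits in 20
  expect_error(plant_motifs(rep("A", 10), "bipartite"), "cannot hold")
})

test_that("perfect tools reproduce the truth as category 4 vs non-nuclear", {
  cfg <- sim_config(n_proteins = 200, rng_seed = 8,
                    tool_sensitivity = c(wolfpsort = 1, yloc = 1,
                                         cello = 1, nucpred = 1),
                    tool_specificity = c(wolfpsort = 1, yloc = 1,
                                         cello = 1, nucpred = 1))
  sim <- generate_proteome(cfg)
  preds <- simulate_tool_predictions(sim$truth, cfg)
  cons <- consensus_categories(normalize_calls(preds))
  m <- merge(cons, sim$truth, by = "locus_id")
  expect_true(all(m$category[m$true_nuclear] == "cat4"))
  expect_true(all(m$category[!m$true_nuclear] == "non_nuclear"))
})

test_that("zero-sensitivity tools call everything non-nuclear", {
  cfg <- sim_config(n_proteins = 50, rng_seed = 9,
                    tool_sensitivity = c(wolfpsort = 0, yloc = 0,
                                         cello = 0, nucpred = 0))
  sim <- generate_proteome(cfg)
  cons <- consensus_categories(normalize_calls(
    simulate_tool_predictions(sim$truth, cfg)))
  expect_true(all(cons$category == "non_nuclear"))
})

test_that("error-free full-coverage evidence agrees perfectly with truth", {
  cfg <- sim_config(n_proteins = 150, rng_seed = 10,
                    evidence_coverage = 1, evidence_error = 0,
                    tool_sensitivity = c(wolfpsort = 1, yloc = 1,
                                         cello = 1, nucpred = 1),
                    tool_specificity = c(wolfpsort = 1, yloc = 1,
                                         cello = 1, nucpred = 1))
  sim <- simulate_dataset(cfg)
  cons <- consensus_categories(normalize_calls(sim$predictions))
  agg <- agreement_by_category(cons, sim$evidence)
  by_cat <- agg$by_category
  expect_equal(by_cat$percent_nuclear[by_cat$category == "cat4"], 100)
  expect_equal(by_cat$percent_nuclear[by_cat$category == "non_nuclear"], 0)
})

test_that("closed-form category distribution is a proper mixture", {
  sens <- c(wolfpsort = 0.6, yloc = 0.72, cello = 0.79, nucpred = 0.16)
  spec <- c(wolfpsort = 0.99, yloc = 0.99, cello = 0.99, nucpred = 0.99)
  pr <- expected_category_probs(sens, spec, 0.5)
  expect_equal(sum(pr), 1)
  expect_equal(names(pr),
               c("non_nuclear", "cat1", "cat2", "cat3", "cat4"))
  # hand check against independent products for the all-or-nothing bins
  expect_equal(unname(pr[["cat4"]]),
               0.5 * prod(sens) + 0.5 * prod(1 - spec))
  expect_equal(unname(pr[["non_nuclear"]]),
               0.5 * prod(1 - sens) + 0.5 * prod(spec))
})

test_that("simulated GO enrichment is near null when class odds are equal", {
  cfg <- sim_config(n_proteins = 2000, rng_seed = 12,
                    go_nucleus_prob = c(nuclear = 0.3, non_nuclear = 0.3),
                    tool_sensitivity = c(wolfpsort = 1, yloc = 1,
                                         cello = 1, nucpred = 1),
                    tool_specificity = c(wolfpsort = 1, yloc = 1,
                                         cello = 1, nucpred = 1))
  sim <- simulate_dataset(cfg)
  cons <- consensus_categories(normalize_calls(sim$predictions))
  res <- go_enrichment(cons, sim$go, categories = "cat4")
  fold_nuc <- res$fold[res$term == "GO:0005634"]
  expect_lt(abs(fold_nuc - 1), 0.15)
  # and strongly enriched when the odds differ
  cfg2 <- sim_config(n_proteins = 2000, rng_seed = 12,
                     go_nucleus_prob = c(nuclear = 0.5, non_nuclear = 0.05),
                     tool_sensitivity = cfg$tool_sensitivity,
                     tool_specificity = cfg$tool_specificity)
  sim2 <- simulate_dataset(cfg2)
  cons2 <- consensus_categories(normalize_calls(sim2$predictions))
  res2 <- go_enrichment(cons2, sim2$go, categories = "cat4")
  expect_lt(res2$p_value[res2$term == "GO:0005634"], 0.01)
})
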