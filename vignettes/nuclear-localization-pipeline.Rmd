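---
title: "Consensus nuclear-localization calling and NLS/NES signal analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus nuclear-localization calling and NLS/NES signal analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucvote)
```

## The problem

Nuclear proteins — transcription factors, chromatin remodelers, splicing and
replication factors — are the regulatory core of a plant cell, but no single
subcellular-localization predictor identifies them reliably. `nucvote`
implements a consensus strategy for proteome-scale nuclear calling, built
around rice seed-expressed proteins but applicable to any protein set:

1. **Consensus voting.** The normalized outputs of four predictors
   (WoLF-PSORT, YLoc, CELLO, NucPred) are each reduced to a binary nuclear
   call, and proteins are sorted into five categories by the number of tools
   voting nuclear (0 = `non_nuclear`, 1-4 = `cat1` ... `cat4`).
2. **Sequence signals.** Each protein is scanned for classical nuclear
   localization signals (NLS) — PAT4, PAT7 and bipartite — and for
   leucine-rich nuclear export signals (NES), then classified as
   nuclear-resident (NLS only), shuttling (NLS + NES), export-signal-only,
   or signal-free.
3. **Benchmarking.** Categories and individual tools are scored against
   curated experimental localization evidence; composition statistics (TF
   fractions, GO-term enrichment, keyword screens, nuclear-proteome
   overlap) probe whether the higher categories look like a nuclear
   proteome should.
4. **Splicing.** Genes with several splice variants are classified by
   whether all, some or none of their protein forms are predicted nuclear.

A synthetic-proteome generator with planted motifs and controlled per-tool
error rates makes every stage testable against known ground truth.

## Normalization and voting rules

* **Argmax tools (WoLF-PSORT, CELLO, YLoc).** The call is nuclear iff the
  nucleus compartment's score is *strictly* greater than every other
  compartment's score. A tie involving the nucleus is counted as
  non-nuclear: the tie rule is not documented by the upstream tools, and
  the conservative reading avoids inflating the high-confidence categories.
  Dual compound labels (e.g. `nucl_cyto`) are out of scope for the
  normalized input format; callers must pre-split such scores per
  compartment — a documented limitation.
* **NucPred.** Nuclear iff score strictly above 0.8 (`nucpred_threshold`,
  configurable). "Above" is read as a strict inequality, so a score of
  exactly 0.8 is non-nuclear.
* **YLoc confidence.** The confidence value is carried through but not
  thresholded: no documented rule exists for combining it with the
  probability argmax, so it is treated as metadata.
* Proteins with no prediction rows are excluded from category tables
  rather than silently binned as non-nuclear; missing individual tools
  count as non-nuclear votes with a warning.

## NLS/NES model

Positions are 1-based and windows are closed intervals throughout.

**PAT4**: every 4-residue window that is either all basic (K/R) or three
basic plus one H/P. **PAT7**: every 7-residue window starting with P in
which some 4-mer at offset 1-3 holds at least 3 basic residues.
**Bipartite**: every 17-residue window with 2 leading basic residues, a
10-residue unconstrained spacer, and at least 3 basic among the final 5.
These are the classical PSORT II predicates; overlapping windows are each
counted (the literature reports per-protein counts without an overlap
convention, and counting distinct starts is the only choice that makes the
scanners exactly equal to exhaustive window enumeration). The unknown
residue X never matches any predicate class.

The **cumulative NLS score** is a weighted motif count,
`w4·n_pat4 + w7·n_pat7 + wb·n_bipartite + base`, with defaults (1, 1, 2,
−1). PSORT II's internal score formula is not published in a recoverable
form, so the weights are surfaced as configuration; the defaults are chosen
so that any single motif of any class makes the score positive, which
matches the qualitative use of a "positive NLS score" as the NLS-containing
criterion. The reported basic-residue percentage counts K and R only
(histidine, though weakly basic, is excluded because the composition
analysis concerns arginine/lysine content).

The **NES score** of a protein is the plain sum of its per-residue score
track. A residue *contributes* when its score exceeds
`nes_residue_threshold` (0.5 for external NetNES-style tracks — NetNES's
own per-residue decision threshold — and 0 for the built-in surrogate,
which emits 0/1 scores). A protein is NES-positive when some window of at
most 15 consecutive positions (`nes_window`) contains at least 3
contributing residues (`nes_min_residues`); "a stretch of 15 amino acids"
is read as any 15 consecutive positions.

The **surrogate NES scorer** stands in for an external per-residue
predictor so the pipeline is self-contained: it scans the leucine-rich
consensus Φ-x(2,3)-Φ-x(2,3)-Φ-x-Φ (Φ ∈ {L, I, V, F, M}) and scores the Φ
anchors of every match 1, all other residues 0.

## The synthetic-data generator

`sim_config()` / `simulate_dataset()` emulate the statistical structure of
a seed-proteome study with known ground truth. Defaults are fixed once and
describe the study conditions:

* **Scale**: 19,441 proteins of uniform length 100-600; half nuclear
  ground truth (the observed split of nuclear-called vs non-nuclear
  proteins is roughly half-and-half).
* **Tools**: sensitivities 0.79 / 0.72 / 0.60 / 0.16 for CELLO / YLoc /
  WoLF-PSORT / NucPred, echoing the published accuracy ranking on
  evidence-supported nuclear proteins (79.12 / 71.62 / 60.44 / 15.74%);
  specificities 0.99 each, calibrated so that about 49% of proteins are
  called non-nuclear by all four tools under 50% nuclear truth, matching
  the observed non-nuclear fraction.
* **Evidence**: 7% coverage (1360 of 19,441 proteins had literature or
  experimental evidence), 5% observation error, and 70% of nuclear
  observations restricted to the nucleus alone (published exclusive-nuclear
  fractions range 42-79% across categories).
* **Annotations**: TF probability 0.15 for nuclear truth vs 0.011 for
  non-nuclear (the non-nuclear category's observed 1.13%); the `nucleus`
  GO term at 0.35 vs 0.15, around a two-fold enrichment.
* **Splicing**: 29% of proteins grouped into 2-3-variant genes
  (5612 of 19,441 genes had expressed splice variants).

The background alphabet excludes K and R entirely rather than down-weighting
them, so un-planted sequences can contain *no* NLS pattern and planted-motif
recall is an exact test, not a statistical one; a `uniform` 20-letter mode
exists for purely statistical checks. Motifs are planted as literals
(`KKKR`, `PKKKRKV`, `KR` + 10-residue spacer + `KKKKK`, `LAALAALAL`) at
random non-overlapping positions; the NES literal carries 4 anchors within
9 residues, guaranteeing a positive windowed call. Each generator stage
seeds its own RNG from `rng_seed` plus a fixed stage offset, so every stage
— and the complete dataset — is byte-reproducible.

**What the generator does not emulate.** Real protein composition (the
basic-free background biases amino-acid frequencies), domain structure,
correlated tool errors (real predictors share training data and fail on the
same hard proteins, so real consensus categories are more polarized than
the independent-error model), evidence ascertainment bias (well-studied
genes are over-represented), and GO-graph structure. Passing tests
therefore demonstrate correctness of the *computations* under controlled
conditions, not field performance of the predictors. One visible
consequence: the surrogate NES consensus is permissive on random
hydrophobic-rich backgrounds (Φ residues are 5 of the 18 background
letters), so most synthetic proteins are NES-positive — far above the
~23% NES-carrier rate NetNES reports on real proteomes. NES-related tests
accordingly check the windowed rule and planted-motif recall, never rate
realism.

## Statistics

Fold enrichment is `(k/n) / (K/N)` against a reference universe — by
default the whole supplied protein set, standing in for a whole-genome
reference. Enrichment p-values are upper-tail hypergeometric
(`P(X ≥ k)`), with Benjamini-Hochberg FDR applied across all terms within
one category (the original web-service's family definition is not
recoverable, and per-category families are the conservative reading).
Score-distribution comparisons use the Welch unequal-variance t-test — the
source analyses say only "t-test", and Welch is the safer default for the
skewed, unequal-size category score sets; groups with fewer than two
values or zero variance report a missing result rather than a misleading
one. The keyword screen is literal case-insensitive substring matching
with no stemming (pass `"ribosom"` to widen deliberately). Percentages are
reported with half-up rounding at 2 decimals; zero denominators always
yield missing values, never 0.

## Degenerate inputs and numerical choices

Sequences shorter than a pattern window return empty match sets. An empty
compartment-score map, a negative YLoc probability, an unknown tool name,
a duplicate per-tool call and a non-1-based track position are hard
errors; unknown amino-acid letters other than X are a hard error (silent
coercion hides data bugs). Categories without evidenced proteins report
missing percentages. Evidence from multiple sources is merged by set union
of compartments, so a protein observed nuclear under any condition counts
as nuclear-evidenced (conditional movers are nuclear) — and merging is
order-independent.

## Worked example

```{r example}
cfg <- sim_config(n_proteins = 300, rng_seed = 42)
sim <- simulate_dataset(cfg)
res <- run_pipeline(sim$records, sim$predictions,
                    evidence = sim$evidence, tf = sim$tf,
                    splice = sim$splice)
res$summary$categories$counts
res$summary$categories$n_cat2_plus
res$summary$evidence$tool_accuracy[, c("tool", "sensitivity_percent")]
res$summary$splicing
```

## Problem sizes

The test suite exercises the scanners and the windowed NES rule against
brute-force oracles on 1,000 random cases each, the full 2^4 consensus
truth table, exhaustive hypergeometric enumeration for universes up to
N = 12, and parameter recovery on a 5,000-protein synthetic proteome
(99% binomial/multinomial bands); `scripts/acceptance.R` re-runs the
pipeline end to end at the same 5,000-protein scale. These sizes were
chosen as the smallest at which the stochastic checks have sampling bands
tight enough to detect an implementation error in any single tool's error
rate.

## Known limitations

* Native output dialects of the four predictors are not parsed; the
  normalized long-format table is the only input contract.
* Non-classical NLSs (PY-NLS and other karyopherin-β signals) are not
  modeled; they are poorly predictable from sequence and outside the
  classical PAT4/PAT7/bipartite scope.
* The NLS score is a motif-count heuristic, not a binding-energy model.
* Cross-tool splice-variant analysis is not attempted: variant concordance
  uses one designated tool (default WoLF-PSORT), matching how gene models
  are typically screened.
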