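# NLS / NES sequence-signal scanning and scoring.
#
# Pattern predicates follow the classical PSORT II definitions:
#   pat4      4-mer, all four residues basic (K/R), or exactly three basic
#             and the fourth H or P.
#   pat7      7-mer starting with P in which some 4-mer beginning at offset
#             1, 2 or 3 has >= 3 basic residues.
#   bipartite 17-mer: 2 basic, 10-residue unconstrained spacer, then >= 3
#             basic among the last 5 (Robbins-Dingwall consensus).
# Positions are 1-based, windows closed intervals; overlapping matches are
# each reported. X never matches any predicate class.

match_df <- function(kind, starts, len, sequence) {
  if (!length(starts)) return(empty_match_df())
  starts <- sort(starts)
  data.frame(kind = kind, start = as.integer(starts), length = as.integer(len),
             match = substring(sequence, starts, starts + len - 1L),
             stringsAsFactors = FALSE)
}

#' Scan for PAT4 monopartite NLS motifs
#'
#' Reports every 4-residue window in which either all four residues are
#' basic (K/R), or exactly three are basic and the fourth is H or P.
#'
#' @param sequence amino-acid string (uppercase, 20 letters plus X).
#' @return data frame with columns `kind`, `start` (1-based), `length`,
#'   `match`, ordered by start; empty for sequences shorter than 4.
#' @export
scan_pat4 <- function(sequence) {
  validate_sequence(sequence)
  ch <- seq_chars(sequence)
  n <- length(ch)
  if (n < 4L) return(empty_match_df())
  z <- ch %in% AA_BASIC
  hp_nonbasic <- ch %in% c("H", "P")        # H/P are never basic
  i <- seq_len(n - 3L)
  nb <- z[i] + z[i + 1L] + z[i + 2L] + z[i + 3L]
  nhp <- hp_nonbasic[i] + hp_nonbasic[i + 1L] +
         hp_nonbasic[i + 2L] + hp_nonbasic[i + 3L]
  hit <- nb == 4L | (nb == 3L & nhp == 1L)
  match_df("pat4", i[hit], 4L, sequence)
}

#' Scan for PAT7 monopartite NLS motifs
#'
#' Reports every 7-residue window starting with proline for which some
#' 4-mer beginning at offset 1, 2 or 3 within the window has at least 3
#' basic residues; each qualifying window is reported once, at its start.
#'
#' @inheritParams scan_pat4
#' @return data frame as in [scan_pat4()].
#' @export
scan_pat7 <- function(sequence) {
  validate_sequence(sequence)
  ch <- seq_chars(sequence)
  n <- length(ch)
  if (n < 7L) return(empty_match_df())
  z <- ch %in% AA_BASIC
  i <- seq_len(n - 6L)
  four <- function(off)
    z[i + off] + z[i + off + 1L] + z[i + off + 2L] + z[i + off + 3L] >= 3L
  hit <- ch[i] == "P" & (four(1L) | four(2L) | four(3L))
  match_df("pat7", i[hit], 7L, sequence)
}

#' Scan for bipartite NLS motifs
#'
#' Reports every 17-residue window whose first two residues are basic
#' (K/R), followed by a 10-residue unconstrained spacer, with at least 3 of
#' the final 5 residues basic.
#'
#' @inheritParams scan_pat4
#' @return data frame as in [scan_pat4()].
#' @export
scan_bipartite <- function(sequence) {
  validate_sequence(sequence)
  ch <- seq_chars(sequence)
  n <- length(ch)
  if (n < 17L) return(empty_match_df())
  z <- ch %in% AA_BASIC
  i <- seq_len(n - 16L)
  tail5 <- z[i + 12L] + z[i + 13L] + z[i + 14L] + z[i + 15L] + z[i + 16L]
  hit <- z[i] & z[i + 1L] & tail5 >= 3L
  match_df("bipartite", i[hit], 17L, sequence)
}

#' Scan a sequence for all NLS motif classes
#'
#' @inheritParams scan_pat4
#' @return data frame combining [scan_pat4()], [scan_pat7()] and
#'   [scan_bipartite()] matches.
#' @export
scan_nls <- function(sequence) {
  rbind(scan_pat4(sequence), scan_pat7(sequence), scan_bipartite(sequence))
}

#' Basic-residue percentage of a sequence
#'
#' Percentage of lysine plus arginine residues; histidine is excluded.
#'
#' @inheritParams scan_pat4
#' @return percentage in `[0, 100]` (unrounded).
#' @export
basic_fraction <- function(sequence) {
  validate_sequence(sequence)
  ch <- seq_chars(sequence)
  100 * sum(ch %in% AA_BASIC) / length(ch)
}

#' Cumulative NLS score
#'
#' Weighted sum of NLS motif counts plus a base offset. Under the default
#' weights (1, 1, 2, base -1) any single motif of any class makes the score
#' positive; a positive score marks the protein as NLS-containing.
#'
#' @param n_pat4,n_pat7,n_bipartite motif counts (vectorized).
#' @param weights named weights `c(pat4, pat7, bipartite, base)`.
#' @return numeric score vector.
#' @export
nls_score <- function(n_pat4, n_pat7, n_bipartite,
                      weights = c(pat4 = 1, pat7 = 1, bipartite = 2, base = -1)) {
  stopifnot(all(n_pat4 >= 0), all(n_pat7 >= 0), all(n_bipartite >= 0))
  weights[["pat4"]] * n_pat4 + weights[["pat7"]] * n_pat7 +
    weights[["bipartite"]] * n_bipartite + weights[["base"]]
}

#' Surrogate per-residue NES track
#'
#' Self-contained stand-in for an external per-residue NES predictor: scans
#' for the leucine-rich NES consensus Phi-x(2,3)-Phi-x(2,3)-Phi-x-Phi with
#' Phi in {L, I, V, F, M}. Residues occupying a Phi anchor of any match
#' (overlaps included) receive score 1; all others 0.
#'
#' @inheritParams scan_pat4
#' @return numeric vector, one score per residue.
#' @export
surrogate_nes_track <- function(sequence) {
  validate_sequence(sequence)
  ch <- seq_chars(sequence)
  n <- length(ch)
  track <- numeric(n)
  phi <- ch %in% AA_PHI
  for (g1 in 2:3) for (g2 in 2:3) {
    span <- g1 + g2 + 4L           # anchors at s, s+g1+1, s+g1+g2+2, s+g1+g2+4
    smax <- n - span
    if (smax < 1L) next
    s <- which(phi[seq_len(smax)])
    s <- s[phi[s + g1 + 1L] & phi[s + g1 + g2 + 2L] & phi[s + g1 + g2 + 4L]]
    if (length(s))
      track[unique(c(s, s + g1 + 1L, s + g1 + g2 + 2L, s + g1 + g2 + 4L))] <- 1
  }
  track
}

#' Windowed NES call from a per-residue track
#'
#' The NES score is the sum of the per-residue scores over the whole
#' protein. A residue "contributes" when its score exceeds
#' `residue_threshold`; the protein is NES-positive when some window of at
#' most `window` consecutive positions contains at least `min_residues`
#' contributing residues.
#'
#' @param track numeric vector of non-negative per-residue scores.
#' @param window window length in residues.
#' @param min_residues minimum contributing residues within one window.
#' @param residue_threshold per-residue contribution threshold.
#' @return list with `nes_score` (sum of track) and `nes_positive`.
#' @export
nes_call <- function(track, window = 15L, min_residues = 3L,
                     residue_threshold = 0.5) {
  stopifnot(window >= 1, min_residues >= 1, all(track >= 0))
  contrib <- which(track > residue_threshold)
  k <- length(contrib)
  positive <- FALSE
  if (k >= min_residues) {
    i <- seq_len(k - min_residues + 1L)
    positive <- any(contrib[i + min_residues - 1L] - contrib[i] <= window - 1L)
  }
  list(nes_score = sum(track), nes_positive = positive)
}

#' Localization class from NLS/NES calls
#'
#' @param nls_positive,nes_positive logical vectors.
#' @return character vector: `nuclear_resident` (NLS only), `shuttling`
#'   (both), `export_signal_only` (NES only) or `no_signal`.
#' @export
classify_localization <- function(nls_positive, nes_positive) {
  LOC_CLASSES[1L + as.integer(nes_positive) + 2L * as.integer(nls_positive)]
}

#' Per-protein signal profiles
#'
#' Runs the three NLS scanners, basic-residue composition, the cumulative
#' NLS score, the NES track (external when supplied in `nes_tracks`,
#' otherwise the surrogate scorer) and the windowed NES call for every
#' protein, then classifies each as nuclear-resident, shuttling,
#' export-signal-only or signal-free.
#'
#' @param records data frame from [read_fasta()].
#' @param config a [pipeline_config()].
#' @param nes_tracks optional named list of per-residue score vectors from
#'   [read_residue_scores()]; proteins without an entry fall back to the
#'   surrogate scorer.
#' @return data frame with one row per protein: `locus_id`, `n_pat4`,
#'   `n_pat7`, `n_bipartite`, `basic_percent`, `nls_score`, `nls_positive`,
#'   `nes_score`, `nes_positive`, `loc_class`.
#' @export
signal_profiles <- function(records, config = pipeline_config(),
                            nes_tracks = NULL) {
  n <- nrow(records)
  out <- data.frame(locus_id = records$locus_id,
                    n_pat4 = integer(n), n_pat7 = integer(n),
                    n_bipartite = integer(n), basic_percent = numeric(n),
                    nls_score = numeric(n), nls_positive = logical(n),
                    nes_score = numeric(n), nes_positive = logical(n),
                    loc_class = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sq <- records$sequence[i]
    id <- records$locus_id[i]
    out$n_pat4[i] <- nrow(scan_pat4(sq))
    out$n_pat7[i] <- nrow(scan_pat7(sq))
    out$n_bipartite[i] <- nrow(scan_bipartite(sq))
    out$basic_percent[i] <- basic_fraction(sq)
    external <- !is.null(nes_tracks) && id %in% names(nes_tracks)
    track <- if (external) {
      tr <- nes_tracks[[id]]
      if (length(tr) < nchar(sq)) tr <- c(tr, numeric(nchar(sq) - length(tr)))
      tr
    } else surrogate_nes_track(sq)
    thr <- if (external) config$nes_residue_threshold else 0
    nes <- nes_call(track, config$nes_window, config$nes_min_residues, thr)
    out$nes_score[i] <- nes$nes_score
    out$nes_positive[i] <- nes$nes_positive
  }
  out$nls_score <- nls_score(out$n_pat4, out$n_pat7, out$n_bipartite,
                             config$nls_weights)
  out$nls_positive <- out$nls_score > 0
  out$loc_class <- classify_localization(out$nls_positive, out$nes_positive)
  out
}
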