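# Independent brute-force oracles: plain per-window loops, written without
# reference to the vectorized scanner implementations.

is_basic <- function(ch) ch == "K" | ch == "R"

oracle_pat4 <- function(s) {
  ch <- strsplit(s, "")[[1]]
  out <- integer(0)
  if (length(ch) >= 4) for (i in 1:(length(ch) - 3)) {
    w <- ch[i:(i + 3)]
    nb <- sum(is_basic(w))
    if (nb == 4) out <- c(out, i)
    else if (nb == 3 && w[!is_basic(w)] %in% c("H", "P")) out <- c(out, i)
  }
  out
}

oracle_pat7 <- function(s) {
  ch <- strsplit(s, "")[[1]]
  out <- integer(0)
  if (length(ch) >= 7) for (i in 1:(length(ch) - 6)) {
    w <- ch[i:(i + 6)]
    if (w[1] != "P") next
    hit <- FALSE
    for (off in 1:3)
      if (sum(is_basic(w[(1 + off):(4 + off)])) >= 3) hit <- TRUE
    if (hit) out <- c(out, i)
  }
  out
}

oracle_bipartite <- function(s) {
  ch <- strsplit(s, "")[[1]]
  out <- integer(0)
  if (length(ch) >= 17) for (i in 1:(length(ch) - 16)) {
    w <- ch[i:(i + 16)]
    if (is_basic(w[1]) && is_basic(w[2]) && sum(is_basic(w[13:17])) >= 3)
      out <- c(out, i)
  }
  out
}

# Sliding-window NES oracle: every window of exactly `window` consecutive
# positions (truncated at the end) counted by brute force.
oracle_nes_positive <- function(track, window = 15, min_residues = 3,
                                threshold = 0.5) {
  contributes <- track > threshold
  n <- length(track)
  if (n == 0) return(FALSE)
  for (i in seq_len(n)) {
    j <- min(n, i + window - 1)
    if (sum(contributes[i:j]) >= min_residues) return(TRUE)
  }
  FALSE
}

# Random test sequences enriched for the residues the predicates read.
random_seq <- function(len, alphabet = c("K", "R", "H", "P", "A", "L", "G",
                                         "S", "E", "D")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of an
# N-element urn whose first K elements are successes.
oracle_hypergeom_upper <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)
  mean(succ >= k)
}

# Hand-written BH step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
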