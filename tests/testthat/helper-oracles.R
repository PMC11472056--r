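# Independent brute-force oracles used to check the package's fast paths.

# Duplex fraction by bisection on K (Ct/2 - x)^2 = x over x in [0, Ct/2].
bisection_alpha <- function(dH, dS, Ct, T_K, iters = 200L) {
  R <- 1.987204
  lnK <- -(dH * 1000 - T_K * dS) / (R * T_K)
  K <- exp(lnK)
  f <- function(x) K * (Ct / 2 - x)^2 - x
  lo <- 0
  hi <- Ct / 2
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  2 * ((lo + hi) / 2) / Ct
}

# Per-position O(nm) substring scan, 0-based offsets, overlaps included.
naive_scan <- function(utr, motif) {
  utr <- chartr("T", "U", toupper(utr))
  motif <- chartr("T", "U", toupper(motif))
  n <- nchar(utr)
  m <- nchar(motif)
  if (n < m) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - m + 1L)) {
    if (substr(utr, i, i + m - 1L) == motif) hits <- c(hits, i - 1L)
  }
  hits
}

# Per-base reverse complement.
naive_revcomp <- function(s) {
  map <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(unname(map[strsplit(s, "")[[1L]]])), collapse = "")
}

# Rank-based quantile normalization for tie-free matrices.
naive_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2L, sort))
  apply(m, 2L, function(col) ref[rank(col)])
}

random_rna_string <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Small truth table for expression-generator tests.
make_truth <- function(n, n_sm, on_target = 1L) {
  is_sm <- c(rep(TRUE, n_sm), rep(FALSE, n - n_sm))
  data.frame(
    transcript_id = sprintf("TX%04d", seq_len(n)),
    is_sm = is_sm,
    n_planted_motifs = as.integer(is_sm),
    is_on_target = seq_len(n) == on_target,
    stringsAsFactors = FALSE
  )
}
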