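# Independent oracles used across the suite. These deliberately use naive
# enumeration / double loops so they share no code with the implementation.

# two-sided Fisher p by full enumeration of all tables with the observed
# margins: sum of hypergeometric point probabilities <= that of the
# observed table (with the customary relative tolerance for ties)
fisher_enumeration_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  if (lo > hi || n == 0) return(1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# brute-force longest shared flank: largest m with suffix(left, m) equal to
# prefix(right, m)
shared_flank_oracle <- function(left, right, cap = min(nchar(left), nchar(right))) {
  best <- 0L
  for (m in seq_len(cap)) {
    if (substr(left, nchar(left) - m + 1, nchar(left)) == substr(right, 1, m))
      best <- m
  }
  best
}

# naive double-loop opposite-homozygote window scan
opposite_hom_scan_oracle <- function(ga, gb, window) {
  n <- length(ga)
  vapply(seq_len(n - window + 1), function(s) {
    cnt <- 0
    for (j in s:(s + window - 1)) {
      if ((ga[j] == 0 && gb[j] == 2) || (ga[j] == 2 && gb[j] == 0)) cnt <- cnt + 1
    }
    cnt / window
  }, numeric(1))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# largest bp span of any window of `window` consecutive SNPs: the scan's
# positional resolution for "within one window" assertions
max_window_span_bp <- function(positions, window) {
  n <- length(positions)
  max(positions[window:n] - positions[1:(n - window + 1)])
}
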