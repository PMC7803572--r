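# Independent brute-force oracles shared across test files.

# Naive island detector: examine every window by substring arithmetic,
# union the qualifying ones, then re-verify merged intervals.
brute_cgis <- function(seq, min_len = 200, min_gc = 0.5, min_oe = 0.6,
                       window = 200) {
  L <- nchar(seq)
  qual <- logical(L)
  for (s in 1:(L - window + 1)) {
    w <- substr(seq, s, s + window - 1)
    if (gc_fraction(w) > min_gc && obs_exp_ratio(w) > min_oe)
      qual[s:(s + window - 1)] <- TRUE
  }
  out <- NULL
  r <- rle(qual)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    sub <- substr(seq, starts[k], ends[k])
    if ((ends[k] - starts[k] + 1) > min_len && gc_fraction(sub) > min_gc &&
        obs_exp_ratio(sub) > min_oe)
      out <- rbind(out, c(starts[k] - 1L, ends[k]))
  }
  out
}

# Binomial upper tail P(X >= N) by explicit pmf summation with choose().
enum_binom_tail <- function(N, size, prob) {
  if (N > size) return(0)
  k <- N:size
  sum(choose(size, k) * prob^k * (1 - prob)^(size - k))
}
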