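# Independent oracles used across tests. These deliberately share no code
# with the package implementation.

# Exhaustive burst oracle: classify each ISI as break (> termination) or
# extender (<= termination); within each maximal run of extenders, a burst
# starts at the first start-qualifying ISI (< onset) and runs to the end of
# the run. Returns burst spike-index ranges like detect_bursts().
oracle_bursts <- function(isi, onset, term) {
  if (!length(isi)) return(data.frame(start_index = integer(), end_index = integer()))
  is_break <- isi > term
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= length(isi)) {
    if (is_break[i]) { i <- i + 1L; next }
    j <- i
    while (j + 1L <= length(isi) && !is_break[j + 1L]) j <- j + 1L
    run <- i:j
    s <- run[which(isi[run] < onset)[1]]
    if (!is.na(s)) {
      starts <- c(starts, s)       # first burst spike index = s
      ends <- c(ends, j + 1L)      # last burst spike = spike after ISI j
    }
    i <- j + 1L
  }
  data.frame(start_index = starts, end_index = ends)
}

# spike-time construction from an ISI sequence
times_from_isi <- function(isi, t0 = 0) cumsum(c(t0, isi))

# closed-form power of a one-way ANOVA with k groups, n per group,
# group means mu, common sd sigma, at level alpha
anova_power_exact <- function(mu, n, sigma, alpha = 0.05) {
  k <- length(mu)
  lambda <- n * sum((mu - mean(mu))^2) / sigma^2
  df1 <- k - 1; df2 <- k * (n - 1)
  1 - stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = lambda)
}

make_train <- function(times, end = max(times) + 1, type = "DA") {
  spike_train(times, 0, end, type)
}
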