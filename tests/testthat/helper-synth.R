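# Shared fixture builders: everything is generated in code at test time.

flat_tonic <- function(level = 2) {
  list(level = level, slope = 0, vlf_amp = 0, vlf_freq = 0.002)
}

# Preprocessed EDA channel carrying a known SCR train on a flat tonic.
make_eda_channel <- function(onsets, amplitudes, level = 2, noise_sd = 0,
                             fs = 100, duration_s = 180) {
  s <- synthesize_eda(onsets, amplitudes, flat_tonic(level),
                      noise_sd = noise_sd, fs = fs, duration_s = duration_s)
  signal_channel(s$trace, fs, "uS")
}

# An rr_series built directly from a known RR vector (beats at cumsum(rr)).
make_rr_series <- function(rr) rr_series(rr)

# Independent step-up FDR oracle used against bh_adjust().
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in seq(m, 1)) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Direct no-tie Kruskal-Wallis formula, independent of the implementation.
kw_oracle_no_ties <- function(values, group) {
  g <- as.factor(group)
  r <- rank(values)
  n <- length(values)
  rbar <- tapply(r, g, mean)
  ni <- tabulate(g)
  12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
}
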