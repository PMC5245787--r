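# Brute-force shot-noise oracle: superpose exponential-decay events at
# uniform random onsets and take the within-window variance.
shot_noise_mc <- function(amp_mean, n_events, tau, interval, cv,
                          reps = 200, dt = 0.5) {
  t <- seq(0, interval, by = dt)
  vs <- vapply(seq_len(reps), function(r) {
    onsets <- runif(n_events, 0, interval)
    amps <- if (cv == 0) rep(amp_mean, n_events) else
      rgamma(n_events, shape = 1 / cv^2, scale = amp_mean * cv^2)
    cur <- numeric(length(t))
    for (k in seq_len(n_events)) {
      m <- t >= onsets[k]
      cur[m] <- cur[m] + amps[k] * exp(-(t[m] - onsets[k]) / tau)
    }
    var(cur)
  }, numeric(1))
  c(mean = mean(vs), se = sd(vs) / sqrt(reps))
}

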