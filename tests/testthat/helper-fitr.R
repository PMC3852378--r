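new_traj_for_test <- function(times, freqs)
  fitr:::new_trajectory_set(times, freqs)

# brute-force FITR statistic from a frequency matrix (rows = times),
# independent of the package's increment/statistic code paths
fitr_stat_oracle <- function(x, R_cols = 2:ncol(x)) {
  L <- nrow(x) - 1L
  tsum <- 0
  for (i in seq_len(L)) {
    d <- (x[i + 1L, ] - x[i, ]) / sqrt(x[i, ] * (1 - x[i, ]))
    tsum <- tsum + d[1L] / sqrt(mean(d[R_cols]^2))
  }
  tsum / sqrt(L)
}
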