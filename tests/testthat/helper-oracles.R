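# Independent brute-force re-implementations of the detection statistics,
# written against the definitions (not the package code paths).

oracle_neigh_idx <- function(center, n_per_side, skip, drop_extrema, amps) {
  idx <- setdiff((center - n_per_side):(center + n_per_side), center)
  if (skip > 0)
    idx <- setdiff(idx, c((center - skip):(center - 1),
                          (center + 1):(center + skip)))
  if (drop_extrema) {
    v <- amps[idx]
    i_max <- idx[which(v == max(v))[1]]
    idx2 <- setdiff(idx, i_max)
    v2 <- amps[idx2]
    i_min <- idx2[which(v2 == min(v2))[1]]
    idx <- setdiff(idx2, i_min)
  }
  idx
}

oracle_bc <- function(amps, center, n_per_side, skip, drop_extrema) {
  idx <- oracle_neigh_idx(center, n_per_side, skip, drop_extrema, amps)
  amps[center] - mean(amps[idx])
}

oracle_z <- function(amps, center, n_per_side, skip) {
  idx <- oracle_neigh_idx(center, n_per_side, skip, FALSE, amps)
  (amps[center] - mean(amps[idx])) / stats::sd(amps[idx])
}

oracle_chunk_sum <- function(amps, bins, half_width) {
  out <- numeric(2 * half_width + 1)
  for (b in bins)
    out <- out + amps[(b - half_width):(b + half_width)]
  out
}

# a random positive spectrum object on an integer-cycle-like grid
random_spectrum <- function(seed, n_bins = 1200, n_ch = 1, df = 1 / 59.5) {
  set.seed(seed)
  amps <- matrix(abs(stats::rnorm(n_ch * n_bins, mean = 1, sd = 0.3)),
                 n_ch, n_bins)
  labels <- sprintf("CH%d", seq_len(n_ch))
  rownames(amps) <- labels
  structure(list(amps = amps, df = df, n_time_samples = 2 * (n_bins - 1),
                 labels = labels, normalization = "2/N single-sided",
                 meta = list()),
            class = "fpvs_spectrum")
}

# single-sinusoid epoch helper
sine_epoch <- function(freq, amp = 1, fs = 256, dur = 59.5, phase = 0,
                       n_ch = 1) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  x <- amp * sin(2 * pi * freq * t + phase)
  epoch(matrix(rep(x, each = n_ch), nrow = n_ch), fs, t0 = 0,
        labels = sprintf("CH%d", seq_len(n_ch)))
}
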