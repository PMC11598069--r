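# Shared fixture builders: synthetic pairs run through segmentation and
# feature extraction, and the naive DFT used as the oracle for the fast
# transform.

synth_fs <- function(asym_amp = 0, asym_freq = 0, noise_sd = 0, seed = 1,
                     M = 10, n_reps = 10, trim = 0, ...) {
  cfg <- synth_config(n_reps = n_reps, asym_amp = asym_amp,
                      asym_freq = asym_freq, noise_sd = noise_sd,
                      seed = seed, ...)
  pair <- generate_pair(cfg)
  if (trim > 0) {
    pair$L <- trim_recording(pair$L, trim, trim)
    pair$R <- trim_recording(pair$R, trim, trim)
  }
  build_feature_set(build_signal_matrix(pair$L, pair$R, M = M))
}

synth_criterion <- function(..., psi = "mixed") {
  global_criterion(synth_fs(...), psi = psi)$C
}

# O(N^2) direct evaluation of the mean-removed DFT of one column.
naive_dft <- function(x) {
  n_len <- length(x)
  xc <- x - mean(x)
  vapply(seq_len(n_len), function(k) {
    sum(xc * exp(-1i * (k - 1) * (seq_len(n_len) - 1) * 2 * pi / n_len))
  }, complex(1))
}

# Write a small recording file by hand (bypasses write_recording so I/O
# tests don't assume the writer is correct).
write_raw_recording <- function(t, a, path, sep = ",") {
  header <- paste(c("time_s", "ax", "ay", "az"), collapse = sep)
  rows <- apply(cbind(t, a), 1L, paste, collapse = sep)
  writeLines(c(header, rows), path)
  path
}
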