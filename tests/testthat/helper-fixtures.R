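# Shared fixtures built in code.

# A tiny deterministic labeled volume with all four ROI labels.
tiny_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(101, shape = c(32, 32, 24))
    cache
  }
})

# Feature table with a known additive/multiplicative batch structure.
make_batch_table <- function(n_features = 4, batches = c("A", "B"),
                             n_scans = 50, gamma = c(0, 2), delta = c(1, 1),
                             noise_sd = 1, scan_sd = 0, seed = 7, rois = 1L) {
  simulate_feature_table(sim_design(
    n_features = n_features, batch_ids = batches, n_scans = n_scans,
    roi_labels = rois, alpha = 1, gamma = gamma, delta = delta,
    noise_sd = noise_sd, scan_sd = scan_sd, seed = seed))
}

batch_mean_gap <- function(tb, batch_a, batch_b) {
  vapply(feature_columns(tb), function(f) {
    abs(mean(tb[[f]][tb$group == batch_b]) - mean(tb[[f]][tb$group == batch_a]))
  }, numeric(1))
}

# Smooth synthetic slices in [0, 1] for GAN tests.
make_slices <- function(n, size = 32, seed = 2) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      m <- matrix(runif(1), size, size) * 0.5 + 0.25
      m <- m + 0.15 * sin(outer(seq_len(size), seq_len(size),
                                function(a, b) a * runif(1) / 3 + b * runif(1) / 3))
      pmin(pmax(m, 0), 1)
    })
  })
}

# Axial (z-direction) high-frequency spectral energy of a volume.
axial_hf_energy <- function(vol, frac = 0.25) {
  d <- dim(vol$intensities)
  sp <- apply(vol$intensities, c(1, 2), function(v) Mod(fft(v))^2)
  # apply returns (z, x, y); frequency index along first dim
  f <- (seq_len(d[3]) - 1) / d[3]
  f[f > 0.5] <- f[f > 0.5] - 1
  sum(sp[abs(f) > frac, , ])
}
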