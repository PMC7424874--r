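# Small synthetic fixtures shared across tests. Everything is generated in
# code; sizes are kept small so the whole suite runs in seconds to minutes.

tiny_basis <- function(...) direction_basis(...)

# a quick participant: few sensors, short epochs
tiny_gt <- function(n_sensors = 8, seed = 1, ...) {
  ground_truth(n_sensors = n_sensors, sampling_rate = 600, seed = seed, ...)
}

# noise-free windowed localizer data at the evoked peak: sensors x trials
peak_patterns <- function(gt, design) {
  C <- channel_amplitudes(gt$basis, design$presented_dir)
  gt$true_weights %*% C
}

# a non-degenerate random training set with full-rank channel design:
# directions drawn over the whole circle so joint fits are identified
random_training <- function(n_sensors = 12, n_trials = 60, seed = 42,
                            basis = direction_basis(), noise_sd = 0) {
  set.seed(seed)
  th <- stats::runif(n_trials, -45, 135)
  W <- matrix(stats::rnorm(n_sensors * length(basis$centers)), n_sensors)
  C <- channel_amplitudes(basis, th)
  B <- W %*% C
  if (noise_sd > 0) B <- B + matrix(stats::rnorm(length(B), sd = noise_sd),
                                    nrow(B))
  list(B = B, C = C, W = W, th = th, basis = basis)
}

# circular absolute difference on the 360-degree direction circle
circ_err <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
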