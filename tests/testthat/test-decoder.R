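test_that("demeaning removes trial means and is idempotent", {
  set.seed(3)
  B <- matrix(rnorm(5 * 12), 5)
  C <- matrix(runif(3 * 12), 3)
  dm <- demean_training(B, C)
  expect_lt(max(abs(rowMeans(dm$B0))), 1e-12)
  expect_lt(max(abs(rowMeans(dm$C0))), 1e-12)
  dm2 <- demean_training(dm$B0, dm$C0)
  expect_equal(dm2$B0, dm$B0)
  # constant rows become all-zero
  Bc <- rbind(B, 7)
  expect_equal(demean_training(Bc, C)$B0[6, ], rep(0, 12))
  expect_error(demean_training(B[, 1, drop = FALSE], C[, 1, drop = FALSE]),
               "at least 2")
})

test_that("noise covariance matches a two-pass residual loop and vanishes for noise-free rank-one data", {
  tr <- random_training(n_sensors = 6, n_trials = 30, seed = 8,
                        noise_sd = 0.7)
  dm <- demean_training(tr$B, tr$C)
  W <- fit_weights(dm$B0, dm$C0)
  covs <- estimate_noise_cov(dm$B0, dm$C0, W)
  i <- 4L
  E <- dm$B0 - W[, i, drop = FALSE] %*% dm$C0[i, , drop = FALSE]
  S_oracle <- matrix(0, 6, 6)
  for (a in 1:6) for (b in 1:6)
    S_oracle[a, b] <- sum(E[a, ] * E[b, ]) / (ncol(E) - 1)
  expect_equal(covs[[i]], S_oracle)
  expect_true(isSymmetric(covs[[i]]))

  # noise-free single-channel data: residual for that channel is zero
  B1 <- W[, i, drop = FALSE] %*% dm$C0[i, , drop = FALSE]
  covs1 <- estimate_noise_cov(B1, dm$C0, W)
  expect_lt(max(abs(covs1[[i]])), 1e-20)
})

test_that("noise covariance of pure white noise converges to a scaled identity", {
  set.seed(21)
  p <- 5; n <- 20000; sigma <- 1.3
  E <- matrix(rnorm(p * n, sd = sigma), p)
  C0 <- matrix(rnorm(2 * n), 2)
  W <- matrix(0, p, 2)  # zero weights: residual is the data itself
  S <- estimate_noise_cov(E, C0, W)[[1]]
  expect_equal(S, diag(sigma^2, p), tolerance = 0.05)
})

test_that("shrinkage limits, invertibility in the trial-starved regime, and condition-number monotonicity", {
  set.seed(4)
  p <- 30; n <- 12  # fewer trials than sensors: raw covariance is singular
  E <- matrix(rnorm(p * n), p)
  E <- E - rowMeans(E)
  S <- E %*% t(E) / (n - 1)
  nu <- mean(diag(S))
  full <- shrink_covariance(S, shrinkage = 1)
  expect_equal(full$Sigma, diag(nu, p))
  none <- shrink_covariance(S, shrinkage = 0)
  expect_equal(none$Sigma, S)

  expect_lt(rcond(S), 1e-12)  # raw covariance is numerically singular
  an <- shrink_covariance(list(S = S, E = E))
  expect_gt(an$lambda, 0)
  expect_lte(an$lambda, 1)
  expect_gt(rcond(an$Sigma), 1e-8)  # shrunk covariance is invertible

  kappa <- sapply(c(0.05, 0.2, 0.5, 0.8, 1), function(l) {
    Sig <- shrink_covariance(S, shrinkage = l)$Sigma
    ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
    max(ev) / min(ev)
  })
  expect_true(all(diff(kappa) <= 1e-8))
  expect_error(shrink_covariance(list(S = matrix(0, 3, 3),
                                      E = matrix(0, 3, 5))),
               "degenerate")
})

test_that("filters reduce to matched filters under identity covariance and obey the unit-gain normalization", {
  tr <- random_training(n_sensors = 9, n_trials = 50, seed = 13,
                        noise_sd = 0.4)
  dm <- demean_training(tr$B, tr$C)
  W <- fit_weights(dm$B0, dm$C0)
  k <- ncol(W)
  V_id <- build_filters(W, replicate(k, diag(9), simplify = FALSE))
  for (i in seq_len(k)) {
    # proportional to the weight pattern, scaled to unit gain
    expect_equal(V_id[, i], W[, i] / sum(W[, i]^2))
  }
  covs <- iemdecode:::iem_noise_with_residuals(dm$B0, dm$C0, W,
                                               "own_channel")
  V <- build_filters(W, lapply(covs, shrink_covariance))
  expect_equal(unname(colSums(V * W)), rep(1, k))  # v_i' w_i = 1
  # decoding a pure channel pattern returns 1 on that channel
  est <- decode_channels(V, W[, 3, drop = FALSE])
  expect_equal(est[3, 1], 1)
})

test_that("channel decoding is linear and validates sensor dimensions", {
  V <- matrix(rnorm(12), 4, 3)
  b1 <- rnorm(4); b2 <- rnorm(4)
  expect_equal(decode_channels(V, cbind(b1 + b2)),
               decode_channels(V, cbind(b1)) + decode_channels(V, cbind(b2)),
               ignore_attr = TRUE)
  expect_equal(decode_channels(V, matrix(0, 4, 2)), matrix(0, 3, 2))
  expect_error(decode_channels(V, matrix(0, 5, 2)), "4 sensors.*5")
})

test_that("readout peaks at a channel center for one-hot estimates and at the midpoint for equal adjacent channels", {
  b <- direction_basis()
  est <- matrix(0, 21, 2)
  est[7, 1] <- 1
  est[7, 2] <- 1; est[8, 2] <- 1
  dec <- readout_direction(est, b)
  expect_equal(dec[1], b$centers[7], tolerance = b$grid_step)
  expect_equal(dec[2], mean(b$centers[7:8]), tolerance = b$grid_step)
})

test_that("readout is scale invariant and matches a 0.001-degree brute-force scan within one grid step", {
  b <- direction_basis()
  set.seed(6)
  est <- matrix(rnorm(21 * 5), 21)
  dec <- readout_direction(est, b)
  expect_equal(readout_direction(3.7 * est, b), dec)

  fine <- seq(b$span[1], b$span[2] - 0.001, by = 0.001)
  Ff <- t(sapply(b$centers, function(cc)
    pmax(0, cos(2 * pi * (fine - cc) / 360))^6))
  ref <- fine[apply(crossprod(Ff, est), 2, which.max)]
  expect_true(all(abs(dec - ref) <= b$grid_step + 1e-9))
})

test_that("flat readout curves are flagged and returned as the span midpoint", {
  b <- direction_basis()
  est <- matrix(0, 21, 1)
  expect_warning(dec <- readout_direction(est, b), "flat")
  expect_equal(as.numeric(dec), mean(b$span))
  expect_true(attr(dec, "degenerate")[1])
})

test_that("covariance-aware filters beat matched filters on correlated noise", {
  set.seed(17)
  p <- 20; n <- 400
  tr <- random_training(n_sensors = p, n_trials = n, seed = 17)
  # strongly correlated noise
  Sig <- 0.8^abs(outer(1:p, 1:p, "-")) * 4
  L <- t(chol(Sig))
  B <- tr$B + L %*% matrix(rnorm(p * n), p)
  dm <- demean_training(B, tr$C)
  W <- fit_weights(dm$B0, dm$C0)
  covs <- iemdecode:::iem_noise_with_residuals(dm$B0, dm$C0, W,
                                               "own_channel")
  V <- build_filters(W, lapply(covs, shrink_covariance))
  V_match <- build_filters(W, replicate(ncol(W), diag(p),
                                        simplify = FALSE))
  # SNR of channel-7 output: signal gain is 1 by normalization, so compare
  # noise variance v' Sig v
  snr <- function(v) 1 / drop(t(v) %*% Sig %*% v)
  expect_gt(snr(V[, 7]), snr(V_match[, 7]))
})
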