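test_that("fisher transform has the closed-form values and inverts tanh", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  r <- c(-0.9, -0.3, 0.2, 0.7)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_equal(fisher_z(tanh(r)), r)
  expect_error(fisher_z(1), "defined")
})

test_that("participant QC correlates mean report per direction and applies the 0.9 threshold", {
  des <- make_main_design(2, 60, seed = 20)
  gt <- tiny_gt(seed = 20, cue_weight = 0, report_noise_sd = 0)
  tt <- simulate_behavior(des, gt)
  qc <- participant_qc(tt)
  expect_equal(qc$qc_r, 1)
  expect_true(qc$pass)
  # hand-computed Pearson on a 5-pair toy (one report per direction)
  toy <- data.frame(task = "main", cue = "cue27",
                    presented_dir = c(9, 27, 45, 63, 81),
                    reported_dir = c(12, 20, 50, 60, 75))
  num <- sum((toy$presented_dir - mean(toy$presented_dir)) *
             (toy$reported_dir - mean(toy$reported_dir)))
  den <- sqrt(sum((toy$presented_dir - mean(toy$presented_dir))^2) *
              sum((toy$reported_dir - mean(toy$reported_dir))^2))
  expect_equal(participant_qc(toy)$qc_r, num / den)
  # constant reports are degenerate and fail
  toy$reported_dir <- 45
  qc2 <- participant_qc(toy)
  expect_true(qc2$degenerate)
  expect_false(qc2$pass)
})

test_that("perceptual bias is the cue-conditional mean report difference", {
  toy <- data.frame(task = "main",
                    cue = c("cue63", "cue63", "cue27", "cue27"),
                    presented_dir = 45,
                    reported_dir = c(48, 46, 46, 44))
  expect_equal(perceptual_bias(toy), 2)
  expect_error(perceptual_bias(toy[toy$cue == "cue63", ]),
               "both cue conditions")
})

test_that("simulated reports recover the 36 * w bias in expectation", {
  w <- 1 / 36
  des <- make_main_design(200, 60, seed = 21)  # 12000 trials
  gt <- tiny_gt(seed = 21, cue_weight = w, report_noise_sd = 5)
  tt <- simulate_behavior(des, gt)
  bias <- perceptual_bias(tt)
  # expectation is 36 * w = 1 degree; the noisiest cells hold ~600 trials,
  # so the bias SE is below 0.1 degree
  expect_lt(abs(bias - 1), 0.4)
  # noise-free boundary cases
  gt1 <- tiny_gt(seed = 21, cue_weight = 1, report_noise_sd = 0)
  expect_equal(perceptual_bias(simulate_behavior(des, gt1)), 36)
  gt0 <- tiny_gt(seed = 21, cue_weight = 0, report_noise_sd = 0)
  expect_equal(perceptual_bias(simulate_behavior(des, gt0)), 0)
})

test_that("bias split assigns zero biases to the unbiased group", {
  s <- split_by_bias(c(2, -1, 0.5))
  expect_equal(s$biased, c(1, 3))
  expect_equal(unname(s$sizes), c(2, 1))
  expect_message(s0 <- split_by_bias(c(1, 0)), "exactly 0")
  expect_equal(s0$unbiased, 2)
})

test_that("cue effect on decoding is null without a cue signal, equals a hand loop on a toy, and balances presented directions", {
  # toy: 10 trials, decoded values chosen by hand
  toy <- data.frame(task = "main",
                    cue = rep(c("cue27", "cue63"), each = 5),
                    presented_dir = rep(c(9, 27, 45, 63, 81), 2))
  dec <- matrix(c(10, 25, 44, 60, 80,   # cue27 trials
                  12, 29, 47, 65, 83),  # cue63 trials
                nrow = 1)
  eff <- cue_effect_timecourse(dec, toy)
  hand <- mean(c(12, 29, 47, 65, 83)) - mean(c(10, 25, 44, 60, 80))
  expect_equal(eff, hand)

  # unbalanced cells: equal cell weighting must ignore the imbalance
  toy2 <- data.frame(task = "main",
                     cue = c(rep("cue27", 6), rep("cue63", 3)),
                     presented_dir = c(27, 27, 27, 27, 45, 45, 27, 45, 45))
  dec2 <- matrix(c(20, 22, 24, 26, 40, 42, 30, 50, 52), 1)
  m27 <- mean(c(mean(c(20, 22, 24, 26)), mean(c(40, 42))))
  m63 <- mean(c(30, mean(c(50, 52))))
  expect_equal(cue_effect_timecourse(dec2, toy2), m63 - m27)

  # label exchangeability: shuffling cues centres the effect at zero
  set.seed(22)
  des <- make_main_design(4, 60, seed = 22)
  dec3 <- matrix(rnorm(3 * nrow(des), mean = 45, sd = 20), 3)
  effs <- replicate(200, {
    sh <- des; sh$cue <- sample(sh$cue)
    cue_effect_timecourse(dec3, sh)[1]
  })
  expect_lt(abs(mean(effs)), 1)
})

test_that("cue effect drops directions missing from one cue condition symmetrically", {
  toy <- data.frame(task = "main",
                    cue = c("cue27", "cue27", "cue63"),
                    presented_dir = c(27, 45, 27))
  dec <- matrix(c(20, 40, 30), 1)
  expect_warning(eff <- cue_effect_timecourse(dec, toy), "missing")
  expect_equal(eff, 30 - 20)  # the 45-degree cell is dropped on both sides
})

test_that("one-sample cluster test finds no clusters in null data and a maximal cluster for a large uniform shift", {
  set.seed(30)
  X0 <- matrix(rnorm(8 * 40), 8)
  r0 <- cluster_perm_one_sample(X0, n_perm = 500, seed = 1)
  expect_true(all(r0$clusters$p > 0.01 | nrow(r0$clusters) == 0))

  X1 <- X0 + 5
  r1 <- cluster_perm_one_sample(X1, n_perm = 500, seed = 1)
  expect_equal(nrow(significant_clusters(r1)), 1)
  expect_equal(r1$clusters$start[1], 1)
  expect_equal(r1$clusters$end[1], 40)
  # p at the resolution floor given the permutation count used
  expect_equal(r1$clusters$p[1], 1 / (1 + r1$n_perm))
  expect_gt(r1$clusters$d[1], 2)
})

test_that("cluster masses and bounds agree with a direct threshold-and-sum computation", {
  set.seed(31)
  X <- matrix(rnorm(10 * 60), 10)
  X[, 20:26] <- X[, 20:26] + 1.2
  res <- cluster_perm_one_sample(X, n_perm = 200, seed = 2)
  tvec <- apply(X, 2, function(col) t.test(col)$statistic)
  tcrit <- qt(0.95, 9)
  runs <- rle(tvec > tcrit)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  exp_mass <- mapply(function(s, e) sum(tvec[s:e]),
                     starts[runs$values], ends[runs$values])
  expect_equal(res$clusters$mass, unname(exp_mass))
  expect_equal(res$clusters$start, unname(starts[runs$values]))
})

test_that("small cohorts trigger exhaustive sign enumeration", {
  set.seed(33)
  X <- matrix(rnorm(5 * 20, mean = 1), 5)
  expect_message(r <- cluster_perm_one_sample(X, n_perm = 1000, seed = 1),
                 "exhaustively")
  expect_true(r$exhaustive)
  expect_equal(r$n_perm, 32)
})

test_that("between-groups cluster test is empty for identical groups, finds injected windows, and is label-symmetric", {
  set.seed(32)
  A <- matrix(rnorm(6 * 50), 6)
  rAA <- cluster_perm_between(A, A, n_perm = 300, seed = 3)
  expect_equal(nrow(significant_clusters(rAA)), 0)

  B <- A; Bshift <- A + 0  # same base noise for a clean window
  grpA <- A; grpA[, 15:25] <- grpA[, 15:25] + 4
  r <- cluster_perm_between(grpA, B, n_perm = 300, seed = 3)
  sig <- significant_clusters(r)
  expect_gte(nrow(sig), 1)
  expect_lte(sig$start[1], 16)
  expect_gte(sig$end[1], 24)

  r2 <- cluster_perm_between(B, grpA, n_perm = 300, seed = 3,
                             tail = "two")
  r1 <- cluster_perm_between(grpA, B, n_perm = 300, seed = 3,
                             tail = "two")
  expect_equal(r1$clusters$mass, -r2$clusters$mass)
  expect_equal(r1$clusters$p, r2$clusters$p)
})

test_that("partial correlation matches the closed-form formula and handles degenerate inputs", {
  dec <- c(10, 20, 31, 39, 52, 58)
  rep_ <- c(12, 18, 33, 41, 49, 61)
  pres <- c(9, 9, 27, 27, 45, 45)
  r_xy <- cor(dec, rep_); r_xz <- cor(dec, pres); r_yz <- cor(rep_, pres)
  oracle <- (r_xy - r_xz * r_yz) /
    sqrt((1 - r_xz^2) * (1 - r_yz^2))
  expect_equal(trial_partial_correlation(dec, rep_, pres), oracle)

  # constant covariate: reduces to the plain correlation
  expect_equal(trial_partial_correlation(dec, dec, rep(45, 6)), 1)
  # decoded identical to presented: residual variance is zero
  expect_warning(
    r <- trial_partial_correlation(as.numeric(pres), rep_, pres),
    "zero residual")
  expect_true(is.na(r))
  # matrix input gives one value per time step
  M <- rbind(dec, rev(dec))
  expect_length(trial_partial_correlation(M, rep_, pres), 2)
  expect_error(trial_partial_correlation(dec[1:3], rep_[1:3], pres[1:3]),
               "at least 4")
})

test_that("categorical covariate control demeans within presented levels", {
  set.seed(35)
  pres <- rep(c(9, 27, 45), each = 10)
  dec <- rnorm(30) + pres
  rep_ <- rnorm(30) + pres
  rx <- dec - ave(dec, pres)
  ry <- rep_ - ave(rep_, pres)
  expect_equal(
    trial_partial_correlation(dec, rep_, pres, covariate = "categorical"),
    cor(rx, ry))
})
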