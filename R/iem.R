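#' Fit an inverted encoding model
#'
#' Trains the two-stage model that decodes a continuous motion direction from
#' multi-sensor data. Stage one estimates a forward weight matrix `W`
#' (sensors x channels) mapping hypothesized channel amplitudes to sensor
#' amplitudes by least squares. Stage two inverts the model into spatial
#' filters `V = Sigma*^-1 W` using per-channel noise covariance matrices
#' regularized by analytic shrinkage, each filter rescaled to unit gain on
#' its own channel pattern. `predict()` then maps unseen sensor data to
#' channel responses and on to a decoded direction.
#'
#' @param B numeric matrix, sensors x trials of (baseline-corrected,
#'   time-averaged) sensor amplitudes.
#' @param directions numeric vector, length `ncol(B)`, presented direction in
#'   degrees for each training trial.
#' @param basis a [direction_basis()]; defaults to the standard 21-channel
#'   basis over \[−45, 135) degrees.
#' @param fit_mode `"per_channel"` (default): each weight-matrix row from a
#'   simple regression of the sensors on that channel's predicted amplitudes;
#'   `"joint"`: multivariate normal equations over all channels at once.
#' @param shrinkage `"analytic"` (default) for the Ledoit-Wolf optimal
#'   shrinkage intensity estimated from the residuals, `"none"` for the raw
#'   sample covariance (pseudo-inverted if singular), or a number in \[0, 1\]
#'   to force a fixed intensity.
#' @param residual `"own_channel"` (default): the noise for channel `i` is
#'   the data minus that channel's own rank-one prediction; `"all_channels"`:
#'   minus the full model prediction `W C`.
#' @return An object of class `"iem"`: list with `W`, `V`, `lambda` (per
#'   channel), `nu` (shrinkage target scale per channel), `basis`,
#'   `fit_mode`, `shrinkage`, `residual`, `n_trials`, `b_mean`/`c_mean`
#'   (training means, retained for diagnostics).
#' @examples
#' b <- direction_basis(n_channels = 8)
#' set.seed(1)
#' W <- matrix(rnorm(16 * 8), 16, 8)
#' th <- rep(seq(-45, 135, by = 20), 3)[1:24]
#' B <- W %*% channel_amplitudes(b, th) + matrix(rnorm(16 * 24, sd = 0.1), 16)
#' m <- iem(B, th, basis = b)
#' m
#' head(predict(m, B))
#' @export
iem <- function(B, directions, basis = direction_basis(),
                fit_mode = c("per_channel", "joint"),
                shrinkage = "analytic",
                residual = c("own_channel", "all_channels")) {
  fit_mode <- match.arg(fit_mode)
  residual <- match.arg(residual)
  B <- as.matrix(B)
  if (ncol(B) != length(directions))
    stop("B has ", ncol(B), " trials but 'directions' has length ",
         length(directions))
  C <- channel_amplitudes(basis, directions)
  dm <- demean_training(B, C)
  W <- fit_weights(dm$B0, dm$C0, fit_mode = fit_mode)
  covs <- iem_noise_with_residuals(dm$B0, dm$C0, W, residual)
  sh <- lapply(covs, shrink_covariance, shrinkage = shrinkage)
  V <- build_filters(W, sh)
  structure(
    list(W = W, V = V,
         lambda = vapply(sh, `[[`, numeric(1), "lambda"),
         nu = vapply(sh, `[[`, numeric(1), "nu"),
         basis = basis, fit_mode = fit_mode,
         shrinkage = shrinkage, residual = residual,
         n_trials = ncol(B), b_mean = dm$b_mean, c_mean = dm$c_mean),
    class = "iem")
}

#' Remove trial means from training matrices
#'
#' Centers the sensor matrix and the channel design matrix so every row has
#' zero mean over trials; the removed means are returned for diagnostics and
#' for consistent application to test data.
#'
#' @param B sensors x trials matrix.
#' @param C channels x trials matrix.
#' @return list with `B0`, `C0` (demeaned) and `b_mean`, `c_mean`.
#' @export
demean_training <- function(B, C) {
  if (ncol(B) < 2L) stop("need at least 2 trials to demean")
  b_mean <- rowMeans(B)
  c_mean <- rowMeans(C)
  list(B0 = B - b_mean, C0 = C - c_mean, b_mean = b_mean, c_mean = c_mean)
}

#' Least-squares estimation of the forward weight matrix
#'
#' @param B0 demeaned sensors x trials matrix.
#' @param C0 demeaned channels x trials matrix.
#' @param fit_mode `"per_channel"`: row `i` of the (transposed) weight matrix
#'   is the simple regression slope of each sensor on channel `i`'s predicted
#'   amplitudes, `w_i = B0 c_i' / (c_i c_i')`; `"joint"`: the multivariate
#'   normal equations `W = B0 C0' (C0 C0')^-1`.
#' @return sensors x channels weight matrix.
#' @export
fit_weights <- function(B0, C0, fit_mode = c("per_channel", "joint")) {
  fit_mode <- match.arg(fit_mode)
  if (ncol(B0) != ncol(C0)) stop("B0 and C0 must have the same trial count")
  if (ncol(C0) < nrow(C0)) stop("need at least as many trials as channels")
  ss <- rowSums(C0^2)
  bad <- which(ss <= .Machine$double.eps * ncol(C0))
  if (length(bad))
    stop("channel(s) with no amplitude variance across trials: ",
         paste(bad, collapse = ", "))
  W <- if (fit_mode == "per_channel") {
    sweep(B0 %*% t(C0), 2, ss, "/")
  } else {
    B0 %*% t(C0) %*% solve(C0 %*% t(C0))
  }
  dimnames(W) <- list(rownames(B0), rownames(C0))
  W
}

#' Per-channel noise covariance of the sensors
#'
#' For each channel the signal carried by that channel is removed from the
#' (demeaned) training data and the sample covariance of the residual is
#' taken as that channel's noise covariance.
#'
#' @param B0,C0 demeaned training matrices (see [demean_training()]).
#' @param W sensors x channels weight matrix.
#' @param residual `"own_channel"` removes only channel `i`'s rank-one
#'   prediction `w_i c_i`; `"all_channels"` removes the full prediction
#'   `W C0`.
#' @return list (length channels) of sensors x sensors covariance matrices,
#'   normalized by `n_trials - 1`.
#' @export
estimate_noise_cov <- function(B0, C0, W,
                               residual = c("own_channel", "all_channels")) {
  residual <- match.arg(residual)
  n <- ncol(B0)
  if (n < 2L) stop("need at least 2 trials to estimate noise covariance")
  k <- nrow(C0)
  full <- if (residual == "all_channels") B0 - W %*% C0 else NULL
  lapply(seq_len(k), function(i) {
    E <- if (residual == "own_channel")
      B0 - W[, i, drop = FALSE] %*% C0[i, , drop = FALSE]
    else full
    S <- E %*% t(E) / (n - 1)
    (S + t(S)) / 2  # enforce exact symmetry
  })
}

# Ledoit-Wolf optimal shrinkage intensity toward nu*I for a sensors x n
# residual matrix E (rows already centred). Standard analytic estimator:
# lambda* = sum_n ||x_n x_n' - S||_F^2 / n^2  /  ||S - nu I||_F^2, clipped
# to [0, 1].
lw_lambda <- function(E, S, nu) {
  n <- ncol(E)
  p <- nrow(E)
  # b2 = (1/n^2) * sum_n || x_n x_n' - S ||_F^2
  #    = (1/n) * mean_n ||x_n||^4 - (1/n) * ||S||_F^2   (with S = XX'/n)
  Sn <- E %*% t(E) / n
  d2 <- sum((Sn - diag(nu, p))^2)
  if (d2 <= 0) return(0)
  b2 <- sum(colSums(E^2)^2) / n^2 - sum(Sn^2) / n
  max(0, min(1, b2 / d2))
}

#' Shrink a sample covariance toward a scaled identity
#'
#' Blends the sample covariance with `nu * I`, where `nu` is the mean sensor
#' variance, using the analytically optimal (Ledoit-Wolf) intensity estimated
#' from the residual sample. Guarantees an invertible matrix whenever the
#' residuals are not identically zero, including the trial-starved regime
#' where the raw covariance is singular.
#'
#' @param cov_or_resid either a plain covariance matrix (analytic shrinkage
#'   then needs the residuals; pass a fixed numeric `shrinkage` instead), or
#'   a list with elements `S` (covariance) and `E` (the centred residual
#'   matrix it came from) from which the analytic intensity is computed.
#' @param shrinkage `"analytic"`, `"none"`, or a number in \[0, 1\].
#' @return list with `Sigma` (the regularized covariance), `lambda`, `nu`.
#' @export
shrink_covariance <- function(cov_or_resid, shrinkage = "analytic") {
  if (is.list(cov_or_resid)) {
    S <- cov_or_resid$S; E <- cov_or_resid$E
  } else {
    S <- cov_or_resid; E <- attr(cov_or_resid, "residuals")
  }
  p <- nrow(S)
  nu <- sum(diag(S)) / p
  if (identical(shrinkage, "none")) {
    return(list(Sigma = S, lambda = 0, nu = nu))
  }
  if (is.numeric(shrinkage)) {
    lam <- shrinkage
    if (lam < 0 || lam > 1) stop("fixed shrinkage intensity must be in [0, 1]")
  } else if (identical(shrinkage, "analytic")) {
    if (nu <= 0) stop("degenerate covariance: residuals are identically zero")
    if (is.null(E))
      stop("analytic shrinkage needs the residual sample; ",
           "pass list(S = , E = ) or a fixed numeric intensity")
    lam <- lw_lambda(E, S, nu)
  } else stop("unknown shrinkage mode: ", shrinkage)
  Sigma <- (1 - lam) * S + lam * nu * diag(p)
  list(Sigma = Sigma, lambda = lam, nu = nu)
}

#' Build normalized noise-covariance-aware spatial filters
#'
#' Each channel's filter is `v_i = Sigma_i*^-1 w_i`, rescaled so that applied
#' to its own channel pattern it returns unit gain (`v_i' w_i = 1`): the
#' filter output is on the scale of the channel activity it recovers.
#'
#' @param W sensors x channels weight matrix.
#' @param shrunk list (per channel) as returned by [shrink_covariance()], or
#'   plain covariance matrices (taken as already regularized; singular ones
#'   are pseudo-inverted).
#' @return sensors x channels decoding matrix `V`.
#' @export
build_filters <- function(W, shrunk) {
  k <- ncol(W)
  if (length(shrunk) != k)
    stop("need one covariance per channel (", k, "), got ", length(shrunk))
  V <- matrix(0, nrow(W), k, dimnames = dimnames(W))
  for (i in seq_len(k)) {
    Sig <- if (is.list(shrunk[[i]])) shrunk[[i]]$Sigma else shrunk[[i]]
    v <- tryCatch(solve(Sig, W[, i]),
                  error = function(e) MASS::ginv(Sig) %*% W[, i])
    g <- sum(v * W[, i])
    if (abs(g) < .Machine$double.eps)
      stop("filter for channel ", i, " has zero gain on its own pattern")
    V[, i] <- v / g
  }
  V
}

#' Estimate channel responses from sensor data
#'
#' @param V sensors x channels decoding matrix.
#' @param B_test sensors x trials matrix of test data.
#' @return channels x trials matrix of estimated channel responses
#'   (`V' B_test`).
#' @export
decode_channels <- function(V, B_test) {
  B_test <- as.matrix(B_test)
  if (nrow(V) != nrow(B_test))
    stop("sensor mismatch: filters have ", nrow(V), " sensors, data has ",
         nrow(B_test))
  t(V) %*% B_test
}

#' Read out a decoded direction from channel responses
#'
#' Forms, for each trial, the weighted sum of the basis tuning curves with
#' the estimated channel responses as weights, evaluates it on a dense grid
#' over the design span, and returns the direction of the maximum. Ties are
#' broken toward the smallest angle. A trial whose curve is entirely flat
#' (all-zero estimates) is returned as the span midpoint and flagged.
#'
#' @param est channels x trials matrix of channel-response estimates.
#' @param basis the [direction_basis()] the estimates refer to.
#' @return numeric vector of decoded directions (degrees), one per trial,
#'   with attribute `"degenerate"`: logical vector marking flat-curve trials.
#' @export
readout_direction <- function(est, basis) {
  est <- as.matrix(est)
  if (any(!is.finite(est))) stop("channel estimates must be finite")
  grid <- seq(basis$span[1], basis$span[2] - basis$grid_step,
              by = basis$grid_step)
  Fg <- basis_matrix(basis, grid)           # channels x grid
  curves <- crossprod(Fg, est)              # grid x trials
  idx <- max.col(t(curves), ties.method = "first")
  out <- grid[idx]
  # a flat curve can only arise from an all-zero estimate vector
  degen <- colSums(abs(est)) == 0
  if (any(degen)) {
    warning(sum(degen), " trial(s) produced a flat readout curve; ",
            "returning the span midpoint")
    out[degen] <- mean(basis$span)
  }
  attr(out, "degenerate") <- degen
  out
}

# ---- iem internals that need residuals for analytic shrinkage ------------
# iem() passes covariance + residuals together; estimate_noise_cov() keeps
# the public matrix-only contract, so the pairing happens here.

iem_noise_with_residuals <- function(B0, C0, W, residual) {
  n <- ncol(B0)
  full <- if (residual == "all_channels") B0 - W %*% C0 else NULL
  lapply(seq_len(ncol(W)), function(i) {
    E <- if (residual == "own_channel")
      B0 - W[, i, drop = FALSE] %*% C0[i, , drop = FALSE]
    else full
    S <- E %*% t(E) / (n - 1)
    list(S = (S + t(S)) / 2, E = E)
  })
}

#' @export
print.iem <- function(x, ...) {
  cat(sprintf("Inverted encoding model: %d sensors, %d channels\n",
              nrow(x$W), ncol(x$W)))
  cat(sprintf("  trained on %d trials; fit mode \"%s\"\n",
              x$n_trials, x$fit_mode))
  cat(sprintf("  shrinkage \"%s\": lambda in [%.3f, %.3f]\n",
              if (is.numeric(x$shrinkage)) "fixed" else x$shrinkage,
              min(x$lambda), max(x$lambda)))
  invisible(x)
}

#' @export
summary.iem <- function(object, ...) {
  out <- list(
    n_sensors = nrow(object$W), n_channels = ncol(object$W),
    n_trials = object$n_trials, fit_mode = object$fit_mode,
    lambda = object$lambda, nu = object$nu,
    filter_gain = colSums(object$V * object$W))
  class(out) <- "summary.iem"
  out
}

#' @export
print.summary.iem <- function(x, ...) {
  cat(sprintf("IEM fit: %d sensors x %d channels, %d training trials\n",
              x$n_sensors, x$n_channels, x$n_trials))
  cat("  shrinkage intensity per channel:\n")
  print(round(x$lambda, 4))
  cat("  filter gain on own pattern (should be 1):\n")
  print(round(x$filter_gain, 6))
  invisible(x)
}

#' @export
coef.iem <- function(object, which = c("weights", "filters"), ...) {
  which <- match.arg(which)
  if (which == "weights") object$W else object$V
}

#' Decode directions (or channel responses) from new sensor data
#'
#' Applies the fitted spatial filters to test data. The training sensor
#' means are subtracted first, mirroring the demeaning applied during
#' training.
#'
#' @param object a fitted [iem()] model.
#' @param newdata sensors x trials matrix.
#' @param type `"direction"` (default) for the decoded direction per trial;
#'   `"channels"` for the raw channels x trials response estimates.
#' @param demean subtract the stored training sensor means (default TRUE).
#' @param ... unused.
#' @return numeric vector of directions, or a channels x trials matrix.
#' @export
predict.iem <- function(object, newdata, type = c("direction", "channels"),
                        demean = TRUE, ...) {
  type <- match.arg(type)
  B <- as.matrix(newdata)
  if (demean) B <- B - object$b_mean
  est <- decode_channels(object$V, B)
  if (type == "channels") return(est)
  readout_direction(est, object$basis)
}
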