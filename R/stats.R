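#' Fisher r-to-Z transform
#'
#' Variance-stabilizing transform `z = atanh(r)` applied to correlation
#' coefficients before group-level testing.
#'
#' @param r correlations, `|r| < 1`.
#' @return transformed values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE))
    stop("fisher_z is defined for |r| < 1")
  atanh(r)
}

#' Behavioral quality control for one participant
#'
#' Correlates the presented directions with the mean reported direction per
#' presented direction; participants below `r = 0.9` are flagged as failing
#' (the exclusion rule applied before any group analysis).
#'
#' @param trials trial table with main-task rows carrying `reported_dir`.
#' @param r_min pass threshold (default 0.9).
#' @return list with `qc_r`, `pass`, `n_missing` (reports dropped as NA) and
#'   `degenerate` (TRUE when the correlation is undefined).
#' @export
participant_qc <- function(trials, r_min = 0.9) {
  rows <- trials[trials$task == "main", ]
  ok <- !is.na(rows$reported_dir)
  n_missing <- sum(!ok)
  rows <- rows[ok, ]
  dirs <- sort(unique(rows$presented_dir))
  if (length(dirs) < 3L)
    stop("QC needs at least 3 distinct presented directions with reports")
  means <- vapply(dirs, function(d)
    mean(rows$reported_dir[rows$presented_dir == d]), numeric(1))
  if (stats::sd(means) == 0)
    return(list(qc_r = NA_real_, pass = FALSE, n_missing = n_missing,
                degenerate = TRUE))
  r <- stats::cor(dirs, means)
  list(qc_r = r, pass = r >= r_min, n_missing = n_missing,
       degenerate = FALSE)
}

#' Cue-induced perceptual bias
#'
#' The mean reported direction when 63 degrees was cued minus the mean when
#' 27 degrees was cued, for physically matched stimuli: reports are first
#' averaged per (presented x cued) cell and the cells are weighted equally
#' within each cue level, so the comparison balances the presented
#' direction (the cued direction is 60% likely, so raw trial means would
#' otherwise differ by part of the 36-degree cue separation even for
#' cue-blind observers). Positive values mean reports are attracted toward
#' the predicted directions.
#'
#' @param trials trial table with main-task reports.
#' @return bias in degrees.
#' @export
perceptual_bias <- function(trials) {
  rows <- trials[trials$task == "main" & !is.na(trials$reported_dir), ]
  if (!any(rows$cue == "cue63") || !any(rows$cue == "cue27"))
    stop("both cue conditions need at least one reported trial")
  dirs <- intersect(unique(rows$presented_dir[rows$cue == "cue63"]),
                    unique(rows$presented_dir[rows$cue == "cue27"]))
  if (!length(dirs))
    stop("no presented direction occurs under both cue conditions")
  cell <- function(d, cc)
    mean(rows$reported_dir[rows$presented_dir == d & rows$cue == cc])
  mean(vapply(dirs, cell, numeric(1), cc = "cue63")) -
    mean(vapply(dirs, cell, numeric(1), cc = "cue27"))
}

#' Split participants by the sign of their perceptual bias
#'
#' @param biases named or unnamed numeric vector of per-participant biases.
#' @return list with `biased` (indices with bias > 0), `unbiased` (bias <=
#'   0; exact zeros land here by the documented tie rule), and `sizes`.
#' @export
split_by_bias <- function(biases) {
  if (any(biases == 0))
    message(sum(biases == 0), " participant(s) with bias exactly 0 ",
            "assigned to the unbiased group")
  biased <- which(biases > 0)
  unbiased <- which(biases <= 0)
  list(biased = biased, unbiased = unbiased,
       sizes = c(biased = length(biased), unbiased = length(unbiased)))
}

#' Cue effect on the decoded direction over time
#'
#' Averages the decoded direction per (presented x predicted) cell, averages
#' cells within each predicted level with equal weight (balancing the
#' presented direction across the two cue conditions), and subtracts the
#' 27-degrees-cued average from the 63-degrees-cued average at each time
#' step.
#'
#' @param decoded time x trials matrix of decoded directions.
#' @param trials aligned trial table (`cue`, `presented_dir`).
#' @return numeric vector of cue effects (degrees) per time step.
#' @export
cue_effect_timecourse <- function(decoded, trials) {
  if (ncol(decoded) != nrow(trials))
    stop("decoded matrix and trial table are not aligned")
  keep <- trials$cue %in% c("cue27", "cue63")
  trials <- trials[keep, , drop = FALSE]
  decoded <- decoded[, keep, drop = FALSE]
  dirs <- sort(unique(trials$presented_dir))
  cells <- expand.grid(dir = dirs, cue = c("cue27", "cue63"),
                       stringsAsFactors = FALSE)
  counts <- mapply(function(d, cc)
    sum(trials$presented_dir == d & trials$cue == cc),
    cells$dir, cells$cue)
  empty_dirs <- unique(cells$dir[counts == 0])
  if (length(empty_dirs)) {
    warning("presented direction(s) ", paste(empty_dirs, collapse = ", "),
            " missing in one cue condition; dropped from both levels")
    dirs <- setdiff(dirs, empty_dirs)
  }
  cell_mean <- function(d, cc) {
    sel <- trials$presented_dir == d & trials$cue == cc
    rowMeans(decoded[, sel, drop = FALSE])
  }
  lvl <- function(cc)
    rowMeans(matrix(vapply(dirs, cell_mean, numeric(nrow(decoded)),
                           cc = cc),
                    nrow = nrow(decoded)))
  unname(lvl("cue63") - lvl("cue27"))
}

# ---- cluster permutation internals ---------------------------------------

# contiguous supra-threshold runs of a t timecourse
find_clusters <- function(tvec, tcrit, tail) {
  mk <- function(mask, sign) {
    if (!any(mask)) return(NULL)
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(start = starts[keep], end = ends[keep],
               mass = vapply(which(keep), function(i)
                 sum(tvec[starts[i]:ends[i]]), numeric(1)),
               sign = sign)
  }
  out <- mk(tvec > tcrit, 1)
  if (tail == "two") out <- rbind(out, mk(tvec < -tcrit, -1))
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(),
                      mass = numeric(), sign = numeric())
  out[order(out$start), , drop = FALSE]
}

# max cluster mass per row of a permutation t matrix (n_perm x n_time),
# fully vectorized: flatten with a guard column so runs never cross rows.
row_max_cluster_mass <- function(Tm, tcrit, tail) {
  one_side <- function(M) {
    np <- nrow(M); nt <- ncol(M)
    G <- cbind(M, -Inf)                      # guard column
    flat <- as.vector(t(G))
    supra <- flat > tcrit
    out <- numeric(np)
    if (!any(supra)) return(out)
    idx <- which(supra)
    grp <- cumsum(c(1L, diff(idx) != 1L))
    sums <- rowsum(flat[idx], grp)
    grp_row <- ((idx[!duplicated(grp)] - 1L) %/% (nt + 1L)) + 1L
    best <- tapply(sums, grp_row, max)
    out[as.integer(names(best))] <- best
    out
  }
  pos <- one_side(Tm)
  if (tail == "one") pos else pmax(pos, one_side(-Tm))
}

# one-sample t per column for sign-flipped data, vectorized over flips
signflip_t <- function(X, flips) {
  n <- nrow(X)
  ss <- colSums(X^2)
  m <- flips %*% X / n                      # n_perm x n_time
  v <- sweep(-n * m^2, 2, ss, "+") / (n - 1)
  v[v < .Machine$double.eps] <- .Machine$double.eps
  m / sqrt(v / n)
}

#' One-sample cluster-based permutation test over time
#'
#' Tests, at every time step, whether the participant values differ from
#' zero, controlling for multiple comparisons across time by cluster mass:
#' pointwise one-sample t statistics are thresholded at the critical value
#' for `threshold_p` (one-tailed by default), contiguous supra-threshold
#' steps are collected into clusters scored by their summed t, and each
#' observed cluster mass is compared with the permutation distribution of
#' the maximal cluster mass under random participant-wise sign flips.
#'
#' @param values participants x time matrix.
#' @param times optional time stamps (ms) for reporting cluster bounds.
#' @param threshold_p cluster-forming pointwise threshold (default 0.05).
#' @param n_perm number of permutations (default 10000). When `n_perm`
#'   meets or exceeds the `2^participants` distinct sign patterns, the null
#'   is enumerated exhaustively instead.
#' @param tail `"one"` (default; positive effects) or `"two"`.
#' @param seed RNG seed for the permutation draws.
#' @return object of class `"cluster_result"`: data.frame `clusters`
#'   (`start`, `end` in ms — or indices when `times` is NULL — `mass`, `p`,
#'   `d`), plus `n_perm`, `threshold_p`, `tail`, `tcrit`, `null` (the
#'   permutation max-mass distribution).
#' @export
cluster_perm_one_sample <- function(values, times = NULL,
                                    threshold_p = 0.05, n_perm = 10000L,
                                    tail = c("one", "two"), seed = 1L) {
  tail <- match.arg(tail)
  X <- as.matrix(values)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 participants")
  tcrit <- stats::qt(1 - threshold_p, df = n - 1)
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[s < .Machine$double.eps] <- .Machine$double.eps
  tobs <- m / (s / sqrt(n))
  cl <- find_clusters(tobs, tcrit, tail)
  exhaustive <- 2^n <= n_perm
  if (exhaustive) {
    message("enumerating all ", 2^n, " sign patterns exhaustively")
    flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    n_eff <- nrow(flips)
  } else {
    set.seed(seed)
    flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    n_perm, n)
    n_eff <- n_perm
  }
  Tp <- signflip_t(X, flips)
  null <- row_max_cluster_mass(Tp, tcrit, tail)
  finish_cluster_result(cl, X, null, n_eff, threshold_p, tail, tcrit,
                        times, exhaustive)
}

#' Between-groups cluster-based permutation test over time
#'
#' As [cluster_perm_one_sample()], but the pointwise statistic is the
#' two-sample (pooled-variance) t between the two participant groups, and
#' the null is built by randomly reassigning participants to groups of the
#' observed sizes.
#'
#' @param groupA,groupB participants x time matrices on a common time axis.
#' @inheritParams cluster_perm_one_sample
#' @return a `"cluster_result"` (see [cluster_perm_one_sample()]).
#' @export
cluster_perm_between <- function(groupA, groupB, times = NULL,
                                 threshold_p = 0.05, n_perm = 10000L,
                                 tail = c("one", "two"), seed = 1L) {
  tail <- match.arg(tail)
  A <- as.matrix(groupA); B <- as.matrix(groupB)
  if (ncol(A) != ncol(B)) stop("groups must share the time axis")
  nA <- nrow(A); nB <- nrow(B)
  if (nA < 2L || nB < 2L) stop("both groups need at least 2 participants")
  X <- rbind(A, B)
  n <- nA + nB
  df <- n - 2
  tcrit <- stats::qt(1 - threshold_p, df = df)
  two_t <- function(idxA) {
    isA <- seq_len(n) %in% idxA
    mA <- colMeans(X[isA, , drop = FALSE])
    mB <- colMeans(X[!isA, , drop = FALSE])
    ssA <- colSums(sweep(X[isA, , drop = FALSE], 2, mA)^2)
    ssB <- colSums(sweep(X[!isA, , drop = FALSE], 2, mB)^2)
    sp2 <- (ssA + ssB) / df
    sp2[sp2 < .Machine$double.eps] <- .Machine$double.eps
    (mA - mB) / sqrt(sp2 * (1 / nA + 1 / nB))
  }
  tobs <- two_t(seq_len(nA))
  cl <- find_clusters(tobs, tcrit, tail)
  set.seed(seed)
  Tp <- matrix(0, n_perm, ncol(X))
  for (p in seq_len(n_perm))
    Tp[p, ] <- two_t(sample.int(n, nA))
  null <- row_max_cluster_mass(Tp, tcrit, tail)
  finish_cluster_result(cl, X, null, n_perm, threshold_p, tail, tcrit,
                        times, FALSE, between = list(nA = nA, nB = nB))
}

# attach p and d to clusters and wrap the result
finish_cluster_result <- function(cl, X, null, n_eff, threshold_p, tail,
                                  tcrit, times, exhaustive,
                                  between = NULL) {
  if (nrow(cl)) {
    cl$p <- vapply(seq_len(nrow(cl)), function(i) {
      obs <- if (tail == "one") cl$mass[i] else abs(cl$mass[i])
      (1 + sum(null >= obs)) / (1 + n_eff)
    }, numeric(1))
    cl$d <- vapply(seq_len(nrow(cl)), function(i) {
      win <- rowMeans(X[, cl$start[i]:cl$end[i], drop = FALSE])
      if (!is.null(between)) {
        a <- win[seq_len(between$nA)]
        b <- win[-seq_len(between$nA)]
        sp <- sqrt(((length(a) - 1) * stats::var(a) +
                    (length(b) - 1) * stats::var(b)) /
                   (length(a) + length(b) - 2))
        (mean(a) - mean(b)) / sp
      } else mean(win) / stats::sd(win)
    }, numeric(1))
  } else {
    cl$p <- numeric(0); cl$d <- numeric(0)
  }
  if (!is.null(times) && nrow(cl)) {
    cl$start_ms <- times[cl$start]
    cl$end_ms <- times[cl$end]
  }
  structure(list(clusters = cl, n_perm = n_eff,
                 threshold_p = threshold_p, tail = tail, tcrit = tcrit,
                 exhaustive = exhaustive, null = null),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "Cluster permutation test (%s-tailed threshold p = %g, %d permutations%s)\n",
    x$tail, x$threshold_p, x$n_perm,
    if (x$exhaustive) ", exhaustive" else ""))
  if (!nrow(x$clusters)) {
    cat("  no supra-threshold clusters\n")
  } else {
    print(x$clusters, row.names = FALSE)
  }
  invisible(x)
}

#' Significant clusters of a cluster_result
#'
#' @param x a `"cluster_result"`.
#' @param alpha significance level (default 0.05).
#' @return the rows of `x$clusters` with `p < alpha`.
#' @export
significant_clusters <- function(x, alpha = 0.05) {
  x$clusters[x$clusters$p < alpha, , drop = FALSE]
}

#' Trialwise partial correlation between decoded and reported direction
#'
#' Correlates the decoded direction with the reported direction across
#' trials after removing the presented direction from both — either as a
#' linear covariate (default) or by demeaning within presented-direction
#' levels.
#'
#' @param decoded per-trial decoded directions: a vector, or a time x
#'   trials matrix (one correlation per row).
#' @param reported per-trial reported directions.
#' @param presented per-trial presented directions (the controlled
#'   covariate).
#' @param covariate `"linear"` or `"categorical"`.
#' @return partial correlation(s); `NA` with a warning where a residual has
#'   zero variance.
#' @export
trial_partial_correlation <- function(decoded, reported, presented,
                                      covariate = c("linear",
                                                    "categorical")) {
  covariate <- match.arg(covariate)
  one <- function(x) {
    ok <- is.finite(x) & is.finite(reported) & is.finite(presented)
    if (sum(ok) < 4L)
      stop("partial correlation needs at least 4 complete trials")
    x <- x[ok]; y <- reported[ok]; z <- presented[ok]
    res <- function(v) {
      if (covariate == "linear") {
        stats::lm.fit(cbind(1, z), v)$residuals
      } else {
        v - stats::ave(v, z)
      }
    }
    rx <- res(x); ry <- res(y)
    if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12) {
      warning("zero residual variance; partial correlation undefined")
      return(NA_real_)
    }
    stats::cor(rx, ry)
  }
  if (is.matrix(decoded)) apply(decoded, 1, one) else one(decoded)
}
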