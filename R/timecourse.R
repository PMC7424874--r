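#' Leave-one-run-out time-resolved decoding of the localizer
#'
#' For each localizer run in turn, an inverted encoding model is trained on
#' all other runs independently at every window step and applied to the
#' held-out run at that same step. Decoded directions are returned in the
#' original trial order, so the trials axis stays aligned to the trial
#' table.
#'
#' @param ep a (baseline-corrected) [epochs()] object; pass it through
#'   [window_average()] first, or set `spec` to have it applied here.
#' @param trials trial table (data.frame) aligned to `ep`, with at least
#'   columns `run` and `presented_dir`.
#' @param basis a [direction_basis()].
#' @param spec optional [window_spec()]; when given, `ep` is window-averaged
#'   before decoding.
#' @param ... further arguments passed to [iem()] (`fit_mode`, `shrinkage`,
#'   `residual`).
#' @return numeric matrix, time x trials, of decoded directions; row names
#'   are the window-centre times in ms (also attribute `"times"`).
#' @export
crossval_localizer <- function(ep, trials, basis = direction_basis(),
                               spec = NULL, ...) {
  stopifnot(inherits(ep, "epochs"))
  if (!is.null(spec)) ep <- window_average(ep, spec)
  if (nrow(trials) != dim(ep$data)[1])
    stop("trial table (", nrow(trials), " rows) does not match epochs (",
         dim(ep$data)[1], " trials)")
  runs <- unique(trials$run)
  if (length(runs) < 2L) stop("leave-one-run-out needs at least 2 runs")
  nt <- length(ep$times)
  decoded <- matrix(NA_real_, nt, nrow(trials),
                    dimnames = list(signif(ep$times, 8), NULL))
  for (r in runs) {
    test <- which(trials$run == r)
    train <- which(trials$run != r)
    th_train <- trials$presented_dir[train]
    if (length(unique(trials$presented_dir[test])) <
        length(unique(trials$presented_dir)))
      warning("run ", r, " is missing some directions")
    for (j in seq_len(nt)) {
      B <- t(ep$data[, , j])                     # sensors x trials
      m <- iem(B[, train, drop = FALSE], th_train, basis = basis, ...)
      decoded[j, test] <- predict(m, B[, test, drop = FALSE])
    }
  }
  attr(decoded, "times") <- ep$times
  decoded
}

#' Localizer decoding performance over time
#'
#' Per time step, averages the decoded direction within each presented
#' direction and correlates those means with the presented directions.
#'
#' @param decoded time x trials matrix from [crossval_localizer()].
#' @param presented per-trial presented direction (degrees).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return numeric vector of correlations, one per time step, named by time.
#' @export
localizer_performance <- function(decoded, presented,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  dirs <- sort(unique(presented))
  if (length(dirs) < 3L)
    stop("correlation over presented directions needs at least 3 distinct ",
         "directions, got ", length(dirs))
  g <- match(presented, dirs)
  apply(decoded, 1, function(row) {
    means <- vapply(seq_along(dirs), function(i) mean(row[g == i]),
                    numeric(1))
    stats::cor(dirs, means, method = method)
  })
}

#' Select each participant's training peak within a group window
#'
#' Finds, per participant, the time of maximal decoding performance inside
#' the group-level window (by default the significant group cluster); the
#' final training set is that peak step plus its `neighbors` window steps on
#' either side.
#'
#' @param perf participants x time matrix of decoding performance (or a
#'   single participant's vector).
#' @param times window-centre times in ms, length `ncol(perf)`.
#' @param group_window length-2 ms interval to search (default `c(90, 110)`).
#' @param neighbors window steps added on each side of the peak (default 2,
#'   i.e. 5 training steps in total).
#' @return data.frame with `peak_ms`, `peak_index`, and a list-column
#'   `train_indices` of the selected window-step indices per participant.
#' @export
select_training_peak <- function(perf, times, group_window = c(90, 110),
                                 neighbors = 2L) {
  if (is.null(dim(perf))) perf <- matrix(perf, nrow = 1)
  sel <- which(times >= group_window[1] & times <= group_window[2])
  if (!length(sel))
    stop("group window [", group_window[1], ", ", group_window[2],
         "] ms lies outside the time axis")
  peak_idx <- sel[apply(perf[, sel, drop = FALSE], 1, which.max)]
  train <- lapply(peak_idx, function(i) {
    idx <- (i - neighbors):(i + neighbors)
    idx[idx >= 1 & idx <= length(times)]
  })
  data.frame(peak_ms = times[peak_idx], peak_index = peak_idx,
             train_indices = I(train))
}

#' Train the final decoder at the peak and decode the main task
#'
#' Trains one inverted encoding model per participant on the localizer data
#' pooled over the selected peak-window steps (each trial contributes one
#' observation per step; the pooled data are demeaned once), then applies it
#' at every window step of the main-task epochs.
#'
#' @param loc_ep window-averaged, baseline-corrected localizer [epochs()].
#' @param loc_trials localizer trial table (needs `presented_dir`).
#' @param train_indices integer vector of window-step indices of `loc_ep` to
#'   pool for training (from [select_training_peak()]).
#' @param main_ep window-averaged, baseline-corrected main-task [epochs()].
#' @param basis a [direction_basis()].
#' @param ... passed to [iem()].
#' @return list of class `"decoded_timecourse"`: `decoded` (time x trials
#'   matrix of directions), `times` (ms), `model` (the fitted [iem()]),
#'   `train_times` (ms of the pooled steps).
#' @export
decode_main <- function(loc_ep, loc_trials, train_indices, main_ep,
                        basis = direction_basis(), ...) {
  stopifnot(inherits(loc_ep, "epochs"), inherits(main_ep, "epochs"))
  if (dim(loc_ep$data)[2] != dim(main_ep$data)[2])
    stop("sensor count differs between localizer (", dim(loc_ep$data)[2],
         ") and main task (", dim(main_ep$data)[2], ")")
  # pool peak-window steps: sensors x (trials * steps)
  B <- do.call(cbind, lapply(train_indices, function(j) t(loc_ep$data[, , j])))
  th <- rep(loc_trials$presented_dir, times = length(train_indices))
  model <- iem(B, th, basis = basis, ...)
  nt <- length(main_ep$times)
  decoded <- matrix(NA_real_, nt, dim(main_ep$data)[1],
                    dimnames = list(signif(main_ep$times, 8), NULL))
  for (j in seq_len(nt))
    decoded[j, ] <- predict(model, t(main_ep$data[, , j]))
  structure(list(decoded = decoded, times = main_ep$times, model = model,
                 train_times = loc_ep$times[train_indices]),
            class = "decoded_timecourse")
}

#' @export
print.decoded_timecourse <- function(x, ...) {
  cat(sprintf("Decoded timecourse: %d time steps x %d trials\n",
              nrow(x$decoded), ncol(x$decoded)))
  cat(sprintf("  time %g to %g ms; trained on %s ms\n",
              x$times[1], x$times[length(x$times)],
              paste(signif(x$train_times, 4), collapse = ", ")))
  invisible(x)
}
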