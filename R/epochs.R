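#' Epoched multi-sensor data
#'
#' Container for trials x sensors x samples data with a uniform time axis in
#' milliseconds relative to stimulus onset. The trials axis aligns
#' one-to-one with a trial table (see [make_main_design()]).
#'
#' @param data numeric array, trials x sensors x samples.
#' @param times numeric vector of sample times in ms, length `dim(data)[3]`,
#'   uniformly spaced.
#' @param sampling_rate sampling rate in Hz.
#' @param sensor_ids character labels, length `dim(data)[2]`; defaults to
#'   `"S001"`, `"S002"`, ...
#' @return An object of class `"epochs"`.
#' @export
epochs <- function(data, times, sampling_rate, sensor_ids = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("data must be a 3-d array (trials x sensors x samples)")
  if (length(times) != dim(data)[3])
    stop("times length (", length(times), ") != sample count (",
         dim(data)[3], ")")
  if (length(times) > 1L) {
    dt <- diff(times)
    if (max(abs(dt - 1000 / sampling_rate)) > 1e-6)
      stop("times must be uniformly spaced at 1000/sampling_rate ms")
  }
  if (is.null(sensor_ids))
    sensor_ids <- sprintf("S%03d", seq_len(dim(data)[2]))
  if (length(sensor_ids) != dim(data)[2])
    stop("sensor_ids length mismatch")
  structure(list(data = data, times = as.numeric(times),
                 sampling_rate = sampling_rate,
                 sensor_ids = as.character(sensor_ids)),
            class = "epochs")
}

#' @export
print.epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epochs: %d trials x %d sensors x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sampling_rate))
  cat(sprintf("  time: %g to %g ms\n", x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' @export
dim.epochs <- function(x) dim(x$data)

#' Baseline-correct epochs
#'
#' Subtracts, per trial and sensor, the mean signal over a reference
#' interval. Idempotent: applying it twice equals applying it once.
#'
#' @param ep an [epochs()] object.
#' @param interval numeric length-2, ms; the baseline window (inclusive).
#' @return a baseline-corrected [epochs()] object.
#' @export
baseline_correct <- function(ep, interval = c(-250, 0)) {
  stopifnot(inherits(ep, "epochs"))
  sel <- ep$times >= interval[1] & ep$times <= interval[2]
  if (!any(sel))
    stop("baseline interval [", interval[1], ", ", interval[2],
         "] ms contains no samples")
  base <- apply(ep$data[, , sel, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - array(base, dim(ep$data))
  ep
}

#' Sliding-window specification
#'
#' Converts the window width and step from milliseconds to samples. The
#' width is rounded to the nearest sample count and decremented by one if
#' even, so windows always hold an odd number of samples and can be centred
#' symmetrically; at 600 Hz the default 28.3 ms width gives 17 samples and
#' the 5 ms step gives 3 samples.
#'
#' @param sampling_rate Hz.
#' @param step_ms window step in ms (default 5).
#' @param width_ms window width in ms (default 28.3).
#' @return list of class `"window_spec"` with `step_ms`, `width_ms`,
#'   `step_samples`, `width_samples`.
#' @export
window_spec <- function(sampling_rate, step_ms = 5, width_ms = 28.3) {
  ws <- round(width_ms * sampling_rate / 1000)
  adjusted <- FALSE
  if (ws %% 2 == 0) { ws <- ws - 1; adjusted <- TRUE }
  if (ws < 1) stop("window width is below one sample at this sampling rate")
  ss <- max(1L, round(step_ms * sampling_rate / 1000))
  if (adjusted)
    message("window width adjusted to ", ws,
            " samples for a symmetric (odd) window")
  structure(list(step_ms = step_ms, width_ms = width_ms,
                 step_samples = as.integer(ss),
                 width_samples = as.integer(ws)),
            class = "window_spec")
}

#' Sliding-window average of epochs
#'
#' Replaces the time axis by the centres of sliding windows and each value
#' by the mean over the corresponding window. Only windows fully inside the
#' epoch are kept.
#'
#' @param ep an [epochs()] object.
#' @param spec a [window_spec()]; defaults to the 5 ms / 28.3 ms windows at
#'   the epochs' own sampling rate.
#' @return an [epochs()]-like object (class `"epochs"`) whose time axis is
#'   the window centres, with attribute `"window"` carrying the spec. Note
#'   the output time axis is spaced at `step_ms`, not the raw sample
#'   interval.
#' @export
window_average <- function(ep, spec = window_spec(ep$sampling_rate)) {
  stopifnot(inherits(ep, "epochs"))
  ws <- spec$width_samples; ss <- spec$step_samples
  n <- dim(ep$data)[3]
  if (ws > n) stop("window (", ws, " samples) exceeds epoch length (", n, ")")
  half <- (ws - 1L) / 2L
  centers <- seq(1L + half, n - half, by = ss)
  d <- dim(ep$data)
  out <- array(0, c(d[1], d[2], length(centers)))
  for (k in seq_along(centers)) {
    idx <- (centers[k] - half):(centers[k] + half)
    out[, , k] <- rowMeans(ep$data[, , idx, drop = FALSE], dims = 2)
  }
  res <- structure(list(data = out, times = ep$times[centers],
                        sampling_rate = ep$sampling_rate,
                        sensor_ids = ep$sensor_ids),
                   class = "epochs")
  attr(res, "window") <- spec
  res
}
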