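#' Ground truth for a simulated participant
#'
#' Bundles the generative quantities behind one simulated participant's
#' recordings: a fixed sensors x channels gain matrix (the generative
#' counterpart of the encoding weights), a spatially correlated /
#' temporally white sensor-noise covariance, an evoked gain profile over
#' peristimulus time, an optional cue-locked "expectation template"
#' (re-activation of the predicted direction in the sensor data), and the
#' behavioral integration weight that mixes the cued direction into the
#' report.
#'
#' @param n_sensors sensor count (default 272; reduce for fast tests — all
#'   operations are dimension-generic, down to e.g. the 2 channels of a gaze
#'   recording).
#' @param sampling_rate Hz (default 600).
#' @param basis the [direction_basis()] the gain matrix refers to.
#' @param true_weights sensors x channels matrix; drawn standard-normal from
#'   `seed` when `NULL`.
#' @param noise_sd marginal sensor noise SD (arbitrary units, default 1).
#' @param noise_rho neighbour correlation of the AR(1)-structured spatial
#'   noise covariance `noise_sd^2 * noise_rho^|i-j|` (default 0.3).
#' @param noise_covariance explicit sensors x sensors positive-definite
#'   matrix; overrides `noise_sd`/`noise_rho`.
#' @param evoked_peak_ms,evoked_width_ms Gaussian evoked gain profile
#'   `g(t) = exp(-(t - peak)^2 / (2 width^2))` for `t > 0`, zero before
#'   stimulus onset (defaults 100 and 20 ms: an early visual response).
#' @param template `NULL` (no expectation signal) or a list with `amplitude`
#'   (unitless, on the scale of the evoked gain), `onset`, `offset` (ms);
#'   injected into main-task trials as the cued direction's sensor pattern.
#' @param cue_weight behavioral integration weight `w` in \[0, 1\]: reports
#'   are `(1 - w) * presented + w * cued` plus noise.
#' @param report_noise_sd SD of the Gaussian report noise in degrees.
#' @param seed integer; fixes the participant (weights and all draws).
#' @return object of class `"ground_truth"`.
#' @export
ground_truth <- function(n_sensors = 272L, sampling_rate = 600,
                         basis = direction_basis(),
                         true_weights = NULL,
                         noise_sd = 1, noise_rho = 0.3,
                         noise_covariance = NULL,
                         evoked_peak_ms = 100, evoked_width_ms = 20,
                         template = NULL,
                         cue_weight = 0, report_noise_sd = 5,
                         seed = 1L) {
  k <- length(basis$centers)
  if (is.null(true_weights)) {
    set.seed(seed)
    true_weights <- matrix(stats::rnorm(n_sensors * k), n_sensors, k)
  }
  if (is.null(noise_covariance)) {
    noise_covariance <-
      noise_sd^2 * noise_rho^abs(outer(seq_len(n_sensors),
                                       seq_len(n_sensors), "-"))
  }
  if (!isSymmetric(noise_covariance, tol = 1e-8))
    stop("noise covariance must be symmetric")
  ev <- eigen(noise_covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("noise covariance must be positive-definite")
  if (cue_weight < 0 || cue_weight > 1) stop("cue_weight must be in [0, 1]")
  if (report_noise_sd < 0) stop("report_noise_sd must be >= 0")
  if (!is.null(template)) {
    stopifnot(is.list(template),
              all(c("amplitude", "onset", "offset") %in% names(template)))
  }
  structure(
    list(n_sensors = as.integer(n_sensors), sampling_rate = sampling_rate,
         basis = basis, true_weights = true_weights,
         noise_covariance = noise_covariance,
         evoked_peak_ms = evoked_peak_ms, evoked_width_ms = evoked_width_ms,
         template = template, cue_weight = cue_weight,
         report_noise_sd = report_noise_sd, seed = as.integer(seed)),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d sensors @ %g Hz, %d channels, seed %d\n",
              x$n_sensors, x$sampling_rate, length(x$basis$centers), x$seed))
  cat(sprintf("  evoked peak %g ms (width %g ms); cue weight w = %g\n",
              x$evoked_peak_ms, x$evoked_width_ms, x$cue_weight))
  if (!is.null(x$template))
    cat(sprintf("  expectation template: amp %g over %g-%g ms\n",
                x$template$amplitude, x$template$onset, x$template$offset))
  invisible(x)
}

# evoked gain g(t): zero strictly before stimulus onset
evoked_gain <- function(gt, t_ms) {
  ifelse(t_ms > 0,
         exp(-(t_ms - gt$evoked_peak_ms)^2 / (2 * gt$evoked_width_ms^2)),
         0)
}

#' Cued direction implied by a cue label
#'
#' @param cue character vector with values `"cue27"`, `"cue63"` or `"none"`.
#' @return numeric vector: 27, 63, or `NA` for `"none"`.
#' @export
cued_direction <- function(cue) {
  out <- rep(NA_real_, length(cue))
  out[cue == "cue27"] <- 27
  out[cue == "cue63"] <- 63
  out
}

#' Main-task trial design
#'
#' Generates the cued motion-direction design: each run holds equally many
#' trials of the two auditory cues in pseudo-random order; given the cue,
#' the presented direction is the cued one with probability 0.6 and each of
#' the four other directions (of 9, 27, 45, 63, 81 degrees) with
#' probability 0.1. Over the experiment, 27 and 63 degrees therefore occur
#' more often than the other directions.
#'
#' @param n_runs number of runs (paper-scale sessions use 5-7).
#' @param trials_per_run trials per run, even (default 60).
#' @param seed integer RNG seed; the design is a pure function of it.
#' @return data.frame (trial table) with columns `trial_id`, `run`, `task`,
#'   `cue`, `presented_dir`, `reported_dir` (NA until
#'   [simulate_behavior()]), `coherence`.
#' @export
make_main_design <- function(n_runs, trials_per_run = 60L, seed = 1L) {
  if (n_runs < 1L) stop("n_runs must be >= 1")
  if (trials_per_run %% 2L != 0L)
    stop("trials_per_run must be even so the two cues can be balanced")
  set.seed(seed)
  dirs <- c(9, 27, 45, 63, 81)
  runs <- lapply(seq_len(n_runs), function(r) {
    cue <- sample(rep(c("cue27", "cue63"), trials_per_run / 2L))
    presented <- vapply(cue, function(cc) {
      cued <- if (cc == "cue27") 27 else 63
      p <- ifelse(dirs == cued, 0.6, 0.1)
      sample(dirs, 1L, prob = p)
    }, numeric(1))
    data.frame(run = sprintf("main%02d", r), task = "main", cue = cue,
               presented_dir = presented, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  data.frame(trial_id = seq_len(nrow(out)), out,
             reported_dir = NA_real_, coherence = 0.2,
             stringsAsFactors = FALSE)
}

#' Localizer trial design
#'
#' Each localizer block presents the 11 training directions (−45 to 135
#' degrees in 18-degree steps) equally often — 8 repetitions each, 88 trials
#' per block — in pseudo-random order, at full coherence and with no cue.
#'
#' @param n_blocks number of localizer blocks (each its own run).
#' @param seed integer RNG seed.
#' @return trial table data.frame as in [make_main_design()], with
#'   `task = "localizer"`, `cue = "none"`, `coherence = 1`.
#' @export
make_localizer_design <- function(n_blocks, seed = 1L) {
  if (n_blocks < 1L) stop("n_blocks must be >= 1")
  set.seed(seed)
  dirs <- c(-45, -27, -9, 9, 27, 45, 63, 81, 99, 117, 135)
  runs <- lapply(seq_len(n_blocks), function(b) {
    presented <- sample(rep(dirs, 8L))
    data.frame(run = sprintf("loc%02d", b), task = "localizer",
               cue = "none", presented_dir = presented,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  data.frame(trial_id = seq_len(nrow(out)), out,
             reported_dir = NA_real_, coherence = 1,
             stringsAsFactors = FALSE)
}

#' Simulate epoched sensor data for a design
#'
#' Generates `data[trial, sensor, t] = (W_true c(theta_trial))_sensor g(t)`
#' plus, on cued main-task trials inside the template window, the cued
#' direction's sensor pattern scaled by the template amplitude, plus sensor
#' noise that is correlated across sensors (by the ground-truth covariance)
#' and white across samples.
#'
#' @param design trial table from [make_main_design()] /
#'   [make_localizer_design()].
#' @param gt a [ground_truth()].
#' @param t_range length-2 ms interval covered by the epochs; must contain
#'   stimulus onset (0 ms).
#' @param noise_scale multiplier on the noise draw (0 gives noise-free
#'   epochs; default 1).
#' @param seed RNG seed; defaults to the participant seed in `gt`.
#' @return an [epochs()] object, trials aligned to `design`.
#' @export
simulate_epochs <- function(design, gt, t_range = c(-300, 500),
                            noise_scale = 1, seed = gt$seed) {
  stopifnot(inherits(gt, "ground_truth"))
  if (nrow(design) == 0L) stop("design is empty")
  if (t_range[1] > 0 || t_range[2] < 0)
    stop("t_range must contain stimulus onset (0 ms)")
  dt <- 1000 / gt$sampling_rate
  times <- seq(ceiling(t_range[1] / dt), floor(t_range[2] / dt)) * dt
  ns <- gt$n_sensors; ntr <- nrow(design); nsmp <- length(times)
  g <- evoked_gain(gt, times)
  S <- gt$true_weights %*% channel_amplitudes(gt$basis, design$presented_dir)
  # template: cued-direction pattern on cued trials, inside [onset, offset]
  Tm <- NULL; box <- NULL
  if (!is.null(gt$template)) {
    cued <- cued_direction(design$cue)
    has <- design$task == "main" & !is.na(cued)
    Tm <- matrix(0, ns, ntr)
    if (any(has))
      Tm[, has] <- gt$template$amplitude *
        (gt$true_weights %*% channel_amplitudes(gt$basis, cued[has]))
    box <- as.numeric(times >= gt$template$onset & times <= gt$template$offset)
  }
  set.seed(seed)
  data <- array(0, c(ntr, ns, nsmp))
  if (noise_scale > 0) {
    L <- t(chol(gt$noise_covariance))
    Z <- matrix(stats::rnorm(ns * ntr * nsmp), ns)
    data <- aperm(array(noise_scale * (L %*% Z), c(ns, ntr, nsmp)),
                  c(2, 1, 3))
  }
  for (j in seq_len(nsmp)) {
    sig <- S * g[j]
    if (!is.null(Tm) && box[j] > 0) sig <- sig + Tm
    data[, , j] <- data[, , j] + t(sig)
  }
  epochs(data, times, gt$sampling_rate)
}

#' Simulate behavioral reports for a design
#'
#' Fills in `reported_dir` on main-task trials as the weighted average of
#' the presented and cued directions, `(1 - w) presented + w cued`, plus
#' Gaussian report noise. The directions at play (9-81 degrees) sit far from
#' the circular wrap, so the mix is taken on the line.
#'
#' @param design trial table.
#' @param gt a [ground_truth()] (provides `cue_weight` and
#'   `report_noise_sd`).
#' @param seed RNG seed; defaults to the participant seed plus one (so
#'   reports are not coupled to the sensor noise draw).
#' @return the trial table with `reported_dir` filled on main-task rows.
#' @export
simulate_behavior <- function(design, gt, seed = gt$seed + 1L) {
  stopifnot(inherits(gt, "ground_truth"))
  set.seed(seed)
  main <- which(design$task == "main")
  cued <- cued_direction(design$cue[main])
  w <- gt$cue_weight
  design$reported_dir[main] <-
    (1 - w) * design$presented_dir[main] + w * cued +
    stats::rnorm(length(main), sd = gt$report_noise_sd)
  design
}
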