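#' Simulate one participant and run the full decoding pipeline
#'
#' Convenience driver tying the stages together for a single simulated
#' participant: generate localizer and main-task designs and epochs,
#' baseline-correct and window-average them, leave-one-run-out decode the
#' localizer around the group peak window, select the individual training
#' peak, train the final model on the peak window steps, decode the main
#' task at every window step, and compute the behavioral and neural
#' summaries.
#'
#' The defaults describe a desk-scale participant (16 sensors at 200 Hz,
#' two localizer blocks, two main-task runs) whose statistical structure
#' matches the full-size experiment; sensor count, sampling rate and run
#' counts scale up freely.
#'
#' @param seed integer; fixes the participant entirely.
#' @param n_sensors,sampling_rate,noise_sd passed to [ground_truth()].
#' @param template_amplitude amplitude of the cue-locked expectation
#'   template (0 disables it).
#' @param template_window length-2 ms interval of the template.
#' @param cue_weight,report_noise_sd behavioral parameters, see
#'   [ground_truth()].
#' @param loc_blocks,main_runs,trials_per_run design sizes.
#' @param grid_step readout grid resolution in degrees.
#' @param loc_t_range,main_t_range epoch intervals (ms).
#' @param peak_window group-level window searched for the individual
#'   decoding peak (default `c(90, 110)` ms).
#' @return list with `times` (main-task window centres, ms), `decoded`
#'   (time x trials), `trials` (main trial table with reports),
#'   `cue_effect` (deg per time step), `bias` (deg), `qc_r`, `peak_ms`,
#'   `peak_r` (localizer performance at the selected peak) and `model`
#'   (the final [iem()] fit).
#' @examples
#' \donttest{
#' pp <- simulate_and_decode(seed = 1, template_amplitude = 0.09)
#' pp$bias
#' max(pp$cue_effect)
#' }
#' @export
simulate_and_decode <- function(seed,
                                n_sensors = 16L, sampling_rate = 200,
                                noise_sd = 1.5,
                                template_amplitude = 0,
                                template_window = c(135, 180),
                                cue_weight = 0, report_noise_sd = 5,
                                loc_blocks = 2L, main_runs = 2L,
                                trials_per_run = 60L,
                                grid_step = 0.5,
                                loc_t_range = c(-200, 300),
                                main_t_range = c(-300, 500),
                                peak_window = c(90, 110)) {
  basis <- direction_basis(grid_step = grid_step)
  template <- if (template_amplitude > 0)
    list(amplitude = template_amplitude,
         onset = template_window[1], offset = template_window[2])
  gt <- ground_truth(n_sensors = n_sensors, sampling_rate = sampling_rate,
                     basis = basis, noise_sd = noise_sd,
                     template = template, cue_weight = cue_weight,
                     report_noise_sd = report_noise_sd, seed = seed)
  loc <- make_localizer_design(loc_blocks, seed = seed)
  main <- make_main_design(main_runs, trials_per_run, seed = seed + 1000L)
  main <- simulate_behavior(main, gt, seed = seed * 7L + 2L)
  loc_ep <- baseline_correct(
    simulate_epochs(loc, gt, loc_t_range, seed = seed * 7L),
    c(loc_t_range[1], 0))
  main_ep <- baseline_correct(
    simulate_epochs(main, gt, main_t_range, seed = seed * 7L + 1L),
    c(-250, 0))
  spec <- suppressMessages(window_spec(sampling_rate))
  locw <- window_average(loc_ep, spec)
  mainw <- window_average(main_ep, spec)
  # decode the localizer only around the group peak window (plus margin for
  # the training neighbours): peak selection never looks elsewhere
  margin <- 2 * spec$step_ms
  sel <- which(locw$times >= peak_window[1] - margin &
               locw$times <= peak_window[2] + margin)
  locp <- locw
  locp$data <- locw$data[, , sel, drop = FALSE]
  locp$times <- locw$times[sel]
  dec_loc <- crossval_localizer(locp, loc, basis = basis)
  perf <- localizer_performance(dec_loc, loc$presented_dir)
  pk <- select_training_peak(perf, locp$times, peak_window)
  dtc <- decode_main(locw, loc, sel[pk$train_indices[[1]]], mainw,
                     basis = basis)
  qc <- participant_qc(main)
  list(times = dtc$times, decoded = dtc$decoded, trials = main,
       cue_effect = cue_effect_timecourse(dtc$decoded, main),
       bias = perceptual_bias(main), qc_r = qc$qc_r,
       peak_ms = pk$peak_ms[1], peak_r = unname(perf[pk$peak_index[1]]),
       model = dtc$model)
}
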