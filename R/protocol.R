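#' Measurement protocol layout
#'
#' Describes the phase/frame structure of a bilateral perfusion recording
#' session: repeated measurement phases at 30-minute intervals (three before
#' and four after the intervention window), each contributing a fixed number
#' of image frames, with an optional set of phases excluded from analysis.
#' The default is the standard protocol: 7 phases of 10 frames each
#' (70 samples per side), with the phase recorded immediately after the
#' intervention (`post-0`) excluded, leaving 60 retained samples per subject.
#'
#' @param phases Character vector of ordered phase labels.
#' @param frames_per_phase Number of image frames per phase.
#' @param excluded_phases Phases dropped from analysis. Must be a subset of
#'   `phases`. `character(0)` retains everything.
#' @return An object of class `protocol_layout`.
#' @examples
#' lay <- protocol_layout()
#' lay$n_total    # 70
#' lay$n_retained # 60
#' @export
protocol_layout <- function(phases = c("pre-60", "pre-30", "pre-0",
                                       "post-0", "post-30", "post-60", "post-90"),
                            frames_per_phase = 10,
                            excluded_phases = "post-0") {
  phases <- as.character(phases)
  if (anyDuplicated(phases))
    stop_config("protocol phases must be unique labels")
  frames_per_phase <- as.integer(frames_per_phase)
  if (length(frames_per_phase) != 1L || is.na(frames_per_phase) || frames_per_phase < 1L)
    stop_config("frames_per_phase must be a single positive integer")
  excluded_phases <- as.character(excluded_phases)
  if (!all(excluded_phases %in% phases))
    stop_config(sprintf("excluded phase(s) not declared in the layout: %s",
                        paste(setdiff(excluded_phases, phases), collapse = ", ")))
  structure(
    list(phases = phases,
         frames_per_phase = frames_per_phase,
         excluded_phases = excluded_phases,
         n_total = length(phases) * frames_per_phase,
         n_retained = (length(phases) - length(excluded_phases)) * frames_per_phase),
    class = "protocol_layout")
}

#' @export
print.protocol_layout <- function(x, ...) {
  cat("Protocol layout:", length(x$phases), "phases x", x$frames_per_phase, "frames\n")
  cat("  phases:  ", paste(x$phases, collapse = ", "), "\n")
  cat("  excluded:", if (length(x$excluded_phases)) paste(x$excluded_phases, collapse = ", ")
      else "(none)", "\n")
  cat("  samples per side:", x$n_total, "recorded,", x$n_retained, "retained\n")
  invisible(x)
}

#' Ground-truth coupling model for synthetic bilateral perfusion data
#'
#' Parameterises the generating process used by [simulate_subject()] and
#' [simulate_group()]. One side (the driving side) follows a mean-reverting
#' positive AR(1) around `baseline_PU`; the contralateral side responds
#' through the fractional-power coupling
#' \deqn{out(k) = a\,out(k-1) + b\,out(k-1)^{0.3} + g_k\{c\,in(k) + d\,in(k)^{0.3}\} + \epsilon(k)}
#' where the cross-side gain multiplier \eqn{g_k} equals 1 before the
#' intervention onset and `intervention_gain` from the onset phase onward,
#' and \eqn{\epsilon} is Gaussian measurement noise with SD `noise_sd_PU`.
#' For stimulated groups the driving side's AR(1) level steps up by
#' `driver_step` at the onset, emulating the local perfusion increase that
#' needling produces.
#'
#' @param a,b,c,d Real coefficients of the coupling model. `c` and `d` carry
#'   the cross-side gain.
#' @param baseline_PU Resting level of the driving side, in perfusion units.
#'   Must be positive.
#' @param noise_sd_PU Measurement-noise SD added to the responding side (PU,
#'   non-negative).
#' @param intervention_gain Multiplier applied to `(c, d)` from the
#'   intervention onset onward (1 = no intervention effect).
#' @param power Exponent of the fractional-power basis (0.3 by default).
#' @param driver_phi AR(1) coefficient of the driving-side process
#'   (0 <= phi < 1).
#' @param driver_sd_PU Innovation SD of the driving-side AR(1) (PU).
#' @param driver_step Multiplicative step applied to the driving side's
#'   reversion level from the intervention onset, for stimulated groups only.
#' @param driver Which side is generated as the driving AR(1) process:
#'   `"stimulated"` (the needled side; left for the control group) or a
#'   fixed `"L"` / `"R"`.
#' @param onset_phase First phase at which the intervention takes effect.
#' @return An object of class `ground_truth`.
#' @seealso [simulate_subject()], [simulate_group()]
#' @export
ground_truth <- function(a = 0.75, b = 0.5, c = 0.22, d = 0.3,
                         baseline_PU = 150, noise_sd_PU = 5,
                         intervention_gain = 1.0, power = 0.3,
                         driver_phi = 0.85, driver_sd_PU = 15,
                         driver_step = 1.4, driver = c("L", "R", "stimulated"),
                         onset_phase = "post-0") {
  driver <- match.arg(driver)
  if (!is.numeric(baseline_PU) || length(baseline_PU) != 1L || baseline_PU <= 0)
    stop_config("baseline_PU must be a single positive number")
  if (!is.numeric(noise_sd_PU) || length(noise_sd_PU) != 1L || noise_sd_PU < 0)
    stop_config("noise_sd_PU must be a single non-negative number")
  if (intervention_gain <= 0)
    stop_config("intervention_gain must be positive")
  if (driver_phi < 0 || driver_phi >= 1)
    stop_config("driver_phi must lie in [0, 1)")
  if (driver_sd_PU < 0) stop_config("driver_sd_PU must be non-negative")
  if (driver_step <= 0) stop_config("driver_step must be positive")
  if (power <= 0) stop_config("power must be positive")
  structure(
    list(a = a, b = b, c = c, d = d,
         baseline_PU = baseline_PU, noise_sd_PU = noise_sd_PU,
         intervention_gain = intervention_gain, power = power,
         driver_phi = driver_phi, driver_sd_PU = driver_sd_PU,
         driver_step = driver_step, driver = driver,
         onset_phase = onset_phase),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground-truth coupling model\n")
  cat(sprintf("  out(k) = %g out(k-1) + %g out(k-1)^%g + g [%g in(k) + %g in(k)^%g] + e\n",
              x$a, x$b, x$power, x$c, x$d, x$power))
  cat(sprintf("  intervention gain g = %g from %s onward (1 before)\n",
              x$intervention_gain, x$onset_phase))
  cat(sprintf("  driver AR(1): phi = %g, sd = %g PU around %g PU (step x%g at onset)\n",
              x$driver_phi, x$driver_sd_PU, x$baseline_PU, x$driver_step))
  cat(sprintf("  measurement noise SD = %g PU\n", x$noise_sd_PU))
  invisible(x)
}
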