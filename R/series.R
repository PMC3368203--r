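#' Single-side perfusion series for one subject
#'
#' A `perfusion_series` holds one side's mean-blood-flux trace for one
#' subject: strictly positive PU values ordered by (phase, frame), with
#' exactly `frames_per_phase` frames per phase of the layout it conforms to.
#'
#' @param group Group label, one of `"A"`, `"B"`, `"C"` (left acupuncture,
#'   right acupuncture, control).
#' @param subject_id Subject identifier.
#' @param side `"L"` or `"R"`.
#' @param phase Character vector of phase labels, one per sample.
#' @param frame Integer frame index within phase (1-based).
#' @param mbf_pu Numeric MBF values in perfusion units; strictly positive.
#' @return An object of class `perfusion_series`.
#' @export
perfusion_series <- function(group, subject_id, side, phase, frame, mbf_pu) {
  side <- match.arg(side, c("L", "R"))
  n <- length(mbf_pu)
  if (length(phase) != n || length(frame) != n)
    stop_structural("phase, frame and mbf_pu must have equal length")
  if (any(!is.finite(mbf_pu)) || any(mbf_pu <= 0))
    stop_positivity(sprintf(
      "perfusion series %s/%s/%s contains non-positive or non-finite MBF values",
      group, subject_id, side))
  structure(
    list(group = as.character(group), subject_id = as.character(subject_id),
         side = side, phase = as.character(phase), frame = as.integer(frame),
         mbf_pu = as.numeric(mbf_pu)),
    class = "perfusion_series")
}

#' @export
print.perfusion_series <- function(x, ...) {
  cat(sprintf("Perfusion series: group %s, subject %s, side %s, %d samples\n",
              x$group, x$subject_id, x$side, length(x$mbf_pu)))
  cat(sprintf("  MBF range %.1f - %.1f PU over phases %s\n",
              min(x$mbf_pu), max(x$mbf_pu),
              paste(unique(x$phase), collapse = ", ")))
  invisible(x)
}

#' Drop excluded measurement phases from a perfusion series
#'
#' Removes every sample whose phase belongs to the layout's excluded set
#' (by default the `post-0` phase, recorded immediately after the
#' intervention, whose frames are contaminated by the nonspecific effect of
#' the needling procedure itself). Relative sample order is preserved and a
#' new series is returned; the input is not modified.
#'
#' @param series A [perfusion_series()].
#' @param layout A [protocol_layout()]; the series must contain every phase
#'   the layout declares.
#' @return A new `perfusion_series` containing only retained phases.
#' @examples
#' lay <- protocol_layout()
#' tr  <- ground_truth(noise_sd_PU = 0)
#' lr  <- simulate_subject(lay, tr, group = "C", subject_id = "s1", seed = 1)
#' length(apply_phase_exclusion(lr$L, lay)$mbf_pu)  # 60
#' @export
apply_phase_exclusion <- function(series, layout) {
  stopifnot(inherits(series, "perfusion_series"), inherits(layout, "protocol_layout"))
  missing_ph <- setdiff(layout$phases, unique(series$phase))
  if (length(missing_ph))
    stop_structural(sprintf("series %s/%s/%s is missing layout phase(s): %s",
                            series$group, series$subject_id, series$side,
                            paste(missing_ph, collapse = ", ")))
  keep <- !(series$phase %in% layout$excluded_phases)
  perfusion_series(series$group, series$subject_id, series$side,
                   series$phase[keep], series$frame[keep], series$mbf_pu[keep])
}
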