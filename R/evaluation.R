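#' Error series between estimated and measured values
#'
#' The model-quality error series `d(k) = estimated(k) - true(k)`,
#' elementwise, with the sign convention estimated-minus-measured.
#'
#' @param estimated,true_values Equal-length numeric series.
#' @return Numeric vector `d(k)`.
#' @export
compute_errors <- function(estimated, true_values) {
  if (length(estimated) != length(true_values))
    stop_structural(sprintf("length mismatch: estimated has %d values, true has %d",
                            length(estimated), length(true_values)))
  as.numeric(estimated) - as.numeric(true_values)
}

#' Signal-to-noise ratio of a mapped series
#'
#' \deqn{sn = \left(\sum_k f^*(k)^2 \Big/ \sum_k d(k)^2\right)^{q}}
#' with exponent `q = 1/2` by default (amplitude SNR, which keeps
#' `sn + d(k)` on a PU-commensurate scale); the exponent is an explicit
#' configuration value.
#'
#' A perfect fit (`d` identically zero) is a distinct outcome, not an
#' infinite ratio: it raises a `fluxmap_perfect_fit_error` so callers must
#' handle it explicitly.
#'
#' @param estimated Mapped series \eqn{f^*(k)}.
#' @param errors Error series `d(k)`, equal length.
#' @param exponent Outer exponent `q` (default `1/2`).
#' @return A single positive number.
#' @examples
#' compute_snr(c(3, 4), c(1, 1))  # sqrt(25/2)
#' @export
compute_snr <- function(estimated, errors, exponent = 1 / 2) {
  if (length(estimated) != length(errors))
    stop_structural("estimated and errors must have equal length")
  if (length(errors) == 0L) stop_structural("cannot compute an SNR of empty series")
  ss_err <- sum(errors^2)
  if (ss_err == 0)
    stop_perfect_fit("errors are identically zero: perfect fit, no finite signal-noise ratio")
  (sum(estimated^2) / ss_err)^exponent
}

#' Characteristic cloud of a probed model
#'
#' Pairs the two subvectors of the model-output characteristic vector into
#' the 2-D distribution the group comparison is based on:
#' `v_x(k) = sn + d(k)` (signal-noise ratio shifted by the error series) and
#' `v_y(k) = f''(k)` (the model's mapped output for the standard probe
#' signal). The distribution center is the centroid
#' `(mean v_x, mean v_y)`; the headline scalar summary is the centroid's
#' Euclidean norm by default (it combines the fit-quality coordinate with
#' the probe-response coordinate and is stable in sign), configurable to
#' plain `mean v_y`.
#'
#' If the two series differ in length (lag loss on one of them), both are
#' truncated to the common length from the front and a message notes it.
#'
#' @param std_output Mapped standard-signal output series \eqn{f''(k)}.
#' @param snr Scalar signal-noise ratio (use 0 for a perfect fit).
#' @param errors Error series `d(k)`.
#' @param summary `"mean-vy"` (default) or `"centroid-norm"`.
#' @return An object of class `flux_cloud`: list with `v_x`, `v_y`,
#'   `center` (length-2 named vector), `summary_type` and `center_scalar`.
#' @export
characteristic_cloud <- function(std_output, snr, errors,
                                 summary = c("centroid-norm", "mean-vy")) {
  summary <- match.arg(summary)
  std_output <- as.numeric(std_output)
  errors <- as.numeric(errors)
  if (length(std_output) == 0L || length(errors) == 0L)
    stop_structural("characteristic cloud needs non-empty series")
  n <- min(length(std_output), length(errors))
  if (length(std_output) != length(errors)) {
    message(sprintf("characteristic cloud: truncating series to common length %d (had %d and %d)",
                    n, length(std_output), length(errors)))
    std_output <- std_output[seq_len(n)]
    errors <- errors[seq_len(n)]
  }
  v_x <- snr + errors
  v_y <- std_output
  center <- c(x = mean(v_x), y = mean(v_y))
  scalar <- if (summary == "mean-vy") unname(center["y"]) else sqrt(sum(center^2))
  structure(list(v_x = v_x, v_y = v_y, center = center,
                 summary_type = summary, center_scalar = scalar, snr = snr),
            class = "flux_cloud")
}

#' @export
print.flux_cloud <- function(x, ...) {
  cat(sprintf("Characteristic cloud: %d points\n", length(x$v_x)))
  cat(sprintf("  center (%.4f, %.4f), scalar summary %.4f (%s), sn %.4f\n",
              x$center["x"], x$center["y"], x$center_scalar, x$summary_type,
              x$snr))
  invisible(x)
}

#' @export
plot.flux_cloud <- function(x, ...,
                            xlab = "v_x = sn + d(k)", ylab = "v_y = f''(k)",
                            pch = 16, cex = 0.4, col = "grey40") {
  graphics::plot(x$v_x, x$v_y, xlab = xlab, ylab = ylab,
                 pch = pch, cex = cex, col = col, ...)
  graphics::points(x$center["x"], x$center["y"], pch = 3, cex = 2, col = "red")
  invisible(x)
}

#' Evaluate a fitted model on its training data
#'
#' Maps the dataset's input side through the model, computes the error
#' series against the measured output side and the signal-noise ratio.
#' A perfect fit (errors zero up to root-refinement precision) is reported
#' with `perfect_fit = TRUE` and `snr = NA` instead of an error.
#'
#' @param model A [fluxmap()] fit.
#' @param dataset The [group_dataset()] the model was fitted on (or
#'   compatible data).
#' @param snr_exponent Outer exponent of [compute_snr()].
#' @return An object of class `flux_evaluation`: list with `estimated`,
#'   `errors`, `snr`, `snr_exponent`, `perfect_fit`.
#' @export
evaluate_model <- function(model, dataset, snr_exponent = 1 / 2) {
  stopifnot(inherits(model, "fluxmap"), inherits(dataset, "group_dataset"))
  est <- map_series(model, dataset$input, subject = dataset$subject)
  kk <- attr(est, "k")
  # the measured outputs aligned with the mapped samples (lag loss removes
  # each block's first frame)
  blocks <- split(seq_along(dataset$output),
                  factor(dataset$subject, levels = unique(dataset$subject)))
  truth <- unlist(lapply(blocks, function(idx) dataset$output[idx[-1L]]),
                  use.names = FALSE)
  d <- compute_errors(as.numeric(est), truth)
  # perfect fit up to root-refinement precision: the error series carries no
  # information and the SNR denominator is numerically void
  perfect <- all(abs(d) <= 1e-8 * max(1, max(abs(est))))
  snr <- if (perfect) NA_real_ else compute_snr(as.numeric(est), d, snr_exponent)
  structure(list(estimated = as.numeric(est), k = kk, errors = d, snr = snr,
                 snr_exponent = snr_exponent, perfect_fit = perfect),
            class = "flux_evaluation")
}

#' @export
print.flux_evaluation <- function(x, ...) {
  cat(sprintf("Model evaluation: %d mapped samples\n", length(x$estimated)))
  if (x$perfect_fit) cat("  perfect fit: error series identically zero\n")
  else cat(sprintf("  error SD %.4g PU, sn = %.4g (exponent %g)\n",
                   stats::sd(x$errors), x$snr, x$snr_exponent))
  invisible(x)
}
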