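#' Standard probe signal
#'
#' The fixed sum-of-sinusoids series used as a common model input so that
#' the mapped outputs of different groups' models are directly comparable:
#' \deqn{s(k) = 10\{\sin(k/100)+\sin(k/80)+\sin(k/60)+\sin(k/40)
#'  +\cos(k/90)+\cos(k/70)+\cos(k/50)+\cos(k/30)\}.}
#' Eight unit-amplitude sinusoids scaled by 10, so `|s(k)| <= 80` for all
#' `k`, and `s(0) = 40` exactly (all sines vanish, all cosines equal 1).
#' The mix of incommensurate periods keeps the probe complex but
#' deterministic.
#'
#' @param k_start,k_end Inclusive integer range of `k` (default 1..2400).
#'   `k = 0` is permitted, e.g. as a lag seed for mapping.
#' @return An object of class `standard_signal`: list with `k` and `values`.
#' @examples
#' s <- standard_signal(0, 5)
#' s$values[1]  # 40
#' @export
standard_signal <- function(k_start = 1L, k_end = 2400L) {
  if (k_start != round(k_start) || k_end != round(k_end))
    stop_config("k_start and k_end must be integers")
  if (k_start > k_end) stop_config("k_start must not exceed k_end")
  k <- seq(as.integer(k_start), as.integer(k_end))
  v <- 10 * (sin(k / 100) + sin(k / 80) + sin(k / 60) + sin(k / 40) +
             cos(k / 90) + cos(k / 70) + cos(k / 50) + cos(k / 30))
  structure(list(k = k, values = v), class = "standard_signal")
}

#' @export
print.standard_signal <- function(x, ...) {
  cat(sprintf("Standard probe signal: k = %d..%d (%d samples), range [%.2f, %.2f]\n",
              x$k[1], x$k[length(x$k)], length(x$k), min(x$values), max(x$values)))
  invisible(x)
}
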