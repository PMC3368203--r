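#' Signed fractional power
#'
#' Real-valued odd extension of `x^p` to negative arguments:
#' `sign(x) * abs(x)^p`. For `0 < p < 1` this is continuous, odd and
#' strictly increasing on the whole real line, which keeps all model
#' arithmetic real when a series (such as the zero-mean standard probe
#' signal) takes negative values; the naive `x^0.3` of a negative number
#' is complex.
#'
#' @param x Numeric vector.
#' @param p Positive exponent.
#' @return `sign(x) * abs(x)^p`, same length as `x`.
#' @examples
#' signed_power(c(-8, 0, 8), 1 / 3)  # -2 0 2
#' @export
signed_power <- function(x, p) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0)
    stop_config("power exponent p must be a single positive number")
  sign(x) * abs(x)^p
}

#' Build the lagged fractional-power regression rows for one group dataset
#'
#' Expands a paired input/output dataset into the design matrix and response
#' of the linear-in-parameters model
#' \deqn{y(k) = a\,y(k-1) + b\,y(k-1)^{0.3} + c\,u(k) + d\,u(k)^{0.3}.}
#' In `"regress-and-invert"` mode (the model family as written) the
#' regressand `y` is the dataset's *input*-side series and the
#' contemporaneous *output* side supplies `u(k)`; mapped contralateral
#' values are later recovered by inverting the `c,d` static nonlinearity.
#' In `"direct-regression"` mode the roles are swapped: the output side is
#' the regressand and the input side is the exogenous term.
#'
#' Lags are taken strictly within subject blocks, so each subject of block
#' length `m` contributes `m - 1` rows (40 subjects x 60 retained pairs
#' give 2360 rows); a flat lag over the concatenated series would
#' manufacture one spurious cross-subject row per boundary.
#'
#' @param dataset A [group_dataset()].
#' @param mode `"regress-and-invert"` (default) or `"direct-regression"`.
#' @param power Fractional exponent of the basis (default 0.3).
#' @return A list with `X` (n x 4 design matrix with columns
#'   `y_lag`, `y_lag_pow`, `u`, `u_pow`), `y` (response vector), and
#'   `subject` (subject label per row).
#' @export
build_regression_rows <- function(dataset,
                                  mode = c("regress-and-invert", "direct-regression"),
                                  power = 0.3) {
  stopifnot(inherits(dataset, "group_dataset"))
  mode <- match.arg(mode)
  if (mode == "regress-and-invert") {
    y_ser <- dataset$input; u_ser <- dataset$output
  } else {
    y_ser <- dataset$output; u_ser <- dataset$input
  }
  blocks <- split(seq_along(y_ser), factor(dataset$subject, levels = unique(dataset$subject)))
  short <- names(blocks)[vapply(blocks, length, 1L) < 2L]
  if (length(short))
    stop_structural(sprintf("subject block(s) with fewer than 2 pairs: %s",
                            paste(short, collapse = ", ")))
  rows <- lapply(blocks, function(idx) {
    k  <- idx[-1L]            # current sample, within-block
    km <- idx[-length(idx)]   # its within-block lag
    cbind(y = y_ser[k],
          y_lag = y_ser[km], y_lag_pow = signed_power(y_ser[km], power),
          u = u_ser[k],      u_pow = signed_power(u_ser[k], power))
  })
  m <- do.call(rbind, rows)
  subj <- rep(names(blocks), vapply(blocks, length, 1L) - 1L)
  list(X = m[, c("y_lag", "y_lag_pow", "u", "u_pow"), drop = FALSE],
       y = as.numeric(m[, "y"]),
       subject = subj)
}
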