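#' Fit a fractional-power cross-side mapping model
#'
#' Identifies the four coefficients of the bilateral coupling model
#' \deqn{y(k) = a\,y(k-1) + b\,y(k-1)^{0.3} + c\,u(k) + d\,u(k)^{0.3}}
#' by ordinary least squares on the lagged regression rows of a paired
#' group dataset (see [build_regression_rows()] for how the two modes
#' assign the regressand). The model is linear in `(a, b, c, d)`, so OLS is
#' the natural estimator; no regularisation or order selection is applied
#' because the structure is fixed.
#'
#' @param data A [group_dataset()] of strictly positive paired PU series,
#'   or a list with elements `X` (n x 4 design) and `y` (response) as
#'   returned by [build_regression_rows()].
#' @param mode `"regress-and-invert"` (the model family as written: the
#'   designated input side is the regressand and mapped values are later
#'   recovered by inverting the static nonlinearity) or
#'   `"direct-regression"` (output side as regressand; mapping is a
#'   recursive free run).
#' @param power Fractional exponent of the basis, default 0.3.
#' @return An object of class `fluxmap`: a list with components
#'   `coefficients` (named `a`, `b`, `c`, `d`), `power`, `mode`, `group`,
#'   `direction`, `n_rows`, `residual_sse`, `sigma2`, `vcov`, `fitted.values`,
#'   `residuals`, `response_mean` and `call`.
#' @examples
#' lay <- protocol_layout()
#' ds  <- simulate_group(lay, ground_truth(), "C", n_subjects = 4, seed = 42)
#' fit <- fluxmap(ds)
#' coef(fit)
#' @export
fluxmap <- function(data, mode = c("regress-and-invert", "direct-regression"),
                    power = 0.3) {
  mode <- match.arg(mode)
  cl <- match.call()
  if (inherits(data, "group_dataset")) {
    rows <- build_regression_rows(data, mode = mode, power = power)
    group <- data$group
    direction <- data$direction
  } else if (is.list(data) && !is.null(data$X) && !is.null(data$y)) {
    rows <- data
    group <- data$group %||% NA_character_
    direction <- data$direction %||% NA_character_
  } else {
    stop_structural("data must be a group_dataset or a list with X and y")
  }
  X <- as.matrix(rows$X)
  y <- as.numeric(rows$y)
  if (nrow(X) < 4L)
    stop_structural("at least 4 regression rows are required to identify 4 coefficients")
  if (ncol(X) != 4L)
    stop_structural("the design must have the 4 basis columns")

  fit <- stats::lm.fit(X, y)
  if (fit$rank < 4L) {
    piv <- fit$qr$pivot
    dropped <- colnames(X)[piv[(fit$rank + 1L):4L]]
    stop_rank(sprintf(
      "design is rank deficient (rank %d): collinear column(s) %s — a constant input makes the power columns collinear with the linear ones",
      fit$rank, paste(dropped, collapse = ", ")), columns = dropped)
  }
  beta <- stats::setNames(fit$coefficients[colnames(X)], c("a", "b", "c", "d"))
  res <- as.numeric(fit$residuals)
  sse <- sum(res^2)
  df <- nrow(X) - 4L
  sigma2 <- if (df > 0) sse / df else NA_real_
  R <- qr.R(fit$qr)[, order(fit$qr$pivot), drop = FALSE]
  XtX_inv <- chol2inv(chol(crossprod(R)))
  dimnames(XtX_inv) <- list(c("a", "b", "c", "d"), c("a", "b", "c", "d"))
  structure(
    list(coefficients = beta, power = power, mode = mode,
         group = group, direction = direction,
         n_rows = nrow(X), residual_sse = sse, sigma2 = sigma2,
         vcov = sigma2 * XtX_inv,
         fitted.values = as.numeric(fit$fitted.values), residuals = res,
         response_mean = mean(y), call = cl),
    class = "fluxmap")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fluxmap <- function(x, digits = max(4L, getOption("digits") - 3L), ...) {
  cat(sprintf("Cross-side flux mapping model (%s)\n", x$mode))
  if (!is.na(x$group))
    cat(sprintf("  group %s, direction %s\n", x$group, x$direction))
  cat(sprintf("  y(k) = a y(k-1) + b y(k-1)^%g + c u(k) + d u(k)^%g\n",
              x$power, x$power))
  print(round(x$coefficients, digits))
  cat(sprintf("  %d rows, residual SSE %.6g\n", x$n_rows, x$residual_sse))
  invisible(x)
}

#' @export
coef.fluxmap <- function(object, ...) object$coefficients

#' @export
vcov.fluxmap <- function(object, ...) object$vcov

#' @export
residuals.fluxmap <- function(object, ...) object$residuals

#' @export
fitted.fluxmap <- function(object, ...) object$fitted.values

#' @export
summary.fluxmap <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tval <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `t value` = tval,
               `Pr(>|t|)` = 2 * stats::pt(abs(tval), object$n_rows - 4L,
                                          lower.tail = FALSE))
  out <- list(model = object, coefficients = tab,
              sigma = sqrt(object$sigma2), df = object$n_rows - 4L)
  class(out) <- "summary.fluxmap"
  out
}

#' @export
print.summary.fluxmap <- function(x, ...) {
  cat(sprintf("Cross-side flux mapping model (%s), %d rows\n",
              x$model$mode, x$model$n_rows))
  stats::printCoefmat(x$coefficients)
  cat(sprintf("Residual SD %.5g on %d degrees of freedom\n", x$sigma, x$df))
  invisible(x)
}

#' Map an input series through a fitted model
#'
#' `predict.fluxmap()` applies [map_series()] to new input values:
#' in regress-and-invert mode each mapped value is the root of the fitted
#' static nonlinearity; in direct-regression mode the model is run as a
#' recursive free simulation.
#'
#' @param object A fitted [fluxmap()] model.
#' @param input Numeric vector of input-series values (or omitted to return
#'   fitted values).
#' @param subject Optional subject labels (same length as `input`); the lag
#'   restarts at each subject boundary.
#' @param lag_seed Optional value standing in for `input(0)`, so that the
#'   mapped series has the same length as the input. Without it the first
#'   sample of each subject block is consumed by the lag.
#' @param ... Unused.
#' @return Numeric vector of mapped (estimated) contralateral values.
#' @export
predict.fluxmap <- function(object, input = NULL, subject = NULL,
                            lag_seed = NULL, ...) {
  if (is.null(input)) return(object$fitted.values)
  map_series(object, input, subject = subject, lag_seed = lag_seed)
}

#' @export
plot.fluxmap <- function(x, ...) {
  graphics::plot(x$fitted.values, x$residuals,
                 xlab = "fitted y(k) [PU]", ylab = "residual [PU]",
                 main = sprintf("fluxmap residuals (%s)", x$mode), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Writes (or returns) a lossless JSON document with the model's group,
#' direction, mode, power, coefficients, row count and residual SSE.
#' [read_model_json()] restores an equivalent `fluxmap` object.
#'
#' @param model A [fluxmap()] fit.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_model_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "fluxmap"))
  doc <- list(group = model$group, direction = model$direction,
              mode = model$mode, power = model$power,
              coefficients = as.list(model$coefficients),
              n_rows = model$n_rows, residual_sse = model$residual_sse,
              response_mean = model$response_mean)
  # 17 significant digits: doubles survive the round trip bit-exactly
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname write_model_json
#' @param json A JSON string or file path produced by [write_model_json()].
#' @export
read_model_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  structure(
    list(coefficients = unlist(doc$coefficients)[c("a", "b", "c", "d")],
         power = doc$power, mode = doc$mode,
         group = doc$group, direction = doc$direction,
         n_rows = doc$n_rows, residual_sse = doc$residual_sse,
         sigma2 = NA_real_, vcov = NULL,
         fitted.values = NULL, residuals = NULL,
         response_mean = doc$response_mean, call = NULL),
    class = "fluxmap")
}
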