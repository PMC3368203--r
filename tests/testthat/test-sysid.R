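test_that("signed power is odd, continuous and total on the reals", {
  expect_identical(signed_power(0, 0.3), 0)
  expect_identical(signed_power(1, 0.3), 1)
  expect_identical(signed_power(-1, 0.3), -1)
  x <- seq(-5, 5, by = 0.25)
  expect_equal(signed_power(-x, 0.3), -signed_power(x, 0.3))
  expect_true(all(diff(signed_power(x, 0.3)) > 0))  # strictly increasing
  expect_error(signed_power(1, -1), class = "fluxmap_config_error")
})

test_that("regression rows lag strictly within subject blocks", {
  ds1 <- noiseless_dataset(n_subjects = 1)
  rows1 <- build_regression_rows(ds1)
  expect_identical(nrow(rows1$X), 59L)           # 60 pairs -> 59 lagged rows
  ds4 <- noiseless_dataset(n_subjects = 4)
  rows4 <- build_regression_rows(ds4)
  expect_identical(nrow(rows4$X), 4L * 59L)
  # oracle: enumerate lagged pairs by hand
  lagged_pairs <- sum(unname(table(ds4$subject)) - 1L)
  expect_identical(nrow(rows4$X), as.integer(lagged_pairs))
  # regress-and-invert puts the input side on the left-hand side
  expect_identical(rows1$y, ds1$input[-1])
  expect_identical(unname(rows1$X[, "u"]), ds1$output[-1])
  # direct-regression swaps the roles
  rd <- build_regression_rows(ds1, mode = "direct-regression")
  expect_identical(rd$y, ds1$output[-1])
  expect_identical(unname(rd$X[, "u"]), ds1$input[-1])
})

test_that("a constant series produces all-ones rows and a rank error at fit time", {
  ds <- group_dataset(rep(1, 10), rep(1, 10), rep("s", 10), "C")
  rows <- build_regression_rows(ds)
  expect_true(all(rows$X == 1))
  expect_true(all(rows$y == 1))
  err <- tryCatch(fluxmap(ds), error = function(e) e)
  expect_s3_class(err, "fluxmap_rank_error")
  expect_true(length(err$columns) >= 1)
})

test_that("subject blocks of fewer than 2 pairs are a structural error naming the subject", {
  ds <- group_dataset(c(1, 2, 3), c(1, 2, 3), c("s1", "s1", "s1"), "C")
  ds$subject <- c("s1", "s1", "s2")  # force an uneven split past the constructor
  expect_error(build_regression_rows(ds), regexp = "s2",
               class = "fluxmap_structural_error")
})

test_that("OLS recovers noiseless coefficients and matches the normal equations", {
  tr <- toy_rows()
  fit <- fluxmap(list(X = tr$X, y = tr$y))
  expect_lt(max(abs(coef(fit) - tr$truth)), 1e-8)
  expect_lt(fit$residual_sse, 1e-12)

  set.seed(42)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    X <- cbind(y_lag = runif(n, 10, 300), y_lag_pow = 0, u = 0, u_pow = 0)
    X[, "y_lag_pow"] <- X[, "y_lag"]^0.3 * runif(n, 0.5, 2)
    X[, "u"] <- runif(n, 10, 300)
    X[, "u_pow"] <- X[, "u"]^0.3 * runif(n, 0.5, 2)
    y <- rnorm(n, 50, 20)
    est <- coef(fluxmap(list(X = X, y = y)))
    ref <- ols_oracle(X, y)
    expect_lt(max(abs(est - ref) / pmax(1e-8, abs(ref))), 1e-8)
  }

  # zero response gives zero coefficients
  z <- fluxmap(list(X = tr$X, y = rep(0, nrow(tr$X))))
  expect_equal(unname(coef(z)), rep(0, 4))
})

test_that("model summary provides OLS standard errors", {
  tr <- toy_rows()
  set.seed(7)
  y <- tr$y + rnorm(length(tr$y), 0, 2)
  fit <- fluxmap(list(X = tr$X, y = y))
  sm <- summary(fit)
  ref <- summary(stats::lm(y ~ 0 + tr$X))$coefficients
  expect_equal(unname(sm$coefficients[, "Estimate"]), unname(ref[, "Estimate"]))
  expect_equal(unname(sm$coefficients[, "Std. Error"]), unname(ref[, "Std. Error"]),
               tolerance = 1e-10)
})

test_that("static-nonlinearity inversion round-trips and flags multiplicity", {
  expect_equal(invert_static_nonlinearity(1, 0, 7)[1], 7)
  expect_equal(invert_static_nonlinearity(0, 1, 1)[1], 1)
  expect_equal(invert_static_nonlinearity(2, 3, 2 * 5 + 3 * 5^0.3)[1], 5,
               tolerance = 1e-9)
  expect_error(invert_static_nonlinearity(0, 0, 1), class = "fluxmap_config_error")

  # property sweep: forward then invert recovers x
  set.seed(11)
  for (i in 1:40) {
    cc <- runif(1, 0.1, 10); dd <- runif(1, 0.1, 10)
    x <- 10^runif(20, -3, 3)
    t <- cc * x + dd * signed_power(x, 0.3)
    xr <- invert_static_nonlinearity(cc, dd, t)
    expect_lt(max(abs(xr - x)), 1e-9)
  }

  # mixed-sign coefficients: up to three roots; nearest to the hint returned
  cc <- 1; dd <- -2
  xs <- (0.3 * 2 / 1)^(1 / 0.7)
  gm <- cc * xs + dd * xs^0.3
  t_mid <- gm / 2                       # strictly inside the three-root window
  r_small <- invert_static_nonlinearity(cc, dd, t_mid, bracket_hint = 0.01)
  r_large <- invert_static_nonlinearity(cc, dd, t_mid, bracket_hint = 100)
  expect_true(attr(r_small, "multiple_roots")[1])
  expect_true(attr(r_large, "multiple_roots")[1])
  expect_false(isTRUE(all.equal(r_small[1], r_large[1])))
  g <- function(x) cc * x + dd * signed_power(x, 0.3)
  expect_lt(abs(g(r_small[1]) - t_mid), 1e-9)
  expect_lt(abs(g(r_large[1]) - t_mid), 1e-9)

  # monotone roots agree with the independent scalar oracle
  for (t in c(-37.5, -2, 0.4, 12)) {
    expect_equal(invert_static_nonlinearity(1.7, 2.3, t)[1],
                 root_oracle(1.7, 2.3, t), tolerance = 1e-8)
  }
})

test_that("an unreachable root reports the searched bracket", {
  # root would be ~1e40, beyond the 2^60-fold bracket expansion
  err <- tryCatch(invert_static_nonlinearity(1e-10, 1e-10, 1e30, bracket_hint = 1),
                  error = function(e) e)
  expect_s3_class(err, "fluxmap_no_root_error")
  expect_true(is.numeric(err$interval))
})

test_that("regress-and-invert mapping is exact on noiseless data and matches a per-point oracle", {
  # identity model: f*(k) = input(k)
  ident <- structure(list(coefficients = c(a = 0, b = 0, c = 1, d = 0),
                          power = 0.3, mode = "regress-and-invert",
                          response_mean = 1),
                     class = "fluxmap")
  u <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(as.numeric(map_series(ident, u)), u[-1], tolerance = 1e-9)

  # noiseless synthetic data, generating model supplied: exact inversion.
  # The generating relation is out(k) = f(out(k-1), in(k)); written in
  # regress-and-invert orientation the regressand is the *output* series,
  # so map from the output side back to the input side.
  tr <- ground_truth(noise_sd_PU = 0)
  ds <- simulate_group(protocol_layout(), tr, "C", 1, 12, direction = "R->L")
  gen <- structure(list(coefficients = c(a = tr$a, b = tr$b, c = tr$c, d = tr$d),
                        power = tr$power, mode = "regress-and-invert",
                        response_mean = mean(ds$output)),
                   class = "fluxmap")
  pre_only <- 1:30   # before the onset the gain is exactly 1
  est <- map_series(gen, ds$input[pre_only])
  expect_lt(max(abs(as.numeric(est) - ds$output[pre_only][-1])), 1e-8)

  # 5-point toy series vs independent scalar root finding at every k
  toy <- structure(list(coefficients = c(a = 0.5, b = 1, c = 2, d = 3),
                        power = 0.3, mode = "regress-and-invert",
                        response_mean = 10),
                   class = "fluxmap")
  u5 <- c(4, 7, 2, 9, 5)
  est5 <- as.numeric(map_series(toy, u5))
  for (k in 2:5) {
    t_k <- u5[k] - 0.5 * u5[k - 1] - 1 * signed_power(u5[k - 1], 0.3)
    expect_equal(est5[k - 1], root_oracle(2, 3, t_k), tolerance = 1e-8)
  }
})

test_that("subject boundaries restart the mapping lag", {
  toy <- structure(list(coefficients = c(a = 0.5, b = 1, c = 2, d = 3),
                        power = 0.3, mode = "regress-and-invert",
                        response_mean = 10),
                   class = "fluxmap")
  u <- c(4, 7, 2, 9, 5, 8)
  subj <- rep(c("s1", "s2"), each = 3)
  est <- map_series(toy, u, subject = subj)
  expect_length(est, 4L)   # each block loses its first sample
  split1 <- as.numeric(map_series(toy, u[1:3]))
  split2 <- as.numeric(map_series(toy, u[4:6]))
  expect_equal(as.numeric(est), c(split1, split2))
  # a lag seed keeps all samples
  est_seed <- map_series(toy, u, subject = subj, lag_seed = 6)
  expect_length(est_seed, 6L)
})

test_that("direct-regression mapping is the documented free run", {
  m <- structure(list(coefficients = c(a = 0.4, b = 0.2, c = 1.1, d = 0.5),
                      power = 0.3, mode = "direct-regression",
                      response_mean = 50),
                 class = "fluxmap")
  u <- c(10, 20, 30, 40)
  est <- as.numeric(map_series(m, u, lag_seed = 0))  # keep all 4 samples
  prev <- 50
  ref <- numeric(4)
  for (k in 1:4) {
    prev <- 0.4 * prev + 0.2 * prev^0.3 + 1.1 * u[k] + 0.5 * u[k]^0.3
    ref[k] <- prev
  }
  expect_equal(est, ref, tolerance = 1e-12)
})

test_that("model JSON serialization round-trips losslessly", {
  ds <- noiseless_dataset(n_subjects = 2)
  fit <- fluxmap(ds)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_identical(coef(back), coef(fit))
  expect_identical(back$mode, fit$mode)
  expect_identical(back$power, fit$power)
  expect_identical(back$n_rows, fit$n_rows)
  expect_equal(back$residual_sse, fit$residual_sse)
  expect_identical(back$group, fit$group)
  expect_identical(back$direction, fit$direction)
})
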