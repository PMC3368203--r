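#' Invert the fitted static nonlinearity
#'
#' Solves \eqn{g(x) = c\,x + d\,\mathrm{sign}(x)|x|^p = t} for `x`, the step
#' that recovers a mapped contralateral value from the model family as
#' written (the measured input side appears on the left-hand side of the
#' model, so the estimated output is the root of the remaining static
#' nonlinearity). `g` is odd and, when `c` and `d` share a sign, strictly
#' monotone; roots are found by bisection inside a bracket expanded
#' geometrically from `bracket_hint` (up to `2^60 * bracket_hint`) and
#' polished by a few damped Newton steps. With mixed-sign coefficients `g`
#' is non-monotone: up to three roots exist, the one closest to
#' `bracket_hint` is returned, and the `multiple_roots` attribute flags the
#' affected targets.
#'
#' @param c,d Coefficients of the static nonlinearity; not both zero.
#' @param target Numeric vector of right-hand sides `t`.
#' @param power Fractional exponent `p` (default 0.3), positive.
#' @param bracket_hint Positive scale from which the search bracket is
#'   expanded (default 1).
#' @return Numeric vector of roots, one per target, each satisfying
#'   `|g(x) - t| <= 1e-9 * max(1, |t|)`. Attribute `multiple_roots` is a
#'   logical vector marking targets with more than one real root.
#' @examples
#' invert_static_nonlinearity(2, 3, 2 * 5 + 3 * 5^0.3)  # 5
#' @export
invert_static_nonlinearity <- function(c, d, target, power = 0.3, bracket_hint = 1) {
  if (!is.numeric(bracket_hint) || bracket_hint <= 0)
    stop_config("bracket_hint must be positive")
  if (power <= 0) stop_config("power must be positive")
  if (c == 0 && d == 0)
    stop_config("(c, d) = (0, 0): the static nonlinearity is identically zero")

  g <- function(x) c * x + d * signed_power(x, power)
  t0 <- as.numeric(target)

  # Normalize to c >= 0: g(x) = t has the same roots as (-g)(x) = -t.
  flip <- (c < 0) || (c == 0 && d < 0)
  cc <- if (flip) -c else c
  dd <- if (flip) -d else d
  tt <- if (flip) -t0 else t0

  multiple <- logical(length(tt))
  if (cc == 0) {                      # pure fractional power: closed form
    x <- signed_power(tt / dd, 1 / power)
  } else if (dd >= 0) {               # strictly increasing g
    x <- solve_branch_odd(cc, dd, power, tt, bracket_hint)
  } else {                            # mixed signs: three monotone branches
    xs <- (power * abs(dd) / cc)^(1 / (1 - power))  # stationary point > 0
    gm <- cc * xs + dd * xs^power                   # branch minimum (< 0)
    x <- numeric(length(tt))
    hi_needed <- tt > -gm             # only the right outer branch
    lo_needed <- tt < gm              # only the left outer branch (oddness)
    mid <- !hi_needed & !lo_needed    # all three branches
    if (any(hi_needed))
      x[hi_needed] <- bisect_mono(cc, dd, power, tt[hi_needed],
                                  lo = rep(xs, sum(hi_needed)), hint = bracket_hint,
                                  increasing = TRUE)
    if (any(lo_needed))
      x[lo_needed] <- -bisect_mono(cc, dd, power, -tt[lo_needed],
                                   lo = rep(xs, sum(lo_needed)), hint = bracket_hint,
                                   increasing = TRUE)
    if (any(mid)) {
      tm <- tt[mid]
      cand_mid <- bisect_interval(cc, dd, power, tm, -xs, xs, increasing = FALSE)
      cand_hi  <- bisect_mono(cc, dd, power, tm, lo = rep(xs, length(tm)),
                              hint = bracket_hint, increasing = TRUE)
      cand_lo  <- -bisect_mono(cc, dd, power, -tm, lo = rep(xs, length(tm)),
                               hint = bracket_hint, increasing = TRUE)
      # strictly inside (gm, -gm) there are three distinct roots
      multiple[mid] <- abs(tm) < abs(gm)
      pick <- cbind(cand_lo, cand_mid, cand_hi)
      dist <- abs(pick - bracket_hint)
      x[mid] <- pick[cbind(seq_along(tm), max.col(-dist, ties.method = "first"))]
    }
  }
  res <- abs(g(x) - t0)
  tol <- 1e-9 * pmax(1, abs(t0))
  if (any(res > tol)) {
    i <- which.max(res / tol)
    stop_no_root(sprintf(
      "root refinement failed for target %g (residual %.3g exceeds tolerance %.3g)",
      t0[i], res[i], tol[i]),
      interval = c(-2^60 * bracket_hint, 2^60 * bracket_hint), target = t0[i])
  }
  attr(x, "multiple_roots") <- multiple
  x
}

# Root of the odd strictly-increasing g on the whole line: by oddness reduce
# to non-negative targets and bisect on [0, hi].
solve_branch_odd <- function(cc, dd, p, tt, hint) {
  s <- sign(tt)
  r <- bisect_mono(cc, dd, p, abs(tt), lo = numeric(length(tt)), hint = hint,
                   increasing = TRUE)
  s * r
}

# Vectorized bisection on the increasing branch starting at `lo` (g(lo) <= t
# required); upper end expanded from `hint` by doubling, at most 60 times.
bisect_mono <- function(cc, dd, p, tt, lo, hint, increasing = TRUE) {
  g <- function(x) cc * x + dd * signed_power(x, p)
  hi <- pmax(lo, hint)
  for (m in 1:61) {
    need <- g(hi) < tt
    if (!any(need)) break
    if (m == 61L)
      stop_no_root(sprintf(
        "no sign change within the maximum bracket [%.3g, %.3g] for target %g",
        min(lo), max(hi), tt[which(need)[1]]),
        interval = c(min(lo), max(hi)), target = tt[which(need)[1]])
    hi[need] <- pmax(hi[need] * 2, hint * 2^m)
  }
  bisect_interval(cc, dd, p, tt, lo, hi, increasing = TRUE)
}

# Plain vectorized bisection on [lo, hi] followed by clamped Newton polish.
# 150 halvings: |x|^p residuals near a zero root shrink slowly in x, so the
# interval must collapse well below double precision of the endpoints.
bisect_interval <- function(cc, dd, p, tt, lo, hi, increasing = TRUE) {
  g <- function(x) cc * x + dd * signed_power(x, p)
  sgn <- if (increasing) 1 else -1
  lo <- rep_len(as.numeric(lo), length(tt))
  hi <- rep_len(as.numeric(hi), length(tt))
  for (i in 1:150) {
    mid <- 0.5 * (lo + hi)
    up <- sgn * (g(mid) - tt) < 0
    up[is.na(up)] <- FALSE
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  x <- 0.5 * (lo + hi)
  for (i in 1:4) {                       # Newton polish, clamped to bracket
    gp <- cc + dd * p * abs(x)^(p - 1)
    gp[!is.finite(gp) | abs(gp) < 1e-300] <- NA
    step <- (g(x) - tt) / gp
    xn <- x - step
    ok <- is.finite(xn) & xn >= lo & xn <= hi
    x <- ifelse(ok, xn, x)
  }
  x
}
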