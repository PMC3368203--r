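#' Deterministic per-subject seed derivation
#'
#' One master seed reproduces the whole study; each subject's RNG stream is
#' seeded by a fixed arithmetic rule on (master seed, group index, subject
#' index), so any subset of subjects can be regenerated independently.
#'
#' @param master Master integer seed.
#' @param group Group label (`"A"`, `"B"`, `"C"`).
#' @param subject_index 1-based subject index within the group.
#' @return An integer seed below 2^31.
#' @export
subject_seed <- function(master, group, subject_index) {
  gi <- match(group, c("A", "B", "C"))
  if (is.na(gi)) gi <- 4L
  as.integer((as.numeric(master) + 7919 * gi + 104729 * subject_index) %% 2147483647)
}

# Side generated as the driving process. Policy "stimulated" drives from
# the needled side (left for group A, right for group B); the control group
# keeps the left-drives-right convention.
driver_side <- function(group, truth) {
  if (!is.null(truth$driver) && truth$driver %in% c("L", "R")) return(truth$driver)
  switch(as.character(group), A = "L", B = "R", C = "L", "L")
}

#' Simulate one subject's bilateral perfusion series
#'
#' Generates the driving side as a mean-reverting positive AR(1) around
#' `baseline_PU` (with a multiplicative level step at the intervention onset
#' for stimulated groups A and B), and the contralateral side through the
#' ground-truth fractional-power coupling plus Gaussian measurement noise.
#' The responding side's recursion is taken over *retained* samples
#' (excluded phases are generated from their chronological neighbour but do
#' not enter the retained lag chain), so that with `noise_sd_PU = 0` every
#' retained lagged pair satisfies the generating equation exactly.
#'
#' Noise draws that would make a PU value non-positive are redrawn up to 100
#' times (the redraw count is recorded in the `redraws` attribute); if a
#' positive value still cannot be produced, generation fails with a
#' positivity error rather than clipping silently.
#'
#' @param layout A [protocol_layout()].
#' @param truth A [ground_truth()].
#' @param group Group label: `"A"` (left acupuncture), `"B"` (right
#'   acupuncture) or `"C"` (control).
#' @param subject_id Subject identifier.
#' @param seed Integer seed; identical inputs reproduce identical series.
#' @return A list with elements `L` and `R` (each a [perfusion_series()]),
#'   attribute `driver` (which side was generated as the driving process)
#'   and attribute `redraws` (number of positivity redraws used).
#' @export
simulate_subject <- function(layout, truth, group, subject_id, seed) {
  stopifnot(inherits(layout, "protocol_layout"), inherits(truth, "ground_truth"))
  .fluxmap_sim$redraws <- 0L
  set.seed(as.integer(seed))
  n_ph <- length(layout$phases)
  fpp <- layout$frames_per_phase
  phase <- rep(layout$phases, each = fpp)
  frame <- rep(seq_len(fpp), times = n_ph)
  n <- n_ph * fpp

  onset_i <- match(truth$onset_phase, layout$phases)
  post <- if (is.na(onset_i)) rep(FALSE, n) else rep(seq_len(n_ph) >= onset_i, each = fpp)
  stimulated <- group %in% c("A", "B")

  # --- driving side: mean-reverting AR(1) around a (possibly stepped) level
  mu <- truth$baseline_PU * ifelse(post & stimulated, truth$driver_step, 1)
  sd_stat <- truth$driver_sd_PU / sqrt(1 - truth$driver_phi^2)
  drv <- numeric(n)
  drv[1] <- positive_draw(mu[1], sd_stat, "driving side")
  if (n >= 2L) for (k in 2:n) {
    m_k <- mu[k] + truth$driver_phi * (drv[k - 1] - mu[k - 1])
    drv[k] <- positive_draw(m_k, truth$driver_sd_PU, "driving side")
  }

  # --- responding side: coupled recursion over the retained lag chain
  gain <- ifelse(post, truth$intervention_gain, 1)
  retained <- !(phase %in% layout$excluded_phases)
  drive_term <- gain * (truth$c * drv + truth$d * signed_power(drv, truth$power))
  init <- coupling_fixed_point(truth, drive_term[1])
  rsp <- numeric(n)
  prev_ret <- NA_real_
  prev_chr <- NA_real_
  for (k in seq_len(n)) {
    base_k <- if (k == 1L) {
      init
    } else {
      prev <- if (retained[k] && !is.na(prev_ret)) prev_ret else prev_chr
      truth$a * prev + truth$b * signed_power(prev, truth$power) + drive_term[k]
    }
    rsp[k] <- positive_draw(base_k, truth$noise_sd_PU, "responding side")
    prev_chr <- rsp[k]
    if (retained[k]) prev_ret <- rsp[k]
  }

  drv_side <- driver_side(group, truth)
  left  <- if (drv_side == "L") drv else rsp
  right <- if (drv_side == "L") rsp else drv
  out <- list(L = perfusion_series(group, subject_id, "L", phase, frame, left),
              R = perfusion_series(group, subject_id, "R", phase, frame, right))
  attr(out, "driver") <- drv_side
  attr(out, "redraws") <- get_redraw_count()
  out
}

# Redraw accounting shared by the generation helpers of one subject call.
.fluxmap_sim <- new.env(parent = emptyenv())
.fluxmap_sim$redraws <- 0L

get_redraw_count <- function() {
  n <- .fluxmap_sim$redraws
  .fluxmap_sim$redraws <- 0L
  n
}

# One Gaussian draw around `mean`, redrawn (up to 100 times) until positive.
# With sd = 0 a non-positive mean is a hard failure: there is nothing to
# redraw.
positive_draw <- function(mean, sd, what) {
  if (sd == 0) {
    if (mean <= 0)
      stop_positivity(sprintf(
        "noiseless %s value %.3g PU is non-positive; check the ground truth",
        what, mean))
    return(mean)
  }
  for (i in 1:100) {
    v <- mean + stats::rnorm(1L, 0, sd)
    if (v > 0) {
      if (i > 1L) .fluxmap_sim$redraws <- .fluxmap_sim$redraws + (i - 1L)
      return(v)
    }
  }
  stop_positivity(sprintf(
    "could not draw a positive %s value around %.3g PU (sd %.3g) in 100 attempts",
    what, mean, sd))
}

# Stable level of the noiseless coupling recursion for a constant drive:
# iterate x <- a x + b x^p + drive from the drive level itself.
coupling_fixed_point <- function(truth, drive) {
  x <- max(drive, truth$baseline_PU)
  for (i in 1:200) {
    xn <- truth$a * x + truth$b * signed_power(x, truth$power) + drive
    if (!is.finite(xn)) break
    if (abs(xn - x) < 1e-12 * max(1, abs(x))) return(xn)
    x <- xn
  }
  if (is.finite(x) && x > 0) x else truth$baseline_PU
}

#' Simulate a whole group and pair it into a mapping dataset
#'
#' Runs [simulate_subject()] for `n_subjects` subjects (per-subject seeds
#' derived by [subject_seed()]), applies the layout's phase exclusion, and
#' concatenates the retained (input, output) pairs in subject order with
#' subject boundaries recorded. With the default layout, each subject
#' contributes 60 retained pairs and a 40-subject group contributes 2400.
#'
#' @inheritParams simulate_subject
#' @param n_subjects Number of subjects (>= 1).
#' @param direction `"L->R"` (left side is the model input) or `"R->L"`.
#' @return A [group_dataset()].
#' @export
simulate_group <- function(layout, truth, group, n_subjects, seed,
                           direction = c("L->R", "R->L")) {
  direction <- match.arg(direction)
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L)
    stop_config("n_subjects must be a positive integer")
  inp <- list(); outp <- list(); subj <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("%s%02d", group, s)
    pair <- simulate_subject(layout, truth, group, sid, subject_seed(seed, group, s))
    l <- apply_phase_exclusion(pair$L, layout)
    r <- apply_phase_exclusion(pair$R, layout)
    inp[[s]]  <- if (direction == "L->R") l$mbf_pu else r$mbf_pu
    outp[[s]] <- if (direction == "L->R") r$mbf_pu else l$mbf_pu
    subj[[s]] <- rep(sid, length(inp[[s]]))
  }
  group_dataset(unlist(inp), unlist(outp), unlist(subj), group, direction)
}

#' Default per-group ground truths for a three-group study
#'
#' Builds the A/B/C ground-truth list from one base model and a vector of
#' per-group cross-side gain multipliers. The defaults encode the study
#' conditions the pipeline is designed around: right-side stimulation (B)
#' couples more strongly than left-side stimulation (A), and the control
#' group (C) has no intervention effect.
#'
#' @param base A [ground_truth()] providing everything except the gains.
#' @param gains Named numeric vector of intervention gains for groups
#'   `A`, `B`, `C`.
#' @return Named list of three `ground_truth` objects.
#' @export
study_truths <- function(base = ground_truth(),
                         gains = c(A = 1.5, B = 3.0, C = 1.0)) {
  stopifnot(inherits(base, "ground_truth"))
  if (!all(c("A", "B", "C") %in% names(gains)))
    stop_config("gains must be named with groups A, B and C")
  lapply(stats::setNames(c("A", "B", "C"), c("A", "B", "C")), function(g) {
    tr <- base
    tr$intervention_gain <- unname(gains[[g]])
    tr
  })
}
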