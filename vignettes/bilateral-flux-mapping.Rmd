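---
title: "Mapping bilateral skin blood flux with fractional-power autoregressive models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping bilateral skin blood flux with fractional-power autoregressive models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmap)
```

## The problem

Skin blood perfusion at homologous left/right sites — here the LI4 (Hegu)
region on the two hands, measured by full-field laser perfusion imaging in
arbitrary perfusion units (PU) — is bilaterally coupled: unilateral
stimulation such as acupuncture raises mean blood flux (MBF) not only
locally but also on the contralateral side. `fluxmap` quantifies that
coupling by system identification. For each intervention group (A = left
acupuncture, B = right acupuncture, C = control) it fits an input–output
model between the two sides' MBF series, probes every fitted model with one
fixed *standard signal* so groups become comparable, and summarises the
probed output as a 2-D characteristic cloud whose center measures
cross-side amplification.

## The model family

With `u(k)` the designated input side and `y(k)` its regressand, the model
is linear in its four parameters over a fractional-power basis:

$$y(k) = a\,y(k-1) + b\,y(k-1)^{0.3} + c\,u(k) + d\,u(k)^{0.3}.$$

The 0.3 exponent is fixed by the model family; the concave power terms give
the model a saturating, level-dependent component alongside the linear
autoregressive and exogenous terms. Because the model is linear in
$(a,b,c,d)$, ordinary least squares is the natural estimator; `fluxmap()`
performs it via QR and reports coefficient standard errors from the usual
OLS covariance. No regularisation or order selection is applied: the
structure is fixed, and the analysis is about what the fixed structure's
coefficients imply.

Two orientations of the same family are supported:

* **regress-and-invert** (default): the model is fitted exactly as written,
  with the designated *input* side on the left-hand side. The mapped
  (estimated) contralateral value is then the root of the remaining static
  nonlinearity, $g(x) = c\,x + d\,\mathrm{sign}(x)|x|^{0.3} = t(k)$ with
  $t(k) = u(k) - a\,u(k-1) - b\,u(k-1)^{0.3}$.
* **direct-regression**: the output side is the regressand and mapping is a
  recursive free-run simulation, initialised at the training-response mean
  (configurable). This is the conventional one-step-ahead orientation; both
  are kept because they answer slightly different questions about the same
  data.

Negative arguments arise when the zero-mean standard signal is pushed
through the power basis, so all fractional powers use the signed extension
$\mathrm{sign}(x)\,|x|^{0.3}$, which is continuous, odd and strictly
increasing — every computation stays real.

### Root finding

$g$ is odd; when $c$ and $d$ share a sign it is strictly monotone and the
root is found by bisection inside a bracket expanded geometrically from
`bracket_hint` (at most $2^{60}$-fold), then polished by clamped Newton
steps. With mixed-sign coefficients $g$ has two stationary points and up to
three real roots; all candidate roots are located (one per monotone
branch), the one closest to `bracket_hint` is returned, and a
`multiple_roots` attribute flags the affected targets. Accepted roots must
satisfy $|g(x)-t| \le 10^{-9}\max(1,|t|)$; in practice the Newton polish
reaches machine precision. Bisection runs 150 halvings because near a zero
root the residual scales like $|x|^{0.3}$ — the interval must collapse far
below the endpoint's precision before the residual test can pass.

## Protocol structure and data layout

A recording session has 7 measurement phases at 30-minute spacing (three
before the intervention, four after), 10 image frames per phase, per side:
70 samples. The 10 frames of the `post-0` phase — recorded immediately
after needle withdrawal — are excluded as contaminated by the nonspecific
effect of the procedure, leaving 60 retained pairs per subject and 2400 per
group of 40. Regression lags are taken strictly within subject blocks
(each block of 60 contributes 59 rows, so a 40-subject group gives 2360):
a flat lag over the concatenated series would manufacture one meaningless
cross-subject row per boundary. The flat indexing remains available by
passing a single-subject label, for forensic comparison.

## Quality measures and the characteristic cloud

The error series is $d(k) = f^*(k) - f(k)$ (estimated minus measured), and
the signal-to-noise ratio is

$$sn = \left(\sum_k f^*(k)^2 \Big/ \sum_k d(k)^2\right)^{q},$$

with exponent $q = 1/2$ by default — the amplitude SNR, which keeps
$sn + d(k)$ on a PU-commensurate scale. The exponent is exposed as
configuration (`snr_exponent`), with $1/2400$ available as an alternative
normalisation. A perfect fit is a distinct outcome, not
an infinite ratio: `compute_snr()` raises a classed error, and the
pipeline records `perfect_fit = TRUE` with `snr = NA`, substituting 0 for
the $sn$ shift in the cloud.

The standard signal
$s(k) = 10\{\sin(k/100)+\sin(k/80)+\sin(k/60)+\sin(k/40)+\cos(k/90)+\cos(k/70)+\cos(k/50)+\cos(k/30)\}$
is mapped through each fitted model to give the probe output $f''(k)$;
mapping needs $s(0)$ as the lag of the first frame, and $s(0)=40$ is
evaluated from the formula rather than dropping a point, so all 2400 probe
samples survive. The characteristic cloud pairs
$v_x(k) = sn + d(k)$ with $v_y(k) = f''(k)$; its center is the centroid
$(\overline{v_x}, \overline{v_y})$. Measured-data errors have 2360 points
while the probe output has 2400, so the cloud truncates both series to the
common length from the front (with a message).

### Which scalar is "the" distribution center?

A 2-D cloud admits more than one natural scalar summary, and analyses of
this kind conventionally report a single PU value per group. Both
candidates are computed here, and the package default is the
**centroid norm**
$\sqrt{\overline{v_x}^2 + \overline{v_y}^2}$ rather than the plain
$\overline{v_y}$. The reason is structural: $g$ is odd for *every*
coefficient vector, so $f'' = g^{-1}(t)$ is an odd transform of a series
derived from the near-zero-mean probe. The sign of $\overline{v_y}$ is
therefore driven by coefficient sampling noise, and a sign-unstable scalar
cannot carry a reproducible group ordering. The centroid norm keeps the
same units, includes the stable fit-quality coordinate $\overline{v_x}
\approx sn$, and behaves reproducibly; `center_summary = "mean-vy"`
restores the plain mean.

## The synthetic-data generator

No measured data are distributed with this analysis, so the package
generates bilateral MBF series with the statistical structure the analysis
assumes. Per subject:

* the **driving side** is a mean-reverting positive AR(1) around
  `baseline_PU`, with a multiplicative level step at the intervention
  onset for stimulated groups (the local perfusion increase produced by
  needling);
* the **responding side** follows the coupling model above, with the
  cross-side gain $(c, d)$ multiplied by the group's `intervention_gain`
  from the onset phase onward, plus Gaussian measurement noise.

The responder's recursion runs over the *retained* lag chain (excluded
`post-0` frames are generated from their chronological neighbour but do not
feed the retained chain), so that noiseless generation satisfies the model
identity exactly on every retained lagged pair — the property the fitting
tests rely on. Draws that would produce non-positive PU values are redrawn
(up to 100 times, counted) and generation fails loudly rather than clip:
fractional powers of negative perfusion values must never arise. One
master seed plus a fixed arithmetic rule (`subject_seed()`) gives every
subject an independent, reproducible stream.

### Default study conditions, and why

The defaults encode one fixed set of study conditions:

| parameter | default | rationale |
|---|---|---|
| `baseline_PU` | 150 PU | typical resting hand-skin MBF order of magnitude |
| `driver_phi`, `driver_sd_PU` | 0.85, 15 PU | stationary CV ≈ 19%: realistic slow vasomotion |
| `a` | 0.75 | strong frame-to-frame autocorrelation of flux at 10-s spacing |
| `b`, `d` | 0.5, 0.3 | mild concave components |
| `c` | 0.22 | steady-state cross-side slope $c/(1-a) \approx 0.9$: resting sides nearly equal |
| `noise_sd_PU` | 5 PU | few-percent instrument/measurement noise |
| `driver_step` | 1.4 | post-needling local MBF increase |
| gains (A, B, C) | 1.5, 3.0, 1.0 | right-side stimulation markedly stronger than left, control null |
| `driver` | `"L"` | see below |

The driving side is fixed to the left for all groups by default, matching
the analysis convention that designates the left series as model input; a
`"stimulated"`-side policy (driver = needled side) is available. This
matters because a one-way generative gain is intrinsically *reciprocal*
under the two fitting directions: if one direction's fitted
contemporaneous coupling scales like $g$, the other's scales like $1/g$,
so no choice of gains alone can make a direction-asymmetric generator
produce the same ordering both ways. With a common driver side, near-unit
steady-state coupling and strong responder autocorrelation, the group
contrast is carried symmetrically enough that the stronger-coupled group
produces the larger distribution center in *both* directions — the
qualitative pattern the pipeline is designed to exhibit and test.

What the generator does *not* emulate: spatial perfusion images and
region-of-interest extraction, slow circadian drifts, heteroscedastic
speckle noise, inter-subject variability in baseline or coupling (all
subjects share one ground truth), and any genuinely bidirectional or
delayed coupling. Passing tests therefore show that the *pipeline*
recovers what it assumes from data of this structure — not that measured
human data satisfy the model.

## Numerical and design choices

* OLS rank is checked; a constant input makes the power columns collinear
  with the linear ones and fails loudly, naming the columns.
* Root acceptance: residual $\le 10^{-9}\max(1,|t|)$; bracket expansion
  capped at $2^{60}\times$`bracket_hint` with a classed no-root error
  carrying the searched interval.
* Free-run initialisation (direct-regression mapping) defaults to the
  training-response mean and is configurable.
* The comparison's "amplification" is each stimulated group's scalar
  center divided by the control center, per direction, with exact ties
  flagged.
* Every group's model is built from that group's own series throughout:
  the control-group model never mixes in another group's values.

## Problem sizes used in the tests

The packaged tests run the full study geometry where the property demands
it (40 subjects/group, 2360 regression rows, 2400 probe samples; the
group-ordering property uses 100 replicated studies and a Monte-Carlo
acceptance of ≥ 95%), and reduced sizes (1–5 subjects) where the property
is structural. These sizes are the package's chosen experiment design;
each test states its own.

## Known limitations

* The regress-and-invert probe response extrapolates the fitted model far
  below the training range of positive PU values; with mixed-sign fitted
  coefficients the inversion can sit near a branch boundary, which is why
  `multiple_roots` flags exist and why the sign-stable centroid norm is
  the default scalar.
* The two orientations (regress-and-invert vs direct-regression) can give
  materially different mapped series on noisy data; there is no ground
  truth for which the original analysis used.
* Group-level inference (tests between clouds) is deliberately absent —
  the analysis summarises, it does not test hypotheses.
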