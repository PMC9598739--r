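---
title: "Life-table demography of Daphnia under calcium limitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Life-table demography of Daphnia under calcium limitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daphcal)
```

## The problem

Soft-water lakes at high altitude and latitude often carry less than
1.5 mg Ca L^-1^, a level that limits heavily calcified cladocerans such as
*Daphnia pulex*. Whether warming and food availability buffer or worsen
that limitation is a population-level question: it is answered by life-table
experiments in which individual females are followed daily across a
factorial gradient of calcium, food and temperature, and the observations
are condensed into survivorship and fertility schedules, an intrinsic rate
of increase, and calcium thresholds for survival, reproduction and
population growth.

`daphcal` implements that full analysis chain, together with an
individual-based generator that emulates the design the chain expects:
4 calcium levels (0.25, 0.41, 1.02, 1.74 mg Ca L^-1^) x 2 food levels
(0.2 and 2.0 mg C L^-1^, "LF"/"HF") x 2 temperatures (17.5 and 21 °C),
12 females per treatment followed daily for 19 days, with vials randomised
over three enclosures ("boxes") per temperature.

## From daily records to population growth

**Life tables.** For a cohort of `n0` females, `l_x` is the fraction alive
at the end of day `x` (`l_0 = 1`; animals alive at day 19 are censored and
count as alive throughout) and `m_x` is the number of neonates released on
day `x` per female alive on day `x`. With this convention `l_x * m_x` is
the expected per-initial-female birth schedule. The per-living-female
denominator is the default; `build_life_table(..., mx_denominator =
"initial")` switches to the per-initial-female definition, since published
descriptions are often ambiguous between the two.

**Euler–Lotka rate.** The intrinsic rate of natural increase `r` solves

$$\sum_x e^{-r(x + 0.5)}\, l_x m_x = 1 .$$

The half-day offset credits births to the middle of the daily census
interval; no alternative offset is offered. The left-hand side is strictly
decreasing in `r` whenever any reproduction occurred, so the root is
unique. `solve_r()` brackets it on [-5, 5] d^-1^ (doubling outward if
needed) and bisects to an interval of 1e-12; the `tol` argument (default
1e-4 on `|LHS - 1|`) only governs a warning, not the precision. The
published description of the stopping rule ("refined until the left-hand
side was 10,000") is read as a misprint for a one-in-ten-thousand
tolerance; since the sum must equal 1 at the root, any literal reading is
impossible.

**No-reproduction fallback.** When a treatment produced no offspring the
rate is taken as `r = (ln(Nt + 0.01) / ln(N0 + 0.01)) / t`, exactly as
printed in the source formula, including its ratio-of-logarithms form.
Note the conventional difference-of-logs estimator would return 0 for a
constant population whereas this form returns `1/t`; the form is
implemented verbatim for fidelity and the discrepancy is documented here
rather than silently corrected.

**Jackknife.** Uncertainty in `r` comes from leave-one-out pseudo-values
`theta_i = n * theta_hat - (n - 1) * theta_(-i)`, each `theta_(-i)`
recomputed from a rebuilt life table. The reported estimate is the mean of
the pseudo-values (the raw full-sample root is also emitted) and the SE is
`sqrt(sum((theta_i - mean)^2) / (n(n-1)))`. For a linear statistic this
reduces exactly to `s/sqrt(n)`, which the tests assert. Leave-one-out
cohorts that lose their only reproducer fall back to the formula above,
with per-pseudo-value method flags and a warning.

## Calcium thresholds

Three thresholds are computed, in increasing order of model content:

* **Survival threshold** (descriptive): a Ca level *passes* when at least
  50% of the cohort is alive at day 19 (a tie at exactly 50% passes) and
  at least one female reproduced; the threshold is bracketed between the
  highest failing level below the lowest passing level and that passing
  level, with 0/Inf sentinels at the gradient edges and an ambiguity flag
  when levels above the bracket fail again.
* **Reproductive saturation point** (descriptive + test): the smallest Ca
  level whose reproduction output does not differ from every higher level
  by a two-sample permutation test at alpha = 0.05, two-sided. The
  comparison test is not prescribed by the source analysis; the
  permutation test was chosen because reproduction output is zero-inflated
  and heteroscedastic.
* **Zero-population-growth threshold Ca~ZPG~** (model-based): the Monod
  model with a growth threshold,
  $r(\mathrm{Ca}) = r_{max}\,(\mathrm{Ca} - \mathrm{Ca_{ZPG}}) /
  (\mathrm{Ca} - \mathrm{Ca_{ZPG}} + K_s)$,
  fitted to the per-treatment mean rates by Levenberg–Marquardt
  (unweighted by default; inverse-variance weights optional). Standard
  errors come from the Jacobian at the optimum and the 95% interval is
  `estimate ± t_{n-3, 0.975} * SE`; the interval may legitimately cross
  zero. A Wald t p-value is emitted so marginal-significance statements
  can be reproduced in kind. Two guard rails matter in practice: the fit
  is *refused* (flag, not error) when every mean rate is negative, the
  situation of the low-food groups; and optima whose denominator
  `Ca - Ca_ZPG + K_s` changes sign inside the data range are rejected with
  a multi-start over `Ca_ZPG`, because the singular hyperbola branch can
  interpolate four points beautifully while being meaningless as a growth
  curve.

## Hazard regression and permutation inference

Deaths recorded in whole days are analysed by person-period expansion (one
row per animal per day at risk) and a binomial GLM with complementary
log-log link, the discrete-time analogue of a proportional-hazards model.
Calcium, food, temperature and the interval index enter untransformed as
continuous covariates, with a Ca x food interaction by default; the trait
models use log-calcium instead, following the convention of the source
tables (the hazard table's scale is consistent with untransformed Ca; both
choices are switchable). Separation is flagged rather than raised. Random
enclosure intercepts are *screened*, not integrated: the likelihood-ratio
test compares the fixed-effects model with the same model plus box
indicators. Boxes are nested within temperature, so the box factor adds
only `rank` (here 4) contrasts, not `n_boxes - 1`; the degrees of freedom
are computed from the realised rank difference. Full mixed-model
estimation is deliberately out of scope.

Reproduction output and the growth-rate pseudo-values violate normality
and homoscedasticity, so fixed effects on them are tested by null-model
permutation: the observed statistic is the Gaussian likelihood-ratio
chi-square between the full model and the model without the term, and each
of `B` permutations shuffles the *null-model residuals*, adds them back to
the null fitted values and recomputes the statistic (Freedman–Lane). The
exact permutation scheme used by the original mixed-model software is not
published; this scheme was chosen because it permutes under the null model
and holds its nominal size, which the acceptance tests verify directly
(type-I error within [0.03, 0.07] at alpha = 0.05) rather than assuming
bit-for-bit agreement. The p-value uses the add-one estimator
`(1 + #{stat_b >= stat_obs}) / (1 + B)` and is never zero. In the
pipeline, each term is tested in the model that excludes higher-order
terms containing it (Type-II marginality); testing a two-way interaction
underneath the three-way term would have almost no power.

## What the generator emulates — and what it does not

The generator is calibrated once, to the published treatment-level
summaries, and its defaults define the conditions every downstream test
runs under:

* **Mortality.** A daily cloglog hazard with the linear-predictor terms
  (intercept, Ca, food, temperature, Ca x food, interval) plus an optional
  *calcium-deficiency stress* term: a logistic step of amplitude
  `4.6 - 0.714 (T - 17.5)` (scaled by `0.6 + 0.2 * food`) centred at a
  critical calcium `0.33 + 0.068 (T - 17.5)` mg Ca L^-1^ of width 0.03.
  The stress term exists because a purely log-linear hazard cannot place a
  survival cliff between 0.25 and 0.41 mg Ca L^-1^ at 17.5 °C *and* move
  it to between 0.41 and 1.02 at 21 °C while leaving animals at
  0.25/21 °C alive long enough to reproduce — the joint pattern the
  emulated study reports. Its two temperature dependencies encode that
  study's two headline findings: the survival threshold rises with
  warming (critical Ca up), while tolerance of low Ca for *reproduction*
  improves (amplitude down). Setting `stress = NULL` leaves a pure GLM
  hazard, which is what all parameter-recovery tests use, so the
  estimator and generator are then exactly self-consistent.
* **Maturity.** First-egg age is normal (SD 1 d) around a mean that rises
  at low Ca (only below 21 °C), rises steeply at low food, and falls with
  warming: about 11 d at 0.25 mg Ca/HF/17.5 °C against about 6 d at
  21 °C. This earlier maturity at 21 °C is the mechanism that lets warm
  low-Ca cohorts achieve positive growth despite dying young.
* **Clutches.** Eggs appear at maturity; neonates are counted at each
  subsequent adult moult (every 3 d at 17.5 °C, 2 d at 21 °C — instar
  durations are not published; these values are consistent with faster
  moulting when warm). Whether neonates were counted on the release day
  or the preceding moult is not documented in the source; tying releases
  to adult moults is this package's choice. Counts are zero-truncated
  Poisson with mean saturating in Ca (scale 0.41 mg Ca L^-1^) up to a
  hard plateau at 1 mg Ca L^-1^ — the reported reproductive saturation
  point — times food and temperature factors calibrated to the reported
  clutch means (3.85 neonates at 0.25 mg Ca/HF/17.5 °C, 7.67 at 1.74,
  8.88 at 1.02/21 °C).
* **Boxes and body size.** Box effects default to zero variance (the
  emulated study found box uninfluential) but a box-intercept SD is
  configurable for power-testing the screen. Day-19 body size is normal
  with a mean increasing in Ca, food and temperature; it exists so the
  trait models have a response, and is simulated only for survivors.

Passing tests on this generator demonstrate that the estimators recover
the structure the generator encodes. They cannot demonstrate robustness to
features real data would add: overdispersed clutch sizes, individual
frailty, non-logistic dose responses, measurement error in maturity day,
or interval-censoring subtleties. The generator is also deliberately
monotone in calcium; occasional non-monotone patterns in small real
cohorts (a level reproducing while its neighbour does not) arise here only
through sampling noise.

## Numerical choices and degenerate inputs

* Euler–Lotka terms with `l_x m_x = 0` are skipped so that extreme
  bracket endpoints cannot produce `Inf * 0`.
* Zero-truncated Poisson means are matched by solving
  `lambda/(1 - e^-lambda) = m` (so a requested clutch mean is the mean of
  what is drawn); requested means are floored at 1.05.
* A hazard coefficient of `-Inf` is a legal way to switch mortality off
  (used in tests); `NA`/`NaN`/`+Inf` coefficients are configuration
  errors reported by name.
* `rztpois`, maturity rounding (minimum day 2) and the box assignment all
  draw from the single experiment-level seed, so identical configurations
  give byte-identical output tables.
* Permutation statistics treat `RSS < 1e-12 * (sum(y^2) + 1)` as zero;
  a perfectly explanatory term yields an infinite observed statistic and
  hence the minimal p-value `1/(B+1)`.

## Problem sizes used by the test-suite

The default experiment (192 animals) is used wherever the design itself is
under test. Calibration checks use 250 animals per cell; the null
calibration of the box screen uses 120 replicate experiments; hazard
coefficient recovery uses 100 replicates of 2000 animals; permutation size
is verified with 1000 simulated null data sets at B = 999; the Monod noise
study uses 500 replicates at noise SD 0.005. These sizes were chosen so
that Monte-Carlo error is comfortably below the tolerances being asserted.

## Known limitations

* No integrated random effects (GLMM); the box screen is a fixed-effects
  proxy, appropriate here because the emulated design found box effects
  negligible.
* No continuous-age life tables, Leslie matrices, bootstrap CIs or
  profile likelihoods.
* The fallback growth-rate formula is reproduced as printed; its
  ratio-of-logs form is unconventional (see above) and values produced by
  it should be compared only with values produced the same way.
* `Ca_ZPG` inference rests on 4 treatment means; its SE and CI are
  asymptotic and should be read qualitatively at that sample size.
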