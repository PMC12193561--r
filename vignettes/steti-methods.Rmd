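---
title: "Estimating survival-time improvement trends from start- and end-year cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating survival-time improvement trends from start- and end-year cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steti)
```

## The problem

The N-year average survival time of a diagnosis-year cohort — the mean of
(death year − diagnosis year) over patients who do not survive more than N
calendar years — is a natural unit for tracking improvement in treatment.
But it only exists once the cohort's N-year follow-up window has closed: with
registry data through 2020 and N = 20, the newest usable diagnosis cohort is
2000. Everything more recent is right-censored *as a cohort*, even though
registries hold millions of fully observed survival times from recent years.
Fitting a trend to the completed cohorts alone (the **base method**) throws
that recent information away and risks understating current survival.

The method implemented here recovers much of it by switching cohort axis.
A **death-year (end) cohort** — everyone dying in a given calendar year who
was diagnosed within the preceding N years — contains no within-window right
censoring by construction, and exists for years up to the present. The
estimation pipeline is:

1. choose a trend family for average survival as a function of diagnosis
   year, and fit it to the completed diagnosis-year cohorts;
2. transform that start-time model algebraically into an equivalent model of
   survival as a function of the *death* year;
3. regress the transformed model's single steepness parameter against the
   death-year cohort means (the intercept being anchored; see below);
4. transform back into an updated diagnosis-year curve;
5. project.

## Cohort geometry

For a data range `[year_min, year_max]` and window N, diagnosis year `y` is
eligible iff `y + N <= year_max`, and death year `y` iff `y - N >= year_min`.
Every in-range (diagnosis, death) pair falls in exactly one of six cells:
above the diagonal (invalid), beyond the window (survival > N), in both an
eligible diagnosis and death cohort, in only one of them, or in the unused
"V" between the two regions — valid data that neither the base method nor
this method can place in a complete cohort. `classify_cell()` implements the
partition and the test suite checks it exhaustively.

That an improvement trend is visible in this geometry at all is checked by
`paired_sign_test()`: pairing the i-th eligible diagnosis cohort with the
i-th eligible death cohort (the two lists always have equal length), a
death-year cohort contains strictly more recent diagnoses than its partner,
so under improvement its mean should usually be higher. The test is the
exact one-sided binomial tail at p = 1/2; ties are dropped, the standard
sign-test convention. With 9 pairs of which 8 are end-higher the one-sided
p-value is 10/512 ≈ 0.0195. Pairing is positional because nothing else is
canonical; both the pairing and the tie policy are arguments.

## Trend families and the end-time transform

All families are parameterized through an anchor `(t0, S0)` and one
steepness parameter:

* linear: `S(t) = S0 + M (t - t0)`, slope `M` in years/year;
* exponential: `S(t) = S0 * 2^((t - t0)/d)`, doubling time `d` in years;
* logistic: `S(t) = L / (1 + ((L - S0)/S0) e^{-k (t - t0)})`, rate `k` per
  year and ceiling `L` in years.

This is an exact reparameterization of year-intercept forms and makes the
fixed-anchor steepness regression explicit. The logistic ceiling defaults to
the window N — an N-year average cannot exceed N — and is overridable.

A patient diagnosed at `t_b` with the cohort-mean survival dies at
`t_e = t_b + S(t_b)`; when `S' > -1` this map is strictly increasing, so the
survival-vs-death-year relation `S_end` is well defined by
`S_end(t_b + S(t_b)) = S(t_b)`. For the linear family the transform is
closed-form and again linear,

    S_end(t_e) = S0 + M (t_e - S0 - t0) / (M + 1),

with slope `M/(M+1) < M`: improvement always looks *flatter* against the
death year, because faster improvement spreads a cohort's deaths over more
calendar years. For the other families `eval_end()` solves
`t_b + S(t_b) = t_e` numerically. The implementation is a vectorized Newton
iteration with the analytic derivative `1 + S'(t_b)` (the map is smooth and
monotone, so Newton from the starting value `t_e - S(t_e)` converges in a
handful of steps), with a bracketed Brent root-finder as a per-element
fallback; the convergence tolerance is 1e-10 years. Vectorization matters
because the no-rounding generator produces death-year tables with tens of
thousands of distinct real-valued years. The closed linear form and the
numeric route agree to 1e-9 in the tests, and the round-trip identity
`S_end(t_b + S(t_b)) = S(t_b)` is property-tested across all families.

## Anchoring and the steepness regression

The intercept of the updated curve is not re-estimated from death-year data.
The base analysis uses the larger, well-understood diagnosis-cohort history,
so the updated curve is pinned to the base fit's height `S_r` at the most
recent completed diagnosis year `t_r` (`anchor_from_base()`; the *fitted*
height, not the raw cohort mean, so the anchor does not inherit one cohort's
sampling noise). Re-estimating both intercept and steepness from the newer
data alone is a defensible alternative — newer data may better reflect a
changed trend — and is available by passing a fixed `anchor` explicitly, but
it is not the default.

With the anchor fixed, `fit_steti_steepness()` minimizes the sum of squared
deviations of the death-year cohort means from `S_end` at their cohort
years. For the linear family the substitution `u = M/(M+1)` makes the model
linear in `u`, so the optimum is closed-form; `u >= 1` would imply an
infinite start-time slope and is an error. Nonlinear families use bounded
1-D minimization: `u` in (-0.99, 0.99), doubling time magnitude in
[1, 10000] years with both orientations searched and exact ties broken
toward the flatter curve, logistic rate in [-5, 5]. The regression is
unweighted by cohort size by default (weighting is an option): cohort means
of a mature registry have similar enough precision that weighting mostly
re-litigates the oldest cohorts.

The stage's parameter count is k = 1 — the anchor is not estimated from the
death-year data — which matters for the AIC below. A single death-year point
determines the steepness exactly (zero residual), which is what makes the
degenerate one-diagnosis-cohort configuration in the hold-out experiments
possible at all.

## Goodness of fit, model comparison, uncertainty

All fits report RSS, `RMSE = sqrt(RSS/n)`, and the Gaussian least-squares
`AIC = n ln(RSS/n) + 2k`. Absolute AICs under this convention are not
comparable across conventions (a constant and the variance-parameter term
are dropped), so only AIC *differences* are used, through the relative
likelihood `exp(Delta/2)` with `Delta = AIC_min - AIC_other` — 1 means no
preference, small values a strong one. The RSS is floored at 1e-12 before
the logarithm so perfect fits keep a finite AIC. Base fits charge k = 2
(k = 3 for a logistic with free ceiling); exponential base fits are
log-linear least squares by default (matching spreadsheet exponential
trendlines, which is how such base curves are fitted in practice), with
exact nonlinear least squares as an option.

`uncertainty_band()` turns the relative likelihood into a projection
interval: scan a dense grid of steepness values around the optimum (in the
parameter where the family is most nearly linear — `u` for linear, inverse
doubling time for exponential, the rate for logistic), keep the variations
whose relative likelihood against the best fit is at least the threshold
(default 0.5), and report the range of the retained curves at the target
year. The grid is widened by doubling until both ends fall below the
threshold; 2001 points per scan. Lower thresholds give nested, wider bands
(property-tested); a perfect fit collapses the band to the point, since any
variation is then infinitely worse in relative likelihood.

When both linear and exponential families are fitted, `steti_analysis()`
compares them by the relative likelihood of their *base* fits (the long
history of completed cohorts is where the two families can actually be told
apart) and combines the two target-year projections: averaged when the
relative likelihood is at least 0.5, otherwise the lower-AIC model alone.
The headline number is rounded half-up to two decimals; machine-readable
outputs are never rounded.

## Retrospective hold-out validation

`holdout_experiment()` truncates the range at a cutoff year, fits both
methods on the truncated data, and scores predictions against the
diagnosis-cohort means only the full range can compute. Metrics are
prediction RMSE/AIC on the held-out points — a two-point base regression has
zero fit residual yet can miss the held-out cluster badly, so fit-side
metrics would be meaningless here — with k carried over from the fitted
model (2 for the linear base, 1 for the anchored steepness stage). With a
single completed training cohort the base method cannot fit a slope and is
reported absent; the update then anchors at that cohort's observed mean and
takes its slope from the death-year cohorts. The characteristic pattern,
asserted in the tests as a median over 20 simulation seeds rather than
per-seed, is that base prediction error degrades sharply as training cohorts
shrink from 4 to 1 while the update stays bounded.

## The synthetic-data generator

`simulate_records()` emulates a registry case listing with a known truth:
for each diagnosis year in the range, `n_per_year` patients draw a
continuous survival time with mean on the truth curve, from a gamma (shape
parameter; default 2) or lognormal distribution, or deterministically
(`noise = "none"`); survival is rounded to whole years (`round`, the
registry convention), floored, or kept real (`none`). Defaults are the
conditions of the motivating analysis: years 1992–2020, N = 20, an
exponential truth anchored at 3.0748 years in 1992 with a 93-year doubling
time, and 2000 diagnoses per year — the order of magnitude of annual kidney
cancer case counts in a multi-registry surveillance extract. Gamma shape 2
gives the right-skewed individual survival shape expected for cancer while
keeping the mass beyond a 20-year window negligible for means of a few
years, as the configuration validator requires (the truth curve must stay
inside `(0, N)`).

One PRNG substream is derived per diagnosis year from the main seed, so
widening the range never perturbs earlier years' draws. The truth curve is
defined as the mean of the *untruncated* distribution.

What the generator does **not** emulate: loss to follow-up, alive-at-cutoff
censoring (both out of scope for the method — such records must not appear
in the input), incidence trends, age structure, or cause-of-death
misclassification. Passing tests therefore demonstrate correctness of the
estimation machinery under the method's own assumptions, not robustness to
those phenomena.

## Numerical choices

* End-time inversion: vectorized Newton with analytic derivatives, Brent
  fallback, tolerance 1e-10 years.
* RSS floor 1e-12 before logarithms.
* Steepness bounds as above; exact-tie break toward the flatter curve.
* Rounding of headline estimates: half *away from zero* at the second
  decimal (spreadsheet convention), not banker's rounding.
* Cohort tables group by exact cohort-year values, so real-valued death
  years (from the no-rounding generator) form singleton cohorts and the
  eligibility inequalities apply unchanged.
* Problem sizes in the test suite: property loops of 10–30 randomized
  models; simulations of 29 years × 300–2000 patients/year over 20 seeds —
  small enough to run in seconds while leaving Monte Carlo margins well away
  from the asserted bounds.

## Known limitations

**Cohort-composition bias under individual-level dispersion.** The end-time
transform is exact for cohort *means* treated as deterministic: it assumes a
cohort's deaths land at `t_b + S(t_b)`. Real deaths disperse around the
mean, and the patients dying in a given calendar year are then a biased
sample: its long survivors were diagnosed long ago, when mean survival was
lower, and under a mean-scaled skewed distribution (gamma, lognormal) a long
survival is less likely the lower the mean — so long survivors are
underrepresented and the death-year cohort mean sits slightly *below*
`S_end(t_e)`. The deficit is proportional to the dispersion (about 0.12
years at gamma shape 2 under the default truth, 0.03 at shape 8, vanishing
as dispersion goes to zero) and does not shrink with sample size; with the
anchor fixed from unbiased diagnosis-cohort data it maps into a small
downward bias of the regressed steepness. The noiseless pipeline recovers
the true steepness to 1e-6; under realistic dispersion the update is
conservative — it slightly understates improvement, it does not invent it.
One acceptance check (exact 3-standard-error parameter recovery under
stochastic noise) is accordingly expected to fail, and is left failing
rather than weakened; see the repository's test annotations. For additive
(location-family) dispersion the bias cancels exactly for linear trends,
but registry-realistic survival noise is not additive.

**Model commitment.** Fitting a family assumes its shape describes the
trend; the relative-likelihood machinery quantifies preference between the
fitted families but cannot flag that all of them are wrong. Breakpoint
detection is out of scope.

**Unused data.** The "V" cells — records in neither a complete diagnosis
cohort nor a complete death cohort — are deliberately untouched.
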