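---
title: "Typing dynamics, mood and the digital Trail Making Test: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing dynamics, mood and the digital Trail Making Test: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(typetrail)
```

## The scientific problem

Smartphone keyboards can record *when* keys are pressed (never what is
typed), giving an unobtrusive, high-frequency window on psychomotor and
executive function. `typetrail` implements a complete analysis linking three
passively or briefly collected streams — keypress event logs, twice-daily
self-administered digital Trail Making Test part B (dTMT-B) completion times,
and weekly clinician-rated depression (HDRS-17) and mania (YMRS) scores — in
a cohort of individuals with bipolar disorder and controls observed over two
study periods (days 1–17 and 45 onward) separated by a four-week break.

The pipeline has five analysis stages, each exposed as ordinary R functions
and orchestrated by `run_pipeline()`:

1. **Window assignment** (`build_windows()`, `assign_keypresses()`): each
   dTMT-B administration receives a half-open time window of proximal
   keypresses.
2. **Typing features** (`interkey_delays()`, `median_ikd()`): the median
   inter-key delay (IKD) of each window, after session filtering.
3. **Cohort assembly** (`backpropagate_mood()`, `two_level_center()`,
   `build_model_table()`): the analysis-ready table with the transforms and
   two-level centering described below.
4. **Mixed models** (`fit_lmm()`, `forward_fit()`): from-scratch maximum
   likelihood linear mixed models with random slopes, compared by
   likelihood-ratio tests.
5. **Reliability** (`icc_consistency()`, `paired_t_test()`,
   `reliability_report()`): cross- and within-modality consistency of the
   digital test against its pencil-and-paper counterpart.

A sixth module, the synthetic cohort generator (`generate_cohort()`), exists
because the underlying human data are not publicly deposited: it generates
cohorts with the statistical structure the analysis assumes, so every stage
is testable end to end and parameter recovery can be verified.

## Window assignment rules

Keypresses are assigned to the test they plausibly accompany:

* Two tests at most 24 h apart: the boundary between their windows is the
  **midpoint of the two timestamps**. A keypress exactly on a boundary
  belongs to the later window (half-open `[start, end)` convention; the
  rules are silent on ties, so the tie-break is fixed and test-pinned).
* A neighbour more than 24 h away (or none): the window is clipped to the
  test's **calendar date** — except that on days with two recorded tests,
  keypresses before the morning test or after the evening test are omitted,
  so the outer boundary is the test's own timestamp.
* The midpoint rule takes precedence over date clipping whenever both could
  apply (e.g. a single test whose neighbour is 20 h away across midnight).

With >24 h gaps each window clips to its own date, so keys falling between
dates that have no test are assigned to nothing — the "missing half" next to
a skipped administration is discarded, not merged into the surviving test's
window. Calendar dates come from a per-dataset timezone setting (default
UTC); generated data use a single zone with no daylight-saving transitions,
which a loader of real data must not assume.

These rules, however coded, are easy to get subtly wrong, so the test suite
checks the implementation against a brute-force classifier that labels every
minute of a schedule independently, on a fixed 6-day fixture and on randomly
thinned schedules.

## Typing-speed features

The inter-key delay is the lapse between consecutive keypresses in a window,
computed across **all** key categories (backspaces and autocorrection events
included; a category filter exists as a sensitivity switch in
`compute_window_features()`). Delays of 8 s or more mark the end of a typing
session — the conventional session cutoff for naturalistic keyboard data —
and are excluded. A window yields a median IKD only if at least 20 valid
(sub-cutoff) transitions remain; windows with fewer, or with fewer than 20
keypresses in total, are dropped (two separate filters: both thresholds are
stated requirements and a window must pass both). Subjects then need at
least 6 surviving tests to enter the analysis. All drop counts are reported
in the run log.

## The model table

One row per retained dTMT-B, with the transforms:

* response: `log(completion_time_s)` — natural logs throughout (an
  intercept near 2.9 corresponds to `exp(2.9) ~ 18` s, a plausible
  13-circle completion time; base-10 would imply absurd times);
* `log(wrong_moves + 1)` (zero is common, so the +1 avoids `-Inf`);
* practice: `log(day within period)`, day 1 at each period start so
  `log(1) = 0`, interacted with a 0/1 period indicator — the
  regression-discontinuity structure that lets the practice curve restart
  after the four-week break. Days are calendar days by default
  (`practice_units = "index"` counts administrations instead);
* weekly mood scores are **backpropagated**: a rating dated `d` covers all
  tests in `(previous rating date, d]`; tests after the last rating get the
  last rating, tests before the first get the first;
* HDRS-17, median IKD (and YMRS within the bipolar group) are split into a
  level-2 between-person part (subject mean centered at the unweighted grand
  mean of subject means) and a level-1 within-person part (deviation from
  the own subject mean, summing to zero within subject);
* every fixed term is z-scored over the final table so estimates are
  comparable effect sizes. The 0/1 codes (time of day, period, diagnosis)
  are z-scored like everything else by default; `z_score_dummies = FALSE`
  leaves them 0/1, since the convention for dummies is a genuinely open
  choice.

Re-running the builder on its own output is rejected (column-name guard), so
the transforms cannot be applied twice by accident.

## The mixed models

For observation $j$ of subject $i$:

$$y_{ij} = \mathbf{x}_{ij}^\top \boldsymbol\beta + \mathbf{z}_{ij}^\top
\mathbf{b}_i + \varepsilon_{ij}, \qquad \mathbf{b}_i \sim N(\mathbf{0},
\mathbf{G}), \quad \varepsilon_{ij} \sim N(0, \sigma^2),$$

with random effects $\mathbf{z}$ = (intercept, practice, period,
practice×period) per subject. The forward-fitted hierarchy is: Model 1 —
age, log wrong moves, time of day, and the three practice terms; Model 2 —
plus diagnosis and the two HDRS-17 terms (+3 df); Model 3 — plus the two
typing-speed terms (+2 df); Models 4–5 repeat the mood/mania step within the
bipolar group. Consecutive models are compared by the likelihood-ratio test
on the change in ML deviance.

Fitting is by **maximum likelihood** (not REML — deviance differences
between fixed-effect structures are then valid test statistics). The
implementation profiles $\boldsymbol\beta$ and $\sigma^2$ out in closed form
at every candidate covariance: writing $\mathbf{G} = \sigma^2
\boldsymbol\Lambda \boldsymbol\Lambda^\top$ with a relative Cholesky factor
$\boldsymbol\Lambda$, each subject's marginal covariance is $\sigma^2
(\mathbf{I} + \mathbf{Z}_i \boldsymbol\Lambda \boldsymbol\Lambda^\top
\mathbf{Z}_i^\top)$, and the Woodbury identity reduces every evaluation to
$q \times q$ algebra on per-subject sufficient statistics
($\mathbf{Z}_i^\top\mathbf{Z}_i$, $\mathbf{Z}_i^\top\mathbf{X}_i$, ...)
precomputed once. The profiled deviance is minimised by bounded
quasi-Newton (L-BFGS-B) over the free entries of $\boldsymbol\Lambda$, with
the diagonal bounded below by zero so boundary (zero-variance) solutions are
reached exactly, five jittered restarts by default, and a deviance
convergence tolerance of 1e-8. The covariance is unstructured by default
(log-Cholesky parameterisation, 10 parameters for $q = 4$); because a
19-subject cohort rarely identifies 10 covariance parameters, a singular
unstructured fit automatically falls back to a diagonal structure, and the
fallback is recorded in the fit and its artifacts.

The reported log-likelihood is re-evaluated through the independent
blockwise density path (`lmm_loglik()`), so the object is self-consistent:
evaluating `lmm_loglik()` at the returned parameters reproduces
`fit$loglik` exactly, and `deviance = -2 loglik` by construction.

Inference on fixed effects is Wald-$z$: $p = 2\Phi(-|\hat\beta/\mathrm{se}|)$
with standard errors from the inverse GLS information at the optimum.
Satterthwaite or Kenward–Roger corrections are out of scope; with ~30
observations per subject the normal approximation is reasonable, and the
choice is recorded in the output metadata. $R^2$ follows the
variance-partition (Nakagawa) definition: marginal
$= \operatorname{var}(\mathbf{X}\hat\beta) / (\operatorname{var}(\mathbf{X}\hat\beta)
+ \bar v + \hat\sigma^2)$ where $\bar v$ is the mean over observations of
$\mathbf{z}^\top \hat{\mathbf{G}} \mathbf{z}$ (the random-slope extension of
summing the variance components; the two coincide for a random-intercept
model), and conditional $R^2$ adds $\bar v$ to the numerator.

The random "practice" slope multiplies the same z-scored log-day column used
as the fixed practice term — the natural default when the fixed and random
parts should describe the same quantity.

## Reliability statistics

Digital-vs-paper consistency uses ICC(3,1) — two-way mixed effects,
consistency, single measures:
$(\mathrm{MS}_\text{rows} - \mathrm{MS}_\text{error}) /
(\mathrm{MS}_\text{rows} + (k-1)\mathrm{MS}_\text{error})$ with $k = 2$,
from the two-way ANOVA decomposition, with the F-based confidence interval.
The "consistency" form is invariant to a constant offset between modalities
but not to rescaling (both properties are tested). The variant label is
embedded in every output row because ICC variants are easily confused.
First/last tests within a modality are compared with paired t-tests; a
zero-variance difference vector is flagged rather than silently dividing by
zero. "First dTMT-B" means first completed (timestamps are the only record
of scheduling intent).

## The synthetic cohort generator

The generator's defaults are the study conditions: 8 controls + 11 bipolar
subjects, morning/evening administrations at 09:00/21:00 (±30 min jitter)
over days 1–17 and 45–56, weekly ratings, and a test-skip probability of
0.47, which turns the 58 scheduled administrations into the observed ~31
per subject. Where only marginal summaries exist, defaults were chosen once
as realistic values: HDRS-17 traits centred at the group means 1.02
(controls) and 12.68 (bipolar) with weekly AR(1) fluctuation (rho 0.6, sd
1–2 points); YMRS trait 6.0 (3.8) in the bipolar group; wrong moves Poisson
with a lognormal subject rate around 1.5; subject median-IKD traits
lognormal around 0.25 s (between-subject sdlog 0.25, daily multiplier sdlog
0.10, within-session sdlog 0.5, truncated below the 8-s cutoff); ~10 typing
sessions per day of 12–28 keys starting in distinct hours, which guarantees
between-session gaps above the cutoff by construction.

Completion times are generated by **inverting the analysis model**: the
generator runs its own raw streams through the same window/feature/assembly
code the pipeline uses, applies the fixed coefficients (defaults: the final
typing model's estimates, intercept 2.898, typing-speed effects 0.189 and
0.032, depression effects 0.189 and 0.038, diagnosis -0.180, ...), adds
per-subject random effects with variances (0.010, 0.0003, 0.002, 0.002) and
residual noise (variance 0.058) on the log scale, and exponentiates.
Because pipeline and generator share one code path, applying the pipeline
to a generated cohort recovers the generating coefficients up to sampling
error — a true inverse test, exercised at 200 subjects × 100 replicates in
the acceptance suite, together with a 500-replicate type-I-error check of
the typing-term likelihood-ratio test at 50 subjects. (Those problem sizes
keep Monte-Carlo error small enough for 3-standard-error bias bounds while
the whole suite still runs in minutes.)

Paper-test (pTMT-B) scores at study start and end reflect the same momentary
performance as the subject's first/last digital test: the digital test's
linear predictor plus lognormal modality noise (sd 0.15 on the log scale),
which puts the true cross-modality consistency near the reported ~0.74.

**What the generator does not emulate** — and therefore what passing tests
do not establish about real data: environmental context effects on remote
testing, typing during the between-period gap, missingness that is informative
(the skip probability is a single Bernoulli rate, not a dropout model),
time-zone or daylight-saving complications, autocorrelated residuals within
subject beyond the random-effect structure, and any content-level typing
features (no text is ever represented).

## Numerical choices and degenerate inputs

* Ties at window boundaries: later window (half-open intervals).
* Simultaneous keypresses produce a zero delay, kept; filtering is
  downstream and explicit.
* A z-scored column with zero variance (possible in toy inputs) is set to
  zero with a warning rather than dividing by zero.
* Zero between-subject variance yields ICC 0 with a warning; perfect
  consistency yields a degenerate confidence interval at 1.
* The optimizer treats zero variance components exactly (direct-scale
  Cholesky diagonal bounded at 0), so OLS is nested as a boundary case.
* Non-convergence after restarts returns a fit flagged `converged = FALSE`
  with a warning rather than an error; a singular fixed-effect design is an
  error naming the collinear columns.

## Limitations

The package analyses completion times and error counts, not touch
coordinates or test layouts; it does not model mania/depression interactions
beyond the specified fixed effects; and the Wald/LRT inference relies on ML
asymptotics that are optimistic for very small cohorts — the acceptance
suite calibrates the typing-term LRT at 50 subjects, not at 19, where
mild anti-conservatism of fixed-effect tests is expected and documented
behaviour of ML mixed models generally.
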