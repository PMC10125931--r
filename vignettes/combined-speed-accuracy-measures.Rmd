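---
title: "Combined speed–accuracy measures and their diffusion-model validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined speed–accuracy measures and their diffusion-model validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satscores)
```

## The problem

Participants in speeded two-choice tasks choose a setting on the
speed–accuracy trade-off (SAT) continuum: responding faster costs accuracy.
When two conditions (or two groups) settle on different SAT settings, mean
response time (mean RT) and proportion correct (PC) shift *together* — one
condition looks slower but more accurate — and neither dependent variable
alone can tell a genuine difficulty or ability effect from a mere criterion
shift.  Combined performance measures address this by integrating mean RT
and PC into a single score per participant-by-condition cell.  This package
implements the main candidates, simulates ground-truth data in which the
nature of the effect is known by construction, and quantifies how each
measure reacts.

A useful conceptual anchor is the classic exponential speed–accuracy curve
(`wickelgren_pc()`): below an x-offset `delta` responding is guessing
(PC = 50% for two alternatives), beyond it PC rises as
$\frac{\lambda}{2}\left(1-e^{-\gamma(\overline{RT}-\delta)}\right)+50$
towards the asymptote $\lambda/2+50$.  A SAT shift moves a responder *along*
this curve, affecting speed and accuracy simultaneously.

## The measures

Let $\overline{RT}_{ij}$ and $PC_{ij}$ be the mean correct-trial RT and the
proportion correct of participant $i$ in condition $j$, and
$PE_{ij} = 1 - PC_{ij}$.

**BIS** (Balanced Integration Score, `bis()`):
$BIS_{ij} = z(PC_{ij}) - z(\overline{RT}_{ij})$, each constituent
z-standardized with the mean and SD computed **across the aggregated
participant-by-condition cells** of the experiment (the "standardization
scope", `measure_context()`).  Higher is better; the scores sum to zero over
the scope and are invariant to positive affine transformations of RT or PC.
`bis_rt_scaled()` maps BIS back to the millisecond scale,
$\overline{\overline{RT}} - S^{\overline{RT}} \cdot BIS_{ij}$, without
changing any contrast.

**LISAS** (Linear Integrated Speed–Accuracy Score, `lisas()`):
$LISAS_{ij} = \overline{RT}_{ij} + \frac{S_i^{RT}}{S_i^{E}}\, PE_{ij}$,
where $S_i^{RT}$ and $S_i^{E}$ are participant $i$'s **trial-level** SDs of
correct-trial RT and of the 0/1 error indicator, pooled over all of that
participant's conditions.  `lisas_cond()` computes both SDs within each cell
instead.

**LISAS^BIS** (`lisas_bis()`) replaces the trial-level SD ratio by the ratio
of across-cell SDs of the aggregated data,
$\overline{RT}_{ij} + \frac{S^{\overline{RT}}}{S^{PE}}\, PE_{ij}$.
Algebraically this is `bis_rt_scaled()` plus the per-experiment constant
$\frac{S^{\overline{RT}}}{S^{PE}}(1-\overline{PC})$, so it behaves exactly
like BIS while staying on the RT scale — which isolates the *standardization
variance*, not the scale, as the property that matters.

Baselines: the Inverse Efficiency Score $IES = \overline{RT}/PC$ (`ies()`)
and the Rate Correct Score, correct responses per total RT in the cell
(`rcs()`).

The central design question these measures answer differently is **which
variance standardizes the error term**: BIS uses the spread of the
aggregated cell means — the data points that actually enter a t test or
ANOVA — whereas LISAS uses raw trial-level spread.  Trial-level RT SDs are
dominated by the shape of the single-trial RT distribution and scale
differently from the SD of cell means, so the two choices weight the error
component very differently.

## Simulating ground truth with a diffusion model

Data are generated from a two-boundary Wiener diffusion: evidence
$X(t) = W(t)\,\sigma + v\,t$ accumulates from $a/2$ until it crosses the
upper threshold $a$ (correct) or 0 (error); the crossing time plus a
non-decision time $t^{ER}$ is the RT.  The model separates the two causal
routes cleanly:

* **drift rate `v`** — higher drift is *faster and more accurate*: a genuine
  difficulty/ability effect;
* **threshold separation `a`** — a wider threshold is *slower and more
  accurate*: a pure SAT shift.

`simulate_trials()` integrates the process by Euler–Maruyama with step
`dt = 1` ms by default (millisecond RT resolution; the whole reference study
runs in minutes on one core).  Correctness is guarded by closed-form
oracles rather than by a tiny step:

* `analytic_accuracy()`:
  $P(\text{correct}) = \frac{1-e^{-2 v\, start/\sigma^2}}{1-e^{-2 v a/\sigma^2}}$;
* `analytic_mean_dt()` (midpoint start):
  $\frac{a}{2v}\tanh\!\left(\frac{va}{2\sigma^2}\right)$.

Discrete-time monitoring misses boundary crossings inside a step, which
biases decision times and accuracy slightly upward.  The effect is
well-described by the standard continuity correction in which each boundary
moves outward by $0.5826\,\sigma\sqrt{dt}$; the test suite checks the
simulator against the corrected closed forms at `dt = 1` and verifies that
the residual bias shrinks as `dt` is reduced.  At the reference parameters
(`v = 0.25`, `a = 125`, `sigma = 4`) the bias is about +11 ms in mean RT
and +0.008 in accuracy — part of the generative definition of the reference
conditions, not noise.  Trials not absorbed within `max_steps = 20000` steps
raise an error in library use and are dropped (and counted) in study mode;
at the reference parameters none occur.

## The within-participants design generator

`design_spec()` describes a two-condition within-participants experiment.
One focal parameter (drift or threshold) takes baseline values $\mu_1,
\mu_2$ and is realized per cell as
$\mu_{ij} = \mu_j + \epsilon_i^{between} + \epsilon_{ij}^{within}$, with
$\epsilon^{between}\!\sim N(0,\sigma_B^2)$ shared by both conditions of a
participant (stable individual differences) and
$\epsilon^{within}\!\sim N(0,\sigma_W^2)$ independent per cell (the
participant-by-condition error term a paired t test works against).  The
implied between-condition correlation of the parameter is
$r = \sigma_B^2 / (\sigma_B^2 + \sigma_W^2)$
(`theoretical_correlation()`), which the generator reproduces empirically —
realistic within-participants data are *highly correlated* across
conditions, and simulations that omit $\sigma_B^2$ misrepresent the design
they claim to study.

Reference conditions (the defaults of `design_drift_effect()` and
`design_sat_effect()`):

| setting | drift design | SAT design |
|---|---|---|
| focal parameter | $v$: 0.246 vs 0.254 | $a$: 120 vs 130 |
| fixed parameter | $a = 125$ | $v = 0.25$ |
| $\sigma_B^2$, $\sigma_W^2$ | $0.01^2$, $0.005^2$ | $20^2$, $10^2$ |
| implied $r$ | .80 | .80 |
| noise scale $\sigma$ | 4 | 4 |
| $t^{ER}$ | $N(300, 20^2)$ ms per participant | same |
| size | 20 participants × 2 × 1000 trials | same |

The non-decision-time spread is written here explicitly as an SD of 20 ms:
variance components elsewhere in the design carry explicit squares
($\sigma_B^2 = 20^2$), so an unsquared 20 is read as an SD; `t_er_sd` is a
knob for sensitivity analyses.  Realizations that would be invalid for the
diffusion ($\mu_{ij} \le 0$, $t^{ER} < 0$) are redrawn cell-wise; at the
reference settings this is a measure-zero safeguard, not a distortion.

## The Monte-Carlo harness

`run_study()` repeats generate → `aggregate_trials()` →
`compute_measures()` → `paired_t()` across `n_experiments` independent
experiments and reports, per measure: mean condition means, mean
$d_z = t/\sqrt{n}$, the percentage of significant two-sided paired t tests
at $\alpha = .05$, and the mean/min/max between-condition correlation.
Two-sided tests are used (the field default for this design).  The sign
convention is condition 1 minus condition 2 throughout.

One master seed drives everything: per-experiment sub-seeds are drawn
up-front, so experiment $k$ is reproducible in isolation and a study prefix
is bit-identical to a shorter study (the suite tests this).  Experiments in
which a statistic is degenerate (possible only at toy sizes, e.g.
single-trial cells) are logged, excluded and counted.

The package default is `n_experiments = 200`.  At the reference conditions
that is 8 million diffusion trials per study — a few minutes on one core —
and gives binomial Monte-Carlo error of about ±1.8 points (1 SE) on a
percentage near 7% and ±2.8 near 80%; raise it for tighter estimates.

```{r small-study}
cfg <- study_config(design_sat_effect(n_participants = 8, n_trials = 100),
                    n_experiments = 20, seed = 7)
run_study(cfg)
```

(The chunk above is deliberately miniature; the reference-scale runs live in
the test suite and in `scripts/acceptance.R`.)

## What the validation shows — and a power caveat on trial counts

Under the reference conditions the qualitative pattern is sharp: a pure
threshold (SAT) manipulation produces large, mostly significant effects on
mean RT, PC, LISAS and LISAS^cond, while BIS (and LISAS^BIS, its affine
image) stays near $d_z \approx 0$ with a significance rate close to the
nominal $\alpha$; a drift manipulation is preserved by all measures, and
the combined measures are *more* often significant than either constituent
because they pool an effect that is distributed over speed and accuracy.
Under a null design every measure's significance rate calibrates to
$100\alpha$.

One quantitative point deserves emphasis, because it governs how results
scale with the number of trials per cell $m$.  PC is a mean of $m$
Bernoulli trials, so its cell-level sampling variance is at least
$p(1-p)/m$, and the paired effect size for a PC difference $\Delta p$ is
bounded by
$d_z \lesssim \Delta p \big/ \sqrt{2\,p(1-p)/m}$
even with *zero* parameter variability in the error term.  At $m = 1000$,
$p \approx .885$ and $\Delta p = .0068$ (the drift design), that bound is
about 0.47; mean-RT effect sizes are limited analogously by the trial-level
RT SD ($\approx$ 150 ms here), and the between-condition correlation of
mean RT is pushed down by the same per-cell sampling variance.  Reported
effect sizes or correlations materially above these bounds imply a larger
effective trial count.  The package makes the dependence explicit —
`n_trials` is a first-class design field — and the harness reports what the
stated conditions actually deliver.

## Numerical conventions and edge cases

* **SD convention**: sample SDs ($n-1$) everywhere, for trial-level and
  across-cell SDs alike (`sd_method = "population"` is available).  BIS
  contrasts are invariant to this choice; LISAS values shift slightly.
* **Zero-error participants**: $S_i^E = 0$ makes the LISAS error term 0/0;
  since $PE_{ij} \to 0$ faster than $S_i^E$, the term is defined as 0 and
  LISAS reduces to mean RT.
* **Degenerate variance**: BIS requires positive across-cell SDs of both
  constituents and refuses to standardize otherwise.
* **PC vs PE**: $z(PC) = -z(PE)$ exactly (identical SDs); BIS is computed
  from PC, and the identity is covered by a test.
* **RT SDs for LISAS** use correct trials only, matching the measure's use
  of mean *correct* RT (`rt_sd_trials = "all"` is available for sensitivity
  checks).
* **Aggregation requires at least one correct trial per cell** for the mean
  correct RT to exist; violations raise an error naming the cell.

## What the generator does and does not emulate

The simulator reproduces the features that matter for the SAT question:
realistic RT distributions from a first-passage process, a tunable split of
between- vs within-participant variance, shared non-decision time across
conditions, and effects injected through interpretable parameters.  It does
**not** include across-trial variability in drift, start point or
non-decision time (the full Ratcliff extensions), biased starting points,
contaminant/outlier RTs, sequential effects between intermixed trials, or
more than two conditions.  Passing the validation therefore shows that the
measures behave as designed *when the generating process matches these
assumptions*; with empirical data, additional steps (outlier treatment,
model-fit checks) remain the analyst's responsibility, and fitting the
diffusion model itself is outside this package's scope.
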