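---
title: "Prediction intervals in random-effects meta-analysis: model, design, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prediction intervals in random-effects meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapi)
```

## The model

`metapi` works with the two standard meta-analysis models. The
fixed-effect (FE) model assumes one common true effect $\theta$ behind all
$k$ studies, so the observed estimates $y_i$ differ only by sampling
error: $y_i \sim N(\theta, se_i^2)$. The random-effects (RE) model adds a
between-study level,

$$\theta_i \sim N(\theta, \tau^2), \qquad y_i \sim N(\theta_i, se_i^2),$$

and its pooled estimate targets $\theta$, the mean of the distribution of
true effects. The FE model is the RE model with $\tau^2 = 0$, and the
package treats it that way: `pool_random()` with the between-study
variance forced to zero reproduces `pool_fixed()` exactly.

All arithmetic happens on a linear analysis scale. Ratio measures (odds
ratios here) enter as log odds ratios, because approximate normality —
the assumption both the pooling and the prediction interval lean on —
holds on the log scale; exponentiation is purely presentational.

Heterogeneity is quantified by Cochran's $Q$ (weighted squared deviations
from the FE pooled value, $df = k - 1$), the DerSimonian–Laird moment
estimator $\hat\tau^2$ (truncated at zero, as is standard), and
$I^2 = \max(0, (Q - df)/Q)$, the share of total variability attributable
to heterogeneity. $I^2$ is computed from $Q$ directly rather than from
$\hat\tau^2$ over a "typical" within-study variance; the two agree in the
usual regimes and the $Q$ form needs no extra convention.

## The prediction interval

The confidence interval of the pooled effect answers "how precisely is
the *average* effect estimated?". Under heterogeneity a distinct question
matters: "where will the *true effect of a new study* lie?" The package's
answer is the t-based prediction interval

$$\hat\theta \pm t_{1-\alpha/2;\,k-2}\,\sqrt{\hat\tau^2 + \widehat{SE}(\hat\theta)^2},$$

implemented in `prediction_interval()`. Design choices:

* **Degrees of freedom are exactly $k - 2$.** Consequently $k \ge 3$ is a
  hard requirement and smaller $k$ is an error, not a silent fallback —
  with one degree of freedom already spent on the mean and one standing in
  for the estimation of $\tau$, there is nothing sensible to fall back to.
* **The CI uses the normal quantile** (Wald), not a Knapp–Hartung
  adjustment. This matches how the package back-solves published
  summaries, where reported CIs are almost always z-based.
* **$\hat\tau^2$ is DL by default but overridable.** Published analyses
  print $\hat\tau$; `pi_from_summary()` accepts it directly (squaring
  internally) so a published chain can be reproduced without per-study
  data. `se_from_ci()` back-derives the pooled standard error from a
  reported interval as $(upper - lower)/(2 z_{1-\alpha/2})$ on the log
  scale.
* **No p-value is attached to a prediction interval.** The PI describes
  dispersion of true effects; statistical significance of the pooled
  effect is judged from the CI alone, and the API enforces the
  distinction. Likewise `run_config()` refuses a PI under the FE model:
  the quantity the PI describes is exactly what that model assumes away.
* Display rounds ratio-scale bounds to 2 decimal places, the convention
  for ratio measures.

Worked end-to-end: a pooled OR of 0.34 with 95% CI (0.22, 0.53),
$\hat\tau = 0.4$ and $k = 8$ gives

```{r}
pi_from_summary(0.34, c(0.22, 0.53), tau = 0.4, k = 8)
```

## Effect-size inputs

`log_odds_ratio()` converts 2×2 tables with the usual closed forms
($\ln(ad/bc)$, $se = \sqrt{1/a + 1/b + 1/c + 1/d}$). Zero cells get the
Haldane–Anscombe +0.5 added to **all four cells of the affected tables
only** — correcting unaffected tables would bias them for no reason — and
a `"strict"` mode errors instead, for users who prefer exclusion or
exact methods done elsewhere. Tables with zero events (or zero
non-events) in *both* arms carry no information about the odds ratio and
are always rejected, naming the offending study. Any other effect measure
enters through the generic effect/standard-error schema; the package
deliberately implements no further effect-size formulas.

## Forest plots

`build_forest_spec()` reduces a plot to data: study rows (estimate,
interval, weight), summary rows (glyph, extents), an axis description,
and a heterogeneity annotation ($\hat\tau$, $I^2$, $Q$ with df — printing
$\hat\tau$ rather than $\hat\tau^2$ keeps it on the effect scale).
Rendering that spec is then a pure function, which is what makes
golden-file testing possible: `render()` writes SVG with a fixed element
order and fixed number formatting, so identical specs yield byte-identical
files, and every glyph carries its data-scale coordinates in `data-*`
attributes so geometry can be verified by parsing the output.

Glyph conventions:

* Study squares have **area proportional to normalized weight** (side
  $\propto \sqrt{w_i}$).
* The pooled effect and its CI are the traditional diamond, labelled
  "Total expectation (95% CI)".
* The PI rectangle sits on its **own row**, labelled
  "95% prediction interval", at 0.6 of a row height, with **no centre
  tick**: the PI has a centre, but the glyph's job is to show a region of
  plausible true effects, not another point estimate. A rectangle also
  presumes nothing about the shape of the effect distribution, unlike a
  bell-curve overlay.
* The hollow-diamond and extended-diamond styles are retained for
  comparison figures, but the PI glyph is **never** the same symbol class
  as the CI diamond in any emitted plot — using one symbol for two
  different intervals is precisely the confusion the rectangle avoids.
* Axes: log scale with reference line at 1 for ratio measures (1-2-5 tick
  ladder), linear with reference at 0 otherwise. A non-positive value on
  a log axis aborts before any file is written.

`rectangle_rationale_demo()` animates the rectangle's justification:
dividing every within-study SE by an inflation factor shrinks the
per-study confidence lines toward points while the squares' spread —
genuine between-study dispersion — remains. Two numerical choices make
the limit clean: $\hat\tau^2$ is frozen at its original DL estimate
(re-estimating it on deflated SEs would let $Q$ explode and the estimate
drift), and the PI's pooled standard error is taken from the plain
inverse-variance combination, which vanishes as studies grow — the RE
pooled SE cannot serve here because it floors at $\sqrt{\tau^2/k}$. The
prediction interval then converges to $\hat\theta \pm t\,\hat\tau$, the
pure between-study band.

## The simulator and what the experiments show

`simulate_meta()` draws directly from the two-level normal hierarchy on
the linear scale — not via binomial 2×2 tables — because that hierarchy
is the model the prediction interval is derived under; simulating
binomial data would confound the PI's properties with those of the
log-OR normal approximation. Within-study standard errors default to
$U(0.1, 0.5)$, a realistic mix of moderately sized trials on a log-OR
scale. `coverage_experiment()` repeatedly simulates a meta-analysis, fits
the RE model, forms the PI, draws one new true effect
$\theta_{new} \sim N(\theta, \tau^2)$, and records whether the PI covers
it — the interval's defining property — alongside CI coverage of
$\theta$, a z-quantile PI variant, and the mean of $\hat\tau^2$.
Reproducibility is by per-replicate seeds derived deterministically from
the single configuration seed.

Problem sizes used by the test suite: 300–800 replicates for property
checks and 2000 replicates for the headline coverage and
$\hat\tau^2$-recovery experiments, at $k$ between 5 and 50 — large enough
for Monte-Carlo standard errors of a few tenths of a percent on a
proportion, small enough to keep the suite fast.

What the experiments show, honestly:

* The **t-based PI always covers more than its z-based variant**, and at
  $\tau^2 = 0$ it is conservative (over-covers), since $\hat\tau^2 \ge 0$
  and $t > z$.
* **DL is consistent in $k$**: at $k = 50$, the mean $\hat\tau^2$ lands
  within 10% of the truth, and the pooled estimate is unbiased for
  $\theta$.
* **CI and PI answer different questions**: with strong heterogeneity the
  CI still covers $\theta$ at a high rate while a newly drawn true effect
  falls outside the CI most of the time.
* **Finite-$k$ coverage of the PI falls short of nominal** in moderate
  regimes: at $k = 10$, $\tau^2 = 0.1$, the measured coverage of
  $\theta_{new}$ is ≈ 0.89 rather than 0.95 (confirmed against an
  independent re-implementation of the fit). This is a known cost of
  plugging a noisy, zero-truncated $\hat\tau^2$ into the formula — the
  two extra degrees of freedom compensate only partially — and the
  corresponding acceptance check is left failing rather than widened,
  because the shortfall is a property of the method, not of the
  implementation.

Because the generator is exactly the model the PI assumes, passing tests
say nothing about non-normal effect distributions, small-study effects,
or correlated estimates in real data; they validate the arithmetic and
the finite-sample behaviour *under the model*.

## Known limitations

Only the DL estimator of $\tau^2$ is provided (no REML/Paule–Mandel), no
Knapp–Hartung CI, no meta-regression or subgroup pooling, normal-theory
PI only, and no Bayesian machinery. These are scope decisions, not
oversights: the package exists to compute and *display* the prediction
interval correctly, and each omitted method has mature implementations
elsewhere.
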