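---
title: "Quantifying the differences trials are designed to detect or rule out"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the differences trials are designed to detect or rule out}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialmargins)
```

## The problem

Every two-arm randomized trial is planned around a difference: a superiority
trial around the smallest treatment effect worth detecting, a noninferiority
trial around the largest unfavorable difference still compatible with
noninferiority (the margin). Together with the type I error rate, the power,
and the outcome variance, this difference determines the sample size — and
since the other inputs follow strong conventions (two-sided 5% α, 80–90%
power), it is the main source of between-trial variability in sample size.
`trialmargins` provides the computational chain for studying these planning
differences across a registry of trial reports: a common effect scale,
forward and inverse sample-size formulas, a calibrated synthetic registry,
and the comparison analysis.

## The effect scale

To compare binary- and continuous-outcome trials on one footing, planning
differences are standardized:

$$d_{\text{means}} = \frac{m_2 - m_1}{SD}, \qquad
  d_{\text{props}} = \frac{P_2 - P_1}{\sqrt{\bar P(1-\bar P)}},$$

where $SD$ is the pooled standard deviation and $\bar P$ the weighted mean
of the two event proportions. Choices the published methods left open, fixed
here as package defaults:

* **SD pooling rule.** The Student-t pooled estimator
  $\sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}$; when a report gives a
  single SD (typically from the results section) it is used directly.
* **Weights of $\bar P$.** Arm sizes when known, equal weights otherwise —
  1:1 allocation dominates two-arm trials, so the equal-weight default is
  rarely consequential.
* **Sign convention.** Experimental minus control ("difference in favor of
  the new treatment"); all registry summaries analyze absolute values, so
  the convention cannot flip group means.
* **Degenerate pooled proportion.** $\bar P \in \{0, 1\}$ makes the
  denominator vanish and is a hard classed error, never a clamped value or
  NaN.

## Sample-size formulas

`n_per_group()` implements the normal-approximation closed forms for the
four design-by-outcome combinations (see the README for the formulas), with
these conventions:

* **Sidedness is data, not convention.** The stated α is used with the
  stated sidedness ($\alpha^* = \alpha/2$ two-sided); nothing is halved
  silently. The synthetic registry defaults to two-sided 0.05 for
  superiority and one-sided 0.025 for noninferiority, the dominant
  real-world conventions.
* **Binary variance term.** Unpooled $P_1(1-P_1) + P_2(1-P_2)$ by default,
  matching the bioequivalence-handbook forms; a pooled-variance variant is
  selectable via `formula_id` for sensitivity checks.
* **Noninferiority planning assumption.** True equality ($P_2 = P_1$;
  true mean difference 0) unless stated otherwise.
* **Rounding.** Ceiling by default (conservative standard practice);
  `"nearest"` exists because the canonical half-SD / 90% power / two-sided
  5% computation yields 84.06, conventionally reported as 84.
* **Normal, not iterated-t, quantiles** for continuous designs — consistent
  with the 84.06 reproduction. The Monte-Carlo oracle (below) quantifies the
  small resulting underpowering.
* **Continuity correction** (`continuity_corrected_n()`): the classical
  $n' = (n/4)(1+\sqrt{1+4/(n|d|)})^2$ inflation approximating Fisher's exact
  test. Always $\geq n$; zero differences are rejected.

`empirical_power()` is the simulation oracle validating these closed forms:
it simulates the actual analysis (two-sample pooled t test via sufficient
statistics for continuous outcomes; unpooled two-proportion z test for
binary; margin-shifted one-sided tests for noninferiority) and returns the
rejection fraction. The tests require agreement with nominal power within 3
Monte-Carlo standard errors at 20,000 replicates, with a 0.01 allowance for
the known t-vs-normal-quantile gap at small n.

## Reconstruction (inverse power analysis)

About a fifth of trial reports state the sample size but omit a planning
parameter. Because the closed forms are monotone in each parameter, the
omission is recoverable:

* `solve_sd()` inverts the continuous formula in closed form:
  $SD = |\delta|\sqrt{n/2}/(z_{1-\alpha^*}+z_{1-\beta})$.
* `solve_p2()` recovers proportions. With the baseline known, the missing
  $P_2$ is root-found (bisection via `uniroot`, tolerance $10^{-10}$) on the
  side of the stated direction of benefit; with no stated direction the two
  sides genuinely differ and an **ambiguity error** is raised rather than a
  silent choice. With only the difference (or margin) known, the quadratic
  constraint admits two roots — but they are reflections
  $(P_1,P_2) \to (1-P_2,1-P_1)$ with identical variance term and pooled
  proportion, hence identical standardized difference; the root with pooled
  proportion $\leq 1/2$ is returned deterministically.

**Rounding-induced uncertainty.** Inversion acts on the pre-rounding
formula, but published n is an integer: the recovered parameter is therefore
perturbed by $O(1/n)$ relative. Two consequences, both deliberate:
(1) round-trips are exact ($10^{-6}$ relative) against raw n and bounded by
the rounding gap against integer n — the masked-registry test asserts the
bound $|d_{rec} - d_{true}| \le 1.5\,d/n$, not an unattainable absolute
tolerance; (2) an integer n can fall just past the formula's feasible range
(e.g. a noninferiority baseline near 0.5, where $P(1-P)$ is maximal). When
n − 1 is feasible, the infeasibility is rounding-induced and the boundary
solution $P = 1/2$ is returned; otherwise a classed infeasibility error with
bracketing diagnostics is raised.

`verify_reported_sample_size()` reports
$|n_{\text{recomputed}} - n_{\text{reported}}|/n_{\text{reported}}$; the
irreconcilability threshold used by `validate_registry()` is 0.15 —
published methods state no tolerance, so it is configurable and documented
rather than hidden. When both the proportions and the difference are
reported and disagree, the proportions win (they are the primary extracted
quantities).

## The synthetic registry: a stated world

No per-trial dataset of planning parameters is published, so
`generate_registry()` emulates one. The defaults *are* the stated world:

* 100 superiority + 100 noninferiority trials; binary outcomes in exactly
  60% and 86% of them (fixed stratum counts, mirroring a fixed observed
  sample composition).
* True standardized differences per (design × scale) stratum from a normal
  truncated to (0.01, 1.6) with means (SDs) 0.37 (0.20) and 0.56 (0.30) for
  superiority proportions/means, 0.27 (0.12) and 0.40 (0.11) for
  noninferiority. A moment-matched lognormal family is available
  (`d_family = "lognormal"`) since the observed spread is right-skewed.
  Truncation at zero biases stratum means upward by at most ~0.02 (largest
  for superiority, where 0 is ~1.9 SDs below the mean) — well inside the
  3-standard-error calibration bands the tests assert.
* Binary baselines uniform on [0.1, 0.7]; if a drawn standardized
  difference is unattainable for a drawn baseline (p2 would exceed 1) the
  baseline is redrawn, and after 200 failures a config error names the
  stratum. Continuous SDs are lognormal in arbitrary outcome units — only
  the ratio δ/SD matters downstream.
* Power mixture 0.6/0.4 over {0.80, 0.90}, reproducing a median of 0.80
  with upper quartile 0.90.
* Covariates (medical context, mortality outcome, multicenter, intervention
  type, age group, funding, year band, statistician involvement) follow the
  published marginal frequencies per design, drawn independently of each
  other *and of the standardized difference*. The joint distribution is
  unidentifiable from printed marginals, and layering covariate effects on
  the standardized difference while preserving the stratum means would
  require deconvolving effects no published source quantifies. A green
  calibration test therefore establishes recovery of the design × scale
  structure, **not** covariate gradients (mortality, context) seen in real
  data; covariate-effect machinery is exercised by purpose-built fixtures
  instead.
* **Masking.** A fixed-size uniform random subset of `round(0.195 · n)`
  records loses exactly the parameters reports most often omit — binary:
  both proportions (difference kept); continuous: the SD — so the
  imputation workload is deterministic (39 of 200) while the subset remains
  random. Every masked record is reconstructible by design.
* The generator's ground truth is kept in the `d_true` column, which real
  registries would leave empty.

All randomness is confined to generation and masking; extraction and
analysis are deterministic. A single pipeline seed fans out to fixed
per-stage substreams (`seed`, `seed + 2^17`) so stages can be rerun
independently.

## Analysis stage

* `two_group_compare()`: pooled Student t by default — the method named by
  the practice being emulated — with Welch and Mann-Whitney variants.
  Two constant equal groups return t = 0, p = 1; constant unequal groups
  are a degenerate-input error.
* `categorical_compare()`: Pearson χ² without Yates correction, switching
  to Fisher's exact test when any expected count is below 5. Notably, the
  uncorrected χ² on a published 67/33 vs 86/14 multicenter composition
  gives 10.04 (p = 0.0015), while the source prints p = 0.001 — the exact
  per-row test choice there is unstated, so the tests assert the recomputed
  value.
* `interaction_test()`: two-way ANOVA, interaction F-test; an empty crossed
  cell (e.g. no elderly noninferiority trials) is an inestimable-interaction
  error, mirrored as NA in the summary tables.
* `adjusted_means_anova()`: main-effects least squares on the absolute
  standardized difference. Adjusted means are **balanced-population marginal
  means** (equal weight per combination of the other factors' levels); the
  estimand used by the emulated analysis is unstated, so observed-margins
  weighting is available via `weighting = "observed"`. Per-factor p-values
  are drop-one F tests (Type II ≡ III for main-effects models); the fit is
  checked against a hand-built normal-equations oracle to $10^{-8}$ in the
  tests. Rank deficiency errors out naming the aliased terms.
* `summarize_registry()`: the by-scale block (proportions / means /
  combined, per design, with Student-t contrasts), the by-covariate block
  (stratum means, per-design p, pooled covariate p from the
  design-adjusted main-effects ANOVA, interaction p), and quartile/range
  distribution summaries. The pooled p is implemented as the main-effect
  test of the two-way model — the stratified alternative is not fully
  specified by the emulated analysis, and the choice is documented here.

## What a green test establishes

The acceptance suite checks: the exact 84-per-group worked computation;
full-pipeline recovery of the configured stratum means within 3 standard
errors (including reconstruction of the 19.5% masked records); forward-
inverse round-trips to $10^{-6}$ on a 208-design grid; closed-form vs
simulated power within 3 Monte-Carlo SEs for 12 designs; hand-computed test
fixtures and 3-SE type-I-error bands; and adjusted-means agreement with the
least-squares oracle plus the noninferiority < superiority ordering on the
calibrated registry. It does **not** establish anything about covariate
gradients in real trial data (see the stated-world limitations above), nor
about designs outside scope: unequal allocation, time-to-event outcomes,
cluster/crossover designs, group-sequential plans.

## Known limitations

* The registry emulates marginal structure only; covariate-covariate and
  covariate-effect dependence is absent by default.
* Reconstruction assumes the report used one of the implemented formula
  variants; a report computed with, say, an arcsine or exact unconditional
  method will show a nonzero consistency gap rather than being recovered
  exactly — which is the intended signal, not a failure.
* Continuous-design formulas use normal quantiles; at very small n (< ~15
  per group) the t-test power at the computed n runs ~1 point below
  nominal.
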