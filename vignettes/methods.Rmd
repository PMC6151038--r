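---
title: "Methods: partial credit calibration and validation of multi-object risk scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partial credit calibration and validation of multi-object risk scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raschval)
```

# The measurement problem

`raschval` implements the psychometric development-and-validation workflow
for polytomous rating scales that are administered repeatedly: every
respondent rates several *assessment objects* (here, tobacco and
nicotine-containing products — conventional cigarettes, a heated tobacco
product, e-cigarettes, nicotine replacement therapy, and smoking
cessation) under one of two *risk framings* (personal risk to the
respondent vs general risk to users). The instrument comprises an 18-item
Perceived Health Risk scale and a 7-item Perceived Addiction Risk scale;
items offer five ordered categories from "no risk" to "very high risk"
plus a "don't know" option, which is informative qualitatively but is
treated as missing in all model-based analyses.

The measurement model is the partial credit model (PCM), the unrestricted
polytomous Rasch model. For an item with thresholds
$\tau_{i1},\dots,\tau_{im}$ ($m = 4$ here) the probability of category
$x \in \{0,\dots,m\}$ at person location $\theta$ is

$$P(X_i = x \mid \theta) \;=\;
  \frac{\exp\!\sum_{k \le x}(\theta - \tau_{ik})}
       {\sum_{c=0}^{m}\exp\!\sum_{k \le c}(\theta - \tau_{ik})},$$

with the empty sum equal to zero. A threshold is the latent location at
which two adjacent categories are equally probable; the item *location*
$\delta_i$ is the mean of its thresholds. The Rasch family is used
deliberately: raw scores are sufficient for $\theta$, so a published
raw-score-to-measure conversion table is exact for complete data, and
parameter separation underwrites the invariance (DIF) testing that the
validation hinges on. Discrimination parameters are out of scope by
design — the generalized partial credit model is exactly what this
workflow chooses *not* to fit.

# Calibration

`calibrate_items()` estimates thresholds by marginal maximum likelihood:
an EM algorithm integrating over a latent normal distribution with
Gauss–Hermite quadrature (49 nodes by default). The latent mean is fixed
at 0 — any overall shift is absorbed by the thresholds — and the latent
SD is estimated. After convergence the item locations are recentred to
$\sum_i \delta_i = 0$, the conventional resolution of the translation
indeterminacy; recentring is applied within each calibration
(scale-by-selection), so measures from different calibrations share only
their origin convention, not an equated metric.

Numerical choices:

* **Convergence** at an absolute log-likelihood change below $10^{-6}$,
  capped at 500 EM cycles. The EM is accelerated by SQUAREM
  extrapolation guarded by a likelihood check (with $10^{-3}$ slack,
  because the quadrature grid adapts to the current latent SD and makes
  successive marginal log-likelihoods comparable only to about that
  level). Typical fits converge in roughly 100 updates.
* **M-step**: three damped Newton steps per item per update on the
  expected complete-data log-likelihood, steps clipped to 1 logit.
* **Null categories** (no observations in a category) leave a threshold
  unidentified: the fit proceeds with thresholds capped at ±8 logits and
  the item flagged, rather than failing.
* **Standard errors** come from the cross-product of per-person marginal
  score vectors (a BHHH approximation, per item); the location SE follows
  by the delta method. Cross-item covariance is ignored, which is
  accurate at the sample sizes this design targets.
* Thresholds are deliberately *unconstrained in order* so that threshold
  disordering remains observable — it is one of the diagnostics.

Person measures come from `estimate_persons()`: maximum likelihood, or
Warm's weighted likelihood (WLE, the default), which maximizes
$\ell(\theta) + \tfrac12\log I(\theta)$ with $I$ the test information.
WLE removes the leading-order bias of the MLE and yields finite, flagged
estimates at extreme raw scores; the package's bias test computes the
exact raw-score distribution at fixed $\theta$ (a convolution, not a
simulation) and verifies $|\mathrm{bias}_{WLE}| \le |\mathrm{bias}_{MLE}|$
at $\theta \in \{-2, 0, 2\}$ for 7- and 18-item forms. SE
$= 1/\sqrt{I(\hat\theta)}$.

# Diagnostics and their null calibration

The diagnostic battery mirrors standard Rasch-measurement practice:
targeting coverage, item fit residuals (±2.5 band), class-interval
chi-squares, threshold ordering, residual correlations (local
dependence), the person separation index (PSI), and residual-ANOVA DIF.
Persons are ranked by $\hat\theta$ and split into $G = 10$ near-equal
class intervals (ties broken by row order), so the item-trait chi-square
has the conventional 9 degrees of freedom.

A methodological point runs through the whole battery: residuals
evaluated at an *estimated* $\hat\theta$ are systematically smaller than
model residuals at the true $\theta$, and naive standardization makes
every statistic conservative (in null simulations the plain class-interval
chi-square averaged ≈ 7.8 against df 9). The package therefore
standardizes through the **conditional distribution given the raw
score**, which for the Rasch family is free of $\theta$ and computable
exactly by the symmetric-function recursion
$P(X_i = c \mid r) = \varepsilon_i(c)\,\gamma_{-i}(r-c)/\gamma(r)$ with
$\varepsilon_i(c) = \exp(-\sum_{k\le c}\tau_{ik})$:

* **Item fit residual**: the sum of squared conditionally standardized
  residuals, which has exact unit mean per observation, normalized by a
  Wilson–Hilferty cube-root transformation. Negative values indicate
  over-discrimination (responses more deterministic than the model),
  positive under-discrimination; ±2.5 is the flag band. Null behaviour
  in simulation: mean ≈ 0.2, SD ≈ 1.05, ≈ 2% beyond ±2.5.
* **Class-interval chi-square**: interval sums of observed minus
  conditional-expected scores, standardized as a Rao–Robson quadratic
  form — the interval covariance is deflated along the threshold
  sensitivity profiles $c_k(r) = \mathrm{Cov}(X, \mathbf 1[X \ge k]\mid r)$
  (which equal $-\partial E[X|r]/\partial\tau_k$) to account for
  threshold estimation, and pseudo-inverted. This restores the
  $\chi^2_{G-1}$ calibration (null simulation: mean 9.4, type-I 5.4% at
  $n = 500$) while keeping the printed df of 9. For very large samples
  the statistic is additionally rescaled by $500/n$ before the p-value
  is computed (never re-estimated), mitigating the excessive power of
  fit testing at panel-size n; the raw statistic is always reported.
* **DIF** (`dif_anova()`): a two-way fixed-effects ANOVA of
  conditionally standardized residuals with the person factor and the
  class interval as factors, type-II sums of squares on the unbalanced
  grid. The factor main effect indicates uniform DIF, the
  factor-by-interval interaction non-uniform DIF; tests are test-wise at
  $\alpha = 0.05$ with an optional Bonferroni switch. Conditional
  standardization matters here: marginal residuals are heteroscedastic
  across extreme intervals, and any factor whose latent means differ
  across levels (smoking group, framing) then shows inflated F-tests;
  with conditional residuals the null flag rate is 5.0% in simulation.
  A caveat discovered during development: a pure discrimination defect
  barely moves the expected-score curve when thresholds span ±3.5
  logits, so the interaction test has little power against it — that
  defect is the fit residual's job (it flags discrimination 0.4 or 2.0
  emphatically), while the ANOVA detects level-dependent difficulty.
* **Residual correlations** use marginal residuals, pairwise-complete,
  with both published rules: the absolute 0.30 criterion and the
  mean + 0.30 criterion. On locally independent data the mean pairwise
  residual correlation is slightly negative (≈ $-1/(L-1)$), so the
  second critical value sits below 0.3, matching the published footnote
  pattern.
* **PSI** $= (\mathrm{var}(\hat\theta) - \overline{se^2}) /
  \mathrm{var}(\hat\theta)$, floored at 0, computed from WLE estimates
  including extreme-score persons (their WLE is finite); persons with
  zero information are excluded. On complete, well-targeted data PSI and
  Cronbach's alpha agree within 0.05.
* **Targeting coverage** is reported as the share of person estimates
  inside the span of the item thresholds; the converse reading (share of
  the threshold span covered by persons) is available via
  `direction = "span"`. The literature leaves this statistic
  under-specified; the person-share reading reproduces the published
  75–90% range under the default generator.

# Item reduction

`reduce_scale()` iterates calibrate → diagnose → flag → remove, at most
three iterations and six removals per iteration, stopping when nothing
is flagged (or everything is, which aborts with a report instead of
emptying the scale). Auto mode ranks removals: misfit first (by
$|$fit residual$|$), then DIF (by largest F), then one member of each
locally dependent pair (the worse-fitting one). A chi-square flag alone
is recorded as supporting evidence but does not drive removal, and the
*removal* DIF flag is Bonferroni-controlled per item across the screened
factors — with six factors and two tests each, test-wise flagging would
discard several clean items per iteration by chance alone. Interactive
mode delegates the choice among flagged items to a callback,
reproducing the judgment loop of a development team. The trail records
every flag table, removal and reason, and serializes to JSON.

# The synthetic survey generator

`generate_survey()` is first-class, tested code — the stand-in for the
proprietary panel data — and its defaults *are* the study conditions:

* 410 respondents per smoking-status stratum (current smokers with and
  without intention to quit, former smokers, never smokers), each
  randomized to one framing. Framing is between-subjects because the
  published group sizes for the two framings are disjoint halves of each
  stratum.
* Latent traits per respondent-object-framing-scale:
  $\theta = \mu_{\text{scale}}(\text{object}, \text{framing}) +
  \Delta_{\text{group}} + b + e$, with object-framing means taken from
  the published object-means table, group offsets (−1.2, −0.4, +0.6,
  +1.0 logits for CS-NIQ, CS-IQ, FS, NS) solved once from the published
  known-group means under equal allocation, person SD 2.9 (health) and
  3.4 (addiction) from the published within-group SDs, and a shared
  respondent component (`person_cor = 0.5`) inducing the
  repeated-measures correlation across an individual's assessments.
* Item truth: the published item locations (recentred to sum to zero;
  the printed values carry ≈ 0.01 rounding drift), with thresholds at
  offsets (−3.5, −3.5/3, +3.5/3, +3.5) about each location. The wide
  span is chosen to reproduce the published effective threshold range of
  roughly −4.5 to +4 logits; narrower conventional offsets (e.g. ±2)
  cannot produce that range or the published coverage band given the
  person distributions above.
* "Don't know" thinning at 12% per response (published range 8–15%),
  missing completely at random by default; an MNAR stress mode inflates
  the rate for never smokers under the personal framing, who found
  personal risk hardest to assess. Never smokers under the personal
  framing skip NRT and Cessation entirely, as in the field design.
* Randomized object sequences per respondent; an optional per-object
  carry-over shift applies from the second position on (default zero —
  the defect-free condition).
* Auxiliary VAS measures: the VAS construct correlates 0.8 with the
  risk trait (the published observed correlations of 0.52–0.68 with
  disattenuated values of 0.68–0.89 imply a construct correlation well
  below 1), and observation noise is set from the target reliability of
  0.6.
* Defect injection: `inject_dif()` (uniform = threshold shift for a
  focal level; non-uniform = discrimination-scaled category weights) and
  `inject_misfit()` (discrimination for everyone). The truth record
  carries every latent trait, threshold and defect label, so recovery is
  scorable.

What the generator does *not* emulate: recruitment and quota-fill
dynamics, dropout, multidimensionality, response styles
(e.g. extreme/midpoint responding), item-specific wording effects, and
any real dependence between "don't know" behaviour and the trait beyond
the optional MNAR mode. Green tests on synthetic data therefore show
that the *pipeline* behaves as specified under the model it assumes —
they do not certify the real instrument, whose raw data are
proprietary.

# Scoring

`build_conversion_table()` exploits raw-score sufficiency: for each raw
score of a fixed administered item set it solves the WLE score equation
(finite at the extremes), attaches $SE = 1/\sqrt{I}$, and maps measures
linearly to a 0–100 metric: $s = 50 + 50\,\theta/\Theta$ with
$\Theta = \max(|\theta_0|, |\theta_{\max}|)$, clamped to $[0, 100]$.
A measure of 0 — the calibration mean — maps to 50 exactly, and the
longer extreme reaches its bound exactly. The published description
("mean to 50, extremes to 0 and 100") is jointly satisfiable by one
linear map only when the extreme measures are symmetric; for calibrated
(slightly asymmetric) instruments the shorter tail stops inside its
bound, and the table flags this in its metadata.

# Validity analyses

`known_group_ttest()` works from (n, mean, SD) triples with the
pooled-variance Student t (the published dfs equal $n_1+n_2-2$
throughout, identifying the pooled test) and Cohen's d on the pooled SD.
`spearman_corr()` and `disattenuate()` implement the convergent-validity
machinery; the attenuation correction $r/\sqrt{rel_a\,rel_b}$ reproduces
both published endpoints (0.52 → 0.68 and 0.68 → 0.89) with the VAS
reliability 0.6 and the health-scale reliability 0.97 — the only pair
consistent with both printed values, documented here as such rather than
asserted as the original authors' computation. `carry_over_assessment()`
compares respondents who assessed an object first against those who
assessed it later, per object and framing.

# Problem sizes and reproducibility

Every stochastic routine takes an explicit seed (default 20140201) and
`generate_survey()` is byte-deterministic given its config. The test
suite sizes its simulations to what the statistical claims need: item
recovery at $n = 2000$ over 10 replicates, chi-square calibration at
$n = 500$ over 200 replicates, DIF power at 500 persons per level over
20 replicates, and the full default survey (1640 respondents, ≈ 7800
stacked assessment rows) for the end-to-end closure check. The
`analysis/` drivers run the same stages at the full default design.

# Known limitations

* Calibration assumes a latent normal; the generator draws normal traits,
  so misspecification robustness is untested here.
* SEs ignore cross-item covariance and quadrature error; both are
  negligible at the design's n but matter below a few hundred persons.
* The chi-square's Rao–Robson correction is asymptotic in the interval
  counts; with fewer than ~30 persons per class interval its calibration
  degrades and G should be reduced.
* DIF ANOVA has little power against pure discrimination defects (see
  above); rely on the fit residual for those.
* Measures from different scale-object calibrations share a centring
  convention, not an equated metric; cross-object comparisons lean on the
  common-calibration design (objects stacked in one calibration), as in
  the original workflow.
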