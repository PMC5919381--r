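---
title: "Predicting maize hybrid field performance from parental metabolic profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting maize hybrid field performance from parental metabolic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hybrid maize breeding must choose, among thousands of possible crosses
between maternal (Dent) and paternal (Flint) inbred pools, the few worth
field-testing. Field trials are slow and expensive; molecular profiles of
the *parents*, measured once on in-vitro grown seedlings, are cheap.
`hybripred` implements a two-step, classification-driven route from
parental metabolite profiles to hybrid field performance (HP, whole-plant
biomass in dt ha^-1^):

1. learn which parental analytes predict how each analyte is *inherited*
   in the hybrids, and
2. use the best-ranked parental analytes to predict the hybrids' field
   biomass, quantitatively and as a good/bad classification.

The premise is that analytes informative about metabolic inheritance are
also informative about heterotic field performance, so step 1 acts as a
biologically grounded feature-selection device for step 2.

## Step 1: encoding metabolic inheritance patterns

For a cross $h = (d, f)$ and analyte $j$, let $b$ and $w$ be the parent
with the higher and lower mean level of $j$. Two contrasts, hybrid$-b$ and
hybrid$-w$, are tested on the replicate profiles of the three genotypes
with **empirical-Bayes moderated t-statistics**: a one-way three-group fit
pools the residual variance $s_j^2$ (with $d_j$ degrees of freedom), which
is shrunk toward a prior $(d_0, s_0^2)$ estimated from all analytes of the
same cross subset,

$$\tilde s_j^2 = \frac{d_0 s_0^2 + d_j s_j^2}{d_0 + d_j},
\qquad t = \frac{\bar X_h - \bar X_b}{\tilde s_j \sqrt{1/n_h + 1/n_b}},$$

with $d_0 + d_j$ degrees of freedom (capped at the subset's pooled residual
df) and no multiplicity adjustment. The prior is fitted by the classical
method of moments on log variances (digamma/trigamma inversion); when the
spread of log variances is at or below its sampling floor the prior is
degenerate ($d_0 = \infty$) and the moderated variance equals the pooled
common variance. The suite cross-checks both the prior fit and the
moderated t against `limma` on identical inputs.

The two significance states translate into the five-class **metabolic
inheritance pattern** (mIP) label $T(h,j)$: $+2/-2$ when the hybrid is
significantly above/below both parents (positive/negative overdominance),
$+1/-1$ when it is significantly above/below exactly one parent
(dominance), and $0$ otherwise (additivity, including the
between-the-parents case where both contrasts are significant with
opposite signs). "Equal" always means "not significant at $\alpha$"
(default $\alpha = 0.05$, two-sided, unadjusted — the conventional level;
it is a configuration knob). Two states that the published conditionals
leave implicit (significant against exactly one parent with the other
contrast non-significant on the *other* side) are mapped to dominance, and
the geometrically unreachable state (above $b$ yet below $w$) to
additivity, making the mapping total.

Two data-driven filters precede modeling:

* **Redundancy filter** — analyte pairs with Pearson $r > 0.85$ (computed
  on genotype-mean profiles, parents and hybrids pooled, so replication
  does not inflate $r$) lose the member with the greater average signed
  correlation to all analytes; one greedy pass in decreasing-$r$ order,
  lexicographic tie-break, zero-variance analytes dropped first. An
  iterative variant (recompute after each removal) is available by flag;
  the one-pass form is the default because removals are sparse and the
  greedy result is then identical in practice.
* **Class-balance filter** — an encoded analyte is dropped when any class
  covers more than 75% of the hybrids, or when any *realized* class has
  2–3 occurrences; a single class with a single occurrence instead
  excludes that one hybrid for that analyte. Absent classes do not count
  against an analyte (a `strict_absent` flag flips that reading for
  sensitivity analysis), and several singleton classes are treated as a
  drop. This is the reading under which both the 0.75 and the relaxed 0.9
  thresholds behave monotonically (relaxing the threshold can only keep
  more analytes), which the suite asserts.

## Step 1 continued: classifiers, model selection, ranking

Each encoded analyte's mIP vector is predicted from the **predictor
matrix** $X_{DF}$: per cross, the Dent parent's replicate-mean profile
concatenated with the Flint parent's (Dent block first), columns z-scored
over the crosses. Seven multi-class classifiers are compared: PLS-DA,
elastic-net multinomial regression, PLS-RF (random forest on PLS scores),
radial-kernel SVM with and without class weights, and random forests with
and without class weights. Class weights $\{10, 5, 1, 5, 10\}$ (symmetric,
additivity cheapest) enter the SVM as per-class misclassification costs
and the forests as class weights — the native mechanism of each family.

The evaluation protocol per (method, analyte): five repetitions of a
stratified 75/25 split with inner stratified 3-fold cross-validation
(5 repetitions) maximizing **Cohen's kappa** over a two-parameter grid
(PLS-DA tunes only its component count), then kappa on the held-out 25%.
Default grids: cost $2^{-2..6}$ × median-heuristic RBF width ×
$\{0.5, 1, 2\}$ for the SVMs; mtry $\sqrt p \times \{0.5, 1, 2\}$ ×
minimum node size $\{1, 5\}$ for the forests (500 trees); mixing
$\alpha \in \{0.1, \dots, 1\}$ × a log-spaced $\lambda$ path for the
elastic net (evaluated from a single path fit per $\alpha$); component
counts for the PLS methods. The published protocol names no grids; these
are the standard search spaces of each family and every grid is a
parameter of the call. A permutation null (labels shuffled once per
analyte before the whole procedure) establishes the no-signal baseline;
its kappas center on zero.

The ranking model is the method with the smallest **coefficient of
variation** of kappa (sd/mean over all analyte × repetition values;
methods with non-positive mean are excluded as undefined). For that model,
one model per encoded analyte is trained on the full sample and a
per-column **variable importance** is extracted, scaled to $[0, 100]$
within each model; the final score is the median across the
encoded-analyte models, ranked with a deterministic lexicographic
tie-break. For kernel SVMs, which have no native importance, the standard
model-agnostic filter importance is used: per column, the one-vs-rest AUC
per realized class (folded about 0.5), averaged over classes. This measure
depends on the data rather than on the fitted kernel machine, so the
ranking step does not refit the SVM; forests use impurity importance, the
elastic net its mean absolute class coefficients, and a permutation
importance is available by flag. Ranking diagnostics report Kendall's
$\tau$ between the Dent-block and Flint-block orders and the cumulative
parental-origin frequencies along the ranking.

## Step 2: hybrid-performance prediction

Thirteen feature-subset scenarios are evaluated: the fixed top/bottom 5
columns; 5 drawn at random from the top/bottom 10, 20, 50 and 100; 5 from
the whole ranking; all columns; and all columns with biomass permuted (the
null). Random subsets are redrawn each repetition. Windows larger than the
available column count clamp to it (relevant for panels smaller than the
272-column study the scenario sizes were named after). Per scenario, 25
repetitions of: random 80/20 split, radial-kernel support-vector
regression tuned by 3-fold cross-validation maximizing $R^2$, then
test-set $R^2$. $R^2$ is the **squared Pearson correlation** of predicted
vs observed (so it lives in $[0,1]$ and is invariant to affine biomass
rescaling); the $1 - \mathrm{SSE}/\mathrm{SST}$ alternative is reported
alongside. The two field trials are pooled in one model — their mean
difference is part of what the model must absorb; a per-trial stratified
variant is a flag.

For qualitative prediction, hybrids are labelled *good* when biomass
$\ge$ the threshold (default: the mean) and an SVM is tuned to maximize
accuracy (or AUC), recording accuracy, kappa, AUC and good-class
probabilities. Probabilities come from **Platt calibration** — a logistic
fit on the SVM decision values — because libsvm's internal
cross-validated estimate is not reproducible across calls within a
process, and stage checksums must be. Precision–recall curves are
computed over a cutoff grid, with precision reported as absent (not zero)
when no hybrid is predicted good; the default 0.5 cutoff is marked. A
threshold sweep re-runs the classification at nine evenly spaced cutoffs
centered on (and including) the mean, spanning 90% of the distance to the
nearer biomass extreme; cutoffs that empty a class are reported as
degenerate rather than evaluated.

## The synthetic panel generator

`simulate_panel()` produces a full panel with known ground truth. Its
defaults are the study conditions used throughout the tests and the
acceptance script:

* **Design**: 24 Dent × 25 Flint lines, 55.3% of the factorial realized
  (~332 crosses), 4 profiled crosses never phenotyped, trials split
  45/55 with a +50 dt ha^-1^ mean offset for the later trial around a
  592 dt ha^-1^ base.
* **Profiles**: 60 analytes on a log10-like scale, 6 replicates per
  genotype, replicate noise sd 0.5, between-line sd 1.0. Background
  analytes additionally load on 3 latent line factors (loading sd 2.5),
  giving realistic analyte–analyte correlation with several pairs above
  the 0.85 redundancy threshold per panel; the causal and encoded blocks
  stay out of the factor structure so that planted signal is not
  duplicated into background columns and remains identifiable. The
  synthetic panel is deliberately less redundant than real GC/MS data
  (where co-detected fragments of one compound made the published filter
  remove half of all features).
* **Inheritance classes**: 20 "encoded" analytes draw their class from
  propensities $(0.10, 0.175, 0.45, 0.175, 0.10)$ by quantile-mapping a
  ±1-weighted sum of 5 standardized causal maternal analyte levels (so
  classifiers and the ranking have a learnable, line-level signal), with
  5% label noise; the proportion of encoded analytes (a third) mirrors
  the real panel. All other analytes are strongly additive
  $(0.01, 0.04, 0.90, 0.04, 0.01)$. Hybrid means realize the class:
  mid-parent for additivity, the dominant parent's level for dominance,
  $\delta = 1$ beyond the parental range for overdominance. Dominance is
  only planted where the parental gap is at least 1.0 (about 3.5 contrast
  standard errors at the default noise): dominance at coinciding parental
  levels is not a detectable, or even meaningful, pattern; infeasible
  draws fall back to additivity and the recorded truth is the final
  label. With the gap rule disabled, planted class frequencies match the
  propensities exactly, which the suite verifies by goodness of fit.
* **Biomass**: a linear function of the standardized causal maternal
  levels with weights $(25, 22, 20, 17, 15)$ dt ha^-1^ plus the trial
  offset and residual sd 25 — metabolic signal, trial effect and noise in
  proportions that put the full-model predictability in the
  0.5–0.7 range typical of this assay.

Under these conditions the encoder recovers planted non-additive labels
at ≥ 80% per class, at least 4 of the 5 causal maternal columns rank in
the top 10, and the scenario medians order Top5 > Random5 > Bottom5 with
the permuted null below 0.05. What passing these checks does *not* show:
the generator draws Gaussian replicates with equal variances and plants
class-conditional means exactly, so it cannot probe robustness to
heteroscedastic or heavy-tailed intensity noise, batch structure within
trials, missing values (rejected at load), or inheritance driven by
paternal or non-linear parental signals.

## Numerical choices and degenerate inputs

* Equality in the encoding is operational ("not significant at
  $\alpha$"), never numeric; a contrast estimate of exactly 0 has sign 0
  and $p = 1$.
* Kappa of a single-class (chance-perfect) confusion matrix is defined
  as 0; confusion matrices are always formed over the full level set of
  the analyte so empty test classes are handled uniformly.
* Tuning skips an (analyte, repetition) and logs it when a training
  stratum is smaller than the fold count — the singleton-exclusion rule
  upstream makes this rare.
* Constant analytes (undefined correlation) are dropped and logged before
  the redundancy pass; a zero-variance predictor column is an error at
  standardization; a constant non-additivity fraction yields an
  "undefined" correlation report rather than a number.
* All stochastic stages expand one master seed into per-task streams, so
  results are independent of task order and reproducible end to end; the
  pipeline manifest records per-stage file checksums, and re-running a
  configuration reproduces them bit for bit.

## Problem sizes used by the tests and the acceptance script

Everything stochastic is demonstrated on the generator's study-condition
panel (~330 crosses, 60 analytes): the moderated-statistics checks use
10,000 simulated null analytes and 5,000 simulated variances; the
classifier checks run compact tuning grids, three methods (the weighted
SVM that the published protocol selects, a forest and the elastic net)
over 10 encoded analytes with 3 repetitions, and the
hybrid-performance scenarios run 25 repetitions with 2 inner
cross-validation repeats. These are the package's chosen demonstration
sizes; the defaults of every function remain the full protocol (all seven
methods, 5 and 25 repetitions, 5 and 10 inner repeats), which on the full
study-sized panel is an hours-long computation.

## Known limitations

* The moderated-contrast model is the plain equal-variance three-group
  fit; no array weights, variance trends or robust empirical Bayes.
* The kernel-SVM importance is a filter measure: it ranks columns by
  their marginal class separation, not by their contribution inside the
  fitted kernel (the permutation alternative probes the latter).
* The published protocol's exact tuning grids and seeds are not stated,
  so numerical results on real data reproduce to sampling tolerance, not
  bit for bit.
* `compare_trials()` is defined for exactly two trials, the design it
  describes.
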