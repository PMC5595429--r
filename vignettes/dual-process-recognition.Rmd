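---
title: "Estimating recollection and familiarity from recognition-memory tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating recollection and familiarity from recognition-memory tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(recmem)
```

## The model

Dual-process accounts of recognition memory distinguish **recollection** —
all-or-none retrieval of contextual detail about the study episode — from
**familiarity**, a graded feeling of prior exposure without context. The two
processes dissociate in amnesia and in lesion studies, so clinical work needs
estimates of each that do not depend on a single task or estimation trick.
`recmem` implements three classical estimators on trial-level data, plus the
group statistics appropriate for small patient samples.

All three estimators share the equal-variance signal-detection core. Hit and
false-alarm rates are corrected as \((x + 0.5)/(n + 1)\) so they never touch
0 or 1, then

\[
d' = z(H) - z(F), \qquad c = -\tfrac{1}{2}\left(z(H) + z(F)\right),
\]

with \(z\) the standard-normal quantile function. \(d'\) is the global
discrimination index; \(c\) is the response criterion (negative = liberal).

### Confidence-ROC task and the dual-process SDT model

Subjects study 120 words and judge 120 + 60 test words on a 6-point
confidence scale (1 = sure new, 6 = sure old). Cumulating the confidence
distribution from the "sure old" end gives a five-point ROC. Under the
dual-process signal-detection (high-threshold) model, an old item is
recollected with probability \(R\), which forces the top confidence
category; otherwise it produces a familiarity strength
\(\mathrm{Normal}(d_f, 1)\) that is partitioned by five ordered criteria,
the same criteria that partition the \(\mathrm{Normal}(0, 1)\) strengths of
new items. `fit_dpsd()` maximizes the multinomial likelihood of the
\(2 \times 6\) count table over \((R, d_f, c_1, \ldots, c_5)\); the fitted
\(R\) and \(d_f\) are the task's recollection and familiarity indices.

Numerical choices, all visible in the code:

* **Likelihood vs least squares.** Maximum likelihood is the default: it is
  efficient and remains well-defined when confidence categories have zero
  counts. A least-squares fit to the five ROC points (`method = "sse"`) is
  kept as a cross-check; on clean tables the two agree.
* **Parameterization.** \(R\) on the logit scale, criteria as first value
  plus log-increments (ordering is structural, never a constraint the
  optimizer can violate), \(d_f\) free.
* **Bounds.** The optimizer is boxed at \(\pm 8\) z-units for \(d_f\) and
  the criteria. Degenerate tables with perfect separation lie on a
  likelihood ridge (recollection at 1 and unbounded familiarity fit
  identically); the box makes the fit settle on the recollection corner,
  which is the conventional reading of an all-top-category table.
* **Multistart.** One moment-based start (criteria from the corrected
  distractor cumulative rates, \(d_f\) from the collapsed yes/no \(d'\),
  \(R\) from the excess of top-category hits) plus fixed perturbations,
  five starts by default. The multistart is deterministic, so fits are
  bit-reproducible with no hidden RNG state.
* **Zero cells.** Predicted category probabilities are floored at
  \(10^{-12}\) inside the likelihood; observed counts are used raw. The
  floor alone keeps the objective finite, so no data smoothing is applied
  to well-populated tables.
* **Encoding depth.** The task mixes shallow and deep encoding; scoring
  collapses across depth, matching the one-index-per-subject reporting.
* A table with all mass in one and the same category for both item classes
  carries no information; the fit is returned flagged non-identifiable
  rather than raising.

### Process dissociation on word pairs

Subjects study 80 word pairs and must accept intact pairs (40) while
rejecting recombined (40) and new (40) pairs. Recollection of the study
pairing supports accepting intact pairs and *vetoes* accepting recombined
ones; familiarity of the component words supports both. With
\(p(\mathrm{inc})\) the acceptance rate of intact pairs and
\(p(\mathrm{exc})\) that of recombined pairs,

\[
R = p(\mathrm{inc}) - p(\mathrm{exc}), \qquad
F = \frac{p(\mathrm{exc})}{1 - R}.
\]

Both rates pass through the Snodgrass–Corwin correction by default, which
keeps \(R < 1\) and hence \(F\) defined; with raw rates (`correct_rates =
FALSE`) an \(R\) of exactly 1 flags \(F\) as undefined instead. \(F\) is
reported on the probability scale — the cross-task summary z-transforms each
task against controls, so no unit conversion is needed. The task's \(d'\)
and \(c\) contrast intact-pair hits with *new*-pair false alarms by default
(recombined pairs are already consumed by the dissociation equations);
pooled false alarms are available via `fa_class = "pooled"`.

### Remember/Know/Guess

Subjects classify each "yes" response as Remember (context retrieved), Know
(no context) or Guess. The default estimator follows the independence
Remember/Know logic: recollection is the corrected Remember-rate difference
between targets and distractors, and familiarity is a \(d'\)-type contrast
of the non-Remember "yes" rates, each renormalized by \(1 - P^{*}(R)\) for
its item class:

\[
F_{\mathrm{old}} = \frac{P^{*}(K \cup G, \mathrm{yes} \mid \mathrm{old})}
                       {1 - P^{*}(R \mid \mathrm{old})},
\qquad
F_{rkg} = z(F_{\mathrm{old}}) - z(F_{\mathrm{new}}).
\]

Two points were genuinely open and are resolved as package defaults with the
alternative kept available:

* The R-index phrasing in the source protocols can be read several ways;
  besides the independence estimator, `variant = "literal"` computes the
  corrected yes-rate difference scaled by \(P(R \mid \mathrm{yes})\).
* Guesses count as familiarity-driven "yes" responses by default (they are
  "yes" responses without context); `drop_guesses = TRUE` removes them from
  counts and class totals for sensitivity analysis. Familiarity is exactly
  invariant to relabeling between K and G, so only the R/no margin matters.

Because the renormalized familiarity rate equals 1 exactly when a row has no
"no" responses, the rate is clamped into the corrected open interval
\([0.5/(n+1),\ 1 - 0.5/(n+1)]\) before the quantile transform, keeping
\(F_{rkg}\) finite for every legal table.

## Group statistics for small clinical samples

Patient/control comparisons use the two-sided Mann–Whitney \(U\) test
(exact by enumeration for \(n_1 n_2 \le 400\) without ties, otherwise a
tie-corrected normal approximation), accompanied by the Vargha–Delaney
\(A\): the probability that a random member of one group exceeds a random
member of the other, ties counting half. Subgroup contrasts (7 vs 5
patients) use a two-sided permutation test on the difference in group means,
enumerated exhaustively whenever \(\binom{n}{n_1} \le 50{,}000\) — the 7-vs-5
split has only 792 assignments — and otherwise estimated from seeded random
shuffles with the add-one p-value \((1 + \#\{|T| \ge |T_{obs}|\})/(1 + B)\).
The mean-difference statistic is the package default; a median-difference
option exists. Spearman's \(\rho\) (exact permutation p for \(n \le 8\),
t approximation above) covers the correlation analyses, Pearson's
\(\chi^2\) the nominal variables, and Bonferroni–Holm the multiplicity
correction. The Holm family is, by default, the three per-task comparisons
of one index — the family grouping is a reporting convention, not a
statistical necessity, and is easy to change upstream of `holm_correct()`.

Because the three tasks measure the same constructs, per-subject indices are
also standardized against the control mean and SD per task and averaged into
summary scores \(zd'\), \(zR\), \(zF\) (`z_summary()`); subjects missing a
task are excluded from summaries and reported.

## The synthetic cohort generator

No subject-level data ship with the package; `simulate_cohort()` generates
trial-level data from the same two-process latent model the estimators
assume: recollection as an all-or-none threshold process with per-subject
probability `rho`, familiarity as an equal-variance Gaussian strength shift
`delta`. That choice makes parameter recovery a fair test of the estimators
— each is consistent under the generative assumptions — which is exactly
what the test suite exploits. It is **not** a claim about real data:
empirical ROCs can show unequal variances, criteria drift over a session,
attribution errors blur R/K/G boundaries, and none of that is simulated.
Passing recovery tests therefore validates the estimation code, not the
model's fit to any particular patient population.

Defaults encode the study conditions: 12 patients (7 dMTT, 5 iMTT) and 25
controls; 120/60 items with 6-point confidence for the ROC task, 40/40/40
pairs for the dissociation task, 60/60 items for Remember/Know/Guess.
Latent distributions were chosen once to mirror the reported effect
pattern and magnitudes — controls at `rho` 0.55 (SD 0.12) and `delta` 1.2
(SD 0.30); patients at `rho` 0.15 with the *same* familiarity distribution,
so the default cohort has the headline dissociation built in: impaired
recollection and discrimination, spared familiarity, with control-vs-patient
stochastic superiority on the summary scores in the large-effect range
(\(A \approx 0.85\text{–}0.95\)) like the study reports. Confidence criteria
default to an evenly spread template \((-0.8, -0.35, 0.1, 0.55, 1.1)\)
shifted per subject (SD 0.15), the yes/no criterion to 0.55 (SD 0.15) —
mildly conservative relative to the midpoint between distributions — and the
guess rate to 0.15. Recombined pairs carry the full component familiarity
(`delta_assoc_frac = 1`, both words were studied), configurable down to 0.

Subgroup-specific distributions (dMTT: `rho` 0.10 and `delta` 0.8; iMTT:
`rho` 0.22, familiarity intact) reproduce the reported subgroup pattern and
are used by `draw_subject()` on request; `simulate_cohort()` only uses them
when `subgroup_effects = TRUE`, so the default cohort keeps familiarity
matched and treats subgroup labels as metadata.

## Worked example

```{r pipeline}
cfg <- sim_config(seed = 7)
cohort <- simulate_cohort(cfg)
indices <- score_subjects(cohort$trials)
results <- run_group_analysis(indices, cohort$groups, seed = 7)
results
```

Parameter recovery at the study design and a 10x design:

```{r recovery}
recover_parameters(cfg, n_replicates = 10, seed = 1)
```

The recovery table illustrates the expected pattern: estimates are nearly
unbiased, and the root-mean-square error shrinks when the item counts grow,
so at the study's own design most of the per-subject error is sampling
noise, which is precisely why the analysis averages three tasks.

## Problem sizes used in the validation suite

The test suite validates estimator consistency on 10,000-item-per-class
designs, the optimizer on model-expected count tables across a
\(R \in \{0, .2, .4, .6\} \times d_f \in \{0.5, 1, 1.5\}\) grid, test
calibration on 1,000 null replicates at the 12-vs-25 group sizes, and the
qualitative dissociation on 200 replicate cohorts at the default design —
sizes at which Monte Carlo error is small relative to the tolerances being
asserted while the whole suite stays comfortably interactive.

## Known limitations

* The equal-variance familiarity assumption is shared by generator and
  estimators; unequal-variance and mixture alternatives are out of scope.
* The dual-process ROC fit needs several populated confidence categories;
  12-item toy tables are fine for boundary checks but clinical use should
  keep the full 6-point scale.
* Permutation and Mann–Whitney p-values are two-sided throughout; one-sided
  hypotheses are not exposed.
* The pipeline reads behavioral CSVs only — imaging, lesion volumetry and
  neuropsychological covariates enter, if at all, as plain numeric columns
  correlated post hoc.
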