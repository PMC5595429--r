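# recmem

Dual-process analysis of recognition memory: estimation of **recollection**
(R) and **familiarity** (F) from trial-level data with three independent
procedures, plus the small-sample nonparametric statistics needed to compare
patient and control groups.

Recognition judgments can rest on recollection — all-or-none retrieval of
contextual detail — or on familiarity, a graded strength signal without
context. Clinical studies (e.g. of diencephalic or medial-temporal amnesia)
need estimates of both that do not hinge on one task or one estimation
procedure. `recmem` implements the three classical routes:

* **Confidence-rating ROC** — maximum-likelihood fit of the dual-process
  signal-detection (high-threshold) model. New items produce
  Normal(0, 1) familiarity strengths partitioned by five ordered confidence
  criteria; old items are recollected with probability R (forcing the top
  confidence category) or else produce Normal(d_f, 1) strengths:
  `fit_dpsd()`.
* **Process dissociation** on associative word pairs — recollection supports
  accepting intact pairs and vetoes accepting recombined ones, so
  R = p(included) − p(excluded) and F = p(excluded)/(1 − R):
  `pdp_indices()`.
* **Remember/Know/Guess** attribution with the independence correction:
  R = P\*(R|old) − P\*(R|new) and a d′-type familiarity contrast of the
  non-Remember "yes" rates: `rkg_indices()`.

Every task also yields equal-variance SDT indices d′ = z(H) − z(F) and
c = −(z(H) + z(F))/2, with all rates Snodgrass–Corwin corrected,
(x + 0.5)/(n + 1). Group inference uses Mann-Whitney U (exact where
feasible), exhaustive or Monte Carlo permutation tests, the Vargha-Delaney
A measure of stochastic superiority, Spearman correlations and
Bonferroni-Holm adjustment. A generative simulator with known latent
parameters (`simulate_cohort()`) supports parameter-recovery and power
studies end to end.

## Worked example

Simulate the default cohort (12 patients with reduced recollection and
matched familiarity, 25 controls; 120/60, 40/40/40 and 60/60 item designs),
score every subject on every task, and run the comparison battery:

```r
library(recmem)

cfg     <- sim_config(seed = 7)
cohort  <- simulate_cohort(cfg)
indices <- score_subjects(cohort$trials)
results <- run_group_analysis(indices, cohort$groups, seed = 7)
results
```

```
Per-task patient-vs-control comparisons (Mann-Whitney):
   index task   U    p    A n1 n2 computed p_holm
 d_prime  ROC 247 0.00 0.82 25 12     TRUE   0.00
 d_prime  PDP 271 0.00 0.90 25 12     TRUE   0.00
 d_prime  RKG 216 0.03 0.72 25 12     TRUE   0.03
       R  ROC 192 0.18 0.64 25 12     TRUE   0.18
       R  PDP 289 0.00 0.96 25 12     TRUE   0.00
       R  RKG 291 0.00 0.97 25 12     TRUE   0.00
       F  ROC 191 0.19 0.64 25 12     TRUE   0.58
       F  PDP 178 0.36 0.59 25 12     TRUE   0.73
       F  RKG 146 0.90 0.49 25 12     TRUE   0.90

Cross-task z-summary comparisons:
    index   U    p    A n1 n2 p_holm
 z_dprime 256 0.00 0.85 25 12   0.00
      z_R 284 0.00 0.95 25 12   0.00
      z_F 171 0.51 0.57 25 12   0.51
```

`U` is the Mann-Whitney statistic for controls vs patients and `A` the
probability that a random control outscores a random patient (0.5 = no
effect, above ~0.71 = large). The cohort shows the dissociation its
generator encodes: discrimination (d′) and recollection deficits across
tasks — strongest on the averaged z summaries (A = 0.85 and 0.95) — with
familiarity statistically indistinguishable (z_F p = 0.51). Per-subject
index tables (`indices`), per-subject z summaries (`results$z_table`),
zR–zF correlations and dMTT/iMTT subgroup permutation contrasts are all in
the returned objects; `write_results_json()` and `results_markdown()`
serialize them.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/recmem.R all --seed 7 --out-dir out/
```

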