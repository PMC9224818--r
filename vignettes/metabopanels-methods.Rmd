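---
title: "MetaboPanels: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MetaboPanels: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaboPanels)
```

MetaboPanels analyzes two-group (case/control) metabolomics and
nutritional cohorts: a subject-by-variable table of continuous
measurements with a diagnostic label and occasional missing cells. The
package implements four connected stages — a distribution-driven
univariate screen, group-contrasted correlation networks, density-based
multiple imputation, and biomarker-panel discovery with Fisher
discriminant analysis (FDA) and linear support vector machines — plus a
synthetic cohort generator that provides planted ground truth for all of
them. This vignette explains the statistical choices, the tunable
parameters, and what the simulations do and do not demonstrate.

## The univariate screen

Each variable is treated on its own. Subjects missing that variable are
dropped for that variable only. The two-sample test is chosen by a
decision tree driven by the data:

1. **Normality.** Shapiro–Wilk per group at `normality_alpha` (default
   0.05). Shapiro–Wilk is the standard choice at the group sizes typical
   of clinical cohorts (tens of subjects per group).
2. **Parametric branch.** If both groups look normal, an F-test on the
   two variances at `variance_alpha` decides between the pooled-variance
   t-test and Welch's unequal-variance t-test.
3. **Nonparametric branch.** Otherwise a two-sample Kolmogorov–Smirnov
   test compares the raw samples at `distribution_alpha`. If it does not
   reject, the groups share a distribution up to location and the
   Mann–Whitney test is used. If it rejects, both samples are centered
   at their means and KS runs again: not rejected routes to
   Mann–Whitney, rejected routes to Welch. Centering is used **only**
   for routing; the reported p-value always comes from the original
   samples. KS is used for both stages of this branch — the minimal
   consistent reading of a two-stage "same nonparametric distribution"
   check.

Mann–Whitney uses midranks for ties, exact enumeration when both groups
have at most 20 subjects and there are no ties, and the normal
approximation with continuity and tie correction otherwise. Inside the
leave-one-out sweeps the p-values are computed from direct formulas
(`pf`, `pt`, `pwilcox`, the asymptotic Kolmogorov series) for speed; the
test suite verifies them against `t.test`, `var.test`, `wilcox.test` and
`ks.test` to numerical precision.

Every variable also gets an AUROC: its values are treated as
classification scores and the rank statistic
\(A = P(\text{case} > \text{control}) + \tfrac12 P(\text{tie})\)
is computed by midranks. The reported AUROC is folded to
\(\max(A, 1-A)\) with a separate direction flag, matching the convention
of reporting discriminative strength plus an up/down arrow.

**Leave-one-out FDR.** Multiplicity is handled by a stability-oriented
variant of Benjamini–Hochberg: each subject is removed in turn, all
variables' p-values are recomputed (including re-routing through the
tree), BH is applied across variables, and each variable keeps its
*worst* q-value over the replicates. The aggregation (maximum) is the
conservative reading of "leave-one-out FDR": a discovery must survive BH
no matter which single subject is dropped. The choice is isolated in
`looFdr()` so an average- or full-data aggregation could be swapped in.
A variable is *significant* when `p < 0.05` and `FDR < 0.10` (both
configurable in `screenConfig()`).

The maximum-aggregation is deliberately strict. On synthetic cohorts
with planted per-variable AUROCs spread uniformly over 0.6–0.9 at
55/44 subjects, the p-gate alone has mean power about 0.90, plain BH
brings the flagged fraction to about 0.85, and the leave-one-out maximum
lowers it further to about 0.80: stability costs a few weak discoveries.
The test suite measures this recall honestly rather than relaxing the
aggregation.

## Correlation networks

Significant variables (optionally plus severity-score columns — any
numeric column can participate) are correlated pairwise with Pearson's
r, per group and combined, using pairwise complete cases (imputation is
reserved for the multivariate stage). The FDR of each pair uses the same
leave-one-out BH machinery, across pairs. An edge enters the network
when |r| > 0.35, p < 0.05 and FDR < 0.10; a stricter display threshold
(e.g. |r| > 0.40) can be applied at export time without touching the
analysis gates. Networks are exported as signed edge tables and SIF
files so a graph tool can color positive and negative correlations
differently.

`compareNetworks()` contrasts the two groups: shared, case-only and
control-only edges, per-node degree differences, and sign agreement on
shared edges. Edge counts follow the unordered-pair convention; the
doubled "directed" counts are reported alongside, because both
conventions occur in published work and the factor of two is a frequent
source of confusion.

## Multiple imputation

Missing cells are imputed from a one-dimensional Gaussian-kernel density
estimate fitted to the observed values of that variable *within the
subject's group* (bandwidth by Silverman's rule, Scott's as an option).
A draw is a resampled observation plus kernel noise; for strictly
positive variables draws are clipped to the observed range so
concentrations cannot go negative. With fewer than five observed values
(or a constant sample) the sampler falls back to empirical resampling
with a warning. Imputation `m` uses seed `base + m`, so any single
completed dataset is reproducible in isolation.

The univariate (per-variable) density is a deliberate simplification:
with at most a handful of missing subjects per variable it is robust and
reproducible, at the cost of ignoring cross-variable structure in the
imputed cells. Classifier results are pooled across imputations by plain
averaging of the AUROC (no Rubin's-rules variance combination), with the
across-imputation standard deviation reported as the spread.

## Fisher discriminant panels

For a panel of k variables, two-class FDA maximizes the Rayleigh
quotient \(J(w) = (w^\top S_B w)/(w^\top S_W w)\); the maximizer is the
closed form \(w \propto S_W^{-1}(\mu_1 - \mu_0)\), which the package
uses instead of a generalized eigendecomposition — equivalent for two
classes, deterministic, and fast enough for millions of leave-one-out
refits. \(S_W\) carries a small per-variable relative ridge
(`1e-6` of each diagonal entry, with an absolute floor for degenerate
variables) so collinear panels — such as two strongly correlated forms
of the same analyte — remain solvable. The relative (per-diagonal) form
keeps scores exactly invariant under per-variable rescaling; a single
trace-proportional ridge would not be. The reported direction is
unit-normalized; leave-one-out scoring keeps the raw solution so all
folds share one scale convention.

Cross-validation is leave-one-out: refit on n−1 subjects, score the
held-out subject, and compute the AUROC of the n held-out scores. With
missing data, LOOCV runs once per completed dataset and the metrics are
averaged; imputation is *not* redone inside each fold (the protocol is
impute-then-analyze, and per-fold re-imputation would multiply cost by n
for data that is only a few percent missing). During search a reduced
imputation count ranks panels (default 5); the retained models can be
re-scored at the full count afterwards. The operating point reported
with each panel maximizes Youden's J over the CV ROC, ties broken toward
higher sensitivity.

**Search protocol.** All panels of size 2–4 over the candidate set are
enumerated exhaustively; the top 1000 by CV AUROC (ties: fitted AUROC,
then lexicographic panel key, so results are bit-reproducible) seed a
greedy extension to sizes 5 and 6: every retained panel is extended by
every absent candidate, children are deduplicated, evaluated, and the
top 1000 retained again. When retention covers all k-panels the greedy
child set provably equals the exhaustive (k+1) enumeration — the test
suite exercises this identity. Marker prevalence (the fraction of
retained panels containing each variable) summarizes which markers
drive the top panels. Variant searches rerun the protocol with named
variables excluded (to surface markers hiding behind a dominant
correlated pair) and restricted to complete-case candidates without
imputation.

## SVM panels

The SVM mirror uses a linear kernel at cost 1 (no tuning — the minimal
interpretable configuration, both exposed in the config), variables
standardized on the training split. Every panel of the configured size
(default 5; 4 is also conventional) is fitted; only panels whose
*training* accuracy clears the gate (default 0.90) earn the
leave-one-out pass, and gated panels are ranked by LOOCV accuracy. On
unstructured data the gate may pass nothing and the ledger is
legitimately empty. The class imbalance of a 55/44 cohort is mild, so no
class weighting is applied; chance-level LOOCV accuracy is bounded by
the 0.556 majority-class rate, which the null-calibration tests check.

## The synthetic cohort generator

The generator exists so that every stage can be tested against known
truth; its defaults are the study conditions assumed throughout the
package: 55 case and 44 control subjects, 155 variables, 46 planted
effects whose per-variable AUROCs span 0.6–0.9, and MCAR missingness on
20 of the planted variables capped at 4 missing subjects per variable
(rate 0.02). The strong markers form sizeable correlated clusters in
both groups (within-cluster r between 0.45 and 0.55, shared effect
direction within a cluster — a metabolic cluster moves together), with
the control group's clusters larger plus one extra, so the control
network is clearly denser: the structure a case group with disrupted
metabolic coupling would show against its control group. Where the
underlying effect spectrum is characterized only by a range, the
generator takes the uniform reading (evenly spaced AUROCs); where
nothing is known — the marginal shapes — the choice is a modeling one:
a mix of normal, lognormal and heavy-tailed (t3) marginals with some
group-heteroscedastic variables, so that every branch of the
test-selection tree occurs in a default cohort.

Variables are built on a latent Gaussian scale, where block correlations
and standardized shifts are exact, and pushed through per-variable
monotone transforms. Monotonicity matters: it makes a planted effect's
AUROC invariant to the marginal family, so the closed-form map
\(\mathrm{AUROC} = \Phi(d/\sqrt2)\) (for a standardized shift d) holds
for every family. The mean-shift-over-pooled-SD contract is exact only
for normal-tagged variables, and correlation-recovery tests use
normal-tagged blocks, since nonlinear marginal transforms perturb
Pearson correlations. Missingness is MCAR with a per-variable cap; no
MNAR mechanism is simulated. The generator does not model assay error,
detection limits or batch effects — passing tests say the *statistics*
behave as designed, not that real assay data will look like this.

## Numerical and engineering choices

* Determinism: generation, imputation and searches are pure functions of
  their seeds; the RNG state of the caller is always restored.
* Degenerate inputs: constant variables are skipped with a log entry by
  the screen, dropped with a warning by the SVM, and absorbed by the
  ridge in FDA; a variable fully missing in one group is a hard error.
* AUROC ties: midranks everywhere (screen, FDA scores, SVM decision
  values); direction ties at A = 0.5 break to "case_higher".
* File formats: delimited text with 17-significant-digit numbers, so
  write-then-read round trips are exact; JSON sidecars carry seeds and
  column conventions.

## Problem sizes used by the test suite

Simulation-based checks run at sizes chosen to keep the whole suite in a
few minutes while leaving the statistical thresholds untouched: null
calibration uses 25 replicate 155-variable cohorts; planted-marker
recovery uses 20 screening replicates and 2 search replicates at 15
candidates; network recovery uses 40 replicates of 10-variable cohorts;
combinatorial counters for the 46-candidate search are verified exactly
in counting mode (k = 3, 4) and by full evaluation at k = 2. The
acceptance script (`scripts/acceptance.R`) runs one full pipeline at the
default study conditions with a 15-candidate FDA search breadth and a
10-candidate SVM search.

## Known limitations

* The leave-one-out/maximum FDR is intentionally conservative; expect a
  few percentage points lower recall for weak effects than plain BH.
* Univariate KDE imputation ignores cross-variable correlation in the
  imputed cells.
* Networks are plain thresholded Pearson graphs: no partial
  correlations, Gaussian graphical models or community detection.
* LOOCV estimates have high variance at n ≈ 100, and fitted AUROCs of
  searched panels are optimistically biased — the honest number for a
  panel is its CV AUROC, and even that is selection-biased for the
  top-ranked panel of a large search.
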