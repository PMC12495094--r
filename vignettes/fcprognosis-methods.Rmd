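---
title: "Prognostic modeling from functional coupling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prognostic modeling from functional coupling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcprognosis)
```

## The scientific problem

Clinical outcomes after a first episode of psychosis vary enormously
between patients, and a biomarker that predicted who will improve
would directly inform treatment choice. One candidate is interregional
functional coupling (FC): the matrix of Pearson correlations between
the resting-state activity time series of parcellated brain regions.
`fcprognosis` implements the full analysis pipeline for asking, with
honest cross-validated inference, whether baseline FC or its 3-month
change predicts 6- and 12-month change in symptoms (a BPRS-like
24-item scale, items scored 1-7) and functioning (a SOFAS-like 0-100
scale).

The outcome target is the proportional change score
$(y_2 - y_1)/y_1$ between baseline and a later visit. Two exploratory
alternatives are provided: the OLS slope of score on visit month over
each subject's available visits, and the proportional change of a
4-item positive-symptom subscale (unusual thought content, conceptual
disorganization, hallucinatory behavior, grandiosity).

## The three prediction algorithms

All predictors operate on the row-major strict-upper-triangle
vectorisation of each subject's FC matrix ($p(p-1)/2$ edges for $p$
regions), so that one fixed edge ordering is shared by every stage.

**Connectome-based predictive modeling (CPM).** Within each training
set, every edge is correlated with the outcome; edges with $r > 0$ and
two-sided $p < \alpha$ (or $r < 0$ and $p < \alpha$ for the negative
model) are selected, with $p$ from the exact t-transform
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df. Selected edge values are
summed into one scalar summary score per subject and a one-variable
OLS line of outcome on summary score is fitted; test subjects are
predicted from their own summary scores. The default threshold is
$\alpha = .05$ uncorrected, with $.001$ as the conventional stricter
alternative. When no edge survives (common under the null at strict
thresholds) the model degenerates, deliberately, to predicting the
training-mean outcome: every split then remains well defined. The
sign condition and the two-sided p-value are checked as two separate
conditions; positive and negative selections on the same training set
are therefore disjoint.

**Kernel ridge regression (KRR).** Each test outcome is a regularised
weighted mean of training outcomes, with weights derived from the
similarity kernel $K_{ij} = \mathrm{cor}(x_i, x_j)$ between subjects'
FC vectors. The dual weights solve $(K + \lambda I)\,\alpha = y -
\bar{y}$, with $\bar y$ re-added at prediction. The penalty $\lambda$
is tuned by an inner loop of 4-fold cross-validation within each
training set, scored by the mean inner-fold Pearson correlation
between predictions and outcomes -- the same metric as the outer
evaluation. The default grid is 16 logarithmically spaced values from
$10^{-3}$ to $10^{4}$ plus 0, in ascending order; ties break toward
the earliest (smallest) grid entry, so selection is deterministic
given the inner fold allocation, which is the only randomness in the
model and is seed-controlled. A $\lambda$ at which $K + \lambda I$ is
numerically singular -- always $\lambda = 0$ when subjects outnumber
edges' effective rank -- is skipped with a warning rather than
aborting the fit.

**Meta-matching-style proxy stacking.** A bank of proxy-phenotype
models is trained on large source cohorts: a first cohort supplies
*base* phenotypes modelled directly from FC, later cohorts supply
*extra* phenotypes modelled from the base-proxy rows (the multilayer,
stacked part). Each phenotype is fitted by two model families: linear
ridge regression, and ridge regression on a seeded random ReLU
feature expansion. The latter is a desk-scale stand-in for a deep
network: it preserves the two-family, two-layer architecture and the
nonlinear basis while remaining trainable in milliseconds and exactly
reproducible from a seed. Target subjects are mapped to
$n_\mathrm{families} \times (n_\mathrm{base} + n_\mathrm{extra})$
proxy features (458 for the reference 67 + 162 two-family
configuration) and a final KRR on the proxies predicts the clinical
target. Because the bank is trained on single-visit source scans,
the stage applies to baseline-FC predictors only. The bank is trained
once, outside the cross-validation loop, which is legitimate: it
never sees the target cohort's outcomes.

## Evaluation and inference

Each model runs 4-fold cross-validation: subjects are partitioned
uniformly at random into folds whose sizes differ by at most one (no
outcome stratification), each fold is held out once, and the
out-of-fold predictions of all subjects are pooled into **one**
Pearson correlation per split. Pooling (rather than averaging four
per-fold correlations) uses every subject exactly once and keeps small
test folds from producing wildly unstable per-fold values. The
performance statistic is $r_\mathrm{mean}$, the mean of this
correlation over repeated random splits (100 in the main-analysis
convention).

Significance comes from permutation: outcomes are shuffled among
subjects by a seeded permutation, the *entire* pipeline -- feature
selection, hyperparameter tuning, everything inside training folds --
is rerun per permutation at a reduced split budget (100 for CPM, 50
for KRR, 20 for meta-matching by convention), and
$p = \#\{r^\mathrm{null}_\mathrm{mean} \ge
r^\mathrm{obs}_\mathrm{mean}\}/n_\mathrm{perm}$. Ties count against
the observed value; the $(b+1)/(n+1)$ estimator is available as a
configuration flag. Familywise error over a grid of models sharing
one algorithm is controlled by the Westfall-Young max-statistic
method: the familywise null value at permutation $k$ is the maximum
null $r_\mathrm{mean}$ across the grid's models at $k$, and each
model's $p_\mathrm{FWE}$ is computed against that single maximum
distribution, guaranteeing $p_\mathrm{FWE} \ge p$ cell by cell.

A property worth knowing: under the null, $r_\mathrm{mean}$ is *not*
centred at zero but is negatively biased (around $-0.2$ for CPM at
$n = 48$ in our synthetic cohorts). Training-fold feature selection
overfits noise, and what overfits in training anti-generalises in the
test fold. This is precisely why inference uses permutation nulls of
the whole pipeline rather than a parametric zero-centred reference,
and why the package's null-distribution tests check the upper tail
rather than symmetry about zero.

Seeding is hierarchical: split $s$ of permutation $k$ derives its
fold allocation from an integer hash of $(\mathrm{seed}, k, s)$
(`mix_seed()`), so every stage is reproducible and independently
addressable; the observed statistic is permutation stream 0.

### Batched engines

`cpm_permutation_study()` and `krr_permutation_study()` evaluate
permutation ensembles in a vectorised form: the CPM engine shares one
edge-outcome correlation pass and one summary-score matrix product
across all (target x sign) models per fold, and the KRR engine builds
the cohort similarity kernel once (it is a pure function of the
features, never of the outcomes or folds) and subsets it per training
fold. Both are exact-equivalence optimisations -- the test suite
asserts agreement with the generic `evaluate_model()` /
`permutation_test()` path to numerical precision with identical seeds
-- not approximations.

## The synthetic cohort generator

No patient data ship with the package; every statistical property is
exercised on synthetic cohorts with known ground truth
(`generate_cohort()`).

**Time series.** Each subject's parcellated scan is drawn from a
low-rank latent-factor model: a cohort-wide backbone loading matrix
$L$ ($p \times k$, $k = 5$ by default) plus a subject-level
perturbation ($\tau = 0.35$) defines subject loadings $D_s$, and the
scan is $D_s Z + E$ with white noise. This produces realistic
between-subject FC variance and correlated edges without modelling
hemodynamics. The 3-month scan adds a further loading drift
($\delta = 0.15$), so change (delta) matrices are non-trivial.

**Planted effect.** A sparse weight vector $w$ places unit positive
weights on `n_causal_edges` random edges -- a sign-coherent circuit in
which stronger coupling tracks better outcomes, the configuration
that signed CPM selection is designed to detect (the negative-sign
model then acts as an internal null). The latent signal is $g_s = w
\cdot \mathrm{vec}(\mathrm{FC}_s)$ computed from each subject's
*realised* baseline FC, so the planted association survives FC
estimation noise exactly. Proportional-change targets are built as
$\mu + \sigma_c(\sqrt{\rho^2}\, z(g) + \sqrt{1-\rho^2}\,
\varepsilon)$ with `effect_r2` $= \rho^2$ the planted fraction of
target variance carried by FC, $\sigma_c = 0.25$ the between-subject
change SD, and visit-specific means $\mu$ matching a treated
first-episode cohort (functioning up about 20%, symptoms down about
25% at 6 months). The noise $\varepsilon$ is correlated 0.3 between
the two scales: symptoms and functioning are related but not
interchangeable.

**Bounded scales with exact ground truth.** Baseline scores are drawn
at realistic cohort moments (SOFAS-like 52.5 +/- 12.4, BPRS-like 57.8
+/- 9.4, truncated inside the scale bounds) and follow-up scores are
derived multiplicatively, $y_2 = y_1(1 + c)$, so the
proportional-change formula recovers the planted target to machine
precision. Where a follow-up score would leave the scale bounds it is
clamped and the clamped change is what is stored as ground truth.
Item-level BPRS scores distribute each total over 24 items by a
per-subject random profile with capped redistribution, so item sums
reproduce the recorded totals and every item stays in [1, 7].

**Attrition** removes the 3-month scan of a
missing-completely-at-random subset (default 35% of subjects),
mirroring a cohort in which outcomes did not differ between subjects
with and without the second scan. Delta-FC models therefore run on
the subjects with both scans; nothing is imputed anywhere in the
pipeline.

**What the generator does not emulate:** scanner artifacts, head
motion, denoising choices, site effects, outcome-dependent dropout,
integer-rounded clinical scoring, or heavy-tailed outcome
distributions. Passing tests show that the *statistical machinery* is
calibrated and powerful under a clean generative model; they cannot
show that real FC carries prognostic signal.

## Problem sizes and numerical choices

Defaults emulate the motivating cohort (55 subjects, 419 regions, 35%
scan attrition, no planted effect -- reflecting that study's null
result). The statistical test batteries run at a deliberately compact
desk scale chosen once: cohorts of n = 48 with an 8-region
parcellation (28 edges), 150 samples per scan, 5 causal edges, 99
permutations and 10 splits per permutation; 200 null cohorts for
calibration and familywise-error checks, 50 cohorts at `effect_r2 =
0.5` for power and edge-recovery checks, and 50 seeds for the
transfer property with source cohorts of n = 2000 (5 base + 10 extra
phenotypes). The compact parcellation keeps the ratio of planted to
total edges high enough that an $r^2 = 0.5$ effect is learnable at
n = 48 -- with tens of thousands of edges and five causal ones, no
algorithm could recover the signal at this sample size, which is a
statement about the design, not about the implementation under test.

Other numerical decisions, made once:

- **No Fisher z-transform** of FC values before prediction, and no
  per-edge standardisation; both exposed as natural extension points
  but off by default for fidelity to raw-correlation modeling.
- **Degenerate inputs are errors, not repairs**: a region with zero
  temporal variance, a subject with a constant feature vector, or a
  constant outcome vector all raise informative errors; a constant
  *edge column* is excluded from CPM selection with a warning, and a
  constant *proxy column* is dropped before the correlation kernel.
- **Constant pooled predictions** in a split (e.g. an all-degenerate
  CPM model) score a correlation of 0 with a warning rather than NA,
  keeping permutation ensembles well defined.
- **Tie-breaking** everywhere is toward the first candidate in a
  documented ordering, never toward a data-dependent choice.
- Eigendecomposition-based dual solves treat $\lambda$ as unusable
  when $\min(d_i + \lambda)$ falls below $10^{-10}$ of the spectral
  scale.

## Known limitations

- On a sparse sign-coherent planted circuit, CPM's selected-sum is
  close to the generating model and outperforms the correlation-kernel
  KRR, which spreads weight over every edge; KRR's power under such
  geometry sits near the detection boundary at n = 48. A distributed
  planted effect would reverse the ordering.
- The nonlinear proxy family is a random-basis ridge, not a trained
  deep network; it reproduces the architecture's structure, not its
  representational capacity.
- The generator's outcome distributions are Gaussian within bounds;
  real clinical scales are integer-valued, skewed, and floor/ceiling
  prone.
- Slope targets use whatever visits exist (2 or 3 points); with two
  points the "slope" is just a scaled difference.
- Permutation p-values at 99 permutations have a resolution of about
  0.01; the main-analysis convention of 1000 permutations is the
  intended inferential scale.
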