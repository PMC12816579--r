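---
title: "Uncertainty-aware models for toxicological points of departure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware models for toxicological points of departure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uamtox)
```

## The problem

A point of departure (POD) is the lowest dose on a dose-response curve at
which adverse effects begin; lower PODs mean more potent chemicals. Curated
in vivo PODs exist for only a few thousand chemicals, while >100,000
chemicals are on the market. QSAR regression models can fill the gap, but a
bare point prediction hides how much the model actually knows about a given
chemical. `uamtox` builds regressors that attach a calibrated 95% confidence
interval to every predicted POD, and ships the diagnostics needed to check
that those intervals mean what they claim.

Two endpoints are distinguished throughout: reproductive/developmental
(`rd`) and general non-cancer (`nc`) effects under chronic oral exposure.
PODs enter in mg/kg-d and are modelled internally in log10(mol/kg-d)
(`convert_pod_units()`), the natural scale for relating molecules to
biological activity; predictions are back-converted to mg/kg-d for
presentation.

## Data curation rules

`standardize_structure()` applies a deliberately simple, fully documented
rule set rather than a full published standardization workflow:

* multi-component SMILES keep the **largest organic component** (largest by
  heavy-atom count; ties broken by molecular weight, then canonical-SMILES
  lexicographic order, so salt stripping is deterministic);
* compounds without carbon are excluded as `inorganic`;
* a metal atom (anything outside H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I)
  in the retained component excludes it as `organometallic`;
* retained components above 1000 g/mol are excluded as `too_large`;
* uninterpretable strings are excluded as `unparseable`.

Exclusions are **returned, not raised**: expanded-dataset workflows keep the
non-standardized chemicals and models trained on them flag their library
predictions as provisional. Tautomer canonicalization and full valence
correction are out of scope.

PODs supported by fewer than four underlying experimental data points are
removed (`filter_by_support()`, `min_points = 4`) because sparsely supported
surrogate PODs carry large aleatoric uncertainty. PODs for dioxin-like
chemicals can be derived from toxic equivalency factors with
`pod_from_tef()`; a TEF is a relative potency against the index compound
2,3,7,8-TCDD, so the derived POD is the index POD **divided** by the TEF
(the literature rarely prints this formula; the direction follows from
"higher relative potency means lower effect dose").

## Featurization and leakage-free preprocessing

Four descriptor families are supported (`featurize()`):

* `morgan_fp` — circular (Morgan/ECFP-type) fingerprints, radius 2, folded
  to 1024 bits. The fingerprint backend is OpenBabel's ECFP implementation
  (via ChemmineOB), folded by OR-ing congruent bit positions.
* `maccs_keys` — MACCS structural keys.
* `physchem_2d` — continuous 2D descriptors: molecular weight, logP, TPSA,
  molar refractivity, H-bond donor/acceptor counts, constitutional counts
  and a cyclomatic ring count.
* `learned_embedding` — embeddings from pretrained neural models are
  *ingested* from a table keyed by `chem_id`, never computed: they require
  a pretrained network that is not this package's business.

Preprocessing (`fit_feature_pipeline()` / `apply_feature_pipeline()`)
follows one rule: **every parameter is estimated on the training rows and
then frozen.** For the knowledge-based families (`maccs_keys`,
`physchem_2d`) features with |Pearson r| > 0.9 are greedily removed —
features are walked in input order and the later member of an offending
pair is dropped, which makes the mask deterministic. The structural
representations (`morgan_fp`, `learned_embedding`) pass through untouched:
they are valid representations only as a whole. `physchem_2d` additionally
gets per-feature Yeo-Johnson transforms (lambda estimated by maximum
likelihood via caret) and centring/scaling to zero mean, unit variance on
the training rows. Zero-variance features are dropped with a warning —
neither transform is defined for them. Whether Pearson correlation on 0/1
MACCS columns should be treated differently from continuous columns is
genuinely open; the package applies the identical rule to both.

Inside cross-validation the pipeline is refitted within each training fold,
so no test-fold value can influence any preprocessing parameter; the test
suite asserts bit-identical pipelines under corrupted test folds.

## The conformalized quantile regression forest

The core regressor is a quantile regression forest: a random forest whose
leaves retain the raw training targets of their bootstrap (inbag) members.
For a query x, training point i receives the Meinshausen weight

$$w_i(x) = \frac{1}{T}\sum_{t=1}^{T} \frac{b_{it}\,\mathbf 1[\ell_t(x_i) = \ell_t(x)]}{\sum_j b_{jt}\,\mathbf 1[\ell_t(x_j) = \ell_t(x)]}$$

(b = inbag counts, l = leaf assignment), and the level-q estimate is the
left-continuous inverse of the weighted empirical CDF,
inf{y : F(y) >= q}. The same left-continuous rule is used inside each
single tree; pinning one quantile definition everywhere is what makes the
implementation checkable against a brute-force oracle, and the test suite
demands *exact* equality with that oracle on small forests.

Conformalization makes the intervals honest. On a calibration set disjoint
from the training rows, each point gets a nonconformity score

$$E_i = \max\left(\frac{q_{lo}(x_i) - y_i}{s(x_i)},\; \frac{y_i - q_{hi}(x_i)}{s(x_i)}\right)$$

where s(x) is the standard deviation of the per-tree median predictions —
the ensemble's *epistemic* spread, floored at 1e-6 so unanimous forests
cannot divide by zero. The conformal quantile `c_hat` is the k-th smallest
score with k = ceil(level(n_cal + 1)), capped at n_cal, and intervals are

$$[\,q_{lo}(x) - \hat c\, s(x),\; q_{hi}(x) + \hat c\, s(x)\,].$$

Scaling scores by s(x) is the uncertainty-aware refinement of
conformalized quantile regression (UACQR): intervals widen where the trees
disagree, while the finite-sample marginal coverage guarantee of split
conformal prediction is untouched. Several variants of this construction
exist; the package implements the spread-scaled score form as default and
plain CQR (s = 1) behind `variant = "cqr"`, because the spread-scaled form
is the one that uses the forest's own epistemic signal. The point estimate
is the ensemble median, and bounds are clipped so lower <= median <= upper.

Forest defaults (`n_trees = 500`, `leaf_min = 5`) follow common
random-forest practice for datasets of a few thousand chemicals and are
config-exposed; nothing in the method depends on them delicately.
`train_uacqr()` wraps the full protocol — a stratified 20% internal
calibration split, forest fit, conformal calibration — which is the same
protocol used inside each CV fold and when retraining a final model before
library screening.

## The Bayesian neural network

The second regressor is a mean-field variational BNN: one ReLU hidden
layer (default width 128) and an output layer with two heads, the
predictive mean and, through a softplus, the predictive SD of a
heteroscedastic Gaussian. Each weight carries a diagonal Gaussian
posterior q(w | mu, softplus(rho)^2); the prior is a scale mixture of two
zero-mean Gaussians (default pi = 0.5, sigma1 = 1, sigma2 = 0.0025 — one
wide, one narrow component). The KL term has no closed form against a
mixture prior, so the negative ELBO is estimated by Monte Carlo using the
same weight samples as the likelihood term, with reparameterized gradients
(w = mu + softplus(rho) * eps) — the Bayes-by-backprop estimator. Training
is full-batch Adam, reproducible from the seed; optimizer settings
(`learning_rate = 0.01`, `n_epochs = 500`) are config-exposed since no
canonical values exist for this architecture family.

Predictions are formed from draws (default 500) that sample weights
(epistemic) and then the Gaussian output (aleatoric);
`summarize_predictive()` reduces draws to median, central interval and SD
using linear interpolation between order statistics — the percentile rule
is pinned so tests are bit-stable. `predict_aleatoric_sd()` exposes the
noise head alone, which is how the tests check that known simulation noise
is recovered. The network width, priors and optimizer were not tuned per
dataset; BNN accuracy is expected to trail the conformal forest, and the
package makes no claim otherwise.

## The calibration suite

Three complementary diagnostics ask three different questions:

* **Confidence-based** (`confidence_calibration()`): across nominal levels
  1%–99% (1% steps), does the observed fraction of targets inside the
  level-p interval match p? Summarized by ECE, the mean absolute gap.
  Degenerate extremes anchor the scale: always-covering and never-covering
  intervals both give ECE = 0.5.
* **Error-based** (`ence()`): sort chemicals by predictive SD, split them
  into B batches, and compare each batch's root mean uncertainty
  RMU = sqrt(mean sigma^2) with its observed RMSE. ENCE is the mean of
  |RMU - RMSE| / RMU. The batch count defaults to the entropy-based
  optimum B = round(sqrt(n)) — `round`, not `floor`, because the rounded
  rule reproduces batch sizes of 42–49 for datasets of 2357 and 1845
  chemicals, the sizes the reference analysis reports. When n is not a
  multiple of B, remainder items go to the highest-uncertainty batches;
  sorting is stable so ties keep input order. Because ENCE is known to be
  sensitive to B, `ence_sensitivity()` sweeps B over 5–200.
* **Distance-based** (`distance_calibration()`): with the same batching,
  does mean predictive SD track mean structural unfamiliarity? Distance is
  the mean Jaccard (Tanimoto) distance to the 5 nearest training
  fingerprints (`knn_jaccard()`; a pair with empty union is defined as
  distance 0). A positive Spearman correlation across batches shows the
  model recognizes chemicals outside its applicability domain.

For conformal models the per-chemical SD entering these diagnostics is the
Gaussian-equivalent sigma = width / (2 * 1.959964) of the 95% interval —
an explicit convention, since conformal intervals are not Gaussian and may
be asymmetric; for the BNN it is the SD of the predictive draws. ECE
levels for the BNN use central percentile intervals.

## Benchmarking and consensus

`run_cross_validation()` implements stratified (repeated, optionally
nested) cross-validation: targets are binned into deciles by default, bins
are shuffled with a seeded RNG and dealt round-robin so fold sizes differ
by at most one. Metrics are MAE, median AE, RMSE, R-squared (and adjusted),
Pearson and Spearman. Baseline learners (linear, ridge, kNN, SVM, random
forest, gradient boosting, feed-forward net) are thin plug-ins over
standard packages — they are benchmarks, not contributions.

`paired_error_test()` supports both degrees-of-freedom conventions that
appear in repeated-CV practice: a classic paired t-test on per-chemical
errors (df = n - 1) and a Nadeau–Bengio corrected t-test on per-repeat
scores (df = repeats - 1), whose variance correction (1/J + n_test/n_train)
compensates the optimism of overlapping training sets. Which convention a
given comparison should use is ambiguous in parts of the literature, so
both are first-class and the caller chooses.

`build_consensus()` averages the predictions of the best conventional model
and every model not significantly worse than it (two-sided p >= 0.05,
corrected test). The phrase "highest statistically significant
performances" admits a stricter reading — keep only the single best model —
which is available as `rule = "best_only"`.

## Screening and class ranking

`predict_library()` featurizes a library with the *training* pipeline,
predicts intervals, and back-converts to mg/kg-d. Chemicals whose
featurization fails are flagged, never silently dropped; non-standardized
chemicals are marked provisional and should only be predicted by models
trained on expanded datasets. `embed_chemical_space()` is an exact
(O(n^2)) t-SNE on squared Jaccard distances between fingerprints —
perplexity 30 by default, deterministic given the seed — suitable for the
few-thousand-chemical maps the package targets. `rank_classes()` groups
chemicals by their lowest available taxonomy level (subclass, then class,
then superclass), drops classes under 30 members, ranks by ascending
median predicted POD and reports each class's high-potency fraction — the
share of members inside the library-wide top 1% most potent medians,
computed per endpoint on the whole standardized library.

## The synthetic generator

`make_synthetic_qsar()` exists so the coverage guarantee and all three
calibration diagnostics can be exercised against known ground truth,
without any downloads. It emulates the statistical features of curated POD
data that matter here:

* log10-scale targets whose realized total variance is calibrated to a
  goal (default 1.17, the general non-cancer regime; 0.69 mimics the
  reproductive/developmental one) by rescaling the signal after fixing the
  noise;
* right-skewed cluster effects (centred-exponential offsets);
* heteroscedastic noise, SD = 0.3 + 0.25 |z2| with z2 a latent descriptor,
  so interval widths have something real to adapt to;
* cluster structure in fingerprint space: sparse prototype bit vectors
  (density 0.1) plus independent per-bit flips. The default flip rate of
  0.02 puts within-cluster Jaccard distances near 0.25 — the coherence of
  a congeneric chemical series, comfortably inside the ~0.5
  applicability-domain shoulder — while distinct clusters sit near
  distance 0.9.

Continuous descriptors are random projections of the fingerprints, because
real 2D descriptors are functions of structure; this is what makes a
held-out cluster *feature*-novel as well as *structure*-novel, so
distance-based calibration has a real signal to find. The generator does
not emulate chemistry: pseudo-fingerprints are not molecules, there are no
activity cliffs, and the noise is Gaussian. Passing tests on synthetic
data therefore demonstrate the statistical machinery (coverage,
calibration, leakage-freedom), not predictive accuracy on real PODs. The
hand-listed `make_toy_fixture()` (20 real SMILES, fabricated PODs)
covers the chemistry paths instead: every standardization branch, both
endpoints, and taxonomy labels.

## Numerical choices, problem sizes, limitations

Numerical pins, chosen once: left-continuous inverse CDF for all forest
quantiles; epistemic-spread floor 1e-6; linear-interpolation percentiles
for BNN draws; stable sorts everywhere ties can occur; conformal rank
ceil(level(n+1)) capped at n_cal; batch remainder to the
highest-uncertainty batches; correlation-filter drops the later feature.

The test suite runs at deliberately modest sizes — forests of 25–500
trees, synthetic datasets of 500–3500 chemicals, 10–20 seeds per
property — chosen so the full suite completes in a couple of minutes while
still giving each statistical assertion enough resolution (a coverage
check on 2000 held-out points has a standard error of ~0.5 percentage
points). The acceptance script uses n_train = 1000, n_cal = 500,
n_test = 2000.

Known limitations: descriptors are 1D/2D only (no conformers,
stereochemistry or enantiomer discrimination); OpenBabel's ECFP bit
hashing differs from other toolkits', so absolute bit positions are not
interchangeable across backends (Jaccard geometry is); the exact t-SNE is
quadratic in n; the BNN is a single fixed architecture with no
hyperparameter search; and no recalibration is offered — the calibration
suite diagnoses, it does not adjust.
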