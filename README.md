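# uamtox

Uncertainty-aware machine learning for toxicological points of departure
(PODs).

A POD is the lowest dose at which a chemical begins to cause adverse
effects; lower PODs mean more potent chemicals. Curated in vivo PODs exist
for only a few thousand substances, so QSAR regression models are used to
estimate them for the rest of the >100,000 marketed chemicals — but a bare
point prediction says nothing about how far to trust it. `uamtox` trains
regressors that attach a **calibrated 95% confidence interval** to every
predicted POD and ships the diagnostics to verify those intervals are
honest.

The core regressor is an **uncertainty-aware conformalized quantile
regression forest (UACQR)**: a quantile regression forest (leaves retain
raw training targets; conditional quantiles via Meinshausen's weighted
empirical CDF, q̂(x) = inf{y : F̂(y|x) ≥ q}) whose central interval
[q_lo(x), q_hi(x)] is widened by split-conformal calibration with
nonconformity scores scaled by the ensemble's epistemic spread s(x) (SD of
per-tree medians):

    E_i = max( (q_lo(x_i) − y_i) / s(x_i), (y_i − q_hi(x_i)) / s(x_i) )
    interval(x) = [ q_lo(x) − ĉ·s(x),  q_hi(x) + ĉ·s(x) ]

with ĉ the ⌈level·(n_cal+1)⌉-th smallest calibration score. Intervals
inherit the finite-sample marginal coverage guarantee of split conformal
prediction and widen where the forest disagrees with itself. A mean-field
variational Bayesian neural network (Bayes-by-backprop, scale-mixture
prior, heteroscedastic Gaussian output) is provided as the probabilistic
alternative.

Around the regressors sits the full pipeline:

- **data_io** — chemical table ingestion, structure standardization (salt
  stripping, inorganic/organometallic/oversize exclusion), POD unit
  conversion mg/kg-d ↔ log10(mol/kg-d), TEF-derived PODs, support-count
  filtering;
- **descriptors** — MACCS keys, Morgan-type circular fingerprints
  (1024 bits, radius 2), 2D physicochemical descriptors, ingested learned
  embeddings; leakage-free fold-wise preprocessing (correlation filter at
  |r| > 0.9, Yeo-Johnson + standardization for continuous descriptors);
- **calibration** — confidence-based (ECE over levels 1–99%), error-based
  (ENCE over √n uncertainty-sorted batches), and distance-based (mean
  Jaccard distance to the 5 nearest training fingerprints) diagnostics;
- **evaluation** — stratified repeated (nested) cross-validation,
  MAE/MdAE/RMSE/R², paired corrected t-tests, consensus baselines;
- **screening** — library prediction in mg/kg-d, exact t-SNE chemical-space
  maps, ClassyFire-style class ranking by median potency with high-potency
  fractions;
- **synthetic** — a generator of structure–toxicity datasets with known
  ground truth (cluster-structured pseudo-fingerprints, heteroscedastic
  noise, calibrated target variance) so every guarantee is testable
  offline.

## Worked example

Train a UACQR model on synthetic data with known ground truth and check
its calibration:

```r
library(uamtox)

dat <- make_synthetic_qsar(synthetic_spec(n_chems = 1500, seed = 42))
train <- 1:1000; test <- 1001:1500

model <- train_uacqr(dat$features[train, ], dat$y[train],
                     level = 0.95, seed = 42)
model
#> <uacqr_model> level=0.95 (uacqr), n_train=800, n_cal=200

iv <- predict(model, dat$features[test, ])
head(iv[, c("chem_id", "median", "lower", "upper", "width", "sigma")], 3)
#>    chem_id  median  lower  upper width sigma
#> 1 SYN01001  0.2239 -1.721  1.967  3.69 0.941
#> 2 SYN01002 -1.1882 -2.365 -0.401  1.96 0.501
#> 3 SYN01003  0.0772 -0.776  0.974  1.75 0.447

mean(dat$y[test] >= iv$lower & dat$y[test] <= iv$upper)
#> coverage: 96.8%

confidence_calibration(dat$y[test],
                       function(p) predict(model, dat$features[test, ],
                                           levels = p))
#> <calibration_curve> confidence  99 points  ECE=0.0240  Spearman=1.000

ence(dat$y[test], iv$median, iv$sigma)$curve
#> <calibration_curve> error  22 points  ENCE=0.1953  Spearman=0.589
```

Reading the output: `median`, `lower`, `upper` are log10(mol/kg-d)
predictions (use `invert_pod_units()` or `predict_library()` for mg/kg-d);
`sigma` is the Gaussian-equivalent SD of the 95% interval
(width / 3.92). The 96.8% empirical coverage matches the 95% nominal level
within sampling error (the conformal guarantee is ≥ 95% in expectation);
ECE of 2.4% says nominal and observed coverage agree closely across all
levels 1–99%; the error-based curve's positive Spearman says wider
intervals do land on chemicals with larger actual errors. On training sets
with a structurally novel held-out cluster, `distance_calibration()`
additionally shows predictive SD tracking Jaccard distance from the
training set — the applicability-domain diagnostic.

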