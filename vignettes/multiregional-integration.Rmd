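---
title: "Modeling multiregional integration from ROI time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling multiregional integration from ROI time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roinet)
```

## The model

roinet treats each region of interest (ROI) in a resting-state fMRI
recording as a target to be explained by the other regions. With activity
expressed in percent signal change (so every series has zero mean over the
recording), the model for target ROI $i$ is the intercept-free weighted sum

$$\hat x_i(t) \;=\; \sum_{j \neq i} \omega_{j,i}\, x_j(t),$$

where $x_j$ is the observed activity of candidate predictor ROI $j$ and
$\omega_{j,i}$ its weight. There is no autoregressive self-term: the question
is how well *other* regions jointly explain a region's activity, not how
predictable it is from its own past.

Accuracy is measured as the normalized prediction error

$$E \;=\; 100 \times
  \frac{\langle (\hat x_i - x_i)^2 \rangle}
       {\langle (x_i - \bar x_i)^2 \rangle},$$

in percent of the activity variance, with $\bar x_i$ the mean of the
observed series over the evaluated segment and all averages using the
population convention (divide by $n$). A model that outputs the segment
mean at every timepoint scores exactly 100% — the chance level — which
`prediction_error()` reproduces to machine precision.

## Segmentation

Each recording is split once into contiguous segments: training (first
half), validation (third quarter), and test (last quarter). All fitting
uses the training rows; all model selection uses validation error; all
reported errors and gains use the test rows, which no selection step ever
sees. Boundaries use the floor rule on 0-based half-open ranges — for
odd-ish lengths such as 661 timepoints the split is $[0, 330)$,
$[330, 495)$, $[495, 661)$. The source data do not dictate how a
non-divisible length apportions its spare timepoints; the floor rule is this
package's fixed choice and is recorded in every run manifest.

Before any fit, each column is centered by its *training-segment* mean (the
same offsets are applied to validation and test rows), guarding against
slow drift between segments while preserving the intercept-free form: the
induced scalar offset is carried in the model object and is zero for
hand-constructed models. Predictors are additionally z-scored by their
training-segment standard deviation; weights are mapped back to the percent
signal-change scale afterwards. Standardization matters because the
elimination rule below compares weight magnitudes across predictors — on
the standardized scale "smallest weight" is scale-invariant.

## Recursive feature elimination

`run_rfe()` implements backward selection:

1. start from all $R-1$ candidate predictors and fit by ordinary least
   squares on the training segment;
2. record the validation error of the model;
3. remove the predictor with the smallest absolute standardized weight
   (ties break toward the lowest ROI id — no predictor is privileged by
   sign, scale or position);
4. refit and repeat until one predictor remains.

One predictor is removed per iteration, which keeps the validation-error
curve interpretable at a per-predictor resolution.

Two rules turn the trace into a final model:

* **RFE** (`select_final_rfe()`): keep a predictor eliminated after step
  $t$ if and only if the validation error at step $t$ was *strictly* below
  the smallest validation error over all later steps — its removal
  permanently raised the error floor. The final surviving predictor is
  always kept: the rule is defined only for eliminated predictors, and
  without the survivor a monotonically improving trace would yield an empty
  model. The kept set is refit by OLS on the training segment. Equality is
  not enough to keep a predictor: if elimination merely failed to lower the
  floor, the predictor was redundant.
* **RFE2** (`select_final_rfe2()`): return the stored model at the minimum
  of the validation curve, without refitting. Ties at the minimum resolve
  toward the later step, i.e. fewer predictors.

The RFE set is provably nested inside the RFE2 set: every kept elimination
occurs at or after the validation-curve minimum, and the survivor belongs
to every model in the trace. RFE therefore always yields the sparser model,
which is the point — the package's aim is suppressing false-positive
predictors, accepting that an inclusive method (elastic net below) may
recover marginal true predictors that RFE prunes.

## Regularized baselines

`fit_lasso_path()` minimizes
$\langle(\hat x_i - x_i)^2\rangle + c\,\lVert\omega\rVert_1$ over a
log-spaced grid of 200 regularization magnitudes from $c_{\max}$ (the
smallest $c$ with an all-zero solution) down to $c_{\max} \times 10^{-4}$,
and returns the candidate with the smallest validation error, dropping
zero-weight predictors. `fit_elastic_net_grid()` extends the penalty to
$c\,[\alpha\lVert\omega\rVert_1 + \tfrac{1-\alpha}{2}\lVert\omega\rVert_2^2]$
over 50 magnitudes for each mixing proportion
$\alpha \in \{0.01, 0.05, 0.1, 0.5, 1\}$ — 250 candidates. Validation-error
ties prefer fewer nonzero predictors, then the stronger penalty: parsimony
is the tie-break everywhere.

The inner solver is glmnet's coordinate descent (convergence threshold
$10^{-16}$, which on these problem sizes is essentially free and keeps
solutions within $10^{-6}$ of the subgradient optimality conditions; the
test suite checks this against an independently coded KKT oracle).
Coefficients below $10^{-10}$ in magnitude are clipped to exact zero —
coordinate-descent dust at the all-zero boundary, not active predictors.
`fit_single_best_predictor()` provides the single-predictor baseline: the
candidate with the largest absolute training-segment Pearson correlation
with the target (ties to the lowest id), OLS-refit. When an OLS system is
underdetermined the minimum-norm (pseudoinverse) solution is returned with
a warning.

## Multiregional prediction gain

The gain of a target ROI is

$$G \;=\; E_{\text{single}} - E_{\text{multi}},$$

the test-segment error of the best single-predictor model minus that of the
multi-predictor model, in percent of activity variance. A region strongly
coupled to one partner gains little from additional predictors; a region
whose activity is uniquely explained only by combining several regions
shows a large gain. Significance uses a *paired* t-test over the
per-timepoint squared errors of the two models: both error series share
timepoints, so pairing is the appropriate layout even though the source
method statement names only a t-test between the square errors.

Weight-permutation null models (`null_model_errors()`) assess whether a
model's accuracy depends on its specific weight-to-predictor assignment:
weights are shuffled across the model's own predictors (500 draws by
default) and the test error recorded. The p-value uses the add-one
estimator $(1 + \#\{E_{\text{perm}} \le E_{\text{obs}}\})/(n+1)$, bounded
away from zero at finite $n$. Note the construction is deliberately
degenerate for models whose weights are all equal (every reordering is the
identity in effect, $p = 1$); informative nulls require heterogeneous
weights, which real fitted models have.

## Group-level analysis

Per-model weights are normalized to percent of the total absolute weight
onto the target, making them comparable within and across subjects. For
one target ROI across subjects, `identify_key_predictors()` tests each
candidate predictor's normalized weight (zero when absent from a subject's
model, so the test reflects selection frequency as well as magnitude)
against null models. The null here places each subject's weight multiset on
a uniformly random subset of all candidate ROIs rather than shuffling
within the model: shuffling a multiset within the model preserves its mean,
so a predictor whose weight sits at the within-model average could never be
distinguished from its null, and "significantly large weight" would be
undefined for it. Reassignment over the full candidate set gives every
candidate a proper null. The t-test is one-sided (larger than null), and
p-values are Bonferroni-corrected by multiplying by the number of
comparisons and capping at 1, with $\alpha = 0.05$. Each subject's null
draws are seeded from its own weights, so results are invariant to subject
ordering.

Group means and 95% confidence intervals use percentile bootstrap with 500
resamples. Integration networks connect integrator ROIs — bootstrap-mean
gain above 13%, *and* mean multi-model test error below 30%: gain estimates
for regions the models cannot predict are noise, so poorly modeled regions
are never classified — to their key predictors, with edges classified by
Euclidean centroid distance (long if > 50 mm), homotopy (same label,
opposite hemisphere) and hemisphere crossing. Because age and head motion
are confounded in typical cohorts, associations between any per-subject
measure and age are reported as partial correlations controlling for mean
head displacement. Temporal signal-to-noise (tSNR) is the mean absolute
percent signal change divided by the series variance.

## The synthetic generator

No subject data ship with the package, so `make_scenario()` /
`simulate_dataset()` provide a ground-truth test surface emulating the
structural features the pipeline must handle:

* temporally autocorrelated signals — all latent series are AR(1) with
  coefficient 0.5 and unit marginal variance, a reasonable autocorrelation
  for BOLD sampled at TR ≈ 2 s;
* sparse linear dependencies — integrator ROIs are weighted sums of
  `k_predictors = 5` driver ROIs plus AR(1) observation noise;
* redundancy — one strongly coupled pair (homotopic labels, activity
  correlation 0.85, matching reported homotopic coupling of ~0.8–0.85);
* a low-tSNR ROI at three times the driver amplitude.

True weight magnitudes are spread linearly over $[0.6, 1.4] \times$
`true_weight` (default mean magnitude 0.2) with alternating signs.
Heterogeneous magnitudes are essential, not cosmetic: with all-equal
weights, permuting weights within a model is a no-op, so weight-permutation
nulls would equal the observed model and the key-predictor analysis would
have no signal to detect — a degenerate situation real fitted weights never
present. Unless overridden, observation noise is calibrated so the true
model leaves about 20% residual variance, the error level of a well-modeled
cortical region. Defaults are 32 ROIs and 660 timepoints: the full series
length of a ~20-minute scan, at an ROI count that keeps a full per-subject
run (every ROI, every method) in the tens of seconds.

Columns are exactly mean-centered but *not* variance-rescaled: rescaling
column $i$ by $s_i$ would silently transform every true weight to
$\omega s_j / s_i$ and break weight-recovery oracles.

What the generator does **not** emulate: hemodynamic convolution,
physiological noise and scanner artifacts, recurrent (loopy) coupling —
mixing is one-shot from exogenous drivers, which keeps the ground-truth
weights identifiable and matches the instantaneous form of the model — and
spatial correlation between neighboring parcels. Passing the recovery
tests therefore shows the estimator chain is correct and well-calibrated
*under the model class it assumes*; it does not show that real BOLD
dependencies are linear, instantaneous, or exogenous.

## Numerical and design choices

* Floor rule at segment boundaries; 0-based half-open ranges in all
  contracts, 1-based rows via `segment_rows()`.
* Strict inequality in the suffix-minimum rule; all ties (elimination,
  best single predictor, validation error) break toward lower ROI id /
  fewer predictors / stronger penalty.
* Population (divide-by-$n$) variance in the error and tSNR definitions.
* Percent-signal-change conversion refuses zero-mean columns instead of
  rescaling silently — a zero-mean column almost always means the data were
  already converted.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; run manifests record all seeds.

The test suite exercises the study-scale conditions at sizes chosen to keep
a full run in well under a minute: recovery and gain-separation properties
use 20 simulation seeds at 32 ROIs × 660 timepoints, and the group-recovery
property uses 10 replicates of 20 simulated subjects. These sizes are the
package's own trade-off between statistical resolution and test-suite
turnaround.

## Limitations

Weights are associational: a key predictor is a region whose activity
carries unique linear information about the target, not necessarily a
direct anatomical connection. The fixed three-segment split follows the
source design rather than cross-validation, so selection is subject to the
idiosyncrasies of one validation segment; the suffix-minimum rule exists
precisely to damp that noise. Gain comparisons are only meaningful among
well-modeled regions, which is why the group pipeline gates integrator
status on model error.
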