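---
title: "Methods: genotype-by-environment yield prediction with convolutional ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-by-environment yield prediction with convolutional ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Multi-environment soybean trials observe yields of many genotypes across
(location, year) environments with daily growing-season weather (April 1 to
October 31, 214 days, seven variables: ADNI, AP, ARH, MDNI, MaxSur, MinSur,
AvgSur). Genotype-by-environment (G-by-E) interaction means a genotype's
ranking depends on the environment, so breeders need models that predict the
yield of *any* genotype under *given* weather — including genotype-location
combinations never trialled together. `gemyield` implements such a workflow:
two neural regressors over weather + categorical inputs, a convex ensemble of
the two, permutation-based attribution, and per-environment top-k genotype
selection; plus a synthetic trial generator so the entire chain is testable
without any external download.

## Preprocessing

* **4-day aggregation.** Each 214-day series becomes 53 period means: periods
  1–52 average consecutive 4-day windows; period 53 averages the remaining 6
  days (209–214). 214 = 52 × 4 + 6, so the final period absorbs the two
  leftover days — the convention keeps all days contributing while matching
  the 214:53 reduction; the alternative (a 2-day tail) would leave the last
  period's mean noisier.
* **z-score normalisation.** Each aggregated weather (and soil) column is
  standardised as `(w - mean) / sd`. The statistics are fitted on the
  *training rows only* by default (`norm_scope = "train"`), preventing
  information from validation/test rows leaking into the scaling;
  `norm_scope = "all"` reproduces a global fit. The sd uses the population
  (divisor-n) convention; at trial-network sample sizes the difference from
  divisor-(n−1) is immaterial, but fixing one convention keeps tests exact.
  Zero-variance columns are flagged and map to 0 rather than NaN.
* **One-hot encoding.** Year, location and genotype are one-hot encoded
  against a registry built from the training split; categories unseen at
  prediction time encode as all-zero blocks. At the cardinalities of the
  motivating dataset (13 years, 159 locations, 5,838 genotypes) the design is
  6,010 one-hot + 371 weather = 6,381 columns, plus 66 when state-level soil
  is merged. Maturity group is parsed and carried but never featurised: the
  groups are region-specific, so they are confounded with location and would
  not transfer across environments.
* **Split by genotype-location combination.** Unique genotype-location
  combinations are shuffled and partitioned 60/20/20, so validation and test
  contain only combinations the model never saw. Any genotype left without a
  training row is repaired by moving its first occurrence (dataset row order,
  validation searched before test) — as a whole combination — into training.

## The regressors

Both models consume the 7 weather series through seven parallel 1-D
convolution branches (separate weights per variable, valid padding, ReLU) and
the one-hot categorical vector through one dense layer with Leaky ReLU
(negative slope 0.3, a common default; only the *placement* of the leaky
activation is prescribed). The published layer widths are the defaults:

* **CNN**: conv features are flattened and concatenated with the categorical
  stream (dense 2,048), then pass through a 3,200-unit dense ReLU layer to a
  scalar output. Dropout (0.5, 0.7, 0.2) applies to the conv features, the
  categorical dense output, and before the output layer.
* **CNN-LSTM**: the per-branch conv feature maps are stacked along the
  channel axis, keeping the downsampled temporal axis as the sequence, and
  fed to a 128-unit LSTM whose final hidden state replaces the flattened conv
  features; dense widths are 1,596 / 1,280 with dropout (0.5, 0.5, 0.7, 0.2).
* An optional **soil branch** (512 dense units, Leaky ReLU, 0.5 dropout)
  joins the concatenation when a state-level soil table is merged.

The per-branch convolution stack defaults to (8 filters, kernel 9, stride 1)
→ (12, 3, 2) → (16, 3, 2), reducing 53 periods to a 10 × 16 feature map.
These numerals are a declared package default — the source architecture
diagrams do not legibly specify them — and every layer is overridable through
`architecture_spec()`. Likewise it is not stated whether the seven branches
share weights; this implementation keeps them separate, the more expressive
choice.

The layers are implemented in-package (im2col convolution, LSTM with
backpropagation through time, inverted dropout, He initialisation, Adam) on
BLAS matrix operations, and the analytic gradients are verified against
central finite differences in the test suite. Training minimises mean squared
error — implied by the RMSE-centred evaluation and by the squared-error
ensemble objective — with Adam at initial learning rate 0.0004 decayed
continuously by a factor 0.96 every 2,500 steps (`lr(step) = 4e-4 ·
0.96^(step/2500)`; a staircase variant would agree at every multiple of
2,500), batch size 48. The published protocol trains for 100,000 iterations;
the package default is 2,000 — the desk-scale point where the synthetic
benchmarks below are already well fit — and the iteration count is a plain
config field for full-scale runs. The output bias is initialised at the
training-mean yield so early iterations model deviations rather than the
~50 bu/ac offset. Training aborts with a diagnostic if the loss becomes
non-finite. With a fixed seed, batching, dropout and initialisation are fully
reproducible on one device.

## The ensemble (GEM)

Base-model predictions on the *validation* split are combined by the
Generalized Ensemble Method: minimise `(1/n) Σ_i (y_i − Σ_j w_j ŷ_ij)²`
subject to `w_j ≥ 0`, `Σ w_j = 1`. The problem is a convex QP over the
simplex; the solver enumerates supports and solves each equality-constrained
KKT system exactly, so the returned weights are globally optimal to machine
precision (the mean form of the objective has the same minimiser as the sum
form). Vertices are feasible, so the fitted ensemble can never be worse than
its best base model on the fitting set — asserted on every fit. Ties among
optimal supports break toward the lower model index (supports are scanned
singletons-first, improvement must be strict). A brute-force simplex-grid
search (`gem_grid_oracle`, k ≤ 3) serves as an independent oracle in tests
only.

## Permutation importance by RMSE change

Baseline RMSE `r0` is computed on the evaluation rows (the test split, by
convention), then each feature group — year / location / genotype one-hot
blocks, the 7 weather variables (53 columns each), optionally soil, or
single 4-day periods of one variable — is jointly row-permuted and the RMSE
recomputed; the importance of the group is the mean RMSE increase. Joint
(coherent) permutation of a group's columns preserves one-hot validity and
within-group covariance, which independent per-column shuffles would destroy.
Changes are averaged over `repetitions` permutations (default 10; a single
permutation is available with `repetitions = 1`) because single-shot
importances are noticeably seed-sensitive at desk-scale test-set sizes. Each
group draws its permutations from a seed derived from the master seed and the
group name, making results independent of group evaluation order.

## Genotype selection

For each distinct (location, year) environment — records sharing both share
one weather block, which is verified — the selector predicts yields for the
full genotype registry (all genotypes, not just those historically planted at
that location; `pool = "planted"` restricts), ranks them, and retains the
top k (default 10), breaking prediction ties by genotype identifier. The
report compares the mean predicted yield of the selected genotypes against
the mean observed yield of the genotypes actually planted, per environment or
aggregated per state-year (the reporting convention of the motivating study
is ambiguous between the two, so both are provided). Gaps are signed: a
negative gap — the planted set already outperforming the selection — is
reported, not clipped.

## The synthetic generator

`simulate_dataset()` draws trials from the structure the method assumes:

```
yield = base + g(genotype) + l(location) + t(year) + gl(genotype, location)
        + Σ_w β_w · z_w(environment) + ε
```

with independent Gaussian effects, `z_w` the across-environment z-score of
the mean of one weather variable over a short window of 4-day periods, and
`ε ~ N(0, σ_resid)`. Weather is a per-variable seasonal sinusoid peaking
mid-season with variable-specific means and amplitudes (e.g. MDNI ~700 W m⁻²
mid-season, AP ~0.1 in/day), an environment-level shift and daily noise;
records in one environment share one block. Window effects are defined on
the *4-day-aggregated standardised* scale precisely so that
importance-recovery tests align with what the preprocessing feeds the models.
Environments are kept with probability `availability_fraction`, emulating
unbalanced trial networks where some locations are observed in only a year
or two. Genotype coverage is enforced constructively at generation time
(every genotype dealt into at least one environment before remaining slots
are sampled), which keeps split-repair testing meaningful; the feasibility
requirement is `n_genotypes ≤ n_environments × genotypes_per_env`.

Defaults: base yield 50.66 bu/ac with effect sds (genotype 5, location 8,
year 3, interaction 2, residual 7) — totalling a marginal yield sd of about
13–14 bu/ac, in line with the ~16 bu/ac spread of large public soybean trial
datasets, with location the dominant component as the importance analyses of
such data find — and two response windows, MDNI at periods 24–26 and AP at
18–20, the early-reproductive-stage windows where soybean yield is most
sensitive to solar radiation and precipitation. Simulated yields are not
truncated at zero by default (`truncate_at_zero` flips this): the Gaussian
model rarely crosses zero at these settings and truncation would bias the
stored effect decomposition.

What the generator does **not** emulate: spatial weather correlation between
nearby locations, year-to-year weather persistence, maturity-group-dependent
phenology, non-Gaussian yield tails, and heteroscedastic residuals. Passing
recovery tests therefore demonstrate that the pipeline's machinery is
correct and that the models can learn the assumed structure — not that the
architecture choices are optimal for real trial data.

## Numerical choices and degenerate inputs

* Zero-variance feature columns standardise to 0 (flagged, never NaN).
* `pearson_r` raises an error on constant input rather than returning 0; a
  silent zero would corrupt report tables.
* GEM weights are clipped at 0 and renormalised only within the solver's
  feasibility tolerance (1e-8 relative); the simplex constraint holds to
  1e-9.
* Ties in top-k selection break by genotype identifier; ties among optimal
  ensemble supports break toward the lower model index.
* A single-environment dataset has zero across-environment weather variance;
  window covariates are then defined as 0 and flagged via the stored window
  sd.
* Splitting errors if a genotype occurs nowhere; building a model errors,
  naming the layer, if a conv kernel exceeds its input length.

## Desk-scale problem sizes

The test suite and the acceptance script exercise the full chain on
generated trials of roughly 2,800–3,000 records (25 locations × 6 years at
60% availability, so about 90 environments; 100 genotypes, 33 per
environment — many environments relative to the location/year dummy count,
so the models must consult weather rather than interpolate environment
means), training reduced
architectures (64-unit dense layers, 32-unit LSTM, lowered dropout — heavy
regularisation is counterproductive at these widths) for 1,200–1,500
iterations. At these sizes the trained ensemble reaches a test RMSE within a
small factor of the simulated residual sd, recovers genotype rankings at
Spearman > 0.9, and localises the planted MDNI response window; the split,
ensemble, metric and selection components are checked exactly at their
contracts. Published-scale settings (full widths, 100,000 iterations, ~93k
records) are configuration choices, not code paths, and are not exercised by
the tests.

A caveat on *period-level* attribution: the convolution stack's receptive
field spans roughly 15 periods per output position, and the LSTM weights
late timesteps more heavily than early ones (its final hidden state is the
regression input), so single-period RMSE changes are smeared over
neighbouring periods and, for the CNN-LSTM, biased toward the late season.
On synthetic runs the CNN's per-period profile covers the planted window
while the CNN-LSTM's can peak spuriously late; the location of the single
largest per-period change is therefore noisier than the window-aggregate
change, and both are reported. Variable-level importance is unaffected
(permuting all 53 periods of a variable removes its whole signal).

## Known limitations

* The in-package neural layers are single-threaded beyond BLAS and have no
  GPU path; full-scale replication of the published training protocol is out
  of desk scope.
* The genotype block is purely categorical (one-hot); no marker or pedigree
  information enters the model, so predictions for genotypes absent from
  training reduce to the environment + average-genotype signal.
* State-level soil merging gives every location in a state identical soil
  covariates; with location unavailable as coordinates, soil adds little
  independent signal (consistent with the motivating study's findings).
* The selection report treats predicted elite yield against observed planted
  yield; it does not model seed availability, agronomic constraints or
  maturity-group feasibility.
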