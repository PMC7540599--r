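---
title: "Conditional safety margins for peak local SAR: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional safety margins for peak local SAR: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarmargin)
```

## The problem

In ultrahigh-field MRI with parallel-transmit arrays, the regulated safety
quantity is the peak local specific absorption rate averaged over 10 g of
tissue (pSAR10g, W/kg). It cannot be measured in the patient; it is
*estimated* — from a generic body model, a model library, a most-similar
model, or a learned predictor — and the estimate deviates from the truth
because the patient is not the model. Underestimation is the safety risk;
overestimation wastes scan efficiency.

The conventional remedy is a **linear safety factor (LSF)**: multiply every
estimate by a constant large enough that no validation case is
underestimated. This over-corrects badly at high estimates, where a large
true-over-estimated ratio is no longer plausible. This package implements
a probabilistic alternative, the **conditional safety margin (CSM)**,
along with the conventional corrections it is compared against and the
simulation machinery needed to exercise all of them without
electromagnetic field data.

## The model

Write $E$ for the estimated and $T$ for the true pSAR10g. Validation pairs
$(E, T)$ are draws from a joint density $f_{E,T}$. The conditional density
of the truth given the estimate is

$$f_{T|E}(t \mid e) = \frac{f_{E,T}(e, t)}{f_E(e)},$$

and the corrected value $\mathrm{pSAR}^{E,C}(e)$ is defined by a
prescribed, small underestimation probability $\varepsilon$ (default
0.001):

$$P\!\left(T > \mathrm{pSAR}^{E,C} \mid E = e\right)
  = \int_{\mathrm{pSAR}^{E,C}}^{\infty} f_{T|E}(t \mid e)\, dt
  = \varepsilon .$$

The margin is therefore the $(1-\varepsilon)$ tail quantile of the
conditional distribution — a *curve* in $e$, not a constant factor. Its
two limits are instructive: for a perfect estimator the curve hugs the
identity, and for an uninformative estimator ($E \perp T$) it flattens at
the marginal $(1-\varepsilon)$-quantile of $T$, the "99.9% certain upper
bound".

### Fitting procedure (`csm()`)

1. **Joint density.** The pairs are fitted with a full-covariance
   bivariate Gaussian mixture; the number of components $K$ is selected by
   BIC over candidates `k = 1:6`. Fitting is delegated to
   `mclust::Mclust` (model `"VVV"`). mclust's model-based agglomerative
   initialisation is deterministic, which makes random EM restarts
   redundant; for more than 5000 pairs the initialisation runs on a
   seeded 2000-point subsample (the EM itself always uses all pairs), so
   the fit is reproducible given `seed`.
2. **Marginal.** $f_E$ is fitted with a gamma distribution by maximum
   likelihood (`MASS::fitdistr`, moment-based starting values). Because
   each conditional column is renormalised (step 4), the gamma fit does
   not shift the curve; it defines the curve's *domain* (step 5).
3. **Discretisation.** Both axes are discretised with spacing
   $\Delta = 0.01$ W/kg from $\Delta$ up to 1.25 times the largest
   observed value. 0.01 W/kg is far below any practically relevant SAR
   difference; the 1.25 headroom keeps the integration lattice clear of
   the largest observations.
4. **Tail integration.** Each column of the lattice (fixed $e$) is
   renormalised to unit mass and cell masses (density $\times \Delta$)
   are accumulated from the top of the $T$ axis downward; the corrected
   value is the node at which the accumulated mass first reaches
   $\varepsilon$. Renormalisation is a deliberate choice: dividing the
   mixture joint by an independently fitted gamma marginal does not
   integrate to exactly 1, and renormalising makes the defining equation
   well-posed per column.
5. **Domain restriction.** Nodes where the fitted gamma density falls
   below $10^{-6}$ of its peak are dropped. Where estimates essentially
   never occur, the conditional is a ratio of two vanishing quantities
   and becomes erratic; restricting the domain removes those anomalies.

`predict()` interpolates the curve linearly. Below the domain, the
leftmost node's ratio corrected/estimate is applied; above it, the
rightmost node's ratio — both conservative linear continuations, since
density estimates outside the feasible estimate range are unreliable.

### Comparator corrections

* `lsf(samples, "worst_case")` — the maximum ratio $T/E$ in validation:
  zero underestimation on the fit set, by construction.
* `lsf(samples, "outer_fence")` — the maximum ratio after removing
  outliers above the Tukey upper outer fence $Q_3 + 3\,\mathrm{IQR}$ of
  the ratio distribution (quartiles by linear interpolation of order
  statistics, `stats::quantile` type 7). The fence constant 3 is the
  conventional "outer" fence.
* `upper_bound(values, level)` — the empirical `level`-quantile of the
  true values (type-7 interpolation); the constant bound.
* `capped_lsf(lsf, ub)` — pointwise $\min(\mathrm{LSF}\cdot e,\ UB)$:
  the linear correction where it is moderate, the bound where the linear
  correction becomes unrealistic.

## SAR computations and estimators

A surrogate body model is a set of 8×8 complex Hermitian PSD Q-matrices,
one per voxel, scaled so $s^{H} Q s$ is local SAR (W/kg) for a drive
vector $s$ in $\sqrt{W}$. True peak SAR is
$\max_r s^H Q_{10g}(r)\, s$ (`psar_true()`).

Model-similarity ranking uses per-voxel **worst-case SAR maps**: the
maximum of $s^H Q s$ over unit-modulus phase vectors. The exact maximum
is NP-hard in general, so two labelled approximations are provided: the
certified bound $\sum_{ij} |Q_{ij}|$, and coordinate-ascent phase
optimisation from 32 random starts (default). The multistart value is a
lower bound on the true worst case, sandwiched between any concrete
drive's SAR and the closed-form bound — the tests verify this bracket on
random fixtures. Since the maps are only consumed through *between-model
RMS differences and rankings* (`build_selection_table()`), the ranking,
not the absolute level, is what matters, and the multistart surrogate is
the default.

Estimators (`cohort_pairs()`): the generic-model estimate evaluates the
drive on one designated model; the model-library estimate takes the
maximum true peak SAR over all *other* models (leave-one-out); model
selection uses the single most map-similar model; multiple-model
selection the maximum over the five most similar (size configurable).
RMSE ties are broken lexicographically by model id so tables are
deterministic.

## Synthetic data: what it emulates and what it does not

No electromagnetic simulation data ship with the package; two generators
stand in for them.

**Q-matrix cohorts** (`generate_cohort()`): every voxel's matrix is built
as $A^H A$, with $A$ a shared per-voxel base plus a model-level
perturbation (scaled by `intersubject_sd`) plus per-voxel jitter
(`intrasubject_jitter`) — PSD by construction, with the entry scale set
so a unit-amplitude drive deposits on the order of 1 W/kg. The default
cohort has 23 models, mirroring a realistic model-library size, and 40
voxels — enough for maxima over space to behave like maxima while keeping
simulation at desk scale. `intersubject_sd` is the single knob that moves
the cohort-based estimators from nearly perfect (small) to poorly
correlated (large). What this does *not* emulate: anatomy, coil physics,
spatially structured correlation between neighbouring voxels, or
registration error between subjects (all models share one grid).

**Parametric pairs** (`generate_joint_pairs()`): bivariate lognormal,
independent-lognormal, and positive-truncated Gaussian-mixture families
for $(E, T)$ directly. Defaults (log-scale mean 0.3, sd 0.35, $\rho$ =
0.9) give a gamma-like marginal with mode near 1–2 W/kg and a 99.9%
quantile near 4 W/kg — a realistic local-SAR scale for a body array at
7 T; these are fixture choices, not measured values. The lognormal family
has closed-form conditional quantiles
(`closed_form_conditional_quantile()`), giving an analytic oracle the
fitted CSM can be compared against.

## Evaluation protocol

`make_splits()` draws, per model, disjoint validation (default 250
drives) and test (default 1000) subsets — 5750 and 23 000 rows for a
23-model cohort. Margins are fitted on validation and scored on test
(`evaluate_corrections()`), reporting the **mean overestimation**
$\overline{(C - T)/T} \times 100\%$ and the empirical underestimation
rate. Mean overestimation here is the *signed* mean over all test rows —
the simplest reading, and the one under which method orderings are stable
in simulation; an over-only mean is available with `over_only = TRUE`.
Plots (scatter with margin overlays, grouped bars) are advisory; the
numeric report is the contract.

## Numerical choices and degenerate inputs

* Quadratic forms clip floating-point negatives above $-10^{-12}$ W/kg
  to zero; anything more negative raises an error (a non-PSD matrix
  signals a broken fixture, not noise).
* Coordinate ascent on phases updates channel $i$ to
  $s_i = b_i/|b_i|$ with $b_i = \sum_{j \ne i} Q_{ij} s_j$, which is
  monotone in the objective; iteration stops at relative improvement
  below $10^{-10}$ or 200 sweeps.
* An exactly degenerate pair set ($E = T$) makes the mixture covariance
  singular; the near-perfect-estimator regime is exercised with a small
  multiplicative jitter instead (`surrogate_estimator(log_sd = 0.02)`).
* All samplers and fits restore the caller's RNG state; a fit or draw is
  a pure function of its arguments including `seed`.
* Serialised margins round-trip bit-exactly (17 significant digits).

## Known limitations

* **Mixture tails.** A maximum-likelihood Gaussian mixture matches the
  bulk of the pair distribution, but its Gaussian tails decay faster
  than lognormal-like SAR data. In simulations against the analytic
  lognormal oracle the fitted curve overshoots the conditional
  99.9%-quantile near the low-estimate edge of the support (conservative,
  up to tens of percent at low correlation) and undershoots a little at
  the extreme high end; with K capped at 6 this residual mismatch is
  structural — more components shrink but do not eliminate it. The
  *coverage* property — the achieved underestimation probability — is far
  more robust, because it averages the fit over the estimate
  distribution: held-out underestimation rates recover $\varepsilon$
  within binomial-plus-fit tolerance in the test suite. Users who need
  tail-accurate curves at weak correlation should treat the low-estimate
  end of the curve as conservative.
* The worst-case map optimiser is a local method; its values are lower
  bounds, certified only by the $\sum |Q_{ij}|$ upper bound.
* Drive ensembles assume every drive equally likely; a pulse-design
  workflow with structured drive statistics should supply its own
  ensemble.
* Problem sizes in the test suite (cohorts of 20–40 voxels, pair sets of
  $10^4$–$10^6$) are chosen so the full suite runs on a laptop; they are
  stated in the tests themselves.

## A worked run

```{r example, fig.width = 6, fig.height = 5}
set.seed(7)
truth <- rlnorm(2e4, 0.3, 0.35)
bad   <- runif(2e4) < 0.01                     # rare severe underestimates
eta   <- ifelse(bad, rnorm(2e4, -0.8, 0.2), rnorm(2e4, 0, 0.1))
pairs <- paired_samples(psar_e = truth * exp(eta), psar_t = truth,
                        model_id = "surrogate", drive_id = seq_len(2e4))
report <- evaluate_corrections(
  pairs, corrections = c("lsf_worst_case", "lsf_outer_fence",
                         "capped_lsf", "csm"),
  n_validation_per_model = 5000, n_test_per_model = 10000, seed = 2)
report
plot(report)
```

The contrast is sharpest exactly where the constant-factor approach
struggles: rare severe underestimates drag the worst-case factor (and its
average cost) up by a multiple, while robustifying it with the outer
fence sacrifices the protection target. The conditional margin holds the
prescribed underestimation probability at a fraction of the worst-case
cost. When the estimator's error distribution is benign and light-tailed,
all corrections land at comparable average overestimation and the CSM's
advantage is mainly the *uniformity* of its protection across the
estimate range.
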