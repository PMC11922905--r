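---
title: "Modelling the light response of PSII photochemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the light response of PSII photochemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(psiilight)
library(dplyr)
```

## Scope and assumptions

`psiilight` models chlorophyll-fluorescence light-response curves of
photosystem II (PSII): how the effective quantum yield of PSII
photochemistry, $\Phi_{PSII}$, and the linear electron transport rate,
ETR, change with incident photosynthetically active irradiance $I$
(µmol photons m⁻² s⁻¹). The package assumes:

* steady-state measurements at each light step (the usual rapid or
  steady light-curve protocol on a pulse-amplitude-modulated
  fluorometer);
* a fixed leaf absorptance $\alpha$ (default 0.5) and PSII partitioning
  fraction $\beta$ (default 0.84), combined in
  $\mathrm{ETR} = \alpha \beta \, \Phi_{PSII} \, I$;
* replicate curves are independent leaves/plants measured on a common
  irradiance grid.

Both response kinds share one parameterisation per model, so a model
fitted to $\Phi_{PSII}$ data and to ETR data can be compared directly.

## The four models

**Mechanistic model** (`ye_params()`). Derived from light absorption by
pigment molecules whose effective absorption cross-section declines as
irradiance rises:

$$\mathrm{ETR}(I) = \alpha_e I \, \frac{1 - \beta_e I}{1 + \gamma_e I},
\qquad
\Phi_{PSII}(I) = \Phi_{PSII\max} \frac{1 - \beta_e I}{1 + \gamma_e I}.$$

$\alpha_e$ is the initial slope, $\beta_e$ (m² s µmol⁻¹) expresses
dynamic down-regulation, $\gamma_e$ saturation. The curve peaks at
$I_{sat} = (\sqrt{(\beta_e + \gamma_e)/\beta_e} - 1)/\gamma_e$ with
$\mathrm{ETR}_{\max} = \alpha_e \left[ (\sqrt{\beta_e + \gamma_e} -
\sqrt{\beta_e})/\gamma_e \right]^2$; with $\beta_e = 0$ the curve is
monotone, $I_{sat}$ is not finite and only the supremum
$\alpha_e/\gamma_e$ exists — `derive_params()` flags both cases rather
than failing.

**Negative exponential** (`negexp_params()`):
$\Phi_{PSII}(I) = \Phi_{PSII\max} e^{-k_w I}$; the ETR curve then peaks
at $I_{sat} = 1/k_w$ with
$\mathrm{ETR}_{\max} = \alpha\beta \, \Phi_{PSII\max} e^{-1} / k_w$.

**Exponential / saturating** (`exp_params()`):
$\Phi_{PSII}(I) = F_v/F_m \,(I_{sat}/I)(1 - e^{-I/I_{sat}})$, whose ETR
form is the familiar saturating exponential. ETR is monotone
increasing, so the reported $\mathrm{ETR}_{\max}$ is, by convention, the
value at $I = I_{sat}$ (a fitted parameter here), i.e.
$\alpha\beta\,F_v/F_m\,I_{sat}(1 - e^{-1})$; the flags
`"fitted-parameter"` and `"value-at-I-sat"` record this.

**Non-rectangular hyperbola** (`nrh_params()`): the smaller root of
$\theta \mathrm{ETR}^2 - (\alpha' I + \mathrm{ETR}_{\max})\mathrm{ETR} +
\alpha' I\, \mathrm{ETR}_{\max} = 0$. ETR approaches its asymptote
$\mathrm{ETR}_{\max}$ from below and never turns over, so $I_{sat}$ is
not defined (flag `"not-defined"`). $\theta = 0$ reduces analytically
to the rectangular hyperbola.

Only some quantities are estimable by each model/kind combination
(e.g. the hyperbola cannot report a saturation irradiance; a
$\Phi_{PSII}$ fit of the negative exponential yields
$\Phi_{PSII\max}$ but its $I_{sat}$ refers to the implied ETR curve).
`build_comparison_table()` encodes this map and emits explicit
`not-estimable` flags instead of numbers that would be artefacts.

## Pigment-level biophysics

The mechanistic coefficients are aggregates of microscopic quantities
(`microscopic_params()`, `aggregate_from_microscopic()`): the
ground-state absorption cross-section $\sigma_{ik}$ (m²), exciton
lifetime $\tau$ (s), de-excitation pathway fractions $\xi_1, \xi_2,
\xi_3$, rate constants $k_P, k_D$ (s⁻¹), and the asymmetry ratio $g$.
From a fitted $\alpha_e$ the package recovers the light-dependent
effective cross-section $\sigma'_{ik}(I)$ (`sigma_eff()`), the
excited-state fraction $N_k/N_0$ (`nk_fraction()`), and $\sigma_{ik}$
itself (`sigma_ik_from_alpha_e()`, which requires the pigment density
$N_0$). The identity
$\Phi_{PSII}(I) = \Phi_{PSII\max}\, \sigma'_{ik}(I) / \sigma_{ik}$
links the two levels and is enforced to $10^{-12}$ relative in the test
suite. Non-photochemical quenching follows the same saturating shape:
$\mathrm{NPQ}(I) = A I/(1 + bI) + \mathrm{NPQ}_0$ (`npq_curve()`).

## Synthetic data generator

`synthetic_truth()` + `generate_synthetic()` emulate the measurement
protocol. Defaults are the study conditions:

* 16-step irradiance grid `protocol_grid()`: 0, 25, 50, 100, 200, 300,
  400, 600, 800, 1000, 1200, 1400, 1600, 1800, 1900, 2000;
* 5 replicates;
* independent Gaussian noise with standard deviation 2% of the
  noiseless curve maximum (`noise_type = "relative"`; an absolute mode
  is available).

Replicates draw their noise from seeds derived deterministically from
the top-level seed (`seed` is required — there is no silent default),
so a stored truth object regenerates its data bit-for-bit. The
generator does *not* emulate instrument drift, light-step carry-over,
or non-Gaussian heteroscedastic error; treat recovery statistics as a
best case.

## Fitting algorithm

`fit_light_curve()` minimises the sum of squared residuals with a
three-stage global strategy designed for these mildly multimodal,
strongly correlated surfaces:

1. **Latin-hypercube starts** (default 20) over box bounds
   (`default_bounds()`); dimensions whose bounds span more than three
   decades are sampled log-uniformly.
2. **Simulated annealing** from the three best starts: Metropolis
   acceptance with geometric cooling (ratio 0.92, 60 proposals per
   temperature, initial temperature set from the spread of start SSRs,
   stop at $10^{-4}$ of the initial temperature).
3. **Bounded Levenberg–Marquardt refinement** (`minpack.lm::nls.lm`,
   `ftol = 1e-10`) from every annealing endpoint and from *every* raw
   start — the local runs are cheap next to annealing, and basins missed
   by the top-ranked starts (e.g. the monotone $\beta_e = 0$ basin of
   peaked data) are still reached from lower-ranked ones.
   Ties within $10^{-12}$ relative SSR break toward the
   smallest $\beta_e$, then $\gamma_e$, so equivalent optima resolve
   deterministically.

Estimates within $10^{-6}$ of a bound (relative to its range) are
flagged `boundary` in the diagnostics. All randomness is scoped with
`withr::local_seed`, so a fixed `fit_config(seed = )` gives
bit-identical results. Curves with fewer distinct irradiances than
parameters + 1 raise `lrc_error_underdetermined`; zero-variance
responses raise `lrc_error_degenerate`.

`fit_replicates()` fits each replicate independently and summarises
terms as mean ± standard error of the per-replicate estimates
(`se = NA` for a single replicate).

## Evaluation conventions

`gof()` reports SSR, MAE, $R^2 = 1 - \mathrm{SSR}/\mathrm{SS}_{tot}$,
and $\mathrm{AIC} = 2k + n \ln(\mathrm{SSR}/n)$. A perfect fit gives
$-\infty$ AIC with a `degenerate-zero-SSR` flag. Two parameter-count
conventions are offered: `"free"` counts only parameters actually
optimised (3/2/2/3 across the four models), while `"paper"` counts the
parameters conventionally reported for each model/kind (e.g. 4 for the
exponential ETR form, which carries $\alpha\beta$ and $F_v/F_m$
separately). SSR never changes between conventions — only AIC shifts
by $2\Delta k$.

Recovery quality is quantified as the **median signed relative bias**:
the median over Monte Carlo repeats of
$(\hat\theta - \theta)/\theta$ per parameter. The median of *signed*
errors isolates systematic bias — symmetric scatter cancels — which is
the quantity the acceptance suite bounds at 5% under the default noise
level (and at $10^{-4}$ noiselessly).

## Problem sizes and budgets

The acceptance tests use 1000 random parameter draws per model for the
closed-form-versus-oracle checks, 200 draws for the algebraic
identities, and 50 Monte Carlo repeats (5 replicates each) for
recovery and model-ranking checks. `scripts/acceptance.R` reproduces
the same quantities with 200 draws and 20 repeats so a full run stays
well inside a few minutes on one CPU; the repeat count trades Monte
Carlo error in the reported medians against runtime and is recorded in
the output (`"n"` per quantity).

## Worked example

```{r example}
truth <- default_truth_params("ye")
syn <- generate_synthetic(
  synthetic_truth(truth, kind = "ETR", seed = 42))

fits <- fit_replicates(syn, fit_config("ye", "ETR", seed = 43))
tidy(fits)

cmp <- compare_models(syn, kind = "ETR", seed = 44)
cmp
```

## Limitations

* The mechanistic model's $\beta_e$ and $\gamma_e$ are strongly
  correlated on 16-point grids; single-replicate interval estimates
  are optimistic. Use replicate spread (`fit_replicates()`), not the
  local curvature, for uncertainty.
* $\mathrm{ETR}_{\max}$ of the exponential model is a convention
  (value at $I_{sat}$), not an observable plateau; comparisons across
  models should use the flags carried through the tables.
* The NPQ model here is the saturating empirical form; it is not fitted
  by `compare_models()`, which targets the four $\Phi/\mathrm{ETR}$
  models.
* Optical constants $\alpha$ and $\beta$ are treated as known. If they
  are mis-specified, $\alpha_e$-derived cross-sections scale
  accordingly.
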