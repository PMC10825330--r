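---
title: "Modeling ultrasound-assisted extraction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ultrasound-assisted extraction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uaextract)
```

## Scope

`uaextract` implements the modeling chain used to characterize
ultrasound-assisted solid-liquid extraction of fruit-peel phytochemicals.
Four process factors — ultrasonic power $X_P$ (150–350 W), temperature
$X_T$ (30–70 °C), solvent-to-solid ratio $X_S$ (15–35 ml/g) and ethanol
concentration $X_C$ (40–80 %) — drive four responses: total phenolic
content $Y_P$ (mg GAE/g), DPPH antioxidant activity $Y_A$ (%), total
beta-carotenoid content $Y_B$ (µg/g) and total flavonoid content $Y_F$
(mg QE/g). The chain is: designed experiment → neural-network surrogate →
input-influence analysis → genetic-algorithm optimization →
pseudo-second-order kinetics → Arrhenius / Van't Hoff / Gibbs
thermodynamics → transport numbers. A synthetic-study generator emulates
the whole experimental structure so every stage can be validated without
laboratory data.

## Experimental design

`generate_ccd()` builds a central composite circumscribed design:
$2^k$ factorial points at coded $\pm 1$, $2k$ axial points at $\pm\alpha$
(rotatable default $\alpha = 2^{k/4}$, $= 2$ for $k = 4$) and $n_c$ center
replicates. With four factors and six center points this is the 30-run
layout of the study. Run order is deterministic (factorial block in binary
counting order, axial by factor, then centers); randomized run order is
out of scope.

The source tables state only the factor minima/centers/maxima, not whether
those extremes sit at the factorial ($\pm 1$) or axial ($\pm\alpha$)
distance. The package defaults to *table-levels-are-axial* — tabulated
extremes at $\pm\alpha$, factorial levels inside — because the reported
responses never exceed the tabulated factor ranges, which is what one
observes when the design's outermost points coincide with the tabulated
extremes. The alternative convention is available via the `convention`
argument of `generate_ccd()` / `code_value()`.

## The network surrogate

The surrogate is a single-hidden-layer feed-forward network,
$4\text{–}H\text{–}4$ with log-sigmoid activation on both the hidden and
output layers:
$$h = \sigma(u\,x + \theta_h), \qquad
  \hat y = \sigma(w\,h + \theta_o), \qquad
  \sigma(z) = (1 + e^{-z})^{-1}.$$
Inputs and targets are affinely scaled to $[0.05, 0.95]$; the margin keeps
targets away from sigmoid saturation. With $H = 12$ the network has
$12\cdot4 + 12 + 4\cdot12 + 4 = 112$ parameters, exactly the number of
values in the published weight table, which is why the package treats the
network as having four inputs even though the source text elsewhere
mentions three input neurons — an internal inconsistency of the source
that the package documents rather than resolves. The published weight
table's partition order is unstated; `load_published_ann()` applies a
documented default layout and the fixture is used for structural tests
only, never for numeric claims.

Training (`train_lm()`) is a from-scratch Levenberg–Marquardt
implementation: the residual Jacobian is computed analytically per
pattern (verified against central finite differences to $10^{-6}$), and
each cycle solves the damped normal equations
$(J^\top J + \mu I)\,\delta = -J^\top r$, growing $\mu$ tenfold after a
rejected step and shrinking it after an accepted one, so training SSE is
non-increasing over accepted steps. As $\mu \to 0$ the step tends to
Gauss–Newton; as $\mu \to \infty$ to scaled gradient descent. Patterns
are split 70/15/15 into training/validation/test by a seeded shuffle.

Early stopping is **off by default** (`patience = Inf`): with 112
parameters and about 21 training patterns the 4–5-point validation split
is too noisy to steer stopping reliably, and full LM convergence is what
reproduces the exact-interpolation contracts (a single pattern is fitted
to machine precision; a noiseless quadratic surface to $R^2 > 0.99$).
Setting a finite `patience` enables validation-based stopping with
best-validation restore. `select_hidden_neurons()` implements the study's
size-selection rule: train each candidate (3–15) under the same seed and
keep the one with the lowest validation MSE, ties to the smaller network.

Input influence (`relative_influence()`) defaults to the signed
connection-weights (Olden) measure
$RI_{io} = \sum_h u_{hi} w_{oh}$ — signed, because the published influence
table is signed — with Garson's normalized unsigned measure as an
alternative. No attempt is made to reproduce the published influence
*magnitudes*: their normalization is not recoverable from the source, so
only qualitative sign checks are made, and those against the packaged
fixture only.

## Genetic-algorithm optimization

All four responses are maximized jointly. The scalarization is the sum of
min–max-normalized responses,
$FF = \sum_r (y_r - y_r^{\min})/(y_r^{\max} - y_r^{\min}) \in [0, 4]$,
with the normalization ranges defaulting to the observed response ranges
of the training design; this is consistent with the study's reported best
fitness of 3.087 lying in $[0, 4]$. (The printed objective mixes "max"
and "min" across responses, but the accompanying text states all four
were maximized; the text wins, and per-response directions are
configurable.)

`ga_optimize()` is a real-coded GA: tournament selection (size 3),
BLX-$\alpha$ blend crossover ($p = 0.8$), Gaussian mutation
($p = 0.1$, $\sigma = 5\%$ of each factor range), boundary clipping and
elitism (2), population 50, 200 generations — unstated in the source, so
these are conventional defaults, all configurable. With elitism the
best-fitness trace is non-decreasing, and runs are bit-reproducible under
a fixed seed. "Feeding the network output as the initial population" is
read as seeding the initial population with the training-design points.

In `run_pipeline()` the GA search is additionally confined to the sphere
of coded radius $\alpha$ (a $-\infty$ penalty outside). A circumscribed
design supports predictions only out to that radius; the corners of the
factor box lie at coded radius 4, where an interpolating surrogate is
pure extrapolation and routinely hallucinates optima. The truth surfaces
of the synthetic study are concave, so their optima are interior and the
restriction does not move them.

## Extraction kinetics

Extraction at fixed conditions follows the pseudo-second-order rate law
$$\frac{dC_t}{dt} = k\,(C_s - C_t)^2
  \quad\Longrightarrow\quad
  C_t = \frac{C_s^2 k t}{1 + C_s k t},$$
with rate constant $k$ and saturation concentration $C_s$. `fit_pso()`
estimates both by nonlinear least squares (via `minpack.lm`), initialized
from the linearized form $t/C_t = 1/(kC_s^2) + t/C_s$, whose closed-form
solution is also exposed (`method = "linearized"`) and serves as an
independent oracle: on noiseless model data the two agree to machine
precision, and on noisy data the iterative fit can only lower the SSE.
Least squares is unweighted (the source states no weights). Whether the
original analysis fitted the nonlinear or the linearized form is
unstated; both are provided and compared. Rate constants are stored in
absolute units (e.g. 0.00556) and only formatted as $k \times 10^{-2}$
for display.

## Thermodynamics and transport

`arrhenius_fit()` regresses $\ln k$ on $1/T$: $E_a = -\text{slope}\cdot R$,
$k_0 = e^{\text{intercept}}$, $R = 8.314$ J/(mol K) fixed. The
Celsius-to-kelvin conversion is $T = °C + 273$ exactly — not 273.15 —
because that offset reproduces the published Gibbs-energy table to its
printed three decimals.

The equilibrium constant is $K_e = C_s/(C_{max} - C_s)$, where $C_{max}$
is the concentration after complete extraction. $C_{max}$ is never
printed in the source; it is a required input (the synthetic truth
supplies it; examples default to the maximum observed response).
`vant_hoff_fit()` regresses $\ln K_e$ on $1/T$ to give
$\Delta H^\circ = -\text{slope}\cdot R$ and
$\Delta S^\circ = \text{intercept}\cdot R$, and
$\Delta G^\circ = \Delta H^\circ - T\Delta S^\circ = -RT\ln K_e$ on the
fitted line. Energies are joules per mole internally; kilojoules only at
presentation.

The source reports effective diffusivities $D_e$, mass-transfer
coefficients $K_t$ and Biot numbers without stating how they were
computed. The package therefore implements *declared* estimators:
$D_e$ from the slope of $\ln(1 - C_t/C_s)$ versus time via the first term
of the Fourier series for a slab of half-thickness $L$
($\text{slope} = -\pi^2 D_e / 4L^2$; sphere optional), $K_t$ from the
initial-rate film model $K_t = k\,C_s\,L$, and $Bi = K_t L / D_e$
(definition inferred; the source does not define $Bi$). Neither $L$ nor
the particle geometry is stated anywhere; however, the ratio
$Bi \cdot D_e / K_t$ is constant to 0.06 % across all sixteen published
temperature-response rows, implying a single characteristic length
$L \approx 1.52\times10^{-4}$ m, which the pipeline adopts as its
default. Only that internal consistency is asserted numerically; the
published $D_e$/$K_t$ magnitudes are not an acceptance surface for the
package's own estimators, whose method assumptions differ unknowably
from the original ones.

## Goodness-of-fit statistics

`fit_metrics()` reports $R^2 = 1 - SSE/SST$, $RMSE = \sqrt{SSE/(n-1)}$,
$\chi^2 = \sum (Y_p - Y_e)^2 / Y_e$ and the mean absolute relative
deviation $R_d = (100/n)\sum |Y_e - Y_p|/Y_e$. The source's printed
$R^2$/RMSE formulas omit the squaring and the root — transcription
artifacts; the standard squared forms are implemented. $R_d$ uses $100/n$
by default so that a single-pair deviation reproduces the published
optimum-validation percentages (e.g. 6.960 % for the phenolic response);
the printed $100/(n-1)$ variant is selectable. The assay conversions
(Folin–Ciocalteu phenolics $cV/w$, DPPH inhibition $(1 - A_s/A_c)\cdot
100$, beta-carotene $AD/(A_{1\%}C_{1\%})$ with $A_{1\%} = 2592$ AU,
$C_{1\%} = 10$ mg/ml) are pure unit conversions; the flavonoid assay has
no closed formula beyond the calibration pattern and reuses the
calibration conversion with quercetin units.

## The synthetic study

`study_spec()` fixes the study conditions the generators emulate:

* **Response surfaces.** Full quadratics in the coded factors — a CCD
  identifies quadratics, so the network surrogate must *approximate*
  them, a fair test of the surrogate stage. Linear coefficients carry the
  signed influence pattern of the real study (power positive on every
  response), curvature is negative (interior optimum), and each surface
  was calibrated once so its noiseless values over the 30 runs span
  exactly the published response ranges (phenolics 7.723–24.619 mg GAE/g,
  antioxidant 51.35–85.584 %, carotenoids 24.782–56.558 µg/g, flavonoids
  0.291–1.970 mg QE/g). The coefficients are frozen in
  `default_surface_truth()`.
* **Measurement noise.** Additive homoscedastic Gaussian, sd = 2 % of
  each response range (the source reports triplicate standard deviations
  of roughly this order but no structure); configurable.
* **Kinetics.** $k(T)$ follows the Arrhenius law exactly with $k(303\,K)$
  and $E_a$ matching the published per-response fits; $C_s(T)$ follows a
  Van't-Hoff-consistent law
  $C_s = C_{max} K_e/(1 + K_e)$, $K_e = e^{-\Delta G^\circ/RT}$, with the
  published $\Delta H^\circ$/$\Delta S^\circ$ and $C_{max}$ chosen once
  (24.8, 87.0, 66.8, 2.81 in response units) so that $C_s(T)$ tracks the
  published saturation ranges. Time grid 2.5–25 min (the study's 25-min
  window), temperatures 30/40/50/60 °C, noise sd = 1 % of the local
  $C_s$.
* **Determinism.** All noise derives from the spec seed; identical seeds
  give identical studies.

What passing tests on these data do *not* show: the generator is
homoscedastic-Gaussian and exactly model-consistent, so it cannot reveal
robustness to heteroscedastic error, model misspecification (e.g.
two-site kinetics), or factor-measurement error in real extracts.

## Numerical choices and degenerate inputs

Damping starts at $10^{-3}$ with factor-10 adaptation, capped at
$10^{10}$ (beyond which training aborts with a diagnostic); SSE
convergence at a relative decrease below $10^{-12}$; gradient norm floor
$10^{-10}$. Singular normal equations are retried at higher damping.
Degenerate factor ranges are rejected; a single training pattern widens
its (degenerate) scaling range symmetrically. Kinetic fitting requires at
least three positive observations and strictly increasing times; a fitted
$C_s$ below 80 % of the largest observation triggers a warning rather
than an error. The equilibrium constant is undefined at $C_s \ge
C_{max}$ and errors; in the pipeline, noise-inflated fitted $C_s$ values
are capped just below $C_{max}$. Hidden-size selection breaks exact
validation ties toward the smaller network. GA individuals with
non-finite fitness are demoted to $-\infty$ and counted, never fatal.

## Problem sizes used in the shipped checks

The test-suite and acceptance computations use the study-scale problems
throughout: the 30-run design, 12 hidden units, GA populations of 30–50
over 60–200 generations, a $21^4$ dense grid as the optimization oracle,
20-replicate Monte-Carlo noise studies for kinetic recovery, and
two-temperature-series transport estimation. These are the sizes the
original study implies; nothing is scaled beyond them.

## Known limitations

* With 112 parameters trained on ~21 patterns, the surrogate
  near-interpolates its training data. Its held-out quality on the 4–5
  test-split points is intrinsically high-variance (observed roughly
  0.5–0.95 across seeds): a 30-run design simply does not support a
  stable small-sample $R^2$ estimate for a network of this size. The
  package therefore treats training $R^2$ as the surrogate-quality
  headline and reports the held-out value for transparency.
* For the same reason, optimizing *through* the surrogate lands within a
  few percent — not arbitrarily close — of the true-surface optimum under
  the default noise; the trust-region restriction keeps this gap bounded
  (observed ≲ 10 %). When the optimum of the *true* surface is the
  target (as in the oracle comparisons), running the GA on it directly
  recovers the dense-grid optimum to well under 1 %.
* The published trained-network outputs (the specific optimum
  230.176 W / 50.661 °C / 28.273 ml/g / 62.750 %, its fitness 3.087, and
  the influence-table magnitudes) depend on the original stochastic
  training run and an under-specified weight-table layout; they are
  documented as context, not reproduced numerically.
* Transport estimation rests on declared geometry/film assumptions (see
  above); its absolute magnitudes are therefore method-conditional.
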