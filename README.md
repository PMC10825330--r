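# uaextract

Modeling and optimization of ultrasound-assisted (UAE) solid–liquid
extraction of fruit-peel phytochemicals, for extraction and bioprocess
engineers who need the full modeling chain of a UAE characterization
study as reusable, tested code:

1. **Designed experiment** — a four-factor central composite circumscribed
   design (ultrasonic power 150–350 W, temperature 30–70 °C,
   solvent-to-solid ratio 15–35 ml/g, ethanol 40–80 %), 30 runs;
2. **Surrogate model** — a 4–12–4 log-sigmoid feed-forward network trained
   by a from-scratch Levenberg–Marquardt optimizer with analytic
   Jacobians, plus signed connection-weight influence analysis;
3. **Optimization** — a real-coded genetic algorithm maximizing the summed
   min–max-normalized responses `FF = Σᵣ (yᵣ − yᵣᵐⁱⁿ)/(yᵣᵐᵃˣ − yᵣᵐⁱⁿ)`
   over the factor box;
4. **Kinetics** — the pseudo-second-order model
   `dCₜ/dt = k (Cₛ − Cₜ)²`, closed form `Cₜ = Cₛ²kt / (1 + Cₛkt)`, fitted
   per temperature by nonlinear least squares with a linearized
   closed-form cross-check;
5. **Thermodynamics** — Arrhenius activation energy from `ln k` vs `1/T`,
   Van't Hoff enthalpy/entropy from `ln Kₑ` vs `1/T` with
   `Kₑ = Cₛ/(Cmax − Cₛ)`, and `ΔG° = ΔH° − TΔS° = −RT ln Kₑ`;
6. **Transport** — effective diffusivity (first-term Fourier slab model),
   film mass-transfer coefficient, and Biot number `Bi = Kₜ·L/Dₑ`;
7. **Synthetic studies** — a generator producing design tables and
   multi-temperature kinetic time courses with exactly the statistical
   structure the analysis assumes, so the whole chain is testable
   end-to-end (`run_pipeline()`).

The packaged reference tables (factor levels, network weights, kinetic
and thermodynamic parameters) are plain-text transcriptions used by the
consistency checks in `validate_fixtures()`.

## Worked example

Generate a synthetic study, fit the phenolic-content kinetics across
temperature, and run the thermodynamic chain:

```r
library(uaextract)

design <- generate_surface_study(study_spec(seed = 42))
fit <- train_lm(design, training_config(seed = 42), hidden_n = 12)
fit
#> <ann_fit> 4-12-4 network, 52 cycles, train R2 = 0.9984

tc <- generate_kinetics_study(study_spec(seed = 42))
series <- fit_pso_series(tc[tc$response == "YP", ], response = "YP")
series
#> <pso_series>
#>  temperature_C           k       Cs        R2      RMSE
#>             30 0.005227937 16.75600 0.9988464 0.1126349
#>             40 0.005997463 19.64167 0.9960567 0.2485708
#>             50 0.006786918 21.63541 0.9959278 0.2821259
#>             60 0.006767003 23.09399 0.9994151 0.1119612

Ke <- equilibrium_constant(series$coef$Cs, Cmax = 24.8)
vh <- vant_hoff_fit(kelvin(series$coef$temperature_C), Ke)
vh
#> <vant_hoff_fit> dH = 51.938 kJ/mol, dS = 177.244 J/(mol K)
round(gibbs(vh$dH, vh$dS, kelvin(c(30, 60))) / 1000, 3)
#> [1] -1.767 -7.084
```

The fitted rate constant and saturation concentration rise with
temperature (a warning flags the small noise-induced dip at 60 °C), the
positive enthalpy marks the extraction as endothermic, and the negative,
temperature-decreasing Gibbs energies mark it as spontaneous — the
recovered ΔH° (51.94 kJ/mol) and ΔS° (177.2 J/mol K) sit within noise of
the generating truth (51.975, 177.321). `run_pipeline(seed = 42)` chains
all stages (design → training → influence → GA optimum → kinetics →
thermodynamics → transport) and, given an `outdir`, writes byte-stable
CSV/JSON artifacts with seed and configuration-hash provenance.

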