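#' Universal gas constant, J/(mol K)
#' @export
GAS_CONSTANT <- 8.314

#' Celsius-to-kelvin conversion used throughout the package
#'
#' Uses `T[K] = T[degC] + 273` exactly; this offset reproduces the
#' published Gibbs-energy table to its printed three decimals, so it is
#' fixed rather than 273.15.
#'
#' @param temperature_C Temperature(s) in degrees Celsius.
#' @return Temperature(s) in kelvin.
#' @export
kelvin <- function(temperature_C) temperature_C + 273

#' Arrhenius regression of rate constants on temperature
#'
#' Ordinary least squares of `ln k` on `1/T` for `k = k0 exp(-Ea / (R T))`:
#' the activation energy is `-slope * R` and the pre-exponential factor is
#' `exp(intercept)`.
#'
#' @param temperature_K Temperatures in kelvin (at least 2 distinct).
#' @param k Positive rate constants.
#' @return An object of class `arrhenius_fit`: `Ea` (J/mol), `k0`,
#'   `r_squared`, `residuals`, and the underlying `lm` fit.
#' @examples
#' arrhenius_fit(kelvin(c(30, 40, 50, 60)),
#'               c(0.233, 0.332, 0.479, 0.564) * 1e-2)$Ea / 1000  # ~25.4
#' @export
arrhenius_fit <- function(temperature_K, k) {
  if (length(temperature_K) != length(k)) stop("lengths differ")
  if (any(k <= 0)) stop("rate constants must be positive")
  if (length(unique(temperature_K)) < 2)
    stop("need at least 2 distinct temperatures")
  fit <- stats::lm(log(k) ~ I(1 / temperature_K))
  r2 <- if (length(k) > 2) suppressWarnings(summary(fit)$r.squared) else 1
  structure(list(Ea = -stats::coef(fit)[[2]] * GAS_CONSTANT,
                 k0 = exp(stats::coef(fit)[[1]]),
                 r_squared = r2, residuals = stats::residuals(fit),
                 lm = fit),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> Ea = %.3f kJ/mol, k0 = %.4g (R2 = %.4f)\n",
              x$Ea / 1000, x$k0, x$r_squared))
  invisible(x)
}

#' Extraction equilibrium constant
#'
#' `Ke = Cs / (Cmax - Cs)`: the ratio of the saturation concentration
#' reached at a given temperature to the still-unextracted share of the
#' totally extractable concentration `Cmax`.
#'
#' @param Cs Saturation concentration (response units), `0 < Cs < Cmax`.
#' @param Cmax Concentration after complete extraction (same units).
#' @return Dimensionless equilibrium constant.
#' @export
equilibrium_constant <- function(Cs, Cmax) {
  if (any(Cs <= 0)) stop("Cs must be positive")
  if (any(Cs >= Cmax))
    stop("Cs must be below Cmax (extraction cannot exceed the total ",
         "extractable concentration)")
  Cs / (Cmax - Cs)
}

#' Van't Hoff regression of equilibrium constants on temperature
#'
#' OLS of `ln Ke` on `1/T` for `ln Ke = -dH/(R T) + dS/R`: the enthalpy
#' change is `-slope * R` and the entropy change is `intercept * R`.
#'
#' @param temperature_K Temperatures in kelvin (at least 2 distinct).
#' @param Ke Positive equilibrium constants.
#' @return A list of class `vant_hoff_fit`: `dH` (J/mol), `dS` (J/mol K),
#'   `r_squared`, `residuals`, `lm`.
#' @export
vant_hoff_fit <- function(temperature_K, Ke) {
  if (length(temperature_K) != length(Ke)) stop("lengths differ")
  if (any(Ke <= 0)) stop("equilibrium constants must be positive")
  if (length(unique(temperature_K)) < 2)
    stop("need at least 2 distinct temperatures")
  fit <- stats::lm(log(Ke) ~ I(1 / temperature_K))
  r2 <- if (length(Ke) > 2) suppressWarnings(summary(fit)$r.squared) else 1
  structure(list(dH = -stats::coef(fit)[[2]] * GAS_CONSTANT,
                 dS = stats::coef(fit)[[1]] * GAS_CONSTANT,
                 r_squared = r2, residuals = stats::residuals(fit), lm = fit),
            class = "vant_hoff_fit")
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf("<vant_hoff_fit> dH = %.3f kJ/mol, dS = %.3f J/(mol K)\n",
              x$dH / 1000, x$dS))
  invisible(x)
}

#' Gibbs free energy from enthalpy and entropy
#'
#' `dG = dH - T dS`. Negative values indicate a thermodynamically
#' spontaneous extraction.
#'
#' @param dH Enthalpy change, J/mol.
#' @param dS Entropy change, J/(mol K).
#' @param temperature_K Temperature(s), kelvin, `> 0`.
#' @return Gibbs free energy change(s), J/mol.
#' @export
gibbs <- function(dH, dS, temperature_K) {
  if (any(temperature_K <= 0)) stop("temperature must be positive kelvin")
  dH - temperature_K * dS
}

#' Gibbs free energy from an equilibrium constant
#'
#' The isotherm `dG = -R T ln Ke`; consistent with [gibbs()] whenever `Ke`
#' lies on the fitted Van't Hoff line.
#'
#' @param Ke Positive equilibrium constant(s).
#' @param temperature_K Temperature(s), kelvin, `> 0`.
#' @return Gibbs free energy change(s), J/mol.
#' @export
gibbs_from_ke <- function(Ke, temperature_K) {
  if (any(Ke <= 0)) stop("Ke must be positive")
  if (any(temperature_K <= 0)) stop("temperature must be positive kelvin")
  -GAS_CONSTANT * temperature_K * log(Ke)
}

#' Biot number for solid-liquid mass transfer
#'
#' `Bi = Kt L / De`: the ratio of external film mass transfer to internal
#' diffusion over the characteristic length `L`.
#'
#' @param Kt Mass transfer coefficient, m/s.
#' @param L Characteristic length, m.
#' @param De Effective diffusion coefficient, m^2/s, `> 0`.
#' @return Dimensionless Biot number.
#' @export
biot <- function(Kt, L, De) {
  if (any(De <= 0)) stop("De must be positive")
  if (any(Kt < 0) || any(L < 0)) stop("Kt and L must be nonnegative")
  Kt * L / De
}

#' Estimate transport coefficients from a fitted kinetic curve
#'
#' Effective diffusivity `De` comes from the slope of
#' `ln(1 - Ct/Cs)` versus time using the first term of the Fourier series
#' solution for the chosen geometry (slab of half-thickness `L`:
#' `slope = -pi^2 De / (4 L^2)`; sphere of radius `L`:
#' `slope = -pi^2 De / L^2`). The film mass-transfer coefficient uses the
#' initial-rate film model `dC/dt(0) = (Kt / L) Cs`, i.e. `Kt = k Cs L`
#' with the model's initial rate `k Cs^2`. Times are converted from
#' minutes to seconds. Both estimators are stated package assumptions; the
#' record carries the geometry label.
#'
#' @param fit A [fit_pso()] result (its stored data are used unless `data`
#'   is given).
#' @param L Characteristic length, m.
#' @param geometry `"slab"` (default) or `"sphere"`.
#' @param data Optional data frame with columns `t` (min) and `Ct`.
#' @return A list of class `transport_record`: `temperature_C`, `De`
#'   (m^2/s), `Kt` (m/s), `Bi`, `L`, `geometry`; `Bi` equals
#'   `Kt * L / De` exactly by construction.
#' @export
estimate_transport <- function(fit, L, geometry = c("slab", "sphere"),
                               data = fit$data) {
  geometry <- match.arg(geometry)
  if (L <= 0) stop("characteristic length must be positive")
  t_sec <- data$t * 60
  frac <- 1 - data$Ct / fit$Cs
  if (any(frac <= 0))
    stop("observed concentration reaches or exceeds the fitted saturation; ",
         "log-domain slope is undefined")
  sl <- stats::coef(stats::lm(log(frac) ~ t_sec))[[2]]
  if (sl >= 0) stop("non-negative diffusion slope; data do not decay")
  De <- if (geometry == "slab") -4 * L^2 * sl / pi^2 else -L^2 * sl / pi^2
  Kt <- (fit$k / 60) * fit$Cs * L
  structure(list(temperature_C = fit$temperature_C, De = De, Kt = Kt,
                 Bi = biot(Kt, L, De), L = L, geometry = geometry),
            class = "transport_record")
}

#' @export
print.transport_record <- function(x, ...) {
  cat(sprintf("<transport_record %s> De = %.4g m2/s, Kt = %.4g m/s, Bi = %.3f\n",
              x$geometry, x$De, x$Kt, x$Bi))
  invisible(x)
}
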