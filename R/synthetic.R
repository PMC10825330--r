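response_names <- c("YP", "YA", "YB", "YF")

#' Ground-truth response surfaces of the default synthetic study
#'
#' Full quadratics in the coded factors (factorial levels at +/- 1, axial
#' at +/- 2): `y = b0 + lin.x + quad.x^2 + interactions`. The linear
#' coefficients carry the signed influence pattern reported for the real
#' study (power positive everywhere; temperature, ratio and ethanol mixed),
#' curvature is negative (interior optimum), and each surface was
#' calibrated once so that its noiseless values over the 30-run design span
#' exactly the observed response ranges: total phenolics 7.723-24.619
#' mg GAE/g, DPPH inhibition 51.35-85.584 %, beta-carotenoids
#' 24.782-56.558 ug/g, flavonoids 0.291-1.970 mg QE/g.
#'
#' @return Named list per response: `b0`, `lin` (4), `quad` (4), `int`
#'   (coefficients of x1 x2, x1 x3, x2 x4), `range` (lo, hi).
#' @export
default_surface_truth <- function() {
  list(
    YP = list(b0 = 20.876933,
              lin = c(3.337081, -2.583808, -2.016828, -0.259191),
              quad = c(-1.619942, -1.214957, -0.971965, -0.809971),
              int = c(0.404986, -0.323988, 0.242991),
              range = c(7.723, 24.619)),
    YA = list(b0 = 75.612027,
              lin = c(6.409814, 5.218976, -2.102088, 3.386122),
              quad = c(-2.588778, -1.863920, -1.035511, -1.553267),
              int = c(0.621307, 0.310653, -0.414204),
              range = c(51.350, 85.584)),
    YB = list(b0 = 48.483770,
              lin = c(6.149727, -2.546710, 3.660896, -3.530667),
              quad = c(-2.604590, -1.736393, -1.446995, -1.736393),
              int = c(0.578798, 0.723497, -0.434098),
              range = c(24.782, 56.558)),
    YF = list(b0 = 1.442146,
              lin = c(0.355328, -0.213270, -0.104249, 0.144995),
              quad = c(-0.110122, -0.055061, -0.036707, -0.066073),
              int = c(0.018354, -0.011012, 0.014683),
              range = c(0.291, 1.970)))
}

#' Evaluate a quadratic truth surface at coded points
#'
#' @param truth One element of [default_surface_truth()].
#' @param X Coded design matrix (columns = factors).
#' @return Noiseless response vector.
#' @export
eval_surface_truth <- function(truth, X) {
  X <- as.matrix(X)
  drop(truth$b0 + X %*% truth$lin + (X^2) %*% truth$quad +
         truth$int[1] * X[, 1] * X[, 2] + truth$int[2] * X[, 1] * X[, 3] +
         truth$int[3] * X[, 2] * X[, 4])
}

#' Ground-truth kinetic and thermodynamic parameters of the synthetic study
#'
#' Per response: the rate constant at 303 K and the activation energy
#' (matching the fitted values of the real study, so the Arrhenius spread
#' of `k` over 30-60 deg C is realistic), and a Van't-Hoff-consistent
#' saturation law: enthalpy/entropy taken from the published thermodynamic
#' table with `Cmax` chosen so that
#' `Cs(T) = Cmax Ke(T) / (1 + Ke(T))`, `Ke(T) = exp(-(dH - T dS)/(R T))`,
#' tracks the published saturation-concentration ranges.
#'
#' @return Named list per response: `k303`, `Ea` (J/mol), `k0`, `dH`
#'   (J/mol), `dS` (J/mol K), `Cmax` (response units).
#' @export
default_kinetic_truth <- function() {
  base <- list(
    YP = list(k303 = 0.00556, Ea = 5965.4, dH = 51975, dS = 177.321,
              Cmax = 24.8),
    YA = list(k303 = 0.00233, Ea = 25406.9, dH = 28083, dS = 106.943,
              Cmax = 87.0),
    YB = list(k303 = 0.00439, Ea = 12555.7, dH = 66896, dS = 227.280,
              Cmax = 66.8),
    YF = list(k303 = 0.07007, Ea = 12188.6, dH = 44486, dS = 148.646,
              Cmax = 2.81))
  lapply(base, function(tr) {
    tr$k0 <- tr$k303 * exp(tr$Ea / (GAS_CONSTANT * 303))
    tr
  })
}

truth_rate_constant <- function(tr, temperature_K)
  tr$k0 * exp(-tr$Ea / (GAS_CONSTANT * temperature_K))

truth_saturation <- function(tr, temperature_K) {
  Ke <- exp(-gibbs(tr$dH, tr$dS, temperature_K) /
              (GAS_CONSTANT * temperature_K))
  Cs <- tr$Cmax * Ke / (1 + Ke)
  if (any(Cs >= tr$Cmax)) stop("infeasible saturation law (Cs >= Cmax)")
  Cs
}

#' Specification of a synthetic extraction study
#'
#' Bundles everything the generators need: the factor set, the quadratic
#' truth surfaces with their measurement-noise level (default 2% of each
#' response range), the kinetic/thermodynamic truths with their noise
#' level (default 1% of the local saturation concentration), the kinetic
#' time grid (default 2.5-25 min) and temperatures (default 30-60 deg C),
#' and the seed.
#'
#' @param seed Integer seed driving all generated noise.
#' @param factors List of [factor_spec()]s.
#' @param surface Truth surfaces, see [default_surface_truth()].
#' @param kinetics Kinetic truths, see [default_kinetic_truth()].
#' @param surface_noise_frac Gaussian noise sd as a fraction of each
#'   response range (default 0.02).
#' @param kinetic_noise_frac Gaussian noise sd as a fraction of the local
#'   `Cs(T)` (default 0.01).
#' @param time_grid Kinetic sampling times, min.
#' @param temperatures Kinetic temperatures, deg C.
#' @param n_center Center replicates of the design (default 6).
#' @return A list of class `study_spec`.
#' @export
study_spec <- function(seed = 1, factors = default_factors(),
                       surface = default_surface_truth(),
                       kinetics = default_kinetic_truth(),
                       surface_noise_frac = 0.02,
                       kinetic_noise_frac = 0.01,
                       time_grid = c(2.5, 5, 10, 15, 20, 25),
                       temperatures = c(30, 40, 50, 60), n_center = 6) {
  if (surface_noise_frac < 0 || kinetic_noise_frac < 0)
    stop("noise fractions must be nonnegative")
  for (r in names(kinetics)) {
    tr <- kinetics[[r]]
    kk <- truth_rate_constant(tr, kelvin(temperatures))
    if (any(kk <= 0 | kk >= 1))
      stop("kinetic truth yields rate constants outside (0, 1)")
    truth_saturation(tr, kelvin(temperatures))  # errors if infeasible
  }
  structure(list(seed = seed, factors = factors, surface = surface,
                 kinetics = kinetics, surface_noise_frac = surface_noise_frac,
                 kinetic_noise_frac = kinetic_noise_frac,
                 time_grid = time_grid, temperatures = temperatures,
                 n_center = n_center),
            class = "study_spec")
}

#' Generate a synthetic designed-experiment response table
#'
#' Builds the central composite design, evaluates the quadratic truth
#' surfaces at the coded points, and adds seeded homoscedastic Gaussian
#' noise (sd = `surface_noise_frac` of each response range). The returned
#' table carries the noiseless truth as attribute `"truth_responses"`.
#'
#' @param spec A [study_spec()].
#' @return A `ccd_design` data frame with response columns `Y_P`, `Y_A`,
#'   `Y_B`, `Y_F`.
#' @export
generate_surface_study <- function(spec = study_spec()) {
  design <- generate_ccd(spec$factors, n_center = spec$n_center)
  X <- design_matrix(design, "coded")
  truth <- sapply(response_names, function(r)
    eval_surface_truth(spec$surface[[r]], X))
  if (any(truth < 0))
    stop("truth surface produced a negative response; adjust the spec")
  set.seed(spec$seed)
  noisy <- truth
  for (j in seq_along(response_names)) {
    r <- response_names[j]
    sd_j <- spec$surface_noise_frac * diff(spec$surface[[r]]$range)
    noisy[, j] <- truth[, j] + stats::rnorm(nrow(truth), sd = sd_j)
  }
  design$Y_P <- noisy[, "YP"]; design$Y_A <- noisy[, "YA"]
  design$Y_B <- noisy[, "YB"]; design$Y_F <- noisy[, "YF"]
  attr(design, "truth_responses") <- truth
  design
}

#' Generate synthetic multi-temperature kinetic time courses
#'
#' For each response and temperature, the rate constant follows the
#' Arrhenius truth exactly and the saturation concentration follows the
#' Van't-Hoff-consistent law; observations are the pseudo-second-order
#' curve on the time grid plus seeded Gaussian noise
#' (sd = `kinetic_noise_frac * Cs(T)`).
#'
#' @param spec A [study_spec()].
#' @param responses Responses to generate (default all four).
#' @return Data frame with columns `response`, `temperature_C`, `t_min`,
#'   `Ct`; the per-condition truth (`k`, `Cs`) is attached as attribute
#'   `"truth_kinetics"`.
#' @export
generate_kinetics_study <- function(spec = study_spec(),
                                    responses = response_names) {
  set.seed(spec$seed + 1)
  rows <- list(); truth_rows <- list()
  for (r in responses) {
    tr <- spec$kinetics[[r]]
    for (tc in spec$temperatures) {
      TK <- kelvin(tc)
      k <- truth_rate_constant(tr, TK)
      Cs <- truth_saturation(tr, TK)
      ct <- predict_ct(k, Cs, spec$time_grid) +
        stats::rnorm(length(spec$time_grid),
                     sd = spec$kinetic_noise_frac * Cs)
      rows[[length(rows) + 1]] <- data.frame(
        response = r, temperature_C = tc, t_min = spec$time_grid, Ct = ct)
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        response = r, temperature_C = tc, k = k, Cs = Cs)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth_kinetics") <- do.call(rbind, truth_rows)
  out
}

#' Construct an exactly Van't-Hoff-consistent saturation series
#'
#' Builds `Ke(T)` from chosen enthalpy/entropy so that the Van't Hoff
#' regression recovers them with zero residual, together with the implied
#' `Cs(T)` and Gibbs energies (the isotherm and the `dH - T dS` line agree
#' exactly by construction).
#'
#' @param spec A [study_spec()].
#' @param response Which response's truth to use.
#' @return List: `temperature_K`, `Cs`, `Ke`, `dG` (J/mol), `dH`, `dS`,
#'   `Cmax`.
#' @export
generate_thermo_consistent <- function(spec = study_spec(), response = "YP") {
  tr <- spec$kinetics[[match.arg(response, response_names)]]
  TK <- kelvin(spec$temperatures)
  dG <- gibbs(tr$dH, tr$dS, TK)
  Ke <- exp(-dG / (GAS_CONSTANT * TK))
  Cs <- tr$Cmax * Ke / (1 + Ke)
  if (any(Cs >= tr$Cmax)) stop("infeasible: implied Cs reaches Cmax")
  list(temperature_K = TK, Cs = Cs, Ke = Ke, dG = dG,
       dH = tr$dH, dS = tr$dS, Cmax = tr$Cmax)
}
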