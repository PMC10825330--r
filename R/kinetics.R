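#' Pseudo-second-order extraction curve
#'
#' Closed-form solution `Ct = Cs^2 k t / (1 + Cs k t)` of the rate law
#' `dCt/dt = k (Cs - Ct)^2`: concentration rises from 0 at `t = 0`,
#' monotonically and concavely, towards the saturation concentration `Cs`.
#'
#' @param k Rate constant, (response unit)^-1 min^-1, `> 0`.
#' @param Cs Saturation concentration in response units, `> 0`.
#' @param t Extraction time(s), min, `>= 0`.
#' @return Predicted concentration(s) at `t`.
#' @examples
#' predict_ct(0.00556, 16.536, 25)  # ~11.52
#' @export
predict_ct <- function(k, Cs, t) {
  if (k <= 0 || Cs <= 0) stop("k and Cs must be positive")
  if (any(t < 0)) stop("negative extraction time")
  Cs^2 * k * t / (1 + Cs * k * t)
}

# Closed-form fit of the linearized form t/Ct = 1/(k Cs^2) + t/Cs.
fit_pso_linearized <- function(t, Ct) {
  keep <- t > 0 & Ct > 0
  if (sum(keep) < 2) stop("need at least 2 positive observations")
  f <- stats::lm(I(t[keep] / Ct[keep]) ~ t[keep])
  a <- stats::coef(f)[[1]]; b <- stats::coef(f)[[2]]
  if (b <= 0 || a <= 0)
    stop("linearized fit yields non-positive parameters; ",
         "data are not pseudo-second-order shaped")
  list(k = b^2 / a, Cs = 1 / b)
}

#' Fit the pseudo-second-order model to a kinetic time course
#'
#' Default method: nonlinear least squares on the closed-form curve,
#' initialized from the linearized regression of `t/Ct` on `t` (whose
#' closed-form estimates are also exposed as `method = "linearized"` and
#' serve as an independent check: on noiseless model data the two agree to
#' machine precision). Goodness of fit is reported via [fit_metrics()].
#'
#' @param t Time points, min (strictly increasing, `>= 0`).
#' @param Ct Concentrations in response units (`>= 0`, at least 3 points).
#' @param method `"nls"` (default) or `"linearized"`.
#' @param temperature_C Optional temperature label carried in the result.
#' @param response Optional response label carried in the result.
#' @return An object of class `pso_fit`: `k`, `Cs`, `se` (named standard
#'   errors, NA for the linearized route), `metrics` ([fit_metrics()]),
#'   `method`, `data`, plus any labels.
#' @export
fit_pso <- function(t, Ct, method = c("nls", "linearized"),
                    temperature_C = NA_real_, response = NA_character_) {
  method <- match.arg(method)
  if (length(t) != length(Ct)) stop("t and Ct must have equal length")
  if (length(t) < 3) stop("need at least 3 observations")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (any(t < 0) || any(Ct < 0)) stop("t and Ct must be nonnegative")
  if (all(Ct == 0)) stop("all concentrations are zero")

  lin <- fit_pso_linearized(t, Ct)
  if (method == "linearized") {
    k <- lin$k; Cs <- lin$Cs; se <- c(k = NA_real_, Cs = NA_real_)
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(Ct ~ Cs^2 * k * t / (1 + Cs * k * t),
                        start = list(k = lin$k, Cs = lin$Cs),
                        lower = c(k = 1e-12, Cs = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e)
        stop("nonlinear fit failed to converge (", conditionMessage(e),
             "); linearized estimates: k = ", signif(lin$k, 6),
             ", Cs = ", signif(lin$Cs, 6)))
    cf <- stats::coef(fit)
    k <- cf[["k"]]; Cs <- cf[["Cs"]]
    se <- tryCatch(summary(fit)$coefficients[c("k", "Cs"), "Std. Error"],
                   error = function(e) c(k = NA_real_, Cs = NA_real_))
  }
  if (Cs < 0.8 * max(Ct))
    warning("fitted saturation concentration is below 80% of the largest ",
            "observation; the curve may not have approached saturation")
  keep <- Ct > 0
  metrics <- fit_metrics(predict_ct(k, Cs, t[keep]), Ct[keep])
  structure(list(k = k, Cs = Cs, se = se, metrics = metrics, method = method,
                 temperature_C = temperature_C, response = response,
                 data = data.frame(t = t, Ct = Ct)),
            class = "pso_fit")
}

#' @export
print.pso_fit <- function(x, ...) {
  cat(sprintf(
    "<pso_fit %s> k = %.4g, Cs = %.4g (R2 = %.3f, RMSE = %.3g, n = %d)\n",
    x$method, x$k, x$Cs, x$metrics$r_squared, x$metrics$rmse, x$metrics$n))
  invisible(x)
}

#' Fit pseudo-second-order kinetics across temperatures
#'
#' Fits one curve per temperature and collects the parameters. Both the
#' rate constant and the saturation concentration are expected to increase
#' with temperature for a thermally activated, endothermic extraction; a
#' warning is emitted when a fitted series is non-monotone.
#'
#' @param data A data frame with columns `temperature_C`, `t_min`, `Ct`
#'   (a single response).
#' @param method Passed to [fit_pso()].
#' @param response Optional response label.
#' @return An object of class `pso_series`: `fits` (list of `pso_fit` by
#'   temperature) and `coef` (data frame temperature_C, k, Cs, R2, RMSE).
#' @export
fit_pso_series <- function(data, method = "nls", response = NA_character_) {
  temps <- sort(unique(data$temperature_C))
  if (length(temps) < 2) stop("need at least 2 temperatures")
  fits <- lapply(temps, function(tc) {
    d <- data[data$temperature_C == tc, ]
    d <- d[order(d$t_min), ]
    fit_pso(d$t_min, d$Ct, method = method, temperature_C = tc,
            response = response)
  })
  names(fits) <- temps
  k <- vapply(fits, `[[`, numeric(1), "k")
  Cs <- vapply(fits, `[[`, numeric(1), "Cs")
  if (any(diff(k) <= 0))
    warning("fitted rate constants are not strictly increasing with ",
            "temperature")
  if (any(diff(Cs) <= 0))
    warning("fitted saturation concentrations are not strictly increasing ",
            "with temperature")
  structure(list(
    fits = fits,
    coef = data.frame(
      temperature_C = temps, k = k, Cs = Cs,
      R2 = vapply(fits, function(f) f$metrics$r_squared, numeric(1)),
      RMSE = vapply(fits, function(f) f$metrics$rmse, numeric(1)))),
    class = "pso_series")
}

#' @export
print.pso_series <- function(x, ...) {
  cat("<pso_series>\n")
  print(x$coef, row.names = FALSE)
  invisible(x)
}
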