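#' Goodness-of-fit statistics
#'
#' Computes the four statistics used to judge the surrogate and kinetic
#' fits: `R2 = 1 - SSE/SST` (squared residuals about the experimental
#' mean), `RMSE = sqrt(SSE / (n - 1))`, `chi2 = sum((Yp - Ye)^2 / Ye)`,
#' and the mean absolute relative deviation
#' `Rd = (100 / n) sum(|Ye - Yp| / Ye)`. The `Rd` normalization is
#' selectable: `"n"` (default; a single pair then reproduces the
#' optimum-validation deviation) or `"n-1"`.
#'
#' @param predicted Model values `Yp`.
#' @param experimental Observed values `Ye` (non-zero; they appear in the
#'   `chi2` and `Rd` denominators).
#' @param rd_norm `"n"` or `"n-1"`.
#' @return An object of class `fit_metrics` with fields `r_squared`,
#'   `rmse`, `chisq`, `rd`, `n`.
#' @examples
#' m <- fit_metrics(c(1, 2, 4), c(1, 2, 3))
#' m$r_squared  # 0.5
#' @export
fit_metrics <- function(predicted, experimental, rd_norm = c("n", "n-1")) {
  rd_norm <- match.arg(rd_norm)
  if (length(predicted) != length(experimental))
    stop("predicted and experimental must have equal length")
  n <- length(predicted)
  if (n < 2 && rd_norm == "n-1")
    stop("n-1 normalization needs at least 2 points")
  if (any(experimental == 0))
    stop("zero experimental value in chi-squared / Rd denominators")
  sse <- sum((predicted - experimental)^2)
  sst <- sum((experimental - mean(experimental))^2)
  denom <- if (rd_norm == "n") n else n - 1
  structure(list(
    r_squared = if (sst > 0) 1 - sse / sst else as.numeric(sse == 0),
    rmse = sqrt(sse / max(n - 1, 1)),
    chisq = sum((predicted - experimental)^2 / experimental),
    rd = (100 / denom) * sum(abs(experimental - predicted) / experimental),
    n = n), class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("<fit_metrics> R2 = %.4f, RMSE = %.4g, chi2 = %.4g, Rd = %.3f%% (n = %d)\n",
              x$r_squared, x$rmse, x$chisq, x$rd, x$n))
  invisible(x)
}

#' Radical-scavenging (DPPH) inhibition percentage
#'
#' `(1 - As/Ac) * 100` from the 517 nm absorbances of the sample (`As`)
#' and the control (`Ac`).
#'
#' @param As Sample absorbance, `>= 0`.
#' @param Ac Control absorbance, `> 0`.
#' @return Percent inhibition (100 = full quenching).
#' @export
dpph_inhibition <- function(As, Ac) {
  if (any(Ac <= 0)) stop("control absorbance must be positive")
  if (any(As < 0)) stop("sample absorbance must be nonnegative")
  (1 - As / Ac) * 100
}

#' Phenolic (or flavonoid) content from a calibration-line concentration
#'
#' `c * V / w`: calibration concentration (mg equivalent/ml) times extract
#' volume (ml) over sample dry mass (g), giving mg equivalent per g dry
#' weight. The same conversion serves the flavonoid assay with quercetin
#' calibration units.
#'
#' @param c Calibration-line concentration, mg/ml.
#' @param V Extract volume, ml.
#' @param w Sample mass, g, `> 0`.
#' @return Content in mg equivalent per g dry weight.
#' @export
tpc_from_calibration <- function(c, V, w) {
  if (any(w <= 0)) stop("sample mass must be positive")
  c * V / w
}

#' Beta-carotene concentration from 450 nm absorbance
#'
#' `A * D / (A1pct * C1pct)` with the 1% absorption coefficient
#' `A1pct = 2592` AU and the 1% standard concentration `C1pct = 10` mg/ml.
#'
#' @param A Absorbance at 450 nm, `>= 0`.
#' @param D Dilution factor, `>= 0`.
#' @param A1pct,C1pct Calibration constants (defaults 2592 AU, 10 mg/ml).
#' @return Beta-carotene concentration.
#' @export
beta_carotene <- function(A, D, A1pct = 2592, C1pct = 10) {
  if (any(A < 0) || any(D < 0)) stop("A and D must be nonnegative")
  A * D / (A1pct * C1pct)
}
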