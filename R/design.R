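#' Define an extraction process factor
#'
#' A factor is described by its natural low, center, and high levels, e.g.
#' ultrasonic power 150/250/350 W. The center defaults to the midpoint.
#'
#' @param name Descriptive name.
#' @param notation Short symbol used in column names (e.g. `"XP"`).
#' @param low,high Natural low/high levels (must satisfy `low < high`).
#' @param center Natural center level; defaults to `(low + high) / 2`.
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("ultrasonic_power_W", "XP", 150, 350)
#' @export
factor_spec <- function(name, notation, low, high, center = (low + high) / 2) {
  if (!is.finite(low) || !is.finite(high) || !is.finite(center))
    stop("factor bounds must be finite")
  if (!(low < center && center < high))
    stop("factor levels must satisfy low < center < high")
  structure(list(name = name, notation = notation,
                 low = low, center = center, high = high),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor_spec> %s (%s): %g / %g / %g\n",
              x$name, x$notation, x$low, x$center, x$high))
  invisible(x)
}

#' Factor set of the four-variable extraction study
#'
#' Loads the packaged factor table: ultrasonic power (150-350 W), temperature
#' (30-70 deg C), solvent-to-solid ratio (15-35 ml/g), ethanol concentration
#' (40-80 %). The ratio is held internally in ml solvent per g solid.
#'
#' @return A list of four [factor_spec()] objects.
#' @export
default_factors <- function() {
  tab <- read_fixture("table1_factors")
  lapply(seq_len(nrow(tab)), function(i)
    factor_spec(tab$name[i], tab$notation[i], tab$low[i], tab$high[i],
                center = tab$center[i]))
}

resolve_alpha <- function(alpha, k) {
  if (identical(alpha, "rotatable")) return(2^(k / 4))
  if (is.numeric(alpha) && length(alpha) == 1 && alpha > 0) return(alpha)
  stop("alpha must be \"rotatable\" or a positive number")
}

# half-step in natural units per unit of coded distance
coding_step <- function(spec, convention, alpha) {
  convention <- match.arg(convention, c("table-levels-are-axial",
                                        "table-levels-are-factorial"))
  half <- (spec$high - spec$low) / 2
  if (half <= 0) stop("degenerate factor range")
  if (convention == "table-levels-are-axial") half / alpha else half
}

#' Map a natural factor value to its coded value (and back)
#'
#' The coded scale places the factor center at 0. Under the default
#' `"table-levels-are-axial"` convention the tabulated min/max sit at the
#' axial distance +/- alpha, so the factorial levels +/- 1 lie inside the
#' tabulated range; under `"table-levels-are-factorial"` min/max sit at
#' +/- 1 and axial points extend beyond it.
#'
#' @param spec A [factor_spec()].
#' @param natural,coded Value(s) to convert.
#' @param convention Placement of the tabulated min/max levels.
#' @param alpha Axial distance, `"rotatable"` (2^(k/4)) or a number;
#'   for the conversion only its value matters, default 2 (k = 4).
#' @return Numeric vector of converted values.
#' @examples
#' xp <- factor_spec("power_W", "XP", 150, 350)
#' code_value(xp, 350)   # +2 under the default convention
#' decode_value(xp, 0)   # 250
#' @export
code_value <- function(spec, natural,
                       convention = "table-levels-are-axial", alpha = 2) {
  alpha <- resolve_alpha(alpha, 4)
  (natural - spec$center) / coding_step(spec, convention, alpha)
}

#' @rdname code_value
#' @export
decode_value <- function(spec, coded,
                         convention = "table-levels-are-axial", alpha = 2) {
  alpha <- resolve_alpha(alpha, 4)
  spec$center + coded * coding_step(spec, convention, alpha)
}

#' Generate a central composite circumscribed design
#'
#' Builds the 2^k factorial points (coded +/- 1), 2k axial points
#' (coded +/- alpha) and `n_center` center points, in a deterministic order:
#' factorial points in binary counting order (first factor slowest), axial
#' points by factor (minus then plus), then center points. Natural values are
#' filled from the coding convention. For the default four factors with six
#' center points this yields the 30-run design used for surrogate training.
#'
#' @param factors List of [factor_spec()] objects (2 to 6 factors).
#' @param alpha `"rotatable"` (alpha = 2^(k/4), the default, = 2 for k = 4)
#'   or a positive number.
#' @param convention See [code_value()].
#' @param n_center Number of center-point replicates (default 6).
#' @return A `data.frame` of class `ccd_design` with columns `run_id`,
#'   `point_class`, `coded_<notation>` and `natural_<notation>`; the factor
#'   list, convention and alpha are stored as attributes.
#' @examples
#' d <- generate_ccd(default_factors())
#' nrow(d)  # 30
#' @export
generate_ccd <- function(factors = default_factors(), alpha = "rotatable",
                         convention = "table-levels-are-axial", n_center = 6) {
  k <- length(factors)
  if (k < 2 || k > 6) stop("between 2 and 6 factors are supported")
  if (n_center < 1) stop("n_center must be >= 1")
  convention <- match.arg(convention, c("table-levels-are-axial",
                                        "table-levels-are-factorial"))
  a <- resolve_alpha(alpha, k)

  # factorial block, binary counting order (first factor = most significant)
  fact <- matrix(0, 2^k, k)
  for (i in seq_len(2^k)) {
    bits <- as.integer(intToBits(i - 1))[k:1]
    fact[i, ] <- ifelse(bits[seq_len(k)] == 1, 1, -1)
  }
  axial <- matrix(0, 2 * k, k)
  for (j in seq_len(k)) {
    axial[2 * j - 1, j] <- -a
    axial[2 * j, j] <- a
  }
  centers <- matrix(0, n_center, k)
  coded <- rbind(fact, axial, centers)
  point_class <- rep(c("factorial", "axial", "center"),
                     c(2^k, 2 * k, n_center))

  natural <- coded
  for (j in seq_len(k))
    natural[, j] <- decode_value(factors[[j]], coded[, j], convention, a)

  notations <- vapply(factors, `[[`, character(1), "notation")
  out <- data.frame(run_id = seq_len(nrow(coded)), point_class = point_class,
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) out[[paste0("coded_", notations[j])]] <- coded[, j]
  for (j in seq_len(k)) out[[paste0("natural_", notations[j])]] <- natural[, j]
  structure(out, factors = factors, convention = convention, alpha = a,
            class = c("ccd_design", "data.frame"))
}

#' Extract the coded or natural design matrix from a design table
#'
#' @param design A `ccd_design` (or any data frame with `coded_*` /
#'   `natural_*` columns).
#' @param scale `"coded"` or `"natural"`.
#' @return Numeric matrix, one column per factor.
#' @export
design_matrix <- function(design, scale = c("coded", "natural")) {
  scale <- match.arg(scale)
  cols <- grep(paste0("^", scale, "_"), names(design), value = TRUE)
  m <- as.matrix(design[cols])
  colnames(m) <- sub(paste0("^", scale, "_"), "", cols)
  m
}

response_cols <- c("Y_P", "Y_A", "Y_B", "Y_F")

#' Extract the response matrix from a design table
#'
#' @param design A design table with response columns `Y_P`, `Y_A`, `Y_B`,
#'   `Y_F` (any subset).
#' @return Numeric matrix of responses.
#' @export
response_matrix <- function(design) {
  cols <- intersect(response_cols, names(design))
  if (length(cols) == 0) stop("design table carries no response columns")
  as.matrix(design[cols])
}
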