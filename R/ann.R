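logsig <- function(z) 1 / (1 + exp(-z))

#' Construct feed-forward network parameters
#'
#' Holds the weights and biases of a single-hidden-layer log-sigmoid network:
#' hidden weights `u` (hidden x input), hidden biases `Th`, output weights
#' `w` (output x hidden) and output biases `To`. The 4-12-4 configuration
#' with biases has 12*4 + 12 + 4*12 + 4 = 112 parameters.
#'
#' @param u Hidden-by-input weight matrix.
#' @param Th Hidden bias vector.
#' @param w Output-by-hidden weight matrix.
#' @param To Output bias vector.
#' @return An object of class `ann_params`.
#' @export
ann_params <- function(u, Th, w, To) {
  u <- as.matrix(u); w <- as.matrix(w)
  Th <- as.numeric(Th); To <- as.numeric(To)
  if (nrow(u) != length(Th)) stop("u rows must match length(Th)")
  if (ncol(w) != nrow(u)) stop("w columns must match hidden size")
  if (nrow(w) != length(To)) stop("w rows must match length(To)")
  if (!all(is.finite(u), is.finite(Th), is.finite(w), is.finite(To)))
    stop("network parameters must be finite")
  structure(list(u = u, Th = Th, w = w, To = To), class = "ann_params")
}

#' @export
print.ann_params <- function(x, ...) {
  cat(sprintf("<ann_params> %d-%d-%d network, %d parameters\n",
              ncol(x$u), nrow(x$u), nrow(x$w), n_params(x)))
  invisible(x)
}

n_params <- function(p) length(p$u) + length(p$Th) + length(p$w) + length(p$To)

#' Affine input/output scaling for a sigmoid network
#'
#' Maps each natural input range and each natural response range onto
#' [0.05, 0.95]; the margin keeps targets away from sigmoid saturation.
#'
#' @param x_lo,x_hi Natural input ranges (one value per input).
#' @param y_lo,y_hi Natural response ranges (one value per output).
#' @return An object of class `ann_scaling`.
#' @export
ann_scaling <- function(x_lo, x_hi, y_lo, y_hi) {
  if (any(x_hi <= x_lo) || any(y_hi <= y_lo))
    stop("scaling ranges must be non-degenerate")
  structure(list(x_lo = x_lo, x_hi = x_hi, y_lo = y_lo, y_hi = y_hi),
            class = "ann_scaling")
}

scale_to_unit <- function(x, lo, hi) 0.05 + 0.9 * (x - lo) / (hi - lo)
unscale_from_unit <- function(s, lo, hi) lo + (s - 0.05) * (hi - lo) / 0.9

scale_inputs <- function(scaling, X)
  sweep(sweep(X, 2, scaling$x_lo), 2, (scaling$x_hi - scaling$x_lo), "/") * 0.9 + 0.05
scale_outputs <- function(scaling, Y)
  sweep(sweep(Y, 2, scaling$y_lo), 2, (scaling$y_hi - scaling$y_lo), "/") * 0.9 + 0.05
unscale_outputs <- function(scaling, S)
  sweep(sweep(S, 2, 0.05) / 0.9, 2, (scaling$y_hi - scaling$y_lo), "*") +
    matrix(scaling$y_lo, nrow(S), ncol(S), byrow = TRUE)

# forward pass on already-scaled inputs; rows of Xs are patterns
ann_forward_scaled <- function(params, Xs) {
  H <- logsig(Xs %*% t(params$u) +
                matrix(params$Th, nrow(Xs), length(params$Th), byrow = TRUE))
  logsig(H %*% t(params$w) +
           matrix(params$To, nrow(H), length(params$To), byrow = TRUE))
}

#' Evaluate the network surrogate at natural inputs
#'
#' Scales the inputs, applies `logsig` at the hidden and output layers, and
#' unscales the sigmoid outputs back to natural response units. Because the
#' output layer is sigmoidal, predictions are bounded by the output scaling
#' range (extended by the 0.05 margin).
#'
#' @param params An [ann_params()] object.
#' @param scaling An [ann_scaling()] object.
#' @param x Natural input vector, or a matrix with one row per point.
#' @return Matrix of natural responses (one row per input point).
#' @export
ann_forward <- function(params, scaling, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(params$u)) stop("input dimension mismatch")
  unscale_outputs(scaling, ann_forward_scaled(params, scale_inputs(scaling, x)))
}

#' Load the published network weights
#'
#' Partitions the packaged flat sequence of 112 printed values into the
#' hidden weights (48), hidden biases (12), output weights (48) and output
#' biases (4) of the 4-12-4 network. The printed table does not state its
#' partition order or orientation; the default layout reads the sequence as
#' `u` row-major by hidden unit, then `Th`, then `w` row-major by output,
#' then `To`. This fixture supports structural tests only; no numeric claim
#' is attached to any particular layout.
#'
#' @param layout Partition convention; currently `"u-th-w-to"`.
#' @return An [ann_params()] object.
#' @export
load_published_ann <- function(layout = "u-th-w-to") {
  layout <- match.arg(layout, "u-th-w-to")
  v <- read_fixture("table2_ann_weights")$value
  if (length(v) != 112) stop("expected 112 printed values")
  ann_params(u = matrix(v[1:48], nrow = 12, ncol = 4, byrow = TRUE),
             Th = v[49:60],
             w = matrix(v[61:108], nrow = 4, ncol = 12, byrow = TRUE),
             To = v[109:112])
}

#' Signed relative influence of network inputs on outputs
#'
#' The default connection-weights method (after Olden) scores input `i` on
#' output `o` as `sum_h u[h, i] * w[o, h]`; its sign indicates the direction
#' of the input's effect. The Garson alternative distributes `|u| * |w|`
#' shares and normalizes per output, so its values are nonnegative and sum
#' to one per output (sign information is lost).
#'
#' @param params An [ann_params()] object.
#' @param method `"olden"` (signed, default) or `"garson"`.
#' @return A matrix (inputs x outputs) of influence values with a
#'   `method` attribute.
#' @export
relative_influence <- function(params, method = c("olden", "garson")) {
  method <- match.arg(method)
  if (method == "olden") {
    ri <- t(params$u) %*% t(params$w)
  } else {
    absu <- abs(params$u)
    Q <- absu / rowSums(absu)                 # share of hidden unit h per input
    contrib <- t(Q) %*% t(abs(params$w))      # inputs x outputs
    ri <- sweep(contrib, 2, colSums(contrib), "/")
  }
  dimnames(ri) <- list(input = colnames(params$u), output = rownames(params$w))
  attr(ri, "method") <- method
  ri
}
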