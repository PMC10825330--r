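#' Training configuration for the network trainer
#'
#' @param max_cycles Maximum accepted Levenberg-Marquardt steps (default
#'   5000).
#' @param split Train/validation/test fractions (default 0.70/0.15/0.15,
#'   must sum to 1); patterns are assigned by a seeded shuffle of run
#'   indices.
#' @param mu_init,mu_increase,mu_decrease,mu_max Damping schedule: initial
#'   damping, factor applied after a rejected step, factor dividing the
#'   damping after an accepted step, and the ceiling at which training
#'   aborts.
#' @param sse_tol Stop when the relative decrease of the training SSE over
#'   an accepted step falls below this.
#' @param grad_tol Stop when the gradient infinity-norm falls below this.
#' @param patience Consecutive cycles without validation improvement before
#'   early stopping. The default `Inf` disables early stopping (training
#'   runs to convergence and the final parameters are returned); with a
#'   finite patience and a non-empty validation split, training stops when
#'   the validation error stalls and the parameters with the best
#'   validation error are returned.
#' @param seed Seed controlling the split and the weight initialization.
#' @return A list of class `training_config`.
#' @export
training_config <- function(max_cycles = 5000, split = c(0.70, 0.15, 0.15),
                            mu_init = 1e-3, mu_increase = 10,
                            mu_decrease = 10, mu_max = 1e10,
                            sse_tol = 1e-12, grad_tol = 1e-10,
                            patience = Inf, seed = 1) {
  if (max_cycles < 1) stop("max_cycles must be >= 1")
  if (length(split) != 3 || abs(sum(split) - 1) > 1e-8 || any(split < 0))
    stop("split must be three nonnegative fractions summing to 1")
  structure(list(max_cycles = max_cycles, split = split, mu_init = mu_init,
                 mu_increase = mu_increase, mu_decrease = mu_decrease,
                 mu_max = mu_max, sse_tol = sse_tol, grad_tol = grad_tol,
                 patience = patience, seed = seed),
            class = "training_config")
}

pack_params <- function(p) c(as.vector(p$u), p$Th, as.vector(p$w), p$To)

unpack_params <- function(theta, n_in, n_hidden, n_out) {
  i <- 0
  u <- matrix(theta[i + seq_len(n_hidden * n_in)], n_hidden, n_in)
  i <- i + n_hidden * n_in
  Th <- theta[i + seq_len(n_hidden)]; i <- i + n_hidden
  w <- matrix(theta[i + seq_len(n_out * n_hidden)], n_out, n_hidden)
  i <- i + n_out * n_hidden
  To <- theta[i + seq_len(n_out)]
  ann_params(u, Th, w, To)
}

# Residuals (scaled prediction - scaled target), pattern-major ordering.
ann_residuals <- function(params, Xs, Ts) {
  as.vector(t(ann_forward_scaled(params, Xs) - Ts))
}

# Analytic Jacobian of the residual vector w.r.t. pack_params() ordering.
# Row (p-1)*O + o holds d yhat[p, o] / d theta.
ann_jacobian <- function(params, Xs) {
  P <- nrow(Xs); I <- ncol(params$u)
  H <- nrow(params$u); O <- nrow(params$w)
  Hm <- logsig(Xs %*% t(params$u) + matrix(params$Th, P, H, byrow = TRUE))
  Ym <- logsig(Hm %*% t(params$w) + matrix(params$To, P, O, byrow = TRUE))
  J <- matrix(0, P * O, n_params(params))
  iu <- seq_len(H * I); ith <- H * I + seq_len(H)
  iw <- H * I + H + seq_len(O * H); ito <- H * I + H + O * H + seq_len(O)
  for (p in seq_len(P)) {
    x <- Xs[p, ]; h <- Hm[p, ]; dh <- h * (1 - h); dy <- Ym[p, ] * (1 - Ym[p, ])
    for (o in seq_len(O)) {
      row <- (p - 1) * O + o
      wdh <- params$w[o, ] * dh
      J[row, iu] <- dy[o] * as.vector(outer(wdh, x))
      J[row, ith] <- dy[o] * wdh
      J[row, iw[(seq_len(H) - 1) * O + o]] <- dy[o] * h
      J[row, ito[o]] <- dy[o]
    }
  }
  J
}

# One damped normal-equations step: solve (J'J + mu I) step = -J'r.
lm_step <- function(J, r, mu) {
  A <- crossprod(J)
  diag(A) <- diag(A) + mu
  solve(A, -crossprod(J, r))
}

mse_of <- function(params, Xs, Ts) {
  if (nrow(Xs) == 0) return(NA_real_)
  mean((ann_forward_scaled(params, Xs) - Ts)^2)
}

#' Train the extraction surrogate network by Levenberg-Marquardt
#'
#' Fits a single-hidden-layer log-sigmoid network to the responses of a
#' design table. The trainer works in scaled space ([0.05, 0.95] inputs and
#' targets), computes the residual Jacobian analytically per pattern, takes
#' damped normal-equation steps `(J'J + mu I) dtheta = -J'r`, grows the
#' damping after rejected steps and shrinks it after accepted ones, so the
#' training SSE over accepted steps is non-increasing. Patterns are split
#' 70/15/15 into train/validation/test by a seeded shuffle; when a
#' validation split exists, early stopping returns the parameters with the
#' lowest validation error.
#'
#' @param design A design table with responses (see [generate_ccd()] and
#'   [generate_surface_study()]).
#' @param config A [training_config()].
#' @param hidden_n Hidden-layer size (3 to 15 in the study; default 12).
#' @return An object of class `ann_fit`: `params`, `scaling`, `history`
#'   (per-cycle damping and train/validation/test MSE), `split`, `r2`
#'   (per-output and overall R-squared in natural units on each split),
#'   `hidden_n`, `config`.
#' @export
train_lm <- function(design, config = training_config(), hidden_n = 12) {
  X <- design_matrix(design, "natural")
  Y <- response_matrix(design)
  n <- nrow(X)
  if (n < 2 && config$split[1] < 1) stop("need at least one training pattern")

  widen <- function(lo, hi) {       # guard degenerate ranges (single pattern)
    flat <- hi - lo <= 0
    lo[flat] <- lo[flat] - 0.5; hi[flat] <- hi[flat] + 0.5
    list(lo = lo, hi = hi)
  }
  xr <- widen(apply(X, 2, min), apply(X, 2, max))
  yr <- widen(apply(Y, 2, min), apply(Y, 2, max))
  scaling <- ann_scaling(xr$lo, xr$hi, yr$lo, yr$hi)
  Xs <- scale_inputs(scaling, X)
  Ts <- scale_outputs(scaling, Y)

  set.seed(config$seed)
  idx <- sample.int(n)
  n_tr <- max(2, round(config$split[1] * n)); n_tr <- min(n_tr, n)
  if (n == 1) n_tr <- 1
  n_val <- round(config$split[2] * n)
  n_val <- min(n_val, n - n_tr)
  tr <- idx[seq_len(n_tr)]
  val <- if (n_val > 0) idx[n_tr + seq_len(n_val)] else integer(0)
  te <- if (n_tr + n_val < n) idx[(n_tr + n_val + 1):n] else integer(0)

  I <- ncol(X); O <- ncol(Y)
  theta <- stats::runif(hidden_n * I + hidden_n + O * hidden_n + O, -0.5, 0.5)
  params <- unpack_params(theta, I, hidden_n, O)

  r <- ann_residuals(params, Xs[tr, , drop = FALSE], Ts[tr, , drop = FALSE])
  sse <- sum(r^2)
  mu <- config$mu_init
  best_val <- Inf; best_theta <- theta; stall <- 0
  history <- vector("list", config$max_cycles)

  for (cycle in seq_len(config$max_cycles)) {
    J <- ann_jacobian(params, Xs[tr, , drop = FALSE])
    g <- crossprod(J, r)
    if (max(abs(g)) < config$grad_tol) break
    accepted <- FALSE
    while (!accepted) {
      step <- tryCatch(lm_step(J, r, mu), error = function(e) NULL)
      if (is.null(step)) {
        if (mu >= config$mu_max)
          stop("singular normal equations at the damping ceiling; ",
               "training cannot proceed (mu = ", mu, ")")
        mu <- mu * config$mu_increase
        next
      }
      theta_new <- theta + as.vector(step)
      params_new <- unpack_params(theta_new, I, hidden_n, O)
      r_new <- ann_residuals(params_new, Xs[tr, , drop = FALSE],
                             Ts[tr, , drop = FALSE])
      sse_new <- sum(r_new^2)
      if (is.finite(sse_new) && sse_new < sse) {
        accepted <- TRUE
        rel_drop <- (sse - sse_new) / max(sse, .Machine$double.eps)
        theta <- theta_new; params <- params_new; r <- r_new; sse <- sse_new
        mu <- max(mu / config$mu_decrease, 1e-20)
      } else {
        mu <- mu * config$mu_increase
        if (mu > config$mu_max) break
      }
    }
    if (!accepted) break
    val_mse <- mse_of(params, Xs[val, , drop = FALSE], Ts[val, , drop = FALSE])
    history[[cycle]] <- data.frame(
      cycle = cycle, mu = mu, train_sse = sse, train_mse = sse / length(r),
      val_mse = val_mse,
      test_mse = mse_of(params, Xs[te, , drop = FALSE], Ts[te, , drop = FALSE]))
    if (length(val) > 0 && is.finite(config$patience)) {
      if (is.finite(val_mse) && val_mse < best_val) {
        best_val <- val_mse; best_theta <- theta; stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= config$patience) break
      }
    }
    if (rel_drop < config$sse_tol) break
  }

  if (length(val) > 0 && is.finite(config$patience))
    params <- unpack_params(best_theta, I, hidden_n, O)
  history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])

  r2_on <- function(rows) {
    if (length(rows) < 2) return(list(overall = NA_real_, per_output = rep(NA_real_, O)))
    pred <- ann_forward(params, scaling, X[rows, , drop = FALSE])
    obs <- Y[rows, , drop = FALSE]
    per <- vapply(seq_len(O), function(o)
      1 - sum((pred[, o] - obs[, o])^2) / sum((obs[, o] - mean(obs[, o]))^2),
      numeric(1))
    list(overall = 1 - sum((pred - obs)^2) /
           sum(sweep(obs, 2, colMeans(obs))^2),
         per_output = stats::setNames(per, colnames(Y)))
  }

  structure(list(params = params, scaling = scaling, history = history,
                 split = list(train = tr, validation = val, test = te),
                 r2 = list(train = r2_on(tr), validation = r2_on(val),
                           test = r2_on(te)),
                 hidden_n = hidden_n, config = config),
            class = "ann_fit")
}

#' @export
print.ann_fit <- function(x, ...) {
  cat(sprintf("<ann_fit> %d-%d-%d network, %d cycles, train R2 = %.4f\n",
              ncol(x$params$u), x$hidden_n, nrow(x$params$w),
              if (is.null(x$history)) 0L else max(x$history$cycle),
              x$r2$train$overall))
  invisible(x)
}

#' Select the hidden-layer size by validation error
#'
#' Trains one network per candidate size under the same seeded
#' configuration and returns the candidate with the lowest validation MSE;
#' exact ties resolve to the smaller network.
#'
#' @param design Design table with responses.
#' @param config A [training_config()]; its split must leave a non-empty
#'   validation set.
#' @param candidates Integer vector of hidden sizes (study range 3 to 15).
#' @return The selected hidden-layer size (integer).
#' @export
select_hidden_neurons <- function(design, config = training_config(),
                                  candidates = 3:15) {
  if (length(candidates) == 0) stop("candidate list is empty")
  candidates <- sort(unique(as.integer(candidates)))
  val_mse <- vapply(candidates, function(h) {
    fit <- train_lm(design, config, hidden_n = h)
    if (length(fit$split$validation) == 0)
      stop("validation split is empty; cannot select hidden size")
    X <- design_matrix(design, "natural")
    Y <- response_matrix(design)
    rows <- fit$split$validation
    mean((ann_forward(fit$params, fit$scaling, X[rows, , drop = FALSE]) -
            Y[rows, , drop = FALSE])^2)
  }, numeric(1))
  candidates[which.min(val_mse)]
}
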