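# Shared independent oracles and small builders used across test files.

# Central finite-difference Jacobian of the scaled network residuals,
# independent of the analytic derivation in the trainer.
fd_jacobian <- function(params, Xs, h = 1e-6) {
  theta <- uaextract:::pack_params(params)
  I <- ncol(params$u); H <- nrow(params$u); O <- nrow(params$w)
  res_at <- function(th) {
    p <- uaextract:::unpack_params(th, I, H, O)
    as.vector(t(uaextract:::ann_forward_scaled(p, Xs)))
  }
  J <- matrix(0, nrow(Xs) * O, length(theta))
  for (j in seq_along(theta)) {
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    J[, j] <- (res_at(up) - res_at(dn)) / (2 * h)
  }
  J
}

random_net <- function(n_in, n_hidden, n_out, scale = 1) {
  ann_params(u = matrix(stats::runif(n_hidden * n_in, -scale, scale),
                        n_hidden, n_in),
             Th = stats::runif(n_hidden, -scale, scale),
             w = matrix(stats::runif(n_out * n_hidden, -scale, scale),
                        n_out, n_hidden),
             To = stats::runif(n_out, -scale, scale))
}

# Dense-grid oracle for the maximum of the summed-normalized truth fitness
# over the coded design sphere/box (21 levels per factor).
grid_fitness_max <- function(lo, hi, levels = 21) {
  g <- seq(-2, 2, length.out = levels)
  G <- as.matrix(expand.grid(g, g, g, g))
  truth <- default_surface_truth()
  Y <- sapply(names(truth), function(r) eval_surface_truth(truth[[r]], G))
  max(rowSums(sweep(sweep(Y, 2, lo), 2, hi - lo, "/")))
}

truth_fitness_at_coded <- function(xc, lo, hi) {
  truth <- default_surface_truth()
  y <- sapply(names(truth), function(r)
    eval_surface_truth(truth[[r]], matrix(xc, 1)))
  fitness_normalized(y, lo, hi)
}
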