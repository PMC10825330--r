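test_that("the analytic Jacobian matches central finite differences", {
  set.seed(42)
  for (rep in 1:3) {
    p <- random_net(2, 3, 2)
    Xs <- matrix(runif(8, 0.1, 0.9), 4, 2)
    J <- uaextract:::ann_jacobian(p, Xs)
    expect_lt(max(abs(J - fd_jacobian(p, Xs))), 1e-6)
  }
})

test_that("a damped step interpolates between Gauss-Newton and gradient descent", {
  set.seed(9)
  J <- matrix(rnorm(10), 5, 2)
  r <- rnorm(5)
  gn <- solve(crossprod(J), -crossprod(J, r))
  expect_equal(uaextract:::lm_step(J, r, 1e-12), gn, tolerance = 1e-6)
  mu <- 1e12
  sd_dir <- -crossprod(J, r) / mu
  expect_equal(uaextract:::lm_step(J, r, mu), sd_dir, tolerance = 1e-6)
})

test_that("one pattern is fitted exactly", {
  d <- data.frame(run_id = 1, point_class = "center",
                  natural_XP = 250, natural_XT = 50, natural_XS = 25,
                  natural_XC = 60, Y_P = 15, Y_A = 70, Y_B = 45, Y_F = 1.5)
  fit <- train_lm(d, training_config(split = c(1, 0, 0), seed = 1),
                  hidden_n = 1)
  expect_lt(tail(fit$history$train_mse, 1), 1e-8)
})

test_that("training SSE over accepted steps never increases", {
  d <- generate_surface_study(study_spec(seed = 4))
  fit <- train_lm(d, training_config(seed = 4, max_cycles = 100), hidden_n = 6)
  expect_true(all(diff(fit$history$train_sse) <= 0))
})

test_that("a teacher network is recovered in function space", {
  # data generated by a known 2-hidden-unit teacher, fitted with 3 hidden
  # units; weights need not match (permutation/sign symmetry) but the
  # function must
  set.seed(8)
  teacher <- random_net(1, 2, 1, scale = 1.5)
  X <- matrix(seq(100, 300, length.out = 25), ncol = 1)
  sc <- ann_scaling(100, 300, 0, 1)
  Ys <- uaextract:::ann_forward_scaled(teacher, uaextract:::scale_inputs(sc, X))
  Y <- uaextract:::unscale_outputs(sc, Ys)
  d <- data.frame(run_id = 1:25, point_class = "factorial",
                  natural_X1 = X[, 1], Y_P = Y[, 1], Y_A = Y[, 1],
                  Y_B = Y[, 1], Y_F = Y[, 1])
  fit <- train_lm(d, training_config(split = c(1, 0, 0), seed = 2),
                  hidden_n = 3)
  # function-space comparison must be in natural units: the fitted net's
  # output scaling (from the observed response range) differs from the
  # teacher's by an affine map
  grid <- matrix(seq(100, 300, length.out = 101), ncol = 1)
  truth_nat <- uaextract:::unscale_outputs(
    sc, uaextract:::ann_forward_scaled(teacher,
                                       uaextract:::scale_inputs(sc, grid)))
  pred_nat <- ann_forward(fit$params, fit$scaling, grid)
  expect_lt(mean((pred_nat[, 1] - truth_nat[, 1])^2), 1e-6)
})

test_that("the noiseless design surface is fitted to high accuracy", {
  d <- generate_surface_study(study_spec(seed = 1, surface_noise_frac = 0))
  fit <- train_lm(d, training_config(seed = 1), hidden_n = 12)
  expect_gte(fit$r2$train$overall, 0.99)
})

test_that("training is deterministic under a fixed seed", {
  d <- generate_surface_study(study_spec(seed = 3))
  f1 <- train_lm(d, training_config(seed = 5), hidden_n = 4)
  f2 <- train_lm(d, training_config(seed = 5), hidden_n = 4)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$split, f2$split)
})

test_that("hidden-size selection prefers adequately sized networks", {
  expect_equal(select_hidden_neurons(
    generate_surface_study(study_spec(seed = 1)),
    training_config(seed = 1, max_cycles = 50), candidates = 12), 12)
  # a surface from a 4-hidden-unit teacher is underfit by 2 hidden units
  set.seed(14)
  teacher <- random_net(4, 4, 4, scale = 3)
  d <- generate_ccd(default_factors())
  X <- design_matrix(d, "natural")
  sc <- ann_scaling(apply(X, 2, min), apply(X, 2, max), rep(0, 4), rep(1, 4))
  Y <- uaextract:::unscale_outputs(
    sc, uaextract:::ann_forward_scaled(teacher,
                                       uaextract:::scale_inputs(sc, X)))
  d$Y_P <- Y[, 1]; d$Y_A <- Y[, 2]; d$Y_B <- Y[, 3]; d$Y_F <- Y[, 4]
  pick <- select_hidden_neurons(d, training_config(seed = 3), c(2, 4, 8))
  expect_true(pick %in% c(4, 8))
  pick2 <- select_hidden_neurons(d, training_config(seed = 3), c(2, 4, 8))
  expect_identical(pick, pick2)
  expect_error(select_hidden_neurons(d, training_config(), integer(0)),
               "empty")
})

test_that("invalid training configurations are rejected", {
  expect_error(training_config(max_cycles = 0), "max_cycles")
  expect_error(training_config(split = c(0.5, 0.5, 0.5)), "summing to 1")
})
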