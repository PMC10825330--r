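test_that("the rate-law curve starts at zero and saturates at Cs", {
  k <- 0.00556; Cs <- 16.536
  expect_equal(predict_ct(k, Cs, 0), 0)
  # fitted phenolic parameters at 30 deg C predict the 25-min yield
  expect_equal(predict_ct(k, Cs, 25), 11.52282, tolerance = 1e-5)
  t_sat <- 100 / (k * Cs)
  expect_gt(predict_ct(k, Cs, t_sat), 0.99 * Cs)
  expect_error(predict_ct(k, Cs, -1), "negative")
  expect_error(predict_ct(-1, Cs, 1), "positive")
})

test_that("the curve is increasing and concave", {
  t <- seq(0, 50, by = 0.25)
  ct <- predict_ct(0.005, 20, t)
  expect_true(all(diff(ct) > 0))
  expect_true(all(diff(diff(ct)) < 0))
})

test_that("noiseless curves invert to the generating parameters", {
  t <- c(5, 10, 15, 20, 25)
  ct <- predict_ct(0.00556, 16.536, t)
  for (m in c("nls", "linearized")) {
    f <- fit_pso(t, ct, method = m)
    expect_equal(f$k, 0.00556, tolerance = 1e-6)
    expect_equal(f$Cs, 16.536, tolerance = 1e-6)
  }
  # the closed-form linearized solution is the oracle for the iterative fit
  fn <- fit_pso(t, ct, "nls"); fl <- fit_pso(t, ct, "linearized")
  expect_equal(fn$k, fl$k, tolerance = 1e-9)
  expect_equal(fn$Cs, fl$Cs, tolerance = 1e-9)
})

test_that("all sixteen published parameter pairs round-trip through refitting", {
  t5 <- read_fixture("table5_kinetics")
  t <- c(2.5, 5, 10, 15, 20, 25)
  for (i in seq_len(nrow(t5))) {
    f <- fit_pso(t, predict_ct(t5$k[i], t5$Cs[i], t))
    expect_equal(f$k, t5$k[i], tolerance = 1e-6)
    expect_equal(f$Cs, t5$Cs[i], tolerance = 1e-6)
  }
})

test_that("median saturation error stays below 5% under 1% noise", {
  t <- c(2.5, 5, 10, 15, 20, 25)
  truth_k <- 0.00556; truth_Cs <- 16.536
  err <- vapply(1:20, function(s) {
    set.seed(s)
    ct <- pmax(predict_ct(truth_k, truth_Cs, t) +
                 rnorm(length(t), sd = 0.01 * truth_Cs), 1e-6)
    abs(fit_pso(t, ct)$Cs - truth_Cs) / truth_Cs
  }, numeric(1))
  expect_lt(median(err) * 100, 5)
})

test_that("the iterative fit never has larger SSE than the linearized one", {
  t <- c(2.5, 5, 10, 15, 20, 25)
  for (s in 1:5) {
    set.seed(100 + s)
    ct <- pmax(predict_ct(0.005, 20, t) + rnorm(length(t), sd = 0.4), 1e-6)
    sse <- function(f) sum((predict_ct(f$k, f$Cs, t) - ct)^2)
    expect_lte(sse(fit_pso(t, ct, "nls")), sse(fit_pso(t, ct, "linearized")) *
                 (1 + 1e-9))
  }
})

test_that("rescaling concentrations rescales Cs and inversely rescales k", {
  t <- c(2.5, 5, 10, 15, 20, 25)
  ct <- predict_ct(0.004, 50, t)
  a <- 3.7
  f1 <- fit_pso(t, ct); f2 <- fit_pso(t, a * ct)
  expect_equal(f2$Cs, a * f1$Cs, tolerance = 1e-6)
  expect_equal(f2$k, f1$k / a, tolerance = 1e-6)
})

test_that("temperature series fit per temperature and flag non-monotone runs", {
  tc <- generate_kinetics_study(study_spec(seed = 2, kinetic_noise_frac = 0))
  s <- fit_pso_series(tc[tc$response == "YA", ], response = "YA")
  expect_equal(s$coef$temperature_C, c(30, 40, 50, 60))
  expect_true(all(diff(s$coef$k) > 0))
  expect_true(all(diff(s$coef$Cs) > 0))
  one <- tc[tc$response == "YA" & tc$temperature_C == 30, ]
  expect_error(fit_pso_series(one), "at least 2 temperatures")
  # a decreasing-k series warns
  dec <- rbind(
    data.frame(temperature_C = 30, t_min = c(2.5, 5, 10, 15, 20, 25),
               Ct = predict_ct(0.006, 20, c(2.5, 5, 10, 15, 20, 25))),
    data.frame(temperature_C = 40, t_min = c(2.5, 5, 10, 15, 20, 25),
               Ct = predict_ct(0.004, 21, c(2.5, 5, 10, 15, 20, 25))))
  expect_warning(fit_pso_series(dec), "not strictly increasing")
})

test_that("degenerate kinetic inputs are rejected", {
  t <- c(2.5, 5, 10, 15, 20, 25)
  expect_error(fit_pso(t, rep(0, 6)), "zero")
  expect_error(fit_pso(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_pso(c(1, 1, 2), c(1, 2, 3)), "strictly increasing")
  # a mid-series spike far above the plateau leaves the fitted Cs below 80%
  # of the largest observation
  expect_warning(fit_pso(1:6, c(8.3, 9.1, 9.4, 9.5, 22, 9.6)), "80%")
})
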