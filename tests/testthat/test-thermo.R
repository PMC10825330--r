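test_that("Arrhenius regression reproduces the published activation energies", {
  TK <- kelvin(c(30, 40, 50, 60))
  ya <- arrhenius_fit(TK, c(0.233, 0.332, 0.479, 0.564) * 1e-2)
  expect_equal(ya$Ea / 1000, 25.407, tolerance = 0.002)
  yb <- arrhenius_fit(TK, c(0.439, 0.497, 0.603, 0.678) * 1e-2)
  expect_equal(yb$Ea / 1000, 12.556, tolerance = 0.002)
  # temperature-independent rates carry no activation energy
  flat <- arrhenius_fit(TK, rep(0.005, 4))
  expect_equal(flat$Ea, 0, tolerance = 1e-10)
  expect_equal(flat$k0, 0.005, tolerance = 1e-10)
})

test_that("two-point fits interpolate exactly and match the closed form", {
  TK <- c(303, 333); k <- c(0.002, 0.006)
  f <- arrhenius_fit(TK, k)
  # closed form from two points: Ea = R ln(k2/k1) / (1/T1 - 1/T2)
  Ea2 <- GAS_CONSTANT * log(k[2] / k[1]) / (1 / TK[1] - 1 / TK[2])
  expect_equal(f$Ea, Ea2, tolerance = 1e-9)
  expect_lt(max(abs(f$residuals)), 1e-12)
  Ke <- c(2, 9)
  v <- vant_hoff_fit(TK, Ke)
  dH2 <- GAS_CONSTANT * log(Ke[2] / Ke[1]) / (1 / TK[1] - 1 / TK[2])
  expect_equal(v$dH, dH2, tolerance = 1e-9)
  expect_lt(max(abs(v$residuals)), 1e-12)
})

test_that("equilibrium constant follows Cs / (Cmax - Cs)", {
  expect_equal(equilibrium_constant(10, 20), 1)
  expect_equal(equilibrium_constant(16.536, 24.619), 2.045775,
               tolerance = 1e-6)
  cs <- seq(1, 23, by = 1)
  expect_true(all(diff(equilibrium_constant(cs, 24)) > 0))
  expect_error(equilibrium_constant(25, 24), "below Cmax")
  expect_error(equilibrium_constant(0, 24), "positive")
})

test_that("Van't Hoff regression inverts the published Gibbs-energy line", {
  # Ke reconstructed from the printed phenolic Gibbs energies; the printed
  # enthalpy/entropy must come back within rounding of the 3-decimal table
  TK <- kelvin(c(30, 40, 50, 60))
  dG <- c(-1.753, -3.526, -5.300, -7.073) * 1000
  Ke <- exp(-dG / (GAS_CONSTANT * TK))
  v <- vant_hoff_fit(TK, Ke)
  expect_equal(v$dH / 1000, 51.975, tolerance = 0.01)
  expect_equal(v$dS, 177.321, tolerance = 0.05)
  # flat equilibrium: dH = 0, dS = R
  v0 <- vant_hoff_fit(TK, rep(exp(1), 4))
  expect_equal(v0$dH, 0, tolerance = 1e-9)
  expect_equal(v0$dS, GAS_CONSTANT, tolerance = 1e-12)
})

test_that("Gibbs energies follow dH - T dS and the isotherm consistently", {
  expect_equal(gibbs(51975, 177.321, 303) / 1000, -1.753, tolerance = 0.001)
  expect_equal(gibbs(51975, 177.321, 333) / 1000, -7.073, tolerance = 0.001)
  expect_equal(gibbs(0, 0, 300), 0)
  expect_equal(gibbs_from_ke(1, 310), 0)
  expect_equal(gibbs_from_ke(2.006, 303) / 1000, -1.753, tolerance = 0.001)
  expect_equal(gibbs_from_ke(exp(1), 1 / GAS_CONSTANT), -1, tolerance = 1e-12)
  # round trip through the isotherm
  g <- gibbs(51975, 177.321, 313)
  expect_equal(gibbs_from_ke(exp(-g / (GAS_CONSTANT * 313)), 313), g,
               tolerance = 1e-9 * abs(g))
  expect_error(gibbs_from_ke(-1, 300), "positive")
})

test_that("the Biot number is the film-to-diffusion ratio", {
  expect_equal(biot(2.087e-6, 1.5203e-4, 3.187e-11), 9.956, tolerance = 0.001)
  expect_equal(biot(2.087e-6, 0, 3.187e-11), 0)
  expect_equal(biot(2 * 2.087e-6, 1e-4, 3.187e-11),
               2 * biot(2.087e-6, 1e-4, 3.187e-11))
  expect_error(biot(1e-6, 1e-4, 0), "positive")
})

test_that("printed Gibbs energies are collinear with printed dH and dS", {
  t7 <- read_fixture("table7_thermo")
  dg <- gibbs(t7$dH_kJ_mol * 1000, t7$dS_J_mol_K, kelvin(t7$temperature_C))
  expect_lt(max(abs(dg - t7$dG_kJ_mol * 1000)), 1)  # within 1 J/mol
})

test_that("the implied characteristic length is constant across the tables", {
  t6 <- read_fixture("table6_transport")
  t7 <- read_fixture("table7_thermo")
  L <- t7$Bi * t6$De_m2_s / t6$Kt_m_s
  expect_lt(100 * (max(L) - min(L)) / mean(L), 0.5)
  expect_equal(mean(L), 1.52e-4, tolerance = 0.01)
})

test_that("slab diffusivity is recovered from a truncated-series curve", {
  # oracle data: 10-term slab series; the estimator inverts with 1 term
  De_true <- 3e-11; L <- 1.5e-4; Cs <- 10
  t_min <- c(10, 15, 20, 25)
  t_sec <- t_min * 60
  series <- sapply(t_sec, function(tt) {
    n <- 0:9
    1 - sum(8 / pi^2 / (2 * n + 1)^2 *
              exp(-(2 * n + 1)^2 * pi^2 * De_true * tt / (4 * L^2)))
  })
  fake_fit <- structure(list(k = 0.005, Cs = Cs, temperature_C = 30,
                             data = data.frame(t = t_min, Ct = Cs * series)),
                        class = "pso_fit")
  rec <- estimate_transport(fake_fit, L = L)
  expect_equal(rec$De, De_true, tolerance = 0.05)
  expect_identical(rec$Bi, rec$Kt * rec$L / rec$De)
  expect_equal(rec$Kt, (0.005 / 60) * Cs * L)
})

test_that("transport coefficients increase with temperature on Arrhenius data", {
  tc <- generate_kinetics_study(study_spec(seed = 5, kinetic_noise_frac = 0))
  s <- fit_pso_series(tc[tc$response == "YB", ], response = "YB")
  recs <- lapply(s$fits, estimate_transport, L = 1.52e-4)
  De <- vapply(recs, `[[`, numeric(1), "De")
  Kt <- vapply(recs, `[[`, numeric(1), "Kt")
  expect_true(all(diff(De) > 0))
  expect_true(all(diff(Kt) > 0))
})

test_that("transport estimation rejects saturated observations", {
  fake <- structure(list(k = 0.01, Cs = 5, temperature_C = 30,
                         data = data.frame(t = c(5, 10), Ct = c(4, 5.2))),
                    class = "pso_fit")
  expect_error(estimate_transport(fake, L = 1e-4), "saturation")
})
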