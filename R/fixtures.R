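#' Packaged reference tables
#'
#' The package ships plain-text transcriptions of the published study tables:
#' `table1_factors` (factor levels), `table2_ann_weights` (the 112 printed
#' network weights/biases in printed order), `table3_influence` (signed
#' relative influences), `table4_optimum` (optimum-point validation),
#' `table5_kinetics` (pseudo-second-order parameters per response and
#' temperature, rate constants in absolute units), `table6_transport`
#' (diffusion and mass-transfer coefficients) and `table7_thermo`
#' (Biot numbers and thermodynamic parameters). Unicode minus signs were
#' normalized to ASCII at transcription time. Loaders validate dimensions.
#'
#' @param name Fixture name (see Details).
#' @return A `data.frame`.
#' @examples
#' nrow(read_fixture("table5_kinetics"))  # 16
#' @export
read_fixture <- function(name) {
  valid <- c("table1_factors", "table2_ann_weights", "table3_influence",
             "table4_optimum", "table5_kinetics", "table6_transport",
             "table7_thermo")
  name <- match.arg(name, valid)
  path <- system.file("extdata", paste0(name, ".csv"), package = "uaextract",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected_rows <- c(table1_factors = 4L, table2_ann_weights = 112L,
                     table3_influence = 4L, table4_optimum = 4L,
                     table5_kinetics = 16L, table6_transport = 16L,
                     table7_thermo = 16L)
  if (nrow(tab) != expected_rows[[name]])
    stop(sprintf("fixture %s has %d rows, expected %d",
                 name, nrow(tab), expected_rows[[name]]))
  tab
}

#' Consistency report over the packaged reference tables
#'
#' Recomputes every quantity that the packaged tables determine on their own
#' and compares it with the printed value: the Arrhenius activation energies
#' implied by the tabulated rate constants (and the percentage reduction of
#' the phenolic-content value relative to the antioxidant one), the
#' collinearity of the printed Gibbs energies with the printed
#' enthalpy/entropy pairs, the constancy of the characteristic length
#' implied by Bi, De and Kt across all sixteen temperature-response rows,
#' and the optimum-point relative deviations.
#'
#' @return A `data.frame` with one row per check: `check`, `value`,
#'   `expected`, `tolerance`, `pass`.
#' @examples
#' rep <- validate_fixtures()
#' all(rep$pass)
#' @export
validate_fixtures <- function() {
  t5 <- read_fixture("table5_kinetics")
  t7 <- read_fixture("table7_thermo")
  t6 <- read_fixture("table6_transport")
  t4 <- read_fixture("table4_optimum")

  checks <- list()
  add <- function(check, value, expected, tolerance)
    checks[[length(checks) + 1]] <<- data.frame(
      check = check, value = value, expected = expected,
      tolerance = tolerance, pass = abs(value - expected) <= tolerance,
      stringsAsFactors = FALSE)

  ea <- sapply(c("YP", "YA", "YB", "YF"), function(r) {
    rows <- t5[t5$response == r, ]
    arrhenius_fit(kelvin(rows$temperature_C), rows$k)$Ea / 1000
  })
  add("Ea_YA_kJ_mol", ea[["YA"]], 25.407, 0.05)
  add("Ea_YB_kJ_mol", ea[["YB"]], 12.556, 0.05)
  add("Ea_YF_kJ_mol", ea[["YF"]], 12.188, 0.05)
  add("Ea_reduction_YP_vs_YA_pct",
      100 * (ea[["YA"]] - ea[["YP"]]) / ea[["YA"]], 76.521, 0.1)

  dg <- gibbs(t7$dH_kJ_mol * 1000, t7$dS_J_mol_K,
              kelvin(t7$temperature_C)) / 1000
  add("gibbs_collinearity_max_abs_err_kJ_mol",
      max(abs(dg - t7$dG_kJ_mol)), 0, 0.002)

  L <- t7$Bi * t6$De_m2_s / t6$Kt_m_s
  add("implied_length_spread_pct",
      100 * (max(L) - min(L)) / mean(L), 0, 0.5)

  dev <- validate_optimum(t4$experimental, t4$predicted)
  for (i in seq_len(nrow(t4)))
    add(paste0("optimum_deviation_", t4$response[i], "_pct"),
        dev[i], t4$relative_deviation_pct[i], 0.01)

  do.call(rbind, checks)
}
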