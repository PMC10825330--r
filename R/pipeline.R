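write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_json_artifact(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full extraction-modeling pipeline on a synthetic study
#'
#' Executes every stage in study order: generate the designed experiment,
#' train the network surrogate, compute signed input influences, optimize
#' the factors by genetic algorithm over the surrogate, generate and fit
#' the multi-temperature kinetic time courses, run the Arrhenius and
#' Van't Hoff / Gibbs analyses, and estimate the transport numbers. A
#' stage failure stops with the stage name; artifacts written so far are
#' retained. With `outdir` set, each stage's result is written as CSV/JSON
#' together with a provenance record (seed and configuration hash), and a
#' rerun with the same seed reproduces the artifacts byte for byte.
#'
#' @param seed Integer seed for the whole run.
#' @param outdir Optional artifact directory (created if missing).
#' @param spec A [study_spec()] (defaults to the study conditions with
#'   this seed).
#' @param design Optional pre-built design table with responses; when
#'   supplied it replaces the synthetic surface stage.
#' @param hidden_n Hidden-layer size for the surrogate (default 12).
#' @param training A [training_config()].
#' @param ga A [ga_control()].
#' @param L Characteristic length for the transport stage, m.
#' @param geometry Particle geometry for the transport stage.
#' @param trust_region Restrict the GA search to the sphere of coded radius
#'   alpha that the circumscribed design actually covers (default `TRUE`);
#'   outside it the surrogate extrapolates without data support.
#' @return A list with one element per stage: `design`, `ann`,
#'   `influence`, `optimum`, `kinetics`, `arrhenius`, `thermo`,
#'   `transport`, `provenance`.
#' @export
run_pipeline <- function(seed = 1, outdir = NULL, spec = study_spec(seed = seed),
                         design = NULL, hidden_n = 12,
                         training = training_config(seed = seed),
                         ga = ga_control(seed = seed),
                         L = 1.52e-4, geometry = "slab", trust_region = TRUE) {
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(x, name, writer) {
    if (!is.null(outdir)) writer(x, file.path(outdir, name))
    x
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  provenance <- list(seed = seed,
                     config_hash = config_hash(list(
                       spec_seed = spec$seed, hidden_n = hidden_n,
                       training = unclass(training), ga = unclass(ga),
                       L = L, geometry = geometry)))

  design <- stage("design", {
    d <- if (is.null(design)) generate_surface_study(spec) else design
    emit(d, "design.csv", function(x, p)
      utils::write.csv(as.data.frame(x), p, row.names = FALSE))
  })

  ann <- stage("train", {
    fit <- train_lm(design, training, hidden_n = hidden_n)
    emit(list(hidden_n = hidden_n,
              u = apply(fit$params$u, 1, identity, simplify = FALSE),
              Th = fit$params$Th,
              w = apply(fit$params$w, 1, identity, simplify = FALSE),
              To = fit$params$To,
              scaling = unclass(fit$scaling),
              r2 = list(train = fit$r2$train$overall,
                        test = fit$r2$test$overall),
              seed = seed, config_hash = provenance$config_hash),
         "model.json", write_json_artifact)
    fit
  })

  influence <- stage("influence", {
    ri <- relative_influence(ann$params, "olden")
    emit(ri, "influence.csv", function(x, p)
      utils::write.csv(as.data.frame(x), p))
  })

  optimum <- stage("optimize", {
    X <- design_matrix(design, "natural")
    Y <- response_matrix(design)
    lo <- apply(Y, 2, min); hi <- apply(Y, 2, max)
    factors <- attr(design, "factors")
    alpha <- attr(design, "alpha")
    conv <- attr(design, "convention")
    coded_of <- function(x) vapply(seq_along(factors), function(j)
      code_value(factors[[j]], x[j], conv, alpha), numeric(1))
    # circumscribed designs support a sphere of coded radius alpha; outside
    # it the surrogate extrapolates, so the search is confined to it
    fn <- function(x) {
      if (trust_region && sqrt(sum(coded_of(x)^2)) > alpha) return(-Inf)
      fitness_normalized(ann_forward(ann$params, ann$scaling, x), lo, hi)
    }
    res <- ga_optimize(fn, apply(X, 2, min), apply(X, 2, max), ga, init = X)
    pred <- drop(ann_forward(ann$params, ann$scaling, res$best_point))
    out <- list(point = as.list(stats::setNames(res$best_point, colnames(X))),
                predicted_responses = as.list(stats::setNames(pred, colnames(Y))),
                fitness = res$best_fitness,
                n_solutions = nrow(res$solution_set),
                seed = seed, config_hash = provenance$config_hash)
    emit(out, "optimum.json", write_json_artifact)
    c(res, list(predicted_responses = pred))
  })

  kinetics <- stage("kinetics", {
    tc <- generate_kinetics_study(spec)
    fits <- lapply(response_names, function(r)
      fit_pso_series(tc[tc$response == r, ], response = r))
    names(fits) <- response_names
    emit(list(
      series = lapply(fits, function(s) as.list(s$coef)),
      seed = seed, config_hash = provenance$config_hash),
      "kinetics.json", write_json_artifact)
    list(data = tc, fits = fits)
  })

  arrhenius <- stage("arrhenius", {
    out <- lapply(kinetics$fits, function(s)
      arrhenius_fit(kelvin(s$coef$temperature_C), s$coef$k))
    emit(list(Ea_J_mol = lapply(out, `[[`, "Ea"),
              k0 = lapply(out, `[[`, "k0"),
              seed = seed, config_hash = provenance$config_hash),
         "arrhenius.json", write_json_artifact)
    out
  })

  thermo <- stage("thermo", {
    out <- lapply(response_names, function(r) {
      s <- kinetics$fits[[r]]$coef
      TK <- kelvin(s$temperature_C)
      # noise can push a fitted Cs to (or past) Cmax; cap just below it so
      # the equilibrium constant stays defined
      Ke <- equilibrium_constant(pmin(s$Cs, spec$kinetics[[r]]$Cmax * 0.999),
                                 spec$kinetics[[r]]$Cmax)
      vh <- vant_hoff_fit(TK, Ke)
      list(response = r, Ke = Ke, dH_J_mol = vh$dH, dS_J_mol_K = vh$dS,
           dG_J_mol = gibbs(vh$dH, vh$dS, TK), temperature_K = TK)
    })
    names(out) <- response_names
    emit(c(out, list(seed = seed, config_hash = provenance$config_hash)),
         "thermo.json", write_json_artifact)
    out
  })

  transport <- stage("transport", {
    out <- lapply(response_names, function(r) {
      lapply(kinetics$fits[[r]]$fits, function(f)
        estimate_transport(f, L = L, geometry = geometry))
    })
    names(out) <- response_names
    emit(list(records = lapply(out, function(recs)
      lapply(recs, function(x) unclass(x))),
      seed = seed, config_hash = provenance$config_hash),
      "transport.json", write_json_artifact)
    out
  })

  if (!is.null(outdir))
    write_json_artifact(provenance, file.path(outdir, "provenance.json"))

  list(design = design, ann = ann, influence = influence, optimum = optimum,
       kinetics = kinetics, arrhenius = arrhenius, thermo = thermo,
       transport = transport, provenance = provenance)
}
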