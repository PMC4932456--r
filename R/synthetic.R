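#' Measurement-noise model for simulated densitometry
#'
#' @param kind `"multiplicative-lognormal"` (default; the error of
#'   chemiluminescent band quantification grows with signal) or
#'   `"additive-gaussian"`.  The multiplicative factors have unit mean
#'   (log-scale mean -sigma^2/2), so the noise is unbiased; additive noise
#'   is clipped at zero.
#' @param sigma Noise scale: dimensionless coefficient of variation for the
#'   multiplicative kind, intensity units for the additive kind.  `sigma =
#'   0` reproduces the noiseless trajectory exactly.
#' @param seed Integer seed for reproducible draws (`NULL` draws from the
#'   caller's RNG stream).
#' @return An object of class `noise_model`.
#' @examples
#' noise_model(sigma = 0.05, seed = 7)
#' @export
noise_model <- function(kind = c("multiplicative-lognormal",
                                 "additive-gaussian"),
                        sigma = 0.05, seed = NULL) {
  kind <- match.arg(kind)
  sigma <- check_scalar(sigma, "sigma")
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("'seed' must be a single integer or NULL", call. = FALSE)
    }
    seed <- as.integer(seed)
  }
  structure(list(kind = kind, sigma = sigma, seed = seed),
            class = "noise_model")
}

#' Simulation scenario for a CHX chase
#'
#' Binds a kinetic parameter set, initial band abundances, a sampling grid
#' and a noise model into a named, reproducible simulation scenario.
#'
#' @param name Scenario label.
#' @param params A [rate_parameters()] object.
#' @param init An [initial_state()] object.
#' @param times Sampling grid in minutes (default 0 to 100 at 20-min
#'   intervals, the usual chase design).
#' @param noise A [noise_model()].
#' @param model `"sequential"` or `"branched"`; a sequential scenario must
#'   have `k_pb = 0`.
#' @return An object of class `scenario_spec`.
#' @seealso [chase_scenarios()] for the built-in strain panel.
#' @examples
#' scenario_spec("custom", rate_parameters(0.1, 0.02, 0.03),
#'               initial_state(0.05, 1, 0.4))
#' @export
scenario_spec <- function(name = "custom", params, init,
                          times = seq(0, 100, by = 20),
                          noise = noise_model(), model = c("sequential",
                                                           "branched")) {
  model <- match.arg(model)
  if (!inherits(params, "rate_parameters")) {
    stop("'params' must be a rate_parameters object", call. = FALSE)
  }
  if (!inherits(init, "initial_state")) {
    stop("'init' must be an initial_state object", call. = FALSE)
  }
  if (!inherits(noise, "noise_model")) {
    stop("'noise' must be a noise_model object", call. = FALSE)
  }
  if (model == "sequential" && params$k_pb != 0) {
    stop("a sequential scenario must have k_pb = 0", call. = FALSE)
  }
  structure(list(name = as.character(name)[1L], params = params,
                 init = init, times = check_times(times), noise = noise,
                 model = model),
            class = "scenario_spec")
}

#' Built-in strain scenarios
#'
#' The panel of named simulation scenarios used throughout the package:
#' wild-type and the protease-mutant strains, each carrying its published
#' A-to-B conversion and B-degradation rate constants.  The precursor
#' cleavage rate is not measurable from the faint PP band and defaults to
#' k_pa = 0.1/min, fast enough that the precursor vanishes within the first
#' sampling interval.  The `yme1` scenario uses the branched model (direct
#' precursor-to-B cleavage at k_pb = k_pa/2) with an elevated initial
#' precursor level (P0 = 0.5), reflecting the precursor accumulation seen
#' in that mutant; all other scenarios are sequential with initial state
#' P0 = 0.05, A0 = 1, B0 = 0.4.
#'
#' @param times Sampling grid (minutes).
#' @param sigma,kind Noise scale and kind passed to [noise_model()]; the
#'   per-scenario seeds are left unset (supply them via [generate_panel()]
#'   or by editing the returned specs).
#' @return A named list of [scenario_spec()] objects.
#' @examples
#' names(chase_scenarios())
#' chase_scenarios()[["wild-type"]]$params$k_ab
#' @export
chase_scenarios <- function(times = seq(0, 100, by = 20), sigma = 0.05,
                            kind = "multiplicative-lognormal") {
  nm <- function() noise_model(kind, sigma, seed = NULL)
  std_init <- initial_state(P0 = 0.05, A0 = 1, B0 = 0.4)
  list(
    `wild-type` = scenario_spec(
      "wild-type", rate_parameters(0.1, 0.0189, 0.0287), std_init,
      times, nm(), "sequential"),
    yta10 = scenario_spec(
      "yta10", rate_parameters(0.1, 0.00575, 0.0437), std_init,
      times, nm(), "sequential"),
    yme1 = scenario_spec(
      "yme1", rate_parameters(0.1, 0.00599, 0.00979, k_pb = 0.05),
      initial_state(P0 = 0.5, A0 = 1, B0 = 0.4), times, nm(), "branched"),
    mcx1 = scenario_spec(
      "mcx1", rate_parameters(0.1, 0.00503, 0.00679), std_init,
      times, nm(), "sequential"),
    `yme1-MPP-overexpression` = scenario_spec(
      "yme1-MPP-overexpression", rate_parameters(0.1, 0.00161, 0.0231),
      std_init, times, nm(), "sequential")
  )
}

#' Simulate a CHX-chase densitometry time course
#'
#' Evaluates the scenario's kinetic model at the sampling grid and corrupts
#' each band intensity independently with the scenario's noise model, using
#' a seeded generator so that the same scenario and seed give bit-identical
#' tables.  The output is raw (unnormalized) and includes the precursor
#' band.
#'
#' @param spec A [scenario_spec()].
#' @return An unnormalized [timecourse()] with bands PP, A, B.
#' @examples
#' sc <- chase_scenarios(sigma = 0.05)[["wild-type"]]
#' sc$noise$seed <- 11
#' simulate_chase(sc)
#' @export
simulate_chase <- function(spec) {
  if (!inherits(spec, "scenario_spec")) {
    stop("'spec' must be a scenario_spec object", call. = FALSE)
  }
  traj <- if (spec$model == "branched") {
    solve_matrix_exponential(build_network(spec$params), spec$init,
                             spec$times)
  } else {
    solve_full_sequential(spec$params, spec$init, spec$times)
  }
  # guard against -1e-17-type round-off from the matrix-exponential path
  raw <- pmax(cbind(PP = traj$P, A = traj$A, B = traj$B), 0)
  nz <- spec$noise
  if (nz$sigma > 0) {
    raw <- eval_with_seed(nz$seed, function() {
      eps <- matrix(rnorm(length(raw)), nrow(raw))
      if (nz$kind == "multiplicative-lognormal") {
        raw * exp(nz$sigma * eps - nz$sigma^2 / 2)
      } else {
        pmax(raw + nz$sigma * eps, 0)
      }
    })
  }
  timecourse(spec$times, A = raw[, "A"], B = raw[, "B"], PP = raw[, "PP"],
             normalized = FALSE)
}

#' Simulate the whole strain panel
#'
#' Draws one chase per built-in scenario (see [chase_scenarios()]) with
#' per-scenario seeds derived deterministically from `seed`, and returns the
#' time courses together with a machine-readable record of the generating
#' truth for recovery tests.  Optionally writes the tables (TSV) and the
#' truth record (JSON) to a fixtures directory.
#'
#' @param seed Integer master seed.
#' @param dir Optional directory to write `<scenario>.tsv` files and
#'   `truth.json` into (created if needed).
#' @param sigma,kind Noise scale and kind for every scenario.
#' @param times Sampling grid (minutes).
#' @return (Invisibly) a list with `timecourses` (named list of
#'   [timecourse()] objects), `truth` (named list of generating parameters)
#'   and `dir`.
#' @examples
#' panel <- generate_panel(seed = 1, sigma = 0)
#' panel$truth[["wild-type"]]$params$k_ab
#' @export
generate_panel <- function(seed, dir = NULL, sigma = 0.05,
                           kind = "multiplicative-lognormal",
                           times = seq(0, 100, by = 20)) {
  scens <- chase_scenarios(times = times, sigma = sigma, kind = kind)
  seeds <- eval_with_seed(seed, function() {
    sample.int(.Machine$integer.max, length(scens))
  })
  tcs <- list()
  truth <- list()
  for (i in seq_along(scens)) {
    sp <- scens[[i]]
    sp$noise$seed <- seeds[[i]]
    key <- names(scens)[[i]]
    tcs[[key]] <- simulate_chase(sp)
    truth[[key]] <- list(
      model = sp$model,
      params = lapply(unclass(sp$params), as.numeric),
      init = lapply(unclass(sp$init), as.numeric),
      times = sp$times,
      noise = list(kind = sp$noise$kind, sigma = sp$noise$sigma,
                   seed = seeds[[i]])
    )
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (key in names(tcs)) {
      write_timecourse(tcs[[key]], file.path(dir, paste0(key, ".tsv")))
    }
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(timecourses = tcs, truth = truth, dir = dir))
}

#' Parameter-recovery experiment
#'
#' Simulates `n_reps` chases from a scenario, fits each with the scenario's
#' own model ([fit_sequential()] or [fit_branched()]) after normalization,
#' and summarizes how well the generating rate constants are recovered.
#' Replicates whose fit errors out or fails to converge are excluded and
#' counted.
#'
#' @param spec A [scenario_spec()].
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer master seed; per-replicate seeds are derived from it.
#' @param fit_bands Bands entering the objective.  The default (A and B)
#'   mirrors fitting real blots whose precursor band is too faint to
#'   quantify; include `"PP"` to fit the full solution against the
#'   simulated precursor band as well.
#' @return A data frame of class `recovery_summary` with one row per
#'   recovered rate (k_ab, k_bx; plus k_pa, k_pb for a branched scenario)
#'   and columns `true`, `median_estimate`, `median_rel_error` (median
#'   absolute relative error), `bias`, `rmse`; attributes `n_reps` and
#'   `n_failed`.
#' @examples
#' sc <- chase_scenarios(sigma = 0.05)[["wild-type"]]
#' recovery_experiment(sc, n_reps = 5, seed = 1)
#' @export
recovery_experiment <- function(spec, n_reps, seed,
                                fit_bands = c("A", "B")) {
  if (!inherits(spec, "scenario_spec")) {
    stop("'spec' must be a scenario_spec object", call. = FALSE)
  }
  n_reps <- as.integer(check_scalar(n_reps, "n_reps", min = 1))
  seeds <- eval_with_seed(seed, function() {
    sample.int(.Machine$integer.max, n_reps)
  })
  want <- if (spec$model == "branched") {
    c("k_pa", "k_pb", "k_ab", "k_bx")
  } else if ("PP" %in% fit_bands) {
    c("k_pa", "k_ab", "k_bx")
  } else {
    c("k_ab", "k_bx")
  }
  est <- matrix(NA_real_, n_reps, length(want),
                dimnames = list(NULL, want))
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    sp <- spec
    sp$noise$seed <- seeds[[r]]
    fit <- tryCatch({
      tc <- normalize_to_reference(simulate_chase(sp))
      f <- suppressWarnings(
        if (spec$model == "branched") fit_branched(tc, fit_bands = fit_bands)
        else fit_sequential(tc, fit_bands = fit_bands))
      if (!f$converged) stop("fit did not converge")
      f
    }, error = function(e) NULL)
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    est[r, ] <- unlist(fit$params[want])
  }
  true <- unlist(spec$params[want])
  err <- sweep(est, 2L, true)
  rel <- sweep(err, 2L, true, "/")
  out <- data.frame(
    parameter = want,
    true = as.numeric(true),
    median_estimate = apply(est, 2L, median, na.rm = TRUE),
    median_rel_error = apply(abs(rel), 2L, median, na.rm = TRUE),
    bias = colMeans(err, na.rm = TRUE),
    rmse = sqrt(colMeans(err^2, na.rm = TRUE)),
    row.names = NULL
  )
  structure(out, class = c("recovery_summary", "data.frame"),
            n_reps = n_reps, n_failed = n_failed)
}

#' Model-selection experiment
#'
#' Simulates `n_reps` chases from a scenario and runs [compare_models()] on
#' each, recording which model the criterion selects.  Used to check that
#' sequential-generated data elect the sequential model and
#' branched-generated data the branched model.
#'
#' @inheritParams recovery_experiment
#' @param criterion Passed to [compare_models()].
#' @param fit_bands Passed to [compare_models()].
#' @return A list of class `selection_experiment` with the per-replicate
#'   `selected` labels, a `counts` table and the fractions selecting each
#'   model (errors and inconclusive comparisons count against both).
#' @examples
#' sc <- chase_scenarios(sigma = 0.05)[["wild-type"]]
#' selection_experiment(sc, n_reps = 3, seed = 1)$fraction_sequential
#' @export
selection_experiment <- function(spec, n_reps, seed,
                                 criterion = c("aicc", "aic", "bic"),
                                 fit_bands = NULL) {
  if (!inherits(spec, "scenario_spec")) {
    stop("'spec' must be a scenario_spec object", call. = FALSE)
  }
  criterion <- match.arg(criterion)
  n_reps <- as.integer(check_scalar(n_reps, "n_reps", min = 1))
  seeds <- eval_with_seed(seed, function() {
    sample.int(.Machine$integer.max, n_reps)
  })
  sel <- character(n_reps)
  for (r in seq_len(n_reps)) {
    sp <- spec
    sp$noise$seed <- seeds[[r]]
    cmp <- tryCatch(
      suppressWarnings(compare_models(normalize_to_reference(
        simulate_chase(sp)), criterion = criterion, fit_bands = fit_bands)),
      error = function(e) NULL)
    sel[r] <- if (is.null(cmp)) {
      "error"
    } else if (cmp$inconclusive) {
      "inconclusive"
    } else {
      cmp$selected
    }
  }
  structure(
    list(selected = sel,
         counts = table(factor(sel, levels = c("sequential", "branched",
                                               "inconclusive", "error"))),
         fraction_sequential = mean(sel == "sequential"),
         fraction_branched = mean(sel == "branched"),
         n_reps = n_reps, criterion = criterion),
    class = "selection_experiment"
  )
}

#' @export
print.selection_experiment <- function(x, ...) {
  cat(sprintf("<selection_experiment: %d replicates, criterion %s>\n",
              x$n_reps, x$criterion))
  print(x$counts)
  invisible(x)
}
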