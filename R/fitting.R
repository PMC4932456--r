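.band_species <- c(PP = "P", A = "A", B = "B")

#' Chase time course of band intensities
#'
#' Container for a quantified CHX-chase experiment: band intensities (A-form
#' and B-form required, precursor PP optional) at a strictly increasing grid
#' of chase times.  The first time point defines t0.
#'
#' @param times Chase times in minutes, strictly increasing.
#' @param A,B Band intensities (>= 0), one value per time point.
#' @param PP Optional precursor-band intensities.
#' @param normalized Whether the intensities are already normalized to the
#'   A-form intensity at t0 (see [normalize_to_reference()]).
#' @return A data frame of class `timecourse` with a `normalized` attribute.
#' @examples
#' timecourse(seq(0, 100, 20), A = exp(-0.0189 * seq(0, 100, 20)),
#'            B = rep(0.4, 6))
#' @export
timecourse <- function(times, A, B, PP = NULL, normalized = FALSE) {
  times <- check_times(times)
  n <- length(times)
  check_band <- function(x, nm) {
    if (!is.numeric(x) || length(x) != n || any(!is.finite(x)) || any(x < 0)) {
      stop(sprintf(
        "band '%s' must hold %d finite non-negative intensities", nm, n),
        call. = FALSE)
    }
    as.numeric(x)
  }
  df <- data.frame(time = times)
  if (!is.null(PP)) df$PP <- check_band(PP, "PP")
  df$A <- check_band(A, "A")
  df$B <- check_band(B, "B")
  structure(df, class = c("timecourse", "data.frame"),
            normalized = isTRUE(normalized))
}

#' @export
#' @rdname timecourse
is_normalized <- function(tc) isTRUE(attr(tc, "normalized"))

tc_bands <- function(tc) intersect(c("PP", "A", "B"), names(tc))

#' Normalize a time course to the A-form intensity at t0
#'
#' Divides every band at every time by the A-form intensity at the first
#' time point, the standard normalization for chase densitometry.  After
#' normalization A(t0) = 1 by construction.
#'
#' @param tc A [timecourse()].
#' @return The normalized `timecourse` (attribute `normalized` set).
#' @examples
#' tc <- timecourse(c(0, 40), A = c(2, 1), B = c(0.8, 0.8))
#' normalize_to_reference(tc)
#' @export
normalize_to_reference <- function(tc) {
  if (!inherits(tc, "timecourse")) {
    stop("'tc' must be a timecourse object", call. = FALSE)
  }
  ref <- tc$A[1L]
  if (!is.finite(ref) || ref <= 0) {
    stop("cannot normalize: the A-band intensity at t0 must be > 0",
         call. = FALSE)
  }
  for (b in tc_bands(tc)) tc[[b]] <- tc[[b]] / ref
  attr(tc, "normalized") <- TRUE
  tc
}

# evaluate the model curves for the fitted bands at the data's time grid;
# uses the unvalidated core solvers (this sits inside the optimizer loop)
model_band_matrix <- function(model, p, times, bands) {
  m <- switch(
    model,
    "sequential-simplified" = core_simplified(
      p[["k_ab"]], p[["k_bx"]], p[["A0"]], p[["B0"]], times),
    "sequential-full" = core_sequential(
      p[["k_pa"]], p[["k_ab"]], p[["k_bx"]],
      p[["P0"]], p[["A0"]], p[["B0"]], times),
    "branched" = core_branched(
      p[["k_pa"]], p[["k_pb"]], p[["k_ab"]], p[["k_bx"]],
      p[["P0"]], p[["A0"]], p[["B0"]], times),
    stop("unknown model: ", model, call. = FALSE)
  )
  m[, .band_species[bands], drop = FALSE]
}

check_fit_input <- function(tc, fit_bands, min_points) {
  if (!inherits(tc, "timecourse")) {
    stop("'tc' must be a timecourse object", call. = FALSE)
  }
  if (!is_normalized(tc)) {
    stop("fitting requires a normalized time course; ",
         "call normalize_to_reference() first", call. = FALSE)
  }
  bad <- setdiff(fit_bands, c("PP", "A", "B"))
  if (length(bad)) {
    stop("unknown band(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  missing_bands <- setdiff(fit_bands, names(tc))
  if (length(missing_bands)) {
    stop("band(s) not present in the time course: ",
         paste(missing_bands, collapse = ", "), call. = FALSE)
  }
  if (nrow(tc) < min_points) {
    stop(sprintf("at least %d time points are required", min_points),
         call. = FALSE)
  }
  tc
}

# deterministic multistart design: when no guess is supplied the free rates
# start on a 5-point log grid over [1e-4, 0.1] 1/min, staggered per rate
# (precursor cleavage faster than the downstream steps) so that no start
# sits on a degenerate equal-rates configuration; initial abundances start
# at the observed t0 intensities
.start_stagger <- c(k_pa = 3, k_pb = 0.5, k_ab = 1, k_bx = 1.7)

build_starts <- function(free, tc, guesses) {
  init_start <- c(P0 = if ("PP" %in% names(tc)) tc$PP[1L] else 0.1,
                  A0 = tc$A[1L], B0 = tc$B[1L])
  rate_names <- intersect(free, c("k_pa", "k_pb", "k_ab", "k_bx"))
  ab_names <- intersect(free, c("P0", "A0", "B0"))
  if (!is.null(guesses)) {
    if (!inherits(guesses, "rate_parameters")) {
      stop("'guesses' must be a rate_parameters object", call. = FALSE)
    }
    return(list(c(unlist(guesses[rate_names]), init_start[ab_names])))
  }
  lapply(10^seq(-4, -1, length.out = 5L), function(g) {
    c(g * .start_stagger[rate_names], init_start[ab_names])
  })
}

new_chase_fit <- function(model, est, fixed, rss, converged, n_obs,
                          fit_bands, info) {
  p <- modifyList(fixed, as.list(est))
  structure(
    list(model = model,
         params = rate_parameters(p$k_pa, p$k_ab, p$k_bx, p$k_pb),
         init = initial_state(p$P0, p$A0, p$B0),
         estimates = est,
         rss = rss,
         half_lives = c(tau_A = log(2) / p$k_ab, tau_B = log(2) / p$k_bx),
         converged = converged,
         n_obs = n_obs,
         n_free = length(est),
         fit_bands = fit_bands,
         optim_info = info),
    class = "chase_fit"
  )
}

# core bounded least-squares engine shared by the sequential and branched
# fits; ties between starts are broken by first-found.  Parameters listed
# in prefer_zero are set to 0 after optimization when that costs nothing
# (relative rss increase <= 1e-9): when the fitted precursor pool P0 is
# (near) zero the branch rate k_pb is unidentifiable and the optimizer
# would otherwise report an arbitrary stranded value for it.
ls_fit_engine <- function(tc, model, free, fixed, fit_bands, starts,
                          prefer_zero = NULL) {
  obs <- as.matrix(as.data.frame(tc)[, fit_bands, drop = FALSE])
  if (all(obs == 0)) {
    stop("degenerate data: all fitted intensities are zero", call. = FALSE)
  }
  n_obs <- length(obs)
  if (n_obs < length(free) + 1L) {
    stop(sprintf(
      "under-determined fit: %d data points for %d free parameters",
      n_obs, length(free)), call. = FALSE)
  }
  scale_max <- max(as.matrix(as.data.frame(tc)[, tc_bands(tc)]))
  lower <- setNames(rep(0, length(free)), free)
  upper <- setNames(ifelse(free %in% c("k_pa", "k_pb", "k_ab", "k_bx"),
                           1, 10 * scale_max), free)
  times <- tc$time
  fn <- function(par) {
    p <- setNames(pmin(pmax(par, lower), upper), free)
    suppressMessages(
      as.vector(model_band_matrix(model, p, times, fit_bands) - obs))
  }
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s[free], lower), upper)
    res <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper, fn = fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) {
    stop("least-squares optimization failed from every start", call. = FALSE)
  }
  est <- setNames(as.numeric(best$par), free)
  rss <- best$deviance
  for (nm in intersect(prefer_zero, free)) {
    cand <- est
    cand[nm] <- 0
    rss_cand <- sum(fn(cand)^2)
    if (rss_cand <= rss + max(1e-12, 1e-9 * rss)) {
      est <- cand
      rss <- rss_cand
    }
  }
  rate_free <- intersect(free, c("k_pa", "k_pb", "k_ab", "k_bx"))
  at_bound <- est[rate_free] > upper[rate_free] - 1e-6
  if (any(at_bound)) {
    warning("rate estimate(s) at the upper bound: ",
            paste(rate_free[at_bound], collapse = ", "), call. = FALSE)
  }
  converged <- best$info %in% c(1L, 2L, 3L, 4L, 6L, 7L, 8L)
  new_chase_fit(model, est, fixed, rss, converged, n_obs,
                fit_bands, best$info)
}

#' Fit the sequential processing model to a chase time course
#'
#' Estimates the rate constants of the sequential cleavage/degradation model
#' by bounded nonlinear least squares (Levenberg-Marquardt, multistart) on
#' the normalized band intensities.  With the default bands (A and B) the
#' precursor is neglected and the simplified two-species solution is fitted
#' with free parameters k_ab, k_bx, A0, B0.  Including `"PP"` in
#' `fit_bands` (or setting `full = TRUE`) switches to the full
#' three-species solution with k_pa and P0 additionally free; `full = TRUE`
#' without the PP band estimates the precursor contribution from its
#' imprint on the A- and B-band curves alone.
#'
#' Rates are constrained to [0, 1] per minute and initial abundances to
#' [0, 10 x max intensity].  When no starting guess is supplied, five
#' deterministic starts spanning 1e-4 to 0.1 per minute (log-spaced) are
#' tried and the best residual sum of squares wins.
#'
#' @param tc A normalized [timecourse()] with at least 4 time points.
#' @param guesses Optional [rate_parameters()] used as the single starting
#'   point instead of the multistart grid.
#' @param fit_bands Which bands enter the objective (subset of
#'   `c("PP","A","B")`; default A and B).
#' @param full Fit the full sequential solution (precursor tracked, k_pa
#'   and P0 free) instead of the simplified one; implied by including
#'   `"PP"` in `fit_bands`.
#' @return An object of class `chase_fit` with elements `model`, `params`,
#'   `init`, `estimates`, `rss`, `half_lives` (tau_A = ln2/k_ab, tau_B =
#'   ln2/k_bx, minutes), `converged`, `n_obs`.
#' @examples
#' tc <- simulate_chase(chase_scenarios(sigma = 0)[["wild-type"]])
#' fit <- fit_sequential(normalize_to_reference(tc))
#' fit$half_lives
#' @export
fit_sequential <- function(tc, guesses = NULL, fit_bands = c("A", "B"),
                           full = "PP" %in% fit_bands) {
  tc <- check_fit_input(tc, fit_bands, min_points = 4L)
  use_full <- isTRUE(full) || "PP" %in% fit_bands
  model <- if (use_full) "sequential-full" else "sequential-simplified"
  free <- if (use_full) c("k_pa", "k_ab", "k_bx", "P0", "A0", "B0")
          else c("k_ab", "k_bx", "A0", "B0")
  fixed <- list(k_pa = 0, k_pb = 0, P0 = 0)
  starts <- build_starts(free, tc, guesses)
  ls_fit_engine(tc, model, free, fixed, fit_bands, starts)
}

#' Fit the branched processing model to a chase time course
#'
#' Like [fit_sequential()], but for the branched network in which part of
#' the precursor is converted directly to the B-form (rate k_pb) in addition
#' to the sequential route.  Trajectories come from
#' [solve_matrix_exponential()] on the branched network; the free parameters
#' are k_pa, k_pb, k_ab, k_bx, P0, A0, B0.  The precursor abundance P0 is
#' estimated as a free parameter, so the PP band need not be quantified
#' (include `"PP"` in `fit_bands` if it is).
#'
#' @inheritParams fit_sequential
#' @param tc A normalized [timecourse()] with at least 5 time points.
#' @return A `chase_fit` object (see [fit_sequential()]).
#' @examples
#' tc <- simulate_chase(chase_scenarios(sigma = 0)[["yme1"]])
#' fit <- fit_branched(normalize_to_reference(tc))
#' fit$params$k_pb
#' @export
fit_branched <- function(tc, guesses = NULL, fit_bands = c("A", "B")) {
  fit_branched_impl(tc, guesses, fit_bands, extra_starts = NULL)
}

fit_branched_impl <- function(tc, guesses, fit_bands, extra_starts) {
  tc <- check_fit_input(tc, fit_bands, min_points = 5L)
  free <- c("k_pa", "k_pb", "k_ab", "k_bx", "P0", "A0", "B0")
  starts <- c(build_starts(free, tc, guesses), extra_starts)
  ls_fit_engine(tc, "branched", free, list(), fit_bands, starts,
                prefer_zero = "k_pb")
}

# Gaussian-error information criteria computed from the residual sum of
# squares; k counts the free parameters plus the error variance
information_criterion <- function(kind, n, k, rss) {
  ll_term <- n * log(rss / n)
  switch(kind,
         aic = ll_term + 2 * k,
         bic = ll_term + log(n) * k,
         aicc = ll_term +
           if (n - k - 1L > 0L) 2 * k + 2 * k * (k + 1) / (n - k - 1L)
           else Inf,
         stop("unknown criterion: ", kind, call. = FALSE))
}

#' Discriminate between the sequential and branched processing models
#'
#' Fits both models to the same normalized time course and selects between
#' them with an information criterion computed from the residual sum of
#' squares under a Gaussian error model.  The sequential side is the full
#' sequential solution (precursor tracked, P0 free), so the two candidates
#' differ only in the direct precursor-to-B edge k_pb and the comparison
#' asks precisely whether that extra route is supported.  The models are
#' nested (the sequential model is the branched model with k_pb = 0), so
#' the branched fit is seeded with the sequential optimum embedded at
#' k_pb = 0, which guarantees branched rss <= sequential rss; ties and
#' equally-supported fits go to the more parsimonious sequential model.
#'
#' The residual sum of squares is floored at n (1e-8 x max intensity)^2
#' before taking logs so that an exact (noise-free) fit by both models is
#' decided by the parsimony penalty rather than by floating-point noise.
#'
#' The two models predict nearly identical A- and B-band curves unless the
#' precursor is pinned down, so by default the comparison fits every band
#' present in the time course, including PP when it was quantified;
#' without the PP band a large, slowly cleaved phantom precursor pool can
#' mimic the branched route and the comparison loses most of its power.
#'
#' @param tc A normalized [timecourse()] suitable for both fits.
#' @param criterion `"aicc"` (default), `"aic"` or `"bic"`.
#' @param fit_bands Bands entering both objectives; `NULL` (default) uses
#'   every band present in `tc`.
#' @return An object of class `model_comparison` with both `chase_fit`
#'   objects, the per-model criterion values, the `selected` model label
#'   (`NA` when either fit failed to converge, flagged `inconclusive`).
#' @examples
#' tc <- simulate_chase(chase_scenarios(sigma = 0)[["yme1"]])
#' cmp <- compare_models(normalize_to_reference(tc))
#' cmp$selected
#' @export
compare_models <- function(tc, criterion = c("aicc", "aic", "bic"),
                           fit_bands = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(fit_bands)) fit_bands <- tc_bands(tc)
  seq_fit <- fit_sequential(tc, fit_bands = fit_bands, full = TRUE)
  embed <- c(k_pa = seq_fit$params$k_pa,
             k_pb = 0,
             k_ab = seq_fit$params$k_ab,
             k_bx = seq_fit$params$k_bx,
             P0 = seq_fit$init$P0,
             A0 = seq_fit$init$A0,
             B0 = seq_fit$init$B0)
  br_fit <- fit_branched_impl(tc, NULL, fit_bands,
                              extra_starts = list(embed))
  if (br_fit$rss > seq_fit$rss) {
    # the nested optimum can never be worse; keep the embedded solution
    br_fit <- new_chase_fit("branched", embed, list(), seq_fit$rss,
                            seq_fit$converged, seq_fit$n_obs, fit_bands,
                            seq_fit$optim_info)
  }
  obs <- as.matrix(as.data.frame(tc)[, fit_bands, drop = FALSE])
  floor_rss <- length(obs) * (1e-8 * max(abs(obs)))^2
  ic <- function(fit) {
    information_criterion(criterion, fit$n_obs, fit$n_free + 1L,
                          max(fit$rss, floor_rss))
  }
  vals <- c(sequential = ic(seq_fit), branched = ic(br_fit))
  inconclusive <- !(seq_fit$converged && br_fit$converged)
  selected <- if (inconclusive) {
    NA_character_
  } else if (vals[["branched"]] < vals[["sequential"]] - 1e-9) {
    "branched"
  } else {
    "sequential"
  }
  structure(
    list(sequential = seq_fit, branched = br_fit, criterion = criterion,
         criterion_values = vals, selected = selected,
         inconclusive = inconclusive),
    class = "model_comparison"
  )
}

#' Turnover summary of a fitted chase
#'
#' Formats the fitted rate constants and half-lives the way turnover tables
#' are printed: rates to 3 significant figures, half-lives rounded
#' (half-up) to the nearest integer minute.
#'
#' @param fit A converged `chase_fit`.
#' @return A one-row data frame with columns `k_ab`, `tau_A`, `k_bx`,
#'   `tau_B` (plus `k_pa`, `k_pb` for a branched fit) and a `"model"`
#'   attribute.
#' @examples
#' tc <- simulate_chase(chase_scenarios(sigma = 0)[["wild-type"]])
#' report_half_lives(fit_sequential(normalize_to_reference(tc)))
#' @export
report_half_lives <- function(fit) {
  if (!inherits(fit, "chase_fit")) {
    stop("'fit' must be a chase_fit object", call. = FALSE)
  }
  if (!isTRUE(fit$converged)) {
    stop("refusing to report half-lives: the fit did not converge",
         call. = FALSE)
  }
  out <- data.frame(
    k_ab = signif(fit$params$k_ab, 3),
    tau_A = round_half_up(fit$half_lives[["tau_A"]]),
    k_bx = signif(fit$params$k_bx, 3),
    tau_B = round_half_up(fit$half_lives[["tau_B"]])
  )
  if (fit$model == "branched") {
    out$k_pa <- signif(fit$params$k_pa, 3)
    out$k_pb <- signif(fit$params$k_pb, 3)
  }
  attr(out, "model") <- fit$model
  out
}

#' @export
print.chase_fit <- function(x, ...) {
  cat(sprintf("<chase_fit: %s model, %d observations>\n", x$model, x$n_obs))
  cat(sprintf("  k_ab = %.4g /min (tau_A = %.1f min)\n",
              x$params$k_ab, x$half_lives[["tau_A"]]))
  cat(sprintf("  k_bx = %.4g /min (tau_B = %.1f min)\n",
              x$params$k_bx, x$half_lives[["tau_B"]]))
  if (x$model == "branched") {
    cat(sprintf("  k_pa = %.4g /min, k_pb = %.4g /min\n",
                x$params$k_pa, x$params$k_pb))
  }
  cat(sprintf("  rss = %.4g, converged: %s\n", x$rss, x$converged))
  invisible(x)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  cat(sprintf("  criterion: %s (sequential %.2f, branched %.2f)\n",
              x$criterion, x$criterion_values[["sequential"]],
              x$criterion_values[["branched"]]))
  cat(sprintf("  rss: sequential %.4g, branched %.4g\n",
              x$sequential$rss, x$branched$rss))
  cat(sprintf("  selected: %s%s\n",
              if (is.na(x$selected)) "-" else x$selected,
              if (x$inconclusive) " (inconclusive)" else ""))
  invisible(x)
}
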