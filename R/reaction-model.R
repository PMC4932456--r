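.species <- c("P", "A", "B", "X")

# pairwise-degeneracy test used to decide when the closed forms are unsafe:
# the closed-form solutions divide by rate differences, so near-coincident
# rates are routed through the matrix exponential instead
rates_degenerate <- function(rates) {
  tol <- 1e-9 * max(rates, .Machine$double.xmin)
  min(diff(sort(rates))) <= tol
}

#' Rate constants of the cleavage/degradation network
#'
#' Bundles the first-order rate constants of the presequence-processing
#' network PP -> A -> B -> X (precursor, first cleavage product, second
#' cleavage product, degraded material), plus an optional direct
#' precursor-to-B route that turns the sequential chain into a branched
#' network.  All rates are in 1/min.
#'
#' @param k_pa Precursor to A-form cleavage rate (1/min).
#' @param k_ab A-form to B-form cleavage rate (1/min).
#' @param k_bx B-form degradation rate (1/min).
#' @param k_pb Direct precursor to B-form cleavage rate (1/min); 0 gives the
#'   purely sequential network.
#' @return An object of class `rate_parameters`: a named list with the four
#'   validated rates.
#' @examples
#' rate_parameters(k_pa = 0.1, k_ab = 0.0189, k_bx = 0.0287)
#' @export
rate_parameters <- function(k_pa, k_ab, k_bx, k_pb = 0) {
  vals <- list(k_pa = k_pa, k_ab = k_ab, k_bx = k_bx, k_pb = k_pb)
  vals <- Map(check_scalar, vals, names(vals))
  structure(vals, class = "rate_parameters")
}

#' Band abundances at the start of the chase
#'
#' @param P0,A0,B0 Abundances of the precursor, A-form and B-form at t = 0,
#'   in (arbitrary) densitometry units, all >= 0.
#' @return An object of class `initial_state`.
#' @examples
#' initial_state(P0 = 0.05, A0 = 1, B0 = 0.4)
#' @export
initial_state <- function(P0 = 0, A0 = 0, B0 = 0) {
  vals <- list(P0 = P0, A0 = A0, B0 = B0)
  vals <- Map(check_scalar, vals, names(vals))
  structure(vals, class = "initial_state")
}

new_trajectory <- function(times, P, A, B, total) {
  structure(
    data.frame(time = times, P = P, A = A, B = B, X = total - P - A - B),
    class = c("trajectory", "data.frame")
  )
}

# ---- plain-matrix core solvers -------------------------------------------
# These return an unclassed matrix with columns P, A, B (no X) and carry no
# validation; they are the hot path shared by the public solvers and the
# least-squares objective.

net_matrix_raw <- function(k_pa, k_ab, k_bx, k_pb) {
  matrix(c(-(k_pa + k_pb), k_pa, k_pb, 0,
           0, -k_ab, k_ab, 0,
           0, 0, -k_bx, k_bx,
           0, 0, 0, 0),
         4L, 4L, dimnames = list(.species, .species))
}

core_matexp <- function(M, x0, times) {
  lam <- diag(M)
  tol <- 1e-9 * max(abs(lam), .Machine$double.xmin)
  if (min(diff(sort(lam))) > tol) {
    e <- eigen(M)
    V <- Re(e$vectors)
    w <- solve(V, x0)
    out <- t(V %*% (exp(outer(Re(e$values), times)) * w))
  } else {
    out <- t(vapply(times,
                    function(tt) as.numeric(Matrix::expm(M * tt) %*% x0),
                    numeric(4L)))
  }
  colnames(out) <- .species
  out[, c("P", "A", "B"), drop = FALSE]
}

core_sequential <- function(k1, k2, k3, P0, A0, B0, times) {
  if (rates_degenerate(c(k1, k2, k3))) {
    return(core_matexp(net_matrix_raw(k1, k2, k3, 0), c(P0, A0, B0, 0),
                       times))
  }
  e1 <- exp(-k1 * times)
  e2 <- exp(-k2 * times)
  e3 <- exp(-k3 * times)
  cbind(P = P0 * e1,
        A = k1 * P0 * (e2 - e1) / (k1 - k2) + A0 * e2,
        B = k1 * k2 * P0 * (e1 / ((k2 - k1) * (k3 - k1)) +
                            e2 / ((k1 - k2) * (k3 - k2)) +
                            e3 / ((k1 - k3) * (k2 - k3))) +
            k2 * A0 * (e2 - e3) / (k3 - k2) + B0 * e3)
}

core_simplified <- function(k2, k3, A0, B0, times) {
  if (rates_degenerate(c(k2, k3))) {
    return(core_matexp(net_matrix_raw(0, k2, k3, 0), c(0, A0, B0, 0),
                       times))
  }
  e2 <- exp(-k2 * times)
  e3 <- exp(-k3 * times)
  cbind(P = rep(0, length(times)),
        A = A0 * e2,
        B = k2 * A0 * (e2 - e3) / (k3 - k2) + B0 * e3)
}

core_branched <- function(k_pa, k_pb, k_ab, k_bx, P0, A0, B0, times) {
  core_matexp(net_matrix_raw(k_pa, k_ab, k_bx, k_pb),
              c(P0, A0, B0, 0), times)
}

#' Build the rate matrix of the reaction network
#'
#' Encodes the network as a linear system d(abundance)/dt = M abundance over
#' the species (P, A, B, X), with X the terminal sink.  Every column of M
#' sums to zero, so total mass is conserved along any trajectory.
#'
#' @param params A [rate_parameters()] object.
#' @return A 4x4 matrix of class `network_matrix` with dimnames
#'   `c("P","A","B","X")`.
#' @examples
#' build_network(rate_parameters(0.1, 0.0189, 0.0287))
#' @export
build_network <- function(params) {
  if (!inherits(params, "rate_parameters")) {
    stop("'params' must be a rate_parameters object", call. = FALSE)
  }
  m <- matrix(0, 4L, 4L, dimnames = list(.species, .species))
  m["P", "P"] <- -(params$k_pa + params$k_pb)
  m["A", "P"] <- params$k_pa
  m["B", "P"] <- params$k_pb
  m["A", "A"] <- -params$k_ab
  m["B", "A"] <- params$k_ab
  m["B", "B"] <- -params$k_bx
  m["X", "B"] <- params$k_bx
  structure(m, class = c("network_matrix", "matrix", "array"))
}

#' Closed-form solution of the sequential network
#'
#' Evaluates the analytic solution of the three consecutive irreversible
#' first-order reactions P -> A -> B -> X for arbitrary initial abundances:
#' \deqn{P(t) = P_0 e^{-k_{pa} t}}
#' \deqn{A(t) = \frac{k_{pa} P_0}{k_{pa}-k_{ab}}\left(e^{-k_{ab} t} -
#'   e^{-k_{pa} t}\right) + A_0 e^{-k_{ab} t}}
#' and the corresponding three-exponential expression for B(t).  The
#' degraded mass X(t) is carried explicitly as total minus P, A, B so that
#' conservation is observable.
#'
#' When any two rates coincide to within a relative tolerance of 1e-9 the
#' closed forms suffer catastrophic cancellation; the call is then routed
#' through [solve_matrix_exponential()] (a message is emitted, not an
#' error).
#'
#' @param params A [rate_parameters()] object with `k_pb = 0`.
#' @param init An [initial_state()] object.
#' @param times Sampling times in minutes (finite, >= 0, strictly
#'   increasing).
#' @return A `trajectory` data frame with columns `time`, `P`, `A`, `B`,
#'   `X`.
#' @examples
#' solve_full_sequential(rate_parameters(0.1, 0.0189, 0.0287),
#'                       initial_state(0.05, 1, 0.4), seq(0, 100, 20))
#' @seealso [solve_simplified()], [solve_matrix_exponential()]
#' @export
solve_full_sequential <- function(params, init, times) {
  if (!inherits(params, "rate_parameters")) {
    stop("'params' must be a rate_parameters object", call. = FALSE)
  }
  if (!inherits(init, "initial_state")) {
    stop("'init' must be an initial_state object", call. = FALSE)
  }
  if (params$k_pb > 0) {
    stop("solve_full_sequential() handles the sequential network only ",
         "(k_pb = 0); use solve_matrix_exponential() for the branched model",
         call. = FALSE)
  }
  times <- check_times(times)
  k1 <- params$k_pa
  k2 <- params$k_ab
  k3 <- params$k_bx
  if (rates_degenerate(c(k1, k2, k3))) {
    message("near-coincident rate constants: ",
            "routing through the matrix-exponential solver")
    return(solve_matrix_exponential(build_network(params), init, times))
  }
  m <- core_sequential(k1, k2, k3, init$P0, init$A0, init$B0, times)
  new_trajectory(times, m[, "P"], m[, "A"], m[, "B"],
                 init$P0 + init$A0 + init$B0)
}

#' Closed-form solution with the precursor neglected
#'
#' When the precursor is cleaved much faster than the downstream steps
#' (k_pa much larger than k_ab) it vanishes within the first sampling
#' interval and the system reduces to A -> B -> X:
#' \deqn{A(t) = A_0 e^{-k_{ab} t}}
#' \deqn{B(t) = \frac{k_{ab} A_0}{k_{bx}-k_{ab}}\left(e^{-k_{ab} t} -
#'   e^{-k_{bx} t}\right) + B_0 e^{-k_{bx} t}}
#' This is the default model used when fitting chase data in which the
#' precursor band is too faint to quantify.
#'
#' @inheritParams solve_full_sequential
#' @param init An [initial_state()] with `P0 = 0`.
#' @return A `trajectory` data frame (`P` identically 0).
#' @examples
#' solve_simplified(rate_parameters(0, 0.0189, 0.0287),
#'                  initial_state(0, 1, 0.4), seq(0, 100, 20))
#' @export
solve_simplified <- function(params, init, times) {
  if (!inherits(params, "rate_parameters")) {
    stop("'params' must be a rate_parameters object", call. = FALSE)
  }
  if (!inherits(init, "initial_state")) {
    stop("'init' must be an initial_state object", call. = FALSE)
  }
  if (init$P0 != 0) {
    stop("the simplified solution neglects the precursor: 'init' must have ",
         "P0 = 0 (use solve_full_sequential() to track the precursor)",
         call. = FALSE)
  }
  times <- check_times(times)
  k2 <- params$k_ab
  k3 <- params$k_bx
  if (rates_degenerate(c(k2, k3))) {
    message("near-coincident rate constants: ",
            "routing through the matrix-exponential solver")
    return(solve_matrix_exponential(build_network(params), init, times))
  }
  m <- core_simplified(k2, k3, init$A0, init$B0, times)
  new_trajectory(times, m[, "P"], m[, "A"], m[, "B"], init$A0 + init$B0)
}

#' Solve the network by matrix exponentiation
#'
#' Evaluates abundance(t) = exp(M t) abundance(0) for the linear system
#' built by [build_network()].  Valid for any rate configuration, including
#' repeated rates (where the closed forms break down) and the branched
#' network with a direct precursor-to-B route (`k_pb > 0`).
#'
#' When the four eigenvalues of M are pairwise distinct the exponential is
#' evaluated through a single eigendecomposition, which makes repeated
#' evaluation cheap during fitting; otherwise each time point falls back to
#' dense scaling-and-squaring via [Matrix::expm()].
#'
#' @param net A `network_matrix` (or a [rate_parameters()] object, which is
#'   converted via [build_network()]).
#' @param init An [initial_state()] object.
#' @param times Sampling times in minutes.
#' @return A `trajectory` data frame.
#' @examples
#' net <- build_network(rate_parameters(0.1, 0.00599, 0.00979, k_pb = 0.05))
#' solve_matrix_exponential(net, initial_state(0.5, 1, 0.4), seq(0, 100, 20))
#' @export
solve_matrix_exponential <- function(net, init, times) {
  if (inherits(net, "rate_parameters")) {
    net <- build_network(net)
  }
  if (!inherits(net, "network_matrix")) {
    stop("'net' must be a network_matrix or rate_parameters object",
         call. = FALSE)
  }
  if (!inherits(init, "initial_state")) {
    stop("'init' must be an initial_state object", call. = FALSE)
  }
  times <- check_times(times)
  x0 <- c(init$P0, init$A0, init$B0, 0)
  m <- core_matexp(unclass(net), x0, times)
  new_trajectory(times, m[, "P"], m[, "A"], m[, "B"], sum(x0))
}

#' First-order half-life
#'
#' @param k Rate constant(s) in 1/min, strictly positive.
#' @param rounded If `TRUE`, report to the nearest integer minute
#'   (round-half-up), the convention used in turnover tables.
#' @return Half-life ln(2)/k in minutes.
#' @examples
#' half_life(0.0189)                 # 36.68 min
#' half_life(0.0189, rounded = TRUE) # 37
#' @export
half_life <- function(k, rounded = FALSE) {
  if (!is.numeric(k) || length(k) < 1L || any(!is.finite(k)) || any(k <= 0)) {
    stop("rate constant 'k' must be finite and > 0", call. = FALSE)
  }
  tau <- log(2) / k
  if (rounded) round_half_up(tau) else tau
}
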