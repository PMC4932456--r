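# Independent adaptive-ODE oracle: integrates the linear system of
# build_network() with deSolve (lsoda, tight tolerances).  Used to check the
# closed-form and matrix-exponential solvers against a third, independent
# numerical route.
ode_oracle <- function(params, init, times) {
  M <- unclass(build_network(params))
  y0 <- c(P = init$P0, A = init$A0, B = init$B0, X = 0)
  tt <- if (times[1L] > 0) c(0, times) else times
  out <- as.data.frame(deSolve::ode(
    y = y0, times = tt, parms = NULL,
    func = function(t, y, p) list(as.vector(M %*% y)),
    rtol = 1e-11, atol = 1e-13))
  out[match(times, out$time), c("P", "A", "B", "X")]
}

# draw three (or four) log-uniform rates in [1e-4, 1], re-drawing until they
# are pairwise separated by at least min_sep relative to the largest, so the
# closed forms are well away from their removable singularities
draw_rates <- function(n = 3L, min_sep = 1e-3) {
  repeat {
    r <- 10^stats::runif(n, -4, 0)
    if (min(diff(sort(r))) > min_sep * max(r)) {
      return(r)
    }
  }
}

traj_matrix <- function(traj) as.matrix(traj[, c("P", "A", "B", "X")])

# noiseless simplified-model time course used by several fitting tests
simplified_timecourse <- function(k_ab, k_bx, A0, B0,
                                  times = seq(0, 100, by = 20)) {
  tr <- solve_simplified(rate_parameters(0, k_ab, k_bx),
                         initial_state(0, A0, B0), times)
  timecourse(times, A = tr$A, B = tr$B, normalized = A0 == 1)
}
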