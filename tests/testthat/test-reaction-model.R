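test_that("build_network encodes the reaction scheme with zero column sums", {
  net <- build_network(rate_parameters(0.1, 0.0189, 0.0287))
  expect_equal(unname(colSums(net)), rep(0, 4))
  expect_equal(net["A", "P"], 0.1)
  expect_equal(net["P", "P"], -0.1)
  expect_equal(net["B", "A"], 0.0189)
  expect_equal(net["X", "B"], 0.0287)
  expect_equal(net["B", "P"], 0)

  # branched edge shows up in the precursor column
  netb <- build_network(rate_parameters(0.1, 0.0189, 0.0287, k_pb = 0.05))
  expect_equal(netb["B", "P"], 0.05)
  expect_equal(netb["P", "P"], -0.15)
  expect_equal(unname(colSums(netb)), rep(0, 4))

  expect_equal(unname(unclass(build_network(rate_parameters(0, 0, 0)))),
               matrix(0, 4, 4))
})

test_that("invalid rates and states are rejected by name", {
  expect_error(rate_parameters(-0.1, 0.01, 0.01), "k_pa")
  expect_error(rate_parameters(0.1, NA, 0.01), "k_ab")
  expect_error(rate_parameters(0.1, 0.01, Inf), "k_bx")
  expect_error(rate_parameters(0.1, 0.01, 0.01, k_pb = -1), "k_pb")
  expect_error(initial_state(A0 = -1), "A0")
  expect_error(solve_full_sequential(rate_parameters(0.1, 0.01, 0.02),
                                     initial_state(0, 1, 0),
                                     c(0, 20, 10)),
               "strictly increasing")
})

test_that("solvers reproduce the initial state at t = 0", {
  p <- rate_parameters(0.1, 0.0189, 0.0287)
  i <- initial_state(0.1, 1, 0.4)
  for (tr in list(solve_full_sequential(p, i, 0),
                  solve_matrix_exponential(build_network(p), i, 0))) {
    expect_equal(tr$P[1], 0.1)
    expect_equal(tr$A[1], 1)
    expect_equal(tr$B[1], 0.4)
    expect_equal(tr$X[1], 0)
  }
  trs <- solve_simplified(rate_parameters(0, 0.0189, 0.0287),
                          initial_state(0, 1, 0.4), 0)
  expect_equal(trs$A[1], 1)
  expect_equal(trs$B[1], 0.4)
})

test_that("all mass funnels into B when degradation is switched off", {
  tr <- solve_full_sequential(rate_parameters(0.1, 0.0189, 0),
                              initial_state(0.1, 1, 0), c(0, 1e5))
  expect_equal(tr$B[2], 1.1, tolerance = 1e-8)
})

test_that("closed forms match the adaptive-ODE oracle at chase-like inputs", {
  p <- rate_parameters(0.1, 0.0189, 0.0287)
  i <- initial_state(0.1, 1, 0.4)
  times <- c(20, 40, 60, 80, 100)
  ora <- ode_oracle(p, i, times)
  full <- solve_full_sequential(p, i, times)
  expect_equal(traj_matrix(full), unname(as.matrix(ora)),
               tolerance = 1e-8, ignore_attr = TRUE)

  ps <- rate_parameters(0, 0.0189, 0.0287)
  is <- initial_state(0, 1, 0.4)
  expect_equal(traj_matrix(solve_simplified(ps, is, 40)),
               unname(as.matrix(ode_oracle(ps, is, 40))),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("closed-form, matrix-exponential and ODE routes agree over random draws", {
  set.seed(42)
  i <- initial_state(0.1, 1, 0.4)
  total <- 1.5
  times <- seq(0, 100, by = 10)
  for (rep in 1:30) {
    r <- draw_rates(3L)
    p <- rate_parameters(r[1], r[2], r[3])
    a <- traj_matrix(solve_full_sequential(p, i, times))
    b <- traj_matrix(solve_matrix_exponential(build_network(p), i, times))
    o <- unname(as.matrix(ode_oracle(p, i, times)))
    expect_lt(max(abs(a - b)) / total, 1e-8)
    expect_lt(max(abs(a - o)) / total, 1e-8)
    # conservation along every route
    expect_lt(max(abs(rowSums(a) - total)), 1e-10)
    expect_lt(max(abs(rowSums(b) - total)), 1e-10)
  }
})

test_that("precursor decays strictly monotonically whenever it is consumed", {
  set.seed(7)
  times <- seq(0, 100, by = 5)
  for (rep in 1:20) {
    r <- draw_rates(4L)
    p <- rate_parameters(r[1], r[2], r[3], k_pb = r[4])
    tr <- solve_matrix_exponential(build_network(p),
                                   initial_state(0.5, 1, 0.4), times)
    expect_true(all(diff(tr$P) < 0))
  }
})

test_that("repeated rates fall back to the matrix exponential and match the limit form", {
  # with k_pa = k_ab = k the A-form from pure precursor is k t exp(-k t) P0
  p <- rate_parameters(0.02, 0.02, 0.05)
  i <- initial_state(1, 0, 0)
  times <- seq(0, 200, by = 25)
  tr <- solve_matrix_exponential(build_network(p), i, times)
  expect_equal(tr$A, 0.02 * times * exp(-0.02 * times), tolerance = 1e-10)
  expect_message(full <- solve_full_sequential(p, i, times),
                 "matrix-exponential")
  expect_equal(full$A, tr$A, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(traj_matrix(tr)) - 1)), 1e-10)
})

test_that("neglecting a fast-cleaved precursor changes the curves by at most 2% of A0", {
  set.seed(11)
  grid <- seq(20, 100, by = 1)
  for (rep in 1:20) {
    k_ab <- stats::runif(1, 0.005, 0.02)
    k_pa <- 50 * k_ab * stats::runif(1, 1, 4)
    k_bx <- 10^stats::runif(1, log10(0.005), log10(0.05))
    if (abs(k_bx - k_ab) < 1e-3 * max(k_ab, k_bx)) next
    A0 <- 1
    P0 <- 0.1 * A0
    B0 <- stats::runif(1, 0, 0.5)
    full <- solve_full_sequential(rate_parameters(k_pa, k_ab, k_bx),
                                  initial_state(P0, A0, B0), grid)
    # the vanished precursor mass is carried as part of the A-form pool
    simp <- solve_simplified(rate_parameters(0, k_ab, k_bx),
                             initial_state(0, A0 + P0, B0), grid)
    dev <- max(abs(full$A - simp$A), abs(full$B - simp$B))
    expect_lt(dev, 0.02 * A0)
  }
})

test_that("the B-form peaks at the two-exponential maximum ln(kab/kbx)/(kab-kbx)", {
  set.seed(3)
  for (rep in 1:15) {
    r <- draw_rates(2L)
    k_ab <- r[1]
    k_bx <- r[2]
    p <- rate_parameters(0, k_ab, k_bx)
    i <- initial_state(0, 1, 0)
    t_star <- log(k_ab / k_bx) / (k_ab - k_bx)
    b_at <- function(tt) solve_simplified(p, i, tt)$B[1]
    opt <- stats::optimize(b_at, c(0, 4 * t_star), maximum = TRUE,
                           tol = 1e-10)
    expect_equal(opt$maximum, t_star, tolerance = 1e-6)
  }
})

test_that("the branched solver with k_pb = 0 reduces to the sequential solution", {
  set.seed(19)
  times <- seq(0, 100, by = 20)
  i <- initial_state(0.2, 1, 0.4)
  for (rep in 1:10) {
    r <- draw_rates(3L)
    p <- rate_parameters(r[1], r[2], r[3], k_pb = 0)
    a <- traj_matrix(solve_full_sequential(p, i, times))
    b <- traj_matrix(solve_matrix_exponential(build_network(p), i, times))
    expect_lt(max(abs(a - b)) / 1.6, 1e-10)
  }
})

test_that("solve_full_sequential rejects a branched parameter set", {
  expect_error(solve_full_sequential(
    rate_parameters(0.1, 0.01, 0.02, k_pb = 0.05),
    initial_state(0, 1, 0), c(0, 20)), "k_pb")
  expect_error(solve_simplified(rate_parameters(0, 0.01, 0.02),
                                initial_state(0.1, 1, 0), c(0, 20)),
               "P0")
})

test_that("half-lives follow ln(2)/k with integer reporting rounded half-up", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(0.0189), log(2) / 0.0189)
  expect_equal(half_life(0.0189, rounded = TRUE), 37)
  expect_equal(half_life(0.00979, rounded = TRUE), 71)
  expect_error(half_life(0), "> 0")
  expect_error(half_life(-1), "> 0")
})
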