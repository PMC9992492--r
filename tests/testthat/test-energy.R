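test_that("Gramian matches closed forms", {
  # A = 0 (1x1): integrand is constant 1
  s1 <- lti_system(dnet(integer(), integer(), n = 1), inputs = 1, tf = 1)
  g1 <- finite_time_gramian(s1)
  expect_equal(g1$W, matrix(1, 1, 1), tolerance = 1e-12)
  expect_equal(g1$mean_energy, 1, tolerance = 1e-10)

  # 2-node chain, input at the head, tf = 1: nilpotent A, exact W known
  s2 <- lti_system(chain_net(2), inputs = 1, tf = 1)
  g2 <- finite_time_gramian(s2)
  expect_equal(g2$W, matrix(c(1, 1 / 2, 1 / 2, 1 / 3), 2, 2),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(g2$mean_energy, 16, tolerance = 1e-8)
  expect_false(g2$singular)
})

test_that("Gramian solves the differential Lyapunov equation (ODE oracle)", {
  skip_if_not_installed("deSolve")
  set.seed(11)
  n <- 4
  g <- rand_net(n, 1.5, seed = 11)
  sys <- lti_system(g, inputs = c(1, 3), tf = 0.8, weights = "random",
                    seed = 12)
  A <- sys$A - 1.5 * diag(n) # stabilized copy
  sys$A <- A
  Q <- sys$B %*% t(sys$B)
  ode_fun <- function(t, w, parms) {
    W <- matrix(w, n, n)
    list(as.vector(A %*% W + W %*% t(A) + Q))
  }
  w_ode <- deSolve::ode(y = as.vector(matrix(0, n, n)),
                        times = c(0, sys$tf), func = ode_fun, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  W_ode <- matrix(w_ode[2, -1], n, n)
  expect_equal(finite_time_gramian(sys)$W, W_ode, tolerance = 1e-7)
})

test_that("positive definiteness tracks the Kalman rank condition", {
  for (s in 1:8) {
    n <- sample(3:6, 1)
    g <- rand_net(n, 1.2, seed = 1100 + s)
    inp <- sort(sample(n, sample(1:2, 1)))
    sys <- lti_system(g, inputs = inp, tf = 1)
    K <- sys$B
    blk <- sys$B
    for (k in seq_len(n - 1)) {
      blk <- sys$A %*% blk
      K <- cbind(K, blk)
    }
    controllable <- qr(K)$rank == n
    gr <- finite_time_gramian(sys, floor_rel = 1e-9)
    expect_equal(!gr$singular, controllable)
  }
})

test_that("optimal signal energy equals the Gramian quadratic form", {
  s2 <- lti_system(chain_net(2), inputs = 1, tf = 1)
  # free evolution costs nothing
  x0 <- c(1, -2)
  xf <- as.vector(lccontrol:::mat_exp(s2$A * s2$tf) %*% x0)
  expect_equal(control_energy(s2, x0, xf), 0, tolerance = 1e-12)

  # 1-node integrator, x0 = 0 -> xf = 1: energy 1
  s1 <- lti_system(dnet(integer(), integer(), n = 1), inputs = 1, tf = 1)
  expect_equal(control_energy(s1, 0, 1), 1, tolerance = 1e-8)

  # quadrature of the explicit signal == v' W^-1 v
  xf2 <- c(1, 2)
  expect_equal(control_energy(s2, c(0, 0), xf2),
               gramian_energy(s2, c(0, 0), xf2), tolerance = 1e-6)
  expect_equal(gramian_energy(s2, c(0, 0), c(0, 1)), 12, tolerance = 1e-8)

  # unreachable target at working precision: flagged
  s_bad <- lti_system(dnet(integer(), integer(), n = 2), inputs = 1, tf = 1)
  expect_error(optimal_signal(s_bad, c(0, 0), c(1, 1)), "singular")
})
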