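test_that("the dendritic kernel is causal, peaks where predicted, and integrates to one", {
  expect_equal(dendrite_kernel(-0.01, 45, 185), 0)
  expect_equal(dendrite_kernel(c(-1, -1e-9), 45, 185), c(0, 0))

  # peak location t = log(beta/alpha)/(beta - alpha)
  tpk <- log(185 / 45) / (185 - 45)
  expect_equal(tpk, 1.0098e-2, tolerance = 1e-4)
  expect_equal(optimize(function(t) dendrite_kernel(t, 45, 185),
                        c(0, 0.1), maximum = TRUE, tol = 1e-10)$maximum, tpk,
               tolerance = 1e-6)
  # alpha = beta degenerate branch and its unit area (quadrature oracle)
  t <- 0.01
  expect_equal(dendrite_kernel(t, 40, 40), 1600 * t * exp(-40 * t))
  area <- integrate(function(u) dendrite_kernel(u, 40, 40), 0, Inf,
                    rel.tol = 1e-10)$value
  expect_lt(abs(area - 1), 1e-6)
})

test_that("kernel area is one across a wide range of rate ratios", {
  for (ratio in c(1, 1.5, 4, 10, 100)) {
    alpha <- 45; beta <- alpha * ratio
    area <- integrate(function(u) dendrite_kernel(u, alpha, beta),
                      0, 50 / alpha, rel.tol = 1e-9)$value
    expect_lt(abs(area - 1), 1e-4)
  }
  # single-exponential limit (one rate infinite) keeps unit area
  area <- integrate(function(u) dendrite_kernel(u, 45, Inf), 0, 2,
                    rel.tol = 1e-10)$value
  expect_lt(abs(area - 1), 1e-6)
  expect_error(dendrite_kernel(0.1, -1, 2), "positive")
  expect_error(dendrite_kernel(0.1, Inf, Inf), "Dirac")
})

test_that("RK4 dendrite stepping reproduces the closed-form impulse response", {
  # impulse at t = 0 corresponds to v = 0, vdot = alpha * beta
  dt <- 1e-4
  st <- dendrite_state(v = 0, vdot = 45 * 185)
  t <- 0
  for (n in 1:200) {
    st <- dendrite_step(st, 0, 0, 45, 185, dt)
    t <- t + dt
    if (any(abs(t - c(0.005, 0.01, 0.02)) < dt / 2)) {
      expect_lt(abs(st$v - dendrite_kernel(t, 45, 185)), 1e-6)
    }
  }
  # critically damped free decay: v(t) = (1 + g t) exp(-g t)
  g <- 40
  st <- dendrite_state(v = 1, vdot = 0); t <- 0
  for (n in 1:500) { st <- dendrite_step(st, 0, 0, g, g, dt); t <- t + dt }
  expect_lt(abs(st$v - (1 + g * t) * exp(-g * t)), 1e-6)
})

test_that("dendrite stepping is fourth order and fixed at constant drive", {
  imp_err <- function(dt) {
    st <- dendrite_state(0, 45 * 185)
    for (i in seq_len(round(0.02 / dt))) st <- dendrite_step(st, 0, 0, 45, 185, dt)
    abs(st$v - dendrite_kernel(0.02, 45, 185))
  }
  order <- log2(imp_err(2e-4) / imp_err(1e-4))
  expect_gt(order, 3.7)
  expect_lt(order, 4.3)

  st <- dendrite_state(v = rep(0.42, 5), vdot = rep(0, 5))
  for (i in 1:100) st <- dendrite_step(st, 0.42, 0.42, 45, 185, 1e-4)
  expect_close(st$v, 0.42, 1e-13)
  expect_close(st$vdot, 0, 1e-13)
})

test_that("soma summation is an elementwise, order-invariant sum", {
  a <- matrix(0.002, 2, 2); b <- matrix(-0.001, 2, 2)
  expect_equal(soma_sum(list(a, b)), matrix(0.001, 2, 2))
  expect_equal(soma_sum(list(a)), a)
  set.seed(3)
  fields <- replicate(4, matrix(rnorm(4), 2, 2), simplify = FALSE)
  expect_equal(soma_sum(fields), soma_sum(rev(fields)))
  expect_equal(soma_sum(list(), zero = numeric(3)), numeric(3))
  expect_error(soma_sum(list(a, numeric(3))), "mismatch")
})

test_that("the sigmoid firing response has the right midpoint, limits and bounds", {
  fr <- nf_firing(qmax = 340, theta = 0.01292, sigma = 0.0038)
  expect_equal(firing_response(0.01292, fr), 170)
  expect_equal(firing_response(10, fr), 340)
  expect_equal(firing_response(-10, fr), 0)
  v <- seq(-0.2, 0.2, length.out = 4001)
  q <- firing_response(v, fr)
  expect_true(all(diff(q) >= 0))
  expect_true(all(q >= 0 & q <= 340))
})

test_that("the linear response is tangent to the sigmoid at the operating point", {
  fr <- nf_firing(340, 0.01292, 0.0038)
  v0 <- 0.002
  rho <- firing_slope(v0, fr)
  lin <- nf_firing_linear(q0 = firing_response(v0, fr), v0 = v0, rho = rho)
  eps <- 1e-4
  err <- abs(firing_response(v0 + eps, fr) - firing_response(v0 + eps, lin))
  # second-order Taylor remainder bound: |S''| <= qmax / (4 sigma^2) * ...
  curvature_bound <- fr$qmax / fr$sigma^2
  expect_lt(err, curvature_bound * eps^2)
  # clipping is opt-in
  lin2 <- nf_firing_linear(10, 0, rho = 1000, clip = FALSE)
  expect_lt(firing_response(-1, lin2), 0)
  lin3 <- nf_firing_linear(10, 0, rho = 1000, clip = TRUE)
  expect_equal(firing_response(-1, lin3), 0)
})

test_that("steady state with no self-consistency reduces to a direct evaluation", {
  # nu_self = 0: V* = nu_ext * phi_ext, Q* = S(V*)
  cfg <- single_e_config(kind = "map", nu_self = 0, nu_ext = 2e-5)
  st <- find_steady_state(cfg)
  fr <- cfg$populations[[1]]$firing
  expect_equal(st$v[1], 2e-5 * 10, tolerance = 1e-9)
  expect_equal(st$q[1], firing_response(2e-5 * 10, fr), tolerance = 1e-7)
  expect_equal(unname(st$phi["2"]), 10)
})

test_that("scan-and-bisect agrees with a brute-force grid search on the self-coupled sigmoid", {
  cfg <- single_e_config(kind = "map", nu_self = 2e-5, nu_ext = 2e-5)
  st <- find_steady_state(cfg)
  fr <- cfg$populations[[1]]$firing
  # brute force over Q in [0, Qmax] with 1e6 points
  qs <- seq(0, fr$qmax, length.out = 1e6 + 1)
  resid <- abs(firing_response(2e-5 * qs + 2e-5 * 10, fr) - qs)
  q_bf <- qs[which.min(resid)]
  expect_lt(abs(st$q[1] - q_bf), 1e-3)      # grid resolution limit
  # the solver root satisfies the fixed-point equation far more tightly
  expect_lt(abs(firing_response(2e-5 * st$q[1] + 2e-4, fr) - st$q[1]), 1e-8)
})

test_that("linear firing mode has the algebraic fixed point", {
  rho <- 800; q0 <- 10; v0 <- 0; nu_ee <- 2e-4; nu_ex <- 1e-4; phi_x <- 10
  cfg <- parse_config(c(
    "linear firing fixed point",
    "Time: 0.01", "Deltat: 1e-4", "Nodes: 4",
    "Connection matrix:", "1 2", "0 0",
    "Population 1: Excitatory", "Length: 0.1",
    "Firing: Linear", paste0("Q0: ", q0), paste0("V0: ", v0),
    paste0("Rho: ", rho),
    "Dendrite 1:", "alpha: 45", "beta: 185",
    "Dendrite 2:", "alpha: 45", "beta: 185",
    "Population 2: External", "Length: 0.1",
    "Stimulus 1:", "Kind: Const", paste0("Amplitude: ", phi_x),
    "Propagator 1: Map", "Tau: 0",
    "Propagator 2: Map", "Tau: 0",
    "Coupling 1:", paste0("nu: ", nu_ee),
    "Coupling 2:", paste0("nu: ", nu_ex),
    "Output:", "Node: 1", "Start: 0", "Interval: 1e-4",
    "Trace: Population.1.Q"))
  st <- find_steady_state(cfg)
  q_exact <- (q0 + rho * (nu_ex * phi_x - v0)) / (1 - rho * nu_ee)
  expect_lt(abs(st$q[1] - q_exact), 1e-10)
})
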