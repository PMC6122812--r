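test_that("Courant numbers follow v dt / dx", {
  expect_equal(courant_number(10, 2^-14, 0.05), 10 * 2^-14 / 0.05)
  expect_equal(courant_number(10, 2^-14, 0.05), 0.012207, tolerance = 1e-5)
  expect_equal(courant_number(0, 1e-4, 0.01), 0)
  expect_equal(courant_number(10, 2e-4, 0.01), 2 * courant_number(10, 1e-4, 0.01))
})

test_that("the 2D stability gate rejects p_max > 1/sqrt(2) and passes otherwise", {
  wave <- function(gamma, range, label = 1) {
    list(kind = "wave", gamma = gamma, range = range, label = label)
  }
  # v = 10, dt = 1e-4, dx = 1e-3 -> p = 1 > 1/sqrt(2)
  expect_error(check_stability(list(wave(50, 0.2)), 1e-4, 1e-3), "Courant")
  # v = 10, dt = 2^-14, dx = 0.01 -> p ~ 0.061
  expect_silent(p <- check_stability(list(wave(50, 0.2)), 2^-14, 0.01))
  expect_equal(p, 10 * 2^-14 / 0.01)
  # no wave propagators: vacuously fine
  expect_equal(check_stability(list(list(kind = "map")), 1e-4, 1e-3), 0)
  # margin warning above 0.15
  expect_warning(check_stability(list(wave(50, 0.2)), 1e-4, 2.5e-3), "margin")
})

test_that("a uniform steady source is a fixed point of the wave scheme", {
  g <- nf_grid(64, 0.5)
  c0 <- as_field(g, 12.5)
  st <- wave_state(c0, c0, gamma = 30, range = 0.2, dt = 6.103515625e-5, dx = g$dx)
  st1 <- wave_step(st, c0)
  expect_close(st1$phi, 12.5, 12.5 * 1e-12)
  # and remains so over 1e4 steps at a coarser step
  st <- wave_state(c0, c0, gamma = 30, range = 0.2, dt = 2e-4, dx = g$dx)
  for (n in 1:10000) st <- wave_step(st, c0)
  expect_close(st$phi, 12.5, 12.5 * 1e-9)
})

test_that("a central impulse spreads with four-fold symmetry", {
  g <- nf_grid(33^2, 0.5)
  zero <- as_field(g, 0)
  spike <- zero; spike[17, 17] <- 1
  st <- wave_state(zero, zero, gamma = 30, range = 0.2, dt = 2e-4, dx = g$dx)
  st <- wave_step(st, spike)
  for (n in 1:50) st <- wave_step(st, zero)
  rot <- st$phi[rev(seq_len(33)), ]      # reflect x about the centre
  expect_close(st$phi, rot, 1e-14)
  rot90 <- t(st$phi)                     # x <-> y
  expect_close(st$phi, rot90, 1e-14)
})

test_that("the wave scheme is second order when dt and dx are halved together", {
  order_err <- function(nx, dt, Tend = 0.05, L = 0.5, gamma = 30, r = 0.2) {
    g <- nf_grid(nx^2, L); k <- 2 * pi / L
    x <- (seq_len(g$nx) - 0.5) * g$dx
    cosx <- matrix(rep(cos(k * x), g$ny), g$nx, g$ny)
    sol <- function(t) exp(-gamma * t) * cos(gamma * r * k * t) * cosx
    st <- wave_state(sol(0), as_field(g, 0), gamma, r, dt, g$dx)
    st$phi_prev <- sol(-dt)
    zero <- as_field(g, 0)
    ns <- round(Tend / dt)
    for (n in seq_len(ns)) st <- wave_step(st, zero)
    max(abs(st$phi - sol(ns * dt)))
  }
  order <- log2(order_err(32, 2e-4) / order_err(64, 1e-4))
  expect_gt(order, 1.7)
  expect_lt(order, 2.3)
})

test_that("wave and harmonic trajectories agree for spatially uniform fields", {
  # uniform free decay from (phi, phi') = (1, 0): the Laplacian term drops
  # and both propagators integrate the same damped oscillator
  run_pair <- function(dt) {
    g <- nf_grid(16, 0.4); gamma <- 60
    u0 <- as_field(g, 1)
    st <- wave_state(u0, as_field(g, 0), gamma, range = 0.2, dt = dt, dx = g$dx)
    st$phi_prev <- as_field(g, (1 - gamma * dt) * exp(gamma * dt)) # exact at -dt
    hphi <- 1; hdot <- 0
    for (n in seq_len(round(0.02 / dt))) {
      st <- wave_step(st, as_field(g, 0))
      h <- harmonic_step(hphi, hdot, 0, 0, gamma, dt)
      hphi <- h$phi; hdot <- h$phidot
    }
    abs(st$phi[1, 1] - hphi)
  }
  d1 <- run_pair(1e-4); d2 <- run_pair(5e-5)
  expect_lt(d1, 1e-9)          # second-order-small at dt = 1e-4
  expect_lt(d2, d1)            # and shrinking with the step
})

test_that("harmonic propagator holds its fixed point and matches the Green function", {
  h <- harmonic_step(3.3, 0, 3.3, 3.3, gamma = 100, dt = 1e-4)
  expect_equal(h$phi, 3.3, tolerance = 1e-13)
  expect_equal(h$phidot, 0, tolerance = 1e-10)

  gam <- 100; dt <- 1e-4; phi <- 0; pd <- gam^2; t <- 0
  for (n in 1:500) {
    r <- harmonic_step(phi, pd, 0, 0, gam, dt)
    phi <- r$phi; pd <- r$phidot; t <- t + dt
    expect_lt(abs(phi - gam^2 * t * exp(-gam * t)), 1e-6)
  }
})

test_that("harmonic stepping error falls ~16x when dt is halved", {
  err_at <- function(dt) {
    gam <- 100; phi <- 0; pd <- gam^2
    for (n in seq_len(round(0.02 / dt))) {
      r <- harmonic_step(phi, pd, 0, 0, gam, dt)
      phi <- r$phi; pd <- r$phidot
    }
    abs(phi - gam^2 * 0.02 * exp(-gam * 0.02))
  }
  order <- log2(err_at(2e-4) / err_at(1e-4))
  expect_gt(order, 3.7)
  expect_lt(order, 4.3)
})

test_that("the map propagator is the identity on the source rate", {
  expect_equal(map_step(numeric(9)), numeric(9))
  set.seed(5)
  q <- matrix(rexp(16), 4, 4)
  expect_identical(map_step(q), q)
})

test_that("the damped wave decays towards zero with a nonincreasing envelope", {
  g <- nf_grid(64, 0.5)
  set.seed(1)
  phi0 <- as_field(g, rnorm(64))
  st <- wave_state(phi0, as_field(g, 0), gamma = 30, range = 0.2,
                   dt = 2e-4, dx = g$dx)
  zero <- as_field(g, 0)
  norms <- numeric(2000)
  for (n in seq_len(2000)) {
    st <- wave_step(st, zero)
    norms[n] <- sqrt(sum(st$phi^2))
  }
  peaks <- norms[which(diff(sign(diff(norms))) < 0) + 1]
  expect_true(all(diff(peaks) < 0))
  expect_lt(norms[2000], 1e-3 * norms[1])
})

test_that("delay depth takes the spatial and connection maximum with a floor of two", {
  dt <- 1e-3
  expect_equal(history_depth(list(0, 0), dt), 2L)
  expect_equal(history_depth(list(3 * dt), dt), 3L)
  # per-node delays: largest over space first, then over connections
  tau_field <- c(0, 2, 5, 1) * dt
  expect_equal(history_depth(list(tau_field, 2 * dt), dt), 5L)
  expect_error(history_depth(list(1.5 * dt), dt), "integer multiple")
  expect_error(history_depth(list(-dt), dt), "nonnegative")
})

test_that("the ring buffer serves lagged reads exactly", {
  buf <- nf_history(3, 4, init = 0)
  fields <- lapply(0:5, function(k) rep(k + 1, 3))
  for (f in fields) buf <- history_push(buf, f)
  expect_equal(history_read(buf, 0), rep(6, 3))   # most recent push
  expect_equal(history_read(buf, 3), rep(3, 3))   # f2 (hand-simulated ring)
  expect_error(history_read(buf, 4), "history")
  expect_error(nf_history(3, 1), "at least 2")

  cbuf <- nf_history(5, 3, init = 7.7)
  for (lag in 0:2) expect_equal(history_read(cbuf, lag), rep(7.7, 5))

  # per-node lags
  buf2 <- nf_history(3, 4)
  for (k in 1:4) buf2 <- history_push(buf2, c(10, 20, 30) + k)
  expect_equal(history_read(buf2, 0, node_lags = c(0, 1, 3)),
               c(14, 23, 31))
})
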