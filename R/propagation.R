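#' Courant number of the explicit wave scheme
#'
#' `p = v * dt / dx`, the number of grid cells a front travelling at the
#' axonal velocity `v = gamma * range` crosses per time step. The explicit 2D
#' scheme is stable only for `p <= 1/sqrt(2)`.
#'
#' @param v Axonal velocity (m/s).
#' @param dt Time step (s).
#' @param dx Grid spacing (m).
#' @return Dimensionless Courant number.
#' @export
courant_number <- function(v, dt, dx) {
  v * dt / dx
}

#' Check the 2D Courant stability condition
#'
#' Computes the Courant number of every wave-type propagator and errors if
#' the maximum exceeds the 2D stability bound `1/sqrt(2)`. A warning is
#' issued above `warn_at` (default 0.15): practical work keeps a wide margin,
#' commonly around p_max = 0.1.
#'
#' @param propagators List of propagator parameter lists; each wave entry
#'   needs `gamma` (s^-1) and `range` (m). Entries whose `kind` is not
#'   `"wave"` are ignored.
#' @param dt Time step (s).
#' @param dx Grid spacing (m) — a scalar, or a vector parallel to
#'   `propagators`.
#' @param warn_at Courant number above which a margin warning is given.
#' @return Invisibly, the maximum Courant number (0 when no wave
#'   propagators exist).
#' @export
check_stability <- function(propagators, dt, dx, warn_at = 0.15) {
  if (length(dx) == 1) dx <- rep(dx, length(propagators))
  pmax_val <- 0
  worst <- NA
  for (i in seq_along(propagators)) {
    pr <- propagators[[i]]
    if (!identical(pr$kind, "wave")) next
    p <- courant_number(pr$gamma * pr$range, dt, dx[[i]])
    if (p > pmax_val) {
      pmax_val <- p
      worst <- if (!is.null(pr$label)) pr$label else i
    }
  }
  if (pmax_val > 1 / sqrt(2)) {
    stop(sprintf(
      "Courant condition violated: p_max = %.4f > 1/sqrt(2) = %.4f (connection %s); reduce dt or refine the grid",
      pmax_val, 1 / sqrt(2), worst))
  }
  if (pmax_val > warn_at) {
    warning(sprintf(
      "Courant number p_max = %.3f (connection %s) leaves little stability margin; p_max around 0.1 is typical practice",
      pmax_val, worst))
  }
  invisible(pmax_val)
}

#' Create the state of an explicit wave propagator
#'
#' Holds the field at the current and previous time levels together with the
#' (already delay-shifted) source firing rate at the current and previous
#' levels, plus the constants of the stepping formula. Starting a simulation
#' from a fixed point fills every level with the equilibrium values.
#'
#' @param phi0 Initial field (nx-by-ny matrix).
#' @param q0 Initial source firing-rate field.
#' @param gamma Damping rate (s^-1).
#' @param range Axonal range r (m); the velocity is `gamma * range`.
#' @param dt Time step (s).
#' @param dx Grid spacing (m).
#' @return A list of class `nf_wave_state`.
#' @export
wave_state <- function(phi0, q0, gamma, range, dt, dx) {
  p <- courant_number(gamma * range, dt, dx)
  if (p > 1 / sqrt(2)) {
    stop(sprintf("wave propagator unstable: p = %.4f > 1/sqrt(2)", p))
  }
  if (gamma * dt > 0.1) {
    warning(sprintf(
      "gamma * dt = %.3f > 0.1: the exponential substitution behind the wave scheme assumes a small step",
      gamma * dt))
  }
  e1 <- exp(-gamma * dt)
  structure(
    list(phi = phi0, phi_prev = phi0, q_now = q0, q_prev = q0,
         p2 = p^2, e1 = e1, e2 = e1^2, b = dt^2 * gamma^2 / 12),
    class = "nf_wave_state"
  )
}

#' Advance a damped-wave field one step
#'
#' Explicit central-difference update of the 2D telegrapher's equation
#' `(1/gamma^2) phi_tt + (2/gamma) phi_t + phi - r^2 lap(phi) = Q`
#' on the periodic grid. With `E = exp(-gamma dt)`, `p` the Courant number
#' and `S(.)` the four-neighbour periodic sum, the update reads
#'
#' ```
#' phi[n+1] = E * ((2 - 4 p^2) phi[n] + p^2 S(phi[n]))   - E^2 phi[n-1]
#'          + (dt^2 gamma^2 / 12) *
#'            ( E * ((10 - 4 p^2) Q[n] + p^2 S(Q[n])) + Q[n+1] + E^2 Q[n-1] )
#' ```
#'
#' in which only decaying exponentials appear. The scheme is second-order
#' accurate in space and time.
#'
#' @param state An [wave_state()] object at level n.
#' @param q_next Source firing rate at level n+1 (already delay-shifted).
#' @return The state advanced to level n+1 (`state$phi` is the new field).
#' @export
wave_step <- function(state, q_next) {
  s <- state
  phi_new <- s$e1 * ((2 - 4 * s$p2) * s$phi + s$p2 * neighbor_sum(s$phi)) -
    s$e2 * s$phi_prev +
    s$b * (s$e1 * ((10 - 4 * s$p2) * s$q_now + s$p2 * neighbor_sum(s$q_now)) +
             q_next + s$e2 * s$q_prev)
  if (!all(is.finite(phi_new))) {
    stop("wave field became non-finite (numerical instability)")
  }
  s$phi_prev <- s$phi
  s$phi <- phi_new
  s$q_prev <- s$q_now
  s$q_now <- q_next
  s
}

#' Advance a harmonic (spatially uniform) propagator one RK4 step
#'
#' Integrates `(1/gamma^2) phi'' + (2/gamma) phi' + phi = Q` per node, the
#' damped-wave operator without its Laplacian — the right description when
#' activity is spatially uniform, and a cheap approximation for weakly
#' spatial fields. The drive at the RK4 half step is the average of the two
#' integer-step values.
#'
#' @param phi,phidot Current field and its time derivative.
#' @param q_now,q_next Source firing rate at the bracketing integer steps.
#' @param gamma Damping rate (s^-1), positive.
#' @param dt Time step (s).
#' @return List with advanced `phi` and `phidot`.
#' @export
harmonic_step <- function(phi, phidot, q_now, q_next, gamma, dt) {
  stopifnot(gamma > 0, dt > 0)
  g2 <- gamma^2
  tg <- 2 * gamma
  q_mid <- 0.5 * (q_now + q_next)
  # y1' = y2 ; y2' = gamma^2 (Q - y1) - 2 gamma y2
  k1v <- phidot
  k1w <- g2 * (q_now - phi) - tg * phidot
  k2v <- phidot + 0.5 * dt * k1w
  k2w <- g2 * (q_mid - (phi + 0.5 * dt * k1v)) - tg * k2v
  k3v <- phidot + 0.5 * dt * k2w
  k3w <- g2 * (q_mid - (phi + 0.5 * dt * k2v)) - tg * k3v
  k4v <- phidot + dt * k3w
  k4w <- g2 * (q_next - (phi + dt * k3v)) - tg * k4v
  phi_new <- phi + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
  w_new <- phidot + dt / 6 * (k1w + 2 * k2w + 2 * k3w + k4w)
  if (!all(is.finite(phi_new))) {
    stop("harmonic field became non-finite (numerical instability)")
  }
  list(phi = phi_new, phidot = w_new)
}

#' Local interaction approximation
#'
#' The zero-range limit of axonal propagation: the arriving field equals the
#' source firing rate instantaneously, `phi = Q`.
#'
#' @param q_now Source firing-rate field.
#' @return The same field.
#' @export
map_step <- function(q_now) {
  q_now
}

#' Delay depth of a population's history buffer
#'
#' The buffer serving delayed reads of a population's firing rate must hold
#' `max_b round(tau_b / dt)` past levels, where the maximum runs over every
#' connection out of the population and, for spatially nonuniform delays,
#' over space first. A floor of 2 levels is applied so the wave scheme always
#' has its two past levels. Delays must be commensurate with the time step:
#' an error is raised when `tau/dt` deviates from an integer by a relative
#' amount above `tol`.
#'
#' @param taus List (or vector) of delays in seconds; each element may be a
#'   scalar or a per-node field.
#' @param dt Time step (s).
#' @param tol Relative tolerance for `tau/dt` being an integer.
#' @return Integer delay depth D (number of stored levels).
#' @export
history_depth <- function(taus, dt, tol = 1e-6) {
  lags <- vapply(taus, function(tau) max(delay_steps(tau, dt, tol)), numeric(1))
  max(2L, as.integer(if (length(lags)) max(lags) else 0))
}

delay_steps <- function(tau, dt, tol = 1e-6) {
  if (any(tau < 0)) stop("delays must be nonnegative")
  d <- tau / dt
  dr <- round(d)
  bad <- abs(d - dr) > tol * pmax(1, abs(d))
  if (any(bad)) {
    stop(sprintf(
      "delay tau = %g s is not an integer multiple of dt = %g s; choose commensurate values",
      tau[bad][1], dt))
  }
  as.integer(dr)
}

#' Ring-buffer history of a population's firing rate
#'
#' `nf_history()` allocates an N-by-depth buffer filled with `init` (the
#' equilibrium firing rate when starting from a fixed point);
#' `history_push()` overwrites the oldest level with a new field;
#' `history_read()` returns the field `lag` steps in the past (lag 0 is the
#' most recently pushed level), optionally with a different lag per node.
#'
#' @param n Number of nodes.
#' @param depth Number of stored levels, at least 2.
#' @param init Initial fill value(s).
#' @return `nf_history()`: a list of class `nf_history`; `history_push()` the
#'   updated buffer; `history_read()` a numeric vector of length `n`.
#' @export
nf_history <- function(n, depth, init = 0) {
  depth <- as.integer(depth)
  if (depth < 2L) stop("history depth must be at least 2")
  structure(
    list(ring = matrix(init, nrow = n, ncol = depth), depth = depth,
         cursor = 0L),
    class = "nf_history"
  )
}

#' @rdname nf_history
#' @param buffer An `nf_history` object.
#' @param field Numeric vector of length `n` to push.
#' @export
history_push <- function(buffer, field) {
  cur <- buffer$cursor %% buffer$depth + 1L
  buffer$ring[, cur] <- field
  buffer$cursor <- cur
  buffer
}

#' @rdname nf_history
#' @param lag Integer lag in steps, `0 <= lag < depth` (scalar).
#' @param node_lags Optional integer vector of per-node lags overriding
#'   `lag`.
#' @export
history_read <- function(buffer, lag, node_lags = NULL) {
  d <- buffer$depth
  if (is.null(node_lags)) {
    if (lag < 0 || lag >= d) {
      stop("lag ", lag, " outside stored history (depth ", d, ")")
    }
    col <- (buffer$cursor - lag - 1L) %% d + 1L
    return(buffer$ring[, col])
  }
  if (any(node_lags < 0 | node_lags >= d)) {
    stop("per-node lag outside stored history (depth ", d, ")")
  }
  cols <- (buffer$cursor - as.integer(node_lags) - 1L) %% d + 1L
  buffer$ring[cbind(seq_len(nrow(buffer$ring)), cols)]
}
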