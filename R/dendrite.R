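#' Biexponential dendritic response kernel
#'
#' Impulse response of the synaptodendritic/soma low-pass filter with decay
#' rate `alpha` and rise rate `beta` (both s^-1, `beta >= alpha` by
#' convention). For `alpha != beta` the kernel is
#' `alpha*beta/(beta - alpha) * (exp(-alpha*t) - exp(-beta*t))`; for
#' `alpha == beta` it degenerates to `alpha^2 * t * exp(-alpha*t)`. The kernel
#' is causal (zero for `t < 0`) and integrates to one, so it conserves the
#' time-averaged input rate. If exactly one of the rates is infinite the
#' kernel collapses to a single exponential; if both are infinite it is a
#' Dirac impulse and this function signals that case with an error (the
#' filter is then the identity and has no finite-valued kernel).
#'
#' The kernel peaks at `t = log(beta/alpha) / (beta - alpha)` when the rates
#' differ, and at `t = 1/alpha` when they coincide.
#'
#' @param t Time (s), vectorized.
#' @param alpha Decay rate (s^-1), positive (may be `Inf`).
#' @param beta Rise rate (s^-1), `beta >= alpha` (may be `Inf`).
#' @return Kernel values (s^-1) at `t`.
#' @export
dendrite_kernel <- function(t, alpha, beta) {
  if (!is.numeric(alpha) || alpha <= 0) stop("`alpha` must be positive")
  if (beta < alpha) stop("`beta` must be >= `alpha`")
  if (is.infinite(alpha) && is.infinite(beta)) {
    stop("alpha = beta = Inf gives a Dirac impulse; the kernel has no finite values")
  }
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  if (is.infinite(beta)) {
    out[pos] <- alpha * exp(-alpha * tp)
  } else if (abs(beta - alpha) < 1e-12 * alpha) {
    out[pos] <- alpha^2 * tp * exp(-alpha * tp)
  } else {
    out[pos] <- alpha * beta / (beta - alpha) * (exp(-alpha * tp) - exp(-beta * tp))
  }
  out
}

#' Advance dendritic subpotentials one time step (RK4)
#'
#' Integrates the second-order dendritic filter
#' `(1/(alpha*beta)) V'' + (1/alpha + 1/beta) V' + V = P(t)`
#' one step of size `dt` with the classical fourth-order Runge-Kutta method,
#' where `P` is the synaptically weighted incoming rate `nu * phi`. The drive
#' is supplied at the two bracketing integer steps; the half-step value used
#' by RK4 is their average (the solver only holds fields at integer steps).
#'
#' Degenerate rates are handled exactly: with one infinite rate the filter is
#' first order (`(1/a) V' + V = P` with `a` the finite rate); with both
#' infinite it is the identity `V = P`.
#'
#' @param state List with numeric fields `v` and `vdot` (same shape as the
#'   drive); create with `dendrite_state(v, vdot)`.
#' @param drive_now,drive_next Drive `P` at the current and next integer step
#'   (fields or scalars).
#' @param alpha,beta Rates (s^-1).
#' @param dt Time step (s).
#' @return Updated state list.
#' @export
dendrite_step <- function(state, drive_now, drive_next, alpha, beta, dt) {
  stopifnot(dt > 0)
  if (is.infinite(alpha) && is.infinite(beta)) {
    return(dendrite_state(v = drive_next, vdot = 0 * drive_next))
  }
  v <- state$v; w <- state$vdot
  drive_mid <- 0.5 * (drive_now + drive_next)
  if (is.infinite(beta) || is.infinite(alpha)) {
    a <- if (is.infinite(beta)) alpha else beta
    f <- function(v, p) a * (p - v)
    k1 <- f(v, drive_now)
    k2 <- f(v + 0.5 * dt * k1, drive_mid)
    k3 <- f(v + 0.5 * dt * k2, drive_mid)
    k4 <- f(v + dt * k3, drive_next)
    vn <- v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    return(dendrite_state(v = vn, vdot = f(vn, drive_next)))
  }
  ab <- alpha * beta
  apb <- alpha + beta
  # y1' = y2 ; y2' = alpha*beta*(P - y1) - (alpha+beta)*y2
  k1v <- w
  k1w <- ab * (drive_now - v) - apb * w
  k2v <- w + 0.5 * dt * k1w
  k2w <- ab * (drive_mid - (v + 0.5 * dt * k1v)) - apb * k2v
  k3v <- w + 0.5 * dt * k2w
  k3w <- ab * (drive_mid - (v + 0.5 * dt * k2v)) - apb * k3v
  k4v <- w + dt * k3w
  k4w <- ab * (drive_next - (v + dt * k3v)) - apb * k4v
  vn <- v + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
  wn <- w + dt / 6 * (k1w + 2 * k2w + 2 * k3w + k4w)
  if (!all(is.finite(vn))) {
    stop("dendrite state became non-finite; the time step is too large for (alpha, beta)")
  }
  dendrite_state(v = vn, vdot = wn)
}

#' @rdname dendrite_step
#' @param v,vdot Initial subpotential (V) and its time derivative (V/s).
#' @export
dendrite_state <- function(v, vdot = 0 * v) {
  list(v = v, vdot = vdot)
}

#' Sum dendritic subpotentials into the soma potential
#'
#' The mean soma potential of a population is the linear sum of the
#' subpotentials contributed by each afferent connection. An empty list
#' yields a zero field of the shape given by `zero`.
#'
#' @param subpotentials List of numeric fields of identical shape.
#' @param zero Template used when `subpotentials` is empty.
#' @return The elementwise sum.
#' @export
soma_sum <- function(subpotentials, zero = 0) {
  if (length(subpotentials) == 0) return(zero)
  lens <- vapply(subpotentials, length, integer(1))
  if (length(unique(lens)) != 1) stop("subpotential fields have mismatched shapes")
  Reduce(`+`, subpotentials)
}

#' Firing response parameters
#'
#' `nf_firing()` describes the default sigmoidal population response with
#' maximum rate `qmax` (s^-1), mean threshold `theta` (V) and threshold
#' spread `sigma` (V; the logistic scale parameter, related to the voltage
#' standard deviation by `sd = sigma * pi / sqrt(3)`).
#' `nf_firing_linear()` describes the linearization around an operating point
#' `(v0, q0)` with slope `rho` (s^-1 V^-1); negative rates are kept by
#' default (the linear form is only valid near the operating point) unless
#' `clip = TRUE`.
#'
#' @param qmax Maximum firing rate (s^-1).
#' @param theta Mean firing threshold (V).
#' @param sigma Threshold spread (V), positive.
#' @return A list of class `nf_firing`.
#' @export
nf_firing <- function(qmax, theta, sigma) {
  stopifnot(qmax > 0, sigma > 0)
  structure(list(mode = "sigmoid", qmax = qmax, theta = theta, sigma = sigma),
            class = "nf_firing")
}

#' @rdname nf_firing
#' @param q0,v0 Operating-point firing rate (s^-1) and voltage (V).
#' @param rho Response slope dQ/dV at the operating point (s^-1 V^-1).
#' @param clip Clip negative rates to zero?
#' @export
nf_firing_linear <- function(q0, v0, rho, clip = FALSE) {
  structure(list(mode = "linear", q0 = q0, v0 = v0, rho = rho, clip = clip),
            class = "nf_firing")
}

#' Population firing response
#'
#' Maps mean soma potential to mean firing rate. In sigmoid mode
#' `Q = qmax / (1 + exp(-(V - theta)/sigma))`, a monotone map from 0 to
#' `qmax`. In linear mode `Q = q0 + rho * (V - v0)`, optionally clipped at
#' zero.
#'
#' @param v Soma potential field (V).
#' @param params An [nf_firing()] or [nf_firing_linear()] object.
#' @return Firing rate field (s^-1), same shape as `v`.
#' @export
firing_response <- function(v, params) {
  stopifnot(inherits(params, "nf_firing"))
  if (params$mode == "sigmoid") {
    params$qmax / (1 + exp(-(v - params$theta) / params$sigma))
  } else {
    q <- params$q0 + params$rho * (v - params$v0)
    if (isTRUE(params$clip)) q <- pmax(q, 0)
    q
  }
}

#' Slope of the firing response
#'
#' dQ/dV evaluated at `v`; for the sigmoid this is
#' `Q (1 - Q/qmax) / sigma`, the gain entering linearized transfer functions.
#'
#' @inheritParams firing_response
#' @return Slope field (s^-1 V^-1).
#' @export
firing_slope <- function(v, params) {
  stopifnot(inherits(params, "nf_firing"))
  if (params$mode == "sigmoid") {
    q <- firing_response(v, params)
    q * (1 - q / params$qmax) / params$sigma
  } else {
    rep(params$rho, length(v))
  }
}
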