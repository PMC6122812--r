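#' Frequency response of the dendritic filter
#'
#' Fourier transform (convention `exp(-i omega t)`, so `d/dt -> -i omega`)
#' of the biexponential kernel:
#' `L(omega) = 1 / ((1 - i omega / alpha) (1 - i omega / beta))`.
#' Unit gain at DC (the kernel has unit area); a monotone low-pass in
#' `|omega|`. Infinite rates drop their factor.
#'
#' @param omega Angular frequency (rad/s), vectorized.
#' @param alpha,beta Dendritic rates (s^-1).
#' @return Complex gain.
#' @export
dendritic_filter <- function(omega, alpha, beta) {
  fa <- if (is.infinite(alpha)) 1 + 0i else 1 - 1i * omega / alpha
  fb <- if (is.infinite(beta)) 1 + 0i else 1 - 1i * omega / beta
  1 / (fa * fb)
}

#' Frequency/wavenumber response of axonal propagation
#'
#' For the damped-wave operator,
#' `A(k, omega) = 1 / ((1 - i omega / gamma)^2 + k^2 r^2)`; with `r = 0`
#' this reduces to the harmonic operator's response at every wavenumber,
#' and the local interaction approximation (map) has unit gain.
#'
#' @param omega Angular frequency (rad/s).
#' @param k2 Squared wavenumber magnitude (m^-2).
#' @param gamma Damping rate (s^-1), positive.
#' @param range Axonal range r (m).
#' @return Complex gain (vectorized over `omega` and/or `k2`).
#' @export
wave_dispersion <- function(omega, k2, gamma, range) {
  stopifnot(gamma > 0)
  1 / ((1 - 1i * omega / gamma)^2 + k2 * range^2)
}

propagator_gain <- function(pr, omega, k2) {
  switch(pr$kind,
    wave = wave_dispersion(omega, k2, pr$gamma, pr$range),
    harmonic = wave_dispersion(omega, 0, pr$gamma, 0) + 0 * k2,
    map = rep(1 + 0i, max(length(omega), length(k2))))
}

#' Linearized model around the fixed point
#'
#' Collects everything the analytic transfer functions need: the fixed
#' point from [find_steady_state()], the firing slope `rho_a = dQ_a/dV_a`
#' there, and per-connection filter parameters. The per-connection gain is
#' `G_l = rho_to(l) * nu_l` (dimensionless).
#'
#' @param cfg An `nf_config`.
#' @return A list of class `nf_linear` with fields `steady`, `rho`
#'   (per population, NA for external), and a per-connection table.
#' @export
nf_linear_model <- function(cfg) {
  stopifnot(inherits(cfg, "nf_config"))
  steady <- find_steady_state(cfg)
  p <- length(cfg$populations)
  rho <- rep(NA_real_, p)
  for (a in steady$internal) {
    rho[a] <- firing_slope(steady$v[a], cfg$populations[[a]]$firing)
  }
  conns <- cfg$connections
  conns$nu <- vapply(as.character(conns$label), function(l) cfg$couplings[[l]]$nu, numeric(1))
  conns$tau <- vapply(as.character(conns$label), function(l) cfg$propagators[[l]]$tau, numeric(1))
  conns$gain <- rho[conns$to] * conns$nu
  structure(list(config = cfg, steady = steady, rho = rho, connections = conns),
            class = "nf_linear")
}

# Transfer functions T(k, omega) from each external population's firing
# fluctuation to the requested trace, for one squared wavenumber.
# Returns a matrix (length(omega) x n_external).
linear_transfer_k <- function(model, omega, k2, trace_info) {
  cfg <- model$config
  conns <- model$connections
  internal <- model$steady$internal
  external <- model$steady$external
  ni <- length(internal)
  nw <- length(omega)

  filt <- vector("list", nrow(conns))
  for (l in seq_len(nrow(conns))) {
    den <- cfg$populations[[conns$to[l]]]$dendrites[[as.character(conns$label[l])]]
    filt[[l]] <- dendritic_filter(omega, den$alpha, den$beta) *
      propagator_gain(cfg$propagators[[as.character(conns$label[l])]], omega, k2) *
      exp(1i * omega * conns$tau[l])
  }

  # Q_int(omega) = (I - M)^{-1} D Q_ext, assembled per frequency
  idx_int <- match(seq_along(model$rho), internal)
  out <- matrix(0 + 0i, nrow = nw, ncol = length(external))
  q_int_all <- array(0 + 0i, dim = c(nw, ni, length(external)))
  if (ni == 1) {
    # scalar loop gain: fully vectorized over frequency
    M1 <- rep(0 + 0i, nw)
    D1 <- matrix(0 + 0i, nw, length(external))
    for (l in seq_len(nrow(conns))) {
      a <- conns$to[l]; b <- conns$from[l]
      if (!(a %in% internal)) next
      g <- model$rho[a] * conns$nu[l] * filt[[l]]
      if (b %in% internal) M1 <- M1 + g
      else D1[, match(b, external)] <- D1[, match(b, external)] + g
    }
    if (any(Mod(1 - M1) < 1e-12)) {
      stop("linear system singular (oscillatory instability) at some frequency")
    }
    q_int_all[, 1, ] <- D1 / (1 - M1)
  } else for (w in seq_len(nw)) {
    M <- matrix(0 + 0i, ni, ni)
    D <- matrix(0 + 0i, ni, length(external))
    for (l in seq_len(nrow(conns))) {
      a <- conns$to[l]; b <- conns$from[l]
      if (!(a %in% internal)) next
      ia <- idx_int[a]
      g <- model$rho[a] * conns$nu[l] * filt[[l]][w]
      if (b %in% internal) M[ia, idx_int[b]] <- M[ia, idx_int[b]] + g
      else D[ia, match(b, external)] <- D[ia, match(b, external)] + g
    }
    sol <- tryCatch(solve(diag(ni) - M, D), error = function(e) {
      stop(sprintf("linear system singular at omega = %.4g rad/s, k^2 = %.4g m^-2 (oscillatory instability)",
                   omega[w], k2))
    })
    q_int_all[w, , ] <- sol
  }

  if (trace_info$object == "Propagator") {
    l <- trace_info$index
    b <- conns$from[l]
    A <- propagator_gain(cfg$propagators[[as.character(l)]], omega, k2) *
      exp(1i * omega * conns$tau[l])
    if (b %in% internal) {
      out <- A * q_int_all[, idx_int[b], , drop = TRUE]
    } else {
      out[, match(b, external)] <- A
    }
  } else { # Population
    a <- trace_info$index
    if (!(a %in% internal)) stop("linear transfer to an external population is trivial")
    out <- q_int_all[, idx_int[a], , drop = TRUE]
    if (trace_info$quantity == "V") out <- out / model$rho[a]
  }
  matrix(out, nrow = nw)
}

#' Closed-form linearized power spectrum
#'
#' Solves the linearized model in the Fourier domain on the same discrete
#' wavenumber modes as the periodic simulation box and accumulates, for
#' white-noise drive entering at the external populations,
#' `P(f) = (1/N) sum_k |T(k, omega)|^2 ASD^2`. The `1/N` reflects that
#' node-independent white noise spreads its one-sided density `ASD^2`
#' evenly over the N spatial modes, which makes the result directly
#' comparable to the Welch spectrum of a single recorded node (or to
#' [nf_spatial_spectrum()] without filtering).
#'
#' Drive amplitudes are read from the configured white stimulus components
#' unless `drive_asd` overrides them (one value per external population).
#'
#' @param cfg An `nf_config`.
#' @param frequencies Frequencies (Hz) at which to evaluate.
#' @param trace Output trace label, e.g. `"Propagator.1.phi"`.
#' @param drive_asd Optional named or ordered vector of amplitude spectral
#'   densities (s^-1 Hz^-1/2) for the external populations.
#' @return An `nf_spectrum` with method metadata `list(analytic = TRUE)`.
#' @export
nf_linear_psd <- function(cfg, frequencies, trace, drive_asd = NULL) {
  model <- nf_linear_model(cfg)
  info <- parse_trace(trace, cfg)
  external <- model$steady$external
  if (is.null(drive_asd)) {
    drive_asd <- vapply(external, function(x) {
      comps <- cfg$populations[[x]]$stimuli
      sqrt(sum(vapply(comps, function(s)
        if (s$kind == "white") s$amplitude^2 else 0, numeric(1))))
    }, numeric(1))
  }
  # DC stability check on the spatially uniform mode
  g0 <- linear_transfer_k(model, 1e-9, 0, info)

  grid <- cfg$grids[[1]]
  kk <- nf_wavenumbers(grid)
  k2_tab <- table(round(as.vector(kk$k2), 9))
  k2_vals <- as.numeric(names(k2_tab))
  k2_mult <- as.integer(k2_tab)
  omega <- 2 * pi * frequencies
  power <- numeric(length(omega))
  for (i in seq_along(k2_vals)) {
    tr <- linear_transfer_k(model, omega, k2_vals[i], info)
    contrib <- Mod(tr)^2 %*% (drive_asd^2)
    power <- power + k2_mult[i] * as.vector(contrib)
  }
  structure(
    list(frequencies = frequencies, power = power / grid$n,
         method = list(analytic = TRUE, trace = trace, drive_asd = drive_asd,
                       n_modes = grid$n)),
    class = "nf_spectrum"
  )
}
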