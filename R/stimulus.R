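#' Stimulus components for external populations
#'
#' External populations emit a prescribed firing-rate field built by adding
#' any number of components:
#'
#' * `const` — a DC level `amplitude` (s^-1), always on.
#' * `sine` — `amplitude * sin(2 pi frequency (t - onset))` while
#'   `onset <= t < onset + duration`.
#' * `pulse` — a square pulse train: `amplitude` during
#'   `[onset + k*period, onset + k*period + duration)`, k = 0, 1, ...
#' * `white` — Gaussian white noise, independent across nodes and steps. The
#'   `amplitude` is an amplitude spectral density (s^-1 Hz^-1/2): draws are
#'   scaled by `1/sqrt(2 dt)` so the one-sided power spectral density of the
#'   discrete sequence equals `amplitude^2` regardless of the step size.
#'
#' Components may be restricted to a subset of nodes via `nodes`; unmasked
#' nodes contribute exactly zero. A `seed` on a white component gives it a
#' private reproducible stream, otherwise draws come from the session RNG
#' (seeded once per simulation).
#'
#' @param kind One of `"const"`, `"sine"`, `"pulse"`, `"white"`.
#' @param amplitude Level, sine amplitude, pulse height (s^-1), or noise
#'   amplitude spectral density (s^-1 Hz^-1/2).
#' @param frequency Sine frequency (Hz).
#' @param onset Start time (s).
#' @param duration On-time (s); `Inf` means always on after onset.
#' @param period Pulse-train repetition period (s).
#' @param nodes Integer node mask, or `NULL` for all nodes.
#' @param seed Optional integer seed for a white component.
#' @return A list of class `nf_stimulus`.
#' @export
nf_stimulus <- function(kind, amplitude, frequency = NULL, onset = 0,
                        duration = Inf, period = NULL, nodes = NULL,
                        seed = NULL) {
  kind <- match.arg(kind, c("const", "sine", "pulse", "white"))
  if (kind == "sine" && is.null(frequency)) stop("sine stimulus needs `frequency`")
  if (kind == "pulse") {
    if (is.null(period)) period <- Inf
    if (period <= 0) stop("pulse `period` must be positive")
    if (duration < 0) stop("pulse `duration` must be nonnegative")
  }
  comp <- list(kind = kind, amplitude = amplitude, frequency = frequency,
               onset = onset, duration = duration, period = period,
               nodes = if (!is.null(nodes)) as.integer(nodes),
               seed = if (!is.null(seed)) as.integer(seed))
  if (!is.null(comp$seed)) {
    # private stream so identical configs reproduce bit-identical noise
    comp$rng <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
      set.seed(comp$seed)
      s <- get(".Random.seed", globalenv())
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      s
    })
  }
  structure(comp, class = "nf_stimulus")
}

#' Gaussian white-noise field with step-invariant spectral density
#'
#' Draws one i.i.d. normal value per node with standard deviation
#' `asd / sqrt(2 dt)`, so the one-sided power spectral density of each node's
#' sequence is `asd^2` (s^-2 Hz^-1) for any step size.
#'
#' @param asd Amplitude spectral density (s^-1 Hz^-1/2).
#' @param dt Time step (s).
#' @param n Number of nodes.
#' @return Numeric vector of length `n`.
#' @export
white_noise_field <- function(asd, dt, n) {
  stopifnot(dt > 0)
  if (asd == 0) return(numeric(n))
  stats::rnorm(n, sd = asd / sqrt(2 * dt))
}

component_value <- function(comp, t, n, dt) {
  on_nodes <- function(values) {
    if (is.null(comp$nodes)) return(values)
    out <- numeric(n)
    out[comp$nodes] <- if (length(values) == 1) values else values[comp$nodes]
    out
  }
  switch(comp$kind,
    const = on_nodes(rep(comp$amplitude, n)),
    sine = {
      tt <- t - comp$onset
      if (tt >= 0 && tt < comp$duration) {
        on_nodes(rep(comp$amplitude * sin(2 * pi * comp$frequency * tt), n))
      } else numeric(n)
    },
    pulse = {
      tt <- t - comp$onset
      phase <- if (is.infinite(comp$period)) tt else tt %% comp$period
      if (tt >= 0 && phase < comp$duration) {
        on_nodes(rep(comp$amplitude, n))
      } else numeric(n)
    },
    white = {
      if (is.null(comp$rng)) {
        on_nodes(white_noise_field(comp$amplitude, dt, n))
      } else {
        if (!exists(".Random.seed", globalenv())) stats::runif(1)
        old <- get(".Random.seed", globalenv())
        assign(".Random.seed", comp$rng, globalenv())
        val <- on_nodes(white_noise_field(comp$amplitude, dt, n))
        new_state <- get(".Random.seed", globalenv())
        assign(".Random.seed", old, globalenv())
        attr(val, "rng") <- new_state
        val
      }
    }
  )
}

#' Evaluate an additive stimulus at one time
#'
#' Sums all components at time `t` over `n` nodes. White components draw
#' fresh noise each call; for reproducible simulation the solver seeds the
#' RNG once from the configuration.
#'
#' @param components List of [nf_stimulus()] components.
#' @param t Time (s).
#' @param n Number of nodes.
#' @param dt Time step (s), needed by white components.
#' @return List with `field` (numeric length `n`) and `components` (the
#'   input list, with private RNG streams advanced).
#' @export
evaluate_stimulus <- function(components, t, n, dt) {
  field <- numeric(n)
  for (i in seq_along(components)) {
    val <- component_value(components[[i]], t, n, dt)
    rng <- attr(val, "rng")
    if (!is.null(rng)) {
      components[[i]]$rng <- rng
      attributes(val) <- NULL
    }
    field <- field + val
  }
  list(field = field, components = components)
}

#' Time-mean of a stimulus
#'
#' The drive used when locating the fixed point: constant components keep
#' their level; sine, pulse and white components average to zero over long
#' times (pulses are transient events, noise has zero mean).
#'
#' @inheritParams evaluate_stimulus
#' @return Numeric vector of length `n`.
#' @export
stimulus_mean <- function(components, n) {
  field <- numeric(n)
  for (comp in components) {
    if (comp$kind == "const") {
      val <- rep(comp$amplitude, n)
      if (!is.null(comp$nodes)) {
        masked <- numeric(n)
        masked[comp$nodes] <- comp$amplitude
        val <- masked
      }
      field <- field + val
    }
  }
  field
}
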