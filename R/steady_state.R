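#' Locate the spatially uniform fixed point of a model
#'
#' With all temporal and spatial derivatives set to zero the model collapses
#' to the algebraic system `phi*_ab = Q*_b`, `V*_ab = nu_ab Q*_b`,
#' `V*_a = sum_b V*_ab`, `Q*_a = S_a(V*_a)`, with external populations held
#' at the time-mean of their stimulus (constant components only). Delays
#' drop out at a fixed point.
#'
#' For a single internal population the fixed points are roots of the scalar
#' function `h(V) = V - nu_aa S(V) - c`; the bracket `[-0.1, 0.1]` V
#' (covering physiological soma potentials) is scanned with `scan_points`
#' test values, each sign change is refined by bisection to `tol` volts, and
#' the root with the lowest firing rate is selected. With several internal
#' populations the vector fixed-point map `Q -> S(nu Q + c)` is solved by
#' damped Picard iteration from a lattice of starting rates, each candidate
#' polished by Newton's method with a numerical Jacobian; converged roots
#' are deduplicated and the one with the lowest total firing rate is kept —
#' the conventional choice of the linearly stable low-firing brain state.
#'
#' @param cfg An `nf_config`.
#' @param scan_points Number of scan values across the voltage bracket.
#' @param bracket Voltage scan interval (V).
#' @param tol Bisection tolerance (V).
#' @return A list of class `nf_steady` with per-population vectors `q` and
#'   `v` (NA voltage for external populations) and per-connection `phi`
#'   (named by connection label).
#' @export
find_steady_state <- function(cfg, scan_points = 1e4,
                              bracket = c(-0.1, 0.1), tol = 1e-12) {
  stopifnot(inherits(cfg, "nf_config"))
  p <- length(cfg$populations)
  internal <- which(!vapply(cfg$populations, `[[`, logical(1), "external"))
  external <- setdiff(seq_len(p), internal)
  if (length(internal) == 0) stop("model has no internal population")

  q_ext <- vapply(external, function(pi) {
    m <- stimulus_mean(cfg$populations[[pi]]$stimuli, cfg$nodes)
    mean(m)
  }, numeric(1))
  names(q_ext) <- as.character(external)

  # nu matrix restricted to internal targets, plus constant external drive
  nu_of <- function(to, from) {
    l <- cfg$matrix[to, from]
    if (l == 0) 0 else cfg$couplings[[as.character(l)]]$nu
  }
  const_drive <- vapply(internal, function(a) {
    sum(vapply(external, function(x) nu_of(a, x) * q_ext[[as.character(x)]],
               numeric(1)))
  }, numeric(1))
  nu_int <- outer(internal, internal, Vectorize(nu_of))

  firing <- lapply(internal, function(a) cfg$populations[[a]]$firing)
  s_of_v <- function(v) {
    vapply(seq_along(internal), function(i) firing_response(v[i], firing[[i]]),
           numeric(1))
  }

  if (length(internal) == 1) {
    fr <- firing[[1]]
    h <- function(v) v - nu_int[1, 1] * firing_response(v, fr) - const_drive
    vs <- seq(bracket[1], bracket[2], length.out = scan_points)
    hv <- vapply(vs, h, numeric(1))
    sgn <- sign(hv)
    cross <- which(sgn[-1] * sgn[-length(sgn)] <= 0 & sgn[-length(sgn)] != 0)
    if (length(cross) == 0) {
      stop(sprintf("no steady state found scanning V in [%g, %g] V with %d points",
                   bracket[1], bracket[2], scan_points))
    }
    roots <- vapply(cross, function(i) {
      lo <- vs[i]; hi <- vs[i + 1]
      while (hi - lo > tol) {
        mid <- 0.5 * (lo + hi)
        if (sign(h(mid)) == sign(h(lo)) && h(mid) != 0) lo <- mid else hi <- mid
      }
      v <- 0.5 * (lo + hi)
      # Newton polish to the limit of double precision
      for (it in 1:5) {
        hp <- 1 - nu_int[1, 1] * firing_slope(v, fr)
        if (abs(hp) < 1e-12) break
        step <- h(v) / hp
        v <- v - step
        if (abs(step) < 1e-16 * max(1, abs(v))) break
      }
      v
    }, numeric(1))
    qs <- firing_response(roots, fr)
    v_star <- roots[which.min(qs)]
    q_star <- firing_response(v_star, fr)
    v_int <- v_star; q_int <- q_star
  } else {
    fmap <- function(q) s_of_v(as.vector(nu_int %*% q) + const_drive)
    resid <- function(q) fmap(q) - q
    qmaxes <- vapply(firing, function(fr) {
      if (fr$mode == "sigmoid") fr$qmax else max(1, 2 * abs(fr$q0))
    }, numeric(1))
    starts <- list(rep(0, length(internal)), qmaxes / 2, qmaxes)
    roots <- list()
    for (q0 in starts) {
      q <- q0
      for (it in 1:500) q <- 0.5 * q + 0.5 * pmin(pmax(fmap(q), -qmaxes), qmaxes * 1.0)
      # Newton polish with numerical Jacobian
      for (it in 1:50) {
        r <- resid(q)
        if (max(abs(r)) < 1e-12) break
        jac <- vapply(seq_along(q), function(j) {
          eps <- 1e-7 * max(1, abs(q[j]))
          qq <- q; qq[j] <- qq[j] + eps
          (resid(qq) - r) / eps
        }, numeric(length(q)))
        step <- tryCatch(solve(jac, -r), error = function(e) NULL)
        if (is.null(step)) break
        q <- q + step
      }
      if (max(abs(resid(q))) < 1e-8) roots[[length(roots) + 1]] <- q
    }
    if (length(roots) == 0) {
      stop("no steady state found: fixed-point iteration and Newton polish failed to converge")
    }
    uniq <- roots[!duplicated(round(do.call(rbind, roots), 6))]
    q_int <- uniq[[which.min(vapply(uniq, sum, numeric(1)))]]
    v_int <- as.vector(nu_int %*% q_int) + const_drive
  }

  q <- numeric(p); v <- rep(NA_real_, p)
  q[internal] <- q_int
  v[internal] <- v_int
  q[external] <- q_ext
  phi <- vapply(seq_len(nrow(cfg$connections)), function(l) {
    q[cfg$connections$from[l]]
  }, numeric(1))
  names(phi) <- as.character(cfg$connections$label)
  structure(list(q = q, v = v, phi = phi, internal = internal,
                 external = external),
            class = "nf_steady")
}

#' @export
print.nf_steady <- function(x, ...) {
  cat("<nf_steady> fixed point\n")
  for (i in seq_along(x$q)) {
    cat(sprintf("  population %d: Q* = %.6g s^-1%s\n", i, x$q[i],
                if (i %in% x$internal) sprintf(", V* = %.6g V", x$v[i]) else " (external)"))
  }
  invisible(x)
}
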