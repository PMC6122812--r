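#' Run a neural-field simulation
#'
#' Integrates the configured model from its spatially uniform fixed point.
#' Every state (dendritic subpotentials, propagator fields and their past
#' levels, delay histories) is initialized at the steady state returned by
#' [find_steady_state()], so a model with zero-variance stimulus stays
#' constant.
#'
#' Each step n -> n+1 proceeds in the order: (1) external stimuli are
#' evaluated at t[n+1]; (2) each internal population advances its dendritic
#' filters (RK4, drive `nu * phi` with the end-of-step value linearly
#' extrapolated from the two stored levels), sums subpotentials into the
#' soma potential and applies the firing response, giving Q at n+1; (3)
#' firing rates are pushed into the per-population delay histories; (4)
#' every propagator advances, the wave scheme consuming the delayed source
#' rate at levels n-1, n, n+1; (5) if n+1 is a sampling step at or beyond
#' `Start`, the requested traces are recorded. Output is pure decimation:
#' recorded samples equal the corresponding full-rate values exactly.
#'
#' @param cfg An `nf_config` (see [parse_config()]).
#' @param seed Integer RNG seed; defaults to the configuration's `Seed` key.
#' @param verbose Log progress (every simulated second) and the maximum
#'   Courant number to standard error.
#' @return An object of class `nf_output`; see [write_output()],
#'   [nf_extract()], [generics::tidy()].
#' @export
run_nf <- function(cfg, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "nf_config"))
  cfg <- validate_physics(cfg)
  if (is.null(seed)) seed <- cfg$seed
  set.seed(seed)

  p <- length(cfg$populations)
  n_nodes <- cfg$nodes
  grid <- cfg$grids[[1]]
  nxs <- vapply(cfg$grids, `[[`, numeric(1), "nx")
  if (length(unique(nxs)) != 1) {
    stop("all populations must share one grid layout (same Longside nodes)")
  }
  dt <- cfg$dt
  n_steps <- as.integer(round(cfg$time / dt))
  k_out <- cfg$output$k
  start_step <- as.integer(round(cfg$output$start / dt))
  internal <- which(!vapply(cfg$populations, `[[`, logical(1), "external"))
  external <- setdiff(seq_len(p), internal)
  conns <- cfg$connections
  n_conn <- nrow(conns)

  if (verbose) {
    pm <- tryCatch(check_stability(cfg$propagators, dt,
                                   vapply(seq_len(n_conn), function(l)
                                     cfg$grids[[conns$from[l]]]$dx, numeric(1))),
                   warning = function(w) suppressWarnings(
                     check_stability(cfg$propagators, dt, vapply(seq_len(n_conn),
                       function(l) cfg$grids[[conns$from[l]]]$dx, numeric(1)))))
    message(sprintf("neurofield: %d populations, %d connections, %d nodes, %d steps, p_max = %.4f",
                    p, n_conn, n_nodes, n_steps, pm))
  }

  steady <- find_steady_state(cfg)

  # --- per-connection setup ----------------------------------------------
  lags <- integer(n_conn)
  props <- vector("list", n_conn)
  for (l in seq_len(n_conn)) {
    pr <- cfg$propagators[[as.character(l)]]
    src <- conns$from[l]
    lags[l] <- delay_steps(pr$tau, dt)
    phi0 <- as_field(grid, steady$q[src])
    props[[l]] <- switch(pr$kind,
      wave = c(list(kind = "wave"),
               wave_state(phi0, phi0, pr$gamma, pr$range, dt,
                          cfg$grids[[src]]$dx)),
      harmonic = list(kind = "harmonic", phi = phi0, phi_prev = phi0,
                      phidot = 0 * phi0, q_now = phi0, gamma = pr$gamma),
      map = list(kind = "map", phi = phi0, phi_prev = phi0)
    )
  }

  # --- histories (delay ring buffers) ------------------------------------
  hist <- vector("list", p)
  for (b in seq_len(p)) {
    from_b <- which(conns$from == b)
    dmax <- if (length(from_b)) max(lags[from_b]) else 0L
    hist[[b]] <- nf_history(n_nodes, dmax + 2L, init = steady$q[b])
  }

  # --- population states --------------------------------------------------
  qfields <- lapply(seq_len(p), function(b) rep(steady$q[b], n_nodes))
  vfields <- lapply(seq_len(p), function(b) {
    if (b %in% internal) rep(steady$v[b], n_nodes) else rep(NA_real_, n_nodes)
  })
  dstates <- vector("list", p)
  stimuli <- vector("list", p)
  for (a in internal) {
    labs <- conns$label[conns$to == a]
    dstates[[a]] <- lapply(stats::setNames(as.character(labs), as.character(labs)),
      function(lab) {
        l <- as.integer(lab)
        nu <- cfg$couplings[[lab]]$nu
        dendrite_state(v = rep(nu * steady$q[conns$from[l]], n_nodes))
      })
  }
  for (x in external) {
    stimuli[[x]] <- cfg$populations[[x]]$stimuli
    # start external fields at the stimulus mean, matching the fixed point
    qfields[[x]] <- stimulus_mean(stimuli[[x]], n_nodes)
  }

  # --- recording ----------------------------------------------------------
  out_nodes <- if (identical(cfg$output$nodes, "all")) seq_len(n_nodes) else cfg$output$nodes
  traces <- cfg$output$traces
  col_labels <- character(0); col_nodes <- integer(0)
  for (tr in traces) {
    col_labels <- c(col_labels, rep(tr, length(out_nodes)))
    col_nodes <- c(col_nodes, out_nodes)
  }
  n_samples <- if (n_steps >= start_step) (n_steps - start_step) %/% k_out + 1L else 0L
  data <- matrix(NA_real_, nrow = n_samples, ncol = length(col_labels))
  times <- numeric(n_samples)

  record_row <- function(row, n) {
    times[row] <<- n * dt
    col <- 0L
    for (tr in traces) {
      info <- parse_trace(tr, cfg)
      vals <- switch(info$object,
        Population = if (info$quantity == "Q") qfields[[info$index]] else vfields[[info$index]],
        Propagator = as.vector(props[[info$index]]$phi),
        Coupling = rep(cfg$couplings[[as.character(info$index)]]$nu, n_nodes)
      )
      data[row, col + seq_along(out_nodes)] <<- vals[out_nodes]
      col <- col + length(out_nodes)
    }
  }

  row <- 0L
  if (start_step == 0L) { row <- 1L; record_row(1L, 0L) }

  next_second <- 1
  for (n in seq_len(n_steps)) {
    t_new <- n * dt

    for (x in external) {
      res <- evaluate_stimulus(stimuli[[x]], t_new, n_nodes, dt)
      qfields[[x]] <- res$field
      stimuli[[x]] <- res$components
    }

    for (a in internal) {
      pop <- cfg$populations[[a]]
      labs <- names(dstates[[a]])
      subs <- vector("list", length(labs))
      for (j in seq_along(labs)) {
        lab <- labs[j]; l <- as.integer(lab)
        nu <- cfg$couplings[[lab]]$nu
        phi_n <- as.vector(props[[l]]$phi)
        phi_m <- as.vector(props[[l]]$phi_prev)
        den <- pop$dendrites[[lab]]
        dstates[[a]][[lab]] <- withCallingHandlers(
          dendrite_step(dstates[[a]][[lab]],
                        drive_now = nu * phi_n,
                        drive_next = nu * (2 * phi_n - phi_m),
                        alpha = den$alpha, beta = den$beta, dt = dt),
          error = function(e) stop("step ", n, ", dendrite ", lab,
                                   " of population ", a, ": ", conditionMessage(e)))
        subs[[j]] <- dstates[[a]][[lab]]$v
      }
      vfields[[a]] <- soma_sum(subs, zero = numeric(n_nodes))
      qfields[[a]] <- firing_response(vfields[[a]], pop$firing)
    }

    for (b in seq_len(p)) hist[[b]] <- history_push(hist[[b]], qfields[[b]])

    for (l in seq_len(n_conn)) {
      st <- props[[l]]
      q_next <- history_read(hist[[conns$from[l]]], lags[l])
      if (st$kind == "wave") {
        st[-1] <- withCallingHandlers(
          wave_step(structure(st[-1], class = "nf_wave_state"),
                    as_field(grid, q_next)),
          error = function(e) stop("step ", n, ", wave propagator ", l, ": ",
                                   conditionMessage(e)))
      } else if (st$kind == "harmonic") {
        st$phi_prev <- st$phi
        adv <- harmonic_step(st$phi, st$phidot, st$q_now, as_field(grid, q_next),
                             st$gamma, dt)
        st$phi <- adv$phi; st$phidot <- adv$phidot
        st$q_now <- as_field(grid, q_next)
      } else {
        st$phi_prev <- st$phi
        st$phi <- as_field(grid, map_step(q_next))
      }
      props[[l]] <- st
    }

    if (n >= start_step && (n - start_step) %% k_out == 0L) {
      row <- row + 1L
      record_row(row, n)
    }
    if (verbose && t_new >= next_second) {
      message(sprintf("neurofield: t = %g s / %g s", next_second, cfg$time))
      next_second <- next_second + 1
    }
  }

  structure(
    list(config = cfg, config_text = serialize_config(cfg),
         labels = col_labels, nodes = col_nodes,
         times = times[seq_len(row)],
         data = data[seq_len(row), , drop = FALSE],
         steady = steady),
    class = "nf_output"
  )
}

#' @export
print.nf_output <- function(x, ...) {
  cat(sprintf("<nf_output> %d samples x %d columns (%s), t in [%g, %g] s\n",
              length(x$times), ncol(x$data),
              paste(unique(x$labels), collapse = ", "),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA))
  invisible(x)
}
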