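#' The plain-text model configuration dialect
#'
#' A simulation is declared in a line-oriented `Key: value` text format, read
#' with [parse_config()] / [read_config()] and written with
#' [serialize_config()]. All values are SI without prefixes (1 mV is written
#' `1e-3`). The file has, in order:
#'
#' 1. An optional free-text description (every line before `Time:`),
#'    preserved verbatim.
#' 2. Global keys: `Time` (s), `Deltat` (s), `Nodes` (grid cells, a perfect
#'    square unless `Longside nodes` is given), optional `Longside nodes`
#'    and `Seed`.
#' 3. A `Connection matrix:` block of P rows by P columns; rows are target
#'    populations, columns sources. Zero means no connection; positive
#'    entries are the consecutive connection labels 1..C, each appearing
#'    once, and label the matching `Propagator`, `Coupling` and `Dendrite`
#'    blocks.
#' 4. One `Population <i>: <Type>` block per population, in order. Internal
#'    populations (`Excitatory`, `Inhibitory`, `Reticular`, `Relay`, ...)
#'    take `Length` (m), optional `Longside nodes`, optional initial rate
#'    `Q` (s^-1), a firing block (`Firing: Sigmoid` with `Qmax`, `Theta`,
#'    `Sigma`, or `Firing: Linear` with `Q0`, `V0`, `Rho`, optional `Clip`)
#'    and one `Dendrite <label>:` block (`alpha`, `beta`) per afferent
#'    connection. `External` populations take `Length` and `Stimulus <k>:`
#'    blocks (`Kind`, `Amplitude`, and the keys of [nf_stimulus()]).
#' 5. One `Propagator <label>: <Kind>` block per connection (`Wave` with
#'    `Tau`, `Range`, `gamma`; `Harmonic` with `Tau`, `gamma`; `Map` with
#'    `Tau`) and one `Coupling <label>:` block with `nu` (V s).
#' 6. An `Output:` block: `Node` (1-based indices or `All`), `Start` (s),
#'    `Interval` (s, an integer multiple of `Deltat`), and one
#'    `Trace:` line per requested timeseries
#'    (`Population.<i>.Q`, `Population.<i>.V`, `Propagator.<label>.phi`,
#'    `Coupling.<label>.nu`).
#'
#' Unknown keys are errors, surfacing typos rather than silently ignoring
#' them.
#'
#' @name conf-format
NULL

pop_block_keys <- c("Length", "Q", "Firing", "Qmax", "Theta", "Sigma",
                    "Q0", "V0", "Rho", "Clip", "Longside nodes")
stim_keys <- c("Kind", "Amplitude", "Frequency", "Onset", "Duration",
               "Period", "Nodes", "Seed")

num1 <- function(value, key) {
  x <- suppressWarnings(as.numeric(value))
  if (length(x) != 1 || is.na(x)) stop("cannot parse numeric value for `", key, "`: ", value)
  x
}

#' Parse a configuration
#'
#' @param text Character scalar (whole file) or vector of lines in the
#'   format of [conf-format].
#' @return A validated object of class `nf_config`.
#' @seealso [read_config()], [serialize_config()], [validate_physics()]
#' @export
parse_config <- function(text) {
  if (length(text) == 1 && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  if (length(text) == 0) stop("empty configuration")
  lines <- sub("\\s+$", "", text)

  first_global <- grep("^\\s*Time\\s*:", lines)
  if (length(first_global) == 0) stop("missing required key `Time`")
  first_global <- first_global[1]
  comment <- trim_trailing_blank(lines[seq_len(first_global - 1)])

  cfg <- list(comment = comment,
              time = NULL, dt = NULL, nodes = NULL, longside = NULL,
              seed = 0L, matrix = NULL, populations = list(),
              couplings = list(), propagators = list(),
              output = list(nodes = "all", start = 0, interval = NULL,
                            traces = character()))

  i <- first_global
  section <- "global"          # global | matrix | population | propagator | coupling | output
  sub_block <- NULL            # within a population: NULL | dendrite | stimulus
  cur_pop <- NULL; cur_label <- NULL
  matrix_rows <- list()

  flush_pop <- function() {
    if (!is.null(cur_pop)) cfg$populations[[cur_pop$index]] <<- cur_pop
  }

  while (i <= length(lines)) {
    line <- trimws(lines[i]); i <- i + 1
    if (nchar(line) == 0) next

    if (section == "matrix" && grepl("^[-0-9 ]+$", line)) {
      matrix_rows[[length(matrix_rows) + 1]] <-
        as.integer(strsplit(line, "\\s+")[[1]])
      next
    }

    m <- regmatches(line, regexec("^([A-Za-z][A-Za-z0-9_ ]*?)\\s*:\\s*(.*)$", line))[[1]]
    if (length(m) == 0) stop("cannot parse configuration line: ", line)
    key <- m[2]; value <- m[3]

    if (key == "Connection matrix") { flush_pop(); cur_pop <- NULL; section <- "matrix"; next }

    hm <- regmatches(key, regexec("^(Population|Dendrite|Stimulus|Propagator|Coupling)\\s+([0-9]+)$", key))[[1]]
    if (length(hm)) {
      block <- hm[2]; idx <- as.integer(hm[3])
      if (block == "Population") {
        flush_pop()
        cur_pop <- list(index = idx, type = value,
                        external = tolower(value) == "external",
                        length = NULL, longside = NULL, q0 = NULL,
                        firing = list(), dendrites = list(), stimuli = list())
        section <- "population"; sub_block <- NULL
      } else if (block == "Dendrite") {
        if (is.null(cur_pop)) stop("`Dendrite ", idx, "` outside a population block")
        cur_pop$dendrites[[as.character(idx)]] <- list(alpha = NULL, beta = NULL)
        sub_block <- c("dendrite", as.character(idx))
      } else if (block == "Stimulus") {
        if (is.null(cur_pop) || !cur_pop$external) {
          stop("`Stimulus ", idx, "` is only valid inside an External population block")
        }
        cur_pop$stimuli[[idx]] <- list()
        sub_block <- c("stimulus", idx)
      } else if (block == "Propagator") {
        flush_pop(); cur_pop <- NULL
        kind <- tolower(value)
        if (!kind %in% c("wave", "harmonic", "map")) {
          stop("unknown propagator kind `", value, "` for connection ", idx)
        }
        cfg$propagators[[as.character(idx)]] <-
          list(label = idx, kind = kind, tau = 0, range = NULL, gamma = NULL)
        cur_label <- as.character(idx); section <- "propagator"
      } else if (block == "Coupling") {
        flush_pop(); cur_pop <- NULL
        cfg$couplings[[as.character(idx)]] <- list(label = idx, nu = NULL)
        cur_label <- as.character(idx); section <- "coupling"
      }
      next
    }
    if (key == "Output") { flush_pop(); cur_pop <- NULL; section <- "output"; next }

    if (section == "global" || key %in% c("Time", "Deltat")) {
      switch(key,
        "Time" = { cfg$time <- num1(value, key) },
        "Deltat" = { cfg$dt <- num1(value, key) },
        "Nodes" = { cfg$nodes <- as.integer(num1(value, key)) },
        "Longside nodes" = { cfg$longside <- as.integer(num1(value, key)) },
        "Seed" = { cfg$seed <- as.integer(num1(value, key)) },
        stop("unknown global key `", key, "`")
      )
      next
    }

    if (section == "population") {
      if (!is.null(sub_block) && sub_block[1] == "dendrite" && key %in% c("alpha", "beta")) {
        cur_pop$dendrites[[sub_block[2]]][[key]] <- num1(value, key)
        next
      }
      if (!is.null(sub_block) && sub_block[1] == "stimulus") {
        k <- as.integer(sub_block[2])
        if (!key %in% stim_keys) stop("unknown stimulus key `", key, "`")
        cur_pop$stimuli[[k]][[tolower(key)]] <-
          if (key == "Kind") tolower(value)
          else if (key == "Nodes") as.integer(strsplit(value, "\\s+")[[1]])
          else num1(value, key)
        next
      }
      if (!key %in% pop_block_keys) stop("unknown population key `", key, "`")
      sub_block <- NULL
      switch(key,
        "Length" = { cur_pop$length <- num1(value, key) },
        "Longside nodes" = { cur_pop$longside <- as.integer(num1(value, key)) },
        "Q" = { cur_pop$q0 <- num1(value, key) },
        "Firing" = { cur_pop$firing$mode <- tolower(value) },
        "Qmax" = { cur_pop$firing$qmax <- num1(value, key) },
        "Theta" = { cur_pop$firing$theta <- num1(value, key) },
        "Sigma" = { cur_pop$firing$sigma <- num1(value, key) },
        "Q0" = { cur_pop$firing$q0 <- num1(value, key) },
        "V0" = { cur_pop$firing$v0 <- num1(value, key) },
        "Rho" = { cur_pop$firing$rho <- num1(value, key) },
        "Clip" = { cur_pop$firing$clip <- num1(value, key) != 0 }
      )
      next
    }

    if (section == "propagator") {
      pr <- cfg$propagators[[cur_label]]
      switch(key,
        "Tau" = { pr$tau <- num1(value, key) },
        "Range" = { pr$range <- num1(value, key) },
        "gamma" = { pr$gamma <- num1(value, key) },
        stop("unknown propagator key `", key, "`")
      )
      cfg$propagators[[cur_label]] <- pr
      next
    }

    if (section == "coupling") {
      if (key != "nu") stop("unknown coupling key `", key, "`")
      cfg$couplings[[cur_label]]$nu <- num1(value, key)
      next
    }

    if (section == "output") {
      switch(key,
        "Node" = {
          cfg$output$nodes <- if (tolower(value) == "all") "all"
                              else as.integer(strsplit(value, "\\s+")[[1]])
        },
        "Start" = { cfg$output$start <- num1(value, key) },
        "Interval" = { cfg$output$interval <- num1(value, key) },
        "Trace" = { cfg$output$traces <- c(cfg$output$traces, value) },
        stop("unknown output key `", key, "`")
      )
      next
    }
    stop("unexpected key `", key, "` in section `", section, "`")
  }
  flush_pop()

  if (length(matrix_rows)) {
    ncols <- unique(vapply(matrix_rows, length, integer(1)))
    if (length(ncols) != 1) stop("connection matrix rows have unequal lengths")
    cfg$matrix <- do.call(rbind, matrix_rows)
  }
  finalize_config(cfg)
}

trim_trailing_blank <- function(x) {
  while (length(x) && nchar(trimws(x[length(x)])) == 0) x <- x[-length(x)]
  x
}

#' @rdname parse_config
#' @param path Path to a `.conf` file.
#' @export
read_config <- function(path) {
  parse_config(readLines(path, warn = FALSE))
}

# Structural validation + derived fields (connection table, grid, stimuli).
finalize_config <- function(cfg) {
  for (key in c("time", "dt", "nodes")) {
    if (is.null(cfg[[key]])) {
      stop("missing required key `",
           c(time = "Time", dt = "Deltat", nodes = "Nodes")[key], "`")
    }
  }
  p <- length(cfg$populations)
  if (p == 0) stop("no populations defined")
  if (any(vapply(cfg$populations, is.null, logical(1)))) {
    stop("population indices must be consecutive starting at 1")
  }
  if (is.null(cfg$matrix)) stop("missing `Connection matrix` block")
  if (!all(dim(cfg$matrix) == c(p, p))) {
    stop("connection matrix is ", nrow(cfg$matrix), "x", ncol(cfg$matrix),
         " but there are ", p, " populations")
  }
  labels <- cfg$matrix[cfg$matrix != 0]
  nc <- length(labels)
  if (nc == 0) stop("connection matrix has no connections")
  if (!setequal(labels, seq_len(nc)) || anyDuplicated(labels)) {
    stop("connection labels must be the consecutive integers 1..",
         nc, ", each used once")
  }
  conn <- which(cfg$matrix != 0, arr.ind = TRUE)
  cfg$connections <- data.frame(
    label = cfg$matrix[conn],
    to = conn[, 1], from = conn[, 2]
  )
  cfg$connections <- cfg$connections[order(cfg$connections$label), , drop = FALSE]
  rownames(cfg$connections) <- NULL

  for (l in seq_len(nc)) {
    lab <- as.character(l)
    tgt <- cfg$connections$to[l]
    if (is.null(cfg$couplings[[lab]]) || is.null(cfg$couplings[[lab]]$nu)) {
      stop("connection ", l, " referenced in the matrix has no `Coupling ", l, "` block with `nu`")
    }
    pr <- cfg$propagators[[lab]]
    if (is.null(pr)) stop("connection ", l, " has no `Propagator ", l, "` block")
    if (pr$kind == "wave" && (is.null(pr$range) || is.null(pr$gamma))) {
      stop("wave propagator ", l, " needs `Range` and `gamma`")
    }
    if (pr$kind == "harmonic" && is.null(pr$gamma)) {
      stop("harmonic propagator ", l, " needs `gamma`")
    }
    pop <- cfg$populations[[tgt]]
    if (!pop$external && is.null(pop$dendrites[[lab]])) {
      stop("population ", tgt, " is the target of connection ", l,
           " but has no `Dendrite ", l, "` block")
    }
  }
  for (pi in seq_len(p)) {
    pop <- cfg$populations[[pi]]
    if (is.null(pop$length)) stop("population ", pi, " is missing `Length`")
    if (!pop$external) {
      fr <- pop$firing
      if (is.null(fr$mode)) stop("population ", pi, " is missing its `Firing` block")
      cfg$populations[[pi]]$firing <- if (fr$mode == "sigmoid") {
        nf_firing(fr$qmax, fr$theta, fr$sigma)
      } else if (fr$mode == "linear") {
        nf_firing_linear(fr$q0, fr$v0, fr$rho, isTRUE(fr$clip))
      } else stop("unknown firing mode `", fr$mode, "` in population ", pi)
      for (lab in names(pop$dendrites)) {
        d <- pop$dendrites[[lab]]
        if (is.null(d$alpha) || is.null(d$beta)) {
          stop("dendrite ", lab, " of population ", pi, " needs `alpha` and `beta`")
        }
        if (cfg$connections$to[as.integer(lab)] != pi) {
          stop("population ", pi, " declares `Dendrite ", lab,
               "` but connection ", lab, " does not target it")
        }
      }
    } else {
      cfg$populations[[pi]]$stimuli <- lapply(pop$stimuli, function(s) {
        if (is.null(s$kind)) stop("stimulus block in population ", pi, " is missing `Kind`")
        nf_stimulus(kind = s$kind,
                    amplitude = if (is.null(s$amplitude)) 0 else s$amplitude,
                    frequency = s$frequency,
                    onset = if (is.null(s$onset)) 0 else s$onset,
                    duration = if (is.null(s$duration)) Inf else s$duration,
                    period = s$period, nodes = s$nodes, seed = s$seed)
      })
    }
  }

  cfg$grids <- lapply(cfg$populations, function(pop) {
    nf_grid(cfg$nodes, pop$length,
            longside = if (!is.null(pop$longside)) pop$longside else cfg$longside)
  })

  out <- cfg$output
  if (is.null(out$interval)) out$interval <- cfg$dt
  k <- out$interval / cfg$dt
  if (abs(k - round(k)) > 1e-6 * max(1, k)) {
    stop("`Interval` (", out$interval, ") must be an integer multiple of `Deltat` (",
         cfg$dt, ")")
  }
  out$k <- as.integer(round(k))
  if (out$start > cfg$time) {
    stop("output `Start` (", out$start, ") cannot be larger than `Time` (", cfg$time, ")")
  }
  if (!identical(out$nodes, "all")) {
    if (any(out$nodes < 1 | out$nodes > cfg$nodes)) {
      stop("output `Node` indices must be within 1..", cfg$nodes)
    }
  }
  for (tr in out$traces) parse_trace(tr, cfg)
  cfg$output <- out
  structure(cfg, class = "nf_config")
}

# "Population.2.Q" -> list(object, index, quantity); validates the reference.
parse_trace <- function(trace, cfg) {
  parts <- strsplit(trace, ".", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("malformed trace `", trace, "`")
  obj <- parts[1]; idx <- as.integer(parts[2]); qty <- parts[3]
  ok <- switch(obj,
    Population = idx >= 1 && idx <= length(cfg$populations) && qty %in% c("Q", "V"),
    Propagator = idx >= 1 && idx <= nrow(cfg$connections) && qty == "phi",
    Coupling = idx >= 1 && idx <= nrow(cfg$connections) && qty == "nu",
    FALSE)
  if (!isTRUE(ok)) stop("trace `", trace, "` does not reference an existing object/quantity")
  if (obj == "Population" && qty == "V" && cfg$populations[[idx]]$external) {
    stop("trace `", trace, "`: external populations have no soma potential")
  }
  list(object = obj, index = idx, quantity = qty)
}

#' Serialize a configuration to text
#'
#' Writes the canonical form of the [conf-format]; parsing the result gives
#' back a semantically identical configuration, and serialization is
#' deterministic.
#'
#' @param cfg An `nf_config`.
#' @return Character vector of lines.
#' @export
serialize_config <- function(cfg) {
  stopifnot(inherits(cfg, "nf_config"))
  num <- function(x) formatC(x, format = "g", digits = 17)
  out <- character()
  if (length(cfg$comment)) out <- c(cfg$comment, "")
  out <- c(out,
           paste0("Time: ", num(cfg$time)),
           paste0("Deltat: ", num(cfg$dt)),
           paste0("Nodes: ", cfg$nodes))
  if (!is.null(cfg$longside)) out <- c(out, paste0("Longside nodes: ", cfg$longside))
  out <- c(out, paste0("Seed: ", cfg$seed), "", "Connection matrix:")
  out <- c(out, apply(cfg$matrix, 1, paste, collapse = " "), "")

  for (pi in seq_along(cfg$populations)) {
    pop <- cfg$populations[[pi]]
    out <- c(out, paste0("Population ", pi, ": ", pop$type),
             paste0("Length: ", num(pop$length)))
    if (!is.null(pop$longside)) out <- c(out, paste0("Longside nodes: ", pop$longside))
    if (!is.null(pop$q0)) out <- c(out, paste0("Q: ", num(pop$q0)))
    if (!pop$external) {
      fr <- pop$firing
      if (fr$mode == "sigmoid") {
        out <- c(out, "Firing: Sigmoid",
                 paste0("Qmax: ", num(fr$qmax)),
                 paste0("Theta: ", num(fr$theta)),
                 paste0("Sigma: ", num(fr$sigma)))
      } else {
        out <- c(out, "Firing: Linear",
                 paste0("Q0: ", num(fr$q0)),
                 paste0("V0: ", num(fr$v0)),
                 paste0("Rho: ", num(fr$rho)),
                 paste0("Clip: ", as.integer(fr$clip)))
      }
      for (lab in as.character(sort(as.integer(names(pop$dendrites))))) {
        d <- pop$dendrites[[lab]]
        out <- c(out, paste0("Dendrite ", lab, ":"),
                 paste0("alpha: ", num(d$alpha)),
                 paste0("beta: ", num(d$beta)))
      }
    } else {
      for (k in seq_along(pop$stimuli)) {
        s <- pop$stimuli[[k]]
        out <- c(out, paste0("Stimulus ", k, ":"),
                 paste0("Kind: ", tools::toTitleCase(s$kind)),
                 paste0("Amplitude: ", num(s$amplitude)))
        if (!is.null(s$frequency)) out <- c(out, paste0("Frequency: ", num(s$frequency)))
        if (s$onset != 0) out <- c(out, paste0("Onset: ", num(s$onset)))
        if (is.finite(s$duration)) out <- c(out, paste0("Duration: ", num(s$duration)))
        if (!is.null(s$period) && is.finite(s$period)) {
          out <- c(out, paste0("Period: ", num(s$period)))
        }
        if (!is.null(s$nodes)) out <- c(out, paste0("Nodes: ", paste(s$nodes, collapse = " ")))
        if (!is.null(s$seed)) out <- c(out, paste0("Seed: ", s$seed))
      }
    }
    out <- c(out, "")
  }

  for (lab in as.character(seq_len(nrow(cfg$connections)))) {
    pr <- cfg$propagators[[lab]]
    out <- c(out, paste0("Propagator ", lab, ": ", tools::toTitleCase(pr$kind)),
             paste0("Tau: ", num(pr$tau)))
    if (pr$kind == "wave") out <- c(out, paste0("Range: ", num(pr$range)))
    if (pr$kind %in% c("wave", "harmonic")) out <- c(out, paste0("gamma: ", num(pr$gamma)))
    out <- c(out, "")
  }
  for (lab in as.character(seq_len(nrow(cfg$connections)))) {
    out <- c(out, paste0("Coupling ", lab, ":"),
             paste0("nu: ", num(cfg$couplings[[lab]]$nu)), "")
  }

  out <- c(out, "Output:",
           paste0("Node: ", if (identical(cfg$output$nodes, "all")) "All"
                  else paste(cfg$output$nodes, collapse = " ")),
           paste0("Start: ", num(cfg$output$start)),
           paste0("Interval: ", num(cfg$output$interval)))
  for (tr in cfg$output$traces) out <- c(out, paste0("Trace: ", tr))
  out
}

#' @export
print.nf_config <- function(x, ...) {
  cat(sprintf("<nf_config> %d population(s), %d connection(s), %d nodes, Time %g s, Deltat %g s\n",
              length(x$populations), nrow(x$connections), x$nodes, x$time, x$dt))
  invisible(x)
}

#' Physical validation of a configuration
#'
#' Beyond structural parsing, checks the numerical-physics contracts:
#' the Courant condition over all wave propagators (hard error above
#' `1/sqrt(2)`, margin warning above 0.15), `beta >= alpha` for every
#' dendrite (swapped with a warning otherwise, the biexponential kernel
#' being symmetric under exchange), `Start <= Time`, and `gamma * dt <= 0.1`
#' for wave propagators (warning: the exponential substitution of the
#' scheme assumes a small step).
#'
#' @param cfg An `nf_config`.
#' @return The (possibly repaired) configuration, invisibly; diagnostics are
#'   raised as conditions naming the offending block.
#' @export
validate_physics <- function(cfg) {
  stopifnot(inherits(cfg, "nf_config"))
  prs <- lapply(cfg$propagators, function(pr) pr)
  dxs <- vapply(seq_len(nrow(cfg$connections)), function(l) {
    src <- cfg$connections$from[l]
    cfg$grids[[src]]$dx
  }, numeric(1))
  check_stability(prs[as.character(seq_len(nrow(cfg$connections)))], cfg$dt, dxs)
  for (pr in cfg$propagators) {
    if (pr$kind %in% c("wave", "harmonic") && pr$gamma * cfg$dt > 0.1) {
      warning("propagator ", pr$label, ": gamma * Deltat = ",
              signif(pr$gamma * cfg$dt, 3), " > 0.1; the step is too coarse for the damping rate")
    }
  }
  for (pi in seq_along(cfg$populations)) {
    pop <- cfg$populations[[pi]]
    if (pop$external) next
    for (lab in names(pop$dendrites)) {
      d <- pop$dendrites[[lab]]
      if (d$beta < d$alpha) {
        warning("dendrite ", lab, " of population ", pi, ": beta < alpha; swapping (the kernel is symmetric in alpha, beta)")
        cfg$populations[[pi]]$dendrites[[lab]] <- list(alpha = d$beta, beta = d$alpha)
      }
    }
  }
  if (cfg$output$start > cfg$time) {
    stop("output `Start` exceeds `Time`")
  }
  invisible(cfg)
}
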