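#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation result
#'
#' One row per (time, trace, node) with the recorded value — the long form
#' used by dplyr/ggplot2 workflows.
#'
#' @param x An `nf_output`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `trace`, `node`, `value`.
#' @method tidy nf_output
#' @export
tidy.nf_output <- function(x, ...) {
  if (ncol(x$data) == 0) {
    return(tibble::tibble(time = x$times, trace = character(length(x$times)),
                          node = integer(length(x$times)),
                          value = numeric(length(x$times)))[0, ])
  }
  tibble::tibble(
    time = rep(x$times, times = ncol(x$data)),
    trace = rep(x$labels, each = length(x$times)),
    node = rep(x$nodes, each = length(x$times)),
    value = as.vector(x$data)
  )
}

#' One-row summary of a simulation result
#'
#' @param x An `nf_output`.
#' @param ... Unused.
#' @return A tibble with sampling and size metadata.
#' @method glance nf_output
#' @export
glance.nf_output <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$times),
    n_columns = ncol(x$data),
    n_traces = length(unique(x$labels)),
    n_nodes = length(unique(x$nodes)),
    start = if (length(x$times)) min(x$times) else NA_real_,
    end = if (length(x$times)) max(x$times) else NA_real_,
    interval = x$config$output$interval,
    dt = x$config$dt
  )
}

#' @export
as.data.frame.nf_output <- function(x, ...) as.data.frame(tidy(x))

#' Tidy a spectrum
#'
#' @param x An `nf_spectrum`.
#' @param ... Unused.
#' @return A tibble with columns `frequency` (Hz) and `power`.
#' @method tidy nf_spectrum
#' @export
tidy.nf_spectrum <- function(x, ...) {
  tibble::tibble(frequency = x$frequencies, power = x$power)
}

#' One-row summary of a spectrum
#'
#' @param x An `nf_spectrum`.
#' @param ... Unused.
#' @return A tibble with estimator metadata and total power.
#' @method glance nf_spectrum
#' @export
glance.nf_spectrum <- function(x, ...) {
  df <- if (length(x$frequencies) > 1) diff(x$frequencies[1:2]) else NA_real_
  tibble::tibble(
    n_frequencies = length(x$frequencies),
    df = df,
    total_power = sum(x$power) * df,
    estimator = if (!is.null(x$method$analytic) && isTRUE(x$method$analytic))
      "analytic" else x$method$estimator
  )
}

#' Plot recorded timeseries
#'
#' Lines of every recorded node, one facet per trace.
#'
#' @param object An `nf_output`.
#' @param traces Optional subset of trace labels.
#' @param nodes Optional subset of node indices.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nf_output
#' @export
autoplot.nf_output <- function(object, traces = NULL, nodes = NULL, ...) {
  df <- tidy(object)
  if (!is.null(traces)) df <- dplyr::filter(df, .data$trace %in% traces)
  if (!is.null(nodes)) df <- dplyr::filter(df, .data$node %in% nodes)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   group = .data$node,
                                   colour = factor(.data$node))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~trace, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "value (SI)", colour = "node") +
    ggplot2::theme_minimal()
}

#' Plot a power spectrum
#'
#' @param object An `nf_spectrum`.
#' @param ... Unused.
#' @return A ggplot object with log10 axes.
#' @method autoplot nf_spectrum
#' @export
autoplot.nf_spectrum <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$frequency > 0, .data$power > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "power (signal² Hz⁻¹)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
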