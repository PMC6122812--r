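#' Extract timeseries from a simulation result
#'
#' Selects the columns of one recorded trace at chosen nodes, keeping the
#' recording order.
#'
#' @param output An `nf_output`.
#' @param trace Trace label, e.g. `"Propagator.1.phi"`.
#' @param nodes Node subset; default all recorded nodes for the trace.
#' @return A tibble with a `time` column and one `node_<n>` column per
#'   selected node.
#' @export
nf_extract <- function(output, trace, nodes = NULL) {
  stopifnot(inherits(output, "nf_output"))
  sel <- output$labels == trace
  if (!any(sel)) {
    stop("trace `", trace, "` not in output (has: ",
         paste(unique(output$labels), collapse = ", "), ")")
  }
  have <- output$nodes[sel]
  if (is.null(nodes)) nodes <- have
  if (length(nodes) == 0) stop("empty node selection")
  missing <- setdiff(nodes, have)
  if (length(missing)) {
    stop("node(s) ", paste(missing, collapse = ", "), " not recorded for `", trace, "`")
  }
  cols <- which(sel)[match(nodes, have)]
  out <- tibble::as_tibble(
    stats::setNames(as.data.frame(output$data[, cols, drop = FALSE]),
                    paste0("node_", nodes)))
  dplyr::bind_cols(tibble::tibble(time = output$times), out)
}

#' Reshape a full-grid trace into a (time, nx, ny) array
#'
#' Requires the trace to have been recorded at all N nodes. Node n maps to
#' cell `(1 + (n-1) %% nx, 1 + (n-1) %/% nx)`, the same layout as
#' [as_field()]; flattening the array restores the recorded columns
#' exactly.
#'
#' @inheritParams nf_extract
#' @return Numeric array with dimensions (time, nx, ny).
#' @export
nf_to_grid <- function(output, trace) {
  stopifnot(inherits(output, "nf_output"))
  grid <- output$config$grids[[1]]
  sel <- output$labels == trace
  if (!any(sel)) stop("trace `", trace, "` not in output")
  have <- output$nodes[sel]
  if (!setequal(have, seq_len(grid$n)) || length(have) != grid$n) {
    stop("trace `", trace, "` does not cover the full grid (",
         length(have), " of ", grid$n, " nodes)")
  }
  cols <- which(sel)[match(seq_len(grid$n), have)]
  arr <- output$data[, cols, drop = FALSE]
  dim(arr) <- c(length(output$times), grid$nx, grid$ny)
  arr
}

hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

# Welch one-sided PSD of the columns of `x` (columns may be complex).
# Returns frequencies and a matrix (freq x column) of per-Hz power.
welch_psd_matrix <- function(x, fs, seg_len, overlap = 0.5, demean = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- hann(seg_len)
  u <- mean(w^2)
  nf <- seg_len %/% 2 + 1L
  acc <- matrix(0, nrow = nf, ncol = ncol(x))
  for (s in starts) {
    seg <- x[s + seq_len(seg_len) - 1L, , drop = FALSE]
    if (demean) seg <- sweep(seg, 2, colMeans(seg))
    seg <- seg * w
    ft <- stats::mvfft(seg)
    pow <- Mod(ft)^2 / (fs * seg_len * u)           # two-sided per-Hz
    one <- pow[seq_len(nf), , drop = FALSE]
    # fold negative frequencies onto positive (skip DC and, if present, Nyquist)
    hi <- seq(seg_len, seg_len - (nf - 2L) + if (seg_len %% 2 == 0) 1L else 0L)
    if (length(hi)) {
      rows <- 1L + seq_along(hi)
      one[rows, ] <- one[rows, ] + pow[hi, , drop = FALSE]
    }
    acc <- acc + one
  }
  list(frequencies = (seq_len(nf) - 1L) * fs / seg_len,
       power = acc / length(starts),
       segments = length(starts), seg_len = seg_len)
}

#' Welch temporal power spectrum
#'
#' One-sided power spectral density of a timeseries, estimated by averaging
#' Hann-windowed, 50%-overlapping segment periodograms (default segment
#' length: 4 s of samples). Normalization is per Hz, so for a
#' zero-mean stationary signal the integral of the PSD over frequency
#' approximates the variance (Parseval). No demeaning is applied: a
#' constant series shows its power at f = 0.
#'
#' @param x Numeric vector, matrix (columns averaged after estimation), or
#'   a tibble from [nf_extract()] (its `time` column sets `fs`).
#' @param fs Sampling frequency (Hz); inferred from a `time` column when
#'   omitted.
#' @param seg_seconds Segment length in seconds.
#' @param overlap Fractional segment overlap.
#' @param demean Subtract each segment's mean before windowing?
#' @return An `nf_spectrum` object: tibble-convertible, with fields
#'   `frequencies` (Hz), `power` (signal^2 Hz^-1) and estimator metadata.
#' @export
nf_spectrum <- function(x, fs = NULL, seg_seconds = 4, overlap = 0.5,
                        demean = FALSE) {
  if (is.data.frame(x)) {
    if (is.null(fs)) {
      if (!"time" %in% names(x)) stop("supply `fs` or a `time` column")
      fs <- 1 / stats::median(diff(x$time))
    }
    x <- as.matrix(x[setdiff(names(x), "time")])
  }
  if (is.null(fs)) stop("supply the sampling frequency `fs`")
  x <- as.matrix(x)
  seg_len <- as.integer(round(seg_seconds * fs))
  if (nrow(x) < 2) stop("series too short for spectral estimation")
  est <- welch_psd_matrix(x, fs, seg_len, overlap, demean = demean)
  structure(
    list(frequencies = est$frequencies,
         power = rowMeans(est$power),
         method = list(estimator = "welch", window = "hann",
                       seg_len = est$seg_len, overlap = overlap,
                       segments = est$segments, fs = fs,
                       n_series = ncol(x))),
    class = "nf_spectrum"
  )
}

#' Spatial wavenumber grid of a periodic sheet
#'
#' The discrete modes supported by the periodic box: `k_m = 2 pi m / L`
#' with integer `m` in the FFT order (`0, 1, ..., -1`) for each axis.
#'
#' @param grid An [nf_grid()].
#' @return List with vectors `kx`, `ky` (m^-1) and the matrix `k2` of
#'   squared magnitudes, nx-by-ny in FFT layout.
#' @export
nf_wavenumbers <- function(grid) {
  fft_freqs <- function(n, l) {
    m <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
    2 * pi * m / l
  }
  kx <- fft_freqs(grid$nx, grid$lx)
  ky <- fft_freqs(grid$ny, grid$ly)
  list(kx = kx, ky = ky, k2 = outer(kx^2, ky^2, `+`))
}

#' Wavenumber-summed spatial power spectrum
#'
#' Decomposes a full-grid trace into the periodic box's spatial Fourier
#' modes, Welch-estimates the temporal PSD of each complex mode amplitude,
#' and returns the sum over modes `P(f) = sum_k P(k, f) F(k)`. The optional
#' filter `F(k) = exp(-k^2 / k0^2)` models volume conduction between cortex
#' and scalp; with `k0 = NULL` (e.g. intracranial signals) no filtering is
#' applied and, for a node-resolved stationary field, `P(f)` equals the
#' node-averaged temporal spectrum. A spatially uniform signal has only its
#' k = 0 mode and reproduces [nf_spectrum()] exactly.
#'
#' @inheritParams nf_to_grid
#' @param k0 Volume-conduction cutoff wavenumber (m^-1), or `NULL` for no
#'   filtering.
#' @param seg_seconds,overlap,demean Welch parameters, as in
#'   [nf_spectrum()].
#' @return An `nf_spectrum` with an extra `k` field (the mode grid) and
#'   `power_k` (frequency x mode matrix, columns in FFT order).
#' @export
nf_spatial_spectrum <- function(output, trace, k0 = NULL, seg_seconds = 4,
                                overlap = 0.5, demean = FALSE) {
  grid <- output$config$grids[[1]]
  arr <- nf_to_grid(output, trace)
  nt <- dim(arr)[1]
  fs <- 1 / output$config$output$interval
  # spatial FFT per time sample; mode amplitudes normalized by N so the
  # k = 0 mode is the spatial mean
  flat <- matrix(arr, nrow = nt)
  modes <- matrix(0 + 0i, nrow = nt, ncol = grid$n)
  for (t in seq_len(nt)) {
    modes[t, ] <- as.vector(stats::fft(matrix(flat[t, ], grid$nx, grid$ny))) / grid$n
  }
  seg_len <- as.integer(round(seg_seconds * fs))
  est <- welch_psd_matrix(modes, fs, seg_len, overlap, demean = demean)
  kk <- nf_wavenumbers(grid)
  filt <- if (is.null(k0)) rep(1, grid$n) else as.vector(exp(-kk$k2 / k0^2))
  structure(
    list(frequencies = est$frequencies,
         power = as.vector(est$power %*% filt),
         power_k = est$power,
         k = kk,
         method = list(estimator = "welch", window = "hann",
                       seg_len = est$seg_len, overlap = overlap,
                       segments = est$segments, fs = fs, k0 = k0)),
    class = "nf_spectrum"
  )
}

#' @export
print.nf_spectrum <- function(x, ...) {
  cat(sprintf("<nf_spectrum> %d frequencies in [%g, %g] Hz (%s, %d segment(s) of %d samples)\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              x$method$estimator, x$method$segments, x$method$seg_len))
  invisible(x)
}

#' Band-averaged power
#'
#' Mean PSD over `band = c(lo, hi)` Hz, the summary used when comparing
#' simulated and analytic spectra.
#'
#' @param spectrum An `nf_spectrum`.
#' @param band Length-2 numeric frequency band (Hz), inclusive.
#' @return Scalar mean power in the band.
#' @export
band_average <- function(spectrum, band) {
  sel <- spectrum$frequencies >= band[1] & spectrum$frequencies <= band[2]
  if (!any(sel)) stop("no frequency bins inside the band")
  mean(spectrum$power[sel])
}

#' Textual summary of a simulation result
#'
#' @param output An `nf_output`.
#' @return A character vector (also printed), one line per reported fact.
#' @export
nf_report <- function(output) {
  stopifnot(inherits(output, "nf_output"))
  cfg <- output$config
  lines <- c(
    sprintf("populations: %d (%d internal)", length(cfg$populations),
            sum(!vapply(cfg$populations, `[[`, logical(1), "external"))),
    sprintf("connections: %d", nrow(cfg$connections)),
    sprintf("grid: %d nodes (%d x %d), dx = %g m",
            cfg$grids[[1]]$n, cfg$grids[[1]]$nx, cfg$grids[[1]]$ny, cfg$grids[[1]]$dx),
    sprintf("time: %g s at dt = %g s; output every %g s from t = %g s",
            cfg$time, cfg$dt, cfg$output$interval, cfg$output$start),
    sprintf("samples: %d x %d columns (%s)", length(output$times), ncol(output$data),
            paste(unique(output$labels), collapse = ", ")))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Write a spectrum as CSV
#'
#' Two columns, `frequency` (Hz) and `power`, one row per bin.
#'
#' @param spectrum An `nf_spectrum`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "nf_spectrum"))
  utils::write.csv(tidy(spectrum), path, row.names = FALSE)
  invisible(path)
}
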