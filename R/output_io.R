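#' Write a simulation result as a plain-text output file
#'
#' The file is self-describing: the full configuration is echoed at the top
#' (so results are reproducible from the output alone), followed by a line
#' of `=` characters, a label line naming each timeseries column, a line of
#' node indices, and one row per sample with the time (seconds) in the
#' first column. Values are scientific notation with nine significant
#' digits, in SI units without prefixes.
#'
#' @param output An `nf_output` from [run_nf()].
#' @param path File path, or `""` to return the lines invisibly only.
#' @return Invisibly, the character vector of lines written.
#' @export
write_output <- function(output, path = "") {
  stopifnot(inherits(output, "nf_output"))
  header <- c(output$config_text,
              strrep("=", 72),
              paste(c("Time", output$labels), collapse = " "),
              paste(c("-", output$nodes), collapse = " "))
  if (ncol(output$data)) {
    body <- vapply(seq_along(output$times), function(i) {
      paste(sprintf("%.8e", c(output$times[i], output$data[i, ])), collapse = " ")
    }, character(1))
  } else {
    body <- sprintf("%.8e", output$times)
  }
  lines <- c(header, body)
  if (nzchar(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a plain-text output file
#'
#' Splits on the `=` separator, re-parses the embedded configuration echo,
#' and returns the same structure [run_nf()] produces.
#'
#' @param x Path to an output file, or a character vector of its lines.
#' @return An `nf_output`.
#' @export
read_output <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x, warn = FALSE) else x
  sep <- which(grepl("^=+$", lines) & nchar(lines) >= 4)
  if (length(sep) == 0) stop("not an output file: missing `=` separator line")
  sep <- sep[1]
  cfg <- parse_config(lines[seq_len(sep - 1)])
  if (length(lines) < sep + 2) stop("output file truncated: missing header lines")
  labels <- strsplit(trimws(lines[sep + 1]), "\\s+")[[1]]
  nodes <- strsplit(trimws(lines[sep + 2]), "\\s+")[[1]]
  if (labels[1] != "Time") stop("malformed label line (expected leading `Time`)")
  labels <- labels[-1]
  nodes <- suppressWarnings(as.integer(nodes[-1]))
  body <- lines[seq(sep + 3, length(lines))]
  body <- body[nzchar(trimws(body))]
  rows <- strsplit(trimws(body), "\\s+")
  widths <- lengths(rows)
  expected <- length(labels) + 1L
  if (any(widths != expected)) {
    bad <- which(widths != expected)[1]
    stop("ragged data row at line ", sep + 2L + bad, ": expected ",
         expected, " values, found ", widths[bad])
  }
  mat <- matrix(as.numeric(unlist(rows)), ncol = expected, byrow = TRUE)
  if (anyNA(mat)) stop("non-numeric value in data rows")
  structure(
    list(config = cfg, config_text = serialize_config(cfg),
         labels = labels, nodes = nodes,
         times = mat[, 1], data = mat[, -1, drop = FALSE],
         steady = NULL),
    class = "nf_output"
  )
}

#' Command-line entry point
#'
#' Runs a simulation from a configuration file, as
#' `neurofield -i model.conf [-o model.output] [-t] [-s seed] [-q]`.
#' Without `-o` the output path is the input name with its extension
#' replaced by `.output`; `-t` appends an ISO 8601 `_YYYY-MM-DDTHHMMSS`
#' timestamp to the name. Progress and the maximum Courant number are
#' logged to standard error unless `-q` is given.
#'
#' @param args Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit status (0 on success), invisibly.
#' @export
nf_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: neurofield -i <model.conf> [-o <model.output>] [-t] [-s <seed>] [-q]",
    "  -i  input configuration file (required)",
    "  -o  output file (default: input name with extension .output)",
    "  -t  append an ISO 8601 _YYYY-MM-DDTHHMMSS timestamp to the output name",
    "  -s  override the configuration's RNG seed",
    "  -q  quiet (no progress logging)",
    sep = "\n")
  input <- NULL; output <- NULL; timestamp <- FALSE; seed <- NULL; quiet <- FALSE
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (a == "-i") { input <- args[i + 1]; i <- i + 2 }
    else if (a == "-o") { output <- args[i + 1]; i <- i + 2 }
    else if (a == "-t") { timestamp <- TRUE; i <- i + 1 }
    else if (a == "-s") { seed <- as.integer(args[i + 1]); i <- i + 2 }
    else if (a == "-q") { quiet <- TRUE; i <- i + 1 }
    else {
      message("unknown argument: ", a, "\n", usage)
      return(invisible(2L))
    }
  }
  if (is.null(input) || is.na(input)) {
    message(usage)
    return(invisible(2L))
  }
  status <- tryCatch({
    if (!file.exists(input)) stop("input file not found: ", input)
    cfg <- read_config(input)
    if (is.null(output)) {
      output <- paste0(tools::file_path_sans_ext(input), ".output")
    }
    if (timestamp) {
      stamp <- format(Sys.time(), "_%Y-%m-%dT%H%M%S")
      output <- paste0(tools::file_path_sans_ext(output), stamp, ".output")
    }
    res <- run_nf(cfg, seed = seed, verbose = !quiet)
    write_output(res, output)
    if (!quiet) message("neurofield: wrote ", output)
    0L
  }, error = function(e) {
    message("neurofield: error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
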