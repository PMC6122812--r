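make_small_output <- function() {
  cfg <- single_e_config(kind = "map", time = 0.02, dt = 1e-3,
                         interval = 1e-3, out_nodes = "1 3",
                         traces = c("Population.1.Q", "Propagator.1.phi"))
  run_nf(cfg)
}

test_that("output files carry the config echo, separator, labels, nodes and time-first rows", {
  out <- make_small_output()
  lines <- write_output(out)
  sep <- which(grepl("^=+$", lines))
  expect_length(sep, 1)
  expect_equal(lines[seq_len(sep - 1)], out$config_text)   # full echo
  labels <- strsplit(lines[sep + 1], "\\s+")[[1]]
  expect_equal(labels[1], "Time")
  expect_equal(labels[-1], out$labels)
  nodes <- strsplit(lines[sep + 2], "\\s+")[[1]]
  expect_equal(as.integer(nodes[-1]), out$nodes)
  first_row <- as.numeric(strsplit(lines[sep + 3], "\\s+")[[1]])
  expect_equal(first_row[1], out$times[1])
})

test_that("write/read round-trips times, labels, node indices and data", {
  out <- make_small_output()
  path <- withr::local_tempfile(fileext = ".output")
  write_output(out, path)
  back <- read_output(path)
  expect_equal(back$labels, out$labels)
  expect_equal(back$nodes, out$nodes)
  expect_equal(back$times, out$times, tolerance = 1e-8)
  expect_equal(back$data, out$data, tolerance = 1e-8)
  # the embedded config reparses to the same text
  expect_identical(serialize_config(back$config), out$config_text)
})

test_that("requested traces map to one column per trace and node", {
  cfg <- single_e_config(kind = "map", time = 0.01, dt = 1e-3,
                         interval = 1e-3, out_nodes = "2",
                         traces = c("Population.1.Q", "Propagator.1.phi"))
  out <- run_nf(cfg)
  lines <- write_output(out)
  sep <- which(grepl("^=+$", lines))
  row <- strsplit(lines[sep + 3], "\\s+")[[1]]
  expect_length(row, 3)                    # time + Q + phi at one node
  expect_equal(ncol(out$data), 2)
})

test_that("zero requested traces leave header plus a bare time column", {
  cfg <- single_e_config(kind = "map", time = 0.01, dt = 1e-3,
                         interval = 1e-3)
  cfg$output$traces <- character()
  out <- run_nf(cfg)
  expect_equal(ncol(out$data), 0)
  lines <- write_output(out)
  sep <- which(grepl("^=+$", lines))
  expect_equal(trimws(lines[sep + 1]), "Time")
  expect_length(strsplit(lines[sep + 3], "\\s+")[[1]], 1)
})

test_that("the recorded sampling grid matches Interval", {
  cfg <- parse_config(c("sampling grid", "Time: 0.05",
                        "Deltat: 6.103515625e-05", "Nodes: 4",
                        "Connection matrix:", "1 2", "0 0",
                        "Population 1: Excitatory", "Length: 0.1",
                        sigmoid_lines,
                        "Dendrite 1:", "alpha: 45", "beta: 185",
                        "Dendrite 2:", "alpha: 45", "beta: 185",
                        "Population 2: External", "Length: 0.1",
                        "Stimulus 1:", "Kind: Const", "Amplitude: 1",
                        "Propagator 1: Map", "Tau: 0",
                        "Propagator 2: Map", "Tau: 0",
                        "Coupling 1:", "nu: 1e-4", "Coupling 2:", "nu: 1e-4",
                        "Output:", "Node: 1", "Start: 0",
                        "Interval: 1.953125e-3", "Trace: Population.1.Q"))
  out <- run_nf(cfg)
  back <- read_output(write_output(out))
  expect_equal(unique(round(diff(back$times), 12)), 1 / 512)
})

test_that("malformed output files are rejected with a line reference", {
  out <- make_small_output()
  lines <- write_output(out)
  expect_error(read_output(lines[!grepl("^=+$", lines)]), "separator")
  truncated <- lines
  truncated[length(truncated)] <-
    sub("\\s+\\S+$", "", truncated[length(truncated)])
  expect_error(read_output(truncated), "line [0-9]+")
})

test_that("the command line runs a config and names outputs as documented", {
  dir <- withr::local_tempdir()
  conf <- file.path(dir, "m.conf")
  cfg <- single_e_config(kind = "map", time = 0.01, dt = 1e-3, interval = 1e-3)
  writeLines(serialize_config(cfg), conf)

  expect_equal(nf_cli(c("-i", conf, "-q")), 0L)
  expect_true(file.exists(file.path(dir, "m.output")))
  back <- read_output(file.path(dir, "m.output"))
  expect_equal(length(back$times), 11)

  expect_equal(nf_cli(c("-i", conf, "-o", file.path(dir, "named.output"),
                        "-q")), 0L)
  expect_true(file.exists(file.path(dir, "named.output")))

  expect_equal(nf_cli(c("-i", conf, "-t", "-q")), 0L)
  stamped <- list.files(dir, pattern = "^m_\\d{4}-\\d{2}-\\d{2}T\\d{6}\\.output$")
  expect_length(stamped, 1)

  expect_equal(suppressMessages(nf_cli(character())), 2L)
  expect_equal(suppressMessages(nf_cli(c("-i", file.path(dir, "absent.conf"),
                                         "-q"))), 1L)
})
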