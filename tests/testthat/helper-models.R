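# Small configuration builders shared across tests. All are built as text so
# the dialect parser is on the hot path of every test that uses them.

sigmoid_lines <- c("Firing: Sigmoid", "Qmax: 340", "Theta: 0.01292",
                   "Sigma: 0.0038")

# Single excitatory population with a self-connection of the given kind and
# an external population delivering `stim_lines`.
single_e_config <- function(kind = "map", nu_self = 2e-5, nu_ext = 2e-5,
                            stim_lines = c("Stimulus 1:", "Kind: Const",
                                           "Amplitude: 10"),
                            nodes = 16, length = 0.5, dt = 1e-4, time = 0.1,
                            interval = dt, out_nodes = "1",
                            traces = c("Population.1.Q", "Propagator.1.phi"),
                            tau = 0, gamma = 30, range = 0.2, start = 0,
                            extra_prop = character()) {
  prop1 <- switch(kind,
    map = c("Propagator 1: Map", paste0("Tau: ", tau)),
    wave = c("Propagator 1: Wave", paste0("Tau: ", tau),
             paste0("Range: ", range), paste0("gamma: ", gamma)),
    harmonic = c("Propagator 1: Harmonic", paste0("Tau: ", tau),
                 paste0("gamma: ", gamma)))
  txt <- c("single excitatory population test model",
           paste0("Time: ", time), paste0("Deltat: ", dt),
           paste0("Nodes: ", nodes), "Seed: 0",
           "Connection matrix:", "1 2", "0 0",
           "Population 1: Excitatory", paste0("Length: ", length),
           sigmoid_lines,
           "Dendrite 1:", "alpha: 45", "beta: 185",
           "Dendrite 2:", "alpha: 45", "beta: 185",
           "Population 2: External", paste0("Length: ", length),
           stim_lines,
           prop1, extra_prop,
           "Propagator 2: Map", "Tau: 0",
           "Coupling 1:", paste0("nu: ", nu_self),
           "Coupling 2:", paste0("nu: ", nu_ext),
           "Output:", paste0("Node: ", out_nodes),
           paste0("Start: ", start), paste0("Interval: ", interval),
           paste0("Trace: ", traces))
  parse_config(txt)
}

# Two internal populations chained x -> 1 -> 2, all map propagators, with a
# delay tau on the 1 -> 2 connection.
chain_config <- function(tau = 0.005, dt = 1e-3, time = 0.2,
                         stim_lines = c("Stimulus 1:", "Kind: Const",
                                        "Amplitude: 10",
                                        "Stimulus 2:", "Kind: Sine",
                                        "Amplitude: 2", "Frequency: 10")) {
  parse_config(c(
    "two-population chain with delayed second hop",
    paste0("Time: ", time), paste0("Deltat: ", dt), "Nodes: 4", "Seed: 0",
    "Connection matrix:", "0 0 1", "2 0 0", "0 0 0",
    "Population 1: Excitatory", "Length: 0.1", sigmoid_lines,
    "Dendrite 1:", "alpha: 45", "beta: 185",
    "Population 2: Excitatory", "Length: 0.1", sigmoid_lines,
    "Dendrite 2:", "alpha: 45", "beta: 185",
    "Population 3: External", "Length: 0.1", stim_lines,
    "Propagator 1: Map", "Tau: 0",
    paste0("Propagator 2: Map"), paste0("Tau: ", tau),
    "Coupling 1:", "nu: 1e-4", "Coupling 2:", "nu: 1e-4",
    "Output:", "Node: 1", "Start: 0", paste0("Interval: ", dt),
    "Trace: Population.1.Q", "Trace: Population.2.Q",
    "Trace: Propagator.2.phi"))
}

# Strip any time-varying stimulus component, leaving the constant mean.
mean_only <- function(cfg) {
  for (i in seq_along(cfg$populations)) {
    pop <- cfg$populations[[i]]
    if (!pop$external) next
    cfg$populations[[i]]$stimuli <- Filter(function(s) s$kind == "const",
                                           pop$stimuli)
  }
  cfg
}

expect_close <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}
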