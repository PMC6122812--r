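#' Bundled example models
#'
#' Ready-made configurations exercising the simulator's surface, returned
#' as parsed `nf_config` objects (they are built as configuration text and
#' run through [parse_config()], so each fixture also exercises the
#' dialect):
#'
#' * `e_pulse` — a single excitatory cortical population with damped-wave
#'   self-connection (range 0.2 m, damping 30 s^-1) on a 64 x 64 grid,
#'   driven by a subcortical external population delivering a constant
#'   background (steady rate near 10 s^-1) plus two brief central pulses:
#'   +2 s^-1 at ~32 ms (node 2000) and -2 s^-1 at ~60 ms (node 2097).
#'   Evoked-response style wave propagation.
#' * `e_white` — the same topology on a 32 x 32 grid driven by Gaussian
#'   white noise, sized for comparing the simulated spectrum against the
#'   linearized closed form.
#' * `ei` — cortical excitatory + inhibitory populations with external
#'   subcortical drive; inhibitory couplings are negative.
#' * `eirs` — corticothalamic model: cortical excitatory and inhibitory,
#'   thalamic reticular and relay populations plus external input, with
#'   40 ms corticothalamic loop delays and an inhibitory reticular-to-relay
#'   projection.
#'
#' Coupling strengths and firing parameters are physiologically plausible
#' package choices (the topologies, the printed wave parameters, and the
#' pulse protocol are fixed by the scenarios above); all fixtures pass
#' [validate_physics()] with Courant numbers at or below 0.15.
#'
#' @param name One of `"e_pulse"`, `"e_white"`, `"ei"`, `"eirs"`.
#' @return A validated `nf_config`.
#' @export
nf_fixture <- function(name = c("e_pulse", "e_white", "ei", "eirs")) {
  name <- match.arg(name)
  text <- switch(name,
                 e_pulse = fixture_e_pulse(),
                 e_white = fixture_e_white(),
                 ei = fixture_ei(),
                 eirs = fixture_eirs())
  parse_config(text)
}

sigmoid_block <- c("Firing: Sigmoid", "Qmax: 340", "Theta: 0.01292",
                   "Sigma: 0.0038")
dendrite_block <- function(label) {
  c(paste0("Dendrite ", label, ":"), "alpha: 45", "beta: 185")
}

fixture_e_pulse <- function() {
  c("Purely excitatory cortical sheet with subcortical input.",
    "Constant background plus two brief central pulses (+2 then -2 /s)",
    "evoke radially propagating damped waves.",
    "",
    "Time: 0.3",
    "Deltat: 6.103515625e-05",
    "Nodes: 4096",
    "Seed: 0",
    "",
    "Connection matrix:",
    "1 2",
    "0 0",
    "",
    "Population 1: Excitatory",
    "Length: 0.5",
    "Q: 10",
    sigmoid_block,
    dendrite_block(1),
    dendrite_block(2),
    "",
    "Population 2: External",
    "Length: 0.5",
    "Stimulus 1:",
    "Kind: Const",
    "Amplitude: 10",
    "Stimulus 2:",
    "Kind: Pulse",
    "Amplitude: 2",
    "Onset: 0.032",
    "Duration: 0.004",
    "Nodes: 2000",
    "Stimulus 3:",
    "Kind: Pulse",
    "Amplitude: -2",
    "Onset: 0.06",
    "Duration: 0.004",
    "Nodes: 2097",
    "",
    "Propagator 1: Wave",
    "Tau: 0",
    "Range: 0.2",
    "gamma: 30",
    "",
    "Propagator 2: Map",
    "Tau: 0",
    "",
    "Coupling 1:",
    "nu: 2e-05",
    "",
    "Coupling 2:",
    "nu: 2e-05",
    "",
    "Output:",
    "Node: 1996 1998 1999 2000 2001 2002 2004 2097",
    "Start: 0",
    "Interval: 1.953125e-03",
    "Trace: Propagator.1.phi",
    "Trace: Population.1.Q")
}

fixture_e_white <- function() {
  # 16 recording sites on a regular 4 x 4 subgrid of the 32 x 32 sheet
  nodes <- as.vector(outer(c(4, 12, 20, 28), (c(4, 12, 20, 28) - 1) * 32, `+`))
  c("Single excitatory population with damped-wave self-connection,",
    "driven by spatiotemporal Gaussian white noise: the stochastic",
    "companion of the linearized closed-form spectrum.",
    "",
    "Time: 65",
    "Deltat: 2.44140625e-04",
    "Nodes: 1024",
    "Seed: 0",
    "",
    "Connection matrix:",
    "1 2",
    "0 0",
    "",
    "Population 1: Excitatory",
    "Length: 0.5",
    "Q: 20",
    sigmoid_block,
    dendrite_block(1),
    dendrite_block(2),
    "",
    "Population 2: External",
    "Length: 0.5",
    "Stimulus 1:",
    "Kind: Const",
    "Amplitude: 10",
    "Stimulus 2:",
    "Kind: White",
    "Amplitude: 0.05",
    "",
    "Propagator 1: Wave",
    "Tau: 0",
    "Range: 0.2",
    "gamma: 30",
    "",
    "Propagator 2: Map",
    "Tau: 0",
    "",
    "Coupling 1:",
    "nu: 1e-04",
    "",
    "Coupling 2:",
    "nu: 1e-04",
    "",
    "Output:",
    paste0("Node: ", paste(sort(nodes), collapse = " ")),
    "Start: 1",
    "Interval: 1.953125e-03",
    "Trace: Propagator.1.phi")
}

fixture_ei <- function() {
  c("Cortical excitatory-inhibitory model with subcortical drive.",
    "",
    "Time: 1",
    "Deltat: 1e-04",
    "Nodes: 256",
    "Seed: 0",
    "",
    "Connection matrix:",
    "1 2 3",
    "4 5 6",
    "0 0 0",
    "",
    "Population 1: Excitatory",
    "Length: 0.5",
    "Q: 9",
    sigmoid_block,
    dendrite_block(1), dendrite_block(2), dendrite_block(3),
    "",
    "Population 2: Inhibitory",
    "Length: 0.5",
    "Q: 9",
    sigmoid_block,
    dendrite_block(4), dendrite_block(5), dendrite_block(6),
    "",
    "Population 3: External",
    "Length: 0.5",
    "Stimulus 1:",
    "Kind: Const",
    "Amplitude: 10",
    "",
    "Propagator 1: Wave",
    "Tau: 0",
    "Range: 0.2",
    "gamma: 30",
    "",
    "Propagator 2: Harmonic",
    "Tau: 0",
    "gamma: 100",
    "",
    "Propagator 3: Map",
    "Tau: 0",
    "",
    "Propagator 4: Harmonic",
    "Tau: 0",
    "gamma: 60",
    "",
    "Propagator 5: Harmonic",
    "Tau: 0",
    "gamma: 100",
    "",
    "Propagator 6: Map",
    "Tau: 0",
    "",
    "Coupling 1:",
    "nu: 2e-04",
    "",
    "Coupling 2:",
    "nu: -4e-04",
    "",
    "Coupling 3:",
    "nu: 1e-04",
    "",
    "Coupling 4:",
    "nu: 2e-04",
    "",
    "Coupling 5:",
    "nu: -4e-04",
    "",
    "Coupling 6:",
    "nu: 1e-04",
    "",
    "Output:",
    "Node: 120",
    "Start: 0",
    "Interval: 1e-03",
    "Trace: Population.1.Q",
    "Trace: Population.2.Q",
    "Trace: Propagator.1.phi")
}

fixture_eirs <- function() {
  c("Corticothalamic model: cortical excitatory (e) and inhibitory (i)",
    "populations, thalamic reticular (r) and relay (s) nuclei, external",
    "nonspecific input (n). Corticothalamic projections carry a 40 ms",
    "conduction delay; reticular-to-relay coupling is inhibitory.",
    "",
    "Time: 1",
    "Deltat: 1e-04",
    "Nodes: 256",
    "Seed: 0",
    "",
    "Connection matrix:",
    "1 2 0 3 0",
    "4 5 0 6 0",
    "7 0 0 8 0",
    "9 0 10 0 11",
    "0 0 0 0 0",
    "",
    "Population 1: Excitatory",
    "Length: 0.5",
    "Q: 9",
    sigmoid_block,
    dendrite_block(1), dendrite_block(2), dendrite_block(3),
    "",
    "Population 2: Inhibitory",
    "Length: 0.5",
    "Q: 9",
    sigmoid_block,
    dendrite_block(4), dendrite_block(5), dendrite_block(6),
    "",
    "Population 3: Reticular",
    "Length: 0.5",
    "Q: 6",
    sigmoid_block,
    dendrite_block(7), dendrite_block(8),
    "",
    "Population 4: Relay",
    "Length: 0.5",
    "Q: 8",
    sigmoid_block,
    dendrite_block(9), dendrite_block(10), dendrite_block(11),
    "",
    "Population 5: External",
    "Length: 0.5",
    "Stimulus 1:",
    "Kind: Const",
    "Amplitude: 10",
    "",
    "Propagator 1: Wave",
    "Tau: 0",
    "Range: 0.2",
    "gamma: 30",
    "",
    "Propagator 2: Harmonic",
    "Tau: 0",
    "gamma: 100",
    "",
    "Propagator 3: Map",
    "Tau: 0.04",
    "",
    "Propagator 4: Harmonic",
    "Tau: 0",
    "gamma: 60",
    "",
    "Propagator 5: Harmonic",
    "Tau: 0",
    "gamma: 100",
    "",
    "Propagator 6: Map",
    "Tau: 0.04",
    "",
    "Propagator 7: Map",
    "Tau: 0.04",
    "",
    "Propagator 8: Harmonic",
    "Tau: 0",
    "gamma: 100",
    "",
    "Propagator 9: Map",
    "Tau: 0.04",
    "",
    "Propagator 10: Harmonic",
    "Tau: 0",
    "gamma: 100",
    "",
    "Propagator 11: Map",
    "Tau: 0",
    "",
    "Coupling 1:",
    "nu: 2e-04",
    "",
    "Coupling 2:",
    "nu: -4e-04",
    "",
    "Coupling 3:",
    "nu: 1e-04",
    "",
    "Coupling 4:",
    "nu: 2e-04",
    "",
    "Coupling 5:",
    "nu: -4e-04",
    "",
    "Coupling 6:",
    "nu: 1e-04",
    "",
    "Coupling 7:",
    "nu: 5e-05",
    "",
    "Coupling 8:",
    "nu: 5e-05",
    "",
    "Coupling 9:",
    "nu: 1e-04",
    "",
    "Coupling 10:",
    "nu: -8e-05",
    "",
    "Coupling 11:",
    "nu: 1e-04",
    "",
    "Output:",
    "Node: 120",
    "Start: 0",
    "Interval: 1e-03",
    "Trace: Population.1.Q",
    "Trace: Population.4.Q",
    "Trace: Propagator.1.phi")
}

#' Write every fixture configuration to a directory
#'
#' @param dir Target directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(c("e_pulse", "e_white", "ei", "eirs"), function(nm) {
    path <- file.path(dir, paste0(nm, ".conf"))
    writeLines(serialize_config(nf_fixture(nm)), path)
    path
  }, character(1))
  invisible(paths)
}
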