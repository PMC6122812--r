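# neurofield

Multiscale neural-field simulation on periodic 2D grids, in R.

Neural field theory describes brain activity by averaging firing rates,
soma potentials and axonal pulse fields over populations of neurons, giving
continuum equations that connect millimetre-scale cortical dynamics to
EEG-scale observables. `neurofield` integrates these equations for an
arbitrary number of interacting populations declared in a plain-text
configuration file, and ships the spectral analysis and closed-form
linearized solutions needed to validate the numerics against theory.

For each connection *a ← b* the model couples four processes:

* **dendritic filtering** — incoming rate `φ_ab(t − τ_ab)` weighted by the
  synaptic strength `ν_ab` (V·s) drives the subpotential `V_ab` through the
  biexponential operator `[(1/αβ) d²/dt² + (1/α + 1/β) d/dt + 1]`, whose
  kernel has unit area and peaks at `ln(β/α)/(β − α)`;
* **soma summation** — `V_a = Σ_b V_ab`;
* **firing response** — the sigmoid
  `Q_a = Qmax / (1 + exp(−(V_a − θ)/σ′))`, or its linearization with slope
  `ρ = dQ/dV`;
* **axonal propagation** — the damped 2D wave equation
  `[(1/γ²) ∂²/∂t² + (2/γ) ∂/∂t + 1 − r²∇²] φ_ab = Q_b`
  with range `r` and damping `γ = v/r` (explicit central differences on a
  periodic five-point stencil, gated by the 2D Courant condition
  `p = vΔt/Δx ≤ 1/√2`), its spatially uniform harmonic limit, or the
  instantaneous local interaction approximation `φ = Q`.

Dendrite and harmonic dynamics step with fixed-step RK4; inter-population
delays are served exactly from ring-buffer histories; simulations start at
the model's low-firing fixed point.

## Worked example

The bundled `ei` model is a cortical excitatory–inhibitory pair with
constant subcortical drive (10 s⁻¹):

```r
library(neurofield)

cfg <- nf_fixture("ei")
cfg
#> <nf_config> 3 population(s), 6 connection(s), 256 nodes, Time 1 s, Deltat 0.0001 s

find_steady_state(cfg)
#> <nf_steady> fixed point
#>   population 1: Q* = 8.96627 s^-1, V* = -0.000793253 V
#>   population 2: Q* = 8.96627 s^-1, V* = -0.000793253 V
#>   population 3: Q* = 10 s^-1 (external)

cfg$time <- 0.5
out <- run_nf(cfg, seed = 1)
out
#> <nf_output> 501 samples x 3 columns (Population.1.Q, Population.2.Q,
#>             Propagator.1.phi), t in [0, 0.5] s
head(tidy(out), 3)
#> # A tibble: 3 × 4
#>    time trace           node value
#> 1 0     Population.1.Q   120  8.97
#> 2 0.001 Population.1.Q   120  8.97
#> 3 0.002 Population.1.Q   120  8.97
```

Both cortical populations settle at 8.97 s⁻¹: the symmetric couplings
(ν_ee = ν_ie = 2×10⁻⁴, ν_ei = ν_ii = −4×10⁻⁴ V·s) make excitatory and
inhibitory rates identical, and with the system started at its fixed point
and a constant stimulus the traces stay flat — the initialization contract
the test suite checks to 10⁻⁶ relative. Replace the constant drive with
pulses (`nf_fixture("e_pulse")`) to watch evoked waves propagate, or with
white noise (`nf_fixture("e_white")`) to estimate EEG-like spectra:

```r
out <- run_nf(nf_fixture("e_white"), seed = 1)       # ~2.5 min, 64 s of data
sp  <- nf_spectrum(nf_extract(out, "Propagator.1.phi"), demean = TRUE)
lin <- nf_linear_psd(nf_fixture("e_white"), sp$frequencies, "Propagator.1.phi")
autoplot(sp)
```

Every result type is tidyverse-friendly: `tidy()` gives long tibbles,
`glance()` one-row summaries, `autoplot()` ggplot figures.

A command-line runner mirrors the R API
(`inst/cli/neurofield -i model.conf [-o out] [-t]`); it writes the
plain-text `.output` format (config echo, `=` separator, label and node
header lines, time-first columns) that `read_output()` parses back.

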