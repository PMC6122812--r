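---
title: "Methods: neural-field simulation in neurofield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neural-field simulation in neurofield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofield)
```

## The model

`neurofield` simulates populations of neurons as continuous fields on
periodic two-dimensional sheets. For each ordered pair of connected
populations $a \leftarrow b$ the model tracks the axonal spike-rate field
$\phi_{ab}(\mathbf r, t)$ arriving at $a$ from $b$, the dendritic
subpotential $V_{ab}$ it induces, the mean soma potential
$V_a = \sum_b V_{ab}$, and the mean firing rate $Q_a$. Four local
transformations close the loop:

1. **Synaptodendritic filtering.** Incoming rate is weighted by the
   synaptic coupling strength $\nu_{ab}$ (V·s, negative for inhibitory
   projections) and low-pass filtered,
   $$\left[\frac{1}{\alpha\beta}\frac{d^2}{dt^2}
     + \Big(\frac{1}{\alpha}+\frac{1}{\beta}\Big)\frac{d}{dt} + 1\right]
     V_{ab} = \nu_{ab}\,\phi_{ab}(t - \tau_{ab}),$$
   whose impulse response is the biexponential kernel with decay rate
   $\alpha$ and rise rate $\beta \ge \alpha$ (both s$^{-1}$), normalized to
   unit area. The kernel peaks at $\ln(\beta/\alpha)/(\beta-\alpha)$, about
   10 ms for the default $\alpha = 45$, $\beta = 185$ s$^{-1}$. Infinite
   rates degrade gracefully to a single exponential or the identity.
   $\tau_{ab}$ is a discrete inter-population conduction delay.
2. **Soma summation.** $V_a = \sum_b V_{ab}$, linear dendritic
   integration.
3. **Firing response.** The sigmoid
   $Q_a = Q^{\max} / (1 + e^{-(V_a - \theta)/\sigma'})$ with maximum rate
   $Q^{\max}$ (s$^{-1}$), threshold $\theta$ (V) and spread $\sigma'$ (V),
   or its linearization $Q = Q^{(0)} + \rho\,(V - V^{(0)})$ with slope
   $\rho = dQ/dV$. The linear form is deliberately not clipped at zero by
   default — it is a small-signal approximation — but a clip flag exists.
4. **Axonal propagation.** Each connection advances its field with one of
   three operators: the 2D damped wave (telegrapher's) equation
   $$\left[\frac{1}{\gamma^2}\partial_t^2 + \frac{2}{\gamma}\partial_t
     + 1 - r^2\nabla^2\right]\phi_{ab} = Q_b,$$
   with axonal range $r$ (m) and damping $\gamma = v/r$ (s$^{-1}$); the
   harmonic operator (the same without the Laplacian, exact for spatially
   uniform activity); or the local interaction approximation
   $\phi_{ab} = Q_b$ (the zero-range neural-mass limit). External
   populations replace steps 1–3 with prescribed stimulus fields.

## Discretization and numerics

**Grid.** Each sheet is split into $N$ square cells, `Nodes` in the
configuration; the default square layout requires $N$ to be a perfect
square, and `Longside nodes` selects a rectangular $N_x \times N_y$ layout.
Spacing is $\Delta x = L_x/N_x$ on both axes. Nodes are labeled 1..N
row-major from the lower-left cell, and every position refers to a cell
centre. All populations share one layout; each may declare its own
physical `Length`, which rescales its $\Delta x$. When populations differ,
a propagator uses the spacing of its *source* population (the sheet the
field leaves); all bundled models use equal lengths, where the distinction
vanishes.

**Wave stepping.** The damped wave equation is advanced with an explicit
central-difference scheme on the five-point periodic stencil. Substituting
$u = \phi e^{\gamma t}$ removes the damping term; discretizing the
resulting undamped equation and back-substituting yields an update in
which only decaying factors $e^{-\gamma\Delta t}$, $e^{-2\gamma\Delta t}$
appear. The scheme is second-order accurate in space and time (the test
suite measures the order on a damped standing wave with a closed-form
solution and requires it in [1.7, 2.3]) and preserves a spatially uniform
equilibrium to $O((\gamma\Delta t)^5)$ per step. Because the substitution
assumes a small step, `validate_physics()` warns when
$\gamma\Delta t > 0.1$. Periodic boundaries are implemented by ghost-cell
copies of the opposite edges (`pad_periodic()`), equivalent to modular
indexing; the production path uses a vectorized shifted-index neighbour
sum that the tests check against the ghost-cell construction.

**Stability.** The explicit 2D scheme requires the Courant number
$p = v\Delta t/\Delta x \le 1/\sqrt 2$ over all wave connections; the
solver refuses to run otherwise and warns above $p = 0.15$, since
practical work keeps $p\approx 0.1$. All bundled models sit at or below
$p = 0.094$.

**Local dynamics.** Dendrite and harmonic-propagator ODEs use classical
RK4 with fixed step $\Delta t$ (order verified as $\approx 4$ by
step-halving). Within a global step the drive at the half and full step is
needed before the corresponding field levels exist; the solver linearly
extrapolates the drive from the two stored levels
($P^{n+1} \approx 2P^n - P^{n-1}$), which is second-order accurate and
therefore never the accuracy bottleneck of the overall second-order
scheme.

**Step ordering.** Each global step evaluates: stimuli at $t_{n+1}$ →
population dendrites, soma sums and firing responses (giving $Q^{n+1}$) →
history pushes → propagators. This ordering exists so the wave update can
consume $Q^{n+1}$ exactly as its stepping formula requires.

**Delays.** Each population keeps one $N \times D$ ring buffer of past
firing rates. The depth required by the physics is
$D_a = \max_b \lceil\tau_{ba}/\Delta t\rceil$ (spatially nonuniform delays
take their maximum over space first), floored at two levels for the wave
scheme's history; `history_depth()` reports exactly this. The solver
allocates two extra levels so that the wave scheme's $Q^{n+1-d}$ read and
the harmonic scheme's interpolated delayed drive are always in range.
Delays must be integer multiples of $\Delta t$ to within $10^{-6}$
relative; incommensurate values raise an error rather than silently
rounding. Delay service is exact: a delayed map connection reproduces the
source series shifted by exactly $k$ samples, bit for bit.

**Initialization.** Simulations start at a spatially uniform fixed point
with all histories filled with equilibrium rates, so a mean-only stimulus
leaves every trace constant (validated to $10^{-6}$ relative over one
simulated second for all bundled models). `find_steady_state()` solves the
fixed-point system with time-varying stimulus components replaced by their
means (constants keep their level; sines, transient pulses and zero-mean
noise contribute nothing). With one internal population the solver scans
the soma voltage over $[-0.1, 0.1]$ V — generous for potentials measured
relative to rest — with $10^4$ test points, bisects each sign change to
$10^{-12}$ V and polishes with Newton steps; with several populations no
single scalar unknown exists in general, so it runs damped Picard
iteration from a lattice of starting rates, polishes each candidate with a
Newton iteration on a numerical Jacobian, and keeps the root with the
lowest total firing rate — the conventional stable low-firing brain
state. Dendrite states initialize at $(V^*, 0)$.

## Stimuli and the noise convention

External populations sum `const`, `sine`, square `pulse`-train, and
Gaussian `white` components, each optionally restricted to a node mask
(unmasked nodes contribute exactly zero). Plain discretized white noise
changes bandwidth with the step size, so the white amplitude is specified
as an amplitude spectral density (s$^{-1}$ Hz$^{-1/2}$): draws are
i.i.d. per node and step with standard deviation
$\mathrm{ASD}/\sqrt{2\Delta t}$, making the one-sided PSD of each node's
sequence equal $\mathrm{ASD}^2$ for any $\Delta t$. No cell-area scaling
is applied by default, preserving per-node independence. Reproducibility
comes from one RNG stream seeded by the configuration's `Seed` (or the
`seed` argument); a white component may carry a private seed, giving it
its own stream.

## Spectral analysis

`nf_spectrum()` is a Welch estimator: Hann-windowed segments (default 4 s)
with 50% overlap, averaged, one-sided and per-Hz, so integrated power
approximates variance (checked to 3% on white noise). No R package in the
supported stack provides Welch averaging, so the estimator is implemented
on `stats::fft`, with its parameters recorded in the result's metadata.
Demeaning is off by default — a constant series shows its power at
$f = 0$ — but should be enabled when estimating small fluctuation spectra
of signals with a large mean, where window leakage from DC would otherwise
swamp the lowest bins. `nf_spatial_spectrum()` Fourier-decomposes a
full-grid trace onto the box modes $k_m = 2\pi m/L$, Welch-estimates each
complex mode amplitude, and sums $P(f) = \sum_k P(k, f) F(k)$ with the
optional volume-conduction filter $F(k) = e^{-k^2/k_0^2}$. The filter's
Gaussian form is this package's choice of a smooth wavenumber low-pass
with a single cutoff parameter (scalp signals need spatial filtering,
intracranial ones do not); $k_0$ defaults to none.

## Linearized validation

`nf_linear_psd()` is the analytic oracle. Around the fixed point each
connection contributes a gain $\rho_a \nu_{ab}$, a dendritic filter
$L(\omega) = [(1 - i\omega/\alpha)(1 - i\omega/\beta)]^{-1}$, a propagator
factor $A(k,\omega) = [(1 - i\omega/\gamma)^2 + k^2 r^2]^{-1}$ (harmonic:
$r = 0$; map: 1), and a delay factor $e^{i\omega\tau}$ (Fourier convention
$e^{-i\omega t}$, so $d/dt \to -i\omega$; only magnitudes enter spectra).
The internal populations form a linear system solved per $(k, \omega)$ on
the same discrete wavenumber lattice as the simulation box, so analytic
and simulated spectra are bin-compatible. For node-independent white drive
the noise divides evenly over the $N$ spatial modes, giving the per-node
prediction $P(f) = N^{-1}\sum_k |T(k,\omega)|^2\,\mathrm{ASD}^2$ — directly
comparable to the Welch spectrum of any single recorded node.

The stochastic validation run (`e_white`) uses a 32 × 32 sheet of 0.5 m,
$\Delta t = 2^{-12}$ s, 64 s of data at 512 Hz from 16 recording sites.
This size gives the Welch estimate (31 segments, ~180 band bins) a
sampling error comfortably below the 5% band-averaged acceptance margin
while keeping the run in the minutes range; the agreement is insensitive
to enlarging the grid. Band-averaged agreement between simulation and
closed form over 1–45 Hz is typically within 2%.

## Bundled models

The fixture generator (`nf_fixture()`) builds four models as configuration
text and parses it, so the dialect is exercised end to end:

* `e_pulse` — one excitatory cortical population, damped-wave
  self-connection with range 0.2 m and damping 30 s$^{-1}$, on a 64 × 64
  grid ($\Delta t = 2^{-14}$ s, 512 Hz output, $p = 0.047$); constant
  subcortical background holding the sheet near 12 s$^{-1}$ plus two 4 ms
  central pulses of ±2 s$^{-1}$ at 32 and 60 ms — an evoked-response
  scenario with radially propagating waves.
* `e_white` — the spectrum-validation companion described above.
* `ei` — cortical excitatory/inhibitory pair with subcortical drive;
  inhibitory couplings negative.
* `eirs` — corticothalamic loop (cortical e/i, thalamic reticular and
  relay, external input) with 40 ms corticothalamic delays and inhibitory
  reticular-to-relay coupling.

Topologies, the printed wave parameters and the pulse protocol are fixed
by the scenarios; coupling strengths and firing parameters
($Q^{\max} = 340$ s$^{-1}$, $\theta = 12.92$ mV, $\sigma' = 3.8$ mV,
$\alpha = 45$, $\beta = 185$ s$^{-1}$) are physiologically plausible
package choices giving each model a unique stable low-firing fixed point
with loop gains below one. They are not a transcription of any published
parameter table, and conclusions from these fixtures are about the
numerics, not about any particular brain state. What the fixtures do not
emulate about real data: measurement noise and sensor forward models,
heterogeneous (position-dependent) parameters, and nonstationary
modulation — passing tests demonstrate correct integration of the stated
equations, not biological validity of a parameter set.

## Degenerate inputs and edge behaviour

Empty afferent lists sum to a zero soma potential; zero requested traces
still produce a valid output file with a bare time column; a zero-range
wave (`r = 0`) is expressed as a harmonic propagator; `alpha = beta`
switches the kernel to its critically damped branch; `beta < alpha` is
repaired by swapping (the kernel is symmetric) with a warning; unknown
configuration keys are hard errors. Non-finite fields abort the run
naming the step and component. Output decimation is pure subsampling —
no interpolation or averaging — so changing `Interval` changes which rows
appear, never their values.

## Known limitations

* The wave stencil supports scalar delays only. Per-node delay reads are
  provided at the API level (`history_read()` with `node_lags`, for map- and
  harmonic-style use); the configuration dialect exposes a scalar `Tau` per
  connection, since the interaction of nonuniform delays with the spatial
  stencil is not defined here.
* Parameters are uniform over space; position-dependent $\gamma$, $r$,
  $\nu$ are out of scope.
* The sheet topology is a torus; spherical or absorbing-boundary domains
  are not provided.
* Fixed-step explicit integration: stiff parameter sets (very large
  $\alpha, \beta, \gamma$ relative to $1/\Delta t$) require a smaller step
  rather than adaptive control, and blow-ups are reported, not recovered.
* The spatially uniform steady state used for initialization means a
  spatially masked constant background would start slightly off-equilibrium;
  bundled models use unmasked backgrounds.
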