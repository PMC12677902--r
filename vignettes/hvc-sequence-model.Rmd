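---
title: "A conductance-based model of sequence propagation in HVC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A conductance-based model of sequence propagation in HVC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvcnet)
```

## The scientific problem

Adult zebra finches sing highly stereotyped songs. The premotor nucleus HVC
generates the underlying temporal sequence: RA-projecting neurons
(HVC~RA~) each fire a single sparse burst (3–6 spikes over roughly 8 ms) at
one fixed moment of the motif, X-projecting neurons (HVC~X~) fire 1–4
rebound bursts of 4–9 spikes, and interneurons (HVC~INT~) fire densely
throughout the song. `hvcnet` implements a biophysical network model of how
these three populations, wired into a feedforward chain of microcircuits
with structured feedback inhibition, can propagate that sequence using only
HVC-intrinsic machinery.

## Model neurons

Each neuron is a single compartment obeying

$$C_m \frac{dV}{dt} = -\sum_i I_i - I_{syn} + I_{stim} + I_{noise},$$

with class-specific ionic currents (all of the form
$g\,\prod_j x_j^{p_j}\,(V - E)$, outward positive and subtracted):

* **HVC~RA~**: leak, delayed-rectifier K⁺ ($n^4$), transient Na⁺
  (instantaneous $m_\infty^3 h$), high-threshold L-type Ca²⁺
  (instantaneous $s_\infty^2$), A-type K⁺ (instantaneous activation,
  slowly inactivating gate $e$), and SK-type Ca²⁺-activated K⁺.
  6 state variables: $V, h, n, e, z, \mathrm{Ca}$.
* **HVC~X~**: the RA set minus A-type, plus low-threshold T-type Ca²⁺
  ($m_T^2 h_T$, both dynamic) and the hyperpolarization-activated inward
  current $I_H$ (gate $r$). 8 state variables.
* **HVC~INT~**: as X but without SK. 7 state variables.

Gates follow Boltzmann steady states
$x_\infty(V) = 1/(1+\exp((V-\theta)/\sigma))$ with first-order relaxation
and bell-shaped time constants
$\tau(V) = \tau_0 + \tau_1/\cosh((V-\theta_t)/\sigma_t)$. Intracellular
calcium obeys a first-order balance,
$d\mathrm{Ca}/dt = -\alpha (I_{CaL}+I_{CaT}) - (\mathrm{Ca}-\mathrm{Ca}_0)/\tau_{Ca}$,
with the baseline chosen so SK is nearly closed at rest. The SK gate is
calcium-activated, $z_\infty = \mathrm{Ca}^2/(\mathrm{Ca}^2+k_s^2)$.

The functional forms follow the published single-compartment HVC models
this family of networks builds on; the parameter values shipped as
defaults were calibrated here so that each class reproduces its
documented phenotype: delayed plateau bursts in RA (delay shrinking with
smaller $g_A$), sag and post-inhibitory rebound in X and INT (T- and
H-current mediated), spike-frequency adaptation in X (SK), fast spiking
with after-hyperpolarizations that undershoot rest in INT, and quiescence
at rest for every class.

Two deliberate design choices deserve emphasis, because they are the
package's own rather than inherited:

* **The RA burst terminator.** The SK conductance of RA neurons enters the
  current at the fourth power of its activation gate,
  $I_{SK} = g_{SK}\, z^4 (V-E_K)$. Because calcium saturates the gate's
  steady state within the first spikes, $z(t)$ becomes a near-pure clock
  ($z \approx 1-e^{-t/\tau_z}$ from burst onset) and $z^4$ turns it into a
  sharp threshold that ends the burst after about 8 ms regardless of the
  exact synaptic drive. This is what makes the per-burst spike count and
  duration essentially seed-invariant across the 120-neuron chain. With a
  first-order SK term the termination point inherits the drive's
  variability and the chain drifts between 4- and 6-spike regimes.
* **Class-specific T/H placement in interneurons.** Interneurons rest
  around −50 mV, far above the X resting potential. If they shared the X
  gating midpoints, their T- and H-currents would be disengaged at rest
  and up-regulating them would do nothing. Their $h_T$ and $r$ midpoints
  therefore sit higher (−65 and −58 mV) and their H reversal is −20 mV,
  so a 10-fold increase of either conductance drives the cell into the
  dense sustained firing that the perturbation experiments require.

## Synapses and noise

AMPA (E = 0 mV) and GABA~A~ (E = −88 mV) synapses use two-state
transmitter kinetics: $ds/dt = \alpha T(V_{pre})(1-s) - \beta s$ with a
sigmoidal release function at −20 mV. Decay times are ~5.5 ms (AMPA) and
8 ms (GABA~A~); the relatively slow AMPA decay is part of the chain
calibration — the tail of one burst's drive must outlast the next
neuron's onset delay for propagation to be self-sustaining. Only the five
legal class pairs exist: RA→RA, RA→INT, X→INT (AMPA); INT→RA, INT→X
(GABA~A~).

The background current is $I_{noise} = \sigma\,\xi(t)$ with unit-variance
Gaussian white noise, scaled by $1/\sqrt{dt}$ in the integrator so its
statistics are step-size independent, and drawn from a counter-based
generator keyed by (seed, step, neuron) so results are reproducible and
independent of evaluation order. $\sigma$ is specified as a percentage of
the network-wide mean synaptic conductance and converted to pA at a
60 mV reference driving force.

## Network architecture

The default network holds 120 RA, 50 INT and 50 X neurons (2:1:1) in 20
microcircuits. Per circuit: 3–10 RA wired as a random feedforward AMPA
chain, 1–4 INT, 1–4 X; circuits are linked last-RA→first-RA. Each INT
receives 3–8 AMPA afferents from RA donors and sends 2–4 GABA synapses to
RA neurons outside its own circuit (the "rules of engagement" that keep
inhibition away from a burst's assigned time); X and INT connect only
within their circuit (X→INT 1–3, INT→X 1–2). Pool partitions are sampled
by rejection over iid uniforms conditioned on the exact pool totals.

Three construction refinements were needed to reach the stated network
behavior and are this package's own decisions:

* RA→INT donors are drawn *stratified along the chain* (one donor per
  chain segment, random within segment). With uniform draws an
  interneuron with few donors can be silent for long stretches of the
  song, contradicting the required tonic activation.
* The INT and X partitions are drawn jointly under the constraint that
  each circuit's interneuron GABA capacity covers its X members, and
  INT→X targets are dealt so that *every* X neuron receives at least one
  inhibitory afferent — an X-projector without inhibition can never fire
  a rebound burst.
* Per-edge conductances are uniform draws from per-pair ranges (defaults:
  RA→RA 23–24.5, RA→INT 12–18, X→INT 2–5, INT→RA 2–5, INT→X 28–45 nS).
  The X→INT range is deliberately small: the X→INT→X loop otherwise
  truncates rebound bursts within 2–3 spikes.

## Integration

The production integrator is fixed-step RK4 (dt = 0.01 ms) over all
neuron and synapse states jointly, with an Euler–Maruyama noise increment
on each membrane potential after the deterministic step; adaptive
stepping is ill-posed with white noise. Spikes are detected online as
threshold-crossing peaks (−20 mV, 1 ms refractory) at full step
resolution. A noiseless adaptive reference (`deSolve::lsoda` on the same
right-hand side, interrupted at stimulus discontinuities) serves as the
cross-integrator oracle; the test suite requires spike-time agreement
within 0.5 ms and first-spike shifts below 0.1 ms when the step is
halved. Initial conditions are per-class resting states found by
relaxing each cell for 4 s of model time (tolerance 1e-8 on the state
derivative); cells that no longer settle after a perturbation fall back
to their end-of-relaxation state.

## What a run looks like

```{r, eval = FALSE}
run <- run_motif(network_seed = 1)        # build + kick-start + integrate
rep <- sequence_metrics(run$result, run$net)
rep
```

The kick-start is a 0.5 nA, 18 ms DC pulse to the first RA neuron of
circuit 1 (the published protocol specifies a small stochastic DC input
without magnitudes; 0.5 nA sits comfortably above the calibrated RA
rheobase). The default 20-circuit sequence completes in roughly 300 ms of
model time; the examples, tests and the acceptance script therefore
simulate 420 ms motifs, while `solver_config()` defaults to a full
1000 ms window for exploratory use.

## Burst analysis and the desired-activity validator

`group_bursts()` groups spikes into bursts at a 15 ms inter-spike
threshold (minimum two spikes). For the *sequence* tally an RA burst must
have at least three spikes — the lower end of the realistic 3–6 range —
so a neuron whose burst is reduced to a doublet by a perturbation counts
as having lost its burst. `sequence_metrics()` checks the desired-network
activity: every RA neuron fires exactly one 3–6 spike burst of at most
10 ms, onsets ordered along the chain; every X neuron 1–4 bursts of 4–9
spikes; interneuron tonicity is operationalized as at least one spike in
every 100 ms window of the active span plus at least two bursts. The
across-seed onset jitter of RA bursts under noise is reported but not
used for pass/fail, since no quantitative criterion is published.

## Known limitations, honestly quantified

* **X-population conformity.** Across network seeds, 82–96 % of X neurons
  meet the "1–4 bursts of 4–9 spikes" bound; the remainder typically show
  one undersized (2–3 spike) rebound episode caused by ragged release
  during the passage of the wave. Calibration over the T-current
  magnitude and kinetics, SK, leak, GABA decay, interneuron density and
  the INT→X coverage plateaued there; removing the X→INT feedback loop
  entirely yields 98–100 %, but that edge class is part of the
  architecture. Experiments that classify whole runs therefore treat the
  X population as realistic when at least 75 % of its members are within
  bounds (each model neuron stands for a pool of similar cells).
* **Inhibition-mediated sequence breaks.** Up-regulating A-type or SK
  conductances in a single RA neuron eliminates its burst and
  demonstrably breaks the chain. The interneuron- and X-mediated breaks,
  in contrast, require GABA~A~ conductances onto RA strong enough to veto
  a burst (~2–3× the chain AMPA conductance, by shunting arithmetic);
  at that strength the *unperturbed* network's dense song-long
  interneuron firing already degrades the sequence, because a saturating
  synapse distinguishes sustained from phasic presynaptic firing by only
  ~1.5×. This robustness–sensitivity trade-off is intrinsic: the
  published model sits on the fragile side (it describes itself as more
  sensitive to inhibition than the experimental literature), this build
  sits on the robust side so that the sequence and its burst statistics
  hold for arbitrary construction seeds. The perturbation battery
  therefore reports, alongside `sequence_complete`, whether each row
  disrupts the desired activity; the interneuron/X rows disrupt realism
  without severing the chain.
* The generator emulates noiseless or white-noise-driven in vivo-like
  activity of an isolated HVC; it does not model brainstem feedback,
  inter-hemispheric coordination, dendrites, NMDA/GABA~B~ receptors,
  temperature dependence, or silent-gap microcircuits. Passing tests
  show internal consistency with the published network's reported
  behavior, not fidelity to any particular bird's physiology.

## Numerical choices

dt = 0.01 ms with trace recording every 0.1 ms (burst statistics are
computed from solver-side spike times and are invariant to the recording
stride); resting-state relaxation 4 s at dt = 0.02 ms; duplicate edges
are resampled rather than merged during wiring; partition rejection
sampling is capped at 1e5 draws; the noise generator is splitmix64-based
Box–Muller, one draw per (seed, step, neuron).
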