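---
title: "Clustered gap-junction networks of inferior olive model neurons: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustered gap-junction networks of inferior olive model neurons: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Inferior olive (IO) neurons communicate exclusively through gap
junctions and generate subthreshold membrane-potential oscillations
below 10 Hz whose peaks time the spikes the nucleus sends to the
cerebellum. Two experimental facts constrain any network model: the
oscillation frequency shifts episodically by a few hertz, and pairs of
neurons hold stable phase differences while sharing one frequency.
`olivenet` implements the hypothesis that both follow from a clustered
architecture — neurons with similar conductance densities grouped into
densely and weakly intra-connected clusters, sparsely and more strongly
inter-connected — in which the inter-cluster electrical coupling
strength is the modulated quantity.

## The cell model and its assumptions

Each neuron is a single isopotential compartment carrying only a leak
and a low-threshold (T-type) Ca²⁺ current:

$$C_m \dot V = -g_l (V - E_l) - g_{Ca}\, m_\infty(V)^3\, h\, (V - E_{Ca}) + i_{gap} + i_{ext},
\qquad \dot h = \frac{h_\infty(V) - h}{\tau_h(V)}.$$

Assumptions: activation is fast relative to everything else and is
treated as instantaneous (`m = m_inf(V)`), leaving inactivation `h` as
the single slow state; all channels that shape action potentials are
omitted, because the model is only asked about the subthreshold regime
(roughly −65 to −50 mV); space is ignored (no dendritic compartments,
no junction geometry).

### Gating kinetics are data

The gating constants are read from a versioned parameter file
(`inst/extdata/kinetics-default.yaml`); an alternative transcription of
the T-type current is a configuration change, not a code change:

```{r}
kin <- gating_kinetics()                      # package default
alt <- gating_kinetics("my-kinetics.yaml")    # alternative transcription
soft <- gating_kinetics(m_slope = 12)         # targeted override
```

The shipped defaults are this package's calibrated parameterization of
the standard T-type functional family (logistic steady states, sigmoidal
`tau_h`). They were fixed, once, against the experimentally reported
phenomenology of IO cells rather than against any single recording:

- an oscillatory region covering roughly half of the admissible
  conductance box `g_l` ∈ [0.15, 0.4], `g_Ca` ∈ [0.2, 1.4] mS/cm², with
  a diagonal onset boundary (`oscillation_boundary()`);
- a *soft* onset: peak-to-peak amplitude grows from under 1 mV at the
  boundary to the mid-teens deep in the region, inside the reported
  0.5–25 mV amplitude range — IO oscillations are low-amplitude and
  quasi-sinusoidal, not relaxation-like;
- intrinsic frequencies of ~6–13 Hz rising with `g_Ca`.

With `E_l` = −63 mV, `E_Ca` = 120 mV and `C_m` = 1 µF/cm², the defaults
are: `m∞` half −58 mV, slope 10 mV, exponent 3; `h∞` half −70 mV, slope
8 mV; `τ_h(V) = 45 + 450/(1 + exp((V + 68)/9))` ms. The oscillatory
region of this parameterization is a *band* in `g_Ca`: at high `g_Ca`
the cell re-stabilizes at a depolarized rest. Only the lower (onset)
boundary is used by the generator.

### Membrane area and units

The model works in conductance densities, but junctional coupling is an
absolute conductance, so each neuron carries an `area` (one default,
10⁻⁴ cm², for all cells). All coupling-coefficient calibration is done
in absolute units; once the coupling coefficients are fixed, network
results are invariant to the area choice.

## Coupling coefficients

The physiological coupling strength is the coupling coefficient (CC):
the steady-state voltage deflection ratio of a paired recording,
`CC = R_peer / (R_peer + R_c)` with `R_c = 1/g_gap`. Experiments bound
it to 2–20%, with most connections below 10%.

The measurement protocol (`measure_cc()`) injects a small
hyperpolarizing step (−0.5 µA/cm², 500 ms) into each endpoint in turn,
in the full network context, and takes the deflection ratio from
100 ms steady-state windows. By default the T-type conductance is
blocked during the measurement (the oscillation-suppressing condition of
paired recordings); the steady state is then exactly the passive
resistor-network solution, which `cc_linear()` computes by solving the
conductance matrix directly. Calibration (`calibrate_gap_conductance()`
and the generator's joint loop) runs on that linear solution using
Sherman–Morrison rank-one updates, which makes calibrating a hundred
junctions a sub-second operation; the simulated protocol is used to
cross-check the linear solution in the tests.

Two conventions matter:

- A junction stores one conductance; the two *directional* CCs differ
  when the endpoint input resistances differ (typical across clusters).
  Calibration drives the **larger** direction to the target so the 20%
  cap can never be exceeded by the hidden direction.
- A junction whose endpoints are already coupled above its drawn target
  through parallel network paths cannot be made weak enough; it is
  clamped to the minimum conductance and its recorded target replaced by
  the achieved coupling (`meta$clamped_junctions`).

## The generator and the study conditions

`generate_network()` draws cluster centers, samples per-neuron
conductances, builds the topology, draws CC targets and calibrates every
junction, then validates the three architectural constraints: every
neuron connected with 1–38 junctions, exactly 4 intra-cluster partners,
all CCs within 2–20%. Defaults: 4 clusters × 12 neurons, intra-cluster
CC targets from [2%, 10%] (the experimental majority), inter-cluster
from [2%, 20%], truncated-normal conductance sampling with σ = 0.005
(g_l) and 0.01 (g_Ca) mS/cm² — resampling on out-of-box draws rather
than clipping, to avoid boundary atoms. The inter-cluster scheme
connects 80% of one cluster's neurons (floor of the product) to distinct
random partners in the other, one junction per source neuron; the
reference scheme is a chain plus one shortcut, and the random scheme
keeps each cluster connected to 1–3 others.

Cluster placement is the key study condition. Centers are placed on the
spontaneous-oscillation onset boundary of the conductance plane,
stratified: half the clusters (rounded up) receive a g_Ca offset drawn
uniformly up to +0.35 mS/cm² *above* the onset curve, the other half an
offset down to −0.25 below it, kept at least three cluster spreads
(0.03) below the curve so their members are predominantly quiescent.
This emulates the published cluster choice: about half of all neurons
oscillate spontaneously, clusters differ in intrinsic frequency by
several hertz, and the coupling-weighted average neuron stays inside the
oscillatory region so the fully coupled network sustains a synchronized
oscillation (at these conditions, typically 8–9.5 Hz). A symmetric
placement band was rejected because it leaves the average neuron on the
quiescent side in about half of the draws, producing networks whose
oscillations collapse — a real behaviour of the model (see below), but
not the regime the protocols study.

Every seeded operation routes through one child-seed stream, so a
generated network is bit-reproducible from its spec, including
calibrated conductances.

## Simulation numerics

The coupled system is one ODE of dimension 2N with the junction
Laplacian applied sparsely. Defaults: `lsoda` with `rtol = atol = 1e-8`
and a 1 ms output grid; initial conditions `V(0) = E_l` plus optional
seeded ±1 mV jitter (symmetry breaking), `h(0) = h_inf(V(0))`. A
fixed-step RK4 integrator (`integrate_rk4()`) is kept as an independent
reference; the suite checks agreement within 0.05 mV over 1 s at
`dt = 0.001` ms, and that measured network frequencies move by less than
0.05 Hz under halved output steps and tightened tolerances. Modulation
events are handled by stop-and-restart at the event time — an
instantaneous conductance switch, never smoothed. Traces are screened
against a sanity window ([−120, 60] mV) and any non-finite state aborts
the run. The first 1 s of every run is excluded from all frequency and
phase measurements (settling transient).

## Analysis conventions

- **Peaks** (`detect_peaks()`): local maxima with prominence ≥ 0.25 mV
  (half the oscillation floor) and ≥ 20 ms separation.
- **Stability** (`is_stable()`): a trace (transient already discarded)
  is a stable oscillation when the final 1 s peak-to-peak amplitude is
  at least 90% of the first 1 s *and* above the 0.5 mV floor — the lower
  edge of the experimental amplitude range.
- **Frequency** (`estimate_frequency()`): mean removal, Hann taper,
  4× zero padding, argmax over 1–20 Hz, parabolic interpolation of the
  log-magnitude peak. Rationale: a 4 s window has 0.25 Hz native
  resolution; interpolation is needed to distinguish, say, 9.0 from
  9.2 Hz. A peak below 10× the in-band median magnitude is flagged
  non-oscillatory.
- **Synchrony** (`network_frequency()`): all neurons oscillatory with
  dominant frequencies within one native resolution bin — one shared
  frequency, phases free.
- **Phases** (`phase_map()`): peak-time based; each peak is matched to
  the nearest reference-neuron peak, the offset expressed in degrees of
  the reference inter-peak interval, and averaged circularly over all
  cycles in the window (the per-cycle and snapshot conventions agree for
  the stable phase relations studied here). Reported in (−180°, 180°],
  reference = 0°.
- **Wave order** (`wave_order()`): per cycle, Kendall concordance
  between cluster mean peak times and descending cluster mean g_Ca; +1
  is a perfect descending-g_Ca activation wave.

## The average-neuron rule

A strongly coupled ensemble behaves like a single cell carrying the
average conductance densities of its members.
`predict_average_neuron_frequency()` weights each neuron by
`1 + (its total junctional conductance)/(network mean)` — a pluggable
rule that reduces to the plain mean under homogeneous coupling and moves
the average toward strongly coupled clusters. Two validity notes,
established with the package's own test ensembles:

- For strongly coupled pairs of two dissimilar oscillators (CC 15–20%),
  the simulated synchronized frequency matches the average-neuron
  frequency within 10% (typically 1–3%).
- The complementary death prediction — no sustained oscillation when the
  average falls in the quiescent region — is a *strong-coupling* rule.
  At the physiological 20% CC cap the junctional shunt is only about a
  fifth of the leak conductance, which can quench oscillators near onset
  but not deep ones; the rule is therefore reliable when the average
  sits at least ~0.03 mS/cm² below onset and no member is more than
  ~0.1 above it.

## Known limitations

- **Modulation direction.** Redistributing inter-cluster coupling
  strengths (the sevenfold trend-consistent rule) moves the synchronized
  frequency of the default networks by only a few tenths of a hertz, and
  the dominant pathway is *pacemaker release*: weakening the binding of
  a fast cluster lets it pull the collective frequency up, while
  strengthening it drags the collective toward the compromise. Under the
  coupling-weighted-average picture the sign would be opposite. The
  direction and multi-hertz magnitude of coupling-controlled frequency
  shifts evidently depend on fine properties of the oscillation
  (its degree of nonlinearity and the shape of the interaction function)
  that the calibrated kinetics do not pin down; treat
  frequency-modulation *direction* results from this package as
  model-specific rather than general.
- Conditional-oscillator and bistable single-cell regimes are not
  distinguished; classification is binary (spontaneous oscillator vs
  stable), which is all the network results require.
- No chemical synapses, noise currents, dendritic structure or
  rectifying junctions; GABAergic control of coupling is represented
  only as conductance rescaling.
- The synthetic networks emulate the *statistical* constraints of IO
  anatomy (cluster sizes, degrees, CC ranges), not any measured circuit;
  passing tests show the mechanisms operate under those constraints, not
  that parameters match a particular animal.

## Problem sizes

The test suite runs single cells and 16–48-neuron networks over 1.5–10 s
of biological time; the constraint-closure property covers 100 random
generator specs; the acceptance script measures amplitudes over ten
4 × 12 networks (5 s each) and phase differences over thirty
inter-cluster coupling resamples of one network. These sizes were chosen
so the full suite completes in minutes on one core while every claim is
still exercised at the reference network scale.
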