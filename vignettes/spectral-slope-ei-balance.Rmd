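---
title: "Does the aperiodic exponent of population activity track EI balance? Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Does the aperiodic exponent of population activity track EI balance? Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question

The 1/f^&gamma; (aperiodic) component of LFP/EEG/MEG spectra has been
proposed as a non-invasive readout of the excitation-inhibition (EI)
balance of the underlying circuit, on the argument that inhibitory
synaptic currents are slower than excitatory ones and therefore shift the
spectrum's high-frequency decay. `eislope` implements the machinery to
test that proposal in silico: two conductance-based spiking network
models in which the ground-truth EI parameters are known exactly, an LFP
proxy, and a spectral pipeline that separates oscillatory peaks from the
aperiodic exponent. The headline observation the pipeline reproduces is a
negative one — across wide parameter sweeps, neither the network's
synaptic weights nor the measured conductance ratio predicts the
aperiodic exponent reliably.

# Models

## Neurons and synapses

All neurons are leaky integrate-and-fire point neurons,

$$C_m \frac{dV}{dt} = -g_L (V - V_{rest}) - \sum_c G_c(t)\,(V - E_c) + I_{ext},$$

with threshold/reset/absolute-refractory spiking. Each presynaptic spike
elicits an alpha-function conductance transient
$G(t) = g_{max} (t/\tau) e^{-t/\tau}$ on the receptor channel it targets;
channels differ only in time constant and reversal potential (a channel
with reversal above threshold is excitatory). The simulator integrates
the synaptic kernels exactly per step (two-state exponential update, so
superposition over spike trains is exact) and the membrane with forward
Euler at 0.1 ms (classical RK4 selectable via `method = "rk4"`). The
accuracy contract is behavioral rather than scheme-bound: halving the
step moves single-neuron spike times by less than 0.2 ms over 200 ms
(threshold crossings are interpolated within the step and the refractory
clock runs in continuous time, so single-neuron timing is second-order
accurate even though network delivery stays on the step grid).

During the refractory period the membrane is clamped at `V_reset` while
synaptic conductances continue to evolve. Initial potentials are drawn
uniformly in `[V_reset, V_th)`; conductances start at zero.

## The two motifs

`build_stn_gpe()` constructs the basal-ganglia loop: an excitatory STN
population (no recurrent E-E connections) and an inhibitory GPe
population, wired with fixed in-degrees (STN&rarr;GPe 20, GPe&rarr;STN
40, GPe&rarr;GPe 40; delays 5/5/2 ms), conductance weights of order 1 nS,
and one excitatory/one inhibitory channel per neuron (&tau; 5 / 10 ms,
reversals 0 / -80 mV). Four quantities are swept: the two background
Poisson rates and the two loop weights. A fifth input — an extra
inhibitory Poisson drive onto GPe, mimicking striatal input — is the
perturbation that externally shifts the EI balance.

`build_cortex()` constructs a recurrent E-I network in which every neuron
receives 800 excitatory afferents, &zeta; of them through slow NMDA
channels (&tau; 30 ms) and the rest through AMPA (&tau; 3 ms), plus 200
GABAergic afferents (&tau; 5 ms). `g` scales the inhibitory weights
relative to the published `g = 4` baseline column; &zeta; and the
background level &eta; complete the swept triple. The printed excitatory
reversal of -10 mV is implemented as printed (it is still 44 mV above
threshold, hence depolarizing; a switch to 0 mV is exposed since the
value is plausibly a typo). The multi-receptor arrangement is realized as
a single compartment with three conductance channels: the original
multi-compartment construction only served to host receptor ports, and
its coupling parameters are not published.

## Unpublished constants and how they were fixed

Several constants the models need are not in the published tables. They
were fixed once, by explicit criteria, and exposed as arguments:

* **Population sizes.** STN 1000 / GPe 2000; cortex E 8000 / I 2000
  (consistent with a 0.1 connection fraction and the 800/200 in-degrees).
  The desk-scale presets keep every in-degree exact and shrink
  populations: STN-GPe to 100/200; cortex to E 1000 / I 250 (an exact
  E 800 would make 800 distinct afferents per E neuron impossible once
  self-connections are excluded). Preserved in-degrees at reduced size
  raise shared-input correlations — see *Limitations*.
* **STN/GPe resting potential** (absent from the parameter table):
  -70 mV, equal to the reset and to the cortical leak reversal.
* **Background drive weights.** STN-GPe: 1.5 nS excitatory background
  (the scale of the STN&rarr;GPe weight) and the GPe recurrent weight
  0.725 nS for the 600 spikes/s inhibitory perturbation. Cortex: 2.0 nS.
  The cortical value is the one genuine calibration in the package: with
  the 0.13 nS recurrent-AMPA scale the pyramidal population saturates
  near 0.4 spikes/s at every drive level (the interneurons, which receive
  the same drive but weaker self-inhibition, always run away first), so
  no background rate reaches the published 0.68 spikes/s operating
  point. At 2.0 nS — a physiological unitary conductance — the E rate
  crosses 0.68 Hz on a wide, stable, asynchronous branch.
* **&eta; units and range.** &eta; multiplies the *threshold rate*
  &nu;~thr~ (`cortex_nu_thr()`): the Poisson rate whose mean (Campbell)
  conductance holds the steady-state potential exactly at threshold.
  With the calibrated background weight, the network's full repertoire —
  quiescent, asynchronous-irregular around the 0.68 Hz base state,
  oscillatory — spans &eta; &asymp; 0.5-1.5, so the sweeps default to
  that range ({0.6, 1.0, 1.4} at desk scale). On this branch the E rate
  *decreases* with &eta;: recurrent inhibition grows faster than the
  direct drive, the classic signature of an inhibition-dominated
  operating point.

## Seeds

A master seed fans out through a deterministic multiply-add scheme
(`seed_streams()`) into separate streams for wiring, initial conditions
and the Poisson drives; trial *k* of a configuration redraws init/drive
streams while the wiring stream is held fixed, so trial variability is
input variability, not structural. Every stage is bit-reproducible from
the master seed, which the tests assert at the level of written CSV
checksums.

# The measurement pipeline

**LFP proxy.** The excitatory and inhibitory conductances and the
membrane potential of 10 recorded excitatory neurons are sampled at
1 kHz; per neuron the synaptic current is
$G_{ex}(V - E_{ex}) + G_{in}(V - E_{in})$, summed (signed, by default)
over channels and neurons. Point neurons admit no better forward model;
a rectified-sum mode exists because the current-conversion convention is
not uniquely determined. A sampling-homogeneity check (10 vs 200
recorded neurons at full population size) confirms the proxy's slope
does not depend on the sample.

**Welch PSD.** Segments of M = 256 samples, 50% overlap, periodic Hann
window, per-segment mean detrend, one-sided density (verified identical
to `scipy.signal.welch` to 1e-13). Each 1700 ms trial contributes its
last 1000 ms (the first 700 ms are settling time), i.e. six averaged
segments at 3.906 Hz resolution.

**Oscillation index.** The PSD restricted to 5-150 Hz is normalized to
unit sum and scored by its normalized Shannon entropy:
OI = 1 - H~s~, so a flat spectrum gives 0 and a single-frequency
spectrum 1. The band is a display-band default (the defining equation
carries no band) and is exposed.

**Aperiodic exponent.** `fit_aperiodic()` parameterizes the 50-150 Hz
log-spectrum as a power law plus up to 16 Gaussian peaks, following the
spectral-parameterization algorithm with fixed aperiodic mode: a robust
initial power-law fit through the lower envelope (positive residuals
clipped before refitting, so peaks cannot drag the baseline up),
iterative peak extraction gated by max(0.01, 2 SD of the flattened
spectrum), band-edge and overlap pruning, joint bounded refinement of
the peaks, and a final plain fit on the peak-removed spectrum. The
reported R² is the squared correlation between log-PSD and the full
model. Non-convergent fits and fits with R² < 0.5 are excluded from
configuration averages with their counts logged. The 50 Hz lower bound
avoids the oscillation bands; 150 Hz avoids spectral plateaus; the wider
5-150 Hz fit is available behind the `band` argument.

**Fit-quality ceiling at desk scale.** Six averaged Welch segments leave
a per-bin log10 noise SD near 0.185 (&chi;² with ~12 degrees of
freedom). For exponents around 3-5 over 50-150 Hz this bounds the
attainable correlation-R² at roughly 0.87-0.95 unless strong in-band
peaks add variance for the model to explain. The STN-GPe sweep averages
R² &asymp; 0.945; the neocortical sweep averages &asymp; 0.90, and
values much above that are not reachable under this window length —
worth keeping in mind when comparing fit quality across studies whose
averaging differs.

# Experiments and statistics

`run_configuration()` simulates `n_trials` trials (25 in the full
protocol, 3 at desk scale) and averages OI, &gamma;, R² and the mean
E/I conductances over valid trials. `classify_state()` applies the
regime thresholds (low oscillation &le; 0.4 < intermediate &le; 0.6 <
high; high exponent &ge; 3); intermediate-OI configurations are excluded
from regime-conditioned statistics but retained in totals.
`transition_angle()` renders a perturbation as the angle of the
(&Delta;OI, &Delta;&gamma;) displacement in raw axis units, with a
min-max-normalized variant reported alongside because axis scaling
changes angles; histograms use 16 bins of 22.5&deg;. Group comparisons
of swept parameters are emitted as medians and IQRs per regime —
descriptive, not inferential.

The EI ratio is mean recorded excitatory over mean inhibitory
conductance; `ei_ratio_analysis()` reports Spearman rank correlations
between the ratio and &gamma;~avg~ per condition and pooled. The
qualitative NMDA result ("more NMDA steepens the spectrum") is scored as
the paired mean of &gamma;~avg~(&zeta;=500) - &gamma;~avg~(&zeta;=0)
across matched (g, &eta;) cells being positive: individual cells can
lose to trial noise at desk scale (typically 7-8 of 9 are positive), and
the paired mean is the faithful rendering of a claim made over a whole
sweep panel.

# The surrogate harness

`generate_powerlaw_signal()` synthesizes signals whose spectrum is
*exactly* a/f^&gamma;~true~ (inverse-FFT synthesis, amplitudes
f^-&gamma;/2, uniform random phases, optional Gaussian peaks in
log-power), which makes exponent recovery a closed-loop test of the
whole spectral pipeline: mean |&gamma;&#770; - &gamma;~true~| stays
below 0.05 for &gamma; in 1-4 over 20 seeds. One synthesis detail
matters: the power law is applied only above a 1 Hz plateau
(`lowcut_hz`), because a pure power law's divergent sub-resolution power
leaks through the analysis window's sidelobes and biases steep
exponents by ~0.3 — a property of unbounded-variance signals that no
physical trace shares, not of the estimator. `generate_shot_noise()`
(Poisson trains through the exact alpha-kernel propagator) closes the
loop on the physics side: its mean obeys Campbell's theorem to within
sampling error, and its 100-150 Hz slope sits near the kernel's f^-4
asymptote (3.9 &plusmn; 0.4 over seeds; the asymptote is only reached as
f&tau; &rarr; &infin;).

# What the desk-scale tests do and do not show

The mini presets (81 STN-GPe configurations, 27 neocortical, 3 trials,
reduced populations) reproduce the study's *qualitative* structure: two
oscillation regimes; GPe inhibition moving &gamma; in both directions
across configurations (transition angles cluster around 67-90&deg; and
270-292&deg;); inhibition increases (g 4&rarr;8, 12) likewise mixed in
sign; the NMDA steepening; and the absence of a strong monotonic
EI-ratio/&gamma; relationship. They do not reproduce population-size-
dependent quantities: shared-input correlations are an order of
magnitude stronger at 1/10 scale, which inflates oscillation indices and
trial variance, and the 10-neuron LFP homogeneity only holds at full
size. The full protocol (625 configurations &times; 25 trials, full
populations) runs through the same code paths via
`run_experiment(..., preset = "full")`.

# Known limitations

* Homogeneous populations, fixed weights per projection, no plasticity,
  no conduction-delay sweeps, no dendritic filtering: the LFP proxy is a
  summed point-neuron current, so spatial aspects of real LFPs are out
  of scope by construction.
* The NMDA channel has no Mg²⁺ block (near-threshold depolarized
  membranes justify the omission at point-neuron resolution).
* Euler overshoot can abort integration during extreme synchronous
  volleys (the simulator then raises a diagnosed numeric error rather
  than returning corrupt data; such trials are flagged and excluded by
  the sweep layer).
* The aperiodic fit assumes a single power law in-band ("fixed" mode);
  knee-mode fitting and spectrograms are out of scope.
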