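# eislope

Can the excitation-inhibition (EI) balance of a neural circuit be read
off the spectrum of its population activity? A widely used argument says
yes: inhibitory synaptic currents are slower than excitatory ones, so the
aperiodic (1/f^γ) exponent of the LFP/EEG spectrum should steepen when
inhibition dominates. `eislope` provides the simulation and analysis
machinery to test that claim where the ground truth is known — in
conductance-based spiking network models — and finds, across wide
parameter sweeps, that it does not hold in general.

The package is aimed at computational neuroscientists who want a
self-contained, seeded, testable pipeline from network specification to
aperiodic exponent.

## What is inside

* **Simulator** — fixed-step (0.1 ms) conductance-based leaky
  integrate-and-fire networks with alpha-function synapses
  (`g_max (t/τ) e^{-t/τ}`, integrated exactly per step), fixed in-degree
  random wiring, per-connection delays, independent Poisson background
  drives, and 1 kHz recording of conductances and membrane potentials
  (Rcpp core; `simulate_network()`).
* **Two network motifs** — the STN–GPe loop of the basal ganglia (E–I
  without E–E recurrence; `build_stn_gpe()`) and a recurrent neocortical
  E–I network with AMPA/NMDA/GABA channels (`build_cortex()`), both built
  from published parameter tables, plus sweep grids (`stn_gpe_grid()`,
  `cortex_grid()`, `enumerate_grid()`).
* **Spectral pipeline** — LFP proxy as the summed synaptic current of 10
  recorded excitatory neurons (`make_lfp()`), Welch PSD (M = 256, 50%
  overlap, Hann; `welch_psd()`), an entropy-based oscillation index
  `OI = 1 − H_s ∈ [0, 1]` (`oscillation_index()`), and aperiodic-exponent
  estimation by spectral parameterization into
  `log10 P(f) = b − γ log10 f` plus up to 16 Gaussian peaks in the
  50–150 Hz band (`fit_aperiodic()`).
* **Experiments** — trial-averaged sweeps (`run_configuration()`,
  `run_sweep()`), regime classification, perturbation experiments with
  transition-angle statistics (GPe inhibition; raising cortical `g`), EI
  conductance-ratio analysis, and a calibration search for the cortical
  base state (`calibrate_cortex_background()`); `run_experiment()` ties a
  whole experiment into a CSV/JSON bundle with a manifest.
* **Surrogate harness** — signals with exactly known aperiodic exponent
  and injected peaks (`generate_powerlaw_signal()`) and alpha-kernel shot
  noise (`generate_shot_noise()`) for closed-loop validation.

The `analysis/` directory holds the numbered drivers that run the study
end to end (surrogate validation, STN-GPe sweep, cortical calibration,
cortical sweep, EI-ratio analysis), writing their tables under
`results/`.

## Worked example

One STN-GPe configuration at desk scale (populations 1/10, published
in-degrees preserved), one 1700 ms trial, then the 3-trial summary:

```r
library(eislope)

cfg <- build_stn_gpe(stn_bg = 1900, gpe_bg = 1200, w_stn_gpe = 1.5,
                     w_gpe_stn = -1.3, sizes = preset_sizes("stn_gpe", "mini"))
sim <- simulate_network(cfg, duration_ms = 1700, seeds = seed_streams(1))
firing_rates(sim, window = c(700, 1700))
#>   STN   GPe
#> 20.69 53.57

analyze_trial(sim)   # last 1000 ms: Welch PSD -> OI + aperiodic fit
#> spectrum_result: OI=0.530 gamma=2.66 R2=0.956 EI=0.52

summ <- run_configuration(cfg, n_trials = 3, master_seed = 1)
summ[, c("OI_avg", "gamma_avg", "mean_R2", "G_ex", "G_in", "EI_ratio")]
#>   OI_avg gamma_avg mean_R2   G_ex G_in EI_ratio
#> 1  0.516     3.364   0.966 14.352   28    0.513
classify_state(summ)
#> $oscillation: "intermediate"   $exponent: "high"
```

STN fires near 21 spikes/s and GPe near 54 spikes/s; the trial's spectrum
has moderate oscillatory concentration (OI 0.53), an aperiodic exponent
averaging 3.4 over trials (a "high exponent" state), and the recorded
neurons receive about twice as much inhibitory as excitatory conductance
(EI ratio 0.51). Adding `perturb_rate = 600` to the builder applies the
inhibitory drive onto GPe; across the sweep grid the same perturbation
raises γ in some configurations and lowers it in others — the core
negative result.

The full study at desk scale:

```sh
Rscript analysis/01_surrogate_validation.R 1
Rscript analysis/02_stn_gpe_sweep.R 1
Rscript analysis/03_cortex_calibration.R 1
Rscript analysis/04_cortex_sweep.R 1
Rscript analysis/05_ei_ratio.R
```

The methods vignette (`vignettes/spectral-slope-ei-balance.Rmd`) explains
the models, every tunable parameter, the unpublished constants and how
they were fixed, and what the desk-scale runs do and do not establish.

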