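# hcspike

Highly comparative analysis of synchrony, oscillations, and phase
relationships in multineuron spike trains.

Neuroscientists quantify collective spiking with many competing
statistics — spike train distances (Victor–Purpura, van Rossum, SPIKE-
and ISI-distance, earth mover's, modulus metric), coincidence and
correlation measures (correlation index, spike time tiling coefficient,
Schreiber/Kruskal correlations, event synchronization), phase measures
(mean phase coherence, pairwise phase consistency), population measures
(Tiesinga–Sejnowski, Golomb–Rinzel, SPIKE-synchronization,
Spike-Contrast, a synfire indicator), univariate ISI variability
statistics, and spectral parameters of the population rate (Welch
spectrum plus an aperiodic `b_L − χ_L·log10 f` component with Gaussian
peaks). Each is sensitive to a different mixture of synchrony,
rhythmicity, firing rate and sample size. `hcspike` evaluates *all* of
them at once — a core set of 46 measures, or an extended set of 131
with 7 timescales (1–64 ms) for the timescale-dependent measures and a
dual-peak spectral model — turning a recording into a
trains-(or windows-)by-measures matrix that can be clustered, embedded,
decoded, and dimension-estimated.

Because real recordings have no ground truth, the package ships the two
synthetic families used to profile the measures:

* **single-scale**: inhomogeneous Poisson processes with rate
  `r(t) = r0 [1 + m sin(2π f0 t + φ)]`, where the phase is either linear
  with Ornstein–Uhlenbeck noise (pseudo-rhythmic) or piecewise linear
  with refractory-exponential inter-node intervals (non-rhythmic);
  `m` controls synchrony;
* **dual-scale**: doubly stochastic processes — population events
  (phase-threshold crossings or a refractory-exponential renewal
  process at rate ≈ `f0`) with per-neuron Gaussian jitter of SD
  `Σ/f0` and deletion probability `p_fail`; `1/Σ` controls synchrony
  tightness.

Both support sequential (leader-to-follower) structure through a duty
cycle `Dc`, and a 900-train benchmark grid crosses all parameters.

## Worked example

```r
library(hcspike)

p  <- dual_scale_params(Sigma = 0.2, p_fail = 0.2, f0 = 12,
                        rhythmic = TRUE, N = 20, T = 10)
st <- generate_dual_scale(p, seed = 7)
st
#> spike_train: 20 neurons over [0, 10) s, 1907 spikes (9.54 Hz/neuron)
#>   meta: family=dual_scale Sigma=0.2 p_fail=0.2 f0=12 rhythmic=TRUE Dc=0 sequential=FALSE seed=7

mv <- measure_vector(st, "core")
round(mv[c("C_i", "STTC", "S_GR", "S_TS", "S_S", "MPC", "PPC",
           "r", "CV_ISI", "f_max", "A_G")], 3)
#>    C_i   STTC   S_GR   S_TS    S_S    MPC    PPC      r CV_ISI  f_max    A_G
#>  1.381  0.007  0.252  0.093  0.646  0.195  0.031  9.535  0.486 12.000  2.203
```

Reading the numbers: spikes are locked to population events every
`1/f0` ≈ 83 ms with 17 ms Gaussian jitter, so the 1 ms correlation
index is only mildly elevated above its chance level of 1
(`C_i = 1.38`) and the 1 ms tiling coefficient is near 0, while the
event structure shows clearly in SPIKE-synchronization (`S_S = 0.65`),
in the spectral peak at exactly the population frequency
(`f_max = 12 Hz`, amplitude `A_G = 2.2` log-power units), and in the
per-neuron rate `r ≈ 9.5 Hz` (12 events/s thinned by
`p_fail = 0.2`).

Downstream, `run_benchmark()` produces the trains × measures matrix
for the full grid, `param_correlations()` profiles every measure
against the generative parameters, `measure_distance_matrix()` +
`cluster_measures()` give the empirical organization of the library,
`bias_variability_sweep()` quantifies finite-window / finite-population
bias and variability, and `windowed_measure_matrix()` +
`silhouette_fingerprint()` + `decode()` apply the same machinery to
windowed recordings. A thin command-line wrapper with subcommands
(`generate`, `measure`, `benchmark`, `profile`, `cluster`, `biasvar`,
`windows`, `fingerprint`, `decode`, `id`) is installed at
`inst/cli/hcspike-cli.R`.

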