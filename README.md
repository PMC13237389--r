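# ecapipg

Analysis of electrically evoked compound action potentials (eCAPs) recorded
through cochlear implants: trial-to-trial neural synchrony via the phase
locking value (PLV), amplitude-growth-function (I/O) feature extraction on
linear and logarithmic stimulus/amplitude scales, sigmoidal and exponential
growth-model fitting, and quantification of the interphase-gap (IPG)
effect — including the stimulation level offset between 7-µs and 42-µs IPG
conditions. Intended for auditory electrophysiologists and methodologists
who need a tested, scriptable implementation of this analysis chain, plus a
seeded synthetic-data module for validating every stage without patient
data.

## The quantities it computes

**Phase locking value.** From N repeated eCAP sweeps, a Hanning-tapered
short-time Fourier transform yields complex spectral estimates F_k(f, t)
(frame size 26 samples ≈ 1268.8 µs at 20 492 Hz, pad ratio 2, six frames at
50 % overlap, six frequencies 788.2–4729.2 Hz), and

    PLV(f, t) = | (1/N) Σ_k F_k(f, t) / |F_k(f, t)| |,

averaged over all 36 time–frequency cells into a single synchrony index in
[0, 1].

**Growth-function features.** Per (electrode, IPG): eCAP threshold (lowest
measured level with amplitude ≥ 5 µV; nC and dB re 1 nC), maximum amplitude
(µV, dB re 1 µV), dynamic range, overall linear slope between threshold and
C level, and the window-method maximum slope (resample to 11 points, eight
sliding 4-point regressions, keep the steepest) — each slope on three
scales: µV/nC, µV/dB re 1 nC, dB re 1 µV/dB re 1 nC.

**Stimulation level offset.** Amplitudes of both IPG conditions are
normalized to the IPG-7 maximum and fitted with

    eCAP_N = y0 + a / (1 + exp(-(x - b)/c));

the offset is the mean difference in stimulation level at 25/50/75 % of the
overlapping fitted amplitude range, obtained by closed-form sigmoid
inversion. The IPG effect of any dependent variable is DV_IPG42 − DV_IPG7.

## Worked example

```r
library(ecapipg)

# neural synchrony from 400 simulated sweeps with realistic jitter + noise
sw <- simulate_sweeps(sweep_sim_config(n_sweeps = 400, latency_jitter_sd = 20,
                                       amplitude_jitter_cv = 0.1, noise_sd = 5,
                                       seed = 42))
plv(sw)
#> PLV grid: 6 frames x 6 frequencies (N = 400 trials), aggregate 0.2391
#>      freq
#> frame 788.2Hz 1576.4Hz 2364.6Hz 3152.8Hz 3941.0Hz 4729.2Hz
#>    t1   0.996    0.991    0.964    0.909    0.766    0.517
#>    t2   0.952    0.806    0.374    0.158    0.028    0.023
#>    t3   0.014    0.064    0.064    0.064    0.097    0.089
#>    ...

# paired-IPG growth functions for a cochlear-nerve-deficiency scenario
pair <- simulate_io_pair(io_sim_config(scenario = "CND",
                                       electrode_position = "apical",
                                       noise_sd = 3, seed = 42))
offset_all_scales(pair[["7"]], pair[["42"]])$S1
#> stimulation level offset (nC): 3.876 (overlap 0.12..1.02)
#>   quantile target_amplitude level_ipg7 level_ipg42 difference
#> 1     0.25            0.344      8.895       5.323      3.571
#> 2     0.50            0.568     10.994       6.974      4.020
#> 3     0.75            0.792     13.090       9.052      4.039
```

Early frames that contain the eCAP deflection phase-lock almost perfectly
(PLV → 1) while later, noise-only frames sit at the random-phase floor
(≈ 0.04 for N = 400), giving the moderate aggregate typical of noisy
recordings. The apical-CND scenario's generating sigmoids are shifted by
4 nC between IPGs; the recovered offset (3.88 nC, per-quantile differences
3.6–4.0) reflects that ground truth through noise. `compute_ipg_effects()`
expands the same pair into the full 13-row effects table (threshold, max
amplitude, slopes, offsets), and `run_study()` scales this to a simulated
cohort with tidy CSV outputs ready for external mixed-model analysis.

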