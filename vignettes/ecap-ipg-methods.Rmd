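---
title: "Methods: eCAP growth functions, neural synchrony, and the IPG effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eCAP growth functions, neural synchrony, and the IPG effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecapipg)
```

## The measurement problem

The electrically evoked compound action potential (eCAP) is the cochlear
nerve's summed response to a single electrical pulse, recorded through a
cochlear implant's own electrodes. Two families of eCAP-derived quantities
are widely used to probe the functional status of the nerve:

* **Neural synchrony** — how reproducibly the nerve fires across repeated
  identical stimuli. This is quantified by the *phase locking value* (PLV),
  a trial-to-trial phase-coherence statistic computed from several hundred
  single-sweep recordings.
* **The interphase-gap (IPG) effect** — how eCAP growth with stimulus level
  changes when the silent gap between the two phases of the biphasic pulse
  is lengthened (here, 7 µs vs. 42 µs). A longer IPG makes the pulse more
  efficient, shifting and steepening the amplitude growth function (AGF;
  also called the input/output or I/O function). Animal work ties the size
  of this effect to the number of surviving nerve fibers, which makes it a
  candidate clinical biomarker.

`ecapipg` implements the complete analysis chain for both families, plus a
seeded synthetic-data module that emulates the sweep sets and paired-IPG
growth functions the analysis expects, so every stage can be exercised and
validated without patient data.

## Phase locking value

For $N$ sweeps, the short-time Fourier transform of sweep $k$ yields a
complex spectral estimate $F_k(f, t)$ per analysis frequency $f$ and time
frame $t$, and

$$\mathrm{PLV}(f,t) = \left| \frac{1}{N} \sum_{k=1}^{N}
\frac{F_k(f,t)}{\left|F_k(f,t)\right|} \right|,$$

the modulus of the mean unit phasor: 0 means no phase agreement across
trials, 1 perfect agreement. A single synchrony index is the arithmetic
mean over all frames and frequencies.

Defaults (all configurable via `plv_config()`):

| parameter | default | why |
|---|---|---|
| frame size | 26 samples (1268.8 µs at 20 492 Hz) | matches the interphase latency scale of the response; sets the 788.2-Hz spectral resolution |
| pad ratio | 2 (DFT length 52) | interpolates the spectrum so the six analysis frequencies land on bins 2, 4, …, 12 |
| taper | Hanning | standard leakage control for short frames |
| frequencies | 788.2–4729.2 Hz, step 788.2 Hz | one spectral-resolution step up to the highest harmonic band that carries meaningful eCAP energy |
| frames | 6, hop 13 samples (50 % overlap) | spans ≈4.44 ms from the start of the record, covering the window where the eCAP is expected |

Two details are deliberate choices rather than given facts. First, the hop:
"partially overlapped" frames admit several placements; 50 % overlap is the
common convention and is configurable. Second, the printed frequencies are
nominal labels: the realized bin frequencies are $k \cdot 20492/52$
(788.15, 1576.3, … Hz); `PLVGrid` objects record both.

Numerical policy: a spectral estimate with zero magnitude carries no phase,
so it raises an error naming the (trial, frame, frequency) cell rather than
being dropped — silent exclusion would bias the mean phasor. All-zero
recordings therefore fail loudly at the PLV stage.

## Growth-function features

For each (electrode, IPG) condition the package extracts, via
`io_features()` and friends:

* **eCAP threshold** — the lowest *measured* level whose amplitude is
  ≥ 5 µV (boundary inclusive), with no interpolation; reported in nC and
  dB re 1 nC. Functions never reaching 5 µV yield a typed "no threshold"
  result that propagates as a missing dependent variable.
* **Maximum amplitude** — max over measured points, in µV and dB re 1 µV.
* **Dynamic range** — C level minus threshold level, in CL steps.
* **Overall linear slope** — OLS slope over all points between threshold
  and C level inclusive.
* **Window-method maximum slope** — the function is resampled to 11 equally
  spaced input values by piecewise-linear interpolation (monotone, no
  overshoot), eight sliding 4-point regressions are fitted, and the
  steepest is kept (ties break toward the lower-level window). This tracks
  the growth function's derivative at its inflection and stays stable when
  the measured range stops short of saturation, where sigmoid fits become
  poorly constrained.

### Scales

Levels are converted CL → current via the device law
$I(\mu A) = 17.5 \times 100^{\mathrm{CL}/255}$ (config-overridable, since
clinical tables state levels in CL without fixing the law), then
current → charge per phase $Q(\mathrm{nC}) = I \cdot \mathrm{phase}/1000$.
Three input/output scales are supported: S1 = (nC, µV),
S2 = (dB re 1 nC, µV), S3 = (dB re 1 nC, dB re 1 µV); both dB axes use the
20-log amplitude convention. The (nC, dB) combination has no physiological
rationale and is rejected at the type level. Offset variants computed on
S2 and S3 are labelled `dB_linear/log` and `dB_log/log`; note the
`dB_linear/log` *label* follows the clinical literature while the axis
convention actually used (log input, linear output) is emitted alongside in
every output, because the literature's own description of that variant is
internally inconsistent.

### Growth models

Two nonlinear models are fitted by Levenberg–Marquardt least squares
(`minpack.lm::nls.lm` core, analytic Jacobians):

$$\mathrm{eCAP}_N = y_0 + \frac{a}{1 + e^{-(x-b)/c}}
\qquad\text{and}\qquad
y = y_0 + a\,(1 - e^{-b x}).$$

Initialization: $y_0 = \min y$, $a = \mathrm{range}(y)$, $b$ at the
half-range crossing, $c = \mathrm{range}(x)/8$ (sigmoid); analogous
moment-based starts for the exponential. Convergence is reported, never
assumed; non-convergence yields a flagged result and downstream stages
propagate missingness instead of fabricating values.

Degeneracy handling deserves a note. Exactly linear data are fitted by a
sigmoid only in the limit $c \to \infty$ (with $a/c$ fixed), and exactly
exponential data only in the limit $a, b \to \infty$: unbounded fits then
crawl along a flat valley and stop at an optimizer-dependent point. The
fits therefore carry explicit degeneracy bounds — $c \le 50 \cdot
\mathrm{range}(x)$ and $a \le 100 \cdot \mathrm{range}(y)$ — which turn
those limits into well-defined constrained optima; a fit on a bound is
flagged `at_bound`. This matters for reproducibility: level offsets
computed through such fits become stable to ~1e-10 against
last-digit perturbations of the input, where the unbounded fits amplified
them to ~1e-7.

### Shape classification

On the S3 (log/log) display some growth functions keep their sigmoidal
look and others appear exponential. The package replaces visual inspection
with a reproducible rule: fit both models on the S3 coordinates and label
the function `exponential-transitioned` when the exponential's adjusted
R² exceeds the sigmoid's by more than a margin (default 0.01, reported in
the result). Because the 4-parameter sigmoid is flexible enough to track
essentially any monotone noise-free curve, transitions are only declared
on data where noise makes the raw fits comparable and the parsimony
correction favors the 3-parameter model — which is also why the margin is
configurable. A fit stopped at the iteration cap still participates via
its adjusted R²; only fits without a usable score leave the function
unclassified.

## Stimulation level offset

The offset between paired IPG conditions is computed exactly as the
clinical method prescribes (`normalize_pair()`,
`stimulation_level_offset()`):

1. normalize both amplitude vectors by the *maximum measured amplitude of
   the IPG-7 function* (before any output log transform, so the IPG-42
   curve may exceed 1);
2. fit the sigmoid to each normalized function on the working scale;
3. intersect the two fitted amplitude ranges, each evaluated over that
   function's measured level span (the "overlapping amplitudes");
4. take amplitude targets at 25/50/75 % of the overlap — on the working
   output scale, so dB-scale offsets use dB-space quantiles;
5. invert each sigmoid in closed form,
   $x = b - c \ln(a/(y-y_0) - 1)$, and average the three level
   differences $x_7(y) - x_{42}(y)$.

Sign convention: positive when the 42-µs IPG reaches equal normalized
amplitude at a lower level (the long gap is more efficient). Every result
carries the overlap endpoints, the per-quantile table, and both fits, so
each reported number can be audited. Any failure — non-converged fit,
empty overlap — yields a missing offset with a reason code.

The IPG effect of any dependent variable is
$\mathrm{DV}_{\mathrm{IPG}42} - \mathrm{DV}_{\mathrm{IPG}7}$
(`compute_ipg_effects()`); offsets are intrinsically paired and enter the
effects table directly.

## The synthetic-data module

Because no public eCAP sweep or AGF data accompany the analysis protocol,
the package ships generators whose defaults define the study conditions
the tests exercise.

**Sweeps** (`simulate_sweeps()`): each sweep is a smooth biphasic template
— a sharp negative Gaussian lobe (N1 trough, 300 µs latency, 80 µs width)
followed by a broad positive lobe (P2, 650 µs, 250 µs width) — re-evaluated
at per-sweep time-shifted points (latency jitter ~ Normal(0, σ), continuous
rather than integer-sample, to avoid quantization artifacts), scaled by a
mean-1 lognormal amplitude factor, plus white noise. The sharp N1 places
harmonic energy into the 3–5 kHz analysis bins, consistent with the
rationale for the 4729.2-Hz upper analysis bound; noise SDs of 2–20 µV
bracket reported device noise floors. Under these defaults, realistic noisy
sweep sets yield aggregate PLVs around 0.15–0.35: the 4.44-ms analysis
window outlives the ~1.5-ms deflection, so late frames contribute
noise-floor cells (for uniformly random phases the expected per-cell PLV is
$\sqrt{\pi/(4N)} \approx 0.044$ at $N = 400$). What the generator does
*not* emulate: stimulus artifact, amplifier saturation, facial-nerve or
vestibular contamination, or any dependence of morphology on level.

**Paired-IPG growth functions** (`simulate_io_pair()`): amplitudes are a
ground-truth sigmoid of charge evaluated on a CL 120–200 grid (step 5,
C level 200), plus Gaussian noise, floored at 0 µV. The preset table
(`scenario_presets()`, version 1) encodes the qualitative group structure
of the three clinical populations — CND (cochlear nerve deficiency): low
maximum amplitude (80–120 µV), shallow slope, and an IPG-42 leftward shift
of 1.5/2.5/4.0 nC at basal/middle/apical electrodes (fiber count falls
base-to-apex in this population); NSCN and GJB2: high amplitude (350–450
µV), steep slope, small shifts (0.7/0.6 nC) without an electrode gradient.
These presets are illustrative constructions, not fits to patient
statistics; tests that "recover" them demonstrate pipeline correctness,
not clinical validity.

**Quadratic forward model** (`brochier_forward()`):
$V = r\,n\,(s\,g\,I)^2$ with recording-electrode factor $r$, local neuron
count $n$, stimulating-electrode factor $s$, and IPG-specific gain $g$.
After log transformation all factors are additive, so level offsets between
two IPG conditions depend only on the gain ratio: on a dB input axis the
offset is $20\log_{10}(g_{42}/g_7)$, independent of $r, n, s$. The offset
module reproduces this invariance numerically — exactly (bitwise) when the
shared factors are IEEE-representable scalings such as powers of two, and
to ~1e-10 for arbitrary factors, the residual being input rounding times
the conditioning of the constrained sigmoid fit on exactly log-linear data.

**Seeding**: every generator is a pure function of (config, seed); the
study driver expands one top-level seed into per-ear substreams via
$\mathrm{seed}_i = (\mathrm{seed} + 7919\,i) \bmod (2^{31}-1)$, and
generators restore the caller's RNG state.

## The study pipeline

`run_study()` simulates a cohort (default 10 subjects × 3 groups × 3
electrode positions), computes per-ear PLVs, per-IPG features, offsets and
effects, and emits tidy long-format tables (`write_study()`: `effects.csv`,
`plv.csv`, `offsets.csv`, `features.csv`, `stats.csv`, `sensitivity.csv`,
`manifest.json`). Group-level mixed-model inference is intentionally *not*
implemented: the effects table carries subject/electrode/group columns
ready for any external mixed-model tool, which is standard machinery rather
than this package's contribution. Built-in statistics are limited to
Spearman PLV–offset correlations (Bonferroni across the three offset
scales), Mann–Whitney comparisons of maximum amplitude and dynamic range
between shape-transitioned and shape-preserved functions (Benjamini–
Hochberg adjusted), and a descriptive three-tier sensitivity
classification of each DV × scale (group and location / group only /
insensitive) based on standardized contrasts with a configurable threshold
(default 0.8) — a simulation-based mirror of the clinical reporting
structure, not a clinical claim. Missing DVs are excluded listwise per
(parameter, scale) and counted in the manifest; per-ear failures are
isolated and reported rather than aborting the run.

Problem sizes: the default demo (90 ears, 400 sweeps each) runs in a few
seconds; the test suite uses 2 subjects per group and 40–60 sweeps where
full scale adds nothing to the property under test.

## Known limitations

* The sweep simulator's two-lobe template is a deliberate idealization;
  PLV values on real recordings depend on morphology details it omits.
* The eCAP threshold inherits every limitation of the 5-µV criterion:
  with realistic noise, sub-threshold points occasionally exceed 5 µV and
  produce spuriously low thresholds — mirroring the measurement's real
  sensitivity to device noise floors.
* Scenario presets encode ordering and separation, not distributions;
  group-level simulated statistics should never be read as predictions of
  patient data.
* The offset is defined only where both sigmoid fits converge and their
  amplitude ranges overlap; strongly non-sigmoidal functions yield missing
  offsets by design.
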