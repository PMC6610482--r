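---
title: "Methods: synthetic optical mapping and OAP analysis in atrialmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic optical mapping and OAP analysis in atrialmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`atrialmap` couples two things: the analysis chain used on real
voltage-dye movies of patterned cardiomyocyte monolayers, and a
simulator that produces such movies with known ground truth. This
vignette is the package's account of the underlying models, the
numerical choices, and what the synthetic validation does and does not
establish about real recordings.

## The tissue model

The monolayer is a two-variable excitable medium on a pixel grid — an
Aliev–Panfilov activator/recovery pair with diffusive coupling:

$$\partial_t u = D \nabla^2 u
  + \tfrac{1}{\tau}\big[-k\,u(u-a)(u-1) - u v + I_{stim}\big],
\qquad
\partial_t v = \tfrac{1}{\tau}\,\varepsilon(u,v)\,
  \big[-v - k\,u(u-a-1)\big],$$

with $\varepsilon(u,v) = \varepsilon_0 + \mu_1 v/(u+\mu_2)$. $u$ is the
normalized membrane potential (0 rest, ~1 peak), $v$ a lumped recovery
variable, and $\tau$ (`time_scale`, ms per dimensionless time unit) maps
the model to milliseconds. This class of phenomenological model
reproduces the features the pipeline measures — upstroke, plateau,
rate-dependent APD shortening (restitution), refractoriness, and
curvature-sensitive propagation — at desk-scale cost; it does not
resolve ionic currents, and no claim about specific channels should be
read into it.

Fibroblast pixels are electrically passive: no reaction terms, a leak
$g_{fb}(u_{rest}^{fb} - u)$ pulling toward a less-negative rest level
(`u_rest = 0.1`), and diffusive coupling retained at a reduced
coefficient (`coupling = 0.6`). They therefore never fire but load and
depolarize their neighbours — an electrotonic/capacitive-loading stand-in
for heterocellular coupling, not a fibroblast membrane model.

Field stimulation is a spatially uniform suprathreshold current over the
pacing zone for a 10 ms pulse width; the experimental voltage-to-current
mapping is not modelled, so the stimulus amplitude (3 on the
dimensionless current scale) is simply comfortably suprathreshold.
Spontaneous beating is modelled as pacemaking at the preset's intrinsic
cycle length from the same zone: the rate is a preset constant, because
in the calibration data the spontaneous rate is a group-level observable,
not something a two-variable model should be asked to predict.

Boundary conditions are no-flux at every tissue border, implemented by a
mask-aware Laplacian whose edge weights are harmonic means of the two
pixels' diffusion coefficients (zero into background).

## Geometries and the recording window

`build_geometry()` constructs the full plate: two discs of 6 mm radius
joined by a strand — 1.5 mm wide by default for the narrow-isthmus model
(the fabricated strands span 1–2 mm; 1.5 mm is the midpoint), 12 mm
(the disc diameter) for the uniform model. `recording_window()` builds
the part the camera sees: a 5.76 × 4.8 mm field from 1.76 mm of strand
across the narrow-to-wide transition into the distal disc, with the
stimulation source mapped to the proximal strand strip inside the
window. Simulating only the window keeps the cost proportional to what
is analysed; the distal disc boundary inside the window is the true
circular arc, so the expansion geometry is exact.

## Numerical choices

- **Grid**: 120 µm pixels by default (the pitch is a parameter). At this
  pitch the 1.5 mm strand spans 12.5 pixels and the conduction
  wavelength hundreds of pixels, which resolves the expansion
  phenomenology; the camera-format 30 µm pitch is available but costs
  ~250× more through the explicit stability bound.
- **Time step**: forward Euler at 0.05 ms, validated against
  `dt <= dx^2/(4D)` and a reaction-stiffness bound `tau/(2k)`;
  configurations violating either are rejected before stepping, and
  non-finite states abort with a diagnostic.
- **Recording**: the membrane potential is stored at the camera frame
  interval (5 or 10 ms).
- **Heterogeneity**: per-preparation excitability jitter multiplies the
  threshold `a` by `1 + 3 * excitability_sd * smooth3(N(0,1))` (3×3
  smoothed so the heterogeneity lives above single-pixel scale). The
  default SD of 1 % keeps the calibrated conduction phenomenology stable
  across seeds while making preparations non-identical.

## The camera model

`render_fluorescence()` maps $u$ to counts as
$F = F_0(1 - g\,u) + \text{drift}(t) + \mathcal{N}(0, \sigma)$, with
$F_0 = 2000$ counts, gain $g = 0.08$ (an 8 % fractional signal, typical
of modern VSD recordings), a small cubic drift (default coefficients 8,
−1.2, 0.06 counts/s^k; emulating photobleaching and illumination drift),
and Gaussian noise of 1 % of $F_0$. The polarity is negative —
fluorescence falls on depolarization — so the pipeline's inversion step
recovers upright OAPs. Background pixels emit a dim (3 % of $F_0$)
baseline with reduced noise, below the 10 % masking threshold by
construction. Frames are digitized to non-negative 16-bit integers,
which is also what makes TIFF round trips bit-exact.

## The conditioning chain

The chain runs in a fixed order — mask → ΔF/F → 3×3 binning → inversion
→ FFT low-pass → polynomial detrending — and records that order in the
result's provenance. Choices the chain's definition leaves open were
resolved as follows:

- **Masking**: a pixel is kept iff its temporal maximum is at least 10 %
  of the field maximum, boundary inclusive.
- **F₀**: the per-pixel 90th percentile of raw intensity over time.
  Under a negative-polarity dye, diastole is bright and occupies most
  frames, so a high percentile tracks the diastolic level and is robust
  to beats occupying a minority of frames.
- **Binning at mask edges**: mean over masked-in neighbours only; zero
  padding would darken the tissue rim.
- **Low-pass**: a full-length DFT with hard zeroing of all bins strictly
  above fs/10, applied per pixel (it precedes ROI selection in the
  chain), no window function — the operation is a stated cutoff, not a
  designed filter.
- **Detrending**: least squares of a cubic (order configurable) on the
  running diastolic baseline — the lowest-residual quartile within each
  of up to 8 time windows, refined over 3 fit/reselect iterations. The
  windowing forces the baseline set to span the record, which keeps the
  polynomial interpolating rather than extrapolating; exact polynomial
  drifts are recovered exactly.

## OAP metrics

Beats are local maxima with prominence at least 30 % of the trace range
and 100 ms minimum separation — permissive enough for 7 Hz pacing
(143 ms period), strict enough to reject filtered noise and the
late-repolarization remnants of previous beats. CL is the mean
peak-to-peak interval. Each beat's baseline is the median of the 50 ms
before its upstroke foot (a same-beat reference robust to residual
drift); APD_x runs from the interpolated 50 %-upstroke crossing to the
interpolated x %-repolarization crossing; d(−F)/dt_max is the maximal
frame difference of the amplitude-normalized upstroke, reported per
frame (the conventional A.U. scale) and per ms. Per-ROI parameters
average the first 5 consecutive beats with complete measurements; the
preparation value averages its usable ROIs (5 programmatic ROIs along
the conduction axis by default — "several ROIs" is unquantified in
practice, so 5 is a fixed choice). Alternans is quantified as
|mean(odd) − mean(even)|/mean(all) over amplitude and APD90.

## Conduction classification

Activation time is the time of OAP peak intensity per pixel within a
one-cycle window, with parabolic sub-frame refinement. A pixel is
*undefined* unless its in-window peak is interior and rises by ≥ 30 % of
the pixel's whole-trace range before the peak: a decaying
repolarization tail entering the window — the classic false-positive in
blocked regions — has its maximum at the window start and is rejected.

An epoch is **maintained** when every stimulus elicits a strand beat and
a beat at every distal ROI within 120 ms (slow monolayer conduction at
~13 cm/s crosses the field in ~40 ms; the bound leaves room for
peak-time lag after filtering); **no-capture** when the strand follows
fewer beats than stimuli; otherwise **impaired**, with the pattern from
distal following counts and ROI geometry, or from activation-map sectors
(omnidirectional < 0.1 activated fraction; unidirectional when one
angular half ≥ 0.6 and the other < 0.2; regional when flank sectors
conduct while the central sector distal to the mouth is blocked; 2:1
when alternate beats fully activate). These thresholds are
operationalizations of figure vocabulary, stored in code as defaults and
reported with results. Success tables apply the carry-forward rule — a
preparation impaired at a lower frequency stays impaired at all higher
ones — and round rates half-up to one decimal. Fisher's exact test
(two-sided, `stats::fisher.test`) compares groups per frequency.

## Preset calibration

The presets are calibrated so that the *full pipeline* — simulation,
camera, conditioning, metrics — recovers the published group means of
atrial-like (ATRA-treated) and control hiPSC-CM monolayers:

| preset | target CL (ms) | target cAPD90 (ms) | recovered (across seeds) |
|---|---|---|---|
| `atrial_like` | 402.5 | 243.7 | ~402, 240–244 |
| `control` | 927.6 | 567.1 | ~923–928, 555–566 |

Calibration adjusted only `time_scale` (and, for `control`, the recovery
constants $a, \mu_1, \mu_2$): the control phenotype holds an APD/CL duty
of ~0.59 at its spontaneous rate, which the atrial kinetics cannot
sustain at 1:1 capture — slower plateau growth with faster diastolic
recovery (smaller $\mu_1$ and $\mu_2$) is required. The same
`atrial_like` preset, unchanged, reproduces the conduction table
phenomenology: 1:1 distal conduction at 5 Hz and distal failure at
6.5 Hz on the narrow isthmus, 1:1 through 6.5 Hz on the uniform
geometry, and loss of 5 Hz conduction with 30 % fibroblasts. These joint
constraints were the calibration targets; nothing downstream of the
presets was fitted.

## What the synthetic validation shows — and what it does not

Passing tests on rendered movies establishes that the chain is
implemented as specified (exact operator identities, linearity,
end-to-end waveform fidelity r > 0.99 on clean movies, plane-wave speed
agreement within 5 %, APD stability across 5 vs 10 ms sampling) and that
the classification logic reproduces the expected phenomenology of
source–sink mismatch and fibroblast loading. The generator emulates
camera geometry, dye polarity, drift, shot-like noise and tissue
heterogeneity, but not motion artifact (excitation–contraction
uncouplers remove it in practice), photobleaching beyond polynomial
drift, biphasic upstrokes, spatially correlated noise, or ionic-model
realism. Results on real recordings therefore inherit the chain's
correctness, not the simulator's biology.

## Problem sizes

Default study sizes mirror the calibration data: 4 isthmus + 3 uniform
preparations (CM-only) swept 5→7 Hz, 3 coculture preparations swept
4→7 Hz, 3 s per pacing epoch with the final 2 s analysed, and 10 s
spontaneous recordings at 5 ms frames for OAP metrics. On the default
120 µm window a full acceptance-style reproduction runs in a few minutes
on one CPU.

## Known limitations

- The two-variable model has no explicit ERP or calcium handling;
  alternans magnitudes are emergent and not calibrated.
- Intermediate-frequency success rates are nearly deterministic given
  the small heterogeneity default; biological scatter between
  preparations is under-dispersed relative to real experiments.
- The uniform-geometry comparison uses identical window coordinates, so
  its "strand" zone is nominal.
- HDF5 I/O is not provided; movies travel as 16-bit multi-page TIFF with
  a JSON sidecar.
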