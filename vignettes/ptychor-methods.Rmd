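---
title: "Models and methods behind ptychor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ptychor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptychor)
```

## The inverse problem

Ptychography recovers two complex images at once from intensity-only data: the
object transmission function $O(\mathbf r)$ of a sample and the illumination
(probe) wavefront $P(\mathbf r)$. The sample is scanned through the beam so
that neighbouring illuminated regions overlap; at each scan position
$\mathbf r_i$ a far-field diffraction pattern is recorded. Under the thin-sample
(multiplicative) approximation the exit wave is

$$\psi_i(\mathbf r) = P(\mathbf r)\, O(\mathbf r - \mathbf r_i),$$

and the measurement is $I_i(u,v) = |D_d\{\psi_i\}|^2$, where $D_d$ is free-space
propagation to the detector — the Fourier transform in the far field, the
angular-spectrum method (ASM) in the near field. For X-rays the object relates
to the projected complex refractive index $n = 1 - \delta + i\beta$ through
$O = e^{-k\beta_p} e^{-ik\delta_p}$ with $k = 2\pi/\lambda$; the phase signal
$\delta_p$ typically dominates absorption, which is why the method is prized
for weakly absorbing (e.g. soft-matter) specimens.

The detector fixes the real-space grid: an $M\times M$ window of pixel pitch
$p$ at distance $d$ samples the reconstruction at $\Delta x = \lambda d/(Mp)$
(`effective_pixel_size()`). Metric scan positions are converted to integer
pixel offsets of the probe window by rounding (ties to even); sub-pixel
remainders are reported but not interpolated, because none of the engines
defines a sub-pixel crop and interpolation would smuggle a low-pass filter
into the forward model.

## Projection engines

All projection engines alternate between two constraint sets: the measurement
set (wavefronts whose propagated modulus matches $\sqrt I$) and the overlap
set (wavefronts of the product form $P \cdot O$). The modulus projector
$\Pi_M$ propagates each probe mode, rescales the mode ensemble by
$\sqrt{I/\sum_m |\Psi_m|^2}$ at trusted pixels, leaves masked-out pixels
untouched, and back-propagates. Two deterministic tie-breaks matter in
practice and are fixed: pixels where the model ensemble has zero amplitude
but the data does not receive $\sqrt{I/K}$ at phase zero, and the propagator
pair is the *unitary*, centred FFT, so the projector needs no renormalization
and Parseval holds to rounding error.

The wavefront updates are, per position,

* **AP** $\psi' = \Pi_M\,\psi$ applied to the current model wave,
* **DM** $\psi' = \psi + \Pi_M\{2\Pi_O\psi - \psi\} - \Pi_O\psi$,
* **RAAR** $\psi' = \beta(\psi + \Pi_M\{2\Pi_O\psi - \psi\}) + (1-2\beta)\Pi_O\psi$,

with DM and RAAR carrying the wavefronts as persistent state and coinciding
exactly at $\beta = 1$ (this identity is asserted bitwise in the tests).
After the wavefront pass, object and probe are re-estimated from the overlap
constraint,

$$O'(\mathbf r) = \frac{\sum_i P^*(\mathbf r - \mathbf r_i)\,\psi_i(\mathbf r)}
                       {\sum_i |P(\mathbf r - \mathbf r_i)|^2}, \qquad
  P'(\mathbf r) = \frac{\sum_i O^*(\mathbf r + \mathbf r_i)\,\psi_i(\mathbf r + \mathbf r_i)}
                       {\sum_i |O(\mathbf r + \mathbf r_i)|^2},$$

with a scale-invariant regularization ($10^{-6}\times$ the denominator
maximum) and prior values retained at never-visited pixels.

**Sequential overlap update.** A genuinely open design point is whether $O'$
and $P'$ are computed simultaneously from the same accumulators or
sequentially. We found the simultaneous form numerically explosive on the
synthetic benchmark — the object/probe scale degree of freedom feeds back and
runs away within tens of iterations — so the driver updates the object first
and then accumulates the probe against the *updated* object, optionally
alternating (`overlap_iters`, default 3), which is the same cure mature
packages apply through their inner overlap loops. The split changes neither
the accumulation algebra nor its batching: both passes are still plain sums
over scan positions.

**Where the convergence metric comes from.** The per-iteration error is the
normalized intensity misfit
$$\epsilon = \frac{\sum_i \sum_{uv} M_i (I_i - \hat I_i)^2}
                  {\sum_i \sum_{uv} M_i\, I_i},$$
evaluated on the *model* exit waves $P\cdot O$ of the current iterate. It is
not evaluated on the projected waves: for AP those satisfy the modulus
constraint by construction and would report an identically null error. An
amplitude-residual variant ($\sqrt I - |\hat\Psi|$) is available through
`error_metric = "amplitude"`; the intensity form is the default and is what
`error_trace` records. Note the intensity form scales with the photon count —
it is a relative number only within one dataset.

**rPIE / mPIE.** The sequential engines visit positions one at a time in
random order (batch size is forcibly 1) and apply the regularized gradient
steps

$$O' = O + s_o \frac{P^*(\psi' - \psi)}{(1-r_o)|P|^2 + r_o|P|^2_{\max}},$$

and the mirrored probe update. Defaults $s_o = s_p = 1$, $r_o = r_p = 0.1$.
mPIE adds heavy-ball momentum every fixed number of position updates
(default: one full sweep): $v \leftarrow \eta v + (X - X_{ck})$,
$X \leftarrow X + \eta v$, with the checkpoint refreshed to the
pre-acceleration iterate — refreshing to the accelerated one double-counts
the boost. With both object *and* probe accelerated, the literature's
friction $\eta = 0.9$ overshoots on densely overlapped scans at every
interval we tried; the package default is a conservative $\eta = 0.3$, which
on the bundled phantom still cuts the misfit by more than two orders of
magnitude relative to plain rPIE at equal iteration count. The value is a
plain config field for users who want the aggressive setting.

**AP stagnates from a cold start.** Pure alternating projection is the
phase-retrieval scheme classically known to stall; on the bundled phantom it
plateaus near $\epsilon \sim 0.1$ regardless of iteration count, while DM and
RAAR drive $\epsilon$ below $10^{-6}$. AP is therefore treated as a
*refinement* engine: the test suite exercises it warm-started through the
standard chained protocol (a short rPIE stage, then AP), which converges to
$\epsilon \sim 10^{-5}$. Chaining is first-class:
`engine = c("rpie", "ap"), iterations = c(100, 300)`.

## Batching, reduction, broadcast

Large scans do not fit device memory, so the parallel engines process scan
indices in contiguous batches of size $B$ assigned to $W$ emulated workers by
a deterministic availability queue (unit cost per batch, i.e. round-robin).
Each worker owns a private numerator/denominator accumulator; partials are
combined by a binary reduction tree ($\lceil \log_2 W \rceil$ combine
rounds) and the updated model is broadcast back, with value equality checked.
Because every accumulated quantity is a plain sum, the reconstruction is
invariant to $(B, W)$ up to float summation order; the tests pin this to a
$10^{-4}$ relative band on the error traces, and observed deviations are at
the $10^{-15}$ level. Workers are emulated in-process: the package makes no
claim about wall-clock parallelism, only about the value contract and the
bounded per-batch working set.

## Maximum-likelihood refinement

The cost $C = \sum_i \sum_{uv} M_i\,\bigl((\hat I_i)^\gamma - I_i^\gamma\bigr)^2$
with $\gamma = \tfrac12$ (amplitude domain, the Poisson surrogate) or
$\gamma = 1$ (intensity domain, the Gaussian surrogate) is minimized by joint
steepest descent on $O$ and all probe modes. Gradients are analytic
(Wirtinger calculus, back-propagating the detector residual through the
unitary propagator's adjoint) and are validated against central finite
differences in the test suite at $8\times8$ scale. The line search is Armijo
backtracking ($c = 10^{-4}$, shrink $0.5$, optimistic doubling after
acceptance), chosen over conjugate-gradient or curvature methods as the
simplest rule with a monotonicity guarantee; a fixed-step mode exists and
aborts with a diagnostic if the cost doubles. At $\gamma = \tfrac12$ the
gradient weight $r/\sqrt{\hat I}$ is taken as zero where the model intensity
vanishes (a subgradient convention). ML is intended as a refinement stage
after a projection engine (`engine = c("ap", "ml")`); its cost history is kept
separately from the projection misfit trace.

## Mixed-state probes, support, position correction

Partially coherent or vibrating beams are modelled as $K$ mutually incoherent
probe modes whose intensities add. The modulus projector applies one shared
rescaling factor to the ensemble. Modes are re-orthogonalized on request via
the eigendecomposition of their $K \times K$ Gram matrix — power-conserving,
ordered by decreasing occupancy, rank-deficiencies kept as trailing zero
modes. A circular probe support of physical diameter can be imposed each
iteration; a support wider than the frame diagonal is a no-op by
construction.

Scan positions are corrected by annealing: per frame, the single-frame
squared intensity residual is evaluated at the current integer offset and at
candidate offsets within a radius (random trials, or exhaustively), keeping
the argmin with ties favouring the incumbent — so exact positions on
noiseless data are never disturbed. The radius cools geometrically between
applications. Two schedule choices are deliberate: correction starts only
once the model has begun to settle (default iteration 15), because annealing
against a half-formed object happily relocates *correct* positions; and a
global $\pm1$ px registration of the whole scan is left alone — it is the
translation ambiguity, not an error. On the bundled phantom with two
corrupted positions, the corrected run's misfit is an order of magnitude
below the uncorrected one.

## The synthetic benchmark

`generate_benchmark_dataset()` is the package's ground-truth source and is a
pure function of (spec, seed). The `full_benchmark` preset mirrors the
published numerical experiment's geometry: a $400\times400$ object built from
two grayscale images (magnitude and phase), a $180\times180$ circular
constant-phase probe, and a $20\times20$ raster grid (400 positions) with
normally distributed jitter breaking the raster-grid pathology. The
`small_test` preset is the same design scaled to $64\times64$ / $32\times32$
/ 25 positions so that the full suite runs in about a minute. Values the
source configuration does not state were fixed once:

* magnitude rescaled to $[0.2, 1]$ (avoids the zero-amplitude pathology),
  phase to $[0, \pi/2]$ (stays unwrapped);
* jitter $\sigma = 0.25 \times$ step — small enough to preserve overlap,
  large enough to break grid symmetry;
* probe diameter $0.75\,M$ ($135$ px full-size, $24$ px small), giving
  linear overlaps of $92\%$ and $67\%$; the manifest reports the overlap and
  warns below $60\%$;
* raster step 11 px with margin 5 at full size (the largest step for which a
  $20\times20$ grid of $180$ px windows fits a $400$ px canvas), 8 px at
  small size.

The built-in image pair is procedural (gradients, disks, bar strokes), so no
external assets are required; any two grayscale matrices can be substituted.
Poisson counting noise is applied by scaling frames to a target mean photon
budget, sampling, and scaling back.

What the generator does *not* emulate — and hence what green tests do not
certify on real data: fly-scan motion blur and genuine partial coherence
(only approximable here by supplying $K>1$ ground-truth modes), detector
point-spread and charge-sharing, hot/dead-pixel patterns beyond binary masks,
background and dark counts, sample drift during the scan, and near-field
datasets (the ASM propagator is tested, but the presets are far-field).

## Ambiguities and metrics

The far-field product model leaves invariances that no engine can (or
should) resolve: a global phase, a complex scale traded between $O$ and $P$,
a linear phase ramp on $O$ paired with a probe tilt, and a rigid translation
of the $(O, P)$ pair. They are quotiented out only in postprocessing:
probe centre-of-mass centring (integer rolls; the sub-pixel remainder is
reported, not applied, to avoid interpolation artifacts), a
wrapped-phase-safe magnitude²-weighted plane fit to the phase gradient for
ramp removal, and a closed-form complex-scale fit inside
`nmse_to_ground_truth()`. COM centring removes translation only up to the
probe's own shape bias, so ground-truth registration optionally searches
residual integer shifts (`shift_radius`). Fidelity is reported as masked
NMSE over the scanned footprint (`scan_coverage_mask()`), because canvas
pixels the probe never visited are untouched initialization values.

## Data container

Datasets travel as a directory: multi-page 32-bit-float TIFF arrays
(intensities, masks, real/imaginary parts of complex fields), a
`positions.csv` of metric scan coordinates, and a JSON manifest carrying the
geometry group, per-array affine scaling (TIFF float samples are stored
normalized to $[0,1]$), optional initial-guess / ground-truth groups, and a
layout-version attribute that guards dialect drift. Storage precision is
32-bit float by design; round-trips are exact at that precision. Event-list
and sparse detector formats are out of scope.

## Numerical choices, collected

* Physical constant $hc = 1.23984193$ keV·nm, fixed so wavelength tests are
  deterministic.
* Unitary, centred FFT in both directions; ASM zeroes (not attenuates)
  evanescent components and warns when $\lambda d/(M p^2) > 1$.
* Offsets round ties-to-even; windows are half-open $[o, o+M)$, row-major,
  0-based externally.
* Division regularizers are relative: $10^{-6} \times \max(\text{den})$.
* Probe updates are frozen for the first two iterations
  (`probe_update_start = 3`) — standard stabilization, configurable to 0.
* All randomness (initialization, sweep order, annealing trials, noise)
  flows from one integer seed; equal seeds give bitwise-equal traces.

## Problem sizes used by the tests

The suite validates operators on frames from $2\times2$ (hand-computable
DFT oracles) to $256\times256$ (unitarity, projector idempotence), and runs
full reconstructions on the 25-frame `small_test` phantom — 150–200
iterations for DM/RAAR, 60 for the PIE family — sizes chosen so the whole
suite completes in about a minute on one core while still exercising every
engine end to end. The full-size `full_benchmark` preset is validated for
its geometry (frame count, canvas fit, overlap) rather than reconstructed in
the tests.

## Known limitations

Single 2-D object slice and far-field presets only; no orthogonal probe
relaxation, multi-slice, ADMM or WASP variants; no sub-pixel positions; the
in-process scheduler verifies value contracts, not true concurrency; and the
maximum-likelihood engine is a reference implementation — correct gradients
and monotone descent, with no performance claims.
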