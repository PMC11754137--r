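---
title: "Beacon-based speed-of-sound tomography: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beacon-based speed-of-sound tomography: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the forward and
inverse models it implements, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical decisions taken where the design was
genuinely open.

## The measurement principle

A photoacoustic reversal beacon (PRB) — a small, strongly light-absorbing
target such as a thin black wire — is scanned on a circle of radius 19 mm
around the imaged object, inside a 128-element, 270-degree ultrasound ring
of radius 40.5 mm. Each laser pulse excites both the beacon and the
object; the beacon's transient traverses the object before reaching each
element, so its time of flight (TOF) encodes a line integral of interior
slowness `1/v`. Scanning the beacon over `N` positions and picking its
arrival on all `M` channels yields `M*N` such integrals — a travel-time
tomography problem on the 40 mm x 40 mm field of view.

## Forward model and inversion

**Straight-ray operator.** `build_path_operator()` constructs the sparse
`(M*N) x K` matrix `W` whose entries are exact per-pixel intersection
lengths of each beacon-to-element segment (parametric Siddon traversal,
implemented in C++; half-open cell membership resolves ties on pixel
edges, and degenerate zero-length intervals are dropped). Beacons (19 mm)
and elements (40.5 mm) lie partly or wholly outside the imaging square, so
each segment's out-of-grid portion is tracked separately and assigned the
background slowness `1/v0` in `forward_tof()`. This convention makes the
homogeneous forward model reproduce the analytic background table exactly,
which in turn makes background subtraction self-consistent. Refraction is
deliberately ignored in `W` — the model is straight-ray by construction —
and bent-ray or full-waveform kernels are out of scope.

**Background subtraction.** The data vector is `delta = t_b - t`, the
background TOF table minus the measured one, vectorized beacon-major to
match `W`'s rows. Working in the slowness deficit `z = 1/v0 - 1/v` rather
than absolute slowness removes the large common-mode part of the travel
times and, just as importantly, cancels any constant arrival-marker bias:
both scans are picked with the same envelope-peak marker, so the
wavelet-shape offset subtracts out (verified to < 0.05 sample in the test
suite).

**Solver.** `solve_deficit()` minimizes `0.5*||Wz - delta||^2 +
lambda*||z||^2` by Nesterov's accelerated gradient method from `z = 0`:
step size `1/L` with `L` the largest eigenvalue of `W'W + 2*lambda*I`
estimated by 100 power iterations from a fixed all-ones start (runs are
bit-reproducible; a Frobenius-norm upper bound is the fallback if the
iteration degenerates), the standard momentum sequence, a hard
200-iteration cap, and a relative objective-change tolerance of 1e-10.
Adaptive gradient-based restart (momentum reset whenever the gradient and
the step direction form an acute angle) is on by default: it recovers a
fast linear rate on well-conditioned systems — the dense ridge oracle in
the tests converges to 1e-6 relative error within the 200-iteration cap —
while leaving the early-stopped behaviour on underdetermined systems
essentially unchanged.

**Regularization weight.** `lambda` defaults to `1e-3 * L_data / K` with
`L_data` the power-iteration estimate of `||W'W||`. At this scale the
explicit ridge term mainly conditions the problem; with the 200-iteration
cap, the effective regularization is early stopping. The weight is fully
exposed in `inversion_config()`, and the solution-norm monotonicity in
`lambda` is property-tested over two decades.

**Assembly.** `assemble_sos()` inverts `v = 1/(1/v0 - z)` pixel-wise,
clipping deficits that would push the speed above `2*v0` (or negative) and
reporting the clip count — physical plausibility is enforced only here,
never during iteration.

## Arrival picking

`extract_strip()` cuts, per channel, the envelope (analytic-signal
magnitude) samples between `d/v_max` and `d/v_min` plus a margin — the
beacon arrival must lie in this bracket if the medium's speeds do. The
defaults `v_min = 1400`, `v_max = 1700` m/s with a 32-sample margin cover
soft-tissue-like media (approximately 1450–1750 m/s) with room to spare.

`dp_pick()` extracts the arrival trace as the exact minimum-cost
channel-ordered path: node cost `1 - e` (envelope normalized to the strip
peak), transition cost `w*|jump|`, and a hard jump limit (default 3
samples). Three calibration points deserve explanation:

* **The jump limit is the continuity constraint.** It must exceed the
  per-channel drift of the arrival *within the window*, which is
  approximately `d_step * (1/v_min - 1/v_max) * fs` plus the
  object-induced slope — about 2 samples for a 128-element, 270-degree
  ring, hence the default of 3. Sparser arrays drift faster: with 48
  elements the limit must be opened to ~10. This is a geometry-dependent
  knob, not a universal constant.
* **The smoothness weight is a tie-breaker, not the constraint.** Its
  default 1e-4 is far below the node-cost increase of leaving the beacon
  wavelet's envelope peak by one sample (~0.3 for a 5 MHz wavelet at
  40 MHz). Larger weights straighten the path at the price of a
  one-sample bias wherever the true arrival falls near a half-sample
  boundary; at 1e-4, noise-free picks are argmax-exact to the
  half-sample quantization limit on every channel of a full scan.
* **The arrival marker is the envelope peak**, not the onset. The marker's
  constant bias cancels in the background subtraction because both scans
  use the identical pipeline.

`max_pick()` (per-channel argmax, no continuity) is retained as the
baseline: on strips with a stronger isolated transient crossing a few
channels it jumps to the interferer while the DP path holds — the
property-tested failure mode that motivates the tracker. Ties in the DP
are broken toward the earlier sample. All-zero strips yield a flagged
low-confidence result instead of an error. `refine_subsample()` adds
three-point parabolic interpolation of the *log*-envelope (exact for
Gaussian-shaped envelopes, and the beacon wavelet's envelope is
Gaussian-like; the plain envelope is the fallback at non-positive
samples), bounded to half a sample, recovering planted fractional arrivals
to better than 0.01 sample noise-free.

## Synthetic data: what it emulates, what it does not

`disc_phantom()` and `multi_region_phantom()` build piecewise-constant SOS
maps with exact geometric region masks (a 500–5000 m/s guard rail rejects
unphysical values). `four_region_phantom()` is the packaged multi-target
study object: discs of 1545/1580/1615/1650 m/s in a 1500 m/s background,
diameters 14/12/10/8 mm at (±7, ±7) mm. The geometry was chosen once:
every disc must stay strictly inside the 19 mm beacon circle (largest
radial extent 16.9 mm) — a beacon cannot scan through the object — and the
sizes decrease with contrast so that higher-speed regions are also the
harder, smaller targets, the regime in which regional errors grow with
contrast.

`synthesize_beacon_sinogram()` places a first-derivative-of-Gaussian
bipolar wavelet (spectral peak at the 5 MHz transducer center frequency)
with its envelope peak at each channel's arrival time, superposes optional
interferer wavelet trains for the object's own signal, and adds seeded
white Gaussian noise. The default record is 2048 samples at 40 MHz
(51.2 µs), covering the worst-case beacon-element path with margin; the
default beacon:target amplitude ratio is 10:1, reflecting the strongly
absorbing beacon design.

Two forward models generate arrival times. The *straight* model applies
`W` to the phantom's slowness — deliberate inverse crime, used for
recovery tests. The *eikonal* model (`eikonal_tof()`) solves `|grad T| =
1/v` by first-order fast marching (C++ binary-heap implementation,
node-centered solver grid at 0.1 mm default, exterior at `v0`, analytic
initialization of `T` within 5 nodes of the source to tame the source
singularity, receiver times by bilinear interpolation). It produces
Fermat first-arrival times — refraction-aware, hence a genuinely different
physics than the inversion assumes — and serves as the package's full-wave
surrogate.

What the generator does **not** emulate: finite transducer aperture and
elevational geometry (the model is strictly 2D), frequency-dependent
attenuation and dispersion, diffraction and multiple scattering, finite
beacon size, transducer impulse response, and correlated system noise.
Passing tests therefore demonstrate correctness of the algorithms under
the stated physics, not performance on any particular instrument.

A first-order fast-marching caveat with practical consequence: the solver
carries a positive discretization bias of up to ~0.5 % of the absolute
travel time, which is *comparable to the beacon delay signal itself*
(sub-microsecond). Benchmarks therefore compute the background table with
the same eikonal solver rather than analytically — exactly as an
experiment measures its background scan with the same system — so the
solver bias cancels in `delta` the way system bias cancels in practice.

## SOS-corrected beamforming

`das()` implements plain delay-and-sum at a uniform speed with linear
temporal interpolation between samples (nearest-sample rounding would add
quantization artifacts; the choice is documented as a deviation from the
discrete-indexing formulation). No apodization, solid-angle weighting or
envelope post-processing is applied. `ti_mdas()` computes per-pixel
delays as straight-ray slowness integrals through the SOS map on a coarse
grid (default 100 x 100, C++ batch traversal), upsamples them to the
reconstruction grid (default 400 x 400) by separable bicubic-spline
interpolation, and sums. Two numerical details:

* The coarse grid is padded by two pixel rings beyond the field of view
  before interpolation so every fine-pixel stencil is interior — clamped
  extrapolation at the border otherwise dominates the error budget.
* Interpolating cubic splines with endpoint-cubic (FMM) end conditions
  reproduce constants exactly and converge at fourth order on smooth
  fields; the uniform-medium identity TI-MDAS = DAS holds to < 1e-6
  relative at the default grid pair, and the mean interpolation error on
  the four-region phantom's TOF volumes is measured in the tests at
  around 1e-5 ms scale, three orders below the TOF itself.

When `coarse_n = fine_n` the interpolation is skipped entirely and the
identity with direct computation is exact to floating-point.

## Metrics

`psnr()` uses `10*log10(MAX^2/MSE)` with `MAX` the reference image's
dynamic range (the "maximum possible range" convention is configurable);
identical images report `Inf`. `ssim()` is the global single-window form
computed from image-wide moments (population variances) with `C1 =
(0.01*MAX)^2`, `C2 = (0.03*MAX)^2`; a sliding-window variant is
deliberately not used for acceptance because the global form is what the
evaluation formulas state. `region_stats()` evaluates mean, standard
deviation and percent error over the exact geometric phantom masks, with
no boundary erosion by default (erosion materially affects the standard
deviation of small regions; exposing it as an option rather than applying
it keeps the statistics conservative).

## Problem sizes and accuracy expectations

The packaged benchmarks run at the reference system scale — `M = 128`,
`K = 100 x 100`, `N` from 10 to 80 — which keeps the full test suite and
the acceptance script within a few minutes on one CPU. Under noise-free
straight-ray data at `N = 80`, all region means (single-disc and
four-region phantoms) are recovered within 1 %. With the eikonal surrogate
the errors are larger and decrease with `N`; at `N = 10` the four-region
maximum regional error is about 5.3 %. Two effects dominate that number:
at `K = 10^4` unknowns and 1280 rays the minimum-norm solution is
coverage-limited (this floor exists even for inverse-crime data), and
first-arrival times exaggerate refraction relative to energy-arrival
picking on full-wave data, adding forward-model mismatch. Both shrink
rapidly with `N`; the packaged four-region experiment configuration
(`default_experiment_config(phantom = "four_region", forward = "eikonal")`)
reproduces the full sweep.

## Known limitations

Straight-ray inversion underestimates sharp, high-contrast inclusions;
bent-ray and full-waveform extensions are explicitly out of scope. The
eikonal surrogate is first-order accurate; its bias is handled by
consistent background subtraction, not eliminated. The DP tracker assumes
exactly one beacon excitation per sinogram; simultaneous multi-beacon
disambiguation is not supported. All geometry is 2D; hemispherical or
elevationally extended detectors are not modeled. On-disk containers are
deliberately simple (flat little-endian binaries with JSON sidecars for
sinograms, TOF tables and operators; 32-bit float TIFF with JSON sidecars
for maps and images) and round-trip bit-exactly at their stated
precisions.
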