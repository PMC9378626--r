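---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the physical model, the tunable parameters, what
the synthetic data generator does and does not emulate, and the design
choices that were genuinely open. It states no empirical result that the
test suite does not itself compute.

## 1. Optical model

All lengths are in nm, angles in mrad at the interface, dose in e⁻/Å².
The electron wavelength is the relativistic de Broglie value with CODATA
2018 constants. The probe is formed by a hard circular aperture of radius
α/λ in frequency space with aberration phase
χ(k) = πλΔf k² + (π/2) Cs λ³ k⁴ applied as e^{−iχ}; free-space propagation
multiplies the spectrum by e^{−iπλdz|k|²} (paraxial; the exact square-root
kernel is available by `exact = TRUE` and differs negligibly below a few
mrad). Sign conventions are pinned by a regression test: negative Δf is
underfocus, and propagating a probe formed at defocus Δf by −Δf recovers
the in-focus Airy probe exactly, because the propagator cancels the
quadratic term of χ.

Analytic summaries: transfer band λ/(α+β) (with β defaulted to α for
bright-field-only work this is λ/(2α)); CTF first zero √(λ|Δf|) for
Cs = 0, otherwise the first positive root of sin χ found by scan +
bisection to 10⁻⁶ relative; geometric probe diameter 2α|Δf|.

**Overlap ratio** is not defined unambiguously in the field. We use the
linear definition 1 − step/diameter as the primary value because it
reproduces the conventional 83% for a 20 nm step on a 120 nm probe; the
areal two-disc overlap is attached as an attribute, clearly labelled. At
the two lower doses of the dose series the printed overlap values (76%,
66%) are not exactly consistent with dose ∝ 1/step² under either
definition; we note this and do not attempt to resolve it.

## 2. Phantom and projection

`build_phantom()` voxelizes gold spheres (optionally wrapped in a DNA
shell), random-walk DNA strands of ~1.3 nm tube radius, and a carbon slab
with band-limited noise texture, on a cubic grid. Densities are phase
shift per nm of thickness; the defaults (gold 0.25, DNA 0.05, carbon
0.01 rad/nm) set the DNA:gold voxel ratio to 0.2, so a volume normalized
to the gold signal puts DNA near 0.2 — the regime of interest for
weak-phase biomolecules beside strong scatterers. Absolute values are
free parameters (experimental data are always reported normalized); they
are chosen so that projected phases stay below π, because the retrieved
phase is the argument of a complex field and would wrap otherwise. For
the same reason 2D experiments should use laterally separated particles:
the default two spheres are stacked along z (their projections add).

Projection rotates the density about the grid centre (intrinsic
y-axis-then-x-axis tilts, then in-plane; trilinear resampling) and sums
along the beam axis times the voxel size — a pure-phase projection with
no amplitude contrast. Trilinear interpolation attenuates high spatial
frequencies; tests that need *exact* projections (the tomography oracle)
instead evaluate the spheres' closed-form Fourier transform on the slice
plane, which also guarantees the truth volume is representable on the
grid. Comparing a band-limited reconstruction against a hard-edged
voxel phantom would otherwise be dominated by the one-voxel edge error.

The default dual-axis tilt scheme steps each axis range in 10° increments
and always includes the range end point, which reproduces the 23-angle
acquisition from the stated ranges (−49.99…53.94° and −53.42…46.40°).

## 3. Forward 4D-STEM model

For each scan position the exit wave is ψ = P(r − p)·e^{iφ(r)} on a fixed
window centred on the probe (multiplicative thin-object approximation; no
multislice), and the recorded pattern is |Fψ|² scaled so its total equals
the electron budget N = dose × (step in Å)², then Poisson sampled. The
detector is an ideal counting detector: no MTF, no readout noise, no
inelastic background. Scan positions are rounded to the pixel grid and
the rounded positions are stored. Patterns are kept fftshift-centred;
the bright-field radius in pixels follows from α/λ and the window
sampling.

## 4. ePIE

Standard object/probe updates with update strengths 0.5 (the probe
strength and its start iteration, default 5, are not standardized
anywhere; both are config knobs). The object initializes with amplitude
exactly 1 and a random phase band-limited to 0.035 nm⁻¹; the amplitude
of that random phase is unknowable from published work, so it is a knob
(default sd 0.1 rad). Zero-count detector pixels are treated as valid
measurements of modulus zero, not masked. Position order is reshuffled
each iteration (seeded); a fixed-order mode exists for exact regression
tests. The per-iteration misfit is Σ(√I − |Ψ|)²/ΣI with the unitary FFT
convention so that model intensities and detector counts share a scale.

Two practical behaviours worth knowing, both visible in the tests: the
random low-frequency initialization decays slowly in weakly illuminated
pixels (low spatial frequencies are weakly constrained by intensity
data), so quality metrics are computed over the region covered by at
least two probe *discs* — the footprint is defined as pixels holding at
least 10% of the peak probe intensity, which tracks the geometric disc of
a defocused probe rather than the much wider numerical window. And with
probe refinement enabled the error trace fluctuates more than 1% per
step late in convergence; with the probe fixed (or fixed ordering) it is
monotone.

**Post-acquisition focusing** re-runs short reconstructions with the
probe formed at each candidate defocus (probe update off — a refining
probe would absorb the defocus error and flatten any score), then refines
by golden-section to 0.5 μm and reconstructs fully at the refined value.
The score is the negative final data misfit. We deliberately did not use
an image-sharpness score as the default: variance of the
Laplacian-filtered phase rewards the high-frequency artifacts of badly
mis-focused short reconstructions and was observed to be non-monotone
around focus, whereas the misfit is unimodal because a probe at the wrong
defocus simply cannot satisfy the measured moduli. Laplacian variance and
gradient-histogram entropy remain available by flag. Re-running with a
different probe is the primary mechanism; propagating the final object
wave is a fast approximation left to `propagate()`.

## 5. Alignment and tomography

Translational alignment estimates per-projection shifts against the
running aligned neighbour, cosine-stretched along the foreshortened axis
when tilts differ. The estimator is plain windowed cross-correlation with
parabolic sub-pixel refinement (or integer peak lags in
`subpixel = FALSE` mode). Classic phase correlation — whitening the
cross-power spectrum — is retained as an option but is not the default:
between projections at neighbouring tilt angles the whitened spectrum is
dominated by decorrelated content and the estimator was observed to fail
by several pixels where cross-correlation stays within ~0.1 px. Alignment
can only fix translations; apparent motion of off-centre 3D features
under tilt is geometry, not misalignment, and remains.

The volume reconstruction grids each projection's padded Fourier
transform onto an oversampled (2×) 3D grid at the coordinates given by
the Fourier slice theorem for its orientation. Samples within 0.7 px of a
grid point contribute with inverse-distance weights (distance floored at
10⁻³ px; collisions averaged by weight — deterministic). Iterations
alternate real-space constraints (positivity, optional support) with
resetting measured Fourier samples. Dual-axis series need no merging
step: every projection carries a full 3D orientation. Oversampling,
radius and iteration count follow common practice for this algorithm
family and are config-exposed. The missing wedge of a limited tilt range
produces the usual z-elongation; a property test asserts the z extent is
never below the lateral extent.

## 6. Metrics

Normalization maps the background histogram peak to 0 and the gold-region
mean to 1 (affine, hence the contrast ratio R is invariant to any affine
rescaling of the raw data — also tested). Histogram peaks are
kernel-smoothed argmaxes (Gaussian, sd 3 bins) over a **fixed** bin grid,
128 bins spanning [−0.2, 1.2] with out-of-range values clamped into the
edge bins; fixing the grid keeps the quantization identical across
datasets being compared, which matters when comparing R across doses.
Ties break toward the lower intensity. The gold level is a mean, not a
peak, following the definition of R. Region definitions: for volumes,
equal-count seeded samples of the material label fields; for 2D images,
label projections thresholded at a minimum projected thickness
(default 2 nm), the analogue of drawing boxes on clearly visible
features. Peak separation (the Fig.-1c-style statement "the DNA peak is
separated from the background") is quantified per curve: each region's
smoothed histogram must drop by the stated ratio between its own peak and
the other region's peak position.

FRC/FSC: mean subtraction and a soft-edged circular/spherical mask
(cosine taper over the outer 10% of the radius) suppress edge
correlation; per-shell correlation |ΣF_a F̄_b|/√(Σ|F_a|²Σ|F_b|²); the
half-bit threshold uses the standard curve with n_eff = raw Fourier
samples per shell (asymmetry factor 1). Resolution is the first downward
crossing, linearly interpolated; if no crossing occurs before Nyquist the
sentinel NA is returned with the curve intact. Fixed 0.143 and 0.5
thresholds are reported side by side because published work rarely prints
its exact threshold formula — for the same reason the published
experimental resolution values are not treated as reproduction targets.

Dataset splitting is a checkerboard on the scan raster by default (two
disjoint, complete halves, no two same-half positions adjacent), each
half carrying halved per-area dose metadata.

## 7. The dose-series experiment

The acceptance experiment for dose-dependent contrast keeps the stated
per-area doses (88/45/26 e⁻/Å²) and the 83% linear overlap of the
highest-dose acquisition, but scales probe and step together (36 nm
probe, 6 nm step) so a 10 × 10 scan covers the phantom on a desk-scale
grid. Dose is varied only through the Poisson budget at fixed geometry —
the real experiment varied overlap to vary dose, which entangles coverage
with noise; isolating the Poisson budget gives the cleaner causal
statement that the test actually asserts (R non-increasing as dose
decreases). With an ideal counting detector at these doses, shot noise is
the *only* degradation, so the dose dependence of R here is much weaker
than in experiments, where detector noise, residual aberrations and beam
damage all grow the effect; a tie in R across doses is a legitimate
outcome of this stated world and the test treats it as such.

## 8. What a green test does and does not establish

The generator emulates: weak-phase strands beside strong spheres on a
textured support, shot noise at stated doses, defocused-probe overlap
geometry, dual-axis tilting, per-tilt defocus variation. It does not
emulate: dynamical/multislice scattering in thick specimens, inelastic
scattering or energy spread, detector MTF/readout, beam damage, stage
drift within a scan, or amplitude contrast. Green tests therefore
establish the correctness and self-consistency of the algorithms under
the projection + multiplicative thin-object approximation — not
instrument-level fidelity. Published experimental values that depend on
the real instrument (FSC resolutions, absolute R values, defocus tables)
are used as geometry and scale inputs, not as assertions.

## 9. Numerical conventions

0-based physical indexing with coordinates at pixel/voxel centres;
(row, col) order; the third volume index is the beam axis. Centred
transforms are fftshift(fft(ifftshift(·))). Master seeds derive per-stage
seeds (`derive_seed`), every randomized stage logs its seed, and the
pipeline is bitwise reproducible for a fixed master seed (asserted).
MRC files are written in a minimal MRC2014 subset (mode-2 float32, voxel
size in the cell header); 4D stacks are an MRC stack plus a JSON sidecar
carrying scan positions, optics, dose and seeds — the environment offers
no HDF5 bindings for R, so the sidecar design keeps stacks reloadable
without side channels.
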