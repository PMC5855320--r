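---
title: "Models and methods for nuclear-dynamics inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for nuclear-dynamics inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models behind `nucdyn`, the choices made
where the design was genuinely open, and what the synthetic-data
validation does and does not establish. It states no numbers that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The reaction-diffusion FRAP model

A nuclear factor is modelled as two interconverting pools on a 2-D
pixel grid restricted to the nucleus mask: free molecules `F(i,j,t)`
that diffuse with constant `D` (µm²/s), and chromatin-bound molecules
`C(i,j,t)` that are immobile while bound:

```
dF/dt = D * Laplacian(F) - k1(i,j) * F + koff * C
dC/dt =                    k1(i,j) * F - koff * C
```

`koff` (1/s) is the unbinding rate; its reciprocal is the mean DNA
residence time. The local binding rate `k1(i,j)` is not a free field:
at equilibrium the fluorescence image is a uniform free level plus the
spatially varying bound pool, so with intensities normalized to a mask
mean of 1,

```
k1 = (koff / Free) * (i_st / i_avg_st - Free),   Free = 1 - bound/100.
```

This makes the bound fraction and the steady-state image jointly
determine the binding-rate map, and `k1 * F = koff * C` holds pointwise
at the equilibrium initialization (a tested invariant). Negative values
of `k1` produced by noisy steady-state images are clipped to zero and
counted.

**Numerics.** Forward Euler with the 5-point Laplacian, no-flux at the
mask edge (molecules do not leave the nucleus; total mass is conserved
to 1e-9 per thousand steps, tested). The time step is 0.8× the tighter
of the diffusion bound `p²/(4D)` and the reaction bound
`1/(max k1 + koff)`; the reaction term matters only for extreme
fast-exchange parameter combinations, a handful of which (residence
~0.1 s at ≥90% bound) remain too stiff and are excluded from grid
searches with a logged message. A 4×-refined grid/time-step oracle
agrees with the production solver within 0.5% on a strip geometry
(tested).

**Image-derived initialization.** Following the standard pipeline, the
pre-bleach mean and the average of the first three post-bleach frames
are Gaussian-smoothed (σ = 5 px) and block-binned (10×10 default, 5×5
supported). Three refinements matter in practice and are part of this
package's design:

- *Mask-normalized smoothing and coverage-weighted binning.* A plain
  blur darkens the nucleus boundary by mixing in background; the ratio
  of the smoothed masked image to the smoothed mask indicator removes
  that bias, and edge blocks are averaged over their in-mask pixels
  only. Without this, the "opposite end" measurement ROI (which sits at
  the mask boundary) drifts by ~10% and corrupts the fit.
- *Bleach-area rescale.* Smoothing leaks surrounding fluorescence into
  the dark bleach spot. The binned fluorescence inside the bleached
  area (the half-depth contour of the post/pre ratio) is rescaled by a
  factor close to 1 so it matches the raw full-resolution fluorescence
  over the same pixels, restoring the true bleach depth.
- *Matched three-frame averaging.* The initial condition is the average
  of the first three post-bleach frames. Because the dynamics are
  linear, a simulation started from that average equals the average of
  the true recovery over the three frame offsets — so the model curve
  is compared against the observed curve's forward three-frame average
  (interpolated where the frame spacing changes), with the last two
  frames dropped. This removes a time-base mismatch that otherwise
  biases the fit by one to two grid cells, with no free alignment
  parameter.

**Fitting.** For each cell of a (residence time × bound fraction) grid
— log-spaced 0.1–100 s × 0–95% by default, chosen to span transient
sub-second binding through minute-scale stable binding — the fields are
re-initialized per replicate, simulated at the observed frame times,
converted to the double-normalized scale (the bleach pulse removes mass,
so model curves are multiplied by the pre/post mass ratio), and scored
by the mean squared error at both measurement ROIs: the bleach spot and
a circle of the same radius at the mask point farthest from it. Errors
are summed over replicates; the best cell (ties broken toward the
smallest residence time, then the smallest bound fraction) and the
region within 1% of its error are reported — the region is typically an
elongated valley expressing the intrinsic residence/bound trade-off and
is always reported, never hidden. The diffusion-only variant drops the
bound pool entirely and scans `D`; it estimates the free-diffusion
constant from a non-binding control.

## The synthetic FRAP generator

`render_frap_movie()` runs the same forward model from a known ground
truth: an elliptical (optionally irregular) nucleus, an equilibrium
intensity map with an optional band-enriched bound pool, a
multiplicative bleach (uniform disk "column", Gaussian "point", or
half-nucleus), pre-bleach frames, and post-bleach frames at the
configured schedule (0.098 s × 300 then 1 s × 100 for the point
protocol; 0.115 s × 300 then 2 s × 100 for the band protocol). Optional
Poisson noise applies at a configurable photon scale; the validation
suite uses noiseless movies so that disagreement between generator and
estimator measures algorithmic error, not photon noise.

Because estimator and generator share the forward model, these
round-trip tests validate the initialization, normalization and search
machinery — not the biological adequacy of the two-state
reaction-diffusion description itself. The rendering resolutions are
package choices: 0.05 µm/px for the free-diffusion benchmark, where the
0.1 µm²/s grid of the refit demands small discretization bias after
5× binning, and 0.1 µm/px for the binding benchmarks, whose slower
kinetics tolerate a 0.5 µm binned grid.

## Single-molecule trajectories and rendering

`simulate_tracks()` draws hidden state sequences from a Markov chain
`(π, A)` and displacements from the isotropic Gaussian of the active
state. Boundaries reflect (a step leaving the domain is mirrored; if
both directions leave, the molecule waits), positions snap to a 15 nm
grid, track lengths are geometric — folding termination and
photobleaching into one per-frame survival probability — and optional
iid Gaussian localization error is added to the stored positions.

The canonical four-state parameter set
(`su_h_four_state_model()`) has D = 0.09, 0.22, 0.50, 1.89 µm²/s for
specific binding, non-specific chromatin interaction, obstructed
diffusion and free diffusion. The outer occupancies are 22% and 21%;
the two intermediate occupancies are not individually published and are
set to 27% and 30% so the four sum to one. Transitions use
`A = a I + (1 - a) 1 π'` with `a = 0.9`, which leaves `π` exactly
stationary, gives every state a self-transition of at least 0.9, and
produces bound-state dwell times near 0.1 s at 10 ms frames.

`render_smt_frames()` integrates each molecule's photons over 10
sub-exposure positions (linear interpolation between frame positions —
an approximation to intra-frame Brownian wander that still produces the
qualitative blur of fast molecules), convolves a 2-D Gaussian PSF
(σ = 120 nm, truncated at 4σ for <0.01% photon loss), adds an optional
flat autofluorescence background, then applies Poisson shot noise and
Gaussian readout noise (σ = 1.1 e⁻ at unit camera gain). Photon counts
per molecule are deliberately exposed configuration, not fixed
constants.

## Detection, linking and motion blur

Spots are detected on the undecimated à-trous B3-spline wavelet
transform: each of 3 detail planes is hard-thresholded at 3 robust
(MAD) noise standard deviations, detections are connected components of
the joint support, positions are intensity-weighted centroids of the
background-subtracted signal, and border-touching components are
dropped. An optional width gate rejects detections whose trimmed
second-moment width exceeds a multiple of the PSF σ — the "resolved
single molecule" criterion used by the motion-blur analysis.

Linking is frame-to-frame globally optimal assignment on squared
displacement (an augmented cost matrix prices every unmatched detection
at the gating radius squared, so a link is made only when it beats
termination), with a hard gate `r_max = 3 sqrt(4 D_max dt)` at
`D_max = 2 µm²/s` by default. No gap closing: a missed detection ends
the track. Tracks with fewer than four localizations are discarded.
This replaces full multiple-hypothesis tracking; under the
conservative gap-free setting the assignment problem per frame pair is
exactly what MHT would solve locally, and the simplification is
testable against a brute-force enumeration oracle (tested).

The motion-blur analysis counts localizations per frame across an
exposure series under identical detection settings. Per-frame counts
are the right observable: an immobile, well-exposed molecule is
detected once per frame regardless of exposure, while a diffusing
molecule smears its photons along its path and drops below the
detection and width criteria as exposure grows. In a 2-D simulation a
bright smear never vanishes completely (in real data defocus in z does
much of that work, and 3-D optics are out of scope), so the mixture
validation checks the measured unblurred fraction against a composition
oracle assembled from the single-population detection rates rather than
against the idealized bound fraction.

## The variational-Bayes diffusion-state model

Displacements are emitted by a K-state HMM; state k has per-axis
variance `2 D_k dt + 2 σ_loc²`. The localization-error term is included
by default at σ_loc = 33 nm — the fixed-sample precision estimate —
because position noise adds variance to every displacement and, left
unmodelled, masquerades as diffusion with `σ_loc²/dt ≈ 0.1 µm²/s`,
larger than the slowest state. The generator applies the same error, so
benchmark and model are consistent; the residual anticorrelation that
iid position noise induces between successive displacements is ignored
by the HMM (as in standard treatments) and is part of why recovered
slow-state parameters scatter more than fast ones.

Inference is conjugate variational EM: a symmetric Dirichlet(1) prior
on the initial distribution, Dirichlet priors on the transition rows
with an extra pseudocount of 9 on the diagonal — encoding the prior
expectation that a molecule stays in its state for a few frames, as the
reference variational treatments of tracking data do; without it the
model is free to split a slow state by step magnitude rather than by
molecule, which the anticorrelated localization noise of bound
molecules actively invites — Gamma priors on the per-state step
precisions (unit prior weight centred on D = 0.5 µm²/s, spanning the
1e-3–10 µm²/s range of interest), forward-backward responsibilities in
C++ in the E-step, closed-form hyperparameter updates in the M-step,
and an evidence lower bound that is monotone by construction and
asserted monotone in the tests. Occupancies are
reported as responsibility-weighted step fractions; states are sorted
by D, with the slowest state playing the role of specific DNA binding.

VB is multimodal, and the failure mode that matters here is merging the
two slow states while splitting the middle of the variance range, which
can cost the slowest state ten percentage points of occupancy. Restart
strategy: 10 restarts seeded from squared-displacement quantiles whose
span varies structurally across restarts (wide, low-heavy, high-heavy),
50 exploration iterations each, a 250-iteration middle phase for the
top five, and full convergence (tolerance 1e-9 relative) for the top
three — on benchmark data the accurate solution is reliably the
highest-ELBO one, and early ELBO ranks runs imperfectly because the
slow-state split emerges late. Model selection fits K = 1…K_max and
keeps the highest final bound.

Dwell times from labelled segments use the exponential survival model
(maximum-likelihood rate = 1/mean); a supplied photobleaching rate is
subtracted from the fitted loss rate, since unbinding and bleaching are
competing exponential losses. A coefficient-of-variation check flags
clearly non-exponential duration sets. Region stratification assigns
each track by its mean position and compares the fraction of tracks
whose modal label is the slowest state inside versus outside the ROI.

## Quantification formulas

The band assay is the ratio of mean fluorescence in the band ROI to a
control ROI on the same chromosome (scale-invariant). Locus profiles
are width-averaged, resampled to 101 samples so replicates of different
physical lengths average cleanly, min-max normalized per nucleus, and
circularly shifted so the locus-tag maximum is central; flat channels
exclude the nucleus with a log entry, and alignment is idempotent
(tested). ATAC fold enrichment and ΔΔCt expression follow the standard
power-of-two formulas with an assumed amplification efficiency of 2;
both are invariant to additive shifts of all Cp/Ct values (tested).

## Problem sizes and limitations

The validation suite runs the benchmarks at desk scale: FRAP refits use
three noiseless replicates on 120×200 px (0.1 µm/px) or 240×400 px
(0.05 µm/px) nuclei with the full 25×20 default parameter grid; the
four-state tracking benchmark uses 2×10⁴ tracks of geometric mean
length 10 at 10 ms frames.

Known limitations, all deliberate: the FRAP model has a single binding
state and 2-D diffusion, and acquisition photobleaching is corrected by
normalization rather than fitted; detection is centroid-based (no PSF
fitting) and tracking has no gap closing; motion-blur bias on fitted D
at long exposures is not corrected; rendering is 2-D with no defocus,
EM gain or dipole effects; and synthetic nuclei lack real chromatin
texture, so passing recovery tests demonstrates correctness of the
estimators under the stated forward models, not robustness to every
property of real microscopy data.
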