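---
title: "Segmenting flexible two-body particles: models, parameters and design choices"
author: "cryoseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting flexible two-body particles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoseg)
```

## The problem

Single-particle cryo-EM averages many noisy 2D projections of "identical"
molecules into a 3D density map. Many complexes are not identical: they are
built from two (or more) rigid bodies that move relative to each other —
a flexible cap on a hexameric ATPase, the ratcheting small subunit of a
ribosome, a dimer of dimers breathing about its interface. Averaging the
whole particle then blurs the mobile body, and masking the 2D images does
not help because both bodies overlap in every projection.

The approach implemented here removes the *signal* of one body instead of
masking it. If the two rigid-body densities $V_1$ and $V_2$ and their
per-particle orientations $E_{1,i}, E_{2,i}$ are known, the expected image
of particle $i$ is the sum of two CTF-modulated central-slice projections.
Subtracting the projection of body $k$ from the raw image leaves an image
of body $h \ne k$ alone, which can be re-windowed into a small box centered
on body $h$'s predicted position and refined/reconstructed as if it were a
single rigid particle:

$$X_{h,i} = \mathrm{Win}\!\left(r_{h,i},\, b\right)\left(X_i -
  \mathrm{CTF}_i \cdot \mathcal{P}_{E_{k,i}} V_k\right),
  \qquad
  r_{h,i} = P_{XY}\, E_{h,i}\, r_{3D,h} + s_i ,$$

where $\mathcal{P}_E$ is projection at orientation $E$, $r_{3D,h}$ the 3D
offset of body $h$'s center from the composite-map center, $P_{XY}$ the
projection onto the image plane, $s_i$ the particle's refined origin
shift, and $b$ the sub-particle box. Because the true $V_k$ is only known
to the current reconstruction's resolution $R_k$, the subtraction residual
is confined to spatial frequencies beyond $1/R_k$; iterating
(subtract body 2 → refine body 1 → subtract body 1 → refine body 2 → …)
tightens $R_k$ and the residual with it. Subtraction can equally be applied
to whole micrographs before any windowing, which keeps the CTF
point-spread fringes that a particle box would truncate and allows crowded
fields to be processed.

## What the package contains

* `geometry`: ZYZ-intrinsic Euler angles (`rot`, `tilt`, `psi`, degrees),
  rotation matrices mapping reference coordinates into the projection
  frame (`Rz(psi) Ry(tilt) Rz(rot)`), relative rotations, and anchor
  projection (`project_anchor`, `predict_center`).
* `optics`: the 2D CTF with astigmatic defocus, spherical aberration,
  amplitude contrast and a B-factor envelope; positive defocus =
  underfocus; protein renders dark (CTF(0) = −amplitude contrast).
* `project`: `fourier_slice_project` (central-slice theorem with 4×
  padding and trilinear interpolation), `real_space_project` (independent
  rotate-and-sum reference), `lowpass` (raised-cosine edge over 5 Fourier
  pixels).
* `segment`: `subtract_projection`, `rewindow`, `predict_center`,
  `subtract_from_micrograph`, `residual_spectrum`.
* `simulate`: a procedural two-body phantom and a full synthetic
  micrograph/particle generator with ground truth.
* `recon`: Wiener-weighted direct Fourier inversion (`backproject`),
  gold-standard FSC with optional phase-randomized mask correction
  (`fsc`), a deterministic hierarchical grid-search refiner
  (`refine_local`), the iterative driver (`iterate_segmentation`) and
  conformational statistics (`conformation_stats`).
* `io`/CLI: minimal MRC/MRCS and loop-STAR readers and writers; the
  `seg_cli()` dispatcher and an `inst/cli/cryoseg` launcher.

## The simulator defines the study conditions

`sim_config()` defaults encode the simulated collection the method is
validated on: 48 micrographs of 150 particles each (7,200 particles),
256-px boxes at 1.32 Å/px, 300 kV, Cs 2.7 mm, amplitude contrast 0.1,
per-micrograph underfocus uniform in 1–3 µm, astigmatism
(defocus_u − defocus_v) Gaussian 100 ± 50 Å, B-factor Gaussian 0 ± 50 Å²
clipped at zero (the negative tail is unphysical for an envelope and the
source protocol does not address it).

Conformational heterogeneity is parameterized by the spread of the
*body-to-body difference*: σ = 10° per Euler angle and 2 px per in-plane
coordinate. Each body receives an independent Gaussian perturbation with
SD σ/√2 on top of a shared uniform global orientation, so the difference
between the bodies has SD exactly σ while both portions move, matching
both the "difference between the bodies" definition of σ and the
"independently tilted portions" construction.

Values the protocol leaves open were fixed once:

* **Micrograph size** 4096 px — 150 particles of 256 px fit with margin.
* **Noise** targets SNR 0.1 (signal variance within particle footprints
  over noise variance), a typical figure for 300 kV counting-camera data;
  half the noise variance is white, half is CTF-coloured, built by
  filtering a white field with the micrograph CTF. The coloured term is a
  spectral surrogate for solvent noise: only its second-order (power
  spectral) structure matters to subtraction and alignment, so a
  molecular-dynamics water box would add realism the algorithm under test
  cannot see.
* **Phantom** bodies are sums of Gaussian pseudo-atoms: an asymmetric
  flattened cluster (the mobile cap) stacked on an exactly C6-symmetric
  blob ring (the hexameric base), anchored at ±0.18·box voxels on the
  composite Z axis. Blob placement is seeded and the blob list is attached
  to the model, so symmetry checks can re-evaluate the *analytic* model
  under an exact rotation instead of resampling grids.

What the simulator does **not** emulate: beam-induced motion, detector
MTF beyond the B-factor envelope, radiation damage, structured background
(carbon, ice contamination), and per-particle defocus gradients (one CTF
per micrograph, as in the simulated protocol). Tests passing on this
generator therefore validate the segmentation *algebra* — subtraction,
windowing, geometry, reconstruction — under realistic spectral SNR, not
robustness to every real-data pathology.

## Numerical design choices

**Projection.** The central-slice projector pads the volume 4× before the
3D FFT and extracts slices by trilinear interpolation on the centered
(DC-at-center) transform. The usual alternative — 2× padding plus a
real-space sinc² "gridding" pre-correction — over-corrects exactly
on-grid samples: at axis-aligned poses the slice samples coincide with
grid points and need no correction at all, and the pre-corrected result
misses the analytic z-sum by several percent. With 4× oversampling and no
pre-correction, axis-aligned projections are exact to machine precision
and random-pose projections agree with the independent rotate-and-sum
projector to ~1.3% relative L2 on a 32³ smooth phantom (the package's
accuracy target is 2%). Origin shifts are always applied as Fourier phase
ramps, never integer rolls, so fractional shifts survive subtraction
exactly.

**Backprojection.** Direct Fourier inversion: each particle transform is
zero-padded 3× (so its slice samples land densely on the 3D grid),
premultiplied by its CTF, spread trilinearly into data and CTF² weight
grids, and normalized by weight plus a Wiener term of 0.01 × the
per-shell mean weight — reconstruction regularization is not specified by
the source protocol, and at this level the constant only prevents
division blow-ups in empty regions. Half-set splitting for gold-standard
FSC is fixed as even/odd particle index. With 2,000 noiseless projections
of a 48³ body the reconstruction-vs-phantom FSC stays above 0.99 to 0.8×
Nyquist.

**Refinement.** The maximum-likelihood auto-refinement used in production
software is out of scope; `refine_local` is a deterministic, CTF-aware
normalized-cross-correlation grid search (matched below a stated
resolution, DC excluded), followed by two halving-step polish levels
around the optimum so each call settles to sub-step accuracy, and a shift
search over phase ramps. Ties break toward the start pose, making the
refiner a fixed point on noiseless data started at the truth.

**Convergence of the iterative loop.** "Until convergence" is made
concrete as: stop when the mean gold-standard FSC resolution of the two
bodies changes by less than 2% between rounds (and flag divergence if
both bodies worsen over two consecutive rounds, returning the best
round). The mean of the pair is used rather than each body separately
because at desk scale (≈1,000 particles, 48-px sub-boxes) a single
half-map FSC crossing carries several percent of shell-sampling jitter
that does not reflect any movement of poses or maps; the pair mean is the
natural scalar state of the alternating loop and markedly stabler. The
per-round FSC is computed inside a soft spherical mask (radius 0.4×box,
4-px raised-cosine edge) with the standard phase-randomization
correction, mirroring the masked refinement practice the protocol itself
uses.

**Windowing.** Re-window centers are rounded to integer pixels and the
fractional remainder is stored in the sub-particle record
(`residual_shift`), so no resampling is ever applied to data; alignment
resumes from a sub-pixel-correct origin. Windows crossing an image edge
are dropped and counted, never padded — padding would fabricate signal.
Micrograph-level subtraction accumulates all projections on a canvas and
subtracts once, so overlapping particles each contribute exactly their
own projection.

**Gray scale.** Projections are subtracted at unit scale by default,
relying on reconstruction and data sharing an absolute gray scale (true
for this package's simulator + backprojector pair); a per-particle
least-squares scale (`scale = "lsq"`) is available for references of
uncalibrated scale. No soft 3D mask is applied to the body before
projection by default; the segmented body maps used here are compact, and
masking is left as an explicit pre-processing step
(`lowpass`/user-supplied masks) rather than a hidden default.

**Sub-particle CTF** is inherited unchanged from the parent particle: at
1–3 µm underfocus the defocus change across a body's Z-offset of a few
nanometres shifts CTF zeros by far less than one Fourier pixel at these
box sizes.

## Scale of the shipped validation runs

The test-suite problem sizes are chosen so the full suite runs on one CPU
core in minutes while still exercising every claim: projector accuracy at
32³; subtraction, equivalence and residual-spectrum checks at 48³ bodies
in 64-px particles; backprojection self-consistency with 2,000 noiseless
48-px projections; and the end-to-end iterative run on 1,000 noisy
particles (8 simulated 512-px micrographs of 125 particles, 72-px boxes,
48³ bodies, SNR 0.1, C1 + C6 bodies), which converges within two rounds
under the criterion above. The initial model for that run is the phantom
pair low-pass filtered to 15 Å: at a 63 Å box the 60 Å initial filter of
the full-scale protocol would leave only the DC term, so the desk-scale
equivalent keeps the same ~9:1 ratio of box size to initial resolution.
Starting poses are the shared global orientation — exactly what a
consensus refinement of the whole particle would provide, with the
per-body deviations (the quantity of interest) unknown.

## Known limitations

* Two bodies only; the data structures name bodies 1 and 2 explicitly.
  Extending to more bodies is a bookkeeping change (subtract all others),
  not an algorithmic one, but it is not exercised.
* The grid-search refiner needs starting poses within its search range
  (±15° by default); it is a local tool, not an ab-initio aligner.
* Cn point-group symmetry only, applied as an orbit average after
  reconstruction; no dihedral or cubic groups.
* The MRC/STAR readers cover the subset of those formats the pipeline
  writes (mode 0/1/2/6 MRC, single-loop STAR blocks) — they are not
  general archival parsers.
* Resolution estimates at desk scale are shell-sampling limited; compare
  trajectories, not single values, across configurations.
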