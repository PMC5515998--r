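# cryoseg

Particle segmentation and signal subtraction for single-particle cryo-EM
of flexible two-body complexes.

Many macromolecular complexes are built from two rigid bodies that move
relative to each other — a flexible cap on a symmetric base, the two
subunits of a ribosome, a dimer of dimers. Conventional single-particle
reconstruction averages the whole particle and blurs whichever body
moves; masking does not help, because both bodies overlap in every 2D
projection. `cryoseg` implements the alternative: **subtract** one body's
CTF-modulated projection from each raw particle image (or from the whole
micrograph), **re-window** the remaining body at its predicted position
as a new, centered sub-particle, reconstruct it on its own, and iterate
between the two bodies until the resolutions stop changing. The refined
per-particle body orientations then describe the conformational
distribution of the complex, particle by particle.

With known body maps $V_1, V_2$ and per-particle body orientations
$E_{1,i}, E_{2,i}$, the segmented image of body $h$ is

$$X_{h,i} = \mathrm{Win}(r_{h,i}, b)\left(X_i -
  F^{-1}\!\left[\mathrm{CTF}_i \cdot A^{E_{k,i}} F(V_k)\right]\right),
\qquad
 r_{h,i} = P_{XY} E_{h,i}\, r_{3D,h} + s_i,$$

where $A^E$ is the central-slice (projection) operator at orientation
$E$, $\mathrm{Win}(r, b)$ re-windows a $b \times b$ box at center $r$,
$r_{3D,h}$ is the 3D offset of body $h$ in the composite map and $s_i$
the particle's origin shift. Because $V_k$ is only known to resolution
$R_k$, the subtraction residual lives above $1/R_k$ and shrinks as the
iteration sharpens $V_k$.

Everything needed to exercise the method without real data is included: a
two-body micrograph simulator with ground-truth metadata, a Fourier-slice
projector and CTF model, a Wiener-weighted direct-Fourier reconstruction
with gold-standard FSC, a deterministic local orientation refiner, and
minimal MRC/MRCS + STAR readers and writers.

## Worked example

Heterogeneity calibration — the simulator draws each body's pose so the
body-to-body difference has the configured spread (10° per Euler angle,
2 px per coordinate):

```r
library(cryoseg)
set.seed(1)
d <- sample_conformation(10000, sigma_euler_deg = 10, sigma_shift_px = 2)
round(c(rot = sd(d$rot1 - d$rot2), tilt = sd(d$tilt1 - d$tilt2),
        psi = sd(d$psi1 - d$psi2), dx = sd(d$dx1 - d$dx2),
        dy = sd(d$dy1 - d$dy2)), 3)
#>    rot   tilt    psi     dx     dy
#> 10.198  9.951 10.035  1.999  1.987
```

Exact-knowledge subtraction strips one body's power from a noiseless
two-body particle, leaving exactly the other body:

```r
model <- make_two_body_phantom(box = 48, voxel_size = 1.32, seed = 2)
ctf <- ctf_params(defocus_u = 20000, cs = 2.7, voltage = 300)
po1 <- pose(20, 50, -40); po2 <- pose(25, 46, -35)
off1 <- project_anchor(model$anchor1, po1)
off2 <- project_anchor(model$anchor2, po2)
p1 <- fourier_slice_project(model$body1,
        pose(po1$rot, po1$tilt, po1$psi, off1[1], off1[2]), ctf, box = 64)
p2 <- fourier_slice_project(model$body2,
        pose(po2$rot, po2$tilt, po2$psi, off2[1], off2[2]), ctf, box = 64)
particle <- image2d(p1$pixels + p2$pixels, 1.32)
clean <- subtract_projection(particle, model$body1,
           pose(po1$rot, po1$tilt, po1$psi, off1[1], off1[2]), ctf)
c(before = sum(particle$pixels^2), after = sum(clean$pixels^2),
  body2_only = sum(p2$pixels^2))
#>     before      after body2_only
#>   5936.182   3904.053   3904.053
```

End-to-end on a small noisy simulation (300 particles, SNR 0.1): simulate,
then two rounds of subtract → re-window → refine → reconstruct per body,
starting from low-pass-filtered references and consensus poses:

```r
cfg <- sim_config(n_micrographs = 4, particles_per_micrograph = 75,
                  micrograph_size = 512, box = 72, pixel_size = 1.32,
                  phantom_box = 48, snr = 0.1, seed = 1)
ds <- generate_dataset(cfg)
ctfs <- lapply(seq_len(nrow(ds$observed)), function(i) {
  r <- ds$observed[i, ]
  ctf_params(r$defocus_u, r$defocus_v, r$astig_angle, r$cs, r$voltage,
             r$amplitude_contrast, r$bfactor)
})
model0 <- two_body_model(lowpass(ds$model$body1, 15),
                         lowpass(ds$model$body2, 15),
                         ds$model$anchor1, ds$model$anchor2)
fit <- iterate_segmentation(ds$particles, ds$observed, model0, ctfs,
                            rounds = 2, sub_box = 48, pixel_size = 1.32,
                            symmetry = c("C1", "C6"), resolution = 8)
print(fit)
#> Iterative two-body segmentation
#>   round 1 body 1: 9.96 A
#>   round 1 body 2: 8.16 A
#>   round 2 body 1: 9.66 A
#>   round 2 body 2: 6.77 A
#>   converged: FALSE (tolerance 2%), best round 2
```

The per-round lines are gold-standard (half-set) FSC resolutions of each
body's reconstruction; the asymmetric cap (body 1) is harder than the C6
base (body 2). At 300 particles the resolution estimates still move
between rounds, so the loop does not yet declare convergence; the shipped
validation run uses 1,000 particles, where the pair-mean resolution
stabilizes within two rounds. The same pipeline is scriptable from a
shell via the installed launcher:

```sh
$(Rscript -e 'cat(system.file("cli", "cryoseg", package = "cryoseg"))') \
  simulate --out sim --metadata-only --seed 1
```

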