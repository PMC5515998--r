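# Shared fixtures: smooth blob phantoms with known analytic structure and
# a two-body render helper. Everything is generated in code at test time.

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# Evaluate a sum of Gaussian blobs on a centered n^3 grid.
eval_blobs <- function(n, centers, sigmas, amps) {
  k <- seq_len(n) - 1 - n %/% 2
  gx <- array(k, c(n, n, n))
  gy <- array(rep(k, each = n), c(n, n, n))
  gz <- array(rep(k, each = n * n), c(n, n, n))
  out <- array(0, c(n, n, n))
  for (i in seq_len(nrow(centers))) {
    d2 <- (gx - centers[i, 1])^2 + (gy - centers[i, 2])^2 +
      (gz - centers[i, 3])^2
    out <- out + amps[i] * exp(-d2 / (2 * sigmas[i]^2))
  }
  out
}

# Smooth compact phantom: wide blobs close to the center, so both
# projectors operate well inside their accuracy regime.
smooth_phantom <- function(n = 32, nblob = 8, seed = 3, voxel = 1) {
  set.seed(seed)
  centers <- matrix(runif(3 * nblob, -0.18 * n, 0.18 * n), ncol = 3)
  sigmas <- runif(nblob, 2.5, 3.5)
  amps <- runif(nblob, 0.5, 1)
  v <- volume3d(eval_blobs(n, centers, sigmas, amps), voxel)
  attr(v, "blobs") <- list(centers = centers, sigmas = sigmas, amps = amps)
  v
}

# Render a noiseless two-body particle: each body projected at its pose
# with the projected anchor offset folded into the shift.
render_body <- function(model, body_id, po, ctf, box, extra_shift = c(0, 0)) {
  off <- project_anchor(model_anchor_t(model, body_id), po) + extra_shift
  p <- pose(po$rot, po$tilt, po$psi, off[1], off[2])
  fourier_slice_project(
    if (body_id == 1) model$body1 else model$body2, p, ctf, box)
}

model_anchor_t <- function(model, body_id) {
  if (body_id == 1) model$anchor1 else model$anchor2
}

# Sub-pixel peak of a cross-correlation surface via parabolic fit.
cc_peak <- function(a, b) {
  n <- nrow(a)
  fa <- ft_centered_t(a)
  fb <- ft_centered_t(b)
  cc <- Re(ift_centered_t(fa * Conj(fb)))
  ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  px <- ij[1]; py <- ij[2]
  dx <- dy <- 0
  if (px > 1 && px < n) {
    c0 <- cc[px, py]; cm <- cc[px - 1, py]; cp <- cc[px + 1, py]
    den <- cm - 2 * c0 + cp
    if (abs(den) > 0) dx <- 0.5 * (cm - cp) / den
  }
  if (py > 1 && py < n) {
    c0 <- cc[px, py]; cm <- cc[px, py - 1]; cp <- cc[px, py + 1]
    den <- cm - 2 * c0 + cp
    if (abs(den) > 0) dy <- 0.5 * (cm - cp) / den
  }
  # offset of b relative to a (centered convention)
  c(px - 1 - n %/% 2 + dx, py - 1 - n %/% 2 + dy)
}

# sharper blobs: spectral power persists to near Nyquist, which the
# backprojection self-consistency checks need
sharp_phantom <- function(n = 32, nblob = 10, seed = 3, voxel = 1) {
  set.seed(seed)
  centers <- matrix(runif(3 * nblob, -0.16 * n, 0.16 * n), ncol = 3)
  sigmas <- runif(nblob, 0.9, 1.6)
  amps <- runif(nblob, 0.5, 1)
  volume3d(eval_blobs(n, centers, sigmas, amps), voxel)
}

ft_centered_t <- function(x) cryoseg:::ft_centered(x)
ift_centered_t <- function(x) cryoseg:::ift_centered(x)

ctf_for_row <- function(r) {
  ctf_params(r$defocus_u, r$defocus_v, r$astig_angle, r$cs, r$voltage,
             r$amplitude_contrast, r$bfactor)
}

ctf_list_for <- function(observed) {
  lapply(seq_len(nrow(observed)), function(i) ctf_for_row(observed[i, ]))
}
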