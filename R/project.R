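# Projection operators: central-slice (Fourier) projection with optional
# CTF, a slow real-space reference projector, and soft low-pass filtering.
# The Fourier projector edge-pads the volume 4x before the 3D FFT:
# oversampling the transform keeps trilinear central-slice interpolation
# errors near 1% while leaving axis-aligned poses exact (slice samples
# land on grid points), which a real-space sinc^2 pre-correction would
# spoil. The backprojector uses its own 2x padding with CTF^2 weight
# normalization, where the spread kernel largely cancels.

PAD_FACTOR <- 4L

# sinc(x) = sin(pi x)/(pi x)
sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))

# Pad a cubic array symmetrically (center preserved) to size p * n.
pad_volume <- function(a, pad = PAD_FACTOR) {
  n <- dim(a)[1]
  p <- n * pad
  out <- array(0, c(p, p, p))
  off <- (p - n) / 2
  out[off + seq_len(n), off + seq_len(n), off + seq_len(n)] <- a
  out
}

# Centered 3D FFT of the padded volume. This is the reusable heavy
# piece: compute once per reference, slice many times.
volume_ft <- function(vol, pad = PAD_FACTOR) {
  stopifnot(inherits(vol, "volume3d"))
  ft_centered(pad_volume(vol$density, pad))
}

#' Project a volume by central-slice extraction
#'
#' Computes the 2D projection of `vol` at `pose` via the projection
#' theorem: 3D FFT of the 4x-padded volume, trilinear extraction of the
#' central plane normal to the rotated Z axis, optional
#' CTF multiplication, sub-pixel origin shift as a Fourier phase ramp, and
#' inverse 2D FFT. At the identity pose the result equals the Z-sum of the
#' volume up to interpolation error.
#'
#' @param vol A [volume3d()], or a precomputed transform from an earlier
#'   call (see `vol_ft`).
#' @param pose A [pose()]; `shift_x`/`shift_y` displace the projection in
#'   the image.
#' @param ctf A [ctf_params()] or `NULL` for no CTF.
#' @param box Output box size in pixels (even; at most the padded volume
#'   size).
#' @param vol_ft Optional centered 3D FFT of the padded volume (from
#'   `volume_ft`) to amortize the FFT across many projections.
#' @return An [image2d()] with the volume's voxel size as pixel size.
#' @export
fourier_slice_project <- function(vol, pose, ctf = NULL, box = NULL,
                                  vol_ft = NULL) {
  stopifnot(inherits(vol, "volume3d"))
  n <- dim(vol$density)[1]
  if (is.null(box)) box <- n
  if (box %% 2 != 0) stop_invalid("box must be even")
  p <- n * PAD_FACTOR
  if (box > p) stop_invalid("box (%d) exceeds padded volume size (%d)", box, p)
  if (is.null(vol_ft)) vol_ft <- volume_ft(vol)
  r <- euler_to_matrix(pose)
  s <- cpp_extract_slice(vol_ft, r, as.integer(box), p / box)
  if (!is.null(ctf)) s <- s * ctf_2d(ctf, box, vol$voxel_size)
  if (pose$shift_x != 0 || pose$shift_y != 0)
    s <- s * phase_ramp2(box, pose$shift_x, pose$shift_y)
  img <- Re(ift_centered(s))
  image2d(img, pixel_size = vol$voxel_size)
}

# Trilinear resampling of a volume under rotation matrix R (optionally a
# translation in voxels): out(x) = V(t(R) %*% x - shift).
rotate_volume_data <- function(a, r, shift = c(0, 0, 0)) {
  n <- dim(a)[1]
  k <- freq_coords(n)
  grid <- cbind(rep(k, times = n * n),
                rep(rep(k, each = n), times = n),
                rep(k, each = n * n))
  pts <- grid %*% r  # row-vectors times R == t(R) %*% x per point
  pts <- sweep(pts, 2, shift)
  array(cpp_sample_volume(a, pts), c(n, n, n))
}

#' Reference real-space projector
#'
#' Rotates the volume by the pose's rotation (trilinear resampling) and
#' sums along Z. Slow but independent of the Fourier machinery; used as
#' the accuracy reference for [fourier_slice_project()].
#'
#' @inheritParams fourier_slice_project
#' @return An [image2d()].
#' @export
real_space_project <- function(vol, pose, box = NULL) {
  stopifnot(inherits(vol, "volume3d"))
  n <- dim(vol$density)[1]
  if (is.null(box)) box <- n
  r <- euler_to_matrix(pose)
  rot <- rotate_volume_data(vol$density, r)
  img <- apply(rot, c(1, 2), sum)
  if (box != n) {
    if (box > n) {
      out <- matrix(0, box, box)
      off <- (box - n) / 2
      out[off + seq_len(n), off + seq_len(n)] <- img
      img <- out
    } else {
      off <- (n - box) / 2
      img <- img[off + seq_len(box), off + seq_len(box)]
    }
  }
  if (pose$shift_x != 0 || pose$shift_y != 0) {
    s <- ft_centered(img) * phase_ramp2(box, pose$shift_x, pose$shift_y)
    img <- Re(ift_centered(s))
  }
  image2d(img, pixel_size = vol$voxel_size)
}

# Raised-cosine low-pass transfer function over a centered radius grid.
lowpass_profile <- function(radius, cutoff, soft = 5) {
  t <- (radius - cutoff) / soft
  w <- ifelse(t <= 0, 1, ifelse(t >= 1, 0, 0.5 * (1 + cos(pi * t))))
  w
}

#' Soft-edged low-pass filter
#'
#' Retains spatial frequencies below `1/resolution` with a raised-cosine
#' roll-off over 5 Fourier pixels. Works on [volume3d()] and [image2d()]
#' objects alike.
#'
#' @param x A [volume3d()] or [image2d()].
#' @param resolution Target resolution in Angstrom (>= 2 * pixel size).
#' @return Same class as `x`.
#' @export
lowpass <- function(x, resolution) {
  ps <- if (inherits(x, "volume3d")) x$voxel_size else x$pixel_size
  if (!is.finite(resolution) || resolution < 2 * ps)
    stop_invalid("resolution must be >= Nyquist (%.3f A)", 2 * ps)
  if (inherits(x, "volume3d")) {
    n <- dim(x$density)[1]
    cutoff <- n * ps / resolution
    w <- lowpass_profile(freq_radius(rep(n, 3)), cutoff)
    out <- Re(ift_centered(ft_centered(x$density) * w))
    volume3d(out, x$voxel_size)
  } else if (inherits(x, "image2d")) {
    n <- nrow(x$pixels)
    cutoff <- n * ps / resolution
    w <- lowpass_profile(freq_radius(rep(n, 2)), cutoff)
    out <- Re(ift_centered(ft_centered(x$pixels) * w))
    image2d(out, x$pixel_size, x$origin)
  } else stop_invalid("x must be a volume3d or image2d")
}
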