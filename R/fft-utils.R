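# Centered FFT helpers. Real-space arrays keep their origin at voxel
# n/2 (0-based); "centered" spectra have DC at the same index. Shifting
# before/after stats::fft keeps interpolated phases smooth, which is what
# makes trilinear central-slice extraction accurate.

shift_idx <- function(n, inverse = FALSE) {
  h <- if (inverse) ceiling(n / 2) else floor(n / 2)
  c(seq_len(n - h) + h, seq_len(h))
}

fftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) return(x[shift_idx(length(x))])
  idx <- lapply(d, shift_idx)
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

ifftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) return(x[shift_idx(length(x), inverse = TRUE)])
  idx <- lapply(d, shift_idx, inverse = TRUE)
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Forward/inverse transforms with origin at the array center (even sizes).
ft_centered <- function(x) fftshift(fft(ifftshift(x)))

ift_centered <- function(X) fftshift(fft(ifftshift(X), inverse = TRUE)) / length(X)

# Centered integer frequency coordinates for an even box.
freq_coords <- function(n) seq_len(n) - 1 - n %/% 2

# 2D grids of centered frequency indices.
freq_grid2 <- function(n) {
  k <- freq_coords(n)
  list(kx = matrix(k, n, n), ky = matrix(k, n, n, byrow = TRUE))
}

# Fourier phase ramp that shifts an image by (dx, dy) pixels when
# multiplied onto its centered transform.
phase_ramp2 <- function(n, dx, dy) {
  g <- freq_grid2(n)
  exp(-2i * pi * (g$kx * dx + g$ky * dy) / n)
}

# Radius (in Fourier pixels) of every element of a centered 2D/3D grid.
freq_radius <- function(dims) {
  k <- lapply(dims, function(n) freq_coords(n))
  if (length(dims) == 2) {
    g <- freq_grid2(dims[1])
    sqrt(g$kx^2 + g$ky^2)
  } else {
    n <- dims[1]
    kx <- array(k[[1]], dims)
    ky <- array(rep(k[[2]], each = n), dims)
    kz <- array(rep(k[[3]], each = n * n), dims)
    sqrt(kx^2 + ky^2 + kz^2)
  }
}

# Mean of x over integer-radius shells; returns value per shell 0..rmax.
shell_mean <- function(x, radius, rmax = NULL) {
  shell <- as.integer(round(radius))
  if (is.null(rmax)) rmax <- max(shell)
  keep <- shell <= rmax
  sums <- tapply(x[keep], shell[keep], mean)
  out <- rep(NA_real_, rmax + 1)
  out[as.integer(names(sums)) + 1] <- as.numeric(sums)
  out
}
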