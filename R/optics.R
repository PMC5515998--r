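#' Contrast transfer function parameters
#'
#' Container for the microscope/defocus parameters that define the 2D CTF.
#' Defocus is positive for underfocus. `astig_angle` is the azimuth of the
#' `defocus_u` axis, measured in degrees from the image x axis.
#'
#' @param defocus_u,defocus_v Defoci along the major/minor astigmatism axes
#'   in Angstrom (positive = underfocus).
#' @param astig_angle Astigmatism azimuth in degrees.
#' @param cs Spherical aberration in mm.
#' @param voltage Acceleration voltage in kV.
#' @param amplitude_contrast Amplitude-contrast fraction in `[0, 1]`.
#' @param bfactor Envelope B-factor in Angstrom^2 (>= 0).
#' @param phase_shift Additional constant phase shift in degrees.
#' @return An object of class `"ctf_params"`.
#' @export
ctf_params <- function(defocus_u = 20000, defocus_v = defocus_u,
                       astig_angle = 0, cs = 2.7, voltage = 300,
                       amplitude_contrast = 0.1, bfactor = 0,
                       phase_shift = 0) {
  if (!all(is.finite(c(defocus_u, defocus_v, astig_angle, cs, voltage,
                       amplitude_contrast, bfactor, phase_shift))))
    stop_invalid("CTF parameters must be finite")
  if (voltage <= 0) stop_invalid("voltage must be positive")
  if (cs < 0) stop_invalid("spherical aberration must be >= 0")
  if (amplitude_contrast < 0 || amplitude_contrast > 1)
    stop_invalid("amplitude contrast must lie in [0, 1]")
  if (bfactor < 0) stop_invalid("bfactor must be >= 0")
  structure(list(defocus_u = defocus_u, defocus_v = defocus_v,
                 astig_angle = astig_angle, cs = cs, voltage = voltage,
                 amplitude_contrast = amplitude_contrast, bfactor = bfactor,
                 phase_shift = phase_shift),
            class = "ctf_params")
}

#' @export
print.ctf_params <- function(x, ...) {
  cat(sprintf(
    "ctf: defocus %.0f/%.0f A (astig %.1f deg), Cs %.2f mm, %.0f kV, w %.2f, B %.1f A^2\n",
    x$defocus_u, x$defocus_v, x$astig_angle, x$cs, x$voltage,
    x$amplitude_contrast, x$bfactor))
  invisible(x)
}

# Relativistic electron wavelength in Angstrom for voltage in kV.
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1e3
  12.2643 / sqrt(v * (1 + v * 0.978476e-6))
}

#' Evaluate the 2D contrast transfer function
#'
#' Computes `CTF(k) = -(sqrt(1 - w^2) sin(chi) + w cos(chi)) exp(-B |k|^2 / 4)`
#' with phase `chi(k) = pi lambda df(theta) |k|^2 - (pi/2) Cs lambda^3 |k|^4
#' + phase_shift` and astigmatic defocus
#' `df(theta) = (df_u + df_v)/2 + (df_u - df_v)/2 cos(2 (theta - theta_a))`.
#' At the origin the value is `-w`, so protein appears dark in simulated
#' images. The array is laid out on the centered Fourier grid of `box`
#' (DC at index `box/2 + 1`); use [ifftshift()] for standard FFT layout.
#'
#' @param params A [ctf_params()] object.
#' @param box Box size in pixels (even, >= 2).
#' @param pixel_size Pixel size in Angstrom.
#' @return A `box` x `box` real matrix.
#' @export
ctf_2d <- function(params, box, pixel_size) {
  if (!inherits(params, "ctf_params")) stop_invalid("params must be ctf_params")
  if (box < 2) stop_invalid("box must be >= 2")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop_invalid("pixel_size must be positive")
  g <- freq_grid2(box)
  kx <- g$kx / (box * pixel_size)
  ky <- g$ky / (box * pixel_size)
  k2 <- kx^2 + ky^2
  theta <- atan2(ky, kx)
  lambda <- electron_wavelength(params$voltage)
  df <- 0.5 * (params$defocus_u + params$defocus_v +
               (params$defocus_u - params$defocus_v) *
                 cos(2 * (theta - deg2rad(params$astig_angle))))
  chi <- pi * lambda * df * k2 -
    (pi / 2) * (params$cs * 1e7) * lambda^3 * k2^2 +
    deg2rad(params$phase_shift)
  w <- params$amplitude_contrast
  env <- exp(-params$bfactor * k2 / 4)
  -(sqrt(1 - w^2) * sin(chi) + w * cos(chi)) * env
}

#' Apply a CTF to an image transform
#'
#' Element-wise product of a centered 2D Fourier transform with the CTF of
#' the same grid. Applying twice multiplies by the squared CTF.
#'
#' @param image_ft Complex matrix (centered layout, as from `ft_centered`).
#' @param params A [ctf_params()] object.
#' @param pixel_size Pixel size in Angstrom.
#' @return Complex matrix of the same shape.
#' @export
apply_ctf <- function(image_ft, params, pixel_size) {
  if (!is.matrix(image_ft) || nrow(image_ft) != ncol(image_ft))
    stop_invalid("image_ft must be a square matrix")
  image_ft * ctf_2d(params, nrow(image_ft), pixel_size)
}
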