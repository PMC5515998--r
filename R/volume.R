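#' Cubic 3D density volume
#'
#' A real cubic density grid with its voxel size. Data are stored as an R
#' array `a[ix, iy, iz]` with x fastest; the volume center sits at voxel
#' `N/2` (0-based), i.e. R index `N/2 + 1`.
#'
#' @param density Numeric N x N x N array (N even).
#' @param voxel_size Voxel size in Angstrom.
#' @return Object of class `"volume3d"`.
#' @export
volume3d <- function(density, voxel_size = 1) {
  d <- dim(density)
  if (length(d) != 3 || length(unique(d)) != 1)
    stop_invalid("density must be a cubic N x N x N array")
  if (d[1] %% 2 != 0) stop_invalid("volume side must be even")
  if (!all(is.finite(density))) stop_invalid("density must be finite")
  if (!is.finite(voxel_size) || voxel_size <= 0)
    stop_invalid("voxel_size must be positive")
  structure(list(density = density, voxel_size = voxel_size),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  n <- dim(x$density)[1]
  cat(sprintf("volume3d: %d^3 voxels at %.3f A/voxel (sum %.4g)\n",
              n, x$voxel_size, sum(x$density)))
  invisible(x)
}

#' Square 2D image
#'
#' @param pixels Numeric b x b matrix (b even).
#' @param pixel_size Pixel size in Angstrom.
#' @param origin Optional `c(x, y)` 0-based position of the window's lower
#'   corner in a parent micrograph/image.
#' @return Object of class `"image2d"`.
#' @export
image2d <- function(pixels, pixel_size = 1, origin = NULL) {
  if (!is.matrix(pixels) || nrow(pixels) != ncol(pixels))
    stop_invalid("pixels must be a square matrix")
  if (nrow(pixels) %% 2 != 0) stop_invalid("image side must be even")
  if (!all(is.finite(pixels))) stop_invalid("pixels must be finite")
  structure(list(pixels = pixels, pixel_size = pixel_size, origin = origin),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("image2d: %d x %d px at %.3f A/px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size))
  invisible(x)
}

#' Two-body model: rigid-body volumes plus their anchors
#'
#' Holds the two rigid-body density maps, each centered in its own box,
#' together with the 3D offsets of their centers from the composite-volume
#' center (`anchor1`, `anchor2`, voxels).
#'
#' @param body1,body2 [volume3d()] objects with equal voxel sizes.
#' @param anchor1,anchor2 Length-3 voxel offsets.
#' @return Object of class `"two_body_model"`.
#' @export
two_body_model <- function(body1, body2, anchor1, anchor2) {
  if (!inherits(body1, "volume3d") || !inherits(body2, "volume3d"))
    stop_invalid("bodies must be volume3d objects")
  if (abs(body1$voxel_size - body2$voxel_size) > 1e-9)
    stop_invalid("bodies must share a voxel size")
  anchor1 <- as.numeric(anchor1); anchor2 <- as.numeric(anchor2)
  if (length(anchor1) != 3 || length(anchor2) != 3 ||
      !all(is.finite(c(anchor1, anchor2))))
    stop_invalid("anchors must be finite length-3 vectors")
  structure(list(body1 = body1, body2 = body2,
                 anchor1 = anchor1, anchor2 = anchor2),
            class = "two_body_model")
}

model_body <- function(model, body_id) {
  if (body_id == 1) model$body1 else model$body2
}

model_anchor <- function(model, body_id) {
  if (body_id == 1) model$anchor1 else model$anchor2
}
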