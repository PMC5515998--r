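# Signal subtraction and sub-particle extraction: remove one rigid body's
# CTF-modulated projection from a particle image or a whole micrograph,
# re-window the other body at its predicted center, and quantify what the
# subtraction leaves behind.

#' Subtract a body's projection from a particle image
#'
#' Renders `P = fourier_slice_project(body, pose, ctf, box)` and returns
#' `particle - scale * P`. By default the reference is subtracted at unit
#' scale, relying on reconstruction and data sharing an absolute gray
#' scale; `scale = "lsq"` instead fits a per-particle least-squares scale
#' factor of the projection against the image.
#'
#' @param particle An [image2d()].
#' @param body A [volume3d()] with the particle's pixel size.
#' @param pose Body pose ([pose()]); the shift must already place the
#'   projection at the body's in-image position (see [predict_center()]).
#' @param ctf [ctf_params()] of the parent micrograph, or `NULL`.
#' @param scale `1` (default) or `"lsq"`.
#' @param vol_ft Optional precomputed `volume_ft(body)`.
#' @return An [image2d()] with the body's signal removed.
#' @export
subtract_projection <- function(particle, body, pose, ctf = NULL, scale = 1,
                                vol_ft = NULL) {
  stopifnot(inherits(particle, "image2d"), inherits(body, "volume3d"))
  if (abs(particle$pixel_size - body$voxel_size) > 1e-9)
    stop_invalid("pixel size mismatch: particle %.4f vs volume %.4f A",
                 particle$pixel_size, body$voxel_size)
  b <- nrow(particle$pixels)
  proj <- fourier_slice_project(body, pose, ctf, box = b, vol_ft = vol_ft)
  s <- if (identical(scale, "lsq")) {
    denom <- sum(proj$pixels^2)
    if (denom > 0) sum(proj$pixels * particle$pixels) / denom else 1
  } else scale
  image2d(particle$pixels - s * proj$pixels, particle$pixel_size,
          particle$origin)
}

#' Re-window a sub-particle at a predicted center
#'
#' Extracts a `box` x `box` window centered on `round(center)` (0-based
#' pixel coordinates of the parent). The fractional remainder is recorded
#' as `residual_shift` so downstream alignment can start sub-pixel
#' correct; the image itself is never resampled. The window mean is
#' subtracted (background flattening). Windows that cross the parent edge
#' are not padded: the record comes back flagged with `ok = FALSE` and an
#' all-zero image.
#'
#' @param parent An [image2d()] (particle or micrograph).
#' @param center Numeric `c(x, y)`, float pixels, 0-based.
#' @param box Window size in pixels (even, > 0).
#' @return List with `image` ([image2d()]) and `record` (fields `center`,
#'   `residual_shift`, `box`, `window_origin`, `ok`).
#' @export
rewindow <- function(parent, center, box) {
  stopifnot(inherits(parent, "image2d"))
  if (box <= 0 || box %% 2 != 0) stop_invalid("box must be even and > 0")
  center <- as.numeric(center)
  ci <- round(center)
  x0 <- ci[1] - box / 2
  y0 <- ci[2] - box / 2
  n <- nrow(parent$pixels)
  ok <- x0 >= 0 && y0 >= 0 && x0 + box <= n && y0 + box <= ncol(parent$pixels)
  if (ok) {
    w <- parent$pixels[x0 + seq_len(box), y0 + seq_len(box)]
    w <- w - mean(w)
  } else {
    w <- matrix(0, box, box)
  }
  list(image = image2d(w, parent$pixel_size, origin = c(x0, y0)),
       record = list(center = center, residual_shift = center - ci,
                     box = box, window_origin = c(x0, y0), ok = ok))
}

#' Predict a body's re-window center
#'
#' Composes the projected 3D anchor offset with the particle's own
#' position: `particle_xy + P_XY(E %*% anchor) + pose shift`. With the
#' default `particle_xy = box/2` convention the result is an in-box
#' 0-based center; pass the particle's micrograph coordinates to obtain an
#' absolute micrograph center.
#'
#' @param pose The body's [pose()] (shift = body translation relative to
#'   the particle center, pixels).
#' @param model A [two_body_model()].
#' @param body_id 1 or 2.
#' @param particle_xy Numeric `c(x, y)` position of the particle center in
#'   the parent frame (0-based pixels).
#' @return Numeric `c(x, y)` float pixels.
#' @export
predict_center <- function(pose, model, body_id, particle_xy = c(0, 0)) {
  stopifnot(inherits(model, "two_body_model"), body_id %in% c(1, 2))
  particle_xy + project_anchor(model_anchor(model, body_id), pose)
}

#' Subtract body projections from a whole micrograph
#'
#' For every particle record, renders the body's CTF-modulated projection
#' in a patch centered at the particle's (rounded) micrograph coordinates,
#' placing it sub-pixel exactly with a Fourier phase ramp, accumulates all
#' patches into a canvas, and subtracts the canvas once. Accumulating
#' first means overlapping particles each contribute exactly their own
#' projection. Patches that cross the micrograph edge have their in-bounds
#' part subtracted and the record flagged.
#'
#' @param mic An [image2d()] micrograph.
#' @param records Data frame with columns `coord_x`, `coord_y` (particle
#'   centers, 0-based float pixels) and `rot`, `tilt`, `psi`, `shift_x`,
#'   `shift_y` (body pose per particle).
#' @param body A [volume3d()].
#' @param ctf One [ctf_params()] shared by the micrograph, or `NULL`.
#' @param anchor The body's 3D anchor offset (voxels) used to place its
#'   projection relative to the particle center.
#' @param box Patch size in pixels; defaults to twice the body box
#'   (clipped to the micrograph size) so CTF fringes are retained.
#' @return List with `micrograph` (subtracted [image2d()]), `n_subtracted`
#'   and `flagged` (indices of edge-clipped records).
#' @export
subtract_from_micrograph <- function(mic, records, body, ctf = NULL,
                                     anchor = c(0, 0, 0), box = NULL) {
  stopifnot(inherits(mic, "image2d"), inherits(body, "volume3d"))
  n <- nrow(mic$pixels)
  if (is.null(box)) box <- min(2L * dim(body$density)[1], n)
  box <- box - box %% 2
  canvas <- matrix(0, n, n)
  flagged <- integer(0)
  nrec <- if (is.null(records)) 0L else nrow(records)
  if (nrec > 0) {
    vft <- volume_ft(body)
    for (i in seq_len(nrec)) {
      rec <- records[i, ]
      p0 <- round(c(rec$coord_x, rec$coord_y))
      frac <- c(rec$coord_x, rec$coord_y) - p0
      po <- pose(rec$rot, rec$tilt, rec$psi,
                 shift_x = rec$shift_x, shift_y = rec$shift_y)
      off <- project_anchor(anchor, po) + frac
      po$shift_x <- off[1]
      po$shift_y <- off[2]
      proj <- fourier_slice_project(body, po, ctf, box = box, vol_ft = vft)
      x0 <- p0[1] - box / 2
      y0 <- p0[2] - box / 2
      xs <- x0 + seq_len(box)
      ys <- y0 + seq_len(box)
      inx <- xs >= 1 & xs <= n
      iny <- ys >= 1 & ys <= n
      if (!all(inx) || !all(iny)) flagged <- c(flagged, i)
      if (any(inx) && any(iny))
        canvas[xs[inx], ys[iny]] <- canvas[xs[inx], ys[iny]] +
          proj$pixels[inx, iny]
    }
  }
  list(micrograph = image2d(mic$pixels - canvas, mic$pixel_size, mic$origin),
       n_subtracted = nrec, flagged = flagged)
}

#' Rotationally averaged residual power spectrum
#'
#' Spherically (here: azimuthally) averaged power of the difference
#' between a subtracted image and the ideal remaining signal, plus the
#' fraction of residual power below the reference-resolution cutoff
#' `1/ref_resolution`. When the subtracted reference was a low-pass
#' filtered estimate of the true body, the residual should be confined to
#' frequencies above that cutoff.
#'
#' @param subtracted,ideal_other [image2d()]s on the same grid.
#' @param ref_resolution Reference resolution `R_k` in Angstrom.
#' @return Object of class `"residual_spectrum"`: `freq` (1/Angstrom),
#'   `power`, `below_fraction`, `ref_resolution`.
#' @export
residual_spectrum <- function(subtracted, ideal_other, ref_resolution = NULL) {
  stopifnot(inherits(subtracted, "image2d"), inherits(ideal_other, "image2d"))
  if (!all(dim(subtracted$pixels) == dim(ideal_other$pixels)))
    stop_invalid("images must share a grid")
  n <- nrow(subtracted$pixels)
  ps <- subtracted$pixel_size
  d <- subtracted$pixels - ideal_other$pixels
  pw <- Mod(ft_centered(d))^2
  rad <- freq_radius(rep(n, 2))
  rmax <- n %/% 2
  prof <- shell_mean(pw, rad, rmax)
  below <- NA_real_
  if (!is.null(ref_resolution)) {
    cutoff <- n * ps / ref_resolution
    tot <- sum(pw[rad <= rmax])
    below <- if (tot > 0) sum(pw[rad < cutoff]) / tot else 0
  }
  structure(list(freq = (0:rmax) / (n * ps), power = prof,
                 below_fraction = below, ref_resolution = ref_resolution),
            class = "residual_spectrum")
}

#' @export
print.residual_spectrum <- function(x, ...) {
  cat(sprintf("residual spectrum: %d shells", length(x$freq)))
  if (!is.null(x$ref_resolution))
    cat(sprintf("; %.2f%% of power below 1/%.1f A", 100 * x$below_fraction,
                x$ref_resolution))
  cat("\n")
  invisible(x)
}
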