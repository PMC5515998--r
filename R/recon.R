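# Reconstruction back-end: direct Fourier inversion with Wiener-style
# CTF^2 weighting, gold-standard FSC with optional phase-randomized mask
# correction, a deterministic local grid-search pose refiner, the
# iterative segmentation/reconstruction loop, and conformational
# statistics of the refined per-body poses.

# Cn symmetrization by orbit averaging: every output voxel is the mean of
# the volume sampled at its n Z-rotated positions (single trilinear
# resampling pass from the source grid).
symmetrize_volume <- function(vol, n_fold) {
  if (n_fold <= 1) return(vol)
  a <- vol$density
  n <- dim(a)[1]
  k <- freq_coords(n)
  grid <- cbind(rep(k, times = n * n),
                rep(rep(k, each = n), times = n),
                rep(k, each = n * n))
  acc <- numeric(n^3)
  for (s in seq_len(n_fold) - 1) {
    r <- rot_z(deg2rad(360 * s / n_fold))
    acc <- acc + cpp_sample_volume(a, grid %*% r)
  }
  volume3d(array(acc / n_fold, c(n, n, n)), vol$voxel_size)
}

parse_symmetry <- function(symmetry) {
  if (is.numeric(symmetry)) return(as.integer(symmetry))
  m <- regmatches(symmetry, regexec("^[Cc]([0-9]+)$", symmetry))[[1]]
  if (length(m) < 2) stop_invalid("symmetry must be 'Cn'")
  as.integer(m[2])
}

#' Direct Fourier-inversion reconstruction
#'
#' Inserts the CTF-premultiplied centered 2D Fourier transforms of the
#' particle images as central slices into a padded 3D grid with trilinear
#' spreading, accumulating CTF^2 weights, then divides by the weights plus
#' a Wiener term (`wiener` times the per-shell mean weight), inverse
#' transforms, crops, corrects for the trilinear spread and optionally
#' applies Cn symmetry. Origin shifts in the poses are removed before
#' insertion so every body lands centered.
#'
#' @param particles b x b x n array (or list of [image2d()]).
#' @param poses List of [pose()] per particle.
#' @param ctfs List of [ctf_params()] per particle, a single
#'   [ctf_params()], or `NULL` (CTF treated as 1).
#' @param pixel_size Pixel size in Angstrom.
#' @param box Output volume side (defaults to the particle box).
#' @param symmetry `"Cn"` string or integer n.
#' @param wiener Wiener constant as a fraction of the per-shell mean
#'   weight.
#' @return A [volume3d()].
#' @export
backproject <- function(particles, poses, ctfs = NULL, pixel_size = 1,
                        box = NULL, symmetry = "C1", wiener = 0.01) {
  if (is.list(particles) && length(particles) > 0 &&
      inherits(particles[[1]], "image2d")) {
    pixel_size <- particles[[1]]$pixel_size
    particles <- simplify2array(lapply(particles, function(p) p$pixels))
  }
  if (length(dim(particles)) != 3 || dim(particles)[3] < 1)
    stop_invalid("particles must be a non-empty b x b x n array")
  b <- dim(particles)[1]
  n <- dim(particles)[3]
  if (length(poses) != n) stop_invalid("need one pose per particle")
  if (is.null(box)) box <- b
  n_fold <- parse_symmetry(symmetry)
  P <- 3L * box  # insertion oversampling: images are zero-padded to P so
                 # slice samples land densely on the 3D grid
  off <- (P - b) / 2
  single_ctf <- inherits(ctfs, "ctf_params")
  ctf_grid <- if (single_ctf) ctf_2d(ctfs, P, pixel_size) else NULL
  data <- array(0i, rep(P, 3))
  w <- array(0, rep(P, 3))
  chunk <- max(1L, floor(2^22 / P^2))  # ~64 MB of complex slices per batch
  for (lo in seq(1, n, by = chunk)) {
    hi <- min(lo + chunk - 1, n)
    m <- hi - lo + 1
    slices <- array(0i, c(P, P, m))
    rots <- array(0, c(3, 3, m))
    carr <- array(1, c(P, P, m))
    for (j in seq_len(m)) {
      i <- lo + j - 1
      po <- poses[[i]]
      img <- matrix(0, P, P)
      img[off + seq_len(b), off + seq_len(b)] <- particles[, , i]
      s <- ft_centered(img)
      if (po$shift_x != 0 || po$shift_y != 0)
        s <- s * phase_ramp2(P, -po$shift_x, -po$shift_y)
      slices[, , j] <- s
      rots[, , j] <- euler_to_matrix(po)
      if (!is.null(ctfs)) {
        carr[, , j] <- if (single_ctf) ctf_grid
          else ctf_2d(ctfs[[i]], P, pixel_size)
      }
    }
    acc <- cpp_backproject(slices, rots, carr, as.integer(P), 1)
    data <- data + acc$data
    w <- w + acc$weight
  }
  rad <- freq_radius(rep(P, 3))
  shells <- shell_mean(w, rad, P %/% 2)
  shells[is.na(shells) | shells <= 0] <- min(shells[shells > 0], na.rm = TRUE)
  wien <- wiener * shells[pmin(round(rad), P %/% 2) + 1]
  G <- data / (w + wien)
  volp <- Re(ift_centered(G))
  off <- (P - box) / 2
  volc <- volp[off + seq_len(box), off + seq_len(box), off + seq_len(box)]
  # undo the trilinear-spread envelope
  kr <- sinc(freq_coords(box) / P)^2
  volc <- volc / outer(outer(kr, kr), kr)
  out <- volume3d(volc, pixel_size)
  if (n_fold > 1) out <- symmetrize_volume(out, n_fold)
  out
}

#' Fourier shell correlation between two volumes
#'
#' Shell-wise normalized cross-correlation of two (half-set) maps, with
#' the resolution reported at the first crossing of `threshold` (0.143 by
#' default). When a soft mask volume is supplied, additionally computes
#' the phase-randomization corrected curve: beyond `randomize_from` the
#' reported FSC is `(FSC_masked - FSC_rand) / (1 - FSC_rand)` where
#' FSC_rand comes from the same half maps with phases randomized beyond
#' that frequency and the same mask applied.
#'
#' @param vol_a,vol_b [volume3d()]s on the same grid.
#' @param mask Optional [volume3d()] (or array) soft mask.
#' @param threshold FSC resolution threshold.
#' @param randomize_from Resolution (Angstrom) beyond which phases are
#'   randomized for the mask correction.
#' @return Object of class `"fsc_curve"`: `freq` (1/Angstrom), `fsc`,
#'   `resolution` (Angstrom), and the uncorrected curve when masked.
#' @export
fsc <- function(vol_a, vol_b, mask = NULL, threshold = 0.143,
                randomize_from = NULL) {
  stopifnot(inherits(vol_a, "volume3d"), inherits(vol_b, "volume3d"))
  if (!all(dim(vol_a$density) == dim(vol_b$density)))
    stop_invalid("volumes must share a grid")
  n <- dim(vol_a$density)[1]
  ps <- vol_a$voxel_size
  rad <- freq_radius(rep(n, 3))
  rmax <- n %/% 2
  shell_fsc <- function(a, b) {
    fa <- ft_centered(a)
    fb <- ft_centered(b)
    num <- shell_mean(Re(fa * Conj(fb)), rad, rmax)
    da <- shell_mean(Mod(fa)^2, rad, rmax)
    db <- shell_mean(Mod(fb)^2, rad, rmax)
    num / sqrt(pmax(da * db, .Machine$double.xmin))
  }
  if (is.null(mask)) {
    curve <- shell_fsc(vol_a$density, vol_b$density)
  } else {
    mk <- if (inherits(mask, "volume3d")) mask$density else mask
    masked <- shell_fsc(vol_a$density * mk, vol_b$density * mk)
    if (is.null(randomize_from)) randomize_from <- 4 * ps
    r0 <- n * ps / randomize_from
    randomize <- function(a) {
      fa <- ft_centered(a)
      high <- rad > r0
      ph <- exp(2i * pi * runif(sum(high)))
      fa[high] <- Mod(fa[high]) * ph
      Re(ift_centered(fa))
    }
    ra <- randomize(vol_a$density) * mk
    rb <- randomize(vol_b$density) * mk
    frand <- shell_fsc(ra, rb)
    curve <- masked
    beyond <- (0:rmax) > r0 + 2
    corr <- (masked - frand) / pmax(1 - frand, 1e-6)
    curve[beyond] <- corr[beyond]
    curve[is.na(curve)] <- 0
  }
  curve[1] <- 1
  freq <- (0:rmax) / (n * ps)
  res <- 2 * ps
  cross <- which(curve < threshold)
  cross <- cross[cross > 1]
  if (length(cross) > 0) {
    i <- cross[1]
    f1 <- freq[i - 1]; f2 <- freq[i]
    c1 <- curve[i - 1]; c2 <- curve[i]
    fc <- f1 + (threshold - c1) * (f2 - f1) / (c2 - c1)
    res <- 1 / fc
  }
  out <- list(freq = freq, fsc = curve, resolution = res,
              threshold = threshold)
  if (!is.null(mask)) out$fsc_masked <- masked
  structure(out, class = "fsc_curve")
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("FSC curve (%d shells): resolution %.2f A at %.3f\n",
              length(x$freq), x$resolution, x$threshold))
  invisible(x)
}

#' @export
plot.fsc_curve <- function(x, ...) {
  plot(x$freq, x$fsc, type = "l", xlab = "spatial frequency (1/A)",
       ylab = "FSC", ylim = c(min(0, min(x$fsc)), 1), ...)
  abline(h = x$threshold, lty = 2)
  abline(v = 1 / x$resolution, lty = 3)
  invisible(x)
}

# Soft-edged spherical mask (raised cosine over `soft` voxels).
soft_sphere_mask <- function(n, radius = 0.4 * n, soft = 4) {
  r <- freq_radius(rep(n, 3))  # same centered radius grid as Fourier use
  t <- (r - radius) / soft
  array(ifelse(t <= 0, 1, ifelse(t >= 1, 0, 0.5 * (1 + cos(pi * t)))),
        rep(n, 3))
}

# Candidate angular offsets ordered by distance from the start pose so
# ties resolve toward it.
angle_grid <- function(range_deg, step_deg) {
  g <- seq(-range_deg, range_deg, by = step_deg)
  g[order(abs(g))]
}

#' Local grid-search pose refinement
#'
#' Exhaustive deterministic search over a local neighbourhood of each
#' particle's start pose: all combinations of Euler-angle offsets in
#' `[-angular_range, angular_range]` at `angular_step`, scored by
#' CTF-aware normalized cross-correlation between the particle and the
#' reference projection (computed over Fourier pixels up to the matching
#' resolution, DC excluded), followed by a shift search on a
#' `[-shift_range, shift_range]` pixel grid for the winning orientation.
#' Ties break toward the start pose. Particles scoring below
#' `score_threshold` are flagged unconverged.
#'
#' @param particles b x b x n array (or list of [image2d()]).
#' @param reference A [volume3d()].
#' @param start_poses List of [pose()].
#' @param ctfs Per-particle [ctf_params()] list, single object, or `NULL`.
#' @param angular_range_deg,angular_step_deg Angular search grid (deg).
#' @param shift_range_px,shift_step_px Shift search grid (px).
#' @param resolution Matching resolution in Angstrom (reference and data
#'   are compared only below this frequency).
#' @param pixel_size Pixel size (taken from images when given as list).
#' @param score_threshold Convergence flag threshold on the score.
#' @return Object of class `"refinement_result"`: `poses`, `scores`,
#'   `converged`.
#' @export
refine_local <- function(particles, reference, start_poses, ctfs = NULL,
                         angular_range_deg = 15, angular_step_deg = 5,
                         shift_range_px = 2, shift_step_px = 1,
                         resolution = NULL, pixel_size = 1,
                         score_threshold = 0.1) {
  if (angular_step_deg > angular_range_deg && angular_range_deg > 0)
    stop_invalid("angular_step_deg must be <= angular_range_deg")
  if (is.list(particles) && length(particles) > 0 &&
      inherits(particles[[1]], "image2d")) {
    pixel_size <- particles[[1]]$pixel_size
    particles <- simplify2array(lapply(particles, function(p) p$pixels))
  }
  b <- dim(particles)[1]
  n <- dim(particles)[3]
  stopifnot(length(start_poses) == n, inherits(reference, "volume3d"))
  if (is.null(resolution)) resolution <- max(4 * pixel_size, 8)
  vft <- volume_ft(reference)
  P <- PAD_FACTOR * dim(reference$density)[1]
  scale <- P / b
  # masked frequency list below the matching resolution, DC excluded
  g <- freq_grid2(b)
  rmask <- b * pixel_size / resolution
  sel <- which(sqrt(g$kx^2 + g$ky^2) <= rmask & !(g$kx == 0 & g$ky == 0))
  kxy <- cbind(as.numeric(g$kx)[sel], as.numeric(g$ky)[sel])
  # angular candidates
  da <- if (angular_range_deg > 0) angle_grid(angular_range_deg, angular_step_deg) else 0
  cand <- expand.grid(drot = da, dtilt = da, dpsi = da)
  cand <- cand[order(abs(cand$drot) + abs(cand$dtilt) + abs(cand$dpsi)), ]
  # shift candidates (offsets added to the start shift)
  ds <- if (shift_range_px > 0) {
    s <- seq(-shift_range_px, shift_range_px, by = shift_step_px)
    s[order(abs(s))]
  } else 0
  sh <- expand.grid(dx = ds, dy = ds)
  sh <- sh[order(abs(sh$dx) + abs(sh$dy)), ]
  single_ctf <- inherits(ctfs, "ctf_params")
  poses_out <- vector("list", n)
  scores <- numeric(n)
  run_level <- function(po, cand_lvl, sh_lvl, Xsel, cvec) {
    rots <- array(0, c(3, 3, nrow(cand_lvl)))
    for (j in seq_len(nrow(cand_lvl)))
      rots[, , j] <- euler_to_matrix(c(po$rot + cand_lvl$drot[j],
                                       po$tilt + cand_lvl$dtilt[j],
                                       po$psi + cand_lvl$dpsi[j]))
    # pre-center the particle at the current shift so orientation scoring
    # already accounts for it; ramp columns then carry offsets only
    Xc <- Xsel * exp(2i * pi * (kxy[, 1] * po$shift_x +
                                  kxy[, 2] * po$shift_y) / b)
    ramps <- sapply(seq_len(nrow(sh_lvl)), function(s) {
      exp(-2i * pi * (kxy[, 1] * sh_lvl$dx[s] + kxy[, 2] * sh_lvl$dy[s]) / b)
    })
    if (is.null(dim(ramps))) ramps <- matrix(ramps, ncol = 1)
    fit <- cpp_refine(vft, rots, kxy, Xc, cvec, ramps, scale)
    list(pose = pose(po$rot + cand_lvl$drot[fit$rot],
                     po$tilt + cand_lvl$dtilt[fit$rot],
                     po$psi + cand_lvl$dpsi[fit$rot],
                     po$shift_x + sh_lvl$dx[fit$shift],
                     po$shift_y + sh_lvl$dy[fit$shift]),
         score = fit$score)
  }
  local_grid <- function(step_a, step_s) {
    da2 <- c(0, -step_a, step_a)
    cl <- expand.grid(drot = da2, dtilt = da2, dpsi = da2)
    ds2 <- c(0, -step_s, step_s)
    sl <- expand.grid(dx = ds2, dy = ds2)
    list(cand = cl, sh = sl)
  }
  for (i in seq_len(n)) {
    po <- start_poses[[i]]
    X <- ft_centered(particles[, , i])
    Xsel <- X[sel]
    cvec <- if (is.null(ctfs)) rep(1, length(sel)) else {
      ci <- if (single_ctf) ctfs else ctfs[[i]]
      ctf_2d(ci, b, pixel_size)[sel]
    }
    fit <- run_level(po, cand, sh, Xsel, cvec)
    # hierarchical polish: halve the angular/shift steps around the
    # current optimum so each call settles to sub-step accuracy
    sa <- angular_step_deg / 2
    ss <- shift_step_px / 2
    while (sa >= angular_step_deg / 4 && angular_range_deg > 0) {
      g2 <- local_grid(sa, ss)
      fit <- run_level(fit$pose, g2$cand, g2$sh, Xsel, cvec)
      sa <- sa / 2
      ss <- ss / 2
    }
    poses_out[[i]] <- fit$pose
    scores[i] <- fit$score
  }
  structure(list(poses = poses_out, scores = scores,
                 converged = scores >= score_threshold),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("refinement: %d particles, mean score %.3f, %d%% converged\n",
              length(x$poses), mean(x$scores),
              round(100 * mean(x$converged))))
  invisible(x)
}

# Shift applied to the raw particle that centers body `body_id`:
# the in-box body center minus box center.
body_center_in_box <- function(po, model, body_id, box) {
  predict_center(po, model, body_id, particle_xy = c(box / 2, box / 2))
}

#' Iterative two-body segmentation and reconstruction
#'
#' The driver of the method: per round and per body, subtract the current
#' estimate of the other body from every raw particle, re-window the body
#' of interest at its predicted center, refine its pose by local grid
#' search against the current body reference, reconstruct gold-standard
#' half maps (even/odd particle split) and measure the FSC resolution.
#' Iteration stops at `rounds`, on convergence (resolution change of both
#' bodies below `tol` between rounds) or on divergence (resolution
#' worsening two consecutive rounds; the best round is returned).
#'
#' @param particles b x b x n array of raw particle images.
#' @param meta Data frame with per-particle starting poses for both bodies
#'   (`rot1`..`psi2` or shared `rot`,`tilt`,`psi`), shifts (`shift_x`,
#'   `shift_y`), and optional per-body translations.
#' @param model Initial [two_body_model()] (e.g. segmented from a global
#'   reconstruction, low-pass filtered).
#' @param ctfs Per-particle list of [ctf_params()] (or single object).
#' @param rounds Maximum number of rounds.
#' @param sub_box Sub-particle box size (defaults to the body box).
#' @param pixel_size Pixel size in Angstrom.
#' @param symmetry Length-2 vector of Cn symmetry per body, e.g.
#'   `c("C1", "C6")`.
#' @param angular_range_deg,angular_step_deg,shift_range_px Search
#'   parameters passed to [refine_local()] (second and later rounds use a
#'   halved angular grid).
#' @param resolution Matching resolution for refinement (Angstrom).
#' @param tol Relative resolution change defining convergence.
#' @param wiener Wiener constant for [backproject()].
#' @param verbose Print a per-round log line.
#' @return Object of class `"seg_refine"`: refined `model`, `rounds` log
#'   data frame (round, body, resolution), `poses` (per body), `fsc`
#'   curves, `converged`, `best_round`.
#' @export
iterate_segmentation <- function(particles, meta, model, ctfs = NULL,
                                 rounds = 2, sub_box = NULL, pixel_size = 1,
                                 symmetry = c("C1", "C1"),
                                 angular_range_deg = 15,
                                 angular_step_deg = 5, shift_range_px = 2,
                                 resolution = NULL, tol = 0.02,
                                 wiener = 0.01, verbose = FALSE) {
  stopifnot(inherits(model, "two_body_model"))
  n <- dim(particles)[3]
  box <- dim(particles)[1]
  nb <- dim(model$body1$density)[1]
  if (is.null(sub_box)) sub_box <- nb
  single_ctf <- inherits(ctfs, "ctf_params")
  get_ctf <- function(i) {
    if (is.null(ctfs)) NULL else if (single_ctf) ctfs else ctfs[[i]]
  }
  # starting per-body poses from metadata
  ang_cols <- function(k) {
    if (all(paste0(c("rot", "tilt", "psi"), k) %in% names(meta)))
      paste0(c("rot", "tilt", "psi"), k)
    else c("rot", "tilt", "psi")
  }
  shift_xy <- function(i) {
    c(if ("shift_x" %in% names(meta)) meta$shift_x[i] else 0,
      if ("shift_y" %in% names(meta)) meta$shift_y[i] else 0)
  }
  poses <- lapply(1:2, function(k) {
    cols <- ang_cols(k)
    lapply(seq_len(n), function(i) {
      s <- shift_xy(i)
      pose(meta[[cols[1]]][i], meta[[cols[2]]][i], meta[[cols[3]]][i],
           s[1], s[2])
    })
  })
  log_df <- data.frame(round = integer(0), body = integer(0),
                       resolution = numeric(0))
  fsc_curves <- list()
  if (rounds <= 0) {
    return(structure(list(model = model, rounds = log_df, poses = poses,
                          fsc = fsc_curves, converged = FALSE,
                          best_round = 0, tol = tol),
                     class = "seg_refine"))
  }
  res_hist <- matrix(NA_real_, nrow = rounds, ncol = 2)
  models <- list(model)
  converged <- FALSE
  diverged <- FALSE
  cur <- model
  for (r in seq_len(rounds)) {
    rng <- if (r == 1) angular_range_deg else angular_range_deg / 2
    stp <- if (r == 1) angular_step_deg else max(angular_step_deg / 2, 1)
    for (h in 1:2) {
      k <- 3 - h
      vft_k <- volume_ft(model_body(cur, k))
      subs <- array(0, c(sub_box, sub_box, n))
      sub_poses <- vector("list", n)
      ok <- logical(n)
      for (i in seq_len(n)) {
        po_k <- poses[[k]][[i]]
        ctr_k <- body_center_in_box(po_k, cur, k, box)
        po_render <- pose(po_k$rot, po_k$tilt, po_k$psi,
                          ctr_k[1] - box / 2, ctr_k[2] - box / 2)
        part <- image2d(particles[, , i], pixel_size)
        clean <- subtract_projection(part, model_body(cur, k), po_render,
                                     get_ctf(i), vol_ft = vft_k)
        po_h <- poses[[h]][[i]]
        ctr_h <- body_center_in_box(po_h, cur, h, box)
        rw <- rewindow(clean, ctr_h, sub_box)
        ok[i] <- rw$record$ok
        subs[, , i] <- rw$image$pixels
        sub_poses[[i]] <- pose(po_h$rot, po_h$tilt, po_h$psi,
                               rw$record$residual_shift[1],
                               rw$record$residual_shift[2])
      }
      idx <- which(ok)
      ref <- model_body(cur, h)
      fit <- refine_local(subs[, , idx, drop = FALSE], ref, sub_poses[idx],
                          ctfs = if (is.null(ctfs)) NULL
                                 else if (single_ctf) ctfs else ctfs[idx],
                          angular_range_deg = rng, angular_step_deg = stp,
                          shift_range_px = shift_range_px,
                          resolution = resolution, pixel_size = pixel_size)
      for (j in seq_along(idx)) {
        i <- idx[j]
        newp <- fit$poses[[j]]
        # pose update: angles absolute; translation update = refined shift
        # minus the windowing residual
        dsh <- c(newp$shift_x - sub_poses[[i]]$shift_x,
                 newp$shift_y - sub_poses[[i]]$shift_y)
        po_h <- poses[[h]][[i]]
        poses[[h]][[i]] <- pose(newp$rot, newp$tilt, newp$psi,
                                po_h$shift_x + dsh[1], po_h$shift_y + dsh[2])
        sub_poses[[i]] <- newp
      }
      nf <- parse_symmetry(symmetry[h])
      half <- idx %% 2
      ctf_sub <- function(sel) {
        if (is.null(ctfs)) NULL else if (single_ctf) ctfs else ctfs[sel]
      }
      rec_half <- lapply(0:1, function(hs) {
        sel <- idx[half == hs]
        backproject(subs[, , sel, drop = FALSE], sub_poses[sel],
                    ctf_sub(sel), pixel_size, box = sub_box,
                    symmetry = nf, wiener = wiener)
      })
      msk <- soft_sphere_mask(sub_box)
      fc <- fsc(rec_half[[1]], rec_half[[2]], mask = msk)
      full <- backproject(subs[, , idx, drop = FALSE], sub_poses[idx],
                          ctf_sub(idx), pixel_size, box = sub_box,
                          symmetry = nf, wiener = wiener)
      if (h == 1) cur <- two_body_model(full, cur$body2, cur$anchor1, cur$anchor2)
      else cur <- two_body_model(cur$body1, full, cur$anchor1, cur$anchor2)
      res_hist[r, h] <- fc$resolution
      log_df <- rbind(log_df, data.frame(round = r, body = h,
                                         resolution = fc$resolution))
      fsc_curves[[sprintf("round%d_body%d", r, h)]] <- fc
      if (verbose)
        message(sprintf("round %d body %d: %.2f A (%d sub-particles)",
                        r, h, fc$resolution, length(idx)))
    }
    models[[r + 1]] <- cur
    if (r >= 2) {
      # convergence on the mean resolution of the body pair
      m_now <- mean(res_hist[r, ])
      m_prev <- mean(res_hist[r - 1, ])
      if (abs(m_now - m_prev) / m_prev < tol) {
        converged <- TRUE
        break
      }
      if (r >= 3 &&
          all(res_hist[r, ] > res_hist[r - 1, ]) &&
          all(res_hist[r - 1, ] > res_hist[r - 2, ])) {
        diverged <- TRUE
        break
      }
    }
  }
  done <- which(!is.na(res_hist[, 1]))
  mean_res <- rowMeans(res_hist[done, , drop = FALSE])
  best_round <- done[which.min(mean_res)]
  final <- if (diverged) models[[best_round + 1]] else cur
  structure(list(model = final, rounds = log_df, poses = poses,
                 fsc = fsc_curves, converged = converged,
                 diverged = diverged, best_round = best_round, tol = tol),
            class = "seg_refine")
}

#' @export
print.seg_refine <- function(x, ...) {
  cat("Iterative two-body segmentation\n")
  if (nrow(x$rounds) == 0) {
    cat("  no rounds run (input model returned)\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$rounds)))
    cat(sprintf("  round %d body %d: %.2f A\n", x$rounds$round[i],
                x$rounds$body[i], x$rounds$resolution[i]))
  cat(sprintf("  converged: %s (tolerance %.0f%%), best round %d\n",
              x$converged, 100 * x$tol, x$best_round))
  invisible(x)
}

#' @export
summary.seg_refine <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.seg_refine <- function(x, ...) {
  if (nrow(x$rounds) == 0) return(invisible(x))
  with(x$rounds, {
    plot(round[body == 1], resolution[body == 1], type = "b", pch = 16,
         xlab = "round", ylab = "FSC resolution (A)",
         ylim = range(resolution), ...)
    lines(round[body == 2], resolution[body == 2], type = "b", pch = 1,
          lty = 2)
  })
  legend("topright", legend = c("body 1", "body 2"), pch = c(16, 1),
         lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Conformational statistics of paired body poses
#'
#' For every particle, computes the relative rotation between the two
#' refined body poses ([relative_rotation()]): the total rotation angle,
#' the per-Euler-angle differences, a histogram of the total angle with
#' peak detection, and per-angle sample SDs.
#'
#' @param poses_body1,poses_body2 Lists of [pose()] (same length), or data
#'   frames with `rot`, `tilt`, `psi` columns.
#' @param bin_width Histogram bin width in degrees.
#' @param peak_min_frac Minimum fraction of the maximum count for a local
#'   maximum to count as a peak.
#' @return Object of class `"conformation_stats"`: `angle` (per-particle
#'   total rotation, degrees), `dEuler` (matrix of per-angle differences),
#'   `sd` (per-angle SDs), `hist`, `peaks` (bin centers of detected
#'   peaks).
#' @export
conformation_stats <- function(poses_body1, poses_body2, bin_width = 1,
                               peak_min_frac = 0.1) {
  as_pose_list <- function(x) {
    if (is.data.frame(x))
      lapply(seq_len(nrow(x)), function(i) pose(x$rot[i], x$tilt[i], x$psi[i]))
    else x
  }
  p1 <- as_pose_list(poses_body1)
  p2 <- as_pose_list(poses_body2)
  if (length(p1) != length(p2))
    stop_invalid("pose lists must have equal length")
  n <- length(p1)
  ang <- numeric(n)
  for (i in seq_len(n)) ang[i] <- relative_rotation(p1[[i]], p2[[i]])$angle
  de <- cbind(rot = wrap_angle(vapply(p1, `[[`, 0, "rot") -
                                 vapply(p2, `[[`, 0, "rot")),
              tilt = vapply(p1, `[[`, 0, "tilt") -
                vapply(p2, `[[`, 0, "tilt"),
              psi = wrap_angle(vapply(p1, `[[`, 0, "psi") -
                                 vapply(p2, `[[`, 0, "psi")))
  brks <- seq(0, max(ang, bin_width) + bin_width, by = bin_width)
  h <- hist(ang, breaks = brks, plot = FALSE)
  ct <- h$counts
  peaks <- integer(0)
  if (length(ct) > 0) {
    thr <- peak_min_frac * max(ct)
    for (i in seq_along(ct)) {
      left <- if (i > 1) ct[i - 1] else -Inf
      right <- if (i < length(ct)) ct[i + 1] else -Inf
      if (ct[i] >= thr && ct[i] > left && ct[i] >= right)
        peaks <- c(peaks, i)
    }
  }
  structure(list(angle = ang, dEuler = de,
                 sd = apply(de, 2, sd), hist = h,
                 peaks = h$mids[peaks]),
            class = "conformation_stats")
}

#' @export
print.conformation_stats <- function(x, ...) {
  cat(sprintf(
    "conformational distribution: n = %d, mean relative angle %.2f deg\n",
    length(x$angle), mean(x$angle)))
  cat(sprintf("  per-angle SD (rot, tilt, psi): %.2f, %.2f, %.2f deg\n",
              x$sd[1], x$sd[2], x$sd[3]))
  cat(sprintf("  peaks at: %s deg\n",
              paste(sprintf("%.1f", x$peaks), collapse = ", ")))
  invisible(x)
}

#' @export
plot.conformation_stats <- function(x, ...) {
  plot(x$hist, xlab = "relative rotation (deg)", main = "", ...)
  abline(v = x$peaks, lty = 3)
  invisible(x)
}
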