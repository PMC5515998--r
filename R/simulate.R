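# Synthetic two-body micrograph simulator with ground truth. The phantom
# stands in for an atomic-model pair: an asymmetric blob cluster stacked
# on a C6-symmetrized blob ring, mimicking a small flexible cap on a
# hexameric base. Imaging parameters default to a 300 kV counting-camera
# collection; heterogeneity defaults follow the two-body conformational
# spread the dataset is designed to probe (10 deg / 2 px SD of the
# body-to-body pose difference).

#' Simulation configuration
#'
#' All tunables of the synthetic dataset. Defocus is stored positive for
#' underfocus; astigmatism is defined as `defocus_u - defocus_v`.
#' `sigma_euler_deg` and `sigma_shift_px` parameterize the standard
#' deviation of the per-particle BODY-TO-BODY difference of Euler angles
#' and in-plane coordinates; each body receives an independent Gaussian
#' perturbation with SD `sigma/sqrt(2)` so the difference has SD `sigma`.
#'
#' @param n_micrographs,particles_per_micrograph Dataset cardinality.
#' @param micrograph_size Micrograph side in pixels.
#' @param box Particle box size in pixels.
#' @param pixel_size Pixel size in Angstrom.
#' @param voltage,cs,amplitude_contrast Microscope parameters (kV, mm,
#'   fraction).
#' @param defocus_range Underfocus range in micrometres, `c(min, max)`.
#' @param astigmatism_mean,astigmatism_sd Gaussian astigmatism draw in
#'   Angstrom (per micrograph).
#' @param bfactor_mean,bfactor_sd Gaussian B-factor draw in Angstrom^2,
#'   clipped at 0.
#' @param sigma_euler_deg,sigma_shift_px Conformational heterogeneity.
#' @param snr Target signal-to-noise ratio (signal variance over noise
#'   variance inside particle footprints).
#' @param noise_sigma Optional absolute noise SD overriding `snr`.
#' @param colored_fraction Fraction of noise variance given to the
#'   CTF-coloured component.
#' @param phantom_box Phantom body box in voxels.
#' @param seed RNG seed making the whole dataset reproducible.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_micrographs = 48, particles_per_micrograph = 150,
                       micrograph_size = 4096, box = 256, pixel_size = 1.32,
                       voltage = 300, cs = 2.7, defocus_range = c(1, 3),
                       astigmatism_mean = 100, astigmatism_sd = 50,
                       amplitude_contrast = 0.1,
                       bfactor_mean = 0, bfactor_sd = 50,
                       sigma_euler_deg = 10, sigma_shift_px = 2,
                       snr = 0.1, noise_sigma = NULL,
                       colored_fraction = 0.5,
                       phantom_box = 128, seed = 1) {
  cfg <- list(n_micrographs = n_micrographs,
              particles_per_micrograph = particles_per_micrograph,
              micrograph_size = micrograph_size, box = box,
              pixel_size = pixel_size, voltage = voltage, cs = cs,
              defocus_range = defocus_range,
              astigmatism_mean = astigmatism_mean,
              astigmatism_sd = astigmatism_sd,
              amplitude_contrast = amplitude_contrast,
              bfactor_mean = bfactor_mean, bfactor_sd = bfactor_sd,
              sigma_euler_deg = sigma_euler_deg,
              sigma_shift_px = sigma_shift_px,
              snr = snr, noise_sigma = noise_sigma,
              colored_fraction = colored_fraction,
              phantom_box = phantom_box, seed = seed)
  with(cfg, {
    if (n_micrographs < 0 || particles_per_micrograph < 0)
      stop_invalid("counts must be >= 0")
    if (box >= micrograph_size) stop_invalid("box must be < micrograph_size")
    if (defocus_range[1] >= defocus_range[2])
      stop_invalid("defocus_range must be increasing")
    if (sigma_euler_deg < 0 || sigma_shift_px < 0)
      stop_invalid("heterogeneity sigmas must be >= 0")
  })
  structure(cfg, class = "sim_config")
}

# Z offsets of the two body anchors for a given phantom box.
phantom_anchor_z <- function(box) round(0.18 * box)

blob_field <- function(box, centers, sigmas, amps) {
  k <- freq_coords(box)
  gx <- array(k, c(box, box, box))
  gy <- array(rep(k, each = box), c(box, box, box))
  gz <- array(rep(k, each = box * box), c(box, box, box))
  out <- array(0, c(box, box, box))
  for (i in seq_len(nrow(centers))) {
    d2 <- (gx - centers[i, 1])^2 + (gy - centers[i, 2])^2 +
      (gz - centers[i, 3])^2
    out <- out + amps[i] * exp(-d2 / (2 * sigmas[i]^2))
  }
  out
}

#' Procedural two-body phantom
#'
#' Builds the two rigid-body reference maps as sums of Gaussian
#' pseudo-atoms: body 1 is an asymmetric cluster of blobs, body 2 a ring
#' of blobs with exact C6 symmetry imposed by replicating one asymmetric
#' unit at 60-degree steps. The bodies sit on the Z axis of the composite
#' frame at opposite anchor offsets. Deterministic for a given seed. The
#' blob parameters are attached as attribute `"blobs"` so the analytic
#' model can be re-evaluated (e.g. under an exact rotation).
#'
#' @param box Body box size in voxels (>= 32, even).
#' @param voxel_size Voxel size in Angstrom.
#' @param seed RNG seed.
#' @return A [two_body_model()].
#' @export
make_two_body_phantom <- function(box = 48, voxel_size = 1.32, seed = 1) {
  if (box < 32 || box %% 2 != 0) stop_invalid("box must be even and >= 32")
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(seed)
  # body 1: flattened asymmetric cluster
  n1 <- 14
  c1 <- cbind(runif(n1, -0.20, 0.20) * box,
              runif(n1, -0.20, 0.20) * box,
              runif(n1, -0.10, 0.10) * box)
  s1 <- runif(n1, 1.4, 2.6)
  a1 <- runif(n1, 0.5, 1)
  # body 2: C6 ring built from one asymmetric unit
  nasu <- 3
  r0 <- 0.22 * box
  asu <- cbind(r0 + rnorm(nasu, 0, 1.2), rnorm(nasu, 0, 1.8),
               rnorm(nasu, 0, 1.2))
  sasu <- runif(nasu, 1.6, 2.4)
  aasu <- runif(nasu, 0.6, 1)
  c2 <- NULL
  for (k in 0:5) {
    ang <- deg2rad(60 * k)
    rot <- cbind(asu[, 1] * cos(ang) - asu[, 2] * sin(ang),
                 asu[, 1] * sin(ang) + asu[, 2] * cos(ang),
                 asu[, 3])
    c2 <- rbind(c2, rot)
  }
  s2 <- rep(sasu, 6)
  a2 <- rep(aasu, 6)
  zoff <- phantom_anchor_z(box)
  model <- two_body_model(
    volume3d(blob_field(box, c1, s1, a1), voxel_size),
    volume3d(blob_field(box, c2, s2, a2), voxel_size),
    anchor1 = c(0, 0, zoff), anchor2 = c(0, 0, -zoff))
  attr(model, "blobs") <- list(
    body1 = list(centers = c1, sigmas = s1, amps = a1),
    body2 = list(centers = c2, sigmas = s2, amps = a2))
  model
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' Draw per-particle two-body conformations
#'
#' Draws, for `n` particles, a shared global orientation uniform on SO(3),
#' a uniform in-micrograph position (with a `box/2` edge margin), and
#' independent Gaussian perturbations of each body's three Euler angles
#' (SD `sigma_euler_deg / sqrt(2)`) and in-plane coordinates (SD
#' `sigma_shift_px / sqrt(2)`), so the body-to-body differences have SD
#' `sigma_euler_deg` and `sigma_shift_px`. Angles are stored unwrapped.
#'
#' @param n Number of particles.
#' @param sigma_euler_deg,sigma_shift_px Heterogeneity SDs (of the
#'   difference).
#' @param micrograph_size,box Geometry used for position sampling; when
#'   `micrograph_size` is `NULL` positions are set to 0.
#' @return Data frame with global pose, per-body angles and shifts, and
#'   positions.
#' @export
sample_conformation <- function(n, sigma_euler_deg = 10, sigma_shift_px = 2,
                                micrograph_size = NULL, box = 0) {
  if (sigma_euler_deg < 0 || sigma_shift_px < 0)
    stop_invalid("sigmas must be >= 0")
  se <- sigma_euler_deg / sqrt(2)
  ss <- sigma_shift_px / sqrt(2)
  rot <- runif(n, -180, 180)
  tilt <- rad2deg(acos(runif(n, -1, 1)))
  psi <- runif(n, -180, 180)
  d <- data.frame(
    rot = rot, tilt = tilt, psi = psi,
    rot1 = rot + rnorm(n, 0, se), tilt1 = tilt + rnorm(n, 0, se),
    psi1 = psi + rnorm(n, 0, se),
    rot2 = rot + rnorm(n, 0, se), tilt2 = tilt + rnorm(n, 0, se),
    psi2 = psi + rnorm(n, 0, se),
    dx1 = rnorm(n, 0, ss), dy1 = rnorm(n, 0, ss),
    dx2 = rnorm(n, 0, ss), dy2 = rnorm(n, 0, ss))
  if (!is.null(micrograph_size)) {
    m <- box / 2
    d$coord_x <- runif(n, m, micrograph_size - m)
    d$coord_y <- runif(n, m, micrograph_size - m)
  } else {
    d$coord_x <- d$coord_y <- rep(0, n)
  }
  d
}

# One per-micrograph CTF draw from the configured ranges.
draw_ctf <- function(cfg) {
  df <- runif(1, cfg$defocus_range[1], cfg$defocus_range[2]) * 1e4
  astig <- rnorm(1, cfg$astigmatism_mean, cfg$astigmatism_sd)
  bf <- max(0, rnorm(1, cfg$bfactor_mean, cfg$bfactor_sd))
  ctf_params(defocus_u = df + astig / 2, defocus_v = df - astig / 2,
             astig_angle = runif(1, 0, 180), cs = cfg$cs,
             voltage = cfg$voltage,
             amplitude_contrast = cfg$amplitude_contrast, bfactor = bf)
}

# In-box body pose for rendering: angles from the conformation row, shift
# = window fraction + projected anchor + body translation.
body_render_pose <- function(row, body_id, model, frac = c(0, 0)) {
  ang <- unlist(row[paste0(c("rot", "tilt", "psi"), body_id)])
  dxy <- unlist(row[paste0(c("dx", "dy"), body_id)])
  po <- pose(ang[1], ang[2], ang[3])
  off <- project_anchor(model_anchor(model, body_id), po) + dxy + frac
  po$shift_x <- off[1]
  po$shift_y <- off[2]
  po
}

#' Render one synthetic micrograph
#'
#' Renders every particle as the sum of the two bodies' CTF-modulated
#' Fourier-slice projections at their drawn poses, placed at the drawn
#' positions, then superimposes (a) CTF-independent Gaussian white noise
#' and (b) CTF-coloured noise built by filtering a white field with the
#' micrograph CTF — a spectral surrogate for solvent noise, which shares
#' its second-order statistics. Noise variance is set so that signal
#' variance inside the particle footprints over total noise variance
#' equals `cfg$snr` (unless `cfg$noise_sigma` overrides it).
#'
#' @param model A [two_body_model()].
#' @param conformations Data frame from [sample_conformation()] (with
#'   positions).
#' @param cfg A [sim_config()].
#' @param ctf A [ctf_params()] for the micrograph; drawn from `cfg` if
#'   `NULL`.
#' @return List with `micrograph` ([image2d()]), `truth` (ground-truth
#'   data frame) and `ctf`.
#' @export
render_micrograph <- function(model, conformations, cfg, ctf = NULL) {
  stopifnot(inherits(model, "two_body_model"), inherits(cfg, "sim_config"))
  if (is.null(ctf)) ctf <- draw_ctf(cfg)
  S <- cfg$micrograph_size
  box <- cfg$box
  mic <- matrix(0, S, S)
  n <- nrow(conformations)
  vft <- list(volume_ft(model$body1), volume_ft(model$body2))
  truth <- NULL
  sig_var <- 0
  if (n > 0) {
    for (i in seq_len(n)) {
      row <- conformations[i, ]
      p0 <- round(c(row$coord_x, row$coord_y))
      frac <- c(row$coord_x, row$coord_y) - p0
      patch <- matrix(0, box, box)
      centers <- list()
      for (k in 1:2) {
        po <- body_render_pose(row, k, model, frac)
        pr <- fourier_slice_project(model_body(model, k), po, ctf,
                                    box = box, vol_ft = vft[[k]])
        patch <- patch + pr$pixels
        centers[[k]] <- c(p0[1] + po$shift_x, p0[2] + po$shift_y)
      }
      xs <- p0[1] - box / 2 + seq_len(box)
      ys <- p0[2] - box / 2 + seq_len(box)
      mic[xs, ys] <- mic[xs, ys] + patch
      truth <- rbind(truth, data.frame(
        particle = i, coord_x = row$coord_x, coord_y = row$coord_y,
        rot = row$rot, tilt = row$tilt, psi = row$psi,
        rot1 = row$rot1, tilt1 = row$tilt1, psi1 = row$psi1,
        rot2 = row$rot2, tilt2 = row$tilt2, psi2 = row$psi2,
        dx1 = row$dx1, dy1 = row$dy1, dx2 = row$dx2, dy2 = row$dy2,
        center_x1 = centers[[1]][1], center_y1 = centers[[1]][2],
        center_x2 = centers[[2]][1], center_y2 = centers[[2]][2]))
      sig_var <- sig_var + sum(patch^2)
    }
    sig_var <- sig_var / (n * box * box)
    # overlap flags: another particle center within one box
    dmat <- as.matrix(stats::dist(cbind(truth$coord_x, truth$coord_y)))
    diag(dmat) <- Inf
    truth$overlaps <- apply(dmat, 1, min) < box
  }
  noise_var <- if (!is.null(cfg$noise_sigma)) cfg$noise_sigma^2
               else if (n > 0 && cfg$snr > 0) sig_var / cfg$snr else
                 if (!is.null(cfg$snr) && cfg$snr > 0) 1 else 0
  if (noise_var > 0) {
    sw <- sqrt(noise_var * (1 - cfg$colored_fraction))
    sc <- sqrt(noise_var * cfg$colored_fraction)
    mic <- mic + matrix(rnorm(S * S, 0, sw), S, S)
    if (sc > 0) {
      white <- matrix(rnorm(S * S), S, S)
      col <- Re(ift_centered(ft_centered(white) * ctf_2d(ctf, S, cfg$pixel_size)))
      col <- col / sd(as.numeric(col))
      mic <- mic + sc * col
    }
  }
  if (!is.null(truth)) {
    truth$defocus_u <- ctf$defocus_u
    truth$defocus_v <- ctf$defocus_v
    truth$astig_angle <- ctf$astig_angle
    truth$bfactor <- ctf$bfactor
  }
  list(micrograph = image2d(mic, cfg$pixel_size), truth = truth, ctf = ctf)
}

#' Generate a full synthetic dataset
#'
#' Draws per-micrograph CTFs and per-particle conformations, renders the
#' micrographs, extracts the particle stack, and assembles ground-truth
#' and observed metadata tables. The observed table carries what a
#' consensus (whole-particle) refinement would know: the shared global
#' pose, coordinates and CTF — not the per-body heterogeneity. With
#' `metadata_only = TRUE` no pixels are rendered. Fully reproducible from
#' `cfg$seed`. If `out_dir` is given, micrographs (`mic_###.mrc`), the
#' particle stack (`particles.mrcs`) and both STAR tables are written
#' there.
#'
#' @param cfg A [sim_config()].
#' @param model Optional [two_body_model()]; built from
#'   `cfg$phantom_box`/`cfg$seed` when `NULL`.
#' @param metadata_only Skip pixel rendering.
#' @param out_dir Optional output directory.
#' @return List with `truth`, `observed` (data frames), and unless
#'   `metadata_only`: `micrographs` (list of [image2d()]), `particles`
#'   (b x b x n array), `ctfs`.
#' @export
generate_dataset <- function(cfg, model = NULL, metadata_only = FALSE,
                             out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  anchor_z <- phantom_anchor_z(cfg$phantom_box)
  if (!metadata_only && is.null(model))
    model <- make_two_body_phantom(cfg$phantom_box, cfg$pixel_size, cfg$seed)
  mics <- list()
  ctfs <- list()
  truth_all <- NULL
  stack <- NULL
  for (m in seq_len(cfg$n_micrographs)) {
    ctf <- draw_ctf(cfg)
    conf <- sample_conformation(cfg$particles_per_micrograph,
                                cfg$sigma_euler_deg, cfg$sigma_shift_px,
                                cfg$micrograph_size, cfg$box)
    if (metadata_only) {
      truth <- if (nrow(conf) > 0) {
        po <- lapply(1:2, function(k) {
          t(mapply(function(r, tl, p, dx, dy) {
            e <- euler_to_matrix(c(r, tl, p))
            (e %*% c(0, 0, ifelse(k == 1, anchor_z, -anchor_z)))[1:2] + c(dx, dy)
          }, conf[[paste0("rot", k)]], conf[[paste0("tilt", k)]],
             conf[[paste0("psi", k)]], conf[[paste0("dx", k)]],
             conf[[paste0("dy", k)]]))
        })
        data.frame(particle = seq_len(nrow(conf)), conf,
                   center_x1 = conf$coord_x + po[[1]][, 1],
                   center_y1 = conf$coord_y + po[[1]][, 2],
                   center_x2 = conf$coord_x + po[[2]][, 1],
                   center_y2 = conf$coord_y + po[[2]][, 2],
                   overlaps = FALSE,
                   defocus_u = ctf$defocus_u, defocus_v = ctf$defocus_v,
                   astig_angle = ctf$astig_angle, bfactor = ctf$bfactor)
      } else NULL
      rend <- list(truth = truth, ctf = ctf)
    } else {
      rend <- render_micrograph(model, conf, cfg, ctf)
      mics[[m]] <- rend$micrograph
    }
    ctfs[[m]] <- ctf
    if (!is.null(rend$truth)) {
      rend$truth <- cbind(micrograph = m, rend$truth)
      truth_all <- rbind(truth_all, rend$truth)
    }
  }
  if (!metadata_only && !is.null(truth_all)) {
    stack <- array(0, c(cfg$box, cfg$box, nrow(truth_all)))
    j <- 0
    for (m in seq_len(cfg$n_micrographs)) {
      rows <- which(truth_all$micrograph == m)
      for (i in rows) {
        j <- j + 1
        p0 <- round(c(truth_all$coord_x[i], truth_all$coord_y[i]))
        xs <- p0[1] - cfg$box / 2 + seq_len(cfg$box)
        ys <- p0[2] - cfg$box / 2 + seq_len(cfg$box)
        stack[, , j] <- mics[[m]]$pixels[xs, ys]
      }
    }
  }
  observed <- if (!is.null(truth_all)) {
    data.frame(micrograph = truth_all$micrograph,
               particle = truth_all$particle,
               coord_x = truth_all$coord_x, coord_y = truth_all$coord_y,
               rot = truth_all$rot, tilt = truth_all$tilt,
               psi = truth_all$psi,
               shift_x = truth_all$coord_x - round(truth_all$coord_x),
               shift_y = truth_all$coord_y - round(truth_all$coord_y),
               defocus_u = truth_all$defocus_u,
               defocus_v = truth_all$defocus_v,
               astig_angle = truth_all$astig_angle,
               voltage = cfg$voltage, cs = cfg$cs,
               amplitude_contrast = cfg$amplitude_contrast,
               bfactor = truth_all$bfactor)
  } else NULL
  out <- list(truth = truth_all, observed = observed, ctfs = ctfs,
              micrographs = if (metadata_only) NULL else mics,
              particles = stack, model = model, cfg = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(truth_all))
      write_star(truth_all, file.path(out_dir, "ground_truth.star"),
                 block = "particles")
    if (!is.null(observed))
      write_star(observed, file.path(out_dir, "observed.star"),
                 block = "particles")
    if (!metadata_only) {
      for (m in seq_along(mics))
        write_mrc(mics[[m]], file.path(out_dir, sprintf("mic_%03d.mrc", m)))
      if (!is.null(stack))
        write_mrc(stack, file.path(out_dir, "particles.mrcs"),
                  pixel_size = cfg$pixel_size)
    }
  }
  out
}
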