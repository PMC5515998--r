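# Synthetic dataset generator: phantom symmetry, conformational draws,
# rendering, dataset assembly and reproducibility.

test_that("the phantom has exact C6 symmetry in body 2 and none in body 1", {
  model <- make_two_body_phantom(48, 1.32, seed = 2)
  blobs <- attr(model, "blobs")
  rot60 <- function(centers) {
    a <- pi / 3
    cbind(centers[, 1] * cos(a) - centers[, 2] * sin(a),
          centers[, 1] * sin(a) + centers[, 2] * cos(a),
          centers[, 3])
  }
  # analytic rotation: the C6 blob set maps onto itself
  b2rot <- eval_blobs(48, rot60(blobs$body2$centers), blobs$body2$sigmas,
                      blobs$body2$amps)
  expect_lt(rel_l2(b2rot, model$body2$density), 1e-6)
  # the asymmetric body does not
  b1rot <- eval_blobs(48, rot60(blobs$body1$centers), blobs$body1$sigmas,
                      blobs$body1$amps)
  expect_gt(rel_l2(b1rot, model$body1$density), 0.1)
  # determinism and anchors
  model2 <- make_two_body_phantom(48, 1.32, seed = 2)
  expect_identical(model$body1$density, model2$body1$density)
  expect_identical(model$body2$density, model2$body2$density)
  expect_equal(model$anchor1, -model$anchor2)
  expect_gt(model$anchor1[3], 0)
  expect_error(make_two_body_phantom(20), ">= 32")
})

test_that("conformation draws have the configured heterogeneity", {
  set.seed(1)
  d0 <- sample_conformation(50, 0, 0)
  expect_equal(d0$rot1, d0$rot2)
  expect_equal(d0$rot1, d0$rot)
  expect_equal(d0$dx1, rep(0, 50))
  set.seed(1)
  d <- sample_conformation(10000, 10, 2)
  # per-angle SD of the body-to-body difference
  for (a in c("rot", "tilt", "psi")) {
    dd <- d[[paste0(a, 1)]] - d[[paste0(a, 2)]]
    expect_lt(abs(sd(dd) - 10), 0.3)
  }
  for (a in c("x", "y")) {
    dd <- d[[paste0("d", a, 1)]] - d[[paste0("d", a, 2)]]
    expect_lt(abs(sd(dd) - 2), 0.06)
  }
  # uniform orientation: tilt density follows sin(theta)
  expect_lt(abs(mean(cos(d$tilt * pi / 180))), 0.03)
  # positions honour the margin
  set.seed(2)
  dp <- sample_conformation(500, 10, 2, micrograph_size = 512, box = 64)
  expect_true(all(dp$coord_x >= 32 & dp$coord_x <= 480))
})

test_that("rendering places noiseless particles exactly and draws CTFs
           from the configured ranges", {
  cfg <- sim_config(n_micrographs = 1, particles_per_micrograph = 1,
                    micrograph_size = 192, box = 64, pixel_size = 1.32,
                    phantom_box = 48, noise_sigma = 0, seed = 5)
  model <- make_two_body_phantom(48, 1.32, seed = 5)
  set.seed(5)
  conf <- sample_conformation(1, cfg$sigma_euler_deg, cfg$sigma_shift_px,
                              192, 64)
  ctf <- cryoseg:::draw_ctf(cfg)
  rend <- render_micrograph(model, conf, cfg, ctf)
  # re-render the two projections independently
  p0 <- round(c(conf$coord_x, conf$coord_y))
  frac <- c(conf$coord_x, conf$coord_y) - p0
  expected <- matrix(0, 64, 64)
  for (k in 1:2) {
    po <- cryoseg:::body_render_pose(conf[1, ], k, model, frac)
    expected <- expected +
      fourier_slice_project(cryoseg:::model_body(model, k), po, ctf,
                            64)$pixels
  }
  xs <- p0[1] - 32 + 1:64
  ys <- p0[2] - 32 + 1:64
  expect_equal(rend$micrograph$pixels[xs, ys], expected, tolerance = 1e-12)
  # truth records carry the drawn CTF
  expect_equal(rend$truth$defocus_u, ctf$defocus_u)
  # CTF draws across many micrographs stay in the configured ranges
  cfg2 <- sim_config(n_micrographs = 200, particles_per_micrograph = 1,
                     micrograph_size = 512, box = 64, seed = 7)
  ds <- generate_dataset(cfg2, metadata_only = TRUE)
  df <- (ds$truth$defocus_u + ds$truth$defocus_v) / 2
  expect_true(all(df >= 1e4 & df <= 3e4))
  astig <- ds$truth$defocus_u - ds$truth$defocus_v
  expect_lt(abs(mean(astig) - 100), 15)
  expect_lt(abs(sd(astig) - 50), 15)
  expect_true(all(ds$truth$bfactor >= 0))
})

test_that("noise terms have the configured variance and spectrum", {
  cfg <- sim_config(n_micrographs = 1, particles_per_micrograph = 0,
                    micrograph_size = 256, box = 64, pixel_size = 1.32,
                    noise_sigma = 1.5, colored_fraction = 0, seed = 6)
  model <- make_two_body_phantom(48, 1.32, seed = 6)
  set.seed(6)
  rend <- render_micrograph(model, sample_conformation(0, 10, 2, 256, 64),
                            cfg)
  expect_lt(abs(stats::var(as.numeric(rend$micrograph$pixels)) / 1.5^2 - 1),
            0.02)
  # fully coloured noise: radial power profile proportional to CTF^2
  cfgc <- sim_config(n_micrographs = 1, particles_per_micrograph = 0,
                     micrograph_size = 256, box = 64, pixel_size = 1.32,
                     noise_sigma = 1, colored_fraction = 1, seed = 8)
  set.seed(8)
  ctf <- cryoseg:::draw_ctf(cfgc)
  rend_c <- render_micrograph(model, sample_conformation(0, 10, 2, 256, 64),
                              cfgc, ctf)
  spec <- Mod(ft_centered_t(rend_c$micrograph$pixels))^2
  rad <- cryoseg:::freq_radius(c(256, 256))
  prof <- cryoseg:::shell_mean(spec, rad, 120)
  cprof <- cryoseg:::shell_mean(ctf_2d(ctf, 256, 1.32)^2, rad, 120)
  keep <- 10:120
  expect_gt(stats::cor(prof[keep], cprof[keep]), 0.95)
})

test_that("generate_dataset is reproducible and has the right cardinality", {
  cfg <- sim_config(n_micrographs = 3, particles_per_micrograph = 7,
                    micrograph_size = 256, box = 64, seed = 11)
  ds <- generate_dataset(cfg, metadata_only = TRUE)
  expect_equal(nrow(ds$truth), 21)
  expect_equal(nrow(ds$observed), 21)
  expect_equal(unique(ds$truth$micrograph), 1:3)
  # empty micrograph case
  cfg0 <- sim_config(n_micrographs = 1, particles_per_micrograph = 0,
                     micrograph_size = 256, box = 64, seed = 11)
  ds0 <- generate_dataset(cfg0, metadata_only = TRUE)
  expect_null(ds0$truth)
  # byte-for-byte STAR determinism
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  generate_dataset(cfg, metadata_only = TRUE, out_dir = d1)
  generate_dataset(cfg, metadata_only = TRUE, out_dir = d2)
  expect_identical(readLines(file.path(d1, "ground_truth.star")),
                   readLines(file.path(d2, "ground_truth.star")))
  # rendered mode writes micrographs and a stack that match the records
  cfgr <- sim_config(n_micrographs = 1, particles_per_micrograph = 3,
                     micrograph_size = 192, box = 48, phantom_box = 32,
                     snr = 0.5, seed = 12)
  dr <- file.path(tempdir(), "sim_r")
  dsr <- generate_dataset(cfgr, out_dir = dr)
  expect_equal(dim(dsr$particles), c(48, 48, 3))
  expect_true(file.exists(file.path(dr, "mic_001.mrc")))
  stk <- read_mrc(file.path(dr, "particles.mrcs"))
  expect_equal(dim(stk), c(48, 48, 3))
  expect_equal(as.numeric(stk), as.numeric(dsr$particles), tolerance = 1e-6)
})

test_that("ground-truth poses let subtraction strip a body from noiseless
           renders", {
  cfg <- sim_config(n_micrographs = 5, particles_per_micrograph = 1,
                    micrograph_size = 192, box = 64, phantom_box = 48,
                    noise_sigma = 0, seed = 13)
  ds <- generate_dataset(cfg)
  model <- ds$model
  for (i in seq_len(5)) {
    tr <- ds$truth[i, ]
    ctf <- ctf_for_row(ds$observed[i, ])
    part <- image2d(ds$particles[, , i], cfg$pixel_size)
    frac <- c(tr$coord_x, tr$coord_y) - round(c(tr$coord_x, tr$coord_y))
    po1 <- pose(tr$rot1, tr$tilt1, tr$psi1,
                tr$center_x1 - round(tr$coord_x),
                tr$center_y1 - round(tr$coord_y))
    res <- subtract_projection(part, model$body1, po1, ctf)
    p2pow <- sum(ds$particles[, , i]^2) - sum(res$pixels^2)
    # at least 98% of body-1 power removed: residual equals body 2 alone
    po2 <- pose(tr$rot2, tr$tilt2, tr$psi2,
                tr$center_x2 - round(tr$coord_x),
                tr$center_y2 - round(tr$coord_y))
    p2 <- fourier_slice_project(model$body2, po2, ctf, 64)
    expect_lt(rel_l2(res$pixels, p2$pixels), 0.02)
  }
})
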