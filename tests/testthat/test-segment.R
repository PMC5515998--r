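# Signal subtraction, re-windowing, center prediction, micrograph-level
# subtraction and the residual spectrum.

seg_model <- function() make_two_body_phantom(48, 1.32, seed = 2)
seg_ctf <- function() ctf_params(defocus_u = 20000, defocus_v = 18000,
                                 astig_angle = 30, bfactor = 30)

test_that("subtracting the known projection removes the body's signal", {
  model <- seg_model()
  ctf <- seg_ctf()
  box <- 64
  po1 <- pose(20, 50, -40)
  po2 <- pose(25, 46, -35)
  p1 <- render_body(model, 1, po1, ctf, box)
  p2 <- render_body(model, 2, po2, ctf, box)
  # exact-knowledge limit: particle contains body 1 only
  off1 <- project_anchor(model$anchor1, po1)
  ren1 <- pose(po1$rot, po1$tilt, po1$psi, off1[1], off1[2])
  res <- subtract_projection(p1, model$body1, ren1, ctf)
  expect_lt(sqrt(sum(res$pixels^2) / sum(p1$pixels^2)), 0.02)
  # linearity: subtracting body 1 from the two-body image leaves body 2
  part <- image2d(p1$pixels + p2$pixels, 1.32)
  res2 <- subtract_projection(part, model$body1, ren1, ctf)
  expect_lt(rel_l2(res2$pixels, p2$pixels), 1e-10)
  # least-squares scale recovers a global gray-scale factor
  part_scaled <- image2d(1.7 * p1$pixels, 1.32)
  res3 <- subtract_projection(part_scaled, model$body1, ren1, ctf,
                              scale = "lsq")
  expect_lt(sqrt(sum(res3$pixels^2) / sum(part_scaled$pixels^2)), 0.02)
  expect_error(subtract_projection(image2d(p1$pixels, 2.0), model$body1,
                                   ren1, ctf), "mismatch")
})

test_that("subtraction residual is confined above the reference cutoff and
           shrinks as the reference improves", {
  model <- seg_model()
  ctf <- seg_ctf()
  box <- 64
  po <- pose(75, 64, 12)
  truth <- render_body(model, 1, po, ctf, box)
  off <- project_anchor(model$anchor1, po)
  ren <- pose(po$rot, po$tilt, po$psi, off[1], off[2])
  zero <- image2d(matrix(0, box, box), 1.32)
  total_power <- c()
  for (rk in c(20, 12, 8)) {
    ref <- lowpass(model$body1, rk)
    res <- subtract_projection(truth, ref, ren, ctf)
    sp <- residual_spectrum(res, zero, ref_resolution = rk)
    expect_lt(sp$below_fraction, 0.05)
    total_power <- c(total_power, sum(res$pixels^2))
  }
  # a sharper reference leaves strictly less residual
  expect_true(all(diff(total_power) < 0))
  # identical inputs give a zero spectrum; white-noise difference is flat
  sp0 <- residual_spectrum(truth, truth)
  expect_equal(max(sp0$power), 0)
  set.seed(12)
  wn <- image2d(matrix(rnorm(128 * 128), 128, 128), 1)
  spw <- residual_spectrum(wn, image2d(matrix(0, 128, 128), 1))
  mid <- spw$power[5:60]
  expect_lt(sd(mid) / mean(mid), 0.35)
  expect_error(residual_spectrum(truth, wn), "grid")
})

test_that("rewindow crops at the rounded center and records the remainder", {
  set.seed(13)
  parent <- image2d(matrix(rnorm(200 * 200), 200, 200), 1.32)
  # identity crop at the exact center
  rw <- rewindow(parent, c(100, 100), 200)
  expect_equal(rw$image$pixels, parent$pixels - mean(parent$pixels))
  expect_equal(rw$record$residual_shift, c(0, 0))
  # rounding contract
  rw2 <- rewindow(parent, c(100.4, 50.0), 64)
  expect_equal(rw2$record$window_origin, c(68, 18))
  expect_equal(rw2$record$residual_shift, c(0.4, 0.0))
  expect_equal(abs(mean(rw2$image$pixels)), 0, tolerance = 1e-12)
  # edge crossing flags, does not throw
  rw3 <- rewindow(parent, c(10, 100), 64)
  expect_false(rw3$record$ok)
  expect_equal(max(abs(rw3$image$pixels)), 0)
  expect_error(rewindow(parent, c(100, 100), 63), "even")
})

test_that("re-windowing with the recorded residual shift centers the body", {
  model <- seg_model()
  box <- 96
  po <- pose(140, 75, -30)
  # body rendered off-center in a large parent frame
  offset <- c(7.37, -4.61)
  ren <- pose(po$rot, po$tilt, po$psi, offset[1], offset[2])
  parent <- fourier_slice_project(model$body1, ren, NULL, box)
  rw <- rewindow(parent, c(48, 48) + offset, 48)
  expect_true(rw$record$ok)
  # reference: body projected at the residual sub-pixel shift
  ref <- fourier_slice_project(model$body1,
                               pose(po$rot, po$tilt, po$psi,
                                    rw$record$residual_shift[1],
                                    rw$record$residual_shift[2]),
                               NULL, 48)
  peak <- cc_peak(rw$image$pixels, ref$pixels - mean(ref$pixels))
  expect_lt(max(abs(peak)), 0.1)
})

test_that("predict_center matches the explicit matrix product and the
           rendered body position", {
  model <- seg_model()
  po <- pose(33, 61, -50, shift_x = 0.75, shift_y = -1.2)
  # anchor at the composite center: the particle's own center
  m0 <- two_body_model(model$body1, model$body2, c(0, 0, 0), c(0, 0, 0))
  expect_equal(predict_center(po, m0, 1, particle_xy = c(32, 32)),
               c(32 + 0.75, 32 - 1.2))
  # brute force: rotate, drop z, add shifts
  e <- euler_to_matrix(po)
  v <- e %*% model$anchor2
  expect_equal(predict_center(po, model, 2, particle_xy = c(10, 20)),
               c(10 + v[1] + 0.75, 20 + v[2] - 1.2), tolerance = 1e-12)
  # rendered bodies sit where Eq-style center prediction says: locate
  # each body in a noiseless particle by cross-correlation
  ctf <- NULL
  box <- 72
  set.seed(14)
  errs <- c()
  for (i in 1:12) {
    po1 <- pose(runif(1, -180, 180), 180 / pi * acos(runif(1, -1, 1)),
                runif(1, -180, 180),
                shift_x = runif(1, -1.5, 1.5), shift_y = runif(1, -1.5, 1.5))
    off <- project_anchor(model$anchor1, po1)
    ren <- pose(po1$rot, po1$tilt, po1$psi, off[1], off[2])
    img <- fourier_slice_project(model$body1, ren, ctf, box)
    ref <- fourier_slice_project(model$body1,
                                 pose(po1$rot, po1$tilt, po1$psi), ctf, box)
    peak <- cc_peak(img$pixels, ref$pixels)
    predicted <- predict_center(po1, model, 1, particle_xy = c(0, 0))
    errs <- c(errs, sum((peak - predicted)^2))
  }
  expect_lt(sqrt(mean(errs)), 0.5)
})

test_that("micrograph-level subtraction matches particle-level subtraction
           and leaves untouched micrographs alone", {
  model <- seg_model()
  ctf <- seg_ctf()
  box <- 64
  S <- 256
  mic <- matrix(0, S, S)
  coord <- c(130.4, 120.7)
  p0 <- round(coord)
  frac <- coord - p0
  po1 <- pose(20, 50, -40)
  po2 <- pose(25, 46, -35)
  pm1 <- render_body(model, 1, po1, ctf, box, extra_shift = frac)
  pm2 <- render_body(model, 2, po2, ctf, box, extra_shift = frac)
  xs <- p0[1] - box / 2 + seq_len(box)
  ys <- p0[2] - box / 2 + seq_len(box)
  mic[xs, ys] <- pm1$pixels + pm2$pixels
  micim <- image2d(mic, 1.32)
  # zero records: bit-exact identity
  un <- subtract_from_micrograph(micim, NULL, model$body1, ctf)
  expect_identical(un$micrograph$pixels, micim$pixels)
  expect_equal(un$n_subtracted, 0L)
  recs <- data.frame(coord_x = coord[1], coord_y = coord[2],
                     rot = po1$rot, tilt = po1$tilt, psi = po1$psi,
                     shift_x = 0, shift_y = 0)
  res <- subtract_from_micrograph(micim, recs, model$body1, ctf,
                                  anchor = model$anchor1, box = box)
  expect_equal(res$n_subtracted, 1)
  expect_length(res$flagged, 0)
  # footprint power drops to the remaining body's share
  expect_lt(sum(res$micrograph$pixels[xs, ys]^2) / sum(mic[xs, ys]^2), 0.05 +
              sum(pm2$pixels^2) / sum(mic[xs, ys]^2))
  # equivalence with subtract_projection + rewindow away from edges
  part <- rewindow(micim, coord, box)$image
  off1 <- project_anchor(model$anchor1, po1) + frac
  sub_p <- subtract_projection(part, model$body1,
                               pose(po1$rot, po1$tilt, po1$psi,
                                    off1[1], off1[2]), ctf)
  rw_m <- rewindow(res$micrograph, coord, box)$image$pixels
  sp <- sub_p$pixels - mean(sub_p$pixels)
  inner <- 9:(box - 8)
  expect_lt(rel_l2(rw_m[inner, inner], sp[inner, inner]), 1e-3)
  # patch at the edge: in-bounds part subtracted, record flagged
  recs_edge <- recs
  recs_edge$coord_x <- 20
  res_e <- subtract_from_micrograph(micim, recs_edge, model$body1, ctf,
                                    anchor = model$anchor1, box = box)
  expect_equal(res_e$flagged, 1L)
})

test_that("subtraction leaves the noise statistics unchanged", {
  model <- seg_model()
  ctf <- seg_ctf()
  box <- 48
  po <- pose(20, 50, -40)
  off <- project_anchor(model$anchor1, po)
  ren <- pose(po$rot, po$tilt, po$psi, off[1], off[2])
  vft <- cryoseg:::volume_ft(model$body1)
  clean <- fourier_slice_project(model$body1, ren, ctf, box, vol_ft = vft)
  sigma <- 0.5
  set.seed(15)
  ratios <- replicate(100, {
    noisy <- image2d(clean$pixels + matrix(rnorm(box^2, 0, sigma), box, box),
                     1.32)
    res <- subtract_projection(noisy, model$body1, ren, ctf, vol_ft = vft)
    stats::var(as.numeric(res$pixels)) / sigma^2
  })
  expect_lt(abs(mean(ratios) - 1), 0.01)
})
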