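# A rasterized bright bar: the shared fixture for ridge-response checks.
bar_image <- function(width_um = 30, pitch = 5, nr = 101, nc = 101,
                      horizontal = TRUE) {
  px <- matrix(0, nr, nc)
  half <- width_um / pitch / 2
  mid <- (nr + 1) / 2
  rows <- which(abs(seq_len(nr) - mid) < half)
  if (horizontal) px[rows, ] <- 1 else px <- t(`[<-`(t(px), rows, , 1))
  angiogram(px, pitch, pitch, "SCP")
}

test_that("constant images give zero response from every filter", {
  img <- flat_img(0.4)
  expect_identical(max(hessian_vesselness(img)$pixels), 0)
  big <- flat_img(0.4, 200, 200) # the default Gabor support needs 177 px
  expect_identical(max(gabor_enhance(big)$pixels), 0)
  expect_error(gabor_enhance(img), "smaller than the filter support")
  brt <- bayesian_residual_enhance(img, brt_params(noise_sd_estimate = 0.05))
  expect_equal(brt$pixels, img$pixels, tolerance = 1e-12)
})

test_that("Hessian vesselness peaks on the centerline of a 30-um bar", {
  img <- bar_image(width_um = 30, pitch = 5)
  v <- hessian_vesselness(img)$pixels
  center <- 51L
  far <- center + 3L * 6L # three bar-widths away (bar is 6 px at 5 um/px)
  expect_gt(mean(v[center, 20:80]), mean(v[far, 20:80]) + 0.2)
  # argmax along a column transect is the centerline row
  expect_equal(which.max(v[, 50]), center)
  expect_true(all(v >= 0 & v <= 1))
})

test_that("Hessian response is equivariant under 90-degree rotation", {
  set.seed(2)
  noise <- matrix(runif(101 * 101), 101, 101)
  base <- angiogram((noise - min(noise)) / diff(range(noise)), 5, 5, "SCP")
  sm <- bayesian_residual_enhance(base, brt_params(noise_sd_estimate = 0.2))
  rot <- angiogram(rot90(sm$pixels), 5, 5, "SCP")
  vA <- hessian_vesselness(sm)$pixels
  vB <- hessian_vesselness(rot)$pixels
  expect_lt(max(abs(rot90(vA) - vB)), 1e-8)
})

test_that("Hessian ignores dark ridges and rejects bad scale ranges", {
  img <- bar_image(width_um = 30, pitch = 5)
  dark <- angiogram(1 - img$pixels, 5, 5, "SCP")
  vd <- hessian_vesselness(dark)$pixels
  expect_equal(max(vd[49:53, 20:80]), 0) # inverted bar is a dark ridge
  expect_error(hessian_params(size_range_um = c(44, 15)))
})

test_that("the Gabor argmax orientation tracks the bar orientation", {
  p <- gabor_params(wavelength_px = 20)
  himg <- bar_image(width_um = 30, pitch = 5, horizontal = TRUE)
  vimg <- bar_image(width_um = 30, pitch = 5, horizontal = FALSE)
  gh <- gabor_enhance(himg, p, return_orientation = TRUE)
  gv <- gabor_enhance(vimg, p, return_orientation = TRUE)
  # orientation index 1 is theta = 0 (horizontal); index 9 is pi/2
  expect_equal(attr(gh$pixels, "orientation")[51, 51], 1L)
  expect_equal(attr(gv$pixels, "orientation")[51, 51], 9L)
  expect_true(all(gh$pixels >= 0 & gh$pixels <= 1))
})

test_that("Gabor responses commute with 180-degree rotation", {
  sc <- generate_retina_scene(spec_crop(seed = 4))
  p <- gabor_params(wavelength_px = 20)
  g1 <- gabor_enhance(sc$img, p)$pixels
  rot <- set_pixels_for_test(sc$img, rot180(sc$img$pixels))
  g2 <- gabor_enhance(rot, p)$pixels
  expect_lt(max(abs(rot180(g1) - g2)), 1e-8)
})

test_that("Gabor parameter validation enforces the orientation span", {
  expect_error(gabor_params(wavelength_px = 1.5))
  expect_error(gabor_params(n_orientations = 12L)) # 12 * pi/16 != pi
  ok <- gabor_params(n_orientations = 8L, orientation_interval_rad = pi / 8)
  expect_equal(ok$n_orientations, 8L)
})

test_that("Bayesian residual shrinkage denoises without touching structure", {
  set.seed(9)
  noise <- matrix(pmin(pmax(stats::rnorm(128 * 128, 0.5, 0.1), 0), 1), 128, 128)
  img <- angiogram(noise, 18.75, 9000 / 534, "SCP")
  # identity in the zero-noise limit
  ident <- bayesian_residual_enhance(img, brt_params(noise_sd_estimate = 0))
  expect_lt(max(abs(ident$pixels - img$pixels)), 1e-12)
  # variance reduction on a pure-noise image
  den <- bayesian_residual_enhance(img, brt_params(noise_sd_estimate = 0.1))
  expect_lt(stats::var(as.vector(den$pixels)),
            stats::var(as.vector(img$pixels)))
  # SNR on a noisy bar never degrades (contrast / background SD)
  bar <- bar_image(width_um = 60, pitch = 5)
  set.seed(10)
  noisy <- clip_for_test(bar$pixels * 0.6 + 0.2 +
                           matrix(stats::rnorm(101 * 101, 0, 0.08), 101))
  nimg <- angiogram(noisy, 5, 5, "SCP")
  snr <- function(px) {
    fg <- mean(px[49:53, ]); bgv <- px[c(1:30, 72:101), ]
    (fg - mean(bgv)) / stats::sd(bgv)
  }
  out <- bayesian_residual_enhance(nimg, brt_params())
  expect_gte(snr(out$pixels), snr(nimg$pixels))
  expect_error(brt_params(n_levels = 1L))
})

test_that("filters preserve image metadata and never emit NaN", {
  sc <- generate_retina_scene(spec_crop(seed = 6))
  img <- sc$img
  img$subject_id <- "S001"; img$visit <- 2L; img$eye <- "OS"
  for (f in c("hessian", "gabor", "bayesian")) {
    out <- apply_filter(img, f)
    expect_identical(out[c("pitch_x_um", "pitch_y_um", "slab", "subject_id",
                           "visit", "eye")],
                     img[c("pitch_x_um", "pitch_y_um", "slab", "subject_id",
                           "visit", "eye")])
    expect_false(anyNA(out$pixels))
    expect_true(all(is.finite(out$pixels)))
    expect_true(min(out$pixels) >= 0 && max(out$pixels) <= 1)
  }
})

test_that("filters are shift-equivariant away from boundaries", {
  sc <- generate_retina_scene(spec_crop(seed = 8, width_px = 220L,
                                        height_px = 150L))
  px <- sc$img$pixels
  shift <- 7L
  a <- angiogram(px[, 1:200], sc$img$pitch_x_um, sc$img$pitch_y_um, "SCP")
  b <- angiogram(px[, (1 + shift):(200 + shift)], sc$img$pitch_x_um,
                 sc$img$pitch_y_um, "SCP")
  va <- hessian_vesselness(a)$pixels
  vb <- hessian_vesselness(b)$pixels
  interior_a <- va[40:110, (60 + shift):(140 + shift)]
  interior_b <- vb[40:110, 60:140]
  expect_lt(max(abs(interior_a - interior_b)), 1e-8)
})
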