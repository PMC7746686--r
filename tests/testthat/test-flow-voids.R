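test_that("prepare_cc composes exclusions into the analysable region", {
  img <- flat_img(0.5, 100, 100, slab = "CC")
  expect_true(all(prepare_cc(img)$analysable))
  lv <- matrix(FALSE, 100, 100); lv[1:5, ] <- TRUE     # 5%
  disc <- matrix(FALSE, 100, 100); disc[6:10, ] <- TRUE # disjoint 5%
  prep <- prepare_cc(img, lv, disc)
  expect_equal(mean(prep$analysable), 0.90)
  expect_identical(prep$img$pixels, img$pixels)
  expect_error(prepare_cc(img, disc = matrix(TRUE, 100, 100)), "empty")
})

test_that("a constant image yields zero flow voids", {
  img <- flat_img(0.37, 120, 120, slab = "CC")
  fv <- suppressMessages(detect_flow_voids(img))
  expect_identical(fv$metrics$count, 0L)
  expect_identical(fv$metrics$area_percent, 0)
  expect_identical(fv$metrics$mean_size_um2, 0)
})

test_that("no detected void pixel falls inside an exclusion mask", {
  cc <- generate_cc_scene(spec_crop(seed = 21))
  lv <- matrix(FALSE, 134, 200); lv[, 90:110] <- TRUE
  disc <- disc_mask(c(134L, 200L), c(60, 30), 15)
  prep <- prepare_cc(cc$img, lv, disc)
  fv <- detect_flow_voids(prep$img, prep$analysable)
  expect_false(any(fv$void_mask & (lv | disc)))
})

test_that("mean void size times count equals the total void area exactly", {
  cc <- generate_cc_scene(spec_small(seed = 22))
  part <- make_partition(dim(cc$img$pixels), cc$img$pitch_x_um,
                         cc$img$pitch_y_um)
  fv <- detect_flow_voids(cc$img, partition = part)
  px_um2 <- cc$img$pitch_x_um * cc$img$pitch_y_um
  m <- fv$metrics
  whole <- m[m$region == "whole", ]
  expect_equal(whole$mean_size_um2 * whole$count, sum(fv$void_mask) * px_um2)
  # region-assigned component areas add up to the whole
  reg <- m[m$region != "whole", ]
  expect_equal(sum(reg$mean_size_um2 * reg$count),
               whole$mean_size_um2 * whole$count)
  expect_equal(sum(reg$count), whole$count)
})

test_that("the void pixel set is non-increasing in the threshold multiplier", {
  for (seed in c(31, 32, 33)) {
    cc <- generate_cc_scene(spec_crop(seed = seed))
    f1 <- detect_flow_voids(cc$img, p = flow_void_params(k_sd = 1))
    f125 <- detect_flow_voids(cc$img, p = flow_void_params(k_sd = 1.25))
    expect_true(all(f1$void_mask[f125$void_mask])) # subset
    expect_lte(f125$metrics$area_percent, f1$metrics$area_percent)
  }
})

test_that("connectivity and minimum component size act as configured", {
  img_px <- matrix(0.9, 30, 30)
  img_px[10, 10] <- 0; img_px[11, 11] <- 0 # two diagonal void pixels
  img_px[20:22, 20:22] <- 0                # one 9-px void
  img <- angiogram(img_px, 18.75, 9000 / 534, "CC")
  f8 <- detect_flow_voids(img, p = flow_void_params(connectivity = 8L))
  f4 <- detect_flow_voids(img, p = flow_void_params(connectivity = 4L))
  expect_equal(f8$metrics$count, 2L) # diagonal pair merges under 8-conn
  expect_equal(f4$metrics$count, 3L)
  fmin <- detect_flow_voids(img, p = flow_void_params(min_component_px = 5L))
  expect_equal(fmin$metrics$count, 1L) # only the 9-px void survives
  expect_equal(sum(fmin$void_mask), 9L)
})

test_that("void recovery reports Dice and count agreement", {
  truth <- matrix(FALSE, 50, 50); truth[10:20, 10:20] <- TRUE
  expect_equal(flow_void_recovery(truth, truth)$dice, 1)
  expect_equal(flow_void_recovery(truth, matrix(FALSE, 50, 50))$dice, 0)
  cc <- generate_cc_scene(spec_small(seed = 23),
                          cc_scene_params(void_fraction_target = 0.15,
                                          speckle_sigma = 0.02))
  fv <- detect_flow_voids(cc$img, p = flow_void_params(k_sd = 1))
  rec <- flow_void_recovery(cc$truth$void_mask, fv$void_mask)
  expect_gte(rec$dice, 0.6)
})
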