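test_that("an empty scene is a uniform background with zero perfusion", {
  sc <- generate_retina_scene(
    spec_crop(seed = 7),
    retina_scene_params(large_vessel_count = 0L, capillary_density_target = 0,
                        vignetting_strength = 0, speckle_sigma = 0))
  expect_equal(length(unique(as.vector(sc$img$pixels))), 1L)
  expect_identical(sc$truth$true_pd_percent, 0)
  expect_false(any(sc$truth$union_mask))
})

test_that("scene generation is deterministic and leaves the caller's RNG alone", {
  set.seed(123); before <- runif(1)
  set.seed(123)
  a <- generate_retina_scene(spec_crop(seed = 7))
  mid <- runif(1)
  b <- generate_retina_scene(spec_crop(seed = 7))
  expect_identical(a$img$pixels, b$img$pixels)
  expect_identical(a$truth, b$truth)
  expect_identical(before, mid) # generator must not consume the global stream
  cc1 <- generate_cc_scene(spec_crop(seed = 9))
  cc2 <- generate_cc_scene(spec_crop(seed = 9))
  expect_identical(cc1$img$pixels, cc2$img$pixels)
  expect_false(identical(cc1$img$pixels,
                         generate_cc_scene(spec_crop(seed = 10))$img$pixels))
})

test_that("ground-truth masks share the scene grid and match their fractions", {
  sc <- generate_retina_scene(spec_small(seed = 3),
                              clean_retina(capillary_density_target = 0.35))
  expect_identical(dim(sc$truth$large_vessel_mask), dim(sc$img$pixels))
  expect_identical(dim(sc$truth$union_mask), dim(sc$img$pixels))
  # union = capillary target plus a small vessel-tree contribution
  expect_lt(abs(mean(sc$truth$union_mask) - 0.35), 0.03)
  expect_equal(sc$truth$true_pd_percent, 100 * mean(sc$truth$union_mask))

  cc <- generate_cc_scene(spec_small(seed = 5),
                          cc_scene_params(void_fraction_target = 0.15,
                                          speckle_sigma = 0))
  expect_identical(dim(cc$truth$void_mask), dim(cc$img$pixels))
  expect_lt(abs(cc$truth$true_void_fraction - 0.15), 0.02)

  cc0 <- generate_cc_scene(spec_crop(seed = 5),
                           cc_scene_params(void_fraction_target = 0))
  expect_false(any(cc0$truth$void_mask))
  expect_identical(cc0$truth$true_void_fraction, 0)
})

test_that("visit pairs share anatomy and degenerate to identical images", {
  pair0 <- generate_visit_pair(spec_crop(seed = 11), retina_scene_params(),
                               within_subject_sd = 0, shared_noise = TRUE)
  expect_identical(pair0$visit1$pixels, pair0$visit2$pixels)

  pair <- generate_visit_pair(spec_crop(seed = 11), retina_scene_params(),
                              within_subject_sd = 0.05)
  expect_gt(mean(abs(pair$visit1$pixels - pair$visit2$pixels)), 0)
  # both visits carry the same ground truth
  expect_identical(dim(pair$truth$union_mask), dim(pair$visit1$pixels))
  expect_error(generate_visit_pair(spec_crop(1), retina_scene_params(),
                                   within_subject_sd = -1))
})

test_that("identical visits across a cohort give ICC exactly 1", {
  pds <- purrr::map_dfr(1:14, function(s) {
    pair <- generate_visit_pair(spec_crop(seed = 100L + s), retina_scene_params(),
                                within_subject_sd = 0, shared_noise = TRUE)
    tibble::tibble(
      subject = s,
      v1 = perfusion_density(local_adaptive_binarize(pair$visit1))$pd_percent,
      v2 = perfusion_density(local_adaptive_binarize(pair$visit2))$pd_percent)
  })
  expect_gt(stats::sd(pds$v1), 0) # non-constant across subjects
  fit <- icc_two_way(pds$v1, pds$v2)
  expect_identical(fit$icc, 1)
})

test_that("the implied ICC follows the variance-ratio formula", {
  expect_identical(implied_icc(cohort_spec(between_subject_sd = 1,
                                           within_subject_sd = 0)), 1)
  expect_equal(implied_icc(cohort_spec(between_subject_sd = 3,
                                       within_subject_sd = 1)), 0.9)
  expect_identical(implied_icc(cohort_spec(between_subject_sd = 0,
                                           within_subject_sd = 1)), 0)
})

test_that("latent variance components are recovered on a large cohort", {
  co <- cohort_spec(n_subjects = 200L, between_subject_sd = 3,
                    within_subject_sd = 1, seed = 77L)
  d <- simulate_paired_metrics(co, mu = 40)
  w <- tidyr::pivot_wider(d[, c("subject", "visit", "value")],
                          names_from = "visit", values_from = "value")
  w_hat <- sqrt(stats::var(w$`1` - w$`2`) / 2)
  b_hat <- sqrt(max(stats::var((w$`1` + w$`2`) / 2) - w_hat^2 / 2, 0))
  expect_lt(abs(w_hat - 1) / 1, 0.15)
  expect_lt(abs(b_hat - 3) / 3, 0.15)
})

test_that("generate_cohort writes a complete, reloadable manifest", {
  dir <- withr::local_tempdir()
  co <- cohort_spec(n_subjects = 2L, base_scene = spec_crop(seed = 1),
                    seed = 5L)
  gen <- generate_cohort(co, dir)
  expect_equal(nrow(gen$manifest), 2 * 2 * 3) # subjects x visits x slabs
  expect_true(all(c("subject_id", "visit", "eye", "slab", "image_path",
                    "pitch_x_um", "pitch_y_um") %in% names(gen$manifest)))
  mf <- read_manifest(file.path(dir, "manifest.csv"))
  expect_true(all(file.exists(mf$image_path)))
  img <- read_image(mf$image_path[1], mf$pitch_x_um[1], mf$pitch_y_um[1],
                    slab = mf$slab[1])
  expect_identical(dim(img$pixels), c(134L, 200L))
  expect_error(cohort_spec(n_subjects = 1L), "n_subjects")
  expect_error(cohort_spec(between_subject_sd = 0, within_subject_sd = 0))
})
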