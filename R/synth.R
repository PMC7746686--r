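#' Scene geometry for synthetic widefield angiograms
#'
#' Defaults mirror the widefield acquisition: an 800 x 534 grid covering
#' 15 x 9 mm, i.e. a pitch of (18.75, 16.854) um/px. (The acquisition is
#' described as isotropically sampled, which is incompatible with exact
#' 15000/800 vs 9000/534 arithmetic; both the grid and the pitch are
#' therefore configurable and carried explicitly everywhere.)
#'
#' @param width_px,height_px Grid size in pixels (>= 64 each).
#' @param pitch_x_um,pitch_y_um Pixel pitch in micrometres.
#' @param fovea_center_px Fovea centre `c(row, col)`, 0-based; default the
#'   geometric centre.
#' @param disc_center_px Optional optic-disc centre `c(row, col)`.
#' @param disc_radius_px Optic-disc radius in pixels (used when a disc
#'   centre is given).
#' @param seed Integer seed; every generator output is a pure function of
#'   (spec, params, seed).
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(width_px = 800L, height_px = 534L,
                       pitch_x_um = 15000 / 800, pitch_y_um = 9000 / 534,
                       fovea_center_px = c((height_px - 1) / 2,
                                           (width_px - 1) / 2),
                       disc_center_px = NULL, disc_radius_px = 40,
                       seed = 1L) {
  stopifnot(width_px >= 64, height_px >= 64, pitch_x_um > 0, pitch_y_um > 0)
  if (fovea_center_px[1] < 0 || fovea_center_px[1] > height_px - 1 ||
      fovea_center_px[2] < 0 || fovea_center_px[2] > width_px - 1) {
    stop("fovea centre must lie inside the image bounds", call. = FALSE)
  }
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pitch_x_um = pitch_x_um, pitch_y_um = pitch_y_um,
                 fovea_center_px = as.numeric(fovea_center_px),
                 disc_center_px = if (is.null(disc_center_px)) NULL
                                  else as.numeric(disc_center_px),
                 disc_radius_px = disc_radius_px,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Appearance parameters for a synthetic retinal-plexus scene
#'
#' @param large_vessel_count Number of arcade roots for the branching
#'   vessel tree.
#' @param large_vessel_width_um Root-calibre range `(min, max)` in
#'   micrometres.
#' @param capillary_density_target Fraction of the frame covered by the
#'   capillary texture, in \[0, 1\].
#' @param capillary_width_um Correlation scale of the capillary texture.
#' @param vignetting_strength Peripheral multiplicative falloff in \[0, 1):
#'   the corner-most signal is reduced by this fraction.
#' @param speckle_sigma Speckle noise scale: the image is multiplied by
#'   `1 + N(0, sigma)` and offset by `N(0, sigma / 2)`, then clipped.
#' @param background_level Baseline intensity of avascular tissue.
#' @return A list of class `retina_scene_params`.
#' @export
retina_scene_params <- function(large_vessel_count = 4L,
                                large_vessel_width_um = c(40, 110),
                                capillary_density_target = 0.35,
                                capillary_width_um = 12,
                                vignetting_strength = 0.25,
                                speckle_sigma = 0.05,
                                background_level = 0.15) {
  stopifnot(large_vessel_count >= 0,
            length(large_vessel_width_um) == 2,
            large_vessel_width_um[1] <= large_vessel_width_um[2],
            capillary_density_target >= 0, capillary_density_target <= 1,
            capillary_width_um > 0,
            capillary_width_um < large_vessel_width_um[1],
            vignetting_strength >= 0, vignetting_strength < 1,
            speckle_sigma >= 0,
            background_level >= 0, background_level <= 1)
  structure(list(large_vessel_count = as.integer(large_vessel_count),
                 large_vessel_width_um = as.numeric(large_vessel_width_um),
                 capillary_density_target = capillary_density_target,
                 capillary_width_um = capillary_width_um,
                 vignetting_strength = vignetting_strength,
                 speckle_sigma = speckle_sigma,
                 background_level = background_level),
            class = "retina_scene_params")
}

#' Appearance parameters for a synthetic choriocapillaris scene
#'
#' @param texture_correlation_um Correlation scale of the granular
#'   background texture.
#' @param void_fraction_target Fraction of the frame covered by flow voids,
#'   in \[0, 1\].
#' @param void_size_um2_mean Mean individual void area in square
#'   micrometres (healthy voids are small, a few hundred um^2).
#' @param void_contrast Multiplicative darkening inside voids, in (0, 1\];
#'   lower is darker.
#' @param speckle_sigma As in [retina_scene_params()].
#' @return A list of class `cc_scene_params`.
#' @export
cc_scene_params <- function(texture_correlation_um = 40,
                            void_fraction_target = 0.15,
                            void_size_um2_mean = 700,
                            void_contrast = 0.35,
                            speckle_sigma = 0.03) {
  stopifnot(texture_correlation_um > 0,
            void_fraction_target >= 0, void_fraction_target <= 1,
            void_size_um2_mean > 0, void_contrast > 0, void_contrast <= 1,
            speckle_sigma >= 0)
  structure(list(texture_correlation_um = texture_correlation_um,
                 void_fraction_target = void_fraction_target,
                 void_size_um2_mean = void_size_um2_mean,
                 void_contrast = void_contrast,
                 speckle_sigma = speckle_sigma),
            class = "cc_scene_params")
}

# Multiplicative speckle plus additive noise, clipped; consumes the current
# RNG stream.
apply_speckle <- function(m, sigma) {
  if (sigma <= 0) return(clip01(m))
  n <- length(m)
  clip01(m * (1 + matrix(stats::rnorm(n, 0, sigma), nrow(m))) +
           matrix(stats::rnorm(n, 0, sigma / 2), nrow(m)))
}

# Radially symmetric multiplicative vignetting centred on the frame.
vignette_field <- function(shape, strength) {
  if (strength <= 0) return(matrix(1, shape[1], shape[2]))
  cy <- (shape[1] - 1) / 2; cx <- (shape[2] - 1) / 2
  ry <- (seq_len(shape[1]) - 1 - cy) / max(cy, 1)
  rx <- (seq_len(shape[2]) - 1 - cx) / max(cx, 1)
  rho2 <- outer(ry^2, rx^2, `+`) / 2 # corners reach 1
  1 - strength * rho2
}

# Linear indices of the pixels whose centres fall inside an ellipse.
# Centre in 0-based (row, col); radii in pixels per axis. A sub-pixel
# ellipse still claims its nearest pixel centre.
ellipse_idx <- function(shape, center, radius_row, radius_col, angle = 0) {
  nr <- shape[1]; nc <- shape[2]
  r0 <- max(1L, floor(center[1] + 1 - max(radius_row, radius_col)))
  r1 <- min(nr, ceiling(center[1] + 1 + max(radius_row, radius_col)))
  c0 <- max(1L, floor(center[2] + 1 - max(radius_row, radius_col)))
  c1 <- min(nc, ceiling(center[2] + 1 + max(radius_row, radius_col)))
  nearest <- function() {
    pr <- min(max(round(center[1]) + 1, 1L), nr)
    pc <- min(max(round(center[2]) + 1, 1L), nc)
    (pc - 1L) * nr + pr
  }
  if (r0 > r1 || c0 > c1) return(nearest())
  rr <- (r0:r1) - 1 - center[1]
  cc <- (c0:c1) - 1 - center[2]
  RR <- rep(rr, times = length(cc))
  CC <- rep(cc, each = length(rr))
  u <- CC * cos(angle) + RR * sin(angle)
  v <- -CC * sin(angle) + RR * cos(angle)
  inside <- (u / radius_col)^2 + (v / radius_row)^2 <= 1
  if (!any(inside)) return(nearest())
  rows <- rep(r0:r1, times = length(cc))[inside]
  cols <- rep(c0:c1, each = length(rr))[inside]
  (cols - 1L) * nr + rows
}

# Stamp a filled ellipse (pixel-centre inclusion) into a logical matrix.
stamp_ellipse <- function(mask, center, radius_row, radius_col, angle = 0) {
  mask[ellipse_idx(dim(mask), center, radius_row, radius_col, angle)] <- TRUE
  mask
}

# Branching random-walk vessel tree rasterized as a logical mask.
# Roots start near the disc side of the frame and sweep across it in
# arcade-like curves; each branch tapers and may spawn a child at 70% of
# its width. Consumes the current RNG stream.
draw_vessel_tree <- function(spec, params) {
  nr <- spec$height_px; nc <- spec$width_px
  mask <- matrix(FALSE, nr, nc)
  if (params$large_vessel_count == 0L) return(mask)
  wmin <- params$large_vessel_width_um[1]
  wmax <- params$large_vessel_width_um[2]
  origin <- if (!is.null(spec$disc_center_px)) spec$disc_center_px
            else c((nr - 1) / 2, (nc - 1) * 0.06)
  step_px <- 2
  queue <- list()
  for (i in seq_len(params$large_vessel_count)) {
    # fan the roots across [-70, 70] degrees around the +x direction
    ang <- (i - 0.5) / params$large_vessel_count * 2.4 - 1.2 +
      stats::rnorm(1, 0, 0.08)
    w <- stats::runif(1, wmin + 0.5 * (wmax - wmin), wmax)
    queue[[length(queue) + 1]] <- list(pos = origin, ang = ang, w = w)
  }
  max_segments <- 60L * params$large_vessel_count
  n_seg <- 0L
  while (length(queue) > 0 && n_seg < max_segments) {
    seg <- queue[[1]]; queue[[1]] <- NULL
    n_seg <- n_seg + 1L
    pos <- seg$pos; ang <- seg$ang; w <- seg$w
    for (s in seq_len(600L)) {
      mask <- stamp_ellipse(mask, pos,
                            radius_row = w / (2 * spec$pitch_y_um),
                            radius_col = w / (2 * spec$pitch_x_um))
      ang <- ang + stats::rnorm(1, 0, 0.09)
      # gentle pull back toward horizontal keeps arcades sweeping across
      ang <- ang - 0.02 * sin(ang)
      pos <- pos + step_px * c(sin(ang), cos(ang))
      w <- w * 0.997
      if (pos[1] < 0 || pos[1] > nr - 1 || pos[2] < 0 || pos[2] > nc - 1) break
      if (w < wmin * 0.8) break
      if (stats::runif(1) < 0.015 && w * 0.7 >= wmin * 0.8) {
        queue[[length(queue) + 1]] <-
          list(pos = pos, ang = ang + sample(c(-1, 1), 1) * stats::runif(1, 0.5, 0.9),
               w = w * 0.7)
        w <- w * 0.85
      }
    }
  }
  mask
}

# Capillary texture as spatially correlated noise thresholded at the
# quantile that realizes the requested coverage fraction exactly (up to
# ties, which have probability zero for continuous noise).
draw_capillary_texture <- function(spec, params) {
  nr <- spec$height_px; nc <- spec$width_px
  if (params$capillary_density_target <= 0) return(matrix(FALSE, nr, nc))
  if (params$capillary_density_target >= 1) return(matrix(TRUE, nr, nc))
  field <- matrix(stats::rnorm(nr * nc), nr, nc)
  sy <- params$capillary_width_um / (2 * spec$pitch_y_um)
  sx <- params$capillary_width_um / (2 * spec$pitch_x_um)
  field <- gaussian_deriv(field, max(sy, 0.3), max(sx, 0.3))
  thr <- stats::quantile(field, 1 - params$capillary_density_target,
                         names = FALSE)
  field > thr
}

#' Generate a synthetic retinal-plexus angiogram with ground truth
#'
#' Builds a bright branching large-vessel tree over a capillary texture on
#' a uniform background, applies radial vignetting and speckle noise, and
#' returns the exact rasterized masks alongside the image. Identical
#' (spec, params) inputs reproduce the image bit for bit; the caller's RNG
#' state is untouched.
#'
#' @param spec A [scene_spec()].
#' @param params A [retina_scene_params()].
#' @param slab Slab label for the output image, default `"SCP"`.
#' @param noise_seed Seed of the speckle substream; defaults to a stream
#'   derived from the scene seed. The cohort generator overrides it per
#'   visit so visits share anatomy but not noise.
#' @return A list with `img` (an [angiogram()]) and `truth` (a list with
#'   `large_vessel_mask`, `capillary_mask`, `union_mask`,
#'   `true_pd_percent`).
#' @export
#' @examples
#' sc <- generate_retina_scene(scene_spec(width_px = 128, height_px = 96, seed = 7))
#' sc$truth$true_pd_percent
generate_retina_scene <- function(spec, params = retina_scene_params(),
                                  slab = "SCP",
                                  noise_seed = substream_seed(spec$seed, "noise")) {
  anatomy <- with_seed(substream_seed(spec$seed, "anatomy"), {
    vessels <- draw_vessel_tree(spec, params)
    caps <- draw_capillary_texture(spec, params)
    list(vessels = vessels, caps = caps)
  })
  union_mask <- anatomy$vessels | anatomy$caps
  base <- matrix(params$background_level, spec$height_px, spec$width_px)
  base[anatomy$caps] <- pmin(params$background_level + 0.40, 1)
  base[anatomy$vessels] <- pmin(params$background_level + 0.70, 1)
  base <- base * vignette_field(dim(base), params$vignetting_strength)
  img_px <- with_seed(noise_seed, apply_speckle(base, params$speckle_sigma))
  img <- angiogram(img_px, spec$pitch_x_um, spec$pitch_y_um, slab = slab)
  truth <- list(large_vessel_mask = anatomy$vessels,
                capillary_mask = anatomy$caps,
                union_mask = union_mask,
                true_pd_percent = 100 * sum(union_mask) / length(union_mask))
  list(img = img, truth = truth)
}

# Draw one batch of candidate voids (centres + ellipse shapes); the batch
# size is fixed so the candidate sequence is identical whatever coverage
# target consumes it (visit pairs stay nested).
draw_void_batch <- function(spec, params, batch = 1000L) {
  px_um2 <- spec$pitch_x_um * spec$pitch_y_um
  tibble::tibble(
    row = stats::runif(batch, 0, spec$height_px - 1),
    col = stats::runif(batch, 0, spec$width_px - 1),
    area_um2 = stats::rexp(batch, 1 / params$void_size_um2_mean),
    aspect = stats::runif(batch, 0.5, 1),
    angle = stats::runif(batch, 0, pi)) |>
    dplyr::mutate(
      # area = pi * a * b with b = aspect * a, in um2; convert to px radii
      a_um = sqrt(.data$area_um2 / (pi * .data$aspect)),
      radius_col = .data$a_um / spec$pitch_x_um,
      radius_row = .data$a_um * .data$aspect / spec$pitch_y_um,
      px_est = pmax(.data$area_um2 / px_um2, 1))
}

#' Generate a synthetic choriocapillaris angiogram with ground truth
#'
#' A stationary granular texture (spatially correlated noise at
#' `texture_correlation_um`) darkened by small elliptical flow voids whose
#' union covers approximately `void_fraction_target` of the frame. Voids
#' are stamped from a deterministic candidate stream until the target
#' coverage is reached, so scenes generated from the same seed with
#' different targets have nested void sets.
#'
#' @param spec A [scene_spec()].
#' @param params A [cc_scene_params()].
#' @inheritParams generate_retina_scene
#' @return A list with `img` (an [angiogram()], slab `"CC"`) and `truth`
#'   (with `void_mask` and `true_void_fraction`).
#' @export
generate_cc_scene <- function(spec, params = cc_scene_params(),
                              noise_seed = substream_seed(spec$seed, "noise")) {
  nr <- spec$height_px; nc <- spec$width_px
  n_px <- nr * nc
  anatomy_seed <- substream_seed(spec$seed, "anatomy")
  scene <- with_seed(anatomy_seed, {
    field <- matrix(stats::rnorm(n_px), nr, nc)
    sy <- params$texture_correlation_um / (2 * spec$pitch_y_um)
    sx <- params$texture_correlation_um / (2 * spec$pitch_x_um)
    field <- gaussian_deriv(field, max(sy, 0.3), max(sx, 0.3))
    field <- (field - mean(field)) / stats::sd(field)
    texture <- clip01(0.60 + 0.08 * field)
    void_mask <- matrix(FALSE, nr, nc)
    target_px <- round(params$void_fraction_target * n_px)
    covered <- 0L
    guard <- 0L
    while (covered < target_px && guard < 200L) {
      cand <- draw_void_batch(spec, params)
      for (i in seq_len(nrow(cand))) {
        idx <- ellipse_idx(c(nr, nc), c(cand$row[i], cand$col[i]),
                           cand$radius_row[i], cand$radius_col[i],
                           cand$angle[i])
        covered <- covered + sum(!void_mask[idx])
        void_mask[idx] <- TRUE
        if (covered >= target_px) break
      }
      guard <- guard + 1L
    }
    list(texture = texture, void_mask = void_mask)
  })
  img_px <- scene$texture
  img_px[scene$void_mask] <- img_px[scene$void_mask] * params$void_contrast
  img_px <- with_seed(noise_seed, apply_speckle(img_px, params$speckle_sigma))
  img <- angiogram(img_px, spec$pitch_x_um, spec$pitch_y_um, slab = "CC")
  truth <- list(void_mask = scene$void_mask,
                true_void_fraction = sum(scene$void_mask) / n_px)
  list(img = img, truth = truth)
}

#' Generate a two-visit pair of angiograms sharing one anatomy
#'
#' Both visits share the noise-free anatomy generated from the scene seed;
#' visit 2 differs by freshly sampled speckle, a global gain factor
#' `1 + N(0, within_subject_sd)`, and (optionally) a sub-pixel translation.
#' With `within_subject_sd = 0` and `shared_noise = TRUE` the two visits
#' are identical.
#'
#' @param spec A [scene_spec()].
#' @param params A [retina_scene_params()] or [cc_scene_params()]; the
#'   scene kind is inferred from the class.
#' @param within_subject_sd SD of the per-visit global gain perturbation
#'   (>= 0).
#' @param shared_noise If `TRUE` both visits reuse the same speckle stream.
#' @param shift_px Optional `c(row, col)` sub-pixel translation applied to
#'   visit 2 (bilinear, reflect edges).
#' @return A list with `visit1`, `visit2` (angiograms) and the shared
#'   `truth`.
#' @export
generate_visit_pair <- function(spec, params = retina_scene_params(),
                                within_subject_sd = 0.02,
                                shared_noise = FALSE, shift_px = c(0, 0)) {
  stopifnot(within_subject_sd >= 0)
  clean_params <- params
  clean_params$speckle_sigma <- 0
  scene <- if (inherits(params, "cc_scene_params")) {
    generate_cc_scene(spec, clean_params)
  } else {
    generate_retina_scene(spec, clean_params)
  }
  clean <- scene$img$pixels
  make_visit <- function(v) {
    gain <- with_seed(substream_seed(spec$seed, paste0("visit", v)),
                      1 + stats::rnorm(1, 0, within_subject_sd))
    px <- clean * gain
    if (v == 2L && any(shift_px != 0)) px <- shift_bilinear(px, shift_px)
    noise_name <- if (shared_noise) "noise-shared" else paste0("noise", v)
    px <- with_seed(substream_seed(spec$seed, noise_name),
                    apply_speckle(px, params$speckle_sigma))
    set_pixels(scene$img, clip01(px))
  }
  list(visit1 = make_visit(1L), visit2 = make_visit(2L), truth = scene$truth)
}

# Sub-pixel bilinear translation with edge clamping.
shift_bilinear <- function(m, shift) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(seq_len(nr) - shift[1], 1), nr)
  cl <- pmin(pmax(seq_len(nc) - shift[2], 1), nc)
  r0 <- floor(r); r1 <- pmin(r0 + 1, nr); fr <- r - r0
  c0 <- floor(cl); c1 <- pmin(c0 + 1, nc); fc <- cl - c0
  (1 - fr) %o% (1 - fc) * m[r0, c0] + (1 - fr) %o% fc * m[r0, c1] +
    fr %o% (1 - fc) * m[r1, c0] + fr %o% fc * m[r1, c1]
}

#' Cohort design for paired-visit simulation
#'
#' The latent metric of subject s at visit v is
#' `mu + b_s + w_sv` with `b_s ~ N(0, between_subject_sd^2)` and
#' `w_sv ~ N(0, within_subject_sd^2)`, so the implied true ICC is
#' `b^2 / (b^2 + w^2)`. Defaults follow the reference study design: 14
#' subjects, 2 visits.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_visits Number of visits (>= 2; the study design uses 2).
#' @param between_subject_sd,within_subject_sd Latent-metric SDs, in the
#'   metric's own units (percentage points for perfusion density / void
#'   fraction). At least one must be positive.
#' @param base_scene A [scene_spec()] used for every image.
#' @param seed Cohort seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 14L, n_visits = 2L,
                        between_subject_sd = 0.8, within_subject_sd = 0.4,
                        base_scene = scene_spec(), seed = 1L) {
  stopifnot(n_subjects >= 2, n_visits >= 2,
            between_subject_sd >= 0, within_subject_sd >= 0)
  if (between_subject_sd == 0 && within_subject_sd == 0) {
    stop("at least one variance component must be positive", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_visits = as.integer(n_visits),
                 between_subject_sd = between_subject_sd,
                 within_subject_sd = within_subject_sd,
                 base_scene = base_scene, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Implied true ICC of a cohort design
#'
#' @param cohort A [cohort_spec()] (or anything with the two SD fields).
#' @return `b^2 / (b^2 + w^2)`.
#' @export
implied_icc <- function(cohort) {
  b2 <- cohort$between_subject_sd^2
  w2 <- cohort$within_subject_sd^2
  b2 / (b2 + w2)
}

#' Simulate latent paired-visit metrics (no images)
#'
#' Draws the latent metric `mu + b_s + w_sv` for every subject and visit.
#' This is the light-weight arm of the cohort generator, used for
#' statistical calibration (ICC recovery, CI coverage) where rendering
#' images would add nothing.
#'
#' @param cohort A [cohort_spec()].
#' @param mu Latent-metric grand mean.
#' @return A tibble with `subject`, `visit`, `b`, `w`, `value`.
#' @export
simulate_paired_metrics <- function(cohort, mu = 0) {
  with_seed(cohort$seed, {
    b <- stats::rnorm(cohort$n_subjects, 0, cohort$between_subject_sd)
    w <- stats::rnorm(cohort$n_subjects * cohort$n_visits, 0,
                      cohort$within_subject_sd)
    tibble::tibble(
      subject = rep(seq_len(cohort$n_subjects), times = cohort$n_visits),
      visit = rep(seq_len(cohort$n_visits), each = cohort$n_subjects),
      b = rep(b, times = cohort$n_visits), w = w,
      value = mu + .data$b + .data$w)
  })
}

#' Generate an image cohort with a manifest and ground truth
#'
#' For every subject and visit, renders the requested slabs and writes them
#' as 16-bit grayscale TIFFs together with a manifest CSV (one row per
#' image: subject_id, visit, eye, slab, image_path, pitch, fovea) and a
#' ground-truth CSV of the latent and rasterized metrics. Subjects share
#' their anatomy across visits (fixed anatomy seed); the between/within
#' variance components act on the latent capillary density (retina slabs)
#' and void fraction (CC slab), and each visit gets fresh speckle.
#'
#' @param cohort A [cohort_spec()].
#' @param out_dir Output directory (created if needed).
#' @param slabs Subset of `c("SCP", "DCP", "CC")` to render.
#' @param retina_params,cc_params Base appearance parameters; the DCP slab
#'   reuses `retina_params` with no large-vessel tree and a slightly denser
#'   capillary bed.
#' @return A list with `manifest` and `truth` tibbles (also written as
#'   `manifest.csv` and `truth.csv` under `out_dir`).
#' @export
generate_cohort <- function(cohort, out_dir,
                            slabs = c("SCP", "DCP", "CC"),
                            retina_params = retina_scene_params(),
                            cc_params = cc_scene_params()) {
  slabs <- match.arg(slabs, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lat <- simulate_paired_metrics(cohort)
  rows <- list(); truths <- list()
  for (s in seq_len(cohort$n_subjects)) {
    subj_id <- sprintf("S%03d", s)
    anatomy_seed <- substream_seed(cohort$seed, paste0("subject", s))
    for (v in seq_len(cohort$n_visits)) {
      shift <- lat$value[lat$subject == s & lat$visit == v]
      for (slab in slabs) {
        sp <- cohort$base_scene
        # distinct anatomy stream per slab, shared across visits; the
        # speckle stream is re-keyed per visit
        sp$seed <- substream_seed(anatomy_seed, slab)
        vseed <- substream_seed(sp$seed, paste0("noise-v", v))
        if (slab == "CC") {
          pr <- cc_params
          pr$void_fraction_target <-
            min(max(pr$void_fraction_target + shift / 100, 0), 1)
          scene <- generate_cc_scene(sp, pr, noise_seed = vseed)
          truth_row <- tibble::tibble(
            subject_id = subj_id, visit = v, slab = slab,
            latent_value = pr$void_fraction_target * 100,
            true_pd_percent = NA_real_,
            true_void_fraction = scene$truth$true_void_fraction)
        } else {
          pr <- retina_params
          if (slab == "DCP") {
            pr$large_vessel_count <- 0L
            pr$capillary_density_target <-
              min(pr$capillary_density_target + 0.05, 1)
          }
          pr$capillary_density_target <-
            min(max(pr$capillary_density_target + shift / 100, 0), 1)
          scene <- generate_retina_scene(sp, pr, slab = slab,
                                         noise_seed = vseed)
          truth_row <- tibble::tibble(
            subject_id = subj_id, visit = v, slab = slab,
            latent_value = pr$capillary_density_target * 100,
            true_pd_percent = scene$truth$true_pd_percent,
            true_void_fraction = NA_real_)
        }
        fn <- sprintf("%s_v%d_%s.tif", subj_id, v, slab)
        write_image(scene$img, file.path(out_dir, fn))
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject_id = subj_id, visit = v, eye = "OD", slab = slab,
          image_path = fn,
          pitch_x_um = sp$pitch_x_um, pitch_y_um = sp$pitch_y_um,
          fovea_row = sp$fovea_center_px[1], fovea_col = sp$fovea_center_px[2])
        truths[[length(truths) + 1]] <- truth_row
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  truth <- dplyr::bind_rows(truths)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  readr::write_csv(truth, file.path(out_dir, "truth.csv"))
  invisible(list(manifest = manifest, truth = truth))
}
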