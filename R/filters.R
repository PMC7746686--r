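#' Parameters for the multi-scale Hessian (Frangi) vesselness filter
#'
#' The filter responds to bright curvilinear structures whose diameters fall
#' in `size_range_um`. Each diameter d is mapped to a Gaussian scale
#' sigma = d / 4 (per axis, in pixels via the pitch): a Gaussian ridge of
#' width d has its strongest second-derivative response near that sigma.
#'
#' @param size_range_um Vessel diameter range in micrometres, default
#'   `c(15, 44)` (retinal capillary to small-arteriole calibre).
#' @param n_scales Number of log-spaced scales spanning the range.
#' @param beta Blobness sensitivity (Frangi's beta), default 0.5.
#' @param c_frac Structureness constant as a fraction of the per-scale
#'   maximum Frobenius norm of the Hessian, default 0.5.
#' @return A list of class `hessian_params`.
#' @export
hessian_params <- function(size_range_um = c(15, 44), n_scales = 4L,
                           beta = 0.5, c_frac = 0.5) {
  stopifnot(length(size_range_um) == 2, size_range_um[1] > 0,
            size_range_um[1] < size_range_um[2],
            n_scales >= 2, beta > 0, c_frac > 0)
  structure(list(size_range_um = as.numeric(size_range_um),
                 n_scales = as.integer(n_scales),
                 beta = beta, c_frac = c_frac),
            class = "hessian_params")
}

#' Multi-scale Hessian vesselness (Frangi) enhancement
#'
#' Computes, at each of `n_scales` log-spaced vessel diameters, the
#' scale-normalized Hessian (gamma = 2) with per-axis sigmas
#' `d / (4 * pitch)`, orders its eigenvalues by magnitude and scores bright
#' ridges (lambda2 < 0) with the Frangi vesselness
#' `exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))`, where
#' `Rb = |lambda1| / |lambda2|` and `S` is the Frobenius norm of the Hessian.
#' The output is the per-pixel maximum over scales, in \[0, 1\]; dark ridges
#' and flat regions score 0. Metadata is untouched.
#'
#' @param img An [angiogram()].
#' @param p A [hessian_params()] object.
#' @return An `angiogram` whose pixels hold the vesselness score.
#' @export
#' @examples
#' img <- angiogram(matrix(0.5, 64, 64), 18.75, 16.854, "SCP")
#' v <- hessian_vesselness(img)
#' max(v$pixels) # constant image has no ridge structure
hessian_vesselness <- function(img, p = hessian_params()) {
  m <- img$pixels
  diameters <- exp(seq(log(p$size_range_um[1]), log(p$size_range_um[2]),
                       length.out = p$n_scales))
  best <- matrix(0, nrow(m), ncol(m))
  for (d in diameters) {
    sy <- d / (4 * img$pitch_y_um)
    sx <- d / (4 * img$pitch_x_um)
    # gamma = 2 scale normalization with the geometric-mean sigma
    norm <- sy * sx
    hyy <- norm * gaussian_deriv(m, sy, sx, 2L, 0L)
    hxx <- norm * gaussian_deriv(m, sy, sx, 0L, 2L)
    hxy <- norm * gaussian_deriv(m, sy, sx, 1L, 1L)
    # closed-form 2x2 symmetric eigenvalues
    tr <- hxx + hyy
    disc <- sqrt(pmax((hxx - hyy)^2 + 4 * hxy^2, 0))
    e1 <- (tr + disc) / 2
    e2 <- (tr - disc) / 2
    # order by magnitude: l2 is the larger-magnitude eigenvalue
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1)
    l2 <- ifelse(swap, e1, e2)
    s2 <- hxx^2 + hyy^2 + 2 * hxy^2
    cc <- p$c_frac * sqrt(max(s2))
    # no real curvature at this scale (flat image up to FFT roundoff)
    if (cc <= 1e-10) next
    rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    v <- exp(-rb2 / (2 * p$beta^2)) * (1 - exp(-s2 / (2 * cc^2)))
    v[l2 >= 0] <- 0
    best <- pmax(best, v)
  }
  set_pixels(img, clip01(best))
}

#' Parameters for the Gabor vessel-enhancement bank
#'
#' Sixteen oriented even-symmetric Gabor kernels spaced pi/16 apart spanning
#' \[0, pi). The default wavelength is 20 * pi pixels (about 62.8 px); the
#' envelope width follows `sigma = 0.56 * wavelength` and the across-stripe
#' aspect ratio is 0.5, common defaults for vessel enhancement.
#'
#' @param wavelength_px Carrier wavelength in pixels (> 2 to avoid aliasing).
#' @param n_orientations Number of orientations; with
#'   `orientation_interval_rad` they must span pi.
#' @param orientation_interval_rad Angular step between kernels.
#' @param sigma_px Gaussian envelope sigma in pixels.
#' @param gamma_aspect Spatial aspect ratio (across / along the stripe).
#' @param radius_factor Kernel support radius as a multiple of `sigma_px`.
#' @return A list of class `gabor_params`.
#' @export
gabor_params <- function(wavelength_px = 20 * pi, n_orientations = 16L,
                         orientation_interval_rad = pi / 16,
                         sigma_px = 0.56 * wavelength_px,
                         gamma_aspect = 0.5, radius_factor = 2.5) {
  stopifnot(wavelength_px > 2, n_orientations >= 2, sigma_px > 0,
            gamma_aspect > 0, radius_factor > 0)
  if (abs(n_orientations * orientation_interval_rad - pi) > 1e-8) {
    stop("n_orientations * orientation_interval_rad must span pi",
         call. = FALSE)
  }
  structure(list(wavelength_px = wavelength_px,
                 n_orientations = as.integer(n_orientations),
                 orientation_interval_rad = orientation_interval_rad,
                 sigma_px = sigma_px, gamma_aspect = gamma_aspect,
                 radius_factor = radius_factor),
            class = "gabor_params")
}

# Even (cosine) Gabor kernel whose stripes run along orientation theta
# (theta = 0 responds maximally to a horizontal bar). The carrier therefore
# runs perpendicular to theta. Mean-subtracted so a constant image yields
# exactly zero response.
gabor_kernel <- function(p, theta) {
  r <- max(3L, ceiling(p$radius_factor * p$sigma_px))
  x <- seq(-r, r)
  X <- matrix(rep(x, each = length(x)), length(x))   # column offsets
  Y <- matrix(rep(x, times = length(x)), length(x))  # row offsets
  carrier <- theta + pi / 2
  xr <- X * cos(carrier) + Y * sin(carrier)
  yr <- -X * sin(carrier) + Y * cos(carrier)
  env <- exp(-(xr^2 + (p$gamma_aspect * yr)^2) / (2 * p$sigma_px^2))
  k <- env * cos(2 * pi * xr / p$wavelength_px)
  k - sum(k) / length(k)
}

#' Gabor filter-bank vessel enhancement
#'
#' Convolves the image with the even Gabor kernel at each orientation
#' `0, pi/16, ..., 15 pi/16`, takes the per-pixel maximum of the responses
#' and min-max rescales the result to \[0, 1\]. Because the kernels are
#' zero-mean, a constant image gives an identically zero raw response.
#'
#' @inheritParams hessian_vesselness
#' @param p A [gabor_params()] object.
#' @param return_orientation If `TRUE`, also attach the argmax orientation
#'   index (1-based) as attribute `"orientation"` of the pixel matrix.
#' @return An `angiogram` with the enhanced image.
#' @export
gabor_enhance <- function(img, p = gabor_params(), return_orientation = FALSE) {
  m <- img$pixels
  thetas <- (seq_len(p$n_orientations) - 1L) * p$orientation_interval_rad
  best <- matrix(-Inf, nrow(m), ncol(m))
  ori <- if (return_orientation) matrix(1L, nrow(m), ncol(m)) else NULL
  for (i in seq_along(thetas)) {
    resp <- convolve2(m, gabor_kernel(p, thetas[i]))
    if (return_orientation) ori[resp > best] <- i
    best <- pmax(best, resp)
  }
  out <- rescale01(best)
  if (return_orientation) attr(out, "orientation") <- ori
  set_pixels(img, out)
}

#' Parameters for the Bayesian residual-shrinkage filter
#'
#' @param n_levels Number of residual layers (>= 2).
#' @param noise_sd_estimate Noise SD on the \[0, 1\] intensity scale, or
#'   `"auto"` to estimate it from the finest residual layer by the robust
#'   median-absolute-deviation rule `sd = median(|r|) / 0.6745`.
#' @param shrinkage `"soft"` (default) or `"hard"` thresholding.
#' @param base_sigma_px Gaussian sigma of the first smoothing level; each
#'   subsequent level doubles it.
#' @return A list of class `brt_params`.
#' @export
brt_params <- function(n_levels = 4L, noise_sd_estimate = "auto",
                       shrinkage = c("soft", "hard"), base_sigma_px = 1) {
  shrinkage <- match.arg(shrinkage)
  if (n_levels < 2) stop("n_levels must be >= 2", call. = FALSE)
  if (!(identical(noise_sd_estimate, "auto") ||
        (is.numeric(noise_sd_estimate) && noise_sd_estimate >= 0))) {
    stop("noise_sd_estimate must be \"auto\" or a non-negative number",
         call. = FALSE)
  }
  structure(list(n_levels = as.integer(n_levels),
                 noise_sd_estimate = noise_sd_estimate,
                 shrinkage = shrinkage, base_sigma_px = base_sigma_px),
            class = "brt_params")
}

#' Bayesian residual-transform denoising filter
#'
#' Decomposes the image into a residual pyramid by iterated Gaussian
#' smoothing (`residual_i = smooth_{i-1} - smooth_i`, plus the final coarse
#' layer), applies Bayesian minimum-MSE shrinkage to each residual layer
#' under a Gaussian noise model, and reconstructs by summation. The
#' per-layer soft threshold is the BayesShrink rule
#' `T = sigma_n^2 / sigma_s` with signal SD
#' `sigma_s = sqrt(max(var(r) - sigma_n^2, 0))`; a layer indistinguishable
#' from noise is suppressed entirely. With `noise_sd_estimate = 0` the
#' reconstruction equals the input exactly. Output clipped to \[0, 1\].
#'
#' @inheritParams hessian_vesselness
#' @param p A [brt_params()] object.
#' @return An `angiogram` with the denoised image.
#' @export
bayesian_residual_enhance <- function(img, p = brt_params()) {
  m <- img$pixels
  smooth_prev <- m
  layers <- vector("list", p$n_levels)
  for (i in seq_len(p$n_levels)) {
    smooth_i <- gaussian_smooth(smooth_prev, p$base_sigma_px * 2^(i - 1))
    layers[[i]] <- smooth_prev - smooth_i
    smooth_prev <- smooth_i
  }
  sigma_n <- if (identical(p$noise_sd_estimate, "auto")) {
    stats::median(abs(layers[[1]])) / 0.6745
  } else p$noise_sd_estimate
  recon <- smooth_prev # coarse layer passes through unshrunk
  for (r in layers) {
    v <- mean(r^2) # residual layers are zero-mean by construction
    sigma_s <- sqrt(max(v - sigma_n^2, 0))
    if (sigma_n == 0) {
      recon <- recon + r
    } else if (sigma_s == 0) {
      # layer is all noise: drop it
    } else if (p$shrinkage == "soft") {
      thr <- sigma_n^2 / sigma_s
      recon <- recon + sign(r) * pmax(abs(r) - thr, 0)
    } else {
      thr <- sigma_n^2 / sigma_s
      recon <- recon + r * (abs(r) > thr)
    }
  }
  set_pixels(img, clip01(recon))
}

#' Apply a named enhancement filter
#'
#' Convenience dispatcher used by the pipeline: `"none"` returns the input
#' unchanged; the other names call the corresponding filter with its
#' default parameters (overridable via `params`).
#'
#' @inheritParams hessian_vesselness
#' @param filter One of `"none"`, `"hessian"`, `"gabor"`, `"bayesian"`.
#' @param params Optional parameter object for the chosen filter.
#' @return The filtered `angiogram`.
#' @export
apply_filter <- function(img, filter = c("none", "hessian", "gabor", "bayesian"),
                         params = NULL) {
  filter <- match.arg(filter)
  switch(filter,
         none = img,
         hessian = hessian_vesselness(img, params %||% hessian_params()),
         gabor = gabor_enhance(img, params %||% gabor_params()),
         bayesian = bayesian_residual_enhance(img, params %||% brt_params()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
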