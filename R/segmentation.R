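#' Parameters for local adaptive binarization
#'
#' @param window_mm Side of the square local-mean neighbourhood in
#'   millimetres; default 1.25 mm, a balance between suppressing background
#'   noise in avascular regions and compensating illuminance unevenness in
#'   the widefield periphery. Converted per axis to the nearest odd pixel
#'   count (>= 3) via the pitch.
#' @param offset Added to the local mean before comparison; default 0.
#' @return A list of class `binarize_params`.
#' @export
binarize_params <- function(window_mm = 1.25, offset = 0) {
  stopifnot(window_mm > 0)
  structure(list(window_mm = window_mm, offset = offset),
            class = "binarize_params")
}

# Physical window (mm) to the nearest odd pixel count on one axis.
window_px <- function(window_mm, pitch_um) {
  w <- nearest_odd(window_mm * 1000 / pitch_um)
  if (w < 3) stop("binarization window smaller than 3 px", call. = FALSE)
  w
}

#' Local adaptive (mean) binarization
#'
#' A pixel is vessel iff its intensity is strictly greater than the local
#' mean over a `window_mm` square neighbourhood plus `offset`. Ties go to
#' background, so a constant image yields an empty mask. The local mean is a
#' box filter with reflect padding; window sizes are computed per axis from
#' the pitch (at the default 18.75 um x-pitch, 1.25 mm maps to 67 px).
#'
#' @param img An [angiogram()].
#' @param p A [binarize_params()] object.
#' @return A logical matrix (vessel mask) of the image's shape.
#' @export
local_adaptive_binarize <- function(img, p = binarize_params()) {
  m <- img$pixels
  wx <- window_px(p$window_mm, img$pitch_x_um)
  wy <- window_px(p$window_mm, img$pitch_y_um)
  box <- matrix(1 / (wx * wy), wy, wx)
  local_mean <- convolve2(m, box)
  # the 1e-8 guard keeps the strict-> tie rule exact under FFT roundoff:
  # a constant image binarizes to background
  m > local_mean + p$offset + 1e-8
}

#' Parameters for large-vessel segmentation
#'
#' @param size_range_um Hessian diameter band restricted to large vessels;
#'   default 30-44 um (the upper part of the enhancement range).
#' @param mean_factor The segmentation threshold is `mean_factor` times the
#'   mean of the combined enhancement image; default 2.
#' @param min_component_px Connected components smaller than this are
#'   discarded as capillary speckle; default 50 px.
#' @param gabor A [gabor_params()] object for the Gabor half of the
#'   enhancement. The default wavelength here is matched to large-vessel
#'   calibre in pixels at the default pitch (large vessels span 2-6 px)
#'   rather than the much coarser plexus-enhancement default, so the
#'   response stays tight around the vessel walls.
#' @return A list of class `large_vessel_params`.
#' @export
large_vessel_params <- function(size_range_um = c(30, 44), mean_factor = 2,
                                min_component_px = 50L,
                                gabor = gabor_params(wavelength_px = 4,
                                                     gamma_aspect = 1)) {
  stopifnot(mean_factor > 0, min_component_px >= 0)
  structure(list(size_range_um = as.numeric(size_range_um),
                 mean_factor = mean_factor,
                 min_component_px = as.integer(min_component_px),
                 gabor = gabor),
            class = "large_vessel_params")
}

#' Segment large retinal vessels
#'
#' Combines Gabor and Hessian enhancement (per-pixel maximum, the Hessian
#' restricted to the large-vessel scale band) to boost vessel contrast,
#' thresholds at `mean_factor x mean` of the enhanced image, and removes
#' small connected components. Typically run on the superficial slab; the
#' resulting mask is reused for the deep slab and for choriocapillaris
#' large-vessel exclusion of the same eye.
#'
#' @param img An [angiogram()], normally the SCP slab.
#' @param p A [large_vessel_params()] object.
#' @param enhanced Optional precomputed enhancement (an `angiogram`), e.g.
#'   to reuse a Gabor response already computed for the same image.
#' @return A logical large-vessel mask.
#' @export
segment_large_vessels <- function(img, p = large_vessel_params(),
                                  enhanced = NULL) {
  if (is.null(enhanced)) {
    g <- gabor_enhance(img, p$gabor)
    h <- hessian_vesselness(img, hessian_params(size_range_um = p$size_range_um))
    e <- pmax(g$pixels, h$pixels)
  } else {
    e <- as_angiogram_matrix(enhanced)
  }
  mu <- mean(e)
  mask <- e > p$mean_factor * mu
  if (p$min_component_px > 1 && any(mask)) {
    mask <- drop_small_components(mask, p$min_component_px, connectivity = 8L)
  }
  mask
}

#' Perfusion density of a vessel mask within a region
#'
#' The percentage of the effective region area (region minus exclusions)
#' covered by vessel pixels.
#'
#' @param vessel Logical vessel mask.
#' @param region Logical region mask (same shape). Defaults to the whole
#'   grid.
#' @param exclusions Optional logical mask of pixels removed from the
#'   denominator (and numerator), e.g. the optic disc.
#' @param ... Metadata columns (e.g. `slab`, `filter`, `region_name`) added
#'   to the returned row.
#' @return A one-row tibble with columns `pd_percent`, `vessel_px`,
#'   `region_px` plus any metadata supplied.
#' @export
#' @examples
#' v <- matrix(FALSE, 10, 10); v[1:5, ] <- TRUE
#' perfusion_density(v)$pd_percent # 50
perfusion_density <- function(vessel, region = NULL, exclusions = NULL, ...) {
  if (is.null(region)) region <- array(TRUE, dim(vessel))
  stopifnot(identical(dim(vessel), dim(region)))
  eff <- region
  if (!is.null(exclusions)) {
    stopifnot(identical(dim(exclusions), dim(region)))
    eff <- eff & !exclusions
  }
  denom <- sum(eff)
  if (denom == 0) stop("effective region is empty", call. = FALSE)
  num <- sum(vessel & eff)
  tibble::tibble(..., pd_percent = 100 * num / denom,
                 vessel_px = num, region_px = denom)
}

# Remove connected components below min_px pixels.
drop_small_components <- function(mask, min_px, connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  array(lab %in% keep, dim(mask))
}
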