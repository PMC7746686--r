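#' En-face angiogram object
#'
#' The universal pipeline input: a 2-D grid of intensities normalized to
#' \[0, 1\] plus the physical pixel pitch and acquisition metadata. Rows run
#' along the slow (y) axis, columns along the fast (x) axis; `pitch_x_um`
#' applies to columns and `pitch_y_um` to rows. The default widefield grid is
#' 800 x 534 pixels covering 15 x 9 mm, i.e. a pitch of (18.75, 16.854)
#' micrometres per pixel.
#'
#' @param pixels Numeric matrix of intensities in \[0, 1\] (rows = y, cols = x).
#' @param pitch_x_um,pitch_y_um Physical pixel pitch in micrometres per pixel.
#' @param slab Slab identity: `"SCP"`, `"DCP"` or `"CC"`.
#' @param subject_id,visit,eye Optional acquisition identifiers.
#' @return An object of class `angiogram`.
#' @export
#' @examples
#' img <- angiogram(matrix(runif(64 * 64), 64, 64), 18.75, 16.854, slab = "SCP")
#' dim(img)
angiogram <- function(pixels, pitch_x_um, pitch_y_um,
                      slab = c("SCP", "DCP", "CC"),
                      subject_id = NA_character_, visit = NA_integer_,
                      eye = NA_character_) {
  slab <- match.arg(slab)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("`pixels` must be finite with no missing values", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("`pixels` must be normalized to [0, 1]", call. = FALSE)
  }
  if (!is.numeric(pitch_x_um) || pitch_x_um <= 0 ||
      !is.numeric(pitch_y_um) || pitch_y_um <= 0) {
    stop("pixel pitch must be a positive number of micrometres", call. = FALSE)
  }
  structure(
    list(pixels = pixels,
         pitch_x_um = as.numeric(pitch_x_um),
         pitch_y_um = as.numeric(pitch_y_um),
         slab = slab, subject_id = subject_id,
         visit = visit, eye = eye),
    class = "angiogram")
}

#' @export
dim.angiogram <- function(x) dim(x$pixels)

#' @export
print.angiogram <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<angiogram> %s slab, %d x %d px (%.2f x %.2f mm), pitch (%.3f, %.3f) um/px\n",
    x$slab, d[2], d[1],
    d[2] * x$pitch_x_um / 1000, d[1] * x$pitch_y_um / 1000,
    x$pitch_x_um, x$pitch_y_um))
  if (!is.na(x$subject_id)) {
    cat(sprintf("  subject %s, visit %s, eye %s\n",
                x$subject_id, x$visit, x$eye))
  }
  invisible(x)
}

# Replace the pixel grid, keeping all metadata. Filters use this so pitch,
# slab and ids survive enhancement.
set_pixels <- function(img, pixels) {
  stopifnot(identical(dim(pixels), dim(img$pixels)))
  img$pixels <- pixels
  img
}

as_angiogram_matrix <- function(img) {
  if (inherits(img, "angiogram")) img$pixels
  else if (is.matrix(img)) img
  else stop("expected an `angiogram` or a matrix", call. = FALSE)
}

#' Convert an angiogram to a long tibble of pixel records
#'
#' One row per pixel with 0-based `row`/`col` indices, physical coordinates in
#' micrometres (pixel centres, origin at the top-left pixel centre) and the
#' intensity. Mainly useful for ggplot2 display and spot checks; image-scale
#' processing stays on the matrix.
#'
#' @param x An `angiogram`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x_um`, `y_um`, `intensity`.
#' @method as_tibble angiogram
#' @export
as_tibble.angiogram <- function(x, ...) {
  d <- dim(x$pixels)
  tibble::tibble(
    row = rep(seq_len(d[1]) - 1L, times = d[2]),
    col = rep(seq_len(d[2]) - 1L, each = d[1]),
    x_um = (rep(seq_len(d[2]) - 1L, each = d[1])) * x$pitch_x_um,
    y_um = (rep(seq_len(d[1]) - 1L, times = d[2])) * x$pitch_y_um,
    intensity = as.vector(x$pixels))
}

#' Display an angiogram or binary mask
#'
#' @param object An `angiogram` or logical matrix.
#' @param downsample Keep every `downsample`-th pixel on each axis (display
#'   only; 1 keeps all).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot angiogram
#' @export
autoplot.angiogram <- function(object, downsample = 2L, ...) {
  px <- object$pixels
  keep_r <- seq(1L, nrow(px), by = downsample)
  keep_c <- seq(1L, ncol(px), by = downsample)
  df <- tibble::tibble(
    col = rep(keep_c, each = length(keep_r)),
    row = rep(keep_r, times = length(keep_c)),
    intensity = as.vector(px[keep_r, keep_c]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed(ratio = object$pitch_y_um / object$pitch_x_um) +
    ggplot2::labs(x = "column (px)", y = "row (px)", fill = "intensity",
                  title = sprintf("%s slab", object$slab)) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
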