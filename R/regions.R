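#' Macular / peripheral region partition
#'
#' Builds the fovea-centred macular rectangle (default 6 x 6 mm) and its
#' peripheral complement on a pixel grid. A pixel belongs to the macula iff
#' its centre lies in the half-open square
#' `[centre - size/2, centre + size/2)` on each physical axis; the half-open
#' rule makes the two regions an exact partition with no double-counted
#' border pixels. Coordinates are 0-based (row, col) throughout the package.
#'
#' @param shape Integer vector `c(rows, cols)` of the grid.
#' @param pitch_x_um,pitch_y_um Pixel pitch in micrometres.
#' @param fovea_center_px Fovea centre as `c(row, col)` in 0-based pixel
#'   coordinates (fractional allowed). Defaults to the geometric image
#'   centre, matching a fovea-centred scan.
#' @param macula_size_mm Side of the macular square in millimetres.
#' @return A list of class `region_partition` with logical masks `macula`
#'   and `periphery` and the centre used.
#' @export
#' @examples
#' part <- make_partition(c(534, 800), 18.75, 9000 / 534)
#' sum(part$macula) + sum(part$periphery) == 534 * 800
make_partition <- function(shape, pitch_x_um, pitch_y_um,
                           fovea_center_px = (shape - 1) / 2,
                           macula_size_mm = 6) {
  stopifnot(length(shape) == 2, all(shape >= 1),
            pitch_x_um > 0, pitch_y_um > 0, macula_size_mm > 0)
  half_um <- macula_size_mm * 1000 / 2
  row_um <- (seq_len(shape[1]) - 1 - fovea_center_px[1]) * pitch_y_um
  col_um <- (seq_len(shape[2]) - 1 - fovea_center_px[2]) * pitch_x_um
  in_rows <- row_um >= -half_um & row_um < half_um
  in_cols <- col_um >= -half_um & col_um < half_um
  if (!any(in_rows) || !any(in_cols)) {
    stop("macular rectangle lies outside the grid", call. = FALSE)
  }
  # the rectangle must fit within the outer pixel boundaries of the grid
  tol <- 1e-9
  if (-half_um < row_um[1] - pitch_y_um / 2 - tol ||
      half_um > row_um[shape[1]] + pitch_y_um / 2 + tol ||
      -half_um < col_um[1] - pitch_x_um / 2 - tol ||
      half_um > col_um[shape[2]] + pitch_x_um / 2 + tol) {
    stop("macular rectangle exceeds the image bounds", call. = FALSE)
  }
  macula <- outer(in_rows, in_cols, `&`)
  structure(list(macula = macula, periphery = !macula,
                 fovea_center_px = as.numeric(fovea_center_px),
                 macula_size_mm = macula_size_mm),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf(
    "<region_partition> %.1f x %.1f mm macula at (%.1f, %.1f): %d macular px, %d peripheral px\n",
    x$macula_size_mm, x$macula_size_mm,
    x$fovea_center_px[1], x$fovea_center_px[2],
    sum(x$macula), sum(x$periphery)))
  invisible(x)
}

#' Rasterize a circular optic-disc mask
#'
#' A pixel is in the disc iff its centre lies within `radius_px` of the
#' given centre (0-based row/col, fractional allowed).
#'
#' @param shape Grid shape `c(rows, cols)`.
#' @param center_px Disc centre `c(row, col)`.
#' @param radius_px Disc radius in pixels; 0 gives an empty mask.
#' @return A logical mask.
#' @export
disc_mask <- function(shape, center_px, radius_px) {
  stopifnot(radius_px >= 0)
  if (radius_px == 0) return(array(FALSE, shape))
  dr <- (seq_len(shape[1]) - 1 - center_px[1])^2
  dc <- (seq_len(shape[2]) - 1 - center_px[2])^2
  outer(dr, dc, `+`) <= radius_px^2
}

#' Load a binary mask, drawing it if given a circle spec
#'
#' @param source Either a path to a `{0, 255}` PNG mask, or a list
#'   `list(center_px = c(row, col), radius_px = r)` rasterized with
#'   [disc_mask()].
#' @param shape Expected grid shape; a mismatching file is an error.
#' @return A logical mask.
#' @export
load_or_draw_disc_mask <- function(source, shape) {
  if (is.character(source)) {
    m <- read_mask(source)
    if (!identical(dim(m), as.integer(shape))) {
      stop(sprintf("mask shape %d x %d does not match grid %d x %d",
                   nrow(m), ncol(m), shape[1], shape[2]), call. = FALSE)
    }
    m
  } else if (is.list(source)) {
    disc_mask(shape, source$center_px, source$radius_px)
  } else {
    stop("source must be a file path or a circle spec list", call. = FALSE)
  }
}
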