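#' Read a grayscale angiogram image
#'
#' Supports 8/16-bit grayscale TIFF and PNG. Intensities are normalized to
#' \[0, 1\] on read. Pixel pitch is never trusted from image headers: it
#' must come from the manifest or configuration.
#'
#' @param path Image path (`.tif`, `.tiff` or `.png`).
#' @param pitch_x_um,pitch_y_um Pixel pitch in micrometres.
#' @param slab,subject_id,visit,eye Metadata to attach.
#' @return An [angiogram()].
#' @export
read_image <- function(path, pitch_x_um, pitch_y_um, slab = "SCP",
                       subject_id = NA_character_, visit = NA_integer_,
                       eye = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               tif = , tiff = tiff::readTIFF(path),
               png = png::readPNG(path),
               stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(px)) == 3) px <- px[, , 1] # collapse grayscale-as-RGB
  angiogram(px, pitch_x_um, pitch_y_um, slab = slab, subject_id = subject_id,
            visit = visit, eye = eye)
}

#' Write a grayscale angiogram image
#'
#' @param img An [angiogram()] or numeric matrix in \[0, 1\].
#' @param path Destination path (`.tif`/`.tiff` for 16-bit TIFF, `.png` for
#'   PNG).
#' @param bits Bits per sample for TIFF output (8 or 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 16L) {
  px <- as_angiogram_matrix(img)
  # quantize so the written file round-trips exactly
  levels <- 2^bits - 1
  px <- round(px * levels) / levels
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = tiff::writeTIFF(px, path, bits.per.sample = bits),
         png = png::writePNG(px, path),
         stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Read a binary mask from a 0/255 PNG
#'
#' @param path PNG path.
#' @return A logical matrix (`TRUE` where the file is > 0.5).
#' @export
read_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  px > 0.5
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask Logical matrix.
#' @param path Destination PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

manifest_required_cols <- c("subject_id", "visit", "eye", "slab",
                            "image_path", "pitch_x_um", "pitch_y_um")

#' Read and validate a cohort manifest
#'
#' The manifest maps subject / visit / eye / slab to an image file and its
#' physical pitch; optional columns `fovea_row`, `fovea_col` and
#' `disc_mask_path` override per-image geometry. Relative image paths are
#' resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @param check_files If `TRUE` (default), error on missing image files.
#' @return A tibble.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  mf <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(manifest_required_cols, names(mf))
  if (length(missing_cols) > 0) {
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyNA(mf$pitch_x_um) || anyNA(mf$pitch_y_um) ||
      any(mf$pitch_x_um <= 0) || any(mf$pitch_y_um <= 0)) {
    stop("manifest pitch_x_um / pitch_y_um must be positive and complete",
         call. = FALSE)
  }
  root <- dirname(path)
  mf$image_path <- ifelse(file.path_is_absolute(mf$image_path),
                          mf$image_path, file.path(root, mf$image_path))
  if (check_files) {
    missing_files <- mf$image_path[!file.exists(mf$image_path)]
    if (length(missing_files) > 0) {
      stop("manifest references missing file(s): ",
           paste(utils::head(missing_files, 3), collapse = ", "),
           call. = FALSE)
    }
  }
  mf
}

file.path_is_absolute <- function(p) grepl("^(/|[A-Za-z]:)", p)

#' Write a result table with a fixed column order
#'
#' @param x A data frame.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
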