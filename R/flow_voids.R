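#' Parameters for choriocapillaris flow-void detection
#'
#' @param k_sd Threshold multiplier: the inverted angiogram is thresholded
#'   at mean + `k_sd` x SD over the analysable region. The reference
#'   settings are 1 and 1.25.
#' @param connectivity Component connectivity, 4 or 8 (default 8).
#' @param min_component_px Components smaller than this are discarded
#'   (default 1, i.e. keep all).
#' @param stats_over `"analysable"` (default) computes the threshold mean/SD
#'   over the analysable region only; `"image"` uses the whole frame.
#' @return A list of class `flow_void_params`.
#' @export
flow_void_params <- function(k_sd = 1, connectivity = 8L,
                             min_component_px = 1L,
                             stats_over = c("analysable", "image")) {
  stats_over <- match.arg(stats_over)
  stopifnot(k_sd > 0, connectivity %in% c(4L, 8L), min_component_px >= 1)
  structure(list(k_sd = k_sd, connectivity = as.integer(connectivity),
                 min_component_px = as.integer(min_component_px),
                 stats_over = stats_over),
            class = "flow_void_params")
}

#' Prepare a choriocapillaris slab for flow-void analysis
#'
#' Removes large vessels (segmented from the superficial slab of the same
#' eye) and the optic disc from the analysable area. The image itself is
#' unchanged.
#'
#' @param img The CC [angiogram()].
#' @param large_vessels Optional logical mask of large vessels to exclude.
#' @param disc Optional logical optic-disc mask to exclude.
#' @return A list with the unchanged `img` and the logical `analysable`
#'   mask.
#' @export
prepare_cc <- function(img, large_vessels = NULL, disc = NULL) {
  shape <- dim(img$pixels)
  analysable <- array(TRUE, shape)
  if (!is.null(large_vessels)) {
    stopifnot(identical(dim(large_vessels), shape))
    analysable <- analysable & !large_vessels
  }
  if (!is.null(disc)) {
    stopifnot(identical(dim(disc), shape))
    analysable <- analysable & !disc
  }
  if (!any(analysable)) stop("empty analysable region", call. = FALSE)
  list(img = img, analysable = analysable)
}

# Connected-component labeling at 4 or 8 connectivity. EBImage::bwlabel is
# 4-connected; 8-connectivity merges diagonally adjacent 4-labels with a
# union-find pass over the (small) label adjacency set.
label_components <- function(mask, connectivity = 8L) {
  storage.mode(mask) <- "integer"
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (connectivity == 4L || n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]   # down-right diagonal pairs
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]  # up-right diagonal pairs
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  dense <- match(root, sort(unique(root)))
  lab[lab > 0L] <- dense[lab[lab > 0L]]
  lab
}

#' Detect choriocapillaris flow voids by SD thresholding
#'
#' Inverts the angiogram (`1 - intensity`), thresholds at
#' `mean + k_sd x SD` (population SD) computed over the analysable region,
#' and labels the surviving pixels into connected components. Per region,
#' reports the flow-void area percentage (void pixels over analysable
#' region pixels), the number of voids (components assigned to the region
#' by majority pixel membership, ties to the macula), and the mean void
#' size in square micrometres (total assigned component area over count).
#'
#' @param img The CC [angiogram()].
#' @param analysable Logical mask of analysable pixels (see [prepare_cc()]);
#'   defaults to the whole grid.
#' @param p A [flow_void_params()] object.
#' @param partition Optional [make_partition()] result; when supplied the
#'   metrics are reported for `macula` and `periphery` in addition to
#'   `whole`.
#' @return A list with the logical `void_mask` and a tibble `metrics` with
#'   columns `region`, `k_sd`, `area_percent`, `count`, `mean_size_um2`.
#' @export
detect_flow_voids <- function(img, analysable = NULL, p = flow_void_params(),
                              partition = NULL) {
  m <- img$pixels
  shape <- dim(m)
  if (is.null(analysable)) analysable <- array(TRUE, shape)
  stopifnot(identical(dim(analysable), shape))
  if (!any(analysable)) stop("empty analysable region", call. = FALSE)
  inv <- 1 - m
  vals <- if (p$stats_over == "analysable") inv[analysable] else as.vector(inv)
  mu <- mean(vals)
  sd_pop <- sqrt(mean((vals - mu)^2))
  if (sd_pop == 0) {
    message("constant image over analysable region: no pixel exceeds the threshold")
  }
  thr <- mu + p$k_sd * sd_pop
  # 1e-12 tie guard: a constant region yields zero voids by the strict ">"
  voids <- (inv > thr + 1e-12) & analysable
  lab <- label_components(voids, p$connectivity)
  if (p$min_component_px > 1L && max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= p$min_component_px)
    voids <- array(lab %in% keep, shape)
    lab <- label_components(voids, p$connectivity)
  }
  px_um2 <- img$pitch_x_um * img$pitch_y_um
  regions <- list(whole = array(TRUE, shape))
  if (!is.null(partition)) {
    regions$macula <- partition$macula
    regions$periphery <- partition$periphery
  }
  n_comp <- max(lab)
  comp_region <- NULL
  if (n_comp > 0L && !is.null(partition)) {
    # majority membership; exact ties go to the macula
    in_mac <- tabulate(lab[lab > 0L & partition$macula], nbins = n_comp)
    tot <- tabulate(lab[lab > 0L], nbins = n_comp)
    comp_region <- ifelse(in_mac * 2L >= tot, "macula", "periphery")
  }
  metrics <- purrr::map_dfr(names(regions), function(rn) {
    R <- regions[[rn]]
    denom <- sum(R & analysable)
    area_pc <- if (denom > 0) 100 * sum(voids & R & analysable) / denom else NA_real_
    if (n_comp == 0L) {
      cnt <- 0L; mean_sz <- 0
    } else if (rn == "whole") {
      cnt <- n_comp
      mean_sz <- sum(voids) * px_um2 / cnt
    } else {
      idx <- which(comp_region == rn)
      cnt <- length(idx)
      tot_px <- sum(tabulate(lab[lab > 0L], nbins = n_comp)[idx])
      mean_sz <- if (cnt > 0) tot_px * px_um2 / cnt else 0
    }
    tibble::tibble(region = rn, k_sd = p$k_sd, area_percent = area_pc,
                   count = cnt, mean_size_um2 = mean_sz)
  })
  list(void_mask = voids, labels = lab, threshold = thr, metrics = metrics)
}

#' Dice overlap between detected and ground-truth flow voids
#'
#' @param truth Logical ground-truth void mask.
#' @param detected Logical detected void mask.
#' @return A one-row tibble with `dice`, `count_ratio` (detected / true
#'   component counts, 8-connectivity) and the two pixel areas.
#' @export
flow_void_recovery <- function(truth, detected) {
  stopifnot(identical(dim(truth), dim(detected)))
  inter <- sum(truth & detected)
  denom <- sum(truth) + sum(detected)
  dice <- if (denom == 0) 1 else 2 * inter / denom
  n_true <- max(label_components(truth, 8L))
  n_det <- max(label_components(detected, 8L))
  tibble::tibble(dice = dice,
                 count_ratio = if (n_true > 0) n_det / n_true else NA_real_,
                 true_px = sum(truth), detected_px = sum(detected))
}
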