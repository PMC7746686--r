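#' Default pipeline configuration
#'
#' Every physical quantity carries its unit in the key name. Unknown keys
#' in a user configuration are rejected.
#'
#' @param manifest Path to the cohort manifest CSV.
#' @param out_dir Output directory for CSVs.
#' @param filters Enhancement variants to evaluate on the plexus slabs.
#' @param window_mm Adaptive-binarization window.
#' @param binarize_offset Offset added to the local mean.
#' @param k_sd Flow-void threshold multipliers.
#' @param connectivity Flow-void component connectivity (4 or 8).
#' @param min_component_px Minimum flow-void component size.
#' @param macula_size_mm Side of the macular square.
#' @param large_vessel_mean_factor Threshold factor for large-vessel
#'   segmentation.
#' @param alpha Repeatability CI level is `1 - alpha`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, out_dir,
                            filters = c("none", "hessian", "gabor", "bayesian"),
                            window_mm = 1.25, binarize_offset = 0,
                            k_sd = c(1, 1.25), connectivity = 8L,
                            min_component_px = 1L, macula_size_mm = 6,
                            large_vessel_mean_factor = 2, alpha = 0.05) {
  filters <- match.arg(filters, several.ok = TRUE)
  structure(list(manifest = manifest, out_dir = out_dir, filters = filters,
                 window_mm = window_mm, binarize_offset = binarize_offset,
                 k_sd = k_sd, connectivity = as.integer(connectivity),
                 min_component_px = as.integer(min_component_px),
                 macula_size_mm = macula_size_mm,
                 large_vessel_mean_factor = large_vessel_mean_factor,
                 alpha = alpha),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()]; unknown keys are an error.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

# Measure one eye-visit: large-vessel PD from the SCP, filtered PD on both
# plexus slabs, flow voids on the CC. Returns long-format metric rows.
measure_visit <- function(images, config, partition) {
  rows <- list()
  regions <- list(macula = partition$macula, periphery = partition$periphery)
  lv_mask <- NULL
  scp <- images[["SCP"]]
  if (!is.null(scp)) {
    lvp <- large_vessel_params(mean_factor = config$large_vessel_mean_factor)
    gab <- gabor_enhance(scp, lvp$gabor)
    hes <- hessian_vesselness(scp, hessian_params(size_range_um = lvp$size_range_um))
    lv_mask <- segment_large_vessels(scp, lvp,
                                     enhanced = pmax(gab$pixels, hes$pixels))
    for (rn in names(regions)) {
      pd <- perfusion_density(lv_mask, regions[[rn]])
      rows[[length(rows) + 1]] <- tibble::tibble(
        slab = "SCP", metric = "pd_large", region = rn, variant = "combined",
        value = pd$pd_percent)
    }
  }
  bp <- binarize_params(window_mm = config$window_mm,
                        offset = config$binarize_offset)
  for (slab in intersect(c("SCP", "DCP"), names(images))) {
    img <- images[[slab]]
    for (f in config$filters) {
      enhanced <- apply_filter(img, f)
      vm <- local_adaptive_binarize(enhanced, bp)
      for (rn in names(regions)) {
        pd <- perfusion_density(vm, regions[[rn]])
        rows[[length(rows) + 1]] <- tibble::tibble(
          slab = slab, metric = paste0("pd_", tolower(slab)), region = rn,
          variant = f, value = pd$pd_percent)
      }
    }
  }
  cc <- images[["CC"]]
  if (!is.null(cc)) {
    disc <- attr(cc, "disc_mask")
    prep <- prepare_cc(cc, large_vessels = lv_mask, disc = disc)
    for (k in config$k_sd) {
      fv <- detect_flow_voids(prep$img, prep$analysable,
                              flow_void_params(k_sd = k,
                                               connectivity = config$connectivity,
                                               min_component_px = config$min_component_px),
                              partition = partition)
      mm <- fv$metrics[fv$metrics$region != "whole", ]
      for (i in seq_len(nrow(mm))) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          slab = "CC",
          metric = c("fv_area", "fv_count", "fv_size"),
          region = mm$region[i], variant = format(k),
          value = c(mm$area_percent[i], as.numeric(mm$count[i]),
                    mm$mean_size_um2[i]))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full post-processing pipeline over a cohort
#'
#' For every subject and visit in the manifest: segments large vessels on
#' the superficial slab and measures their perfusion density; applies each
#' enhancement filter to the superficial and deep slabs, binarizes by local
#' adaptive thresholding and measures perfusion density; detects
#' choriocapillaris flow voids at each threshold multiplier (large vessels
#' and optic disc excluded); all metrics are reported for the macular and
#' peripheral regions. Finally computes the inter-visit repeatability
#' report. The run is deterministic: identical inputs and configuration
#' give byte-identical CSVs. A subject whose images fail to process is
#' dropped from the paired statistics and reported in `failures`.
#'
#' @param config A [pipeline_config()] or the path to a YAML file for
#'   [read_config()].
#' @return A list with tibbles `metrics`, `report`, `ba_points` and
#'   `failures`; also written to `out_dir` as `metrics.csv`, `report.csv`,
#'   `ba_points.csv`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  mf <- read_manifest(config$manifest)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  keys <- mf |> dplyr::distinct(.data$subject_id, .data$visit)
  metric_rows <- list(); failures <- list()
  for (i in seq_len(nrow(keys))) {
    sid <- keys$subject_id[i]; v <- keys$visit[i]
    sub <- mf[mf$subject_id == sid & mf$visit == v, ]
    res <- tryCatch({
      images <- list()
      for (j in seq_len(nrow(sub))) {
        img <- read_image(sub$image_path[j], sub$pitch_x_um[j],
                          sub$pitch_y_um[j], slab = sub$slab[j],
                          subject_id = sid, visit = v, eye = sub$eye[j])
        if ("disc_mask_path" %in% names(sub) &&
            !is.na(sub$disc_mask_path[j]) && nzchar(sub$disc_mask_path[j])) {
          attr(img, "disc_mask") <- read_mask(sub$disc_mask_path[j])
        }
        images[[sub$slab[j]]] <- img
      }
      ref <- images[[1]]
      fovea <- if (all(c("fovea_row", "fovea_col") %in% names(sub)) &&
                   !anyNA(sub[1, c("fovea_row", "fovea_col")])) {
        c(sub$fovea_row[1], sub$fovea_col[1])
      } else (dim(ref$pixels) - 1) / 2
      partition <- make_partition(dim(ref$pixels), ref$pitch_x_um,
                                  ref$pitch_y_um, fovea_center_px = fovea,
                                  macula_size_mm = config$macula_size_mm)
      measure_visit(images, config, partition) |>
        dplyr::mutate(subject = sid, visit = v, .before = 1)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- tibble::tibble(
        subject = sid, visit = v, error = conditionMessage(res))
    } else {
      metric_rows[[length(metric_rows) + 1]] <- res
    }
  }
  metrics <- dplyr::bind_rows(metric_rows)
  failures <- if (length(failures) > 0) dplyr::bind_rows(failures) else
    tibble::tibble(subject = character(), visit = integer(), error = character())
  # subjects with a failed visit are excluded from paired statistics
  if (nrow(failures) > 0) {
    metrics_paired <- metrics[!(metrics$subject %in% failures$subject), ]
  } else metrics_paired <- metrics
  reference <- c(pd_scp = "none", pd_dcp = "none",
                 fv_area = format(config$k_sd[1]),
                 fv_count = format(config$k_sd[1]),
                 fv_size = format(config$k_sd[1]))
  report <- build_report(metrics_paired, reference = reference,
                         alpha = config$alpha)
  ba_points <- metrics_paired |>
    tidyr::pivot_wider(id_cols = c("subject", "slab", "metric", "region",
                                   "variant"),
                       names_from = "visit", values_from = "value",
                       names_prefix = "v") |>
    dplyr::mutate(mean = (.data$v1 + .data$v2) / 2,
                  diff = .data$v1 - .data$v2)
  write_table(metrics, file.path(config$out_dir, "metrics.csv"))
  write_table(report, file.path(config$out_dir, "report.csv"))
  write_table(ba_points, file.path(config$out_dir, "ba_points.csv"))
  if (nrow(failures) > 0) {
    write_table(failures, file.path(config$out_dir, "failures.csv"))
  }
  list(metrics = metrics, report = report, ba_points = ba_points,
       failures = failures)
}
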