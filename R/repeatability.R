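#' Paired (dependent) t-test with degenerate-variance guard
#'
#' Classical two-sided paired t-test on visit differences with
#' `df = n - 1`. When the differences have zero variance the test statistic
#' is undefined: identical visits are reported as `p = 1` and flagged; a
#' constant non-zero difference is flagged as degenerate with `p = NA`.
#'
#' @param visit1,visit2 Numeric vectors of paired measurements (n >= 3).
#' @return A one-row tibble with `n`, `mean_diff`, `t`, `df`, `p_value`,
#'   `degenerate` (logical flag).
#' @export
#' @examples
#' paired_t_test(c(1, 2, 3, 4), c(1.1, 2.2, 2.9, 4.3))
paired_t_test <- function(visit1, visit2) {
  stopifnot(length(visit1) == length(visit2))
  if (anyNA(visit1) || anyNA(visit2)) stop("missing values not allowed", call. = FALSE)
  n <- length(visit1)
  if (n < 3) stop("need at least 3 paired measurements", call. = FALSE)
  d <- visit1 - visit2
  if (stats::sd(d) == 0) {
    p <- if (mean(d) == 0) 1 else NA_real_
    return(tibble::tibble(n = n, mean_diff = mean(d), t = NA_real_,
                          df = n - 1, p_value = p, degenerate = TRUE))
  }
  tt <- stats::t.test(visit1, visit2, paired = TRUE)
  tibble::tibble(n = n, mean_diff = unname(tt$estimate),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, degenerate = FALSE)
}

icc_band <- function(icc) {
  # banded interpretation: <0.50 poor, 0.50-0.75 moderate, 0.75-0.90 good,
  # >0.90 excellent (exactly 0.90 falls in "good")
  if (is.na(icc)) NA_character_
  else if (icc < 0.50) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc <= 0.90) "good"
  else "excellent"
}

#' Two-way random-effects ICC for inter-visit repeatability
#'
#' ICC(2,1): two-way random effects, absolute agreement, single
#' measurement. Computed from the two-way ANOVA mean squares
#' (subjects x visits, fitted with [stats::aov()]):
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#' The confidence interval uses the F-based method of McGraw and Wong.
#' Absolute agreement penalizes a systematic shift between visits, which is
#' the appropriate notion when the same device rescans the same eye.
#'
#' @param visit1,visit2 Paired measurements, or a matrix `n x k` of ratings
#'   passed as `visit1` with `visit2 = NULL` (k >= 2 raters/visits).
#' @param alpha CI level is `1 - alpha` (default 95%).
#' @return An object of class `icc_fit`; see [tidy.icc_fit()].
#' @export
#' @examples
#' fit <- icc_two_way(c(7, 8, 9, 10), c(7.1, 8.2, 8.8, 10.3))
#' glance(fit)
icc_two_way <- function(visit1, visit2 = NULL, alpha = 0.05) {
  ratings <- if (is.null(visit2)) as.matrix(visit1) else cbind(visit1, visit2)
  if (anyNA(ratings)) stop("missing values not allowed", call. = FALSE)
  ns <- nrow(ratings); nr <- ncol(ratings)
  if (ns < 3) stop("need at least 3 subjects", call. = FALSE)
  if (nr < 2) stop("need at least 2 visits", call. = FALSE)
  degenerate <- FALSE
  if (stats::var(as.vector(ratings)) == 0) {
    # all values identical: perfect agreement by convention
    fit <- list(icc = 1, ci = c(1, 1), band = "excellent", n = ns, k = nr,
                ms = c(msr = 0, msc = 0, mse = 0), alpha = alpha,
                degenerate = TRUE)
    class(fit) <- "icc_fit"
    return(fit)
  }
  df <- data.frame(value = as.vector(ratings),
                   subject = factor(rep(seq_len(ns), times = nr)),
                   rater = factor(rep(seq_len(nr), each = ns)))
  aov_fit <- stats::aov(value ~ subject + rater, data = df)
  ms <- summary(aov_fit)[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc <- (msr - mse) / (msr + (nr - 1) * mse + nr / ns * (msc - mse))
  denom_spread <- nr * msc + (nr * ns - nr - ns) * mse
  if (msc + mse <= 1e-10 * msr || icc >= 1 - 1e-12) {
    # visits agree to numerical precision: the F-based CI collapses
    if (abs(icc - 1) < 1e-9) icc <- 1
    ci <- c(icc, icc)
    degenerate <- TRUE
  } else {
    a <- (nr * icc) / (ns * (1 - icc))
    b <- 1 + (nr * icc * (ns - 1)) / (ns * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (nr - 1) + (b * mse)^2 / ((ns - 1) * (nr - 1)))
    fl <- stats::qf(1 - alpha / 2, ns - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, ns - 1)
    lo <- ns * (msr - fl * mse) / (fl * denom_spread + ns * msr)
    hi <- ns * (fu * msr - mse) / (denom_spread + ns * fu * msr)
    ci <- c(lo, hi)
  }
  fit <- list(icc = icc, ci = ci, band = icc_band(icc), n = ns, k = nr,
              ms = c(msr = msr, msc = msc, mse = mse), alpha = alpha,
              degenerate = degenerate)
  class(fit) <- "icc_fit"
  fit
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f (%d%% CI %.3f to %.3f), %s repeatability; n = %d, k = %d\n",
              x$icc, round(100 * (1 - x$alpha)), x$ci[1], x$ci[2],
              x$band, x$n, x$k))
  if (x$degenerate) cat("  note: degenerate variance structure\n")
  invisible(x)
}

#' Tidy an ICC fit
#'
#' @param x An `icc_fit` from [icc_two_way()].
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `conf.low`, `conf.high`,
#'   `band`.
#' @method tidy icc_fit
#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(term = "ICC(2,1)", estimate = x$icc,
                 conf.low = x$ci[1], conf.high = x$ci[2], band = x$band)
}

#' One-row model summary of an ICC fit
#'
#' @inheritParams tidy.icc_fit
#' @return A one-row tibble with the estimate, CI, band, ANOVA mean squares
#'   and sizes.
#' @method glance icc_fit
#' @export
glance.icc_fit <- function(x, ...) {
  tibble::tibble(icc = x$icc, conf.low = x$ci[1], conf.high = x$ci[2],
                 band = x$band, msr = x$ms[["msr"]], msc = x$ms[["msc"]],
                 mse = x$ms[["mse"]], n = x$n, k = x$k,
                 degenerate = x$degenerate)
}

#' Bland-Altman agreement analysis
#'
#' Differences are `visit1 - visit2` by default. Limits of agreement are
#' `mean(d) +/- 1.96 x sample SD(d)`.
#'
#' @param visit1,visit2 Paired measurements (n >= 2; the SD of the
#'   differences must be defined).
#' @param orientation `"v1_minus_v2"` (default) or `"v2_minus_v1"`.
#' @return An object of class `bland_altman` with `mean_diff`, `loa_lo`,
#'   `loa_hi` and a tibble `points` of (mean, difference) pairs.
#' @export
#' @examples
#' ba <- bland_altman(c(10, 11, 12), c(10.2, 10.9, 12.1))
#' ba$loa_hi
bland_altman <- function(visit1, visit2,
                         orientation = c("v1_minus_v2", "v2_minus_v1")) {
  orientation <- match.arg(orientation)
  stopifnot(length(visit1) == length(visit2))
  if (length(visit1) < 2) stop("need at least 2 paired measurements", call. = FALSE)
  d <- if (orientation == "v1_minus_v2") visit1 - visit2 else visit2 - visit1
  md <- mean(d)
  s <- stats::sd(d)
  out <- list(mean_diff = md, loa_lo = md - 1.96 * s, loa_hi = md + 1.96 * s,
              sd_diff = s, orientation = orientation,
              points = tibble::tibble(mean = (visit1 + visit2) / 2, diff = d))
  class(out) <- "bland_altman"
  out
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s): mean difference %.4g, 95%% LoA [%.4g, %.4g], n = %d\n",
              x$orientation, x$mean_diff, x$loa_lo, x$loa_hi, nrow(x$points)))
  invisible(x)
}

#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, loa_lo = x$loa_lo,
                 loa_hi = x$loa_hi, sd_diff = x$sd_diff)
}

#' Bland-Altman plot
#'
#' @param object A [bland_altman()] object.
#' @param ... Unused.
#' @return A ggplot: per-subject (mean, difference) points with the mean
#'   difference (solid) and 95% limits of agreement (dashed).
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_diff) +
    ggplot2::geom_hline(yintercept = c(object$loa_lo, object$loa_hi),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of visits", y = "Difference between visits") +
    ggplot2::theme_minimal()
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Numeric vectors (n >= 4), e.g. a filtered metric against the
#'   original-scan metric.
#' @param alpha CI level is `1 - alpha`.
#' @return A one-row tibble with `r`, `conf.low`, `conf.high`, `p_value`,
#'   `n`.
#' @export
pearson_with_ci <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need at least 4 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, conf.level = 1 - alpha)
  tibble::tibble(r = unname(ct$estimate), conf.low = ct$conf.int[1],
                 conf.high = ct$conf.int[2], p_value = ct$p.value,
                 n = length(x))
}

#' Build the per-metric repeatability report
#'
#' Takes long-format paired-visit measurements and produces one row per
#' (metric, region, variant) with the averaged-visit mean (SD), the paired-t
#' p-value, ICC(2,1) with CI and band, Bland-Altman mean difference and
#' limits of agreement, and the Pearson correlation of each variant against
#' the designated reference variant (computed on per-subject two-visit
#' averages; the reference row itself gets NA).
#'
#' @param data A data frame with columns `subject`, `visit` (two distinct
#'   values), `metric`, `region`, `variant`, `value`.
#' @param reference Named character vector mapping metric -> reference
#'   variant, or a single variant name used for all metrics, or `NULL` for
#'   no Pearson column.
#' @param alpha CI level is `1 - alpha`.
#' @return A tibble with one row per (metric, region, variant).
#' @export
build_report <- function(data, reference = NULL, alpha = 0.05) {
  req <- c("subject", "visit", "metric", "region", "variant", "value")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  visits <- sort(unique(data$visit))
  if (length(visits) != 2) stop("exactly two visits required", call. = FALSE)
  wide <- data |>
    dplyr::mutate(visit = ifelse(.data$visit == visits[1], "v1", "v2")) |>
    tidyr::pivot_wider(id_cols = c("subject", "metric", "region", "variant"),
                       names_from = "visit", values_from = "value") |>
    dplyr::filter(!is.na(.data$v1) & !is.na(.data$v2)) |>
    dplyr::mutate(avg = (.data$v1 + .data$v2) / 2)

  ref_for <- function(metric) {
    if (is.null(reference)) NA_character_
    else if (length(reference) == 1 && is.null(names(reference))) reference
    else if (metric %in% names(reference)) reference[[metric]]
    else NA_character_
  }

  groups <- wide |> dplyr::distinct(.data$metric, .data$region, .data$variant)
  purrr::pmap_dfr(groups, function(metric, region, variant) {
    g <- wide[wide$metric == metric & wide$region == region &
                wide$variant == variant, ]
    if (nrow(g) < 3) {
      # too few paired subjects for inference; report descriptives only
      return(tibble::tibble(
        metric = metric, region = region, variant = variant, n = nrow(g),
        mean_avg = mean(g$avg), sd_avg = stats::sd(g$avg),
        t_p_value = NA_real_, t_degenerate = NA,
        icc = NA_real_, icc_lo = NA_real_, icc_hi = NA_real_,
        icc_band = NA_character_,
        mean_diff = mean(g$v1 - g$v2), loa_lo = NA_real_, loa_hi = NA_real_,
        pearson_r = NA_real_, pearson_lo = NA_real_, pearson_hi = NA_real_,
        pearson_p = NA_real_))
    }
    tt <- paired_t_test(g$v1, g$v2)
    fit <- icc_two_way(g$v1, g$v2, alpha = alpha)
    ba <- bland_altman(g$v1, g$v2)
    ref <- ref_for(metric)
    pear <- if (!is.na(ref) && variant != ref) {
      r <- wide[wide$metric == metric & wide$region == region &
                  wide$variant == ref, ]
      if (nrow(r) == 0) stop("missing reference variant '", ref, "'",
                             call. = FALSE)
      common <- intersect(g$subject, r$subject)
      if (length(common) >= 4) {
        pearson_with_ci(g$avg[match(common, g$subject)],
                        r$avg[match(common, r$subject)], alpha = alpha)
      } else {
        tibble::tibble(r = NA_real_, conf.low = NA_real_,
                       conf.high = NA_real_, p_value = NA_real_,
                       n = length(common))
      }
    } else {
      tibble::tibble(r = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
                     p_value = NA_real_, n = NA_integer_)
    }
    tibble::tibble(
      metric = metric, region = region, variant = variant, n = nrow(g),
      mean_avg = mean(g$avg), sd_avg = stats::sd(g$avg),
      t_p_value = tt$p_value, t_degenerate = tt$degenerate,
      icc = fit$icc, icc_lo = fit$ci[1], icc_hi = fit$ci[2],
      icc_band = fit$band,
      mean_diff = ba$mean_diff, loa_lo = ba$loa_lo, loa_hi = ba$loa_hi,
      pearson_r = pear$r, pearson_lo = pear$conf.low,
      pearson_hi = pear$conf.high, pearson_p = pear$p_value)
  })
}
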