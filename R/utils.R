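# Internal numerical helpers shared across modules.

# Reflect-pad a matrix by (py, px) pixels on each side. Reflection is about
# the edge pixel (no repeated border sample), the usual "symmetric" rule.
pad_reflect <- function(m, py, px) {
  nr <- nrow(m); nc <- ncol(m)
  if (py >= nr || px >= nc) {
    stop(sprintf(
      "image (%d x %d) is smaller than the filter support (pad %d x %d)",
      nr, nc, py, px), call. = FALSE)
  }
  ridx <- c(rev(seq_len(py) + 1L), seq_len(nr), nr - seq_len(py))
  cidx <- c(rev(seq_len(px) + 1L), seq_len(nc), nc - seq_len(px))
  m[ridx, cidx, drop = FALSE]
}

# 2-D convolution with reflect boundary handling. Kernel dims must be odd.
# EBImage::filter2 does the FFT work on the padded grid; the pad is then
# cropped so boundary wrap never reaches the valid region.
convolve2 <- function(m, kernel) {
  kd <- dim(kernel)
  if (any(kd %% 2L == 0L)) stop("kernel dimensions must be odd", call. = FALSE)
  py <- (kd[1] - 1L) %/% 2L
  px <- (kd[2] - 1L) %/% 2L
  if (py == 0L && px == 0L) return(m * kernel[1, 1])
  pm <- pad_reflect(m, py, px)
  out <- EBImage::filter2(pm, kernel, boundary = "circular")
  out[(py + 1L):(py + nrow(m)), (px + 1L):(px + ncol(m)), drop = FALSE]
}

# 1-D Gaussian and its derivatives, sampled on integer offsets.
gauss_1d <- function(sigma, order = 0L, radius = max(1L, ceiling(3.5 * sigma))) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
         "0" = g,
         "1" = -x / sigma^2 * g,
         "2" = {
           k <- (x^2 - sigma^2) / sigma^4 * g
           k - mean(k) # discrete kernel must annihilate constants
         },
         stop("order must be 0, 1 or 2"))
}

# Separable Gaussian-derivative filter with per-axis sigma (rows = y).
gaussian_deriv <- function(m, sigma_y, sigma_x, order_y = 0L, order_x = 0L) {
  ky <- gauss_1d(sigma_y, order_y)
  kx <- gauss_1d(sigma_x, order_x)
  convolve2(m, outer(ky, kx))
}

# Isotropic (in pixels) Gaussian smoothing.
gaussian_smooth <- function(m, sigma) {
  gaussian_deriv(m, sigma, sigma, 0L, 0L)
}

clip01 <- function(m) pmin(pmax(m, 0), 1)

# Min-max rescale to [0, 1]; a flat response (constant up to numerical
# roundoff) maps to all zeros instead of amplifying noise.
rescale01 <- function(m) {
  r <- range(m)
  if (r[2] - r[1] <= 1e-10) return(m * 0)
  (m - r[1]) / (r[2] - r[1])
}

# Nearest odd integer; used when converting physical windows to pixels.
nearest_odd <- function(x) {
  lo <- 2 * floor((x - 1) / 2) + 1
  hi <- lo + 2
  as.integer(ifelse(x - lo <= hi - x, lo, hi))
}

# Deterministic derived seeds for named substreams (anatomy / noise / visit),
# so one scene seed drives independent reproducible RNG streams.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed %% 2147483629), expr)
}
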