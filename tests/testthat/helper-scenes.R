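# Shared fixtures: scenes are generated in code at test time.

# Full 15 x 9 mm field sampled at half resolution; keeps filter scales
# physical while quartering convolution cost.
spec_small <- function(seed = 1L) {
  scene_spec(width_px = 400L, height_px = 267L,
             pitch_x_um = 15000 / 400, pitch_y_um = 9000 / 267, seed = seed)
}

# Small crop at native pitch (3.75 x 2.26 mm field): for texture-level
# tests where the physical field size is irrelevant.
spec_crop <- function(seed = 1L, width_px = 200L, height_px = 134L) {
  scene_spec(width_px = width_px, height_px = height_px, seed = seed)
}

# Clean (noise- and vignetting-free) retina parameters.
clean_retina <- function(...) {
  retina_scene_params(speckle_sigma = 0, vignetting_strength = 0, ...)
}

rot90 <- function(m) t(m)[, nrow(m):1]
rot180 <- function(m) m[nrow(m):1, ncol(m):1]

flat_img <- function(value = 0.5, nr = 64, nc = 64, pitch_x = 18.75,
                     pitch_y = 9000 / 534, slab = "SCP") {
  angiogram(matrix(value, nr, nc), pitch_x, pitch_y, slab = slab)
}

dice_of <- function(a, b) {
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

# From-definitions two-way ANOVA ICC(2,1) oracle: explicit sums of squares,
# independent of the package's aov-based route.
icc_oracle <- function(X) {
  n <- nrow(X); k <- ncol(X)
  gm <- mean(X)
  msr <- k * sum((rowMeans(X) - gm)^2) / (n - 1)
  msc <- n * sum((colMeans(X) - gm)^2) / (k - 1)
  sse <- sum((X - gm)^2) - k * sum((rowMeans(X) - gm)^2) -
    n * sum((colMeans(X) - gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

set_pixels_for_test <- function(img, px) {
  img$pixels <- px
  img
}

clip_for_test <- function(m) pmin(pmax(m, 0), 1)
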