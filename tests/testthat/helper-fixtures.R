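# Shared fixtures: a default two-stain basis and small scene builders.

default_basis <- function() {
  pr <- stain_presets()
  complete_stain_basis(pr$oil_red_o, pr$hematoxylin)
}

# Canonical axis-aligned basis: channels coincide with colour planes, so
# expected values are readable by eye.
axis_basis <- function() {
  complete_stain_basis(normalize_stain_vector(c(1, 0, 0), "red_dye"),
                       normalize_stain_vector(c(0, 1, 0), "green_dye"))
}

# Uniform 8-bit image of one value per plane.
flat_image <- function(value, h = 8, w = 8, pixel_size_um = 1) {
  px <- array(as.integer(value), c(h, w, 3))
  rgb_image(px, pixel_size_um = pixel_size_um, mode = "8bit")
}

# Calibration pair from scalar dark/light levels.
flat_calibration <- function(dark, light, h = 8, w = 8) {
  calibration_pair(flat_image(dark, h, w), flat_image(light, h, w))
}

# A scene with one stained disk per channel, for readable ground truth.
two_disk_scene <- function(size = 64, conc1 = 0.8, conc2 = 0.6, ...) {
  synthetic_scene(size, size, regions = list(
    list(shape = "disk", cx = size * 0.3, cy = size * 0.3,
         rx = size * 0.15, ry = size * 0.15, stain = 1, conc = conc1),
    list(shape = "disk", cx = size * 0.7, cy = size * 0.7,
         rx = size * 0.2, ry = size * 0.2, stain = 2, conc = conc2)), ...)
}

# Exhaustive between-class-variance maximizer: the independent Otsu oracle.
brute_force_otsu <- function(values) {
  h <- tabulate(as.integer(values) + 1L, 256L)
  n <- sum(h)
  best <- -1; best_t <- 0L
  for (t in 0:255) {
    i0 <- 1:(t + 1L)
    w0 <- sum(h[i0]); w1 <- n - w0
    v <- if (w0 == 0 || w1 == 0) 0 else {
      m0 <- sum(h[i0] * (0:t)) / w0
      m1 <- sum(h[-i0] * ((t + 1L):255)) / w1
      (w0 / n) * (w1 / n) * (m0 - m1)^2
    }
    if (v > best) { best <- v; best_t <- t }  # strict: keeps smallest tie
  }
  as.integer(best_t)
}
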