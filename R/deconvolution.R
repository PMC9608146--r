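# Two-stain colour deconvolution via the Beer-Lambert optical-density
# model: each dye contributes an additive OD signature (its stain vector)
# per colour plane, so per-pixel stain amounts are recovered by inverting
# the stacked stain basis.

OD_FLOOR <- 1 / 255  # transmittance floor; OD is capped at log10(255)

#' Normalize a raw OD triple into a unit stain vector
#'
#' @param raw numeric length-3, non-negative, not all zero: the dye's
#'   optical-density absorbance in the R, G, B planes.
#' @param name stain label.
#' @return A `stain_vector` with unit Euclidean norm.
#' @export
normalize_stain_vector <- function(raw, name = "stain") {
  if (length(raw) != 3L || !is.numeric(raw) || any(!is.finite(raw)))
    stopf("stain vector must be 3 finite numbers")
  if (any(raw < 0))
    stopf("stain vector components must be non-negative (absorbances)")
  nrm <- sqrt(sum(raw^2))
  if (nrm == 0) stopf("stain vector must not be the zero vector")
  structure(list(name = name, od = raw / nrm), class = "stain_vector")
}

#' Built-in stain vector presets
#'
#' Starting points for the dyes used in tri-lineage differentiation
#' histology. These are calibration-recommended defaults: stain colour
#' varies with batch, counterstain and microscope, so production use should
#' refine them per study with [estimate_stain_vector()] or config overrides.
#'
#' @return Named list of `stain_vector`s: `hematoxylin`, `oil_red_o`,
#'   `alcian_blue`, `nuclear_fast_red`, `alizarin_red_s`, `osteo_purple`.
#' @export
stain_presets <- function() {
  raw <- list(
    hematoxylin      = c(0.650, 0.704, 0.286),  # blue-purple nuclear
    oil_red_o        = c(0.120, 0.800, 0.600),  # red lipid droplets
    alcian_blue      = c(0.780, 0.570, 0.260),  # blue GAG matrix
    nuclear_fast_red = c(0.200, 0.740, 0.640),  # red-pink nuclear
    alizarin_red_s   = c(0.180, 0.830, 0.530),  # red calcium deposits
    osteo_purple     = c(0.580, 0.720, 0.380)   # purple non-mineralized area
  )
  lapply(names(raw), function(n) normalize_stain_vector(raw[[n]], n)) |>
    stats::setNames(names(raw))
}

#' Complete a two-stain basis with its residual vector
#'
#' The third (residual) vector is the unit cross product of the two stain
#' vectors, sign-flipped so its component sum is non-negative; it absorbs
#' colour outside the plane spanned by the two dyes and is never
#' thresholded. The unmixing matrix is the inverse of the row-stacked basis.
#'
#' @param v1 `stain_vector` for the differentiation dye (channel 1).
#' @param v2 `stain_vector` for the counterpart (channel 2).
#' @return A `stain_basis` with `v1`, `v2`, `v3`, `matrix` (rows v1, v2,
#'   v3) and `unmix` (its inverse).
#' @export
complete_stain_basis <- function(v1, v2) {
  stopifnot(inherits(v1, "stain_vector"), inherits(v2, "stain_vector"))
  if (abs(sum(v1$od * v2$od)) >= 1 - 1e-6)
    stopf("stain vectors '%s' and '%s' are collinear; cannot unmix",
          v1$name, v2$name)
  a <- v1$od; b <- v2$od
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  cr <- cr / sqrt(sum(cr^2))
  if (sum(cr) < 0) cr <- -cr
  M <- rbind(v1$od, v2$od, cr)
  rownames(M) <- c(v1$name, v2$name, "residual")
  structure(list(
    v1 = v1, v2 = v2,
    v3 = structure(list(name = "residual", od = cr), class = "stain_vector"),
    matrix = M, unmix = solve(M)), class = "stain_basis")
}

#' @export
print.stain_basis <- function(x, ...) {
  cat(sprintf("<stain_basis %s / %s>\n", x$v1$name, x$v2$name))
  print(round(x$matrix, 4))
  invisible(x)
}

#' Transmittance image to optical density
#'
#' `od = -log10(max(I, 1/255))` per plane: Beer-Lambert absorbance with a
#' transmittance floor of one grey level, capping OD at `log10(255)`.
#'
#' @param image a `"real"`-mode `rgb_image` (run [correct_illumination()]
#'   first, or divide an 8-bit image by 255 explicitly).
#' @return H x W x 3 OD array with attribute `od_floor_count`, the number
#'   of plane values clamped at the floor.
#' @export
rgb_to_od <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  if (image$mode != "real")
    stopf("rgb_to_od expects a corrected, unit-interval image; run correct_illumination() (or divide by 255 explicitly)")
  px <- image$pixels
  floored <- sum(px < OD_FLOOR)
  od <- -log10(pmax(px, OD_FLOOR))
  attr(od, "od_floor_count") <- floored
  od
}

#' Unmix an OD image into per-stain concentration maps
#'
#' Applies the basis inverse to every pixel's OD vector. Concentrations
#' falling outside the stain cone come out negative; they are floored to
#' zero after counting.
#'
#' @param od H x W x 3 OD array from [rgb_to_od()].
#' @param basis a `stain_basis`.
#' @return A `concentration_maps` object: matrices `c1`, `c2`, `c3`,
#'   `neg_floor_counts` (per channel) and `od_floor_count` carried through.
#' @export
unmix_image <- function(od, basis) {
  stopifnot(inherits(basis, "stain_basis"))
  d <- dim(od)
  if (length(d) != 3L || d[3] != 3L) stopf("od must be an H x W x 3 array")
  flat <- matrix(od, ncol = 3L)           # N x 3, od vectors as rows
  conc <- flat %*% basis$unmix            # row i: od_i . M^-1 = concentrations
  neg <- colSums(conc < -1e-12)
  conc[conc < 0] <- 0
  structure(list(
    c1 = matrix(conc[, 1], d[1], d[2]),
    c2 = matrix(conc[, 2], d[1], d[2]),
    c3 = matrix(conc[, 3], d[1], d[2]),
    neg_floor_counts = as.integer(neg),
    od_floor_count = attr(od, "od_floor_count") %||% NA_integer_),
    class = "concentration_maps")
}

#' Convert a concentration map to a transmittance-coded 8-bit channel
#'
#' `pixel = clip(round(255 * 10^(-c)), 0, 255)` with half-away-from-zero
#' rounding: 255 = no stain, 0 = saturated stain.
#'
#' @param c H x W non-negative concentration matrix.
#' @param name stain label carried on the channel.
#' @return A `channel_image`: integer matrix in `[0, 255]` with attributes
#'   `stain` and `coding = "transmittance"`.
#' @export
concentration_to_channel <- function(c, name = "stain") {
  if (min(c) < 0) stopf("concentrations must be non-negative (floor first)")
  px <- round_half_up(255 * 10^(-c))
  px <- pmin(pmax(px, 0), 255)
  storage.mode(px) <- "integer"
  structure(px, stain = name, coding = "transmittance",
            class = c("channel_image", class(px)))
}

#' Estimate a stain vector from a region of interest
#'
#' Mechanizes stain-vector calibration: the mean optical density over a
#' visibly stained ROI, normalized to unit length. Assemble the ROI from a
#' collage of differentiated and control material of the same staining so
#' the vector averages over stain intensity.
#'
#' @param pixels N x 3 matrix of corrected RGB values in `[0, 1]` (N >= 10).
#' @param name stain label for the result.
#' @return A `stain_vector`.
#' @export
estimate_stain_vector <- function(pixels, name = "estimated") {
  if (!is.matrix(pixels) || ncol(pixels) != 3L)
    stopf("pixels must be an N x 3 matrix of corrected RGB values")
  if (nrow(pixels) < 10L)
    stopf("need at least 10 ROI pixels to estimate a stain vector (got %d)",
          nrow(pixels))
  if (min(pixels) < 0 || max(pixels) > 1)
    stopf("ROI pixels must be corrected values in [0, 1]")
  od <- -log10(pmax(pixels, OD_FLOOR))
  m <- colMeans(od)
  if (sqrt(sum(m^2)) < 0.05)
    stopf("ROI contains no stain (mean OD norm %.4f < 0.05)", sqrt(sum(m^2)))
  normalize_stain_vector(m, name)
}
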