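#' Darkfield/brightfield calibration pair
#'
#' The darkfield (`dark`) is captured with a closed illumination path and
#' carries the sensor offset plus fixed-pattern noise (hot pixels); the
#' brightfield (`light`) images an empty well and carries the illumination
#' profile. Together they define the flat-field correction.
#'
#' @param dark,light `rgb_image`s in `"8bit"` mode with identical dimensions.
#' @return A `calibration_pair` (unrepaired; see [repair_calibration()]).
#' @export
calibration_pair <- function(dark, light) {
  stopifnot(inherits(dark, "rgb_image"), inherits(light, "rgb_image"))
  if (!identical(dim(dark$pixels), dim(light$pixels)))
    stopf("dark (%s) and light (%s) dimensions differ",
          paste(dim(dark$pixels), collapse = "x"),
          paste(dim(light$pixels), collapse = "x"))
  structure(list(dark = dark, light = light,
                 repaired = NULL, n_repaired = NA_integer_),
            class = "calibration_pair")
}

# Median of the valid 8-neighbours of site (i, j) in matrix m; sites listed
# in `bad` are excluded. Returns NA if no valid neighbour exists.
neighbor_median <- function(m, bad, i, j) {
  H <- nrow(m); W <- ncol(m)
  vals <- c()
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ii <- i + di; jj <- j + dj
    if (ii < 1 || ii > H || jj < 1 || jj > W) next
    if (bad[ii, jj]) next
    vals <- c(vals, m[ii, jj])
  }
  if (length(vals) == 0L) return(NA_real_)
  stats::median(vals)
}

#' Repair fixed-pattern defects in a calibration pair
#'
#' A site is defective when `light <= dark` in any colour plane (a hot or
#' dead pixel leaves no usable dynamic range there). Defective sites are
#' replaced, in both calibration frames and all planes, by the median of
#' their valid 8-neighbours, iterating until none remain (at most
#' `max_iter` passes). More than `max_frac` defective sites is treated as a
#' failed calibration rather than silently repaired.
#'
#' @param calib a `calibration_pair`.
#' @param max_frac maximum tolerated fraction of defective sites (default 1\%).
#' @param max_iter maximum repair sweeps.
#' @return The repaired `calibration_pair`, with `repaired` (H x W logical
#'   mask of touched sites) and `n_repaired` filled in.
#' @export
repair_calibration <- function(calib, max_frac = 0.01, max_iter = 10L) {
  stopifnot(inherits(calib, "calibration_pair"))
  dk <- calib$dark$pixels * 1.0
  lt <- calib$light$pixels * 1.0
  H <- dim(dk)[1]; W <- dim(dk)[2]
  bad0 <- (lt[, , 1] <= dk[, , 1]) | (lt[, , 2] <= dk[, , 2]) |
          (lt[, , 3] <= dk[, , 3])
  frac <- mean(bad0)
  if (frac > max_frac)
    stopf("calibration quality failure: %.2f%% of sites have light <= dark (max %.2f%%)",
          100 * frac, 100 * max_frac)
  if (!any(bad0)) {
    out <- calib
    out$repaired <- bad0
    out$n_repaired <- 0L
    return(out)
  }
  repaired <- bad0 & FALSE
  bad <- bad0
  iter <- 0L
  while (any(bad) && iter < max_iter) {
    iter <- iter + 1L
    idx <- which(bad, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      ok <- TRUE
      for (k in 1:3) {
        dv <- neighbor_median(dk[, , k], bad, i, j)
        lv <- neighbor_median(lt[, , k], bad, i, j)
        if (is.na(dv) || is.na(lv)) { ok <- FALSE; break }
        dk[i, j, k] <- dv; lt[i, j, k] <- lv
      }
      if (ok) {
        bad[i, j] <- FALSE
        repaired[i, j] <- TRUE
      }
    }
  }
  if (any(bad))
    stopf("calibration repair did not converge: %d sites remain invalid",
          sum(bad))
  out <- calib
  out$dark$pixels <- dk
  out$light$pixels <- lt
  out$repaired <- repaired
  out$n_repaired <- sum(repaired)
  out
}

#' Flat-field illumination correction
#'
#' Computes the per-pixel, per-plane quotient
#' `(Original - Dark) / (Light - Dark)`, clipped to the unit interval:
#' the standard flat-field transform that removes the illumination gradient
#' and fixed-pattern offset and converts intensities to transmittance.
#' Sites that were repaired in the calibration pair (hot pixels) carry no
#' specimen signal either, so the original's value there is replaced by the
#' median of its 8-neighbours before the quotient.
#'
#' @param original an `"8bit"` `rgb_image` sharing dimensions with the
#'   calibration frames.
#' @param calib a `calibration_pair`; repaired automatically if needed.
#' @return A `"real"` `rgb_image` of transmittances in `[0, 1]`, carrying
#'   `pixel_size_um` through, with attributes `saturation_frac` (fraction of
#'   values clipped at 1) and `n_repaired_sites`.
#' @export
correct_illumination <- function(original, calib) {
  stopifnot(inherits(original, "rgb_image"))
  if (original$mode != "8bit")
    stopf("correct_illumination expects an 8-bit original")
  if (is.null(calib$repaired)) calib <- repair_calibration(calib)
  if (!identical(dim(original$pixels), dim(calib$dark$pixels)))
    stopf("image %s (%s) does not match calibration dimensions (%s)",
          original$source_path,
          paste(dim(original$pixels), collapse = "x"),
          paste(dim(calib$dark$pixels), collapse = "x"))
  O <- original$pixels * 1.0
  if (any(calib$repaired)) {
    idx <- which(calib$repaired, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      for (k in 1:3) {
        v <- neighbor_median(O[, , k], calib$repaired, i, j)
        if (!is.na(v)) O[i, j, k] <- v
      }
    }
  }
  denom <- calib$light$pixels - calib$dark$pixels
  q <- (O - calib$dark$pixels) / denom
  sat <- mean(q > 1)
  q <- pmin(pmax(q, 0), 1)
  out <- rgb_image(q, pixel_size_um = original$pixel_size_um,
                   source_path = original$source_path, mode = "real")
  attr(out, "saturation_frac") <- sat
  attr(out, "n_repaired_sites") <- calib$n_repaired
  out
}
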