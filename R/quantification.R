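# Binarization of transmittance-coded stain channels and the
# differentiation ratio (DR): area% of the differentiation dye divided by
# area% of the counterpart (nuclei or cell-culture area).

channel_histogram <- function(channel) {
  tabulate(as.integer(channel) + 1L, nbins = 256L)  # bins 0..255
}

#' Histogram auto-threshold of an 8-bit channel
#'
#' Supported methods:
#' \describe{
#'   \item{otsu}{maximizes the between-class variance
#'     `w0 * w1 * (mu0 - mu1)^2` over all 256 cut points; ties broken by
#'     the smallest qualifying threshold.}
#'   \item{isodata}{intermeans iteration: `t <- (mu_below + mu_above) / 2`
#'     to a fixed point.}
#'   \item{mean}{floor of the mean grey value.}
#'   \item{triangle}{maximum distance from the histogram to the chord
#'     joining the peak and the far empty end.}
#' }
#' Channels are transmittance-coded (stained = dark); a pixel is positive
#' when its value is `<=` the threshold.
#'
#' @param channel a `channel_image` (or integer matrix in 0..255).
#' @param method one of `"otsu"`, `"mean"`, `"isodata"`, `"triangle"`.
#' @return Integer threshold in `[0, 255]`.
#' @export
auto_threshold <- function(channel,
                           method = c("otsu", "mean", "isodata", "triangle")) {
  method <- match.arg(method)
  h <- channel_histogram(channel)
  n <- sum(h)
  lv <- 0:255
  if (method %in% c("otsu", "isodata") && sum(h > 0) < 2L)
    stopf("degenerate histogram: channel is constant at %d; %s threshold undefined",
          which(h > 0) - 1L, method)
  if (method == "otsu") {
    w0 <- cumsum(h)                      # pixels with value <= t
    s0 <- cumsum(h * lv)
    w1 <- n - w0
    mu0 <- ifelse(w0 > 0, s0 / w0, 0)
    mu1 <- ifelse(w1 > 0, (s0[256] - s0) / w1, 0)
    bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
    return(as.integer(which.max(bcv) - 1L))  # which.max takes the first tie
  }
  if (method == "mean") {
    return(as.integer(floor(sum(h * lv) / n)))
  }
  if (method == "isodata") {
    t <- as.integer(floor(sum(h * lv) / n))
    for (it in 1:256) {
      below <- h[1:(t + 1L)]; above <- if (t < 255L) h[(t + 2L):256] else 0
      mu0 <- if (sum(below) > 0) sum(below * lv[1:(t + 1L)]) / sum(below) else 0
      mu1 <- if (sum(above) > 0) {
        sum(above * lv[(t + 2L):256]) / sum(above)
      } else mu0
      tn <- as.integer(floor((mu0 + mu1) / 2))
      if (tn == t) break
      t <- tn
    }
    return(t)
  }
  # triangle: chord from the histogram peak to the farthest empty tail bin
  peak <- which.max(h) - 1L
  nz <- which(h > 0) - 1L
  lo <- min(nz); hi <- max(nz)
  far <- if ((peak - lo) >= (hi - peak)) lo else hi
  if (far == peak) return(as.integer(peak))
  xs <- seq(min(peak, far), max(peak, far))
  hp <- h[peak + 1L]; hf <- h[far + 1L]
  # distance from (x, h[x]) to the line through (peak, hp) and (far, hf)
  d <- abs((hf - hp) * xs - (far - peak) * h[xs + 1L] + far * hp - peak * hf)
  as.integer(xs[which.max(d)])
}

#' Binarize a transmittance-coded channel
#'
#' @param channel a `channel_image` or integer matrix in 0..255.
#' @param threshold cut point in `[0, 255]`; positive means `value <= threshold`.
#' @param method name recorded on the mask (informational).
#' @return A `binary_mask`: logical matrix with attributes `threshold_used`
#'   and `method`.
#' @export
binarize <- function(channel, threshold, method = "fixed") {
  if (threshold < 0 || threshold > 255) stopf("threshold must lie in [0, 255]")
  m <- unclass(channel) <= threshold
  structure(m, threshold_used = as.integer(threshold), method = method,
            class = c("binary_mask", class(m)))
}

#' Positive-area fraction of a binary mask, in percent
#'
#' @param mask logical matrix (a `binary_mask`).
#' @return `100 * positives / total`.
#' @export
area_fraction <- function(mask) {
  if (length(mask) == 0L) stopf("empty mask")
  100 * sum(mask) / length(mask)
}

#' Differentiation ratio
#'
#' `DR = area%_1 / area%_2`: the differentiation dye's area fraction over
#' the counterpart's. Undefined (NA) when the counterpart fraction is zero;
#' the record is retained but excluded from means.
#'
#' @param af1,af2 area fractions in `[0, 100]` for channels 1 and 2.
#' @return The ratio, or `NA_real_` when `af2 == 0`.
#' @export
differentiation_ratio <- function(af1, af2) {
  if (af1 < 0 || af1 > 100 || af2 < 0 || af2 > 100)
    stopf("area fractions must lie in [0, 100]")
  if (af2 == 0) return(NA_real_)
  af1 / af2
}

#' Quantify one micrograph end to end
#'
#' Deterministic composition of the whole single-image pipeline:
#' flat-field correction, OD transform, unmixing, 8-bit channel conversion,
#' per-channel auto-threshold (computed independently for each channel),
#' binarization, area fractions, DR. Every intermediate decision is
#' recorded in the returned record.
#'
#' @param image an `"8bit"` `rgb_image`.
#' @param calib a `calibration_pair` for the image's acquisition series.
#' @param basis a `stain_basis`.
#' @param method auto-threshold method (see [auto_threshold()]).
#' @param fixed_threshold optional integer 0-255 applied to both channels
#'   instead of the auto-threshold.
#' @return One-row data.frame (a QuantRecord): `image_id`,
#'   `area_fraction_1`, `area_fraction_2`, `dr`, `dr_defined`,
#'   `threshold_1`, `threshold_2`, `method`, `od_floor_count`,
#'   `neg_floor_1`, `neg_floor_2`, `saturation_frac`.
#' @export
quantify_image <- function(image, calib, basis, method = "otsu",
                           fixed_threshold = NULL) {
  corrected <- correct_illumination(image, calib)
  od <- rgb_to_od(corrected)
  maps <- unmix_image(od, basis)
  ch1 <- concentration_to_channel(maps$c1, basis$v1$name)
  ch2 <- concentration_to_channel(maps$c2, basis$v2$name)
  if (is.null(fixed_threshold)) {
    t1 <- tryCatch(auto_threshold(ch1, method),
                   error = function(e) stopf("image %s, channel 1: %s",
                                             image$source_path,
                                             conditionMessage(e)))
    t2 <- tryCatch(auto_threshold(ch2, method),
                   error = function(e) stopf("image %s, channel 2: %s",
                                             image$source_path,
                                             conditionMessage(e)))
    used <- method
  } else {
    t1 <- t2 <- as.integer(fixed_threshold)
    used <- "fixed"
  }
  m1 <- binarize(ch1, t1, used)
  m2 <- binarize(ch2, t2, used)
  af1 <- area_fraction(m1)
  af2 <- area_fraction(m2)
  dr <- differentiation_ratio(af1, af2)
  data.frame(
    image_id = image$source_path,
    area_fraction_1 = af1, area_fraction_2 = af2,
    dr = dr, dr_defined = !is.na(dr),
    threshold_1 = t1, threshold_2 = t2, method = used,
    od_floor_count = attr(od, "od_floor_count"),
    neg_floor_1 = maps$neg_floor_counts[1],
    neg_floor_2 = maps$neg_floor_counts[2],
    saturation_frac = attr(corrected, "saturation_frac"),
    stringsAsFactors = FALSE)
}
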