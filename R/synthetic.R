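# Forward renderer for ground-truth fixtures: scenes of stained regions
# are pushed through the Beer-Lambert model (transmittance
# 10^(-sum_s c_s v_s) per plane), a multiplicative vignette, sensor offset,
# Gaussian intensity noise and hot pixels — so every pipeline stage can be
# tested against known truth without real micrographs.

#' Describe a synthetic stained scene
#'
#' @param width,height canvas size in pixels.
#' @param regions list of regions; each a list with `shape` (`"disk"` or
#'   `"ellipse"`), `cx`, `cy` (centre, 1-based pixel coords), `rx`, `ry`
#'   (radii in px; equal for a disk), `stain` (1 or 2) and `conc`
#'   (optical-density concentration, >= 0).
#' @param vignette_corner_gain multiplicative illumination gain at the
#'   canvas corners, in `(0, 1]`; 1 means flat illumination.
#' @param dark_offset constant sensor offset added to every reading
#'   (0-50 grey levels).
#' @param hot_pixels optional n x 2 matrix of (row, col) sites that read
#'   saturated regardless of signal.
#' @param noise_sd additive Gaussian noise on 8-bit intensities.
#' @param seed integer seed; fully determines the render.
#' @return A `synthetic_scene`.
#' @export
synthetic_scene <- function(width = 128, height = 128, regions = list(),
                            vignette_corner_gain = 1, dark_offset = 0,
                            hot_pixels = NULL, noise_sd = 0, seed = 1L) {
  if (vignette_corner_gain <= 0 || vignette_corner_gain > 1)
    stopf("vignette_corner_gain must lie in (0, 1]")
  for (r in regions)
    if ((r$conc %||% -1) < 0) stopf("region concentrations must be >= 0")
  structure(list(width = width, height = height, regions = regions,
                 vignette_corner_gain = vignette_corner_gain,
                 dark_offset = dark_offset, hot_pixels = hot_pixels,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_scene")
}

# Radial multiplicative illumination field: 1 at the centre, corner_gain at
# the four corners, quadratic falloff in between.
vignette_field <- function(height, width, corner_gain) {
  ci <- (height + 1) / 2; cj <- (width + 1) / 2
  r2 <- outer((seq_len(height) - ci)^2, (seq_len(width) - cj)^2, `+`)
  rmax2 <- (1 - ci)^2 + (1 - cj)^2
  if (rmax2 == 0) return(matrix(1, height, width))
  1 - (1 - corner_gain) * r2 / rmax2
}

# True concentration maps (c1, c2) from the scene's region list; later
# regions overwrite earlier ones, and stain 1 takes priority over stain 2
# so the two stained areas stay disjoint.
scene_concentration_maps <- function(scene) {
  H <- scene$height; W <- scene$width
  c1 <- matrix(0, H, W); c2 <- matrix(0, H, W)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (r in scene$regions) {
    rx <- r$rx %||% r$r; ry <- r$ry %||% r$r
    inside <- ((rows - r$cy) / ry)^2 + ((cols - r$cx) / rx)^2 <= 1
    if (r$stain == 1) c1[inside] <- r$conc else c2[inside] <- r$conc
  }
  c2[c1 > 0] <- 0
  list(c1 = c1, c2 = c2)
}

#' Render a scene into an 8-bit micrograph plus ground truth
#'
#' Per plane k: continuous reading
#' `dark + vignette * (255 - dark) * 10^(-(c1 v1k + c2 v2k))`, rounded
#' half-away-from-zero, plus clipped Gaussian noise, with hot-pixel sites
#' forced to 255.
#'
#' @param scene a `synthetic_scene`.
#' @param basis a `stain_basis`.
#' @param pixel_size_um pixel size stamped on the image.
#' @param mask_cutoff concentration above which a pixel counts as
#'   truly stained (default 0.01).
#' @return List: `image` (`rgb_image`, 8-bit) and `truth` (list with `c1`,
#'   `c2`, `mask1`, `mask2`, `area_fraction_1/2` in percent, `dr`).
#' @export
render_stained_image <- function(scene, basis, pixel_size_um = 1,
                                 mask_cutoff = 0.01) {
  stopifnot(inherits(scene, "synthetic_scene"), inherits(basis, "stain_basis"))
  H <- scene$height; W <- scene$width
  maps <- scene_concentration_maps(scene)
  vig <- vignette_field(H, W, scene$vignette_corner_gain)
  d0 <- scene$dark_offset
  px <- array(0, c(H, W, 3))
  for (k in 1:3) {
    Tk <- 10^(-(maps$c1 * basis$v1$od[k] + maps$c2 * basis$v2$od[k]))
    px[, , k] <- round_half_up(d0 + vig * (255 - d0) * Tk)
  }
  if (scene$noise_sd > 0) {
    set.seed(scene$seed)
    px <- round_half_up(px + stats::rnorm(length(px), 0, scene$noise_sd))
  }
  px <- pmin(pmax(px, 0), 255)
  if (!is.null(scene$hot_pixels)) {
    hp <- scene$hot_pixels
    for (r in seq_len(nrow(hp))) px[hp[r, 1], hp[r, 2], ] <- 255
  }
  storage.mode(px) <- "integer"
  img <- rgb_image(px, pixel_size_um = pixel_size_um,
                   source_path = sprintf("<synthetic seed=%d>", scene$seed),
                   mode = "8bit")
  m1 <- maps$c1 > mask_cutoff; m2 <- maps$c2 > mask_cutoff
  af1 <- 100 * mean(m1); af2 <- 100 * mean(m2)
  truth <- list(c1 = maps$c1, c2 = maps$c2, mask1 = m1, mask2 = m2,
                area_fraction_1 = af1, area_fraction_2 = af2,
                dr = if (af2 > 0) af1 / af2 else NA_real_)
  list(image = img, truth = truth)
}

#' Calibration pair matching a scene's illumination
#'
#' Light images an empty well under the scene's vignette
#' (`round(dark + vignette * (255 - dark))`); Dark is the constant sensor
#' offset. Hot-pixel sites read 255 in both frames, so the repair step has
#' genuine fixed-pattern defects to find.
#'
#' @param scene a `synthetic_scene`.
#' @return An unrepaired `calibration_pair`.
#' @export
make_calibration_pair <- function(scene) {
  H <- scene$height; W <- scene$width
  vig <- vignette_field(H, W, scene$vignette_corner_gain)
  d0 <- scene$dark_offset
  lt <- round_half_up(d0 + vig * (255 - d0))
  dk <- matrix(d0, H, W)
  if (!is.null(scene$hot_pixels)) {
    hp <- scene$hot_pixels
    for (r in seq_len(nrow(hp))) {
      dk[hp[r, 1], hp[r, 2]] <- 255
      lt[hp[r, 1], hp[r, 2]] <- 255
    }
  }
  to3 <- function(m) {
    a <- array(0, c(H, W, 3)); for (k in 1:3) a[, , k] <- m
    storage.mode(a) <- "integer"; a
  }
  calibration_pair(rgb_image(to3(dk), source_path = "<synthetic dark>"),
                   rgb_image(to3(lt), source_path = "<synthetic light>"))
}

# Pack random disjoint regions of one stain until the stained fraction
# reaches `target` of the canvas. Returns the region list.
pack_regions <- function(height, width, target, stain, conc, radius,
                         occupied, rng_fun) {
  regions <- list()
  need <- round(target * height * width)
  got <- 0L
  tries <- 0L
  while (got < need && tries < 4000L) {
    tries <- tries + 1L
    cx <- rng_fun(width); cy <- rng_fun(height)
    rows <- matrix(seq_len(height), height, width)
    cols <- matrix(seq_len(width), height, width, byrow = TRUE)
    inside <- (rows - cy)^2 + (cols - cx)^2 <= radius^2
    fresh <- inside & !occupied
    n_new <- sum(fresh)
    if (n_new == 0L) next
    occupied <- occupied | fresh
    got <- got + n_new
    regions[[length(regions) + 1L]] <-
      list(shape = "disk", cx = cx, cy = cy, rx = radius, ry = radius,
           stain = stain, conc = conc)
  }
  list(regions = regions, occupied = occupied, fraction = got / (height * width))
}

# Build a scene with approximately the requested disjoint stained-area
# fractions p1 (differentiation dye) and p2 (counterstain).
fraction_scene <- function(p1, p2, size = 128, conc1 = 0.8, conc2 = 0.6,
                           noise_sd = 0, vignette_corner_gain = 1,
                           dark_offset = 0, hot_pixels = NULL, seed = 1L) {
  set.seed(seed)
  rng <- function(n) sample.int(n, 1L)
  occ <- matrix(FALSE, size, size)
  s1 <- pack_regions(size, size, p1, 1L, conc1, radius = max(2, size %/% 20),
                     occ, rng)
  s2 <- pack_regions(size, size, p2, 2L, conc2, radius = max(2, size %/% 28),
                     s1$occupied, rng)
  synthetic_scene(size, size, c(s1$regions, s2$regions),
                  vignette_corner_gain = vignette_corner_gain,
                  dark_offset = dark_offset, hot_pixels = hot_pixels,
                  noise_sd = noise_sd, seed = seed)
}

#' Generate a complete synthetic study tree on disk
#'
#' Writes a [discover_study()]-compatible tree
#' `<root>/<donor>/<condition>/<well>/<image>.png` plus a calibration pair
#' under `<root>/calibration/` and a `truth.csv` recording every image's
#' true area fractions, DR, and each donor's expected normalized DR.
#' Differentiated images carry a stained-area fraction equal to
#' `effect_multipliers[donor] * control_fraction`, emulating the replicate
#' structure of a tri-lineage differentiation experiment (three wells with
#' four images each per donor and condition by default).
#'
#' @param root destination directory; must be absent or empty.
#' @param n_donors number of donors (>= 2).
#' @param effect_multipliers per-donor fold change of the differentiation
#'   stain fraction in differentiated vs control wells (length `n_donors`,
#'   all >= 0); all 1 gives a null study.
#' @param wells,images_per_well replicate structure per donor x condition.
#' @param control_fraction true stained-area fraction of the
#'   differentiation dye in control images.
#' @param counter_fraction true counterstain area fraction (all images).
#' @param size canvas edge in pixels.
#' @param noise_sd additive Gaussian noise on 8-bit intensities.
#' @param vignette_corner_gain illumination gain at the corners.
#' @param dark_offset constant sensor offset.
#' @param n_hot_pixels number of randomly placed hot pixels (shared by all
#'   images of the series, like real fixed-pattern noise).
#' @param basis `stain_basis` used by the forward model (default: Oil Red
#'   O vs hematoxylin presets).
#' @param seed master seed; fully determines the tree.
#' @return List: `root`, `truth` (per-image data.frame), `donor_truth`
#'   (expected DR^N per donor), `calibration` paths. `truth.csv` is also
#'   written under `root`.
#' @export
generate_synthetic_study <- function(root, n_donors = 4,
                                     effect_multipliers = rep(2, n_donors),
                                     wells = 3, images_per_well = 4,
                                     control_fraction = 0.05,
                                     counter_fraction = 0.20,
                                     size = 64, noise_sd = 2,
                                     vignette_corner_gain = 0.85,
                                     dark_offset = 4, n_hot_pixels = 3,
                                     basis = NULL, seed = 1L) {
  if (n_donors < 2L) stopf("a study needs at least 2 donors")
  if (length(effect_multipliers) != n_donors || any(effect_multipliers < 0))
    stopf("effect_multipliers must be %d non-negative values", n_donors)
  if (dir.exists(root) && length(list.files(root, all.files = TRUE,
                                            no.. = TRUE)) > 0L)
    stopf("refusing to write into non-empty directory %s", root)
  if (is.null(basis)) {
    pr <- stain_presets()
    basis <- complete_stain_basis(pr$oil_red_o, pr$hematoxylin)
  }
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  hp <- if (n_hot_pixels > 0) {
    cbind(sample(2:(size - 1), n_hot_pixels, replace = TRUE),
          sample(2:(size - 1), n_hot_pixels, replace = TRUE))
  } else NULL
  base_scene <- synthetic_scene(size, size,
                                vignette_corner_gain = vignette_corner_gain,
                                dark_offset = dark_offset, hot_pixels = hp,
                                seed = seed)
  calib <- make_calibration_pair(base_scene)
  dir.create(file.path(root, "calibration"))
  dark_path <- file.path(root, "calibration", "dark.png")
  light_path <- file.path(root, "calibration", "light.png")
  write_rgb_image(calib$dark, dark_path)
  write_rgb_image(calib$light, light_path)

  rows <- list(); counter <- 0L
  for (d in seq_len(n_donors)) {
    donor <- sprintf("donor%02d", d)
    for (cond in c("control", "differentiated")) {
      p1 <- control_fraction *
        (if (cond == "differentiated") effect_multipliers[d] else 1)
      for (w in seq_len(wells)) {
        wdir <- file.path(root, donor, cond, sprintf("well%d", w))
        dir.create(wdir, recursive = TRUE, showWarnings = FALSE)
        for (im in seq_len(images_per_well)) {
          counter <- counter + 1L
          img_seed <- (seed * 10000L + counter) %% .Machine$integer.max
          scene <- fraction_scene(p1, counter_fraction, size = size,
                                  noise_sd = noise_sd,
                                  vignette_corner_gain = vignette_corner_gain,
                                  dark_offset = dark_offset,
                                  hot_pixels = hp, seed = img_seed)
          r <- render_stained_image(scene, basis)
          rel <- file.path(donor, cond, sprintf("well%d", w),
                           sprintf("img%d.png", im))
          write_rgb_image(r$image, file.path(root, rel))
          # paths stored relative to root so trees are location-independent
          rows[[counter]] <- data.frame(
            donor = donor, condition = cond, well = sprintf("well%d", w),
            path = rel, target_fraction_1 = p1,
            true_area_fraction_1 = r$truth$area_fraction_1,
            true_area_fraction_2 = r$truth$area_fraction_2,
            true_dr = r$truth$dr, stringsAsFactors = FALSE)
        }
      }
    }
  }
  truth <- do.call(rbind, rows)
  mean_by <- function(d, cond)
    mean(truth$true_dr[truth$donor == d & truth$condition == cond])
  donor_ids <- sprintf("donor%02d", seq_len(n_donors))
  donor_truth <- data.frame(
    donor = donor_ids,
    effect_multiplier = effect_multipliers,
    expected_drn = vapply(donor_ids, function(d)
      mean_by(d, "differentiated") / mean_by(d, "control"), 0.0))
  write_measurements(truth, file.path(root, "truth.csv"))
  write_measurements(donor_truth, file.path(root, "donor_truth.csv"))
  list(root = root, truth = truth, donor_truth = donor_truth,
       calibration = list(dark = dark_path, light = light_path),
       basis = basis)
}

#' Simulate a study at the measurement level
#'
#' Draws per-image DRs directly — donor baseline x condition effect x
#' lognormal replicate noise — without rendering micrographs. Used to
#' study the donor-level repeated-measures ANOVA (e.g. its type-I error on
#' null studies, where `effect = 1`) at problem sizes where rendering adds
#' nothing but runtime.
#'
#' @param n_donors number of donors.
#' @param effect multiplicative condition effect on differentiated DRs
#'   (1 = null).
#' @param wells,images_per_well replicate structure.
#' @param base_dr median control DR.
#' @param donor_sd,noise_sd standard deviations (log scale) of the donor
#'   random effect and the per-image noise.
#' @param seed RNG seed.
#' @return data.frame of QuantRecord-like rows: `donor`, `condition`,
#'   `well`, `dr`.
#' @export
simulate_dr_study <- function(n_donors = 6, effect = 1, wells = 3,
                              images_per_well = 4, base_dr = 0.5,
                              donor_sd = 0.3, noise_sd = 0.25, seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (d in seq_len(n_donors)) {
    donor_mult <- exp(stats::rnorm(1, 0, donor_sd))
    for (cond in c("control", "differentiated")) {
      mult <- if (cond == "differentiated") effect else 1
      for (w in seq_len(wells)) {
        drs <- base_dr * donor_mult * mult *
          exp(stats::rnorm(images_per_well, 0, noise_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          donor = sprintf("donor%02d", d), condition = cond,
          well = sprintf("well%d", w), dr = drs, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Donor-level ANOVA of a simulated or measured DR table
#'
#' Convenience wrapper: nested-mean aggregation per donor x condition,
#' then [rm_anova_two_condition()].
#'
#' @param records data.frame with `donor`, `condition`, `well`, `dr`.
#' @return An `anova_result`.
#' @export
anova_from_records <- function(records) {
  donors <- sort(unique(records$donor))
  pairs <- do.call(rbind, lapply(donors, function(d) {
    g <- function(cond) {
      sub <- records[records$donor == d & records$condition == cond, ,
                     drop = FALSE]
      if (nrow(sub) == 0L) return(NA_real_)
      tryCatch(aggregate_donor(sub)$mean_dr, error = function(e) NA_real_)
    }
    data.frame(donor = d, differentiated = g("differentiated"),
               control = g("control"))
  }))
  suppressWarnings(rm_anova_two_condition(pairs))
}
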