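# Donor-level aggregation of image DRs, donor normalization, pellet areas
# and the study-level repeated-measures ANOVA.

#' Nested mean DR for one donor x condition
#'
#' Images are averaged within well, wells within donor (replicate
#' structure: three wells x four images for adipogenic/osteogenic; for
#' chondrogenic, sections carry `well = NA` and are averaged directly).
#' Undefined DRs are excluded with a count. Identical to the grand mean for
#' balanced designs; well-defined under dropouts.
#'
#' @param records data.frame of QuantRecords for one donor x condition,
#'   with columns `dr` and `well`.
#' @return List with `mean_dr`, `n_images` (defined DRs used),
#'   `n_undefined`.
#' @export
aggregate_donor <- function(records) {
  stopifnot(is.data.frame(records), all(c("dr", "well") %in% names(records)))
  ok <- records[!is.na(records$dr), , drop = FALSE]
  n_undef <- nrow(records) - nrow(ok)
  if (nrow(ok) == 0L)
    stopf("no defined DRs to aggregate (all %d undefined)", nrow(records))
  if (all(is.na(ok$well))) {
    m <- mean(ok$dr)                               # sections: plain mean
  } else {
    m <- mean(tapply(ok$dr, ok$well, mean))        # mean of well means
  }
  list(mean_dr = m, n_images = nrow(ok), n_undefined = n_undef)
}

#' Donor-normalized differentiation ratio
#'
#' `DR^N = mean DR (differentiated) / mean DR (non-induced control)`.
#' Values below 1 mean less differentiation signal than the donor's own
#' controls; above 1 means more.
#'
#' @param mean_diff,mean_ctrl nested-mean DRs per condition.
#' @return The ratio, or `NA_real_` when the control mean is zero.
#' @export
normalized_dr <- function(mean_diff, mean_ctrl) {
  if (is.na(mean_diff) || is.na(mean_ctrl)) return(NA_real_)
  if (mean_diff < 0 || mean_ctrl < 0) stopf("mean DRs cannot be negative")
  if (mean_ctrl == 0) return(NA_real_)
  mean_diff / mean_ctrl
}

#' Pooled-control fallback for a donor without usable controls
#'
#' When a donor's own non-induced controls are missing or all undefined
#' (e.g. the control pellet never formed), the mean of the other donors'
#' control means in the same lineage stands in as denominator.
#'
#' @param mean_ctrl_others numeric vector of the other donors' control
#'   mean DRs (non-empty).
#' @return Their arithmetic mean.
#' @export
fallback_control <- function(mean_ctrl_others) {
  v <- mean_ctrl_others[!is.na(mean_ctrl_others)]
  if (length(v) == 0L)
    stopf("no other donors with a defined control mean; normalization impossible")
  mean(v)
}

#' Classify a normalized DR against the neutral point 1
#'
#' @param drn normalized DR (>= 0) or NA.
#' @return `"below-control"`, `"neutral"`, `"above-control"`, or
#'   `NA_character_` for undefined input.
#' @export
classify_dr_normalized <- function(drn) {
  if (is.na(drn)) return(NA_character_)
  if (drn < 0) stopf("normalized DR cannot be negative")
  if (drn < 1) "below-control" else if (drn > 1) "above-control" else "neutral"
}

#' Area of a manually fitted ellipse
#'
#' @param major_mm,minor_mm axis lengths in mm, `major >= minor > 0`.
#' @return `pi * (major/2) * (minor/2)` in mm^2.
#' @export
ellipse_area <- function(major_mm, minor_mm) {
  if (!is.finite(major_mm) || !is.finite(minor_mm) ||
      minor_mm <= 0 || major_mm < minor_mm)
    stopf("require major >= minor > 0 (got major %s, minor %s)",
          major_mm, minor_mm)
  pi * (major_mm / 2) * (minor_mm / 2)
}

#' Automatic pellet area from a stained section
#'
#' Foreground is the union of both stain masks after the standard
#' quantification pipeline; the largest 8-connected component is taken as
#' the pellet and its pixel count converted to mm^2 via the pixel size.
#'
#' @param image an `"8bit"` `rgb_image` of the section (pixel size set).
#' @param calib `calibration_pair`, or NULL if `image` needs only a /255
#'   rescale (synthetic, already flat-field-free).
#' @param basis a `stain_basis`.
#' @param method auto-threshold method.
#' @return List: `section_id`, `area_mm2`, `mode = "auto-mask"`,
#'   `n_pixels`, `warning` (character or NA).
#' @export
auto_pellet_area <- function(image, calib, basis, method = "otsu") {
  stopifnot(inherits(image, "rgb_image"))
  if (is.null(calib)) {
    corrected <- rgb_image(image$pixels / 255, image$pixel_size_um,
                           image$source_path, mode = "real")
  } else {
    corrected <- correct_illumination(image, calib)
  }
  od <- rgb_to_od(corrected)
  maps <- unmix_image(od, basis)
  fg <- matrix(FALSE, nrow(maps$c1), ncol(maps$c1))
  for (ch in list(concentration_to_channel(maps$c1),
                  concentration_to_channel(maps$c2))) {
    t <- tryCatch(auto_threshold(ch, method), error = function(e) NULL)
    if (!is.null(t)) fg <- fg | binarize(ch, t)
  }
  wmsg <- NA_character_
  if (!any(fg)) {
    wmsg <- sprintf("empty foreground in %s; pellet area 0", image$source_path)
    warnf("%s", wmsg)
    npx <- 0L
  } else {
    lab <- EBImage::bwlabel(fg)
    npx <- max(tabulate(lab[lab > 0]))
  }
  list(section_id = image$source_path,
       area_mm2 = npx * (image$pixel_size_um / 1000)^2,
       mode = "auto-mask", n_pixels = as.integer(npx), warning = wmsg)
}

#' Univariate repeated-measures ANOVA for two conditions
#'
#' One observation per donor x condition cell (the nested mean DRs).
#' Condition is the fixed factor, donor the random factor:
#' `SS_condition` on 1 df against the donor x condition interaction on
#' `n - 1` df. With two conditions this F equals the squared paired
#' t statistic. A zero interaction SS is reported as `F = Inf, p = 0` with
#' a warning rather than an error.
#'
#' @param donor_means data.frame with columns `donor`, `differentiated`,
#'   `control` (one row per donor). Donors missing either condition are
#'   excluded with a warning.
#' @return An `anova_result`: list with `F`, `df1`, `df2`, `p`,
#'   `mean_differentiated`, `mean_control`, `n_donors`, `excluded`.
#' @export
rm_anova_two_condition <- function(donor_means) {
  stopifnot(is.data.frame(donor_means),
            all(c("differentiated", "control") %in% names(donor_means)))
  complete <- stats::complete.cases(donor_means[, c("differentiated", "control")])
  excluded <- if ("donor" %in% names(donor_means)) {
    as.character(donor_means$donor[!complete])
  } else character(0)
  if (any(!complete))
    warnf("excluding %d donor(s) missing a condition: %s",
          sum(!complete), paste(excluded, collapse = ", "))
  x <- donor_means$differentiated[complete]
  y <- donor_means$control[complete]
  n <- length(x)
  if (n < 2L) stopf("repeated-measures ANOVA needs at least 2 complete donors")
  grand <- mean(c(x, y))
  cm <- c(mean(x), mean(y))                     # condition means
  dm <- (x + y) / 2                             # donor means
  ss_cond <- n * sum((cm - grand)^2)
  # interaction = residual after removing donor and condition main effects
  ss_err <- sum((x - dm - cm[1] + grand)^2) + sum((y - dm - cm[2] + grand)^2)
  df2 <- n - 1L
  if (ss_err == 0) {
    if (ss_cond == 0) {
      Fv <- 0; p <- 1
    } else {
      warnf("zero interaction SS: F reported as Inf, p = 0 (degenerate)")
      Fv <- Inf; p <- 0
    }
  } else {
    Fv <- ss_cond / (ss_err / df2)
    p <- stats::pf(Fv, 1, df2, lower.tail = FALSE)
  }
  structure(list(F = Fv, df1 = 1L, df2 = df2, p = p,
                 mean_differentiated = cm[1], mean_control = cm[2],
                 n_donors = n, excluded = excluded),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("rm-ANOVA (condition fixed, donor random): F(%d,%d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  cat(sprintf("  mean differentiated = %.4g, mean control = %.4g, n = %d donors\n",
              x$mean_differentiated, x$mean_control, x$n_donors))
  invisible(x)
}

#' Process a whole study
#'
#' Quantifies every image in the layout, aggregates to donor level,
#' computes normalized DRs (with the pooled-control fallback where a donor
#' has no usable controls), classifies donors, runs the repeated-measures
#' ANOVA, and — for chondrogenic studies — measures pellet areas per
#' section and runs the same ANOVA on per-donor mean areas. Per-image
#' failures are logged and skipped; the study fails only if more than half
#' of its images fail.
#'
#' @param layout a `study_layout` from [discover_study()].
#' @param calib a `calibration_pair` (one acquisition series), or a named
#'   list of pairs keyed by donor.
#' @param basis a `stain_basis`.
#' @param method auto-threshold method.
#' @param fixed_threshold optional study-wide fixed threshold.
#' @param pixel_size_um pixel size attached to every image.
#' @param pellet_ellipses optional data.frame `section_id, major_mm,
#'   minor_mm` of manually fitted pellet ellipses (chondrogenic); when
#'   absent, pellet areas use the automatic mask.
#' @param out_dir optional directory; when set, writes `records.csv`,
#'   `summary.csv`, `anova.csv` and `run_log.txt`.
#' @return A `study_result`: list with `records`, `summary`, `anova`,
#'   `pellets`, `pellet_anova`, `failures`, `log`.
#' @export
process_study <- function(layout, calib, basis, method = "otsu",
                          fixed_threshold = NULL, pixel_size_um = 1,
                          pellet_ellipses = NULL, out_dir = NULL) {
  stopifnot(inherits(layout, "study_layout"))
  log <- c(sprintf("study: %s lineage, %d images", layout$lineage,
                   nrow(layout$images)),
           layout$warnings)
  get_calib <- function(donor) {
    if (inherits(calib, "calibration_pair")) calib
    else calib[[donor]] %||% stopf("no calibration pair for donor %s", donor)
  }
  recs <- list(); fails <- character(0)
  for (i in seq_len(nrow(layout$images))) {
    row <- layout$images[i, ]
    r <- tryCatch({
      img <- read_rgb_image(row$path, pixel_size_um)
      q <- quantify_image(img, get_calib(row$donor), basis, method,
                          fixed_threshold)
      cbind(donor = row$donor, condition = row$condition, well = row$well, q,
            stringsAsFactors = FALSE)
    }, error = function(e) {
      fails <<- c(fails, sprintf("%s: %s", row$path, conditionMessage(e)))
      NULL
    })
    if (!is.null(r)) recs[[length(recs) + 1L]] <- r
  }
  if (length(fails) > nrow(layout$images) / 2)
    stopf("study failed: %d of %d images could not be quantified:\n%s",
          length(fails), nrow(layout$images),
          paste(utils::head(fails, 10), collapse = "\n"))
  if (length(fails))
    log <- c(log, sprintf("skipped %d failed image(s)", length(fails)), fails)
  records <- do.call(rbind, recs)

  donors <- sort(unique(records$donor))
  agg <- function(d, cond) {
    sub <- records[records$donor == d & records$condition == cond, ,
                   drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    tryCatch(aggregate_donor(sub), error = function(e) NULL)
  }
  srows <- list()
  for (d in donors) {
    ad <- agg(d, "differentiated"); ac <- agg(d, "control")
    srows[[d]] <- data.frame(
      donor = d, lineage = layout$lineage,
      mean_dr_differentiated = if (is.null(ad)) NA_real_ else ad$mean_dr,
      mean_dr_control = if (is.null(ac)) NA_real_ else ac$mean_dr,
      n_images_differentiated = if (is.null(ad)) 0L else ad$n_images,
      n_images_control = if (is.null(ac)) 0L else ac$n_images,
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, srows)
  summary$control_source <- ifelse(is.na(summary$mean_dr_control),
                                   "pooled-fallback", "own")
  ctrl_for <- function(k) {
    if (!is.na(summary$mean_dr_control[k])) return(summary$mean_dr_control[k])
    others <- summary$mean_dr_control[-k]
    tryCatch({
      v <- fallback_control(others)
      log <<- c(log, sprintf(
        "donor %s: pooled-control fallback over %d other donor(s), mean %.6g",
        summary$donor[k], sum(!is.na(others)), v))
      v
    }, error = function(e) {
      log <<- c(log, sprintf("donor %s: %s", summary$donor[k],
                             conditionMessage(e)))
      NA_real_
    })
  }
  summary$dr_normalized <- vapply(seq_len(nrow(summary)), function(k)
    normalized_dr(summary$mean_dr_differentiated[k], ctrl_for(k)), 0.0)
  summary$classification <- vapply(summary$dr_normalized,
                                   classify_dr_normalized, "")

  pairs <- data.frame(donor = summary$donor,
                      differentiated = summary$mean_dr_differentiated,
                      control = summary$mean_dr_control)
  anova <- withCallingHandlers(
    tryCatch(rm_anova_two_condition(pairs), error = function(e) {
      log <<- c(log, sprintf("ANOVA skipped: %s", conditionMessage(e)))
      NULL
    }),
    warning = function(w) {
      log <<- c(log, conditionMessage(w)); invokeRestart("muffleWarning")
    })

  pellets <- NULL; pellet_anova <- NULL
  if (layout$lineage == "chondrogenic") {
    pl <- pellet_measurements(layout, get_calib, basis, method,
                              pixel_size_um, pellet_ellipses)
    pellets <- pl$table; log <- c(log, pl$log)
    pa <- stats::aggregate(area_mm2 ~ donor + condition, data = pellets,
                           FUN = mean)
    wide <- merge(pa[pa$condition == "differentiated",
                     c("donor", "area_mm2")],
                  pa[pa$condition == "control", c("donor", "area_mm2")],
                  by = "donor", all = TRUE,
                  suffixes = c("_differentiated", "_control"))
    names(wide) <- c("donor", "differentiated", "control")
    pellet_anova <- withCallingHandlers(
      tryCatch(rm_anova_two_condition(wide), error = function(e) {
        log <<- c(log, sprintf("pellet ANOVA skipped: %s",
                               conditionMessage(e)))
        NULL
      }),
      warning = function(w) {
        log <<- c(log, conditionMessage(w)); invokeRestart("muffleWarning")
      })
  }

  res <- structure(list(records = records, summary = summary, anova = anova,
                        pellets = pellets, pellet_anova = pellet_anova,
                        failures = fails, log = log),
                   class = "study_result")
  if (!is.null(out_dir)) write_study_result(res, out_dir)
  res
}

pellet_measurements <- function(layout, get_calib, basis, method,
                                pixel_size_um, pellet_ellipses) {
  log <- character(0); rows <- list()
  if (!is.null(pellet_ellipses)) {
    stopifnot(all(c("section_id", "major_mm", "minor_mm") %in%
                    names(pellet_ellipses)))
    for (i in seq_len(nrow(pellet_ellipses))) {
      e <- pellet_ellipses[i, ]
      key <- basename(tools::file_path_sans_ext(layout$images$path)) ==
        e$section_id | layout$images$path == e$section_id
      m <- layout$images[key, , drop = FALSE]
      if (nrow(m) != 1L) {
        log <- c(log, sprintf("ellipse row %s matches %d sections; skipped",
                              e$section_id, nrow(m)))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        donor = m$donor, condition = m$condition, section_id = e$section_id,
        area_mm2 = ellipse_area(e$major_mm, e$minor_mm), mode = "manual-ellipse",
        stringsAsFactors = FALSE)
    }
  } else {
    for (i in seq_len(nrow(layout$images))) {
      row <- layout$images[i, ]
      p <- tryCatch({
        img <- read_rgb_image(row$path, pixel_size_um)
        suppressWarnings(
          auto_pellet_area(img, get_calib(row$donor), basis, method))
      }, error = function(e) NULL)
      if (is.null(p)) {
        log <- c(log, sprintf("pellet measurement failed for %s", row$path))
        next
      }
      if (!is.na(p$warning)) log <- c(log, p$warning)
      rows[[length(rows) + 1L]] <- data.frame(
        donor = row$donor, condition = row$condition,
        section_id = row$path, area_mm2 = p$area_mm2, mode = p$mode,
        stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), log = log)
}

#' Write a study result to disk
#'
#' @param res a `study_result`.
#' @param out_dir destination directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_study_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_measurements(res$records, file.path(out_dir, "records.csv"))
  write_measurements(res$summary, file.path(out_dir, "summary.csv"))
  an <- list()
  if (!is.null(res$anova)) an[["dr"]] <- res$anova
  if (!is.null(res$pellet_anova)) an[["pellet_area"]] <- res$pellet_anova
  if (length(an)) {
    adf <- do.call(rbind, lapply(names(an), function(nm) {
      a <- an[[nm]]
      data.frame(analysis = nm, F = a$F, df1 = a$df1, df2 = a$df2, p = a$p,
                 mean_differentiated = a$mean_differentiated,
                 mean_control = a$mean_control, n_donors = a$n_donors)
    }))
    write_measurements(adf, file.path(out_dir, "anova.csv"))
  }
  if (!is.null(res$pellets))
    write_measurements(res$pellets, file.path(out_dir, "pellets.csv"))
  writeLines(res$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result: %d records, %d donors, %d failures>\n",
              nrow(x$records), nrow(x$summary), length(x$failures)))
  print(x$summary)
  if (!is.null(x$anova)) print(x$anova)
  invisible(x)
}
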