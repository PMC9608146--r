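mk_records <- function(well_drs) {
  do.call(rbind, lapply(names(well_drs), function(w)
    data.frame(well = if (w == "NA") NA_character_ else w,
               dr = well_drs[[w]], stringsAsFactors = FALSE)))
}

test_that("donor aggregation is the mean of well means", {
  # balanced and constant
  r <- mk_records(list(w1 = rep(0.5, 4), w2 = rep(0.5, 4), w3 = rep(0.5, 4)))
  expect_equal(aggregate_donor(r)$mean_dr, 0.5)

  # three wells at distinct levels
  r2 <- mk_records(list(w1 = rep(0.2, 4), w2 = rep(0.4, 4), w3 = rep(0.6, 4)))
  expect_equal(aggregate_donor(r2)$mean_dr, 0.4)

  # unbalanced wells: equals the mean of well means, not the grand mean
  r3 <- mk_records(list(w1 = rep(0.2, 4), w2 = rep(0.4, 4), w3 = rep(0.8, 2)))
  a <- aggregate_donor(r3)
  expect_equal(a$mean_dr, mean(c(0.2, 0.4, 0.8)))
  expect_false(isTRUE(all.equal(a$mean_dr, mean(r3$dr))))

  # sections (no well level) average directly
  r4 <- mk_records(list(`NA` = c(0.1, 0.2, 0.6)))
  expect_equal(aggregate_donor(r4)$mean_dr, 0.3)

  # undefined DRs are excluded and counted
  r5 <- rbind(r2, data.frame(well = "w1", dr = NA_real_))
  a5 <- aggregate_donor(r5)
  expect_equal(a5$mean_dr, 0.4)
  expect_equal(a5$n_undefined, 1L)
  expect_error(aggregate_donor(mk_records(list(w1 = NA_real_))), "no defined")
})

test_that("normalization, fallback and classification follow the DR^N reading", {
  expect_equal(normalized_dr(0.6, 0.4), 1.5)
  expect_equal(normalized_dr(0.4, 0.4), 1.0)
  expect_true(is.na(normalized_dr(0.4, 0)))

  expect_equal(fallback_control(c(0.2, 0.3, 0.4)), 0.3)
  expect_equal(fallback_control(0.5), 0.5)
  expect_error(fallback_control(numeric(0)), "impossible")

  # below 1 = less differentiation than the non-induced control
  expect_equal(classify_dr_normalized(0.86), "below-control")
  expect_equal(classify_dr_normalized(1.46), "above-control")
  expect_equal(classify_dr_normalized(0.75), "below-control")
  expect_equal(classify_dr_normalized(1.0), "neutral")
  expect_true(is.na(classify_dr_normalized(NA_real_)))
})

test_that("DR^N is exactly 1 for identical condition image sets and scales linearly", {
  recs <- mk_records(list(w1 = c(0.31, 0.27), w2 = c(0.42, 0.40)))
  m <- aggregate_donor(recs)$mean_dr
  expect_identical(normalized_dr(m, m), 1)

  # multiplying one donor's image DRs by k multiplies its mean by k
  k <- 2.7
  recs_k <- recs; recs_k$dr <- recs_k$dr * k
  expect_equal(aggregate_donor(recs_k)$mean_dr, k * m)
})

test_that("ellipse and automatic pellet areas agree with geometry", {
  expect_equal(ellipse_area(2, 2), pi)
  expect_equal(ellipse_area(3, 2), 1.5 * pi)
  expect_error(ellipse_area(3, 0), "major >= minor > 0")
  expect_error(ellipse_area(1, 2), "major >= minor > 0")

  # rendered 2 x 1 mm elliptical pellet at 10 um/px: truth 0.5 * pi mm^2
  b <- default_basis()
  sc <- synthetic_scene(260, 260, regions = list(
    list(shape = "ellipse", cx = 130, cy = 130, rx = 100, ry = 50,
         stain = 1, conc = 0.7)))
  r <- render_stained_image(sc, b, pixel_size_um = 10)
  p <- auto_pellet_area(r$image, NULL, b)
  expect_lt(abs(p$area_mm2 / (0.5 * pi) - 1), 0.03)
  expect_equal(p$mode, "auto-mask")

  # two blobs: only the largest connected component counts
  sc2 <- synthetic_scene(200, 200, regions = list(
    list(shape = "disk", cx = 60, cy = 60, rx = 30, ry = 30,
         stain = 1, conc = 0.7),
    list(shape = "disk", cx = 170, cy = 170, rx = 5, ry = 5,
         stain = 2, conc = 0.7)))
  r2 <- render_stained_image(sc2, b, pixel_size_um = 10)
  p2 <- auto_pellet_area(r2$image, NULL, b)
  expect_lt(abs(p2$n_pixels / sum(r2$truth$mask1) - 1), 0.05)

  # blank section: zero area with a warning, not an error
  blank <- flat_image(255, 64, 64)
  expect_warning(p3 <- auto_pellet_area(blank, NULL, b), "empty foreground")
  expect_equal(p3$area_mm2, 0)
})

test_that("the repeated-measures F equals the squared paired t statistic", {
  pairs <- data.frame(donor = 1:4,
                      differentiated = c(0.6, 0.5, 0.7, 0.55),
                      control = c(0.4, 0.45, 0.5, 0.5))
  a <- rm_anova_two_condition(pairs)
  tt <- t.test(pairs$differentiated, pairs$control, paired = TRUE)
  expect_equal(a$F, unname(tt$statistic^2), tolerance = 1e-8)
  expect_equal(a$p, tt$p.value, tolerance = 1e-8)
  expect_equal(a$df1, 1L); expect_equal(a$df2, 3L)

  # independent route: stats::aov with a donor error stratum
  long <- data.frame(donor = factor(rep(pairs$donor, 2)),
                     cond = rep(c("d", "c"), each = 4),
                     y = c(pairs$differentiated, pairs$control))
  sv <- summary(aov(y ~ cond + Error(donor), data = long))
  Faov <- sv[["Error: Within"]][[1]][["F value"]][1]
  expect_equal(a$F, Faov, tolerance = 1e-8)

  # property over random draws
  set.seed(55)
  for (i in 1:50) {
    n <- sample(3:9, 1)
    x <- runif(n); y <- runif(n)
    a2 <- rm_anova_two_condition(data.frame(differentiated = x, control = y))
    t2 <- t.test(x, y, paired = TRUE)
    expect_equal(a2$F, unname(t2$statistic^2), tolerance = 1e-8)
  }
})

test_that("degenerate and incomplete ANOVA inputs behave as documented", {
  # identical conditions: F = 0, p = 1
  a <- rm_anova_two_condition(
    data.frame(differentiated = c(0.3, 0.5, 0.4), control = c(0.3, 0.5, 0.4)))
  expect_equal(a$F, 0); expect_equal(a$p, 1)

  # constant non-zero difference: zero interaction, F = Inf, p = 0
  expect_warning(
    a2 <- rm_anova_two_condition(
      data.frame(differentiated = rep(0.5, 4), control = rep(0.3, 4))),
    "zero interaction")
  expect_identical(a2$F, Inf); expect_equal(a2$p, 0)

  # donors missing one condition are excluded with a warning
  expect_warning(
    a3 <- rm_anova_two_condition(data.frame(
      donor = c("a", "b", "c"),
      differentiated = c(0.6, 0.5, 0.7),
      control = c(0.4, NA, 0.5))),
    "excluding")
  expect_equal(a3$n_donors, 2L)
  expect_equal(a3$excluded, "b")

  expect_error(rm_anova_two_condition(
    data.frame(differentiated = 0.5, control = 0.3)), "at least 2")
})

test_that("process_study aggregates a rendered study and applies the fallback", {
  root <- withr::local_tempdir("study")
  unlink(root, recursive = TRUE)
  g <- generate_synthetic_study(root, n_donors = 3,
                                effect_multipliers = c(4, 4, 4),
                                wells = 2, images_per_well = 2,
                                size = 64, seed = 3)
  # remove one donor's controls to force the pooled fallback
  unlink(file.path(root, "donor03", "control"), recursive = TRUE)
  lay <- discover_study(root, "adipogenic")
  calib <- calibration_pair(read_rgb_image(g$calibration$dark),
                            read_rgb_image(g$calibration$light))
  res <- process_study(lay, calib, g$basis, out_dir = file.path(root, "out"))
  expect_equal(nrow(res$summary), 3)
  expect_equal(res$summary$control_source,
               c("own", "own", "pooled-fallback"))
  expect_true(all(res$summary$classification == "above-control"))
  # fallback denominator is the mean of the other donors' control means
  expect_equal(res$summary$dr_normalized[3],
               res$summary$mean_dr_differentiated[3] /
                 mean(res$summary$mean_dr_control[1:2]))
  for (f in c("records.csv", "summary.csv", "anova.csv", "run_log.txt"))
    expect_true(file.exists(file.path(root, "out", f)))
  # every record traces to exactly one layout path
  expect_setequal(res$records$image_id,
                  lay$images$path[lay$images$donor != "donor03" |
                                    lay$images$condition != "control"])
})
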