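#' RGB micrograph container
#'
#' Wraps an H x W x 3 pixel array with the physical pixel size and source
#' path. Two modes exist: `"8bit"` (integer values 0-255, as read from disk)
#' and `"real"` (unit-interval doubles, after flat-field correction).
#'
#' @param pixels numeric H x W x 3 array.
#' @param pixel_size_um physical edge length of one pixel in micrometres.
#' @param source_path origin identifier (informational).
#' @param mode `"8bit"` or `"real"`.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, pixel_size_um = 1, source_path = "<memory>",
                      mode = c("8bit", "real")) {
  mode <- match.arg(mode)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stopf("pixels must be an H x W x 3 array (got dims: %s)",
          paste(dim(pixels), collapse = "x"))
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stopf("image must have at least one row and one column")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stopf("pixel_size_um must be a single positive number")
  if (mode == "8bit") {
    if (min(pixels) < 0 || max(pixels) > 255)
      stopf("8-bit image values must lie in [0, 255]")
  } else {
    if (min(pixels) < 0 || max(pixels) > 1)
      stopf("real-valued image values must lie in [0, 1]")
  }
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 source_path = source_path, mode = mode),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image %dx%d %s, %.4g um/px, %s>\n",
              d[1], d[2], x$mode, x$pixel_size_um, x$source_path))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)

#' Read an 8-bit RGB image from disk
#'
#' Accepts 8-bit RGB PNG or TIFF. Greyscale images, images of other bit
#' depths and RGBA images with a non-constant alpha plane are rejected with
#' an error naming the path: bit depth is never converted silently.
#'
#' @param path file path (.png, .tif or .tiff).
#' @param pixel_size_um pixel size attached to the result (from study
#'   config; image metadata is not trusted).
#' @return An `rgb_image` in `"8bit"` mode.
#' @export
read_rgb_image <- function(path, pixel_size_um = 1) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    depth <- attr(raw, "info")$bit.depth
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(raw, "bits.per.sample")
  } else {
    stopf("unsupported image format '%s' for %s (use 8-bit PNG or TIFF)",
          ext, path)
  }
  if (!is.null(depth) && !all(depth == 8L))
    stopf("%s is %d-bit; this pipeline requires 8-bit input (convert explicitly)",
          path, max(depth))
  if (is.matrix(raw))
    stopf("%s is single-channel; 3-channel RGB input required", path)
  nch <- dim(raw)[3]
  if (nch == 4L) {
    alpha <- raw[, , 4]
    if (max(alpha) - min(alpha) > 0)
      stopf("%s has a non-constant alpha channel; flatten it before analysis",
            path)
    raw <- raw[, , 1:3, drop = FALSE]
  } else if (nch != 3L) {
    stopf("%s has %d channels; 3-channel RGB input required", path, nch)
  }
  px <- round_half_up(raw * 255)
  attributes(px) <- list(dim = dim(px))  # drop decoder metadata
  storage.mode(px) <- "integer"
  rgb_image(px, pixel_size_um = pixel_size_um, source_path = path,
            mode = "8bit")
}

#' Write an 8-bit RGB image to disk
#'
#' @param img an `rgb_image` in `"8bit"` mode.
#' @param path destination (.png, .tif or .tiff).
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  if (img$mode != "8bit")
    stopf("only 8-bit images are written to disk; got mode '%s'", img$mode)
  ext <- tolower(tools::file_ext(path))
  arr <- img$pixels / 255
  if (ext == "png") {
    png::writePNG(arr, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  } else {
    stopf("unsupported output format '%s'", ext)
  }
  invisible(path)
}

#' Discover the donor/condition/well/image tree of a study
#'
#' Walks `<root>/<donor>/<condition>/<well>/<image>` (adipogenic,
#' osteogenic) or `<root>/<donor>/<condition>/<image>` (chondrogenic:
#' sections, no well level). Conditions are `differentiated` and `control`.
#' Ordering is lexicographic at every level, so the layout is a pure
#' function of the set of paths on disk.
#'
#' @param root study root directory.
#' @param lineage one of `"adipogenic"`, `"chondrogenic"`, `"osteogenic"`.
#' @return A `study_layout`: list with `lineage`, `images` (data.frame with
#'   donor, condition, well, path), per-donor counts and `warnings`.
#' @export
discover_study <- function(root,
                           lineage = c("adipogenic", "chondrogenic",
                                       "osteogenic")) {
  lineage <- match.arg(lineage)
  if (!dir.exists(root)) stopf("study root does not exist: %s", root)
  has_wells <- lineage != "chondrogenic"
  img_re <- "\\.(png|tif|tiff)$"
  donors <- sort(setdiff(list.dirs(root, recursive = FALSE,
                                   full.names = FALSE), "calibration"))
  if (length(donors) == 0L) stopf("no donor directories under %s", root)
  rows <- list(); warnings <- character(0)
  for (d in donors) {
    conds <- sort(intersect(
      list.dirs(file.path(root, d), recursive = FALSE, full.names = FALSE),
      c("differentiated", "control")))
    if (length(conds) == 0L) {
      warnings <- c(warnings, sprintf("donor %s has no condition directories", d))
      next
    }
    if (length(conds) == 1L)
      warnings <- c(warnings, sprintf(
        "donor %s present in only one condition (%s); normalization may need the pooled-control fallback",
        d, conds))
    for (cn in conds) {
      cdir <- file.path(root, d, cn)
      if (has_wells) {
        wells <- sort(list.dirs(cdir, recursive = FALSE, full.names = FALSE))
        for (w in wells) {
          imgs <- sort(list.files(file.path(cdir, w), pattern = img_re,
                                  full.names = TRUE))
          for (p in imgs)
            rows[[length(rows) + 1L]] <- data.frame(
              donor = d, condition = cn, well = w, path = p,
              stringsAsFactors = FALSE)
        }
      } else {
        imgs <- sort(list.files(cdir, pattern = img_re, full.names = TRUE))
        for (p in imgs)
          rows[[length(rows) + 1L]] <- data.frame(
            donor = d, condition = cn, well = NA_character_, path = p,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) stopf("no images found under %s", root)
  images <- do.call(rbind, rows)
  if (anyDuplicated(images$path))
    stopf("duplicate image paths in layout under %s", root)
  counts <- stats::aggregate(path ~ donor + condition, data = images, FUN = length)
  names(counts)[3] <- "n_images"
  structure(list(lineage = lineage, root = root, images = images,
                 counts = counts, warnings = warnings),
            class = "study_layout")
}

#' @export
print.study_layout <- function(x, ...) {
  cat(sprintf("<study_layout %s: %d images, %d donors>\n", x$lineage,
              nrow(x$images), length(unique(x$images$donor))))
  print(x$counts)
  if (length(x$warnings)) cat("warnings:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' Write measurement records to CSV
#'
#' Full-precision CSV (17 significant digits) so that re-reading reproduces
#' every value exactly.
#'
#' @param records non-empty data.frame of records.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stopf("no records to write")
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), NA, sprintf("%.17g", out[[j]]))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}
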