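#' Default per-class MSI intensity calibration
#'
#' Mean 8-bit ROI pixel levels for the 550 nm band, the band at which the
#' tissue classes separate most: ~48 (control WAT) falling to ~20
#' (control BAT), with treated WAT at 33 (day 4) and 23 (day 7); treated
#' BAT matches control BAT. At 680 nm all classes share one common level
#' (band images there show minimal variation), and the 600 nm level is
#' linearly interpolated in wavelength between the two.
#'
#' These levels are deliberately independent generator parameters, not
#' derived from the spectral templates: printed ROI means and spectral
#' ratios need not be consistent under a single illumination gain.
#'
#' @return List with `l550` (named per-class vector) and `l680` (common
#'   scalar level).
#' @export
default_msi_levels <- function() {
  list(
    l550 = c(C_WAT = 48, TrWAT_d4 = 33, TrWAT_d7 = 23, C_BAT = 20,
             TrBAT_d4 = 20, TrBAT_d7 = 20),
    l680 = 50
  )
}

#' Expected ROI pixel level for a class at a band
#'
#' @param class_label one of [class_labels()].
#' @param band_nm 550, 600 or 680.
#' @param levels calibration from [default_msi_levels()].
#' @return Expected mean 8-bit pixel level.
#' @export
msi_level <- function(class_label, band_nm, levels = default_msi_levels()) {
  if (!class_label %in% names(levels$l550)) {
    stop_fmt("unknown class label: %s", class_label)
  }
  if (!band_nm %in% c(550, 600, 680)) stop_fmt("band must be 550, 600 or 680 nm")
  l550 <- levels$l550[[class_label]]
  if (band_nm == 550) return(l550)
  if (band_nm == 680) return(levels$l680)
  l550 + (levels$l680 - l550) * (600 - 550) / (680 - 550)
}

#' Rectangular or mask region of interest
#'
#' @param row0,col0 top-left corner (1-based) of the rectangle.
#' @param height,width rectangle size in pixels.
#' @param mask alternatively, a logical matrix marking ROI pixels; if
#'   given, the rectangle arguments are ignored.
#' @return A `roi_spec` object.
#' @export
roi_spec <- function(row0 = NULL, col0 = NULL, height = NULL, width = NULL,
                     mask = NULL) {
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), is.matrix(mask))
    if (!any(mask)) stop_fmt("ROI mask selects no pixels")
    return(structure(list(type = "mask", mask = mask), class = "roi_spec"))
  }
  stopifnot(row0 >= 1, col0 >= 1, height >= 1, width >= 1)
  structure(list(type = "rect", row0 = as.integer(row0),
                 col0 = as.integer(col0), height = as.integer(height),
                 width = as.integer(width)),
            class = "roi_spec")
}

# Logical mask of ROI pixels for an image of dimensions `dim` (rows, cols),
# with bounds checking.
roi_mask <- function(roi, dim) {
  stopifnot(inherits(roi, "roi_spec"))
  if (roi$type == "mask") {
    if (!identical(base::dim(roi$mask), as.integer(dim))) {
      stop_fmt("ROI mask dimensions (%s) do not match image (%s)",
               paste(base::dim(roi$mask), collapse = "x"),
               paste(dim, collapse = "x"))
    }
    return(roi$mask)
  }
  r1 <- roi$row0 + roi$height - 1L
  c1 <- roi$col0 + roi$width - 1L
  if (r1 > dim[1L] || c1 > dim[2L]) {
    stop_fmt("ROI (rows %d-%d, cols %d-%d) exceeds image bounds %dx%d",
             roi$row0, r1, roi$col0, c1, dim[1L], dim[2L])
  }
  m <- matrix(FALSE, dim[1L], dim[2L])
  m[roi$row0:r1, roi$col0:c1] <- TRUE
  m
}

#' Simulate one band-pass image of a tissue sample
#'
#' Pixels inside the ROI are drawn from a Gaussian around the calibrated
#' class/band level, then clipped to [0, 255] and quantized to 8-bit
#' integers; pixels outside the ROI take a constant background level.
#'
#' @param class_label one of [class_labels()].
#' @param band_nm imaging band, 550, 600 or 680 nm.
#' @param shape image dimensions `c(rows, cols)`.
#' @param roi a [roi_spec()] inside `shape`; default a centered 64x64
#'   square.
#' @param texture_sd Gaussian texture standard deviation (8-bit units).
#' @param seed RNG seed (`NULL` = current stream).
#' @param levels class-level calibration, [default_msi_levels()].
#' @param background background pixel level outside the ROI.
#' @return A [band_image()].
#' @export
simulate_band_image <- function(class_label, band_nm, shape = c(96, 96),
                                roi = default_roi(shape), texture_sd = 3,
                                seed = NULL, levels = default_msi_levels(),
                                background = 5) {
  level <- msi_level(class_label, band_nm, levels)
  mask <- roi_mask(roi, shape)
  pixels <- matrix(as.integer(round(background)), shape[1L], shape[2L])
  n_in <- sum(mask)
  vals <- with_seed(seed, stats::rnorm(n_in, mean = level, sd = texture_sd))
  pixels[mask] <- as.integer(round(pmin(pmax(vals, 0), 255)))
  band_image(pixels, band_nm, bit_depth = 8L)
}

#' Default centered square ROI
#'
#' @param shape image dimensions `c(rows, cols)`.
#' @param size ROI side length in pixels (default 64).
#' @return A [roi_spec()] centered in the image.
#' @export
default_roi <- function(shape = c(96, 96), size = 64) {
  roi_spec(row0 = floor((shape[1L] - size) / 2) + 1L,
           col0 = floor((shape[2L] - size) / 2) + 1L,
           height = size, width = size)
}

#' Simulate band images for a full phantom study
#'
#' @param classes class labels to simulate.
#' @param n_mice samples per class.
#' @param bands imaging bands in nm.
#' @param shape,roi,texture_sd,levels,background per-image parameters, see
#'   [simulate_band_image()].
#' @param seed master seed, split per image.
#' @return List of entries `list(image, sample_id, group, tissue, day)`,
#'   the input of [quantify_msi()] and [write_msi_dataset()].
#' @export
simulate_msi_dataset <- function(classes = class_labels(), n_mice = 8,
                                 bands = c(550, 600, 680), shape = c(96, 96),
                                 roi = default_roi(shape), texture_sd = 3,
                                 seed = NULL, levels = default_msi_levels(),
                                 background = 5) {
  entries <- list()
  for (ci in seq_along(classes)) {
    lab <- classes[ci]
    meta <- parse_class_label(lab)
    for (i in seq_len(n_mice)) {
      day <- if (is.na(meta$day)) (if (i <= n_mice / 2) 4L else 7L) else meta$day
      for (bi in seq_along(bands)) {
        img_seed <- derive_seed(seed, ci * 100000L + i * 10L + bi)
        entries[[length(entries) + 1L]] <- list(
          image = simulate_band_image(lab, bands[bi], shape, roi, texture_sd,
                                      img_seed, levels, background),
          sample_id = sprintf("%s_s%d", lab, i),
          group = meta$group, tissue = meta$tissue, day = day)
      }
    }
  }
  entries
}
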