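#' Construct a band-pass image
#'
#' @param pixels 2D matrix of pixel intensities (integer counts for 8/16
#'   bit data).
#' @param band_center band-pass filter center, one of 550, 600, 680 nm.
#' @param bit_depth 8 or 16.
#' @return A `band_image` object.
#' @export
band_image <- function(pixels, band_center, bit_depth = 8L) {
  stopifnot(is.matrix(pixels), length(pixels) > 0L)
  if (!band_center %in% c(550, 600, 680)) {
    stop_fmt("band_center must be 550, 600 or 680 nm")
  }
  maxval <- 2^bit_depth - 1
  if (any(pixels < 0 | pixels > maxval)) {
    stop_fmt("pixel values outside the declared %d-bit range", bit_depth)
  }
  structure(list(pixels = pixels, band_center = as.integer(band_center),
                 bit_depth = as.integer(bit_depth)),
            class = "band_image")
}

#' @export
print.band_image <- function(x, ...) {
  cat(sprintf("%d-bit band image at %d nm: %dx%d pixels\n",
              x$bit_depth, x$band_center, nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}

#' Load a band image from a TIFF or PNG file
#'
#' RGB images are collapsed to grayscale by the unweighted channel mean
#' (the default: under narrow band-pass illumination the camera's color
#' response carries no information) or by Rec. 601 luma weights.
#'
#' @param path TIFF or PNG file.
#' @param band_center band-pass center in nm to record on the image.
#' @param channel_policy "mean" (unweighted) or "luma" (0.299/0.587/0.114).
#' @return A [band_image()] with integer pixels on the native bit depth.
#' @export
load_band_image <- function(path, band_center,
                            channel_policy = c("mean", "luma")) {
  channel_policy <- match.arg(channel_policy)
  if (!file.exists(path)) stop_fmt("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
    png = {
      a <- png::readPNG(path)
      round(a * 255)  # readPNG rescales to [0,1]; restore 8-bit counts
    },
    stop_fmt("unsupported image format '.%s' (TIFF or PNG expected)", ext))
  if (length(arr) == 0L) stop_fmt("empty image: %s", path)
  if (length(dim(arr)) == 3L) {
    nchan <- min(dim(arr)[3L], 3L)  # drop alpha if present
    w <- if (channel_policy == "mean") rep(1 / nchan, nchan)
         else c(0.299, 0.587, 0.114)[seq_len(nchan)] / sum(c(0.299, 0.587, 0.114)[seq_len(nchan)])
    gray <- matrix(0, dim(arr)[1L], dim(arr)[2L])
    for (k in seq_len(nchan)) gray <- gray + w[k] * arr[, , k]
    arr <- gray
  }
  bit_depth <- if (max(arr) > 255) 16L else 8L
  band_image(as.matrix(arr), band_center, bit_depth)
}

#' Mean pixel intensity over a fixed ROI
#'
#' Arithmetic mean in double precision of all pixels inside the region of
#' interest; pixels outside the ROI never contribute.
#'
#' @param image a [band_image()].
#' @param roi a [roi_spec()] inside the image bounds.
#' @return Mean intensity (intensity units of the image's bit depth).
#' @export
extract_roi_mean <- function(image, roi) {
  stopifnot(inherits(image, "band_image"))
  mask <- roi_mask(roi, dim(image$pixels))
  mean(as.numeric(image$pixels[mask]))
}

#' Quantify ROI intensities for an MSI dataset
#'
#' Extracts the fixed-ROI mean of every image, and summarizes group means
#' +/- SE per band. Raw ROI means are reported by default; pass
#' `normalize_to` to also report intensities relative to a reference
#' class's group mean at the same band.
#'
#' @param entries list of image entries (`image`, `sample_id`, `group`,
#'   `tissue`, `day`), e.g. from [simulate_msi_dataset()] or
#'   [load_msi_dataset()].
#' @param roi a [roi_spec()] shared by all images.
#' @param normalize_to optional reference class label (e.g. `"C_WAT"`).
#' @return List with `samples` (per-image data.frame: metadata, `band`,
#'   `roi_mean`, optionally `normalized`) and `summary` (per band,
#'   [summarize_groups()] output with a `band` column).
#' @export
quantify_msi <- function(entries, roi, normalize_to = NULL) {
  rows <- lapply(entries, function(e) {
    data.frame(sample_id = e$sample_id, group = e$group, tissue = e$tissue,
               day = e$day, cell = analysis_cell(e$group, e$tissue, e$day),
               band = e$image$band_center,
               roi_mean = extract_roi_mean(e$image, roi),
               stringsAsFactors = FALSE)
  })
  samples <- do.call(rbind, rows)
  bands <- sort(unique(samples$band))
  per_sample_bands <- table(samples$sample_id)
  if (length(unique(per_sample_bands)) > 1L) {
    stop_fmt("inconsistent band sets across samples")
  }
  if (!is.null(normalize_to)) {
    samples <- normalize_to_reference(samples, normalize_to)
  }
  summary <- do.call(rbind, lapply(bands, function(b) {
    s <- summarize_groups(samples[samples$band == b, ], "roi_mean")
    cbind(band = b, s)
  }))
  list(samples = samples, summary = summary)
}

#' Normalize ROI intensities to a reference class
#'
#' Divides each sample's ROI mean by the mean ROI intensity of the
#' reference class at the same band, so the reference class normalizes to
#' 1 by construction.
#'
#' @param samples per-image data.frame as produced by [quantify_msi()]
#'   (columns `cell`, `band`, `roi_mean`).
#' @param reference_cell reference class label, default `"C_WAT"`.
#' @return The data.frame with a `normalized` column (re)computed.
#' @export
normalize_to_reference <- function(samples, reference_cell = "C_WAT") {
  samples$normalized <- NA_real_
  for (b in unique(samples$band)) {
    in_band <- samples$band == b
    ref_vals <- samples$roi_mean[in_band & samples$cell == reference_cell]
    if (!length(ref_vals)) {
      stop_fmt("reference class '%s' absent at the %s nm band", reference_cell, b)
    }
    ref_mean <- mean(ref_vals)
    if (ref_mean == 0) stop_fmt("zero reference mean at the %s nm band", b)
    samples$normalized[in_band] <- samples$roi_mean[in_band] / ref_mean
  }
  samples
}
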