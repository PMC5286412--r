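#' Construct a corrected reflectance spectrum
#'
#' @param wavelengths wavelengths in nm (strictly increasing).
#' @param reflectance dimensionless reflectance values.
#' @param mask logical validity flags; masked-out (`FALSE`) points are
#'   excluded from every index computation.
#' @return A `reflectance_spectrum` object.
#' @export
reflectance_spectrum <- function(wavelengths, reflectance,
                                 mask = rep(TRUE, length(wavelengths))) {
  stopifnot(length(wavelengths) == length(reflectance),
            length(mask) == length(wavelengths))
  if (any(diff(wavelengths) <= 0)) {
    stop_fmt("wavelengths must be strictly increasing")
  }
  if (any(!is.finite(reflectance[mask]))) {
    stop_fmt("unmasked reflectance values must be finite")
  }
  structure(list(wavelengths = as.numeric(wavelengths),
                 reflectance = as.numeric(reflectance),
                 mask = as.logical(mask)),
            class = "reflectance_spectrum")
}

#' @export
print.reflectance_spectrum <- function(x, ...) {
  cat(sprintf("Reflectance spectrum: %d points (%d masked), %g-%g nm\n",
              length(x$wavelengths), sum(!x$mask),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Dark- and reference-correct a raw acquisition triple
#'
#' The diffuse reflectance is `R(lambda) = (S - D) / (W - D)` where S, D
#' and W are the sample, dark and reference-standard spectra. Points where
#' the reference signal barely exceeds dark (`W - D <= eps`) are masked as
#' unreliable.
#'
#' @param sample,dark,reference [raw_spectrum()]s on one common grid.
#' @param eps_frac mask threshold as a fraction of `max(W - D)`.
#' @return A [reflectance_spectrum()].
#' @export
compute_reflectance <- function(sample, dark, reference, eps_frac = 1e-6) {
  for (s in list(sample, dark, reference)) stopifnot(inherits(s, "raw_spectrum"))
  if (length(sample$wavelengths) != length(dark$wavelengths) ||
      length(sample$wavelengths) != length(reference$wavelengths) ||
      max(abs(sample$wavelengths - dark$wavelengths)) > 1e-9 ||
      max(abs(sample$wavelengths - reference$wavelengths)) > 1e-9) {
    stop_fmt("sample, dark and reference spectra are not on the same wavelength grid")
  }
  denom <- reference$counts - dark$counts
  eps <- eps_frac * max(denom)
  mask <- denom > eps
  if (!any(mask)) stop_fmt("degenerate input: reference does not exceed dark anywhere")
  refl <- rep(NA_real_, length(denom))
  refl[mask] <- (sample$counts[mask] - dark$counts[mask]) / denom[mask]
  reflectance_spectrum(sample$wavelengths, refl, mask)
}

#' Normalize a reflectance spectrum at a wavelength
#'
#' Divides the whole spectrum by its value at `lambda0` (default 680 nm,
#' where the tissue classes are nearly indistinguishable), making spectra
#' from different illumination intensities comparable.
#'
#' @param R a [reflectance_spectrum()].
#' @param lambda0 normalization wavelength in nm; must be an unmasked grid
#'   point with positive reflectance.
#' @return A [reflectance_spectrum()] with value 1 at `lambda0`.
#' @export
normalize_at <- function(R, lambda0 = 680) {
  stopifnot(inherits(R, "reflectance_spectrum"))
  i <- which.min(abs(R$wavelengths - lambda0))
  if (abs(R$wavelengths[i] - lambda0) > 1e-6) {
    stop_fmt("wavelength %g nm is not on the spectrum grid", lambda0)
  }
  if (!R$mask[i]) stop_fmt("normalization wavelength %g nm is masked", lambda0)
  v0 <- R$reflectance[i]
  if (!is.finite(v0) || v0 <= 0) {
    stop_fmt("reflectance at %g nm is not positive; cannot normalize", lambda0)
  }
  reflectance_spectrum(R$wavelengths, R$reflectance / v0, R$mask)
}

band_indices <- function(R, center, halfwidth) {
  which(R$mask & abs(R$wavelengths - center) <= halfwidth + 1e-9)
}

#' 680/550 nm reflectance intensity ratio
#'
#' First browning index: the ratio of mean reflectance in a narrow band
#' around 680 nm to that around 550 nm. 550 nm sits in the hemoglobin
#' absorption region where browning tissue darkens, 680 nm where all
#' classes look alike, so the ratio rises from white towards brown
#' adipose tissue. Band means (rather than single pixels) are used for
#' noise robustness; the ratio is invariant to global rescaling of R.
#'
#' @param R a [reflectance_spectrum()] (normalization not required).
#' @param lambda_num,lambda_den numerator / denominator band centers, nm.
#' @param halfwidth band half-width in nm.
#' @return Dimensionless ratio.
#' @export
intensity_ratio <- function(R, lambda_num = 680, lambda_den = 550,
                            halfwidth = 2) {
  if (inherits(R, "class_template")) {
    R <- reflectance_spectrum(R$grid, R$values)
  }
  stopifnot(inherits(R, "reflectance_spectrum"))
  num_idx <- band_indices(R, lambda_num, halfwidth)
  den_idx <- band_indices(R, lambda_den, halfwidth)
  if (!length(num_idx) || !length(den_idx)) {
    stop_fmt("empty band: no unmasked points within +/-%g nm of %g nm",
             halfwidth, if (!length(num_idx)) lambda_num else lambda_den)
  }
  den <- mean(R$reflectance[den_idx])
  if (den <= 0) stop_fmt("non-positive mean reflectance in the %g nm band", lambda_den)
  mean(R$reflectance[num_idx]) / den
}

#' 570-630 nm band slope
#'
#' Second browning index: the ordinary least-squares slope of the
#' (680 nm-normalized) reflectance against wavelength over 570-630 nm,
#' reported per 100 nm. Masked points inside the window are dropped from
#' the fit.
#'
#' @param R a [reflectance_spectrum()], normalized at 680 nm by the
#'   pipeline before this call (the slope of an unnormalized spectrum
#'   depends on illumination).
#' @param window slope window `c(lo, hi)` in nm.
#' @return Slope in normalized reflectance per 100 nm.
#' @export
band_slope <- function(R, window = c(570, 630)) {
  if (inherits(R, "class_template")) {
    R <- reflectance_spectrum(R$grid, R$values)
  }
  stopifnot(inherits(R, "reflectance_spectrum"))
  idx <- which(R$mask & R$wavelengths >= window[1L] - 1e-9 &
                 R$wavelengths <= window[2L] + 1e-9)
  if (length(idx) < 3L) {
    stop_fmt("fewer than 3 unmasked points in the %g-%g nm window",
             window[1L], window[2L])
  }
  x <- R$wavelengths[idx]
  y <- R$reflectance[idx]
  fit <- stats::lm.fit(cbind(1, x), y)
  unname(fit$coefficients[2L]) * 100
}

#' Compute the browning indices of one tissue sample
#'
#' For every probe location: dark/reference correction, then the 680/550
#' intensity ratio on the raw reflectance (it is normalization-invariant)
#' and the 570-630 nm slope on the 680 nm-normalized spectrum. Sample
#' values are the unweighted means over locations; per-location values are
#' retained for within-sample dispersion QC.
#'
#' @param record a `sample_record` whose locations are raw triples.
#' @param ratio_bands `c(numerator, denominator)` band centers in nm.
#' @param halfwidth ratio band half-width, nm.
#' @param slope_window slope window `c(lo, hi)` in nm.
#' @param normalize_lambda normalization wavelength for the slope, nm.
#' @return A `browning_indices` object.
#' @export
quantify_sample <- function(record, ratio_bands = c(680, 550), halfwidth = 2,
                            slope_window = c(570, 630),
                            normalize_lambda = 680) {
  stopifnot(inherits(record, "sample_record"))
  n <- length(record$locations)
  ratios <- slopes <- numeric(n)
  for (i in seq_len(n)) {
    triple <- record$locations[[i]]
    R <- tryCatch(
      compute_reflectance(triple$sample, triple$dark, triple$reference),
      error = function(e) stop_fmt("location %d of sample '%s': %s",
                                   i, record$sample_id, conditionMessage(e)))
    ratios[i] <- intensity_ratio(R, ratio_bands[1L], ratio_bands[2L], halfwidth)
    slopes[i] <- band_slope(normalize_at(R, normalize_lambda), slope_window)
  }
  structure(
    list(sample_id = record$sample_id, group = record$group,
         tissue = record$tissue, day = record$day,
         class_label = record$class_label,
         ratio = mean(ratios), slope = mean(slopes),
         per_location_ratios = ratios, per_location_slopes = slopes,
         n_locations = n),
    class = "browning_indices")
}

#' @export
print.browning_indices <- function(x, ...) {
  cat(sprintf("Browning indices for '%s' (%s %s day %s, %d locations)\n",
              x$sample_id, x$group, x$tissue, x$day, x$n_locations))
  cat(sprintf("  680/550 ratio: %.4f   570-630 slope: %.4f per 100 nm\n",
              x$ratio, x$slope))
  invisible(x)
}

#' Quantify every sample of a DRS dataset
#'
#' @param records list of `sample_record`s.
#' @param ... passed to [quantify_sample()].
#' @return data.frame with one row per sample: metadata, `ratio`, `slope`,
#'   `n_locations`, and the analysis `cell` (controls pooled over days).
#' @export
quantify_drs_dataset <- function(records, ...) {
  rows <- lapply(records, function(rec) {
    bi <- quantify_sample(rec, ...)
    data.frame(sample_id = bi$sample_id, group = bi$group, tissue = bi$tissue,
               day = bi$day, cell = analysis_cell(bi$group, bi$tissue, bi$day),
               ratio = bi$ratio, slope = bi$slope,
               n_locations = bi$n_locations, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group means and standard errors
#'
#' Summarizes per-sample values into mean +/- SE per (group, tissue, day)
#' cell, plus pooled control cells (day "4+7") for each control tissue,
#' the convention under which control WAT and BAT are reported.
#'
#' @param df data.frame with columns `group`, `tissue`, `day` and the
#'   value column.
#' @param value_col name of the value column (e.g. `"ratio"`).
#' @return data.frame with `group, tissue, day, mean, se, n`; `se` is `NA`
#'   for singleton cells.
#' @export
summarize_groups <- function(df, value_col = "value") {
  need <- c("group", "tissue", "day", value_col)
  missing <- setdiff(need, names(df))
  if (length(missing)) stop_fmt("missing column(s): %s", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) stop_fmt("no samples to summarize")

  cell_stats <- function(v) {
    n <- length(v)
    data.frame(mean = mean(v),
               se = if (n > 1L) stats::sd(v) / sqrt(n) else NA_real_,
               n = n)
  }
  key <- interaction(df$group, df$tissue, df$day, drop = TRUE)
  per_cell <- do.call(rbind, lapply(levels(key), function(k) {
    sub <- df[key == k, ]
    cbind(data.frame(group = sub$group[1L], tissue = sub$tissue[1L],
                     day = as.character(sub$day[1L]), stringsAsFactors = FALSE),
          cell_stats(sub[[value_col]]))
  }))
  ctrl <- df[df$group == "C", ]
  pooled <- do.call(rbind, lapply(unique(ctrl$tissue), function(tis) {
    sub <- ctrl[ctrl$tissue == tis, ]
    cbind(data.frame(group = "C", tissue = tis, day = "4+7",
                     stringsAsFactors = FALSE),
          cell_stats(sub[[value_col]]))
  }))
  out <- rbind(per_cell, pooled)
  rownames(out) <- NULL
  out
}

#' Rescale group slope summaries to the control-WAT mean
#'
#' Optional post-hoc normalization dividing every group mean and SE by
#' the pooled control-WAT group mean, so control WAT reads 1. Off by
#' default in the pipeline: the headline slope values are reported on
#' their natural per-100 nm scale.
#'
#' @param summary_df output of [summarize_groups()].
#' @return The summary with rescaled `mean` and `se`.
#' @export
normalize_slopes_to_reference <- function(summary_df) {
  ref <- summary_df$mean[summary_df$group == "C" & summary_df$tissue == "WAT" &
                           summary_df$day == "4+7"]
  if (length(ref) != 1L || !is.finite(ref) || ref == 0) {
    stop_fmt("pooled control-WAT cell missing or degenerate; cannot normalize")
  }
  summary_df$mean <- summary_df$mean / ref
  summary_df$se <- summary_df$se / ref
  summary_df
}
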