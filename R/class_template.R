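#' Build a noise-free reflectance template for one tissue class
#'
#' A class template is the ground-truth, 680 nm-normalized reflectance
#' curve of one phantom tissue class, parameterized directly by the two
#' browning indices it must reproduce: the 680/550 nm intensity ratio and
#' the least-squares slope over 570-630 nm (per 100 nm).
#'
#' The curve is built from fixed anchors -- `T(680) = 1`, `T(700) = 1`,
#' `T(550) = 1/ratio`, `T(570) = min(1/ratio, 1 - 0.6*slope) - 0.05`,
#' `T(630) = T(570) + 0.6*slope`, `T(450) = 0.9*T(550)` -- joined by
#' shape-preserving monotone Hermite interpolation. Narrow plateaus around
#' 550 and 680 nm keep the +/-2 nm band means used by
#' [intensity_ratio()] exactly equal to the anchor values, and the
#' 570-630 nm segment is exactly linear so the least-squares slope equals
#' `slope` to machine precision. The dip below `1/ratio` near 570 nm
#' mimics the hemoglobin Q-band absorption seen in adipose spectra.
#'
#' @param ratio target `T(680)/T(550)` ratio (> 0, dimensionless).
#' @param slope target least-squares slope over 570-630 nm, in normalized
#'   reflectance per 100 nm.
#' @param grid wavelength grid in nm; strictly increasing, spanning
#'   exactly 450-700 nm (default 1 nm steps).
#' @param label optional class label stored on the template.
#' @return An object of class `class_template` with fields `label`,
#'   `grid`, `values`, `ratio_param`, `slope_param`.
#' @seealso [default_class_library()]
#' @examples
#' tpl <- build_class_template(2.36, 0.44)
#' template_value(tpl, 550)   # = 1/2.36
#' @export
build_class_template <- function(ratio, slope,
                                 grid = analysis_grid(),
                                 label = NA_character_) {
  if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) || ratio <= 0) {
    stop_fmt("'ratio' must be a single positive number")
  }
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope)) {
    stop_fmt("'slope' must be a single finite number")
  }
  check_grid(grid)

  t550 <- 1 / ratio
  t570 <- min(t550, 1 - 0.6 * slope) - 0.05
  t630 <- t570 + 0.6 * slope
  t450 <- 0.9 * t550

  anchors_wl <- c(450, 548, 550, 552, 570, 630, 678, 680, 682, 700)
  anchors_v  <- c(t450, t550, t550, t550, t570, t630, 1, 1, 1, 1)
  names(anchors_v) <- paste0(anchors_wl, " nm")
  bad <- anchors_v <= 0
  if (any(bad)) {
    stop_fmt("infeasible (ratio, slope) parameterization: anchor at %s is %.4g <= 0",
             names(anchors_v)[bad][1L], anchors_v[bad][1L])
  }

  f <- stats::splinefun(anchors_wl, anchors_v, method = "monoH.FC")
  values <- f(grid)
  # exact plateaus and linear segment (interpolation is only used between
  # anchors; these regions are defined analytically)
  values[grid >= 548 & grid <= 552] <- t550
  values[grid >= 678] <- 1
  lin <- grid >= 570 & grid <= 630
  values[lin] <- t570 + (grid[lin] - 570) * (t630 - t570) / 60

  if (any(values <= 0)) {
    stop_fmt("infeasible (ratio, slope) parameterization: interpolated reflectance not positive")
  }

  structure(
    list(label = label, grid = grid, values = values,
         ratio_param = ratio, slope_param = slope),
    class = "class_template"
  )
}

#' Evaluate a class template at given wavelengths
#'
#' Linear interpolation on the template grid; no extrapolation.
#'
#' @param template a `class_template`.
#' @param wavelengths wavelengths in nm, inside the template grid range.
#' @return Numeric vector of normalized reflectance values.
#' @export
template_value <- function(template, wavelengths) {
  stopifnot(inherits(template, "class_template"))
  if (any(wavelengths < min(template$grid) | wavelengths > max(template$grid))) {
    stop_fmt("wavelength outside template grid range")
  }
  stats::approx(template$grid, template$values, xout = wavelengths)$y
}

#' Default calibrated class library
#'
#' The six tissue-class templates with (ratio, slope) calibrated to the
#' group statistics of the browning study: control WAT (1.08, 0.19),
#' treated WAT day 4 (1.17, 0.30), treated WAT day 7 (1.33, 0.36), and
#' control BAT (2.36, 0.44). Treated BAT shows no change relative to
#' control BAT and reuses its parameters.
#'
#' @return Named list of [build_class_template()] objects, one per
#'   [class_labels()] entry.
#' @export
default_class_library <- function() {
  params <- list(
    C_WAT    = c(1.08, 0.19),
    TrWAT_d4 = c(1.17, 0.30),
    TrWAT_d7 = c(1.33, 0.36),
    C_BAT    = c(2.36, 0.44),
    TrBAT_d4 = c(2.36, 0.44),
    TrBAT_d7 = c(2.36, 0.44)
  )
  out <- lapply(names(params), function(lab) {
    build_class_template(params[[lab]][1L], params[[lab]][2L], label = lab)
  })
  names(out) <- names(params)
  out
}

#' @export
print.class_template <- function(x, ...) {
  cat("Tissue class template", if (!is.na(x$label)) paste0("'", x$label, "'"), "\n")
  cat(sprintf("  grid: %g-%g nm (%d points)\n",
              min(x$grid), max(x$grid), length(x$grid)))
  cat(sprintf("  680/550 ratio: %.3f   570-630 slope: %.3f per 100 nm\n",
              x$ratio_param, x$slope_param))
  invisible(x)
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2L || any(!is.finite(grid))) {
    stop_fmt("grid must be a numeric vector of >= 2 finite wavelengths")
  }
  if (any(diff(grid) <= 0)) stop_fmt("grid wavelengths must be strictly increasing")
  if (abs(min(grid) - 450) > 1e-6 || abs(max(grid) - 700) > 1e-6) {
    stop_fmt("grid must span exactly 450-700 nm")
  }
  invisible(grid)
}

#' The default analysis wavelength grid
#'
#' 450-700 nm in 1 nm steps, the acquisition range of the reflectance
#' measurements.
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
analysis_grid <- function() seq(450, 700, by = 1)
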