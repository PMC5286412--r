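#' Construct a raw spectrometer spectrum
#'
#' @param wavelengths strictly increasing wavelengths in nm (>= 2 points).
#' @param counts detector counts (finite, >= 0), same length.
#' @param role acquisition role: "sample", "dark" or "reference".
#' @param integration_time optional integration time in ms.
#' @param source_path optional file of origin.
#' @param comments character vector of '#' comment lines carried with the
#'   spectrum (round-tripped by [write_spectrum()]).
#' @return A `raw_spectrum` object.
#' @export
raw_spectrum <- function(wavelengths, counts,
                         role = c("sample", "dark", "reference"),
                         integration_time = NULL, source_path = NULL,
                         comments = character()) {
  role <- match.arg(role)
  if (length(wavelengths) != length(counts)) {
    stop_fmt("wavelengths and counts must have equal length")
  }
  if (length(wavelengths) < 2L) stop_fmt("a spectrum needs >= 2 points")
  if (any(!is.finite(wavelengths)) || any(!is.finite(counts))) {
    stop_fmt("wavelengths and counts must be finite")
  }
  if (any(diff(wavelengths) <= 0)) {
    stop_fmt("wavelengths must be strictly increasing")
  }
  if (any(counts < 0)) stop_fmt("counts must be non-negative")
  structure(list(wavelengths = as.numeric(wavelengths),
                 counts = as.numeric(counts), role = role,
                 integration_time = integration_time,
                 source_path = source_path, comments = comments),
            class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("Raw %s spectrum: %d points, %g-%g nm\n",
              x$role, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Read a two-column ASCII spectrum file
#'
#' Plain-text spectrometer export: lines starting with '#' are comments,
#' data lines hold wavelength (nm) and counts separated by whitespace or a
#' comma.
#'
#' @param path file to read.
#' @param role acquisition role to attach ("sample", "dark", "reference").
#' @return A [raw_spectrum()].
#' @export
read_spectrum <- function(path, role = "sample") {
  if (!file.exists(path)) stop_fmt("spectrum file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  comments <- sub("^\\s*#\\s?", "", lines[is_comment])
  data_lines <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(data_lines) < 2L) {
    stop_fmt("spectrum file %s has fewer than 2 data rows", path)
  }
  data_idx <- which(!is_comment & nzchar(trimws(lines)))
  wl <- counts <- numeric(length(data_lines))
  for (i in seq_along(data_lines)) {
    tokens <- strsplit(trimws(data_lines[i]), "[,[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.numeric(tokens))
    if (length(vals) < 2L || any(is.na(vals[1:2]))) {
      stop_fmt("non-numeric token in %s at line %d: '%s'",
               path, data_idx[i], data_lines[i])
    }
    wl[i] <- vals[1L]; counts[i] <- vals[2L]
  }
  if (any(diff(wl) <= 0)) {
    stop_fmt("wavelengths in %s are not strictly increasing", path)
  }
  raw_spectrum(wl, counts, role = role, source_path = path,
               comments = comments)
}

#' Write a spectrum as a two-column ASCII file
#'
#' Comment lines carried on the spectrum are written first ('#'-prefixed),
#' followed by `wavelength<TAB>counts` rows at full double precision, so
#' that [read_spectrum()] reproduces the values.
#'
#' @param spectrum a [raw_spectrum()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  header <- if (length(spectrum$comments)) paste0("# ", spectrum$comments) else character()
  body <- sprintf("%.10g\t%.10g", spectrum$wavelengths, spectrum$counts)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation; strictly no extrapolation — every requested grid
#' point must lie inside the measured range.
#'
#' @param spectrum a [raw_spectrum()].
#' @param grid target wavelengths in nm.
#' @return A [raw_spectrum()] on `grid`, same role.
#' @export
resample_to_grid <- function(spectrum, grid) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  rng <- range(spectrum$wavelengths)
  if (any(grid < rng[1L] - 1e-9 | grid > rng[2L] + 1e-9)) {
    stop_fmt("grid extends outside the measured range %g-%g nm (no extrapolation)",
             rng[1L], rng[2L])
  }
  counts <- stats::approx(spectrum$wavelengths, spectrum$counts, xout = grid)$y
  raw_spectrum(grid, counts, role = spectrum$role,
               integration_time = spectrum$integration_time,
               source_path = spectrum$source_path,
               comments = spectrum$comments)
}
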