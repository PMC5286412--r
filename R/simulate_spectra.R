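#' Measurement noise model for simulated spectra
#'
#' @param multiplicative_cv coefficient of variation of the per-point
#'   multiplicative noise on the reflected signal (fraction, >= 0).
#' @param additive_sd standard deviation of additive detector noise, in
#'   counts (>= 0), applied independently to sample, dark and reference.
#' @param seed integer RNG seed; `NULL` uses the current RNG stream.
#' @return A `noise_model` object.
#' @export
noise_model <- function(multiplicative_cv = 0, additive_sd = 0, seed = NULL) {
  if (multiplicative_cv < 0 || additive_sd < 0) {
    stop_fmt("noise parameters must be non-negative")
  }
  structure(list(multiplicative_cv = multiplicative_cv,
                 additive_sd = additive_sd,
                 seed = seed),
            class = "noise_model")
}

# Smooth broadband lamp emission profile: broad quartic peaking near
# 600 nm, strictly positive over 450-700 nm. Its exact shape is
# immaterial because the reflectance correction divides it out.
lamp_profile <- function(wavelengths) {
  0.2 + 0.8 * (1 - ((wavelengths - 600) / 180)^4)
}

#' Simulate one raw DRS acquisition triple
#'
#' Emulates a spectrometer measurement session: a dark spectrum (lamp
#' off), a reference spectrum from a diffuse reflectance standard, and a
#' sample spectrum whose underlying reflectance is the given class
#' template. With all noise at zero, `(S - D) / (W - D)` reproduces the
#' template exactly at every grid point.
#'
#' @param template a [build_class_template()] object.
#' @param lamp_gain peak reference signal above dark, in counts (> 0).
#' @param dark_level dark (lamp off) counts level (>= 0).
#' @param noise a [noise_model()].
#' @return List with `sample`, `dark` and `reference` [raw_spectrum()]
#'   objects on the template grid.
#' @export
simulate_raw_measurement <- function(template, lamp_gain = 20000,
                                     dark_level = 100,
                                     noise = noise_model()) {
  stopifnot(inherits(template, "class_template"), inherits(noise, "noise_model"))
  if (lamp_gain <= 0) stop_fmt("'lamp_gain' must be positive")
  if (dark_level < 0) stop_fmt("'dark_level' must be non-negative")
  wl <- template$grid
  n <- length(wl)
  dark0 <- rep(dark_level, n)
  ref0 <- dark_level + lamp_gain * lamp_profile(wl)

  with_seed(noise$seed, {
    eps_mult <- stats::rnorm(n, 0, noise$multiplicative_cv)
    add <- matrix(stats::rnorm(3L * n, 0, noise$additive_sd), nrow = 3L)
    sample_counts <- dark0 + (ref0 - dark0) * template$values * (1 + eps_mult) + add[1L, ]
    dark_counts <- dark0 + add[2L, ]
    ref_counts <- ref0 + add[3L, ]
    list(
      sample = raw_spectrum(wl, pmax(sample_counts, 0), role = "sample"),
      dark = raw_spectrum(wl, pmax(dark_counts, 0), role = "dark"),
      reference = raw_spectrum(wl, pmax(ref_counts, 0), role = "reference")
    )
  })
}

#' Simulate all probe locations of one tissue sample
#'
#' One excised tissue sample is probed at several locations; each location
#' yields an independent (sample, dark, reference) acquisition triple
#' drawn from the same class template.
#'
#' @param class_label one of [class_labels()].
#' @param n_locations number of probe locations (>= 1; the protocol uses 5).
#' @param noise a [noise_model()]; its seed (if any) is split into one
#'   sub-seed per location via [derive_seed()].
#' @param template_library list of templates, by default
#'   [default_class_library()].
#' @param sample_id identifier; auto-generated if missing.
#' @param day sacrifice day (4 or 7); defaults to the day encoded in the
#'   class label, or 4 for control classes (controls pool days).
#' @param lamp_gain,dark_level passed to [simulate_raw_measurement()].
#' @return A `sample_record`: metadata plus a list of per-location raw
#'   triples.
#' @export
simulate_sample <- function(class_label, n_locations = 5,
                            noise = noise_model(),
                            template_library = default_class_library(),
                            sample_id = NULL, day = NULL,
                            lamp_gain = 20000, dark_level = 100) {
  if (n_locations < 1) stop_fmt("'n_locations' must be >= 1")
  meta <- parse_class_label(class_label)
  template <- template_library[[class_label]]
  if (is.null(template)) stop_fmt("class '%s' missing from template library", class_label)
  day <- day %||% (if (is.na(meta$day)) 4L else meta$day)
  sample_id <- sample_id %||% paste0(class_label, "_s1")

  locations <- lapply(seq_len(n_locations), function(i) {
    loc_noise <- noise_model(noise$multiplicative_cv, noise$additive_sd,
                             derive_seed(noise$seed, i))
    simulate_raw_measurement(template, lamp_gain, dark_level, loc_noise)
  })
  sample_record(sample_id = sample_id, group = meta$group, tissue = meta$tissue,
                day = day, class_label = class_label, locations = locations)
}

#' Construct a sample record
#'
#' Container for one tissue sample: metadata plus per-location raw
#' acquisition triples (or corrected spectra).
#'
#' @param sample_id sample identifier.
#' @param group "C" (saline control) or "Tr" (beta3-agonist treated).
#' @param tissue "WAT" or "BAT".
#' @param day sacrifice day, 4 or 7.
#' @param locations list of per-location triples, each a list with
#'   `sample`, `dark`, `reference` [raw_spectrum()] entries.
#' @param class_label optional phantom class label.
#' @return A `sample_record` object.
#' @export
sample_record <- function(sample_id, group, tissue, day, locations,
                          class_label = NA_character_) {
  stopifnot(length(locations) >= 1L)
  structure(list(sample_id = sample_id, group = group, tissue = tissue,
                 day = as.integer(day), class_label = class_label,
                 locations = locations),
            class = "sample_record")
}

#' @export
print.sample_record <- function(x, ...) {
  cat(sprintf("Sample record '%s': %s %s day %s, %d location(s)\n",
              x$sample_id, x$group, x$tissue, x$day, length(x$locations)))
  invisible(x)
}

#' Simulate a full DRS phantom study
#'
#' Generates `n_mice` samples for each requested class. Control mice are
#' split between day 4 and day 7 (first half / second half), mirroring a
#' design in which controls are sacrificed alongside each treated cohort
#' and pooled for analysis.
#'
#' @param classes class labels to simulate (default all six).
#' @param n_mice samples per class.
#' @param n_locations probe locations per sample.
#' @param cv multiplicative noise coefficient of variation.
#' @param additive_sd additive detector noise, counts.
#' @param seed master seed; split deterministically across samples.
#' @param template_library templates to draw from.
#' @return List of `sample_record`s.
#' @export
simulate_drs_dataset <- function(classes = class_labels(), n_mice = 8,
                                 n_locations = 5, cv = 0.02, additive_sd = 0,
                                 seed = NULL,
                                 template_library = default_class_library()) {
  records <- list()
  for (ci in seq_along(classes)) {
    lab <- classes[ci]
    meta <- parse_class_label(lab)
    for (i in seq_len(n_mice)) {
      day <- if (is.na(meta$day)) (if (i <= n_mice / 2) 4L else 7L) else meta$day
      rec_seed <- derive_seed(seed, ci * 1000L + i)
      records[[length(records) + 1L]] <- simulate_sample(
        lab, n_locations = n_locations,
        noise = noise_model(cv, additive_sd, rec_seed),
        template_library = template_library,
        sample_id = sprintf("%s_s%d", lab, i), day = day
      )
    }
  }
  records
}
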