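#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end pipeline with their default
#' (study-condition) values. See the package vignette for what each
#' parameter means and why its default was chosen.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    grid_min = 450, grid_max = 700, grid_step = 1,     # nm
    ratio_bands = c(680, 550), halfwidth = 2,          # nm
    slope_window = c(570, 630),                        # nm
    normalize_slope_to_cwat = FALSE,
    bands = c(550, 600, 680),                          # MSI bands, nm
    image_shape = c(96, 96), roi = c(17, 17, 64, 64),  # row0,col0,h,w
    texture_sd = 3, background = 5,                    # 8-bit units
    normalize_msi = FALSE, msi_reference = "C_WAT",
    reference_gene = "ACTB", control_group = "C",
    correction = "tukey", alpha = 0.05,
    n_mice = 8, n_locations = 5, cv = 0.02, additive_sd = 0,
    ct_sd = 0.15,
    seed = 1L, out_dir = "adipoptics-report",
    write_raw = FALSE, figures = TRUE
  )
}

#' Validate a pipeline configuration
#'
#' Accepts either a YAML config file path or a named list; fills defaults,
#' warns on unknown keys, and aggregates every range violation into one
#' error message.
#'
#' @param config file path or named list of overrides (possibly partial).
#' @return A complete, validated configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_fmt("config file not found: %s", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  stopifnot(is.list(config))
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    warning(sprintf("ignoring unknown config key(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
    config <- config[setdiff(names(config), unknown)]
  }
  cfg <- utils::modifyList(defaults, config)

  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(cfg$grid_min < cfg$grid_max, "grid_min must be < grid_max")
  chk(cfg$grid_step > 0, "grid_step must be positive")
  chk(length(cfg$ratio_bands) == 2L && all(cfg$ratio_bands > 0),
      "ratio_bands must be two positive wavelengths")
  chk(cfg$halfwidth > 0 && cfg$halfwidth <= 20,
      "halfwidth must be in (0, 20] nm")
  chk(length(cfg$slope_window) == 2L && cfg$slope_window[1L] < cfg$slope_window[2L],
      "slope_window must be an increasing pair of wavelengths")
  chk(length(cfg$roi) == 4L && all(cfg$roi >= 1),
      "roi must be four positive integers (row0, col0, height, width)")
  chk(length(cfg$image_shape) == 2L && all(cfg$image_shape >= 1),
      "image_shape must be two positive integers")
  chk(cfg$roi[1L] + cfg$roi[3L] - 1 <= cfg$image_shape[1L] &&
        cfg$roi[2L] + cfg$roi[4L] - 1 <= cfg$image_shape[2L],
      "roi must lie inside image_shape")
  chk(all(cfg$bands %in% c(550, 600, 680)), "bands must be among 550, 600, 680 nm")
  chk(cfg$texture_sd >= 0, "texture_sd must be >= 0")
  chk(cfg$cv >= 0, "cv must be >= 0")
  chk(cfg$additive_sd >= 0, "additive_sd must be >= 0")
  chk(cfg$ct_sd >= 0, "ct_sd must be >= 0")
  chk(cfg$n_mice >= 1, "n_mice must be >= 1")
  chk(cfg$n_locations >= 1, "n_locations must be >= 1")
  chk(cfg$correction %in% c("tukey", "bonferroni"),
      "correction must be 'tukey' or 'bonferroni'")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  if (length(problems)) {
    stop_fmt("invalid configuration:\n  - %s", paste(problems, collapse = "\n  - "))
  }
  cfg
}
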