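MANIFEST_COLS <- c("file_path", "sample_id", "group", "tissue", "day",
                   "location", "role")

#' Read a sample manifest CSV
#'
#' The manifest maps spectrum files to sample metadata, with columns
#' `file_path, sample_id, group, tissue, day, location, role`. Unknown
#' extra columns are ignored with a warning.
#'
#' @param path manifest CSV file.
#' @return data.frame with the canonical columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_fmt("manifest not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(MANIFEST_COLS, names(df))
  if (length(missing)) {
    stop_fmt("manifest %s lacks required column(s): %s",
             path, paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), MANIFEST_COLS)
  if (length(extra)) {
    warning(sprintf("ignoring unknown manifest column(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  df <- df[MANIFEST_COLS]
  dup <- duplicated(df[c("sample_id", "location", "role")])
  if (any(dup)) {
    stop_fmt("duplicate (sample_id, location, role) rows in manifest")
  }
  df
}

#' Write simulated sample records to disk
#'
#' Writes every spectrum of every record as a two-column ASCII file plus a
#' manifest CSV, the on-disk layout that [load_dataset()] reads back.
#'
#' @param records list of `sample_record`s (e.g. from
#'   [simulate_drs_dataset()]).
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_spectra_dataset <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (rec in records) {
    for (loc in seq_along(rec$locations)) {
      triple <- rec$locations[[loc]]
      for (role in c("sample", "dark", "reference")) {
        fname <- sprintf("%s_loc%d_%s.txt", rec$sample_id, loc, role)
        write_spectrum(triple[[role]], file.path(dir, fname))
        rows[[length(rows) + 1L]] <- data.frame(
          file_path = fname, sample_id = rec$sample_id, group = rec$group,
          tissue = rec$tissue, day = rec$day, location = loc, role = role,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' Load a spectra dataset from a manifest
#'
#' Reads every referenced spectrum, checks that each (sample, location)
#' has exactly one sample, dark and reference acquisition, resamples all
#' spectra onto the analysis grid and assembles `sample_record`s.
#'
#' @param manifest_path manifest CSV; file paths are resolved relative to
#'   its directory.
#' @param grid analysis wavelength grid (default [analysis_grid()]).
#' @return List of `sample_record`s.
#' @export
load_dataset <- function(manifest_path, grid = analysis_grid()) {
  manifest <- read_manifest(manifest_path)
  base <- dirname(manifest_path)
  records <- list()
  for (sid in unique(manifest$sample_id)) {
    m <- manifest[manifest$sample_id == sid, ]
    locations <- list()
    for (loc in sort(unique(m$location))) {
      ml <- m[m$location == loc, ]
      triple <- list()
      for (role in c("sample", "dark", "reference")) {
        row <- ml[ml$role == role, ]
        if (nrow(row) != 1L) {
          stop_fmt("sample '%s' location %d: expected exactly one '%s' spectrum, found %d",
                   sid, loc, role, nrow(row))
        }
        fp <- row$file_path
        if (!file.exists(fp)) fp <- file.path(base, row$file_path)
        if (!file.exists(fp)) stop_fmt("missing spectrum file: %s", row$file_path)
        triple[[role]] <- resample_to_grid(read_spectrum(fp, role = role), grid)
      }
      locations[[length(locations) + 1L]] <- triple
    }
    records[[length(records) + 1L]] <- sample_record(
      sample_id = sid, group = m$group[1L], tissue = m$tissue[1L],
      day = m$day[1L], locations = locations,
      class_label = analysis_cell(m$group[1L], m$tissue[1L], m$day[1L]))
  }
  records
}

#' Write simulated band images to disk
#'
#' Writes each image as an 8-bit grayscale TIFF plus an image manifest CSV
#' (`file_path, sample_id, group, tissue, day, band`).
#'
#' @param entries list of image entries as produced by
#'   [simulate_msi_dataset()]: each a list with `image` ([band_image()])
#'   and `sample_id`, `group`, `tissue`, `day` metadata.
#' @param dir output directory.
#' @return Invisibly, the manifest path.
#' @export
write_msi_dataset <- function(entries, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(entries, function(e) {
    fname <- sprintf("%s_%dnm.tif", e$sample_id, e$image$band_center)
    tiff::writeTIFF(e$image$pixels / 255, file.path(dir, fname),
                    bits.per.sample = 8L)
    data.frame(file_path = fname, sample_id = e$sample_id, group = e$group,
               tissue = e$tissue, day = e$day, band = e$image$band_center,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "images_manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' Load a band-image dataset from an image manifest
#'
#' @param manifest_path image manifest CSV written by
#'   [write_msi_dataset()] (or hand-built with the same columns).
#' @param channel_policy RGB collapse rule passed to [load_band_image()].
#' @return List of image entries (`image` + metadata), the input format of
#'   [quantify_msi()].
#' @export
load_msi_dataset <- function(manifest_path, channel_policy = "mean") {
  if (!file.exists(manifest_path)) stop_fmt("manifest not found: %s", manifest_path)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("file_path", "sample_id", "group", "tissue", "day", "band")
  missing <- setdiff(need, names(manifest))
  if (length(missing)) {
    stop_fmt("image manifest lacks column(s): %s", paste(missing, collapse = ", "))
  }
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    fp <- manifest$file_path[i]
    if (!file.exists(fp)) fp <- file.path(base, manifest$file_path[i])
    list(image = load_band_image(fp, manifest$band[i], channel_policy),
         sample_id = manifest$sample_id[i], group = manifest$group[i],
         tissue = manifest$tissue[i], day = manifest$day[i])
  })
}

#' Read a Ct table CSV
#'
#' Columns: `sample_id, group, tissue, day, gene, ct`.
#'
#' @param path CSV file.
#' @return data.frame Ct table.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop_fmt("Ct table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "tissue", "day", "gene", "ct")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_fmt("Ct table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(df$ct))) stop_fmt("non-finite Ct values in %s", path)
  df
}
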