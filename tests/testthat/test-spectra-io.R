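test_that("spectrum files parse, with comments and either separator", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# acquired with lamp on", "450,100", "451 101", "452\t99"), path)
  sp <- read_spectrum(path, role = "dark")
  expect_s3_class(sp, "raw_spectrum")
  expect_equal(sp$wavelengths, c(450, 451, 452))
  expect_equal(sp$counts, c(100, 101, 99))
  expect_equal(sp$role, "dark")
  expect_equal(sp$comments, "acquired with lamp on")
})

test_that("malformed spectrum files are rejected with diagnostics", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("500 1", "499 2"), path)
  expect_error(read_spectrum(path), "increasing")

  writeLines("450 1", path)
  expect_error(read_spectrum(path), "fewer than 2")

  writeLines(c("450 1", "451 oops"), path)
  expect_error(read_spectrum(path), "line 2")

  expect_error(read_spectrum(file.path(tempdir(), "nope.txt")), "not found")
})

test_that("write then read is the identity, preserving comments", {
  sp <- raw_spectrum(seq(450, 700, 5), runif(51, 100, 2000),
                     role = "reference", comments = c("probe A", "run 3"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(sp, path)
  back <- read_spectrum(path, role = "reference")
  expect_equal(back$wavelengths, sp$wavelengths, tolerance = 1e-9)
  expect_equal(back$counts, sp$counts, tolerance = 1e-9)
  expect_equal(back$comments, sp$comments)
  # rewrite preserves the comment header
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(back, path2)
  expect_equal(read_spectrum(path2)$comments, sp$comments)
})

test_that("resampling interpolates linearly and refuses to extrapolate", {
  sp <- raw_spectrum(c(500, 502), c(0, 2))
  expect_equal(resample_to_grid(sp, c(500, 501, 502))$counts, c(0, 1.0, 2))
  # own grid: identity
  sp <- raw_spectrum(seq(450, 700, 1), seq_len(251))
  expect_equal(resample_to_grid(sp, sp$wavelengths)$counts, sp$counts)
  expect_error(resample_to_grid(sp, c(449, 500)), "extrapolation")
})

test_that("a simulated dataset written to disk loads back losslessly", {
  records <- simulate_drs_dataset(classes = c("C_WAT", "TrWAT_d7"), n_mice = 2,
                                  n_locations = 2, cv = 0.02,
                                  seed = STUDY_SEED)
  dir <- withr::local_tempdir()
  manifest <- write_spectra_dataset(records, dir)
  loaded <- load_dataset(manifest)
  expect_length(loaded, length(records))
  loaded <- loaded[match(vapply(records, `[[`, "", "sample_id"),
                         vapply(loaded, `[[`, "", "sample_id"))]
  for (i in seq_along(records)) {
    expect_equal(loaded[[i]]$group, records[[i]]$group)
    expect_equal(loaded[[i]]$day, records[[i]]$day)
    for (loc in seq_along(records[[i]]$locations)) {
      for (role in c("sample", "dark", "reference")) {
        expect_equal(loaded[[i]]$locations[[loc]][[role]]$counts,
                     records[[i]]$locations[[loc]][[role]]$counts,
                     tolerance = 1e-9)
      }
    }
  }
  # quantification of the reloaded dataset matches the in-memory one
  expect_equal(quantify_drs_dataset(loaded)[c("ratio", "slope")],
               quantify_drs_dataset(records)[c("ratio", "slope")],
               tolerance = 1e-9)
})

test_that("manifest validation catches missing roles and unknown columns", {
  records <- simulate_drs_dataset(classes = "C_WAT", n_mice = 1,
                                  n_locations = 1, seed = STUDY_SEED)
  dir <- withr::local_tempdir()
  manifest_path <- write_spectra_dataset(records, dir)
  m <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)

  # drop the reference row -> load fails naming the role
  utils::write.csv(m[m$role != "reference", ], manifest_path, row.names = FALSE)
  expect_error(load_dataset(manifest_path), "reference")

  # unknown column -> warning, not error
  m2 <- cbind(m, operator = "xy")
  utils::write.csv(m2, manifest_path, row.names = FALSE)
  expect_warning(load_dataset(manifest_path), "operator")

  # dangling file path
  m$file_path[1] <- "missing.txt"
  utils::write.csv(m, manifest_path, row.names = FALSE)
  expect_error(suppressWarnings(load_dataset(manifest_path)), "missing.txt|one")
})
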