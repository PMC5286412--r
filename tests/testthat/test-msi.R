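test_that("ROI mean matches forced arithmetic and a pixel-loop oracle", {
  img <- band_image(matrix(48L, 10, 10), 550)
  expect_equal(extract_roi_mean(img, roi_spec(1, 1, 10, 10)), 48.0)

  checker <- band_image(matrix(c(0L, 255L, 255L, 0L), 2, 2), 550)
  expect_equal(extract_roi_mean(checker, roi_spec(1, 1, 2, 2)), 127.5)

  # brute-force double loop as the independent oracle
  set.seed(STUDY_SEED)
  for (i in 1:50) {
    nr <- sample(5:30, 1); nc <- sample(5:30, 1)
    img <- band_image(matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc), 600)
    h <- sample(1:nr, 1); w <- sample(1:nc, 1)
    r0 <- sample(1:(nr - h + 1), 1); c0 <- sample(1:(nc - w + 1), 1)
    acc <- 0
    for (r in r0:(r0 + h - 1)) for (cc in c0:(c0 + w - 1)) {
      acc <- acc + img$pixels[r, cc]
    }
    expect_equal(extract_roi_mean(img, roi_spec(r0, c0, h, w)), acc / (h * w),
                 tolerance = 1e-9)
  }
})

test_that("ROI mean ignores everything outside the ROI", {
  img <- simulate_band_image("C_WAT", 550, texture_sd = 3, seed = STUDY_SEED)
  roi <- default_roi()
  before <- extract_roi_mean(img, roi)
  mutated <- img
  mask <- adipoptics:::roi_mask(roi, dim(img$pixels))
  mutated$pixels[!mask] <- 255L
  expect_identical(extract_roi_mean(mutated, roi), before)
})

test_that("ROI bounds and mask dimensions are enforced", {
  img <- band_image(matrix(0L, 8, 8), 680)
  expect_error(extract_roi_mean(img, roi_spec(5, 5, 8, 2)), "bounds")
  expect_error(extract_roi_mean(img, roi_spec(mask = matrix(TRUE, 4, 4))),
               "dimensions")
  expect_error(roi_spec(mask = matrix(FALSE, 8, 8)), "no pixels")
  m <- matrix(FALSE, 8, 8); m[2:3, 2:3] <- TRUE
  expect_equal(extract_roi_mean(img, roi_spec(mask = m)), 0)
})

test_that("TIFF and PNG images load back; RGB collapses by channel mean", {
  dir <- withr::local_tempdir()
  img <- simulate_band_image("TrWAT_d7", 550, seed = STUDY_SEED)
  tif <- file.path(dir, "x.tif")
  tiff::writeTIFF(img$pixels / 255, tif, bits.per.sample = 8L)
  back <- load_band_image(tif, 550)
  expect_equal(back$pixels, img$pixels, ignore_attr = TRUE)

  # RGB pixel (30, 60, 90) -> 60 under the unweighted mean
  rgb <- array(c(30, 60, 90) / 255, dim = c(1, 2, 3))
  pngf <- file.path(dir, "x.png")
  png::writePNG(rgb, pngf)
  expect_equal(load_band_image(pngf, 600)$pixels[1, 1], 60)

  expect_error(load_band_image(file.path(dir, "absent.tif"), 550), "not found")
})

test_that("normalization to the reference class is exact and idempotent", {
  samples <- data.frame(
    sample_id = c("a", "b", "c"), group = c("C", "C", "Tr"),
    tissue = "WAT", day = c(4L, 7L, 7L),
    cell = c("C_WAT", "C_WAT", "TrWAT_d7"), band = 550L,
    roi_mean = c(48, 48, 24), stringsAsFactors = FALSE)
  out <- normalize_to_reference(samples)
  expect_equal(out$normalized, c(1, 1, 0.5))
  # idempotent on the normalized field
  expect_equal(normalize_to_reference(out)$normalized, out$normalized)
  expect_error(normalize_to_reference(samples, "C_BAT"), "absent")
})

test_that("simulated study recovers the printed 550 nm levels and ordering", {
  roi <- default_roi()
  entries <- simulate_msi_dataset(n_mice = 8, seed = STUDY_SEED, roi = roi)
  q <- quantify_msi(entries, roi)

  at550 <- q$summary[q$summary$band == 550, ]
  target <- c("C_WAT" = 48, "TrWAT_d4" = 33, "TrWAT_d7" = 23, "C_BAT" = 20)
  got <- numeric(0)
  for (lab in names(target)) {
    meta <- parse_class_label(lab)
    row <- at550[at550$group == meta$group & at550$tissue == meta$tissue &
                   at550$day == (if (is.na(meta$day)) "4+7" else as.character(meta$day)), ]
    expect_equal(row$mean, unname(target[lab]), tolerance = 1.0 / target[lab])
    got[lab] <- row$mean
  }
  # intensity falls monotonically with browning
  expect_true(all(diff(got) < 0))

  # 680 nm: the common level leaves < 2 units between any two groups
  at680 <- q$summary[q$summary$band == 680 & q$summary$day != "4+7", ]
  expect_lt(max(at680$mean) - min(at680$mean), 2)
})
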