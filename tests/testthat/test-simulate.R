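lib <- default_class_library()

test_that("noise-free acquisitions round-trip the template exactly", {
  for (lab in c("C_WAT", "C_BAT")) {
    tpl <- lib[[lab]]
    triple <- simulate_raw_measurement(tpl, noise = noise_model())
    R <- compute_reflectance(triple$sample, triple$dark, triple$reference)
    expect_lt(max(abs(R$reflectance - tpl$values)), 1e-12)
  }
})

test_that("a perfect reflector reproduces the reference spectrum", {
  tpl <- build_class_template(1.0, 0.0)
  tpl$values[] <- 1  # the reflectance standard itself
  triple <- simulate_raw_measurement(tpl, noise = noise_model())
  expect_equal(triple$sample$counts, triple$reference$counts)
})

test_that("identical seeds give bitwise-identical simulations", {
  n1 <- noise_model(0.02, 5, seed = 123)
  a <- simulate_raw_measurement(lib$C_WAT, noise = n1)
  b <- simulate_raw_measurement(lib$C_WAT, noise = n1)
  expect_identical(a, b)

  r1 <- simulate_sample("TrWAT_d4", noise = noise_model(0.02, 0, seed = 7))
  r2 <- simulate_sample("TrWAT_d4", noise = noise_model(0.02, 0, seed = 7))
  expect_identical(r1, r2)

  d1 <- simulate_drs_dataset(classes = "C_BAT", n_mice = 2, seed = 99)
  d2 <- simulate_drs_dataset(classes = "C_BAT", n_mice = 2, seed = 99)
  expect_identical(d1, d2)
})

test_that("multiplicative noise has the declared coefficient of variation", {
  tpl <- lib$C_WAT
  rel_dev <- replicate(2000, {
    triple <- simulate_raw_measurement(tpl, noise = noise_model(0.02, 0))
    R <- compute_reflectance(triple$sample, triple$dark, triple$reference)
    # one grid point per draw keeps the values independent
    (R$reflectance[100] - tpl$values[100]) / tpl$values[100]
  })
  expect_equal(sd(rel_dev), 0.02, tolerance = 0.05)
})

test_that("noise propagates to per-location index dispersion and scales with cv", {
  rec <- simulate_sample("C_BAT", n_locations = 8,
                         noise = noise_model(0.02, 0, seed = STUDY_SEED))
  bi <- quantify_sample(rec)
  expect_gt(sd(bi$per_location_ratios), 0)

  sds <- vapply(c(0.01, 0.02, 0.05), function(cv) {
    rec <- simulate_sample("C_WAT", n_locations = 1000,
                           noise = noise_model(cv, 0, seed = STUDY_SEED))
    sd(quantify_sample(rec)$per_location_ratios)
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("simulated band images hit the calibrated class levels", {
  roi <- default_roi()
  # zero texture: every ROI pixel is the class level, background elsewhere
  img <- simulate_band_image("TrWAT_d4", 550, texture_sd = 0)
  expect_equal(extract_roi_mean(img, roi), 33)
  expect_equal(img$pixels[1, 1], 5L)

  img <- simulate_band_image("C_WAT", 550, texture_sd = 3, seed = STUDY_SEED)
  expect_equal(extract_roi_mean(img, roi), 48, tolerance = 0.5 / 48)

  # at 680 nm all classes share a common level by construction
  for (lab in class_labels()) {
    img <- simulate_band_image(lab, 680, texture_sd = 0)
    expect_equal(extract_roi_mean(img, roi), 50)
  }
  # 600 nm level interpolates linearly in wavelength
  expect_equal(msi_level("C_WAT", 600), 48 + (50 - 48) * 50 / 130)
})

test_that("simulated Ct tables encode folds in cycles", {
  fm <- data.frame(gene = "UCP1", tissue = "WAT", day = 7L, fold = 1)
  ct <- simulate_ct_table(fm, n_mice = 3, ct_sd = 0)
  ucp1 <- ct[ct$gene == "UCP1", ]
  expect_equal(unique(ucp1$ct[ucp1$group == "Tr"]),
               unique(ucp1$ct[ucp1$group == "C"]))

  fm$fold <- 2
  ct <- simulate_ct_table(fm, n_mice = 3, ct_sd = 0)
  ucp1 <- ct[ct$gene == "UCP1", ]
  expect_equal(unique(ucp1$ct[ucp1$group == "C"]) -
                 unique(ucp1$ct[ucp1$group == "Tr"]), 1)

  fm$fold <- 39
  ct <- simulate_ct_table(fm, n_mice = 3, ct_sd = 0)
  dct <- delta_ct(ct)
  ddct <- mean(dct$delta_ct[dct$group == "Tr"]) - mean(dct$delta_ct[dct$group == "C"])
  expect_equal(ddct, -log2(39), tolerance = 1e-12)

  expect_error(simulate_ct_table(data.frame(gene = "g", tissue = "WAT",
                                            day = 4L, fold = -1)),
               "positive")
  expect_error(simulate_ct_table(n_mice = 1), ">= 2")
})
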