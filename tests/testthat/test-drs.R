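test_that("reflectance correction satisfies its algebraic identities", {
  dark <- const_raw(100, "dark")
  ref <- const_raw(2100, "reference")

  # S = W  ->  R = 1 everywhere
  R <- compute_reflectance(const_raw(2100), dark, ref)
  expect_true(all(abs(R$reflectance - 1) < 1e-12))
  # S = D  ->  R = 0
  R <- compute_reflectance(const_raw(100), dark, ref)
  expect_true(all(abs(R$reflectance) < 1e-12))
  # S = (D + W) / 2  ->  R = 0.5
  R <- compute_reflectance(const_raw(1100), dark, ref)
  expect_true(all(abs(R$reflectance - 0.5) < 1e-12))
})

test_that("reflectance correction masks dead points and checks grids", {
  wl <- analysis_grid()
  dark <- const_raw(100, "dark")
  ref_counts <- rep(2100, length(wl)); ref_counts[wl > 690] <- 100
  ref <- raw_spectrum(wl, ref_counts, role = "reference")
  R <- compute_reflectance(const_raw(500), dark, ref)
  expect_false(any(R$mask[wl > 690]))
  expect_true(all(R$mask[wl <= 690]))

  other <- raw_spectrum(seq(450, 700, 5), rep(1, 51), role = "dark")
  expect_error(compute_reflectance(const_raw(500), other, ref), "grid")
  expect_error(compute_reflectance(const_raw(500), dark,
                                   const_raw(100, "reference")),
               "degenerate")
})

test_that("normalization pins 680 nm to 1 and is scale invariant", {
  tpl <- default_class_library()$TrWAT_d7
  R <- reflectance_spectrum(tpl$grid, tpl$values * 7)
  Rn <- normalize_at(R)
  expect_equal(Rn$reflectance[Rn$wavelengths == 680], 1)
  # templates are already 680-normalized: normalize_at is the identity
  expect_equal(normalize_at(reflectance_spectrum(tpl$grid, tpl$values))$reflectance,
               tpl$values, tolerance = 1e-12)
  expect_error(normalize_at(flat_spectrum(0)), "positive")
})

test_that("intensity ratio: identities and scale invariance", {
  expect_equal(intensity_ratio(flat_spectrum()), 1.0)
  # forced arithmetic: band means 0.6 / 0.4
  wl <- analysis_grid()
  v <- ifelse(wl < 600, 0.4, 0.6)
  expect_equal(intensity_ratio(reflectance_spectrum(wl, v)), 1.5)

  set.seed(STUDY_SEED)
  for (i in 1:20) {
    R <- reflectance_spectrum(wl, runif(length(wl), 0.1, 1))
    c_scale <- runif(1, 0.01, 100)
    Rc <- reflectance_spectrum(wl, R$reflectance * c_scale)
    expect_equal(intensity_ratio(Rc), intensity_ratio(R), tolerance = 1e-12)
  }
  expect_error(intensity_ratio(flat_spectrum(-1)), "non-positive")
})

test_that("band slope equals the closed-form least-squares oracle", {
  expect_equal(band_slope(flat_spectrum()), 0)
  # exact line with slope 0.003 per nm -> 0.30 per 100 nm
  wl <- analysis_grid()
  expect_equal(band_slope(reflectance_spectrum(wl, 0.5 + 0.003 * (wl - 450))),
               0.30, tolerance = 1e-12)

  set.seed(STUDY_SEED)
  for (i in 1:100) {
    R <- reflectance_spectrum(wl, runif(length(wl), 0.1, 1.5))
    in_win <- wl >= 570 & wl <= 630
    expect_equal(band_slope(R),
                 ols_slope_oracle(wl[in_win], R$reflectance[in_win]) * 100,
                 tolerance = 1e-10)
  }

  masked <- flat_spectrum()
  masked$mask[masked$wavelengths >= 569 & masked$wavelengths <= 631] <- FALSE
  expect_error(band_slope(masked), "fewer than 3")
})

test_that("per-sample indices are location means", {
  rec <- simulate_sample("TrWAT_d4", n_locations = 5, noise = noise_model())
  bi <- quantify_sample(rec)
  expect_equal(bi$n_locations, 5)
  expect_equal(bi$per_location_ratios, rep(1.17, 5), tolerance = 1e-9)
  expect_equal(bi$ratio, mean(bi$per_location_ratios))
  expect_equal(bi$slope, mean(bi$per_location_slopes))

  # seeded noisy brown tissue lands near its calibration value
  rec <- simulate_sample("C_BAT", n_locations = 5,
                         noise = noise_model(0.02, 0, seed = STUDY_SEED))
  bi <- quantify_sample(rec)
  expect_equal(bi$ratio, 2.36, tolerance = 3 * 0.02 / sqrt(5) / 2.36 * 2.36)
})

test_that("group summaries report mean, SE and pooled control cells", {
  df <- data.frame(group = "Tr", tissue = "WAT", day = 4L, value = c(1, 2, 3))
  # a lone control sample: SE undefined, reported missing with n = 1
  df <- rbind(df, data.frame(group = "C", tissue = "WAT", day = 4L, value = 5))
  s <- summarize_groups(df)
  trt <- s[s$group == "Tr", ]
  expect_equal(trt$mean, 2)
  expect_equal(trt$se, 1 / sqrt(3), tolerance = 1e-12)
  ctrl <- s[s$group == "C" & s$day == "4", ]
  expect_equal(ctrl$n, 1)
  expect_true(is.na(ctrl$se))

  # pooled control cell averages over both days
  df <- data.frame(group = "C", tissue = "WAT", day = rep(c(4L, 7L), each = 2),
                   value = c(1, 2, 3, 4))
  s <- summarize_groups(df)
  pooled <- s[s$day == "4+7", ]
  expect_equal(pooled$mean, 2.5)
  expect_equal(pooled$n, 4)

  expect_error(summarize_groups(df[0, ]), "no samples")
})

test_that("optional slope rescaling sets pooled control WAT to 1", {
  df <- data.frame(group = c("C", "C", "Tr"), tissue = "WAT",
                   day = c(4L, 7L, 7L), value = c(0.18, 0.20, 0.36))
  s <- normalize_slopes_to_reference(summarize_groups(df))
  expect_equal(s$mean[s$day == "4+7"], 1)
  expect_equal(s$mean[s$group == "Tr"], 0.36 / 0.19, tolerance = 1e-12)
})
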