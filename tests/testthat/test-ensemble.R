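test_that("spectrum correction inverts the acquisition model", {
  wl <- default_wavelengths()
  truth <- synth_spectrum(1.3, noise_sd = 0)
  excitation <- tibble::tibble(wavelength_nm = wl,
                               intensity = 0.5 + 0.4 * sin(wl / 40))
  background <- tibble::tibble(wavelength_nm = wl,
                               intensity = 0.05 + wl / 1e4)
  raw <- tibble::tibble(wavelength_nm = wl,
                        intensity = truth$intensity * excitation$intensity +
                          background$intensity)
  rec <- correct_spectrum(raw, background, excitation)
  expect_equal(rec$intensity, truth$intensity, tolerance = 1e-12)

  expect_equal(correct_spectrum(raw, raw,
                                tibble::tibble(wavelength_nm = wl,
                                               intensity = 1))$intensity,
               rep(0, length(wl)))
  ident <- correct_spectrum(raw,
                            tibble::tibble(wavelength_nm = wl, intensity = 0),
                            tibble::tibble(wavelength_nm = wl, intensity = 1))
  expect_equal(ident$intensity, raw$intensity)
  off_grid <- tibble::tibble(wavelength_nm = wl + 1e4, intensity = 1)
  expect_error(correct_spectrum(raw, off_grid, off_grid), "overlap")
})

test_that("RG of a corrected spectrum ignores excitation rescaling", {
  wl <- default_wavelengths()
  truth <- synth_spectrum(1.4, noise_sd = 0)
  bg <- tibble::tibble(wavelength_nm = wl, intensity = 0.1)
  ex <- tibble::tibble(wavelength_nm = wl, intensity = 0.8)
  raw <- tibble::tibble(wavelength_nm = wl,
                        intensity = truth$intensity * ex$intensity +
                          bg$intensity)
  rg1 <- rg_ratio(correct_spectrum(raw, bg, ex))
  ex2 <- ex; ex2$intensity <- ex$intensity * 37
  raw2 <- tibble::tibble(wavelength_nm = wl,
                         intensity = truth$intensity * ex2$intensity +
                           bg$intensity)
  expect_equal(rg_ratio(correct_spectrum(raw2, bg, ex2)), rg1,
               tolerance = 1e-12)
})

test_that("noiseless titrations are recovered exactly", {
  tt <- synth_titration(slope = 0.106, intercept = 0.902, replicate_sd = 0)
  fit <- fit_calibration(tt)
  expect_equal(fit$slope, 0.106, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.902, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  expect_error(fit_calibration(dplyr::filter(
    tt, concentration_eu_ml %in% c(15, 31))), "3 distinct")
  bad <- tt; bad$concentration_eu_ml[1] <- -5
  expect_error(fit_calibration(bad), "negative")
})

test_that("the fitted line and its inverse agree with hand evaluation", {
  fit <- calibration_fit(slope = 0.106, intercept = 0.902)
  # measured post-incubation RG at 500 EU/ml is 1.563; the line gives
  # 0.106 ln(500) + 0.902
  expect_equal(predict_rg(fit, 500), 0.106 * log(500) + 0.902)
  expect_equal(predict_rg(fit, 500), 1.563, tolerance = 0.002)
  expect_equal(predict_rg(fit, 1), 0.902)

  # inverse pair
  for (c0 in c(2, 25, 500, 4000)) {
    expect_equal(estimate_concentration(fit, predict_rg(fit, c0)), c0,
                 tolerance = 1e-9)
  }
  # the blank-level RG maps between the bracketing tested levels
  c_blank <- estimate_concentration(fit, 1.242)
  expect_gt(c_blank, 15)
  expect_lt(c_blank, 31)
  expect_error(estimate_concentration(calibration_fit(0, 1), 1.2), "slope")
})

test_that("LOD brackets follow the significance flags", {
  lv <- tibble::tibble(concentration_eu_ml = c(15, 31, 62),
                       significant = c(FALSE, TRUE, TRUE))
  expect_equal(unlist(estimate_lod(lv)),
               c(lower_eu_ml = 15, upper_eu_ml = 31))
  lv$significant <- c(FALSE, FALSE, TRUE)
  expect_equal(unlist(estimate_lod(lv)),
               c(lower_eu_ml = 31, upper_eu_ml = 62))
  lv$significant <- c(TRUE, FALSE, TRUE)
  expect_error(estimate_lod(lv), "monotone")
  lv$significant <- c(TRUE, TRUE, TRUE)
  expect_error(estimate_lod(lv), "open")
  lv$significant <- c(FALSE, FALSE, FALSE)
  expect_error(estimate_lod(lv), "open")
})

test_that("LOD flags can be derived from replicate RG values", {
  # blank level placed at the response of the lowest tested concentration,
  # so the response rises monotonically out of the blank band
  blank <- 0.106 * log(15) + 0.902
  tt <- synth_titration(replicate_sd = 0.015, blank_mean = blank, seed = 3)
  lod <- estimate_lod(tt)
  expect_lte(lod$lower_eu_ml, lod$upper_eu_ml)
  expect_true(lod$upper_eu_ml %in% tt$concentration_eu_ml)
  expect_true(lod$lower_eu_ml %in% tt$concentration_eu_ml)
})

test_that("LOD brackets do not widen as replicate noise shrinks", {
  blank <- 0.106 * log(15) + 0.902
  uppers <- vapply(c(0.12, 0.03, 0.008), function(sd) {
    mean(vapply(1:5, function(seed) {
      tt <- synth_titration(replicate_sd = sd, blank_mean = blank,
                            n_replicates = 3, seed = seed)
      # an open or ambiguous bracket counts as the widest possible one
      tryCatch(estimate_lod(tt)$upper_eu_ml, error = function(e) 500)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(uppers) <= 0))
})

test_that("endotoxin units convert to mass at 10 EU per ng", {
  expect_identical(eu_to_ng(500), 50)
  expect_identical(eu_to_ng(4000), 400)
  expect_identical(eu_to_ng(0), 0)
  expect_error(eu_to_ng(-1), "non-negative")
})

test_that("group comparisons use t tests and ANOVA appropriately", {
  g <- c(1.1, 1.2, 1.3)
  same <- compare_groups(list(a = g, b = g))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  three <- compare_groups(list(a = g, b = g, c = g))
  expect_equal(three$test_name, "one-way ANOVA")
  expect_equal(three$statistic, 0)

  expect_error(compare_groups(list(a = c(1, 1), b = c(2, 2))), "degenerate")
  expect_error(compare_groups(list(a = g, b = g, c = g), mode = "two-sample"),
               "exactly 2")
  expect_error(compare_groups(list(a = 1, b = g)), "n >= 2")
})

test_that("well-separated groups are detected with high power", {
  hits <- vapply(1:100, function(seed) {
    set.seed(seed)
    a <- stats::rnorm(3, 0, 0.01)
    b <- stats::rnorm(3, 5, 0.01)
    compare_groups(list(a = a, b = b))$p_value < 0.05
  }, logical(1))
  expect_gte(sum(hits), 99)
})

test_that("calibration objects tidy into broom-style tables", {
  tt <- synth_titration(seed = 9)
  fit <- fit_calibration(tt)
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$estimate, c(fit$intercept, fit$slope))
  gl <- glance(fit)
  expect_equal(gl$r.squared, fit$r_squared)
  cmp <- compare_groups(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_true(tidy(cmp)$significant)
})
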