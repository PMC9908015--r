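test_that("synthetic spectra hit their target RG exactly when noiseless", {
  for (target in c(0.9, 1.242, 1.563, 2.1)) {
    s <- synth_spectrum(target, noise_sd = 0)
    expect_equal(rg_ratio(s), target, tolerance = 1e-12)
  }
  # noiseless output ignores the seed entirely
  expect_identical(synth_spectrum(1.3, noise_sd = 0, seed = 1)$intensity,
                   synth_spectrum(1.3, noise_sd = 0, seed = 99)$intensity)
  expect_error(synth_spectrum(1e4), "not achievable")
  expect_error(synth_spectrum(-1), "> 0")
})

test_that("noisy synthetic spectra stay unbiased in RG", {
  rgs <- vapply(1:100, function(seed) {
    rg_ratio(synth_spectrum(1.563, noise_sd = 0.01, seed = seed))
  }, numeric(1))
  expect_lt(abs(mean(rgs) - 1.563) / 1.563, 0.01)
})

test_that("titration generation closes with the calibration fit", {
  exact <- synth_titration(replicate_sd = 0)
  fit <- fit_calibration(exact)
  gt <- ground_truth(exact)
  expect_equal(fit$slope, gt$parameters$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, gt$parameters$intercept, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  expect_error(fit_calibration(synth_titration(concentrations = 100)),
               "3 distinct")
  expect_error(synth_titration(concentrations = c(0, 10)), "positive")
  expect_identical(synth_titration(seed = 4), synth_titration(seed = 4))
})

test_that("titrations at the measured noise recover the slope reliably", {
  ok <- vapply(1:100, function(seed) {
    tt <- synth_titration(replicate_sd = 0.015, seed = seed)
    fit <- fit_calibration(tt)
    abs(fit$slope - 0.106) / 0.106 < 0.15
  }, logical(1))
  expect_gte(sum(ok), 95)
})

test_that("QCM trace generation closes with the slope and step analysis", {
  steps <- tibble::tibble(label = c("SAM", "aptamer", "endotoxin"),
                          delta_f_hz = c(20, 33, 3),
                          duration_s = c(1800, 3600, 7200),
                          slope_hz_per_min = c(0, 0, -0.021))
  tr <- synth_qcm_trace(steps, noise_sd = 0)
  expect_equal(fit_binding_slope(tr, "endotoxin"), -0.021, tolerance = 1e-9)

  drift_free <- tibble::tibble(label = c("a", "b"), delta_f_hz = c(10, 5),
                               duration_s = c(600, 600))
  tr2 <- synth_qcm_trace(drift_free, noise_sd = 0)
  expect_equal(min(tr2$delta_f_hz), -15, tolerance = 1e-9)
  expect_equal(tr2$delta_f_hz[nrow(tr2)], -15, tolerance = 1e-9)

  n1 <- synth_qcm_trace(steps, noise_sd = 0.1, seed = 1)
  n2 <- synth_qcm_trace(steps, noise_sd = 0.1, seed = 2)
  expect_false(identical(n1$delta_f_hz, n2$delta_f_hz))
  expect_identical(attr(n1, "annotations"), attr(n2, "annotations"))

  expect_error(synth_qcm_trace(tibble::tibble(label = c("a", "a"),
                                              delta_f_hz = c(1, 1),
                                              duration_s = c(10, 10))),
               "unique")
  expect_error(synth_qcm_trace(tibble::tibble(label = "a", delta_f_hz = 1,
                                              duration_s = -5)),
               "> 0")
})

test_that("dark-field generation is reproducible and honest about truth", {
  a <- synth_darkfield_image(seed = 6)
  b <- synth_darkfield_image(seed = 6)
  expect_identical(a$pixels, b$pixels)
  expect_identical(ground_truth(a)$particles, ground_truth(b)$particles)

  gt <- ground_truth(a)
  expect_equal(nn_spacing(gt$particles, a$pixel_size)$mean_um, 3.6,
               tolerance = 0.1)

  # noiseless 10-particle field closes with the detector
  img10 <- synth_darkfield_image(field_size_um = 25, n_particles = 10,
                                 photons = NULL, read_noise_sd = 0, seed = 2)
  expect_equal(nrow(detect_particles(img10)), 10)

  # grayscale RG distribution yields unit ratios everywhere
  gray <- synth_darkfield_image(field_size_um = 30, rg_mean = 1, rg_sd = 0,
                                photons = NULL, read_noise_sd = 0, seed = 3)
  det <- detect_particles(gray)
  expect_true(all(abs(det$rg - 1) <= 0.02))

  expect_error(synth_darkfield_image(field_size_um = 4,
                                     target_spacing_um = 10),
               "at least 2")
  expect_error(synth_darkfield_image(field_size_um = 20, n_particles = 200,
                                     target_spacing_um = 5),
               "cannot place")
})

test_that("generated artifacts carry their ground truth", {
  s <- synth_spectrum(1.3, noise_sd = 0.01, seed = 12)
  gt <- ground_truth(s)
  expect_equal(gt$generator, "synth_spectrum")
  expect_equal(gt$seed, 12)
  expect_equal(gt$parameters$target_rg, 1.3)
  expect_null(ground_truth(tibble::tibble(x = 1)))
})
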