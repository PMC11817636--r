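test_that("default band set matches the device and validates its invariants", {
  b <- spectral_bands()
  expect_equal(b$wavelengths_nm, c(414, 447, 477, 524, 671, 735, 890, 995))
  expect_equal(b$band_count, 8L)
  expect_error(spectral_bands(c(500, 450)), "increasing")
  expect_error(spectral_bands(c(-1, 400)), "positive")
})

test_that("chromophore panel has the required spectral shapes", {
  p <- build_default_chromophore_panel(spectral_bands())
  wl <- attr(p, "wavelengths_nm")
  expect_identical(dim(p), c(4L, 8L))
  # melanin monotonically non-increasing with wavelength
  expect_true(all(diff(p["melanin", ]) <= 0))
  expect_gt(p["melanin", "414"], p["melanin", "995"])
  # water rises toward the NIR and is silent below 700 nm
  expect_gt(p["water", "995"], p["water", "414"])
  expect_true(all(p["water", wl < 700] == 0))
  # hemoglobin peaks in the blue/green with a window near 671 nm
  expect_equal(unname(which.min(p["oxy_hb", ])), which(wl == 671))
  expect_gt(p["oxy_hb", "524"], p["oxy_hb", "671"])
  # degenerate single-band set
  p1 <- build_default_chromophore_panel(spectral_bands(671))
  expect_identical(dim(p1), c(4L, 1L))
})

test_that("lesion synthesis draws concentrations from class ranges", {
  cfg <- sim_config(frame_shape = c(32, 32), seed = 4)
  les <- synthesize_lesion(cfg, "nevus", seed = 11)
  r <- cfg$class_concentration_ranges$nevus
  for (ch in names(r)) {
    expect_gte(les$chromophore_concentrations[[ch]], r[[ch]][1])
    expect_lte(les$chromophore_concentrations[[ch]], r[[ch]][2])
  }
  expect_error(synthesize_lesion(cfg, "wart"), "unknown class")
  # degenerate zero-width ranges are deterministic
  rng <- lapply(cfg$class_concentration_ranges, function(cl)
    lapply(cl, function(x) c(x[1], x[1])))
  cfg2 <- sim_config(frame_shape = c(32, 32), class_concentration_ranges = rng)
  l1 <- synthesize_lesion(cfg2, "bcc", seed = 1)
  l2 <- synthesize_lesion(cfg2, "bcc", seed = 2)
  expect_equal(l1$chromophore_concentrations, l2$chromophore_concentrations)
})

test_that("NIR-only mode separates classes above 700 nm and nowhere below", {
  cfg <- sim_config(frame_shape = c(32, 32), separability_mode = "nir_only",
                    seed = 5)
  panel <- build_default_chromophore_panel(cfg$bands)
  set.seed(5)
  refl <- lapply(c("nevus", "melanoma", "bcc"), function(cl) {
    t(vapply(1:200, function(i) {
      lesion_expected_reflectance(synthesize_lesion(cfg, cl), panel)
    }, numeric(8)))
  })
  for (b in which(cfg$bands$wavelengths_nm < 700)) {
    mus <- vapply(refl, function(m) mean(m[, b]), numeric(1))
    sds <- vapply(refl, function(m) sd(m[, b]), numeric(1))
    expect_lt(max(dist(mus)), mean(sds)) # indistinguishable below 700 nm
  }
  mus <- vapply(refl, function(m) mean(m[, 7]), numeric(1)) # 890 nm
  sds <- vapply(refl, function(m) sd(m[, 7]), numeric(1))
  expect_gt(min(dist(mus)), 2 * mean(sds)) # strong class signal at 890 nm
})

test_that("rendered captures obey the sensor model", {
  cfg <- sim_config(frame_shape = c(32, 32), sensor_noise_sd = 0,
                    dark_noise_sd = 0, illumination_variation = 0,
                    class_counts = c(nevus = 1, melanoma = 1, bcc = 1),
                    seed = 8)
  panel <- build_default_chromophore_panel(cfg$bands)
  les <- synthesize_lesion(cfg, "melanoma", seed = 2)
  cap <- render_capture(les, panel, cfg, seed = 3)
  # noiseless flat field: neutral frame is constant round(d + G k)
  expect_true(all(cap$neutral ==
    round(cfg$dark_offset_mean +
          cfg$illumination_gain * cfg$neutral_reflectance_k)))
  expect_true(all(cap$dark == cfg$dark_offset_mean))
  # absorption darkens the lesion interior at 414 nm
  expect_lt(mean(cap$lesion[, , 1][cap$lesion_mask]),
            mean(cap$lesion[, , 1][!cap$lesion_mask]))
  # all values within the 12-bit range
  expect_gte(min(cap$lesion, cap$dark, cap$neutral), 0)
  expect_lte(max(cap$lesion, cap$dark, cap$neutral), 4095)
  # grossly mis-scaled illumination triggers the saturation guard
  cfg_bad <- cfg; cfg_bad$illumination_gain <- 4e4
  expect_error(render_capture(les, panel, cfg_bad, seed = 3), "saturated")
})

test_that("dark frames carry the configured offset and noise statistics", {
  cfg <- sim_config(frame_shape = c(48, 48), dark_noise_sd = 2,
                    class_counts = c(nevus = 1, melanoma = 1, bcc = 1),
                    seed = 21)
  cap <- simulate_dataset(cfg)[[1]]
  n <- length(cap$dark)
  expect_lt(abs(mean(cap$dark) - cfg$dark_offset_mean),
            3 * cfg$dark_noise_sd / sqrt(n))
})

test_that("simulation respects class counts and is bit-reproducible", {
  cfg <- sim_config(frame_shape = c(24, 24),
                    class_counts = c(nevus = 2, melanoma = 2, bcc = 2),
                    seed = 6)
  caps <- simulate_dataset(cfg)
  expect_length(caps, 6L)
  labs <- vapply(caps, `[[`, character(1), "true_label")
  expect_equal(as.vector(table(factor(labs, c("nevus", "melanoma", "bcc")))),
               c(2L, 2L, 2L))
  expect_identical(caps, simulate_dataset(cfg))
  # provenance carries seed / index / label
  expect_equal(caps[[3]]$provenance$index, 3L)
  expect_equal(caps[[3]]$provenance$seed, 6L)
})

test_that("capture writer round-trips counts exactly through 16-bit TIFF", {
  cfg <- sim_config(frame_shape = c(16, 16),
                    class_counts = c(nevus = 1, melanoma = 1, bcc = 1),
                    seed = 12)
  cap <- simulate_dataset(cfg)[[2]]
  dir <- withr::local_tempdir()
  write_capture(cap, dir)
  expect_true(file.exists(file.path(dir, "capture.json")))
  back <- read_capture(dir)
  expect_identical(back$lesion, cap$lesion)
  expect_identical(back$dark, cap$dark)
  expect_identical(back$neutral, cap$neutral)
  expect_equal(back$k, cap$k)
  expect_equal(back$true_label, cap$true_label)
})
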