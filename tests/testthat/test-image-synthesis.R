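test_that("rasterized coverage integrates to the analytic hole area", {
  lay <- mini_layout(3.0)
  f <- rasterize_layout(lay, 0.39, supersample = 16)
  expect_equal(sum(f) * 0.39^2, nominal_csa(3.0), tolerance = 0.005)
  # empty layout renders an all-zero field
  empty <- phantom_layout(mini_layout()[0, ], complete = FALSE)
  expect_true(all(rasterize_layout(empty, 0.39) == 0))
})

test_that("supersampling converges: 16 vs 32 agree within the bound", {
  lay <- mini_layout(3.0)
  a <- rasterize_layout(lay, 0.39, supersample = 16)
  b <- rasterize_layout(lay, 0.39, supersample = 32)
  expect_lt(max(abs(a - b)), 1 / 16^2 + 1e-12)
  expect_error(rasterize_layout(lay, 0.39, supersample = 2), ">= 4")
})

test_that("contrast lookup matches the iodine/kVp table and rejects others", {
  expect_identical(delta_hu(3, 120), 170)
  expect_identical(delta_hu(6, 120), 390)
  expect_identical(delta_hu(3, 100), 250)
  expect_identical(delta_hu(6, 100), 560)
  expect_error(delta_hu(7, 120), "no contrast entry")
  expect_error(ct_protocol(iodine_pct = 2), "no contrast entry")
})

test_that("noiseless CT stack hits background + delta-HU at lumen centre", {
  lay <- mini_layout(3.2)
  p <- ct_protocol(kvp = 100, iodine_pct = 6, noise_sd_ref_hu = 0,
                   psf_fwhm_mm = 0, n_sections = 1)
  st <- simulate_ct_stack(lay, p, seed = 1, supersample = 16)
  expect_equal(max(st$pixels), p$background_hu + 560, tolerance = 1e-9)
  expect_equal(min(st$pixels), p$background_hu, tolerance = 1e-9)
})

test_that("CT stacks are deterministic per seed", {
  lay <- mini_layout(3.0)
  p <- ct_protocol(n_sections = 2)
  a <- simulate_ct_stack(lay, p, seed = 9)
  b <- simulate_ct_stack(lay, p, seed = 9)
  expect_identical(a$pixels, b$pixels)
  c <- simulate_ct_stack(lay, p, seed = 10)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("background noise follows the 1/sqrt(dose) law", {
  lay <- mini_layout(3.0)
  mk <- function(dose, seed) {
    p <- ct_protocol(ctdi_mgy = dose, asirv_pct = 0, n_sections = 30)
    st <- simulate_ct_stack(lay, p, seed = seed)
    sd(st$pixels[st$background_roi$rows, st$background_roi$cols, ])
  }
  ratio <- mk(20, 3) / mk(5, 4)
  expect_equal(ratio, 0.5, tolerance = 0.05)
})

test_that("noise decreases with reconstruction strength and 5-mm sections", {
  p0 <- ct_protocol(asirv_pct = 0)
  p50 <- ct_protocol(asirv_pct = 50)
  p90 <- ct_protocol(asirv_pct = 90)
  expect_true(ct_noise_sd(p90) < ct_noise_sd(p50) &&
                ct_noise_sd(p50) < ct_noise_sd(p0))
  thick <- ct_protocol(asirv_pct = 0, section_mm = 5.0)
  expect_equal(ct_noise_sd(thick), ct_noise_sd(p0) / sqrt(8),
               tolerance = 1e-12)
})

test_that("lumen contrast increases monotonically with iodine at fixed kVp", {
  lay <- mini_layout(3.2)
  for (kvp in c(100, 120)) {
    means <- vapply(3:6, function(conc) {
      p <- ct_protocol(kvp = kvp, iodine_pct = conc, noise_sd_ref_hu = 0,
                       n_sections = 1)
      st <- simulate_ct_stack(lay, p, seed = 1)
      max(st$pixels) - p$background_hu
    }, numeric(1))
    expect_true(all(diff(means) > 0))
  }
})

test_that("MR signal equals the target SNR at the lumen centre (noiseless)", {
  lay <- mini_layout(3.2)
  p <- mr_protocol(gd_mmol_l = 1.00, psf_fwhm_mm = 0, n_frames = 1)
  st <- simulate_mr_cine(lay, p, seed = 1, noiseless = TRUE,
                         supersample = 16)
  expect_equal(max(st$pixels), p$target_snr, tolerance = 1e-9)
  expect_equal(min(st$pixels), 0)  # PMMA gives no MR signal
})

test_that("measured MR SNR matches the concentration calibration", {
  lay <- full_layout()
  p <- mr_protocol(gd_mmol_l = 1.66, n_frames = 4)
  st <- simulate_mr_cine(lay, p, seed = 2)
  tab <- segment_stack(st, lay)
  s <- measure_snr(st, tab)
  expect_equal(s$mean, p$target_snr, tolerance = 0.10)
  # Rician background magnitude has unit SD by construction
  bg <- st$pixels[st$background_roi$rows, st$background_roi$cols, ]
  expect_equal(sd(bg), 1, tolerance = 0.05)
})

test_that("zero-amplitude motion reproduces the static stack", {
  lay <- mini_layout(3.0)
  p <- ct_protocol(n_sections = 2)
  still <- motion_state(amplitude_mm = 0)
  a <- simulate_ct_stack(lay, p, seed = 5)
  b <- simulate_ct_stack(lay, p, motion = still, seed = 5)
  expect_identical(a$pixels, b$pixels)
})

test_that("motion kernel is a normalized density with the analytic support", {
  m <- motion_state()
  k0 <- motion_density_kernel(m, 0, 0.39)
  expect_identical(as.numeric(k0), 1)
  k <- motion_density_kernel(m, 0.14, 0.39)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  support <- diff(range(attr(k, "offset_px"))) * 0.39
  expect_lt(abs(support - window_displacement(m, 0.14)), 0.39)
  expect_error(motion_density_kernel(m, 1.2, 0.39), "period")
})

test_that("motion blur conserves total excess intensity (noiseless)", {
  lay <- mini_layout(c(3.0, 3.4))
  p <- ct_protocol(noise_sd_ref_hu = 0, n_sections = 1)
  a <- simulate_ct_stack(lay, p, seed = 1)
  b <- simulate_ct_stack(lay, p, motion = motion_state(), seed = 1)
  ex <- function(st) sum(st$pixels[, , 1] - p$background_hu)
  expect_equal(ex(b) / ex(a), 1, tolerance = 0.005)
})

test_that("motion degrades SNR and circularity at matched seed", {
  lay <- full_layout()
  p <- ct_protocol(ctdi_mgy = 5, n_sections = 3)
  stat <- simulate_ct_stack(lay, p, seed = 6)
  mov <- simulate_ct_stack(lay, p, motion = motion_state(), seed = 6)
  ts <- segment_stack(stat, lay)
  tm <- segment_stack(mov, lay)
  expect_lt(mean(tm$circularity[tm$status == "ok"]),
            mean(ts$circularity[ts$status == "ok"]))
  expect_lt(measure_snr(mov, tm)$mean, measure_snr(stat, ts)$mean)
})

test_that("image stacks round-trip through TIFF + sidecar", {
  skip_if_not_installed("tiff")
  lay <- mini_layout(3.0)
  p <- ct_protocol(n_sections = 2)
  st <- simulate_ct_stack(lay, p, seed = 1)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(st, path)
  back <- read_image_stack(path)
  expect_equal(back$pixels, st$pixels, tolerance = 1e-5)
  expect_identical(back$modality, "CT")
  expect_equal(back$pixel_mm, st$pixel_mm)
})
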