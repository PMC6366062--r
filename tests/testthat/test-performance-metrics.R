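mock_table <- function(csa_by_diameter, n = NULL) {
  rows <- do.call(rbind, lapply(names(csa_by_diameter), function(d) {
    v <- csa_by_diameter[[d]]
    data.frame(protocol_id = "mock", hole_id = paste0("h", d),
               diameter_mm = as.numeric(d),
               section_index = seq_along(v), csa_mm2 = v,
               circularity = 1, status = "ok", stringsAsFactors = FALSE)
  }))
  structure(rows, class = c("measurement_table", "data.frame"))
}

# exact-measurement table: every hole reads its nominal CSA, r replicates
exact_table <- function(diameters = phantom_diameters(), r = 5) {
  vals <- lapply(diameters, function(d) rep(nominal_csa(d), r))
  names(vals) <- diameters
  mock_table(vals)
}

test_that("accuracy reports per-diameter bias with shift invariance", {
  tab <- exact_table()
  acc <- csa_accuracy(tab)
  expect_equal(acc$mean, 0, tolerance = 1e-12)
  expect_equal(acc$sd, 0, tolerance = 1e-12)
  shifted <- tab
  shifted$csa_mm2 <- shifted$csa_mm2 - 0.35
  acc2 <- csa_accuracy(shifted)
  expect_equal(acc2$mean, -0.35, tolerance = 1e-12)
  expect_equal(acc2$sd, 0, tolerance = 1e-12)
  expect_error(csa_accuracy(tab[0, ]), "no valid")
})

test_that("precision is the per-diameter sample SD", {
  tab <- exact_table()
  expect_equal(csa_precision(tab)$mean, 0, tolerance = 1e-12)
  # known-sigma Gaussian recovers sigma within the chi-squared band
  set.seed(42)
  vals <- lapply(phantom_diameters(), function(d) {
    rnorm(100, nominal_csa(d), 0.1)
  })
  names(vals) <- phantom_diameters()
  prec <- csa_precision(mock_table(vals))
  expect_equal(prec$mean, 0.1, tolerance = 0.15)
  # singleton diameters are dropped with a warning
  one <- mock_table(list(`3` = 7.07, `3.02` = c(7.1, 7.2)))
  expect_warning(p1 <- csa_precision(one), "single")
  expect_identical(nrow(p1$per_diameter), 1L)
})

test_that("roc_auc equals the brute-force pair count, ties at one half", {
  expect_equal(roc_auc(c(1, 2), c(1, 2)), 0.5)
  expect_equal(roc_auc(c(1, 2), c(3, 4)), 1)
  expect_equal(roc_auc(c(1, 3), c(2, 4)), 0.75)
  expect_error(roc_auc(numeric(0), 1), "nonempty")
  brute <- function(a, b) {
    g <- expand.grid(a = a, b = b)
    (sum(g$b > g$a) + 0.5 * sum(g$b == g$a)) / nrow(g)
  }
  set.seed(7)
  for (i in 1:20) {
    a <- sample(1:8, sample(2:60, 1), replace = TRUE)  # heavy ties
    b <- sample(1:8, sample(2:60, 1), replace = TRUE) + runif(1, -1, 1)
    expect_equal(roc_auc(a, b), brute(a, b), tolerance = 1e-12)
    expect_equal(roc_auc(a, b) + roc_auc(b, a), 1, tolerance = 1e-12)
  }
})

test_that("zero-noise LOD equals the smallest drilled step", {
  lod <- csa_lod(exact_table())
  # every pair separates perfectly, so each reference detects its own
  # adjacent drilled step; the smallest is CSA(3.02) - CSA(3.00)
  step <- pi * (1.51^2 - 1.50^2)  # 0.0946 mm2
  expect_equal(lod$per_reference$lod_mm2[1], step, tolerance = 1e-12)
  expect_equal(min(lod$per_reference$lod_mm2), step, tolerance = 1e-12)
  d <- phantom_diameters()
  expect_equal(lod$per_reference$lod_mm2,
               diff(nominal_csa(d)), tolerance = 1e-12)
  expect_identical(lod$status, "ok")
  expect_equal(lod$frac_undefined, 0)
  expect_equal(lod$lod_pct_mean, 100 * lod$mean / (pi * 1.5^2),
               tolerance = 1e-9)
})

test_that("overwhelming noise yields an undetectable LOD", {
  set.seed(1)
  vals <- lapply(phantom_diameters(), function(d) {
    rnorm(30, nominal_csa(d), 10)
  })
  names(vals) <- phantom_diameters()
  lod <- csa_lod(mock_table(vals))
  expect_identical(lod$status, "LOD undetectable")
  expect_true(is.na(lod$mean))
  expect_error(csa_lod(mock_table(list(`3` = 1:3))), ">= 2 diameters")
})

test_that("Gaussian LOD tracks the analytic AUC crossing", {
  # AUC(delta) = Phi(delta / (sigma sqrt(2))) >= 0.95 at
  # delta = qnorm(0.95) * sigma * sqrt(2); the measured LOD is this value
  # quantized up/down by at most one rung of the drilled-step ladder
  sigma <- 0.08
  analytic <- qnorm(0.95) * sigma * sqrt(2)
  set.seed(11)
  vals <- lapply(phantom_diameters(), function(d) {
    rnorm(100, nominal_csa(d), sigma)
  })
  names(vals) <- phantom_diameters()
  lod <- csa_lod(mock_table(vals))
  step <- pi * (1.51^2 - 1.50^2)
  expect_lt(abs(lod$mean - analytic), step)
})

test_that("LOD is monotone in threshold and in noise level", {
  mk <- function(sigma, seed) {
    set.seed(seed)
    vals <- lapply(phantom_diameters(), function(d) {
      rnorm(60, nominal_csa(d), sigma)
    })
    names(vals) <- phantom_diameters()
    mock_table(vals)
  }
  tab <- mk(0.1, 5)
  lods <- vapply(c(0.90, 0.95, 0.99), function(th) {
    csa_lod(tab, auc_threshold = th)$mean
  }, numeric(1))
  expect_true(all(diff(lods) >= 0))
  by_noise <- vapply(c(0.05, 0.15, 0.45), function(s) {
    csa_lod(mk(s, 6))$mean
  }, numeric(1))
  expect_true(all(diff(by_noise) >= 0))
})

test_that("lod percentage conversion uses the 3-mm reference lumen", {
  expect_equal(csa_percent(0), 0)
  expect_equal(csa_percent(0.16), 2.26, tolerance = 0.005)
  expect_equal(csa_percent(0.52), 7.36, tolerance = 0.005)
  expect_equal(csa_percent(1) / 1, 100 / (pi * 2.25), tolerance = 1e-12)
  expect_error(csa_percent(1, 0), "> 0")
})

test_that("SNR is signal over background SD and scales linearly", {
  lay <- mini_layout(3.2)
  p <- ct_protocol(n_sections = 4)
  st <- simulate_ct_stack(lay, p, seed = 3)
  tab <- segment_stack(st, lay)
  s1 <- measure_snr(st, tab)
  st2 <- st
  st2$pixels <- st$pixels * 2
  tab2 <- tab
  tab2$mean_lumen_signal <- tab$mean_lumen_signal * 2
  s2 <- measure_snr(st2, tab2)
  expect_equal(s2$mean / s1$mean, 1, tolerance = 1e-9)  # noise doubled too
  tab3 <- tab
  tab3$mean_lumen_signal <- tab$mean_lumen_signal * 2
  s3 <- measure_snr(st, tab3)
  expect_equal(s3$mean / s1$mean, 2, tolerance = 1e-9)
  # noiseless input has no defined SNR
  st0 <- noiseless_ct(lay, n_sections = 1)
  tab0 <- segment_stack(st0, lay)
  expect_error(measure_snr(st0, tab0), "zero background SD")
})

test_that("regression recovers exact and affine relations", {
  tab <- exact_table()
  r <- suppressWarnings(csa_regression(tab))  # lm flags the perfect fit
  expect_equal(r$slope, 1, tolerance = 1e-9)
  expect_equal(r$intercept_mm2, 0, tolerance = 1e-9)
  expect_equal(r$r2, 1, tolerance = 1e-9)
  aff <- tab
  aff$csa_mm2 <- 1.2 * nominal_csa(aff$diameter_mm) - 2
  r2 <- suppressWarnings(csa_regression(aff))
  expect_equal(r2$slope, 1.2, tolerance = 1e-9)
  expect_equal(r2$intercept_mm2, -2, tolerance = 1e-9)
  expect_error(csa_regression(mock_table(list(`3` = 1:5))), "diameters")
})

test_that("precision and LOD improve with per-hole averaging", {
  # averaging adjacent sections before the statistics reduces dispersion
  sigma <- 0.2
  set.seed(9)
  vals <- lapply(phantom_diameters(), function(d) {
    rnorm(120, nominal_csa(d), sigma)
  })
  names(vals) <- phantom_diameters()
  raw <- mock_table(vals)
  avg <- mock_table(lapply(vals, function(v) {
    colMeans(matrix(v, nrow = 4))  # 4-section averages
  }))
  expect_lt(csa_precision(avg)$mean, csa_precision(raw)$mean)
  expect_lte(csa_lod(avg)$mean, csa_lod(raw)$mean)
})
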