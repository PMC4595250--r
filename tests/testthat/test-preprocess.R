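test_that("qc_filter rejects exactly the injected oversaturated spectra", {
  co <- generate_cohort(small_config(np = 3))
  sat <- inject_saturation(co, 0.25, seed = 4)
  qc <- qc_filter(sat)
  expect_setequal(qc$rejected$spectrum_id,
                  sat$meta$spectrum_id[sat$meta$saturated])
  expect_true(all(qc$rejected$reason == "oversaturated"))
  # kept + rejected partition the input
  expect_equal(n_spectra(qc$kept) + nrow(qc$rejected), n_spectra(sat))
  expect_true("qc_passed" %in% qc$kept$state)
})

test_that("qc_filter keeps clean cohorts and flags non-finite values", {
  co <- generate_cohort(small_config(np = 3))
  qc <- qc_filter(co)
  expect_equal(nrow(qc$rejected), 0)

  co$intensity[3, 100] <- NaN
  qc2 <- qc_filter(co)
  expect_equal(qc2$rejected$spectrum_id, co$meta$spectrum_id[3])
  expect_equal(qc2$rejected$reason, "nonfinite")
  empty <- sers_cohort(co$wavenumber,
                       matrix(numeric(0), 0, length(co$wavenumber)),
                       co$meta[0, ])
  expect_error(qc_filter(empty), "empty")
})

test_that("baseline removal is exact on pure polynomial backgrounds", {
  x <- seq(200, 1800, by = 2)
  u <- (x - 1000) / 800
  for (k in 1:5) {
    set.seed(k)
    coef <- stats::runif(5, -0.5, 0.5)
    y <- 50 * (drop(cbind(1, u, u^2, u^3, u^4) %*% coef) + 3)  # positive
    s <- sers_spectrum(x, y)
    out <- remove_baseline(s)
    expect_lt(max(abs(out$corrected$intensity)), 1e-6 * max(y))
  }
})

test_that("baseline removal recovers a known injected peak", {
  x <- seq(200, 1800, by = 2)
  u <- (x - 1000) / 800
  baseline <- 500 + 200 * u - 150 * u^2 + 80 * u^3 + 60 * u^4
  lorentz <- 100 / (1 + (2 * (x - 900) / 12)^2)
  s <- sers_spectrum(x, baseline + lorentz)
  out <- remove_baseline(s)
  apex <- max(out$corrected$intensity[abs(x - 900) <= 12])
  expect_lt(abs(apex - 100), 2)           # within 2 % of the true amplitude
  expect_true(all(out$corrected$intensity >= 0))
  expect_true("baseline_corrected" %in% out$corrected$state)
  expect_error(remove_baseline(out$corrected), "already")
})

test_that("baseline removal needs more points than the polynomial degree", {
  s <- sers_spectrum(1:4, rep(1, 4))
  expect_error(remove_baseline(s), "too few points")
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
  x <- seq(200, 1800, by = 2)
  cfg <- preprocess_config(sg_window = 11, sg_polyorder = 3)
  # constant
  s <- smooth_spectrum(sers_spectrum(x, rep(5, length(x))), cfg)
  expect_equal(s$intensity, rep(5, length(x)), tolerance = 1e-10)
  # any polynomial of degree <= polyorder passes through exactly (edges too)
  for (k in 1:3) {
    set.seed(k)
    coef <- stats::runif(k + 1, -1, 1)
    y <- drop(outer((x - 1000) / 800, 0:k, `^`) %*% coef)
    out <- smooth_spectrum(sers_spectrum(x, y + 10), cfg)
    expect_equal(out$intensity, y + 10, tolerance = 1e-8)
    expect_length(out$intensity, length(x))
  }
  expect_error(preprocess_config(sg_window = 10), "odd")
  expect_error(preprocess_config(sg_window = 3, sg_polyorder = 3), "exceed")
})

test_that("Savitzky-Golay smoothing attenuates white noise", {
  # Monte-Carlo oracle: repeated white-noise spectra, SD must shrink
  set.seed(11)
  cfg <- preprocess_config(sg_window = 11, sg_polyorder = 3)
  sds <- replicate(200, {
    y <- stats::rnorm(801)
    c(stats::sd(sersdx:::sg_smooth_vec(y, cfg)), stats::sd(y))
  })
  expect_true(all(sds[1, ] < sds[2, ]))
  # theoretical variance reduction for interior points is substantial
  expect_lt(mean(sds[1, ]) / mean(sds[2, ]), 0.7)
})

test_that("normalization modes satisfy their defining identities", {
  x <- seq(200, 1800, by = 2)
  set.seed(3)
  y <- abs(stats::rnorm(length(x), 10, 2))
  s <- sers_spectrum(x, y)

  area <- normalize_spectrum(s, preprocess_config(normalization = "area"))
  expect_equal(pracma::trapz(x, area$intensity), 1, tolerance = 1e-9)

  vec <- normalize_spectrum(s, preprocess_config(normalization = "vector"))
  expect_equal(sqrt(sum(vec$intensity^2)), 1, tolerance = 1e-9)

  ramp <- sers_spectrum(x, seq(0, 100, length.out = length(x)))
  mm <- normalize_spectrum(ramp, preprocess_config(normalization = "minmax"))
  expect_equal(range(mm$intensity), c(0, 1), tolerance = 1e-12)
  expect_equal(mm$intensity, seq(0, 1, length.out = length(x)),
               tolerance = 1e-12)

  # scale invariance: normalize(k * s) == normalize(s)
  for (mode in c("area", "vector", "minmax")) {
    cfg <- preprocess_config(normalization = mode)
    for (k in c(0.1, 7, 1e4)) {
      ks <- sers_spectrum(x, k * y)
      expect_equal(normalize_spectrum(ks, cfg)$intensity,
                   normalize_spectrum(s, cfg)$intensity,
                   tolerance = 1e-9, info = paste(mode, k))
    }
  }
  # sign pattern preserved in area/vector modes
  s2 <- sers_spectrum(x, y)
  s2$intensity[5] <- 0
  out <- normalize_spectrum(s2, preprocess_config(normalization = "area"))
  expect_identical(sign(out$intensity), sign(s2$intensity))

  zero <- sers_spectrum(x, rep(0, length(x)))
  expect_error(normalize_spectrum(zero), "degenerate")
})

test_that("the preprocessing chain records states and refuses reruns", {
  co <- generate_cohort(small_config(np = 2))
  pp <- preprocess_cohort(co)
  expect_equal(pp$state, c("raw", "qc_passed", "baseline_corrected",
                           "smoothed", "normalized"))
  expect_error(preprocess_cohort(pp), "already preprocessed")
  # deterministic: rerun from the same raw input is bit-identical
  pp2 <- preprocess_cohort(generate_cohort(small_config(np = 2)))
  expect_identical(pp$intensity, pp2$intensity)
  expect_equal(nrow(attr(pp, "rejected")), 0)
})
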