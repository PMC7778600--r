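# template with a clean 1650 peak and a silent 1780-1820 region
qm_template <- function() {
  x <- seq(1500, 1850, by = 1)
  y <- 5 + 100 * exp(-(x - 1650)^2 / (2 * 12^2))
  raman_spectrum(x, y)
}

test_that("snr converges to peak height over noise SD and is scale invariant", {
  tmpl <- qm_template()
  sigma <- 2
  coll <- noisy_replicates(tmpl, 50, sigma, seed = 11)
  got <- snr(coll, band_def())
  expect_lt(abs(got / ((100 + 5) / sigma) - 1), 0.15)

  scaled <- collection_scale(coll, 2)
  expect_equal(snr(scaled, band_def()), got, tolerance = 1e-12)

  same <- spectrum_collection(list(tmpl, tmpl))
  expect_error(snr(same), "zero noise")
})

test_that("spectral CV matches constructions and brute force", {
  tmpl <- qm_template()
  same <- spectrum_collection(list(tmpl, tmpl, tmpl))
  expect_equal(spectral_cv(same), 0)

  scaled <- spectrum_collection(lapply(c(0.9, 1.0, 1.1), function(k)
    raman_spectrum(tmpl$axis, k * tmpl$intensity)))
  expect_equal(spectral_cv(scaled), stats::sd(c(0.9, 1, 1.1)) / 1.0,
               tolerance = 1e-12)

  coll <- noisy_replicates(tmpl, 6, 3, seed = 12)
  m <- as.matrix(coll)
  mu <- colMeans(m); sds <- apply(m, 2, stats::sd)
  keep <- abs(mu) > 1e-12 * max(abs(mu))
  expect_equal(spectral_cv(coll), mean(sds[keep] / abs(mu[keep])))
})

test_that("difference spectra are antisymmetric and locate class effects", {
  a <- noisy_replicates(qm_template(), 4, 1, seed = 13)
  b <- noisy_replicates(qm_template(), 4, 1, seed = 14)
  d_ab <- difference_spectrum(a, b)
  d_ba <- difference_spectrum(b, a)
  expect_equal(d_ab$intensity, -d_ba$intensity)
  expect_equal(d_ab$meta$n_a, 4)

  expect_lt(max(abs(difference_spectrum(a, a)$intensity)), 1e-12)

  shifted <- collection_scale(a, 1)
  shifted$spectra <- lapply(shifted$spectra, function(s)
    raman_spectrum(s$axis, s$intensity + 2.5))
  d_c <- difference_spectrum(spectrum_collection(shifted$spectra), a)
  expect_lt(max(abs(d_c$intensity - 2.5)), 1e-12)

  # generator ground truth: tumour-control differences sit on the
  # class-effect peaks
  cfg <- raman_gen_config(noise_sd = 0, spike_rate = 0,
                          subject_jitter_sd = 0)
  tum <- generate_spectrum("tumour", cfg, seed = 1)
  ctl <- generate_spectrum("control", cfg, seed = 1)
  d <- raman_spectrum(cfg$axis, tum$intensity - ctl$intensity)
  big <- abs(d$intensity) > 0.5 * max(abs(d$intensity))
  expect_true(all(vapply(cfg$axis[big], function(w)
    min(abs(w - c(1265, 1302, 1445, 1655))) < 30, logical(1))))
})

test_that("windowed peak intensity matches a direct scan", {
  x <- seq(1300, 1600, by = 1)
  tri <- pmax(0, 3.7 - abs(x - 1440) / 10)
  s <- raman_spectrum(x, tri)
  expect_equal(peak_intensity(s, 1440, 10), 3.7)
  # window that excludes the apex picks the boundary maximum
  keep <- abs(x - 1470) <= 10
  expect_equal(peak_intensity(s, 1470, 10), max(tri[keep]))
  flat <- raman_spectrum(x, rep(2.2, length(x)))
  expect_equal(peak_intensity(flat, 1440, 10), 2.2)
  expect_error(peak_intensity(s, 5000, 10), "overlaps no channels")
})

test_that("monitoring timecourse normalises to day 0", {
  x <- seq(1350, 1550, by = 1)
  d0 <- raman_spectrum(x, -5 * exp(-(x - 1445)^2 / (2 * 10^2)))
  d3 <- raman_spectrum(x, 0.5 * d0$intensity)
  tc <- monitoring_timecourse(list("0" = d0, "3" = d3, "6" = d0))
  expect_equal(unname(tc), c(1, 0.5, 1))
  tc_abs <- monitoring_timecourse(list("0" = d0, "3" = d3), absolute = TRUE)
  expect_equal(unname(tc_abs[["3"]]), 0.5)
  expect_error(monitoring_timecourse(list("3" = d3)), "day 0")
  zero <- raman_spectrum(x, rep(0, length(x)))
  expect_error(monitoring_timecourse(list("0" = zero, "3" = d3)), "zero")
})

test_that("IQR outlier rule matches the interpolated-quartile definition", {
  expect_equal(iqr_outliers(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(iqr_outliers(rep(3, 6))))
  expect_error(iqr_outliers(1:3), "at least 4")

  v <- praman:::with_seed(15, rnorm(1e4))
  frac <- mean(iqr_outliers(v))
  expect_gt(frac, 0.003); expect_lt(frac, 0.02)
  # brute-force bound check
  q <- stats::quantile(v, c(.25, .75), type = 7, names = FALSE)
  lo <- q[1] - 1.5 * (q[2] - q[1]); hi <- q[2] + 1.5 * (q[2] - q[1])
  expect_identical(iqr_outliers(v), v < lo | v > hi)
})

test_that("welch test matches the reference implementation", {
  a <- c(1, 2, 3); b <- c(1, 2, 3)
  got <- welch_t(a, b)
  expect_equal(got$t, 0); expect_equal(got$p, 1)

  b2 <- c(101, 102.01, 102.99)
  got2 <- welch_t(a, b2)
  expect_lt(got2$p, 1e-4)

  x <- praman:::with_seed(16, rnorm(12, 1)); y <- praman:::with_seed(17, rnorm(9))
  got3 <- welch_t(x, y)
  ref <- stats::t.test(x, y, var.equal = FALSE)
  expect_equal(got3$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got3$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(got3$p, ref$p.value, tolerance = 1e-12)

  expect_equal(welch_t(c(5, 5, 5), c(5, 5))$p, 1)
  expect_error(welch_t(c(5, 5, 5), c(6, 6)), "unequal means")
  expect_error(welch_t(1, c(1, 2)), ">= 2 values")
})

test_that("normalised growth divides by the baseline day", {
  g <- normalized_growth(c("0" = 2, "3" = 4, "6" = 1), 0)
  expect_equal(unname(g), c(1, 2, 0.5))
  expect_equal(unname(normalized_growth(c("0" = 7, "3" = 7))), c(1, 1))
  # the excluded-responder construction: day-3 flux at 22.2% of baseline
  t0 <- 3.1e7
  g2 <- normalized_growth(c("0" = t0, "3" = 0.222 * t0), 0)
  expect_equal(100 * unname(g2[["3"]]), 22.2, tolerance = 1e-9)
  expect_error(normalized_growth(c("0" = 0, "3" = 1)), "positive")
  expect_error(normalized_growth(c("3" = 1)), "not present")
})
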