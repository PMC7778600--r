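test_that("crop keeps the closed interval and copies metadata", {
  s <- raman_spectrum(400:2000, rnorm(1601), meta = list(subject_id = "m1"))
  out <- crop_spectrum(s, 510, 1825)
  expect_equal(length(out$axis), 1316)
  expect_equal(out$axis[1], 510)
  expect_equal(out$axis[length(out$axis)], 1825)
  expect_equal(out$meta$subject_id, "m1")

  low <- crop_spectrum(s, 100, 1825)
  expect_equal(low$axis[1], 400)
  expect_error(crop_spectrum(s, 2000.5, 2100), "excludes all channels")
})

test_that("whittaker baseline reproduces flat and affine signals exactly", {
  x <- seq(500, 899, by = 1)
  flat <- raman_spectrum(x, rep(3.7, 400))
  out <- whittaker_baseline(flat, lam = 1e5)
  expect_lt(max(abs(out$baseline$intensity - 3.7)), 1e-8)
  expect_lt(max(abs(out$corrected$intensity)), 1e-8)

  ramp <- raman_spectrum(x, 2 + 0.05 * seq_along(x))
  out <- whittaker_baseline(ramp, lam = 1e5)
  expect_lt(max(abs(out$corrected$intensity)), 1e-8)
})

test_that("sparse whittaker solve matches the dense oracle", {
  for (seed in 1:3) {
    s <- praman:::with_seed(seed,
      raman_spectrum(seq_len(200) + 400, cumsum(rnorm(200)) + 50))
    got <- whittaker_baseline(s, lam = 1e5, asym_p = 0.001, iters = 10)
    want <- dense_asls_oracle(s$intensity, 1e5, 0.001, 10)
    rel <- max(abs(got$baseline$intensity - want)) /
      max(abs(want))
    expect_lt(rel, 1e-8)
  }
})

test_that("whittaker limits: straight line as lam grows, identity as lam vanishes", {
  s <- praman:::with_seed(7,
    raman_spectrum(seq(500, by = 2, length.out = 150), cumsum(rnorm(150))))
  y <- s$intensity
  z_inf <- whittaker_baseline(s, lam = 1e12, iters = 1)$baseline$intensity
  i <- seq_along(y)
  line <- stats::fitted(stats::lm(y ~ i))
  expect_lt(max(abs(z_inf - line)), 1e-4 * diff(range(y)))

  z_zero <- whittaker_baseline(s, lam = 1e-8, iters = 1)$baseline$intensity
  expect_lt(max(abs(z_zero - y)), 1e-6)
})

test_that("despike touches only spike channels and matches the scan oracle", {
  s <- smooth_spectrum()
  y <- s$intensity
  y[100] <- y[100] + 50 * stats::sd(diff(s$intensity))
  spiked <- raman_spectrum(s$axis, y)
  out <- despike(spiked, spike_z = 8)
  expect_equal(out$intensity[-100], y[-100])
  expect_lt(abs(out$intensity[100] - s$intensity[100]), 2)

  # spike-free input is untouched
  expect_identical(despike(s, 8)$intensity, s$intensity)

  # two adjacent spikes of different height: flags equal the brute scan
  y2 <- s$intensity
  y2[80] <- y2[80] + 300
  y2[81] <- y2[81] + 150
  flags <- praman:::despike_flags(y2, 8)
  expect_identical(flags, despike_flag_oracle(y2, 8))
  expect_true(all(flags[c(80, 81)]))
  out2 <- despike(raman_spectrum(s$axis, y2), 8)
  expect_equal(out2$intensity[!flags], y2[!flags])
})

test_that("savgol reproduces affine signals and matches per-window OLS", {
  x <- seq(400, by = 1, length.out = 120)
  aff <- raman_spectrum(x, 5 + 0.3 * seq_along(x))
  expect_lt(max(abs(savgol(aff, 1, 7)$intensity - aff$intensity)), 1e-10)

  cst <- raman_spectrum(x, rep(2.5, 120))
  expect_lt(max(abs(savgol(cst, 1, 7)$intensity - 2.5)), 1e-12)

  s <- praman:::with_seed(3, raman_spectrum(x, rnorm(120, 50, 10)))
  got <- savgol(s, 1, 7)$intensity
  # oracle: explicit least squares in every (possibly truncated) window
  want <- vapply(seq_along(x), function(i) {
    idx <- max(1, i - 3):min(length(x), i + 3)
    fit <- stats::lm(y ~ d, data.frame(y = s$intensity[idx], d = idx - i))
    unname(stats::coef(fit)[1])
  }, numeric(1))
  expect_lt(max(abs(got - want)), 1e-9)

  expect_error(savgol(s, 1, 6), "odd")
  expect_error(savgol(s, 7, 7), "exceed")
})

test_that("area normalisation is exact, idempotent and scale invariant", {
  s <- smooth_spectrum()
  n1 <- normalize_auc(s)
  expect_equal(pracma::trapz(n1$axis, n1$intensity), 1, tolerance = 1e-12)
  n2 <- normalize_auc(n1)
  expect_lt(max(abs(n2$intensity - n1$intensity)), 1e-12)
  n7 <- normalize_auc(raman_spectrum(s$axis, 7 * s$intensity))
  expect_lt(max(abs(n7$intensity - n1$intensity)), 1e-12)
  zero <- raman_spectrum(s$axis, rep(0, length(s$axis)))
  expect_error(normalize_auc(zero), "zero or negative")
})

test_that("mean centering zeroes column sums and is invertible", {
  coll <- noisy_replicates(smooth_spectrum(), 5, 10, seed = 2)
  mc <- mean_center(coll)
  m <- as.matrix(mc$centered)
  expect_lt(max(abs(colSums(m))), 1e-10)
  rec <- sweep(m, 2, mc$mean$intensity, `+`)
  expect_lt(max(abs(rec - as.matrix(coll))), 1e-12)

  same <- spectrum_collection(list(smooth_spectrum(), smooth_spectrum()))
  expect_lt(max(abs(as.matrix(mean_center(same)$centered))), 1e-12)
})

test_that("full preprocessing chain recovers template peak structure", {
  cfg <- raman_gen_config()
  ds <- generate_classification_dataset(cfg, n_per_class = 10, seed = 21)
  proc <- preprocess_spectra(ds$collection)
  expect_equal(n_spectra(proc), 20)
  expect_equal(proc$labels, ds$labels)

  # template processed without noise: peak ratio must survive the chain
  template <- raman_spectrum(cfg$axis, ds$truth$control$template)
  ptmpl <- preprocess_spectra(spectrum_collection(list(template)))$spectra[[1]]
  ctl <- spectrum_collection(
    proc$spectra[proc$labels == "control"])
  mctl <- mean_spectrum(ctl)
  r_proc <- peak_intensity(mctl, 1445, 10) / peak_intensity(mctl, 1655, 10)
  r_tmpl <- peak_intensity(ptmpl, 1445, 10) / peak_intensity(ptmpl, 1655, 10)
  expect_lt(abs(r_proc / r_tmpl - 1), 0.10)

  # baseline residual: away from peaks the processed template is small
  quiet <- ptmpl$axis >= 1750 & ptmpl$axis <= 1825
  expect_lt(max(abs(ptmpl$intensity[quiet])),
            0.05 * max(ptmpl$intensity))
})

test_that("preprocessing honours config and degenerate inputs", {
  coll <- noisy_replicates(smooth_spectrum(400, 510, 3), 2, 5, seed = 4)
  raw_cfg <- preprocess_config(normalize = "none", crop_lo = 510,
                               crop_hi = 1500)
  out <- preprocess_spectra(coll, raw_cfg)
  areas <- vapply(out$spectra, function(s)
    pracma::trapz(s$axis, s$intensity), numeric(1))
  expect_false(any(abs(areas - 1) < 1e-6))

  empty <- spectrum_collection(list())
  expect_equal(n_spectra(preprocess_spectra(empty)), 0)

  expect_error(preprocess_spectra(coll, preprocess_config(crop_lo = 2000,
                                                          crop_hi = 2100)),
               "\\[crop\\]")
})

test_that("preprocess_config validates its fields", {
  expect_error(preprocess_config(crop_lo = 1000, crop_hi = 900), "crop_lo")
  expect_error(preprocess_config(lam = -1), "lam")
  expect_error(preprocess_config(asym_p = 1.5), "asym_p")
  expect_error(preprocess_config(sg_frame = 6), "odd")
})
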