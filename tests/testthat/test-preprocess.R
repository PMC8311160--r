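wn <- default_grid()

test_that("parameter validation catches ill-formed settings", {
  expect_error(preprocess_params(sg_window = 14), "odd")
  expect_error(preprocess_params(sg_window = 5, sg_order = 5), "smaller than")
  expect_error(preprocess_params(baseline_order = 0), "1..11")
  expect_error(preprocess_params(baseline_order = 12), "1..11")
  expect_error(preprocess_params(tol_rel = 0), "> 0")
})

test_that("a pure polynomial is its own baseline: corrected ~ 0", {
  t <- (wn - 1100) / 700
  y <- 40 + 12 * t - 7 * t^2 + 3 * t^3
  out <- baseline_correct(raman_spectrum(wn, y))
  expect_lt(max(abs(out$corrected$intensities)), 1e-8 * diff(range(y)))
  expect_true(out$converged)
})

test_that("the all-zero spectrum gives zero baseline and zero correction", {
  out <- baseline_correct(raman_spectrum(wn, rep(0, length(wn))))
  expect_equal(max(abs(out$baseline$intensities)), 0)
  expect_equal(max(abs(out$corrected$intensities)), 0)
})

test_that("a Lorentzian on a curved background is recovered within 2%", {
  y <- (100 + 0.05 * wn + 1e-4 * (wn - 1100)^2) + 500 / (1 + ((wn - 1157) / 8)^2)
  out <- baseline_correct(raman_spectrum(wn, y), preprocess_params(max_iter = 500))
  amp <- max(out$corrected$intensities[wn >= 1147 & wn <= 1167])
  expect_lt(abs(amp - 500) / 500, 0.02)
})

test_that("baseline errors and flags: too few points, iteration cap", {
  expect_error(baseline_correct(raman_spectrum(wn[1:5], rnorm(5))), "order\\+2")
  s <- synth_spectrum(profile_with("B73"), seed = 1)
  out <- baseline_correct(s, preprocess_params(max_iter = 1))
  expect_false(out$converged)  # flagged, not an error
  expect_equal(out$iterations, 1L)
})

test_that("baseline iteration is monotone: working trace exactly, fit within float creep", {
  for (seed in 1:3) {
    s <- synth_spectrum(profile_with("B73"), seed = seed)
    tolc <- 1e-5 * diff(range(s$intensities))
    Q <- ramandrought:::poly_basis(wn, 7)
    W <- matrix(s$intensities, ncol = 1)
    fit_old <- NULL
    for (i in 1:60) {
      fit <- Q %*% crossprod(Q, W)
      if (!is.null(fit_old)) expect_lt(max(fit - fit_old), tolc)
      W2 <- pmin(W, fit)
      expect_true(all(W2 <= W))
      W <- W2; fit_old <- fit
    }
  }
})

test_that("Savitzky-Golay reproduces polynomials up to its order at interior points", {
  y <- 1e-6 * (wn - 1000)^3 - 2e-4 * (wn - 900)^2 + 0.3 * wn + 5
  sm <- savgol_smooth(raman_spectrum(wn, y))
  interior <- 8:(length(wn) - 7)
  expect_lt(max(abs(sm$intensities[interior] - y[interior])), 1e-9 * max(abs(y)))
  const <- savgol_smooth(raman_spectrum(wn, rep(4.2, length(wn))))
  expect_equal(const$intensities, rep(4.2, length(wn)), tolerance = 1e-12)
})

test_that("Savitzky-Golay matches a brute-force sliding polynomial fit and reduces noise", {
  set.seed(99)
  n <- 200
  x <- seq_len(n)
  y <- rnorm(n)
  sm <- savgol_smooth(raman_spectrum(x, y))$intensities
  # oracle: independent least-squares cubic fit in each 15-point window
  for (t in seq(8, n - 7, by = 7)) {
    win <- (t - 7):(t + 7)
    fit <- lm.fit(outer(win - t, 0:3, `^`), y[win])
    expect_lt(abs(sm[t] - fit$coefficients[1]), 1e-9)
  }
  expect_lt(var(sm[8:(n - 7)]), var(y[8:(n - 7)]))
})

test_that("Savitzky-Golay refuses non-uniform grids with a resampling hint", {
  s <- raman_spectrum(c(1, 2, 4, 8, 16, 32, 64, 100, 150, 220, 300, 400, 520, 660, 820, 1000),
                      rnorm(16))
  expect_error(savgol_smooth(s), "resample")
})

test_that("unit-vector normalization has norm 1, scale invariance and the 3-4-5 case", {
  s <- synth_spectrum(profile_with("OH28"), seed = 2)
  nrm <- unit_vector_normalize(s)
  expect_equal(sqrt(sum(nrm$intensities^2)), 1, tolerance = 1e-12)
  scaled <- raman_spectrum(s$wavenumbers, 7.3 * s$intensities, s$meta)
  expect_equal(unit_vector_normalize(scaled)$intensities, nrm$intensities,
               tolerance = 1e-12)
  two <- unit_vector_normalize(raman_spectrum(c(1000, 1001), c(3, 4)))
  expect_equal(two$intensities, c(0.6, 0.8))
  expect_error(unit_vector_normalize(raman_spectrum(1:3, rep(0, 3))), "zero-norm")
})

test_that("the full chain is invariant to positive intensity scaling", {
  s <- synth_spectrum(profile_with("CML176"), seed = 5)
  a <- preprocess_spectrum(s)
  b <- preprocess_spectrum(raman_spectrum(s$wavenumbers, 37.5 * s$intensities, s$meta))
  expect_lt(max(abs(a$intensities - b$intensities)), 1e-9)
})

test_that("preprocessed 1157 amplitude is near-proportional to true carotenoid amplitude", {
  pr <- profile_with("B73")
  pp <- preprocess_params()
  a <- seq(0.1, 1, length.out = 12) * pr$amp0
  obs <- vapply(a, function(x) ramandrought:::observable_1157(pr, x, wn, pp), 0)
  expect_true(all(diff(obs) > 0))        # monotone in the true amplitude
  expect_gte(cor(a, obs), 0.999)         # proportional across a 10x range
})

test_that("preprocess_spectrum records provenance and equals the staged chain", {
  s <- synth_spectrum(profile_with("lox2"), seed = 11)
  p <- preprocess_spectrum(s)
  expect_true(p$meta$preprocess$normalized)
  expect_equal(p$meta$preprocess$sg_window, 15L)
  staged <- unit_vector_normalize(savgol_smooth(baseline_correct(s)$corrected))
  expect_equal(p$intensities, staged$intensities, tolerance = 1e-12)
})
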