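test_that("a noiseless Lorentzian is recovered with its analytic volume", {
  sp <- single_peak_spectrum(A = 100, cH = 8.2, cN = 109.5, wH = 0.02, wN = 0.15)
  seed <- pick_peaks(sp, 5, noise_sigma = 1)[1, ]
  fit <- fit_peak(sp, seed)
  expect_true(fit$converged)
  expect_equal(fit$amplitude, 100, tolerance = 1e-3)
  expect_equal(fit$center_H, 8.2, tolerance = 1e-5)
  expect_equal(fit$center_N, 109.5, tolerance = 1e-4)
  expect_equal(fit$fwhm_H, 0.02, tolerance = 1e-3)
  expect_equal(fit$fwhm_N, 0.15, tolerance = 1e-3)
  expect_equal(fit$volume, (pi / 2)^2 * 100 * 0.02 * 0.15, tolerance = 0.01)
})

test_that("centre error stays below a tenth of the linewidth at snr 50", {
  errs <- t(vapply(1:100, function(i) {
    sp <- single_peak_spectrum(A = 100)
    set.seed(1000 + i)
    noisy <- spectrum2d(sp$intensities + rnorm(length(sp$intensities), 0, 2),
                        sp$axis_H, sp$axis_N)
    fit <- fit_peak(noisy, list(center_H = 8.2, center_N = 109.5, height = 100))
    c(abs(fit$center_H - 8.2), abs(fit$center_N - 109.5))
  }, numeric(2)))
  expect_lt(stats::quantile(errs[, 1], 0.95), 0.02 / 10)
  expect_lt(stats::quantile(errs[, 2], 0.95), 0.15 / 10)
})

test_that("a seed displaced by one grid point converges to the same centre", {
  sp <- single_peak_spectrum(A = 100)
  i0 <- which.min(abs(sp$axis_H - 8.2))
  j0 <- which.min(abs(sp$axis_N - 109.5))
  exact <- fit_peak(sp, list(center_H = sp$axis_H[i0], center_N = sp$axis_N[j0],
                             height = 100))
  displaced <- fit_peak(sp, list(center_H = sp$axis_H[i0 + 1],
                                 center_N = sp$axis_N[j0 + 1], height = 90))
  expect_equal(displaced$center_H, exact$center_H, tolerance = 1e-6)
  expect_equal(displaced$center_N, exact$center_N, tolerance = 1e-6)
  expect_equal(displaced$volume, exact$volume, tolerance = 1e-4)
})

test_that("a too-small window is rejected", {
  sp <- single_peak_spectrum()
  expect_error(fit_peak(sp, list(center_H = 8.2, center_N = 109.5, height = 100),
                        window = c(0.001, 0.01)), "window")
})

test_that("fits are scale-equivariant and axis-direction invariant", {
  sp <- single_peak_spectrum(A = 80)
  seed <- list(center_H = 8.2, center_N = 109.5, height = 80)
  base <- fit_peak(sp, seed)
  scaled <- spectrum2d(3 * sp$intensities, sp$axis_H, sp$axis_N)
  fs <- fit_peak(scaled, seed)
  expect_equal(fs$amplitude, 3 * base$amplitude, tolerance = 1e-6)
  expect_equal(fs$volume, 3 * base$volume, tolerance = 1e-6)
  expect_equal(fs$center_H, base$center_H, tolerance = 1e-8)
  expect_equal(fs$fwhm_H, base$fwhm_H, tolerance = 1e-6)
  # reversed storage order must not change ppm-scale results
  flipped <- spectrum2d(sp$intensities[rev(seq_along(sp$axis_H)),
                                       rev(seq_along(sp$axis_N))],
                        rev(sp$axis_H), rev(sp$axis_N))
  ff <- fit_peak(flipped, seed)
  expect_equal(ff$center_H, base$center_H, tolerance = 1e-8)
  expect_equal(ff$volume, base$volume, tolerance = 1e-8)
})

test_that("elliptical integration matches the in-ellipse analytic fraction", {
  sp <- single_peak_spectrum(A = 100, cH = 8.2, cN = 109.5, wH = 0.02, wN = 0.15)
  fit <- fit_peak(sp, list(center_H = 8.2, center_N = 109.5, height = 100))
  analytic <- (pi / 2)^2 * 100 * 0.02 * 0.15
  ell <- integrate_elliptical(sp, fit, radii_multiplier = 3)
  # oracle: numeric integral of the unit 2D Lorentzian over the ellipse
  # with semi-axes 3 fwhm (half-width units: disk of radius 6)
  n <- 2001; r <- 6
  u <- seq(-r, r, length.out = n); du <- diff(u[1:2])
  U <- matrix(u, n, n); V <- t(U)
  inside <- (U / r)^2 + (V / r)^2 <= 1
  frac <- sum((1 / ((1 + U^2) * (1 + V^2)) / pi^2)[inside]) * du^2
  expect_equal(ell$volume / analytic, frac, tolerance = 0.02)
  expect_lt(ell$volume, analytic)  # heavy tails: always an undercount
  expect_false(ell$clipped)
})

test_that("elliptical integration of a zero spectrum is zero and clipping flags", {
  sp <- spectrum2d(matrix(0, 100, 60), seq(8, 8.4, length.out = 100),
                   seq(108, 111, length.out = 60))
  peak <- data.frame(center_H = 8.2, center_N = 109.5, fwhm_H = 0.02, fwhm_N = 0.15)
  expect_equal(integrate_elliptical(sp, peak)$volume, 0)
  edge <- data.frame(center_H = 8.01, center_N = 108.1, fwhm_H = 0.02, fwhm_N = 0.15)
  expect_true(integrate_elliptical(sp, edge)$clipped)
})

test_that("model and elliptical volumes keep a stable ratio across equal shapes", {
  ratios <- vapply(c(30, 60, 120, 240), function(A) {
    sp <- single_peak_spectrum(A = A)
    fit <- fit_peak(sp, list(center_H = 8.2, center_N = 109.5, height = A))
    integrate_elliptical(sp, fit, 3)$volume / fit$volume
  }, numeric(1))
  expect_lt(sd(ratios) / mean(ratios), 0.02)
})
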