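make_dr <- function(bottom, top, ec50, x = default_dose_series()) {
  data.frame(concentration_M = x,
             response = bottom + (top - bottom) / (1 + ec50 / x))
}

test_that("noiseless dose-response parameters are recovered to 4 digits", {
  tab <- make_dr(0.2, 0.8, 1e-6)
  fit <- fit_dose_response(tab)
  expect_true(fit$converged)
  expect_equal(fit$bottom, 0.2, tolerance = 1e-4)
  expect_equal(fit$top, 0.8, tolerance = 1e-4)
  expect_equal(fit$EC50, 1e-6, tolerance = 1e-4)
  # model identity: response at EC50 is the midpoint
  expect_equal(efficacy_at(fit, fit$EC50), (fit$bottom + fit$top) / 2)
  expect_equal(efficacy_at(fit, Inf), fit$top)
  expect_equal(fit$bottom + (fit$top - fit$bottom) / (1 + fit$EC50 / 1e-30),
               efficacy_at(fit, 1e-30))
})

test_that("the fit matches a dense grid-search oracle", {
  tab <- make_dr(0.25, 0.75, 3e-7)
  fit <- fit_dose_response(tab)
  # oracle: exhaustive search over (bottom, top, logEC50)
  bs <- seq(0.1, 0.4, length.out = 61)
  ts <- seq(0.6, 0.9, length.out = 61)
  ls <- seq(-8, -5, length.out = 121)
  best <- c(Inf, NA, NA, NA)
  x <- tab$concentration_M; y <- tab$response
  frac <- 1 / (1 + outer(10^ls, 1 / x))        # length(ls) x n occupancy
  ymat <- matrix(y, length(ls), length(x), byrow = TRUE)
  for (b in bs) for (tt in ts) {
    rss <- rowSums((ymat - (b + (tt - b) * frac))^2)
    k <- which.min(rss)
    if (rss[k] < best[1]) best <- c(rss[k], b, tt, ls[k])
  }
  expect_lt(abs(fit$bottom - best[2]), diff(bs[1:2]))
  expect_lt(abs(fit$top - best[3]), diff(ts[1:2]))
  expect_lt(abs(fit$logEC50 - best[4]), diff(ls[1:2]))
})

test_that("flat data return a non-converged fit with bottom = top = mean", {
  tab <- data.frame(concentration_M = default_dose_series(), response = 0.42)
  fit <- fit_dose_response(tab)
  expect_false(fit$converged)
  expect_equal(fit$bottom, 0.42)
  expect_equal(fit$top, 0.42)
  expect_error(fit_dose_response(make_dr(0, 1, 1e-6, x = c(1e-6, 1e-5, 1e-4))),
               "4 distinct")
})

test_that("unit rescaling shifts logEC50 and nothing else", {
  tab <- make_dr(0.2, 0.8, 1e-6)
  fit_M <- fit_dose_response(tab)
  tab_uM <- data.frame(concentration_M = tab$concentration_M * 1e6,
                       response = tab$response)
  fit_uM <- fit_dose_response(tab_uM)
  expect_equal(fit_uM$logEC50, fit_M$logEC50 + 6, tolerance = 1e-6)
  expect_equal(fit_uM$bottom, fit_M$bottom, tolerance = 1e-6)
  expect_equal(fit_uM$top, fit_M$top, tolerance = 1e-6)
  # response offset shifts bottom/top only
  tab_off <- data.frame(concentration_M = tab$concentration_M,
                        response = tab$response + 5)
  fit_off <- fit_dose_response(tab_off)
  expect_equal(fit_off$bottom, fit_M$bottom + 5, tolerance = 1e-5)
  expect_equal(fit_off$top, fit_M$top + 5, tolerance = 1e-5)
  expect_equal(fit_off$logEC50, fit_M$logEC50, tolerance = 1e-5)
})

test_that("EC50 is recovered within 10 percent in >= 95 percent of noisy curves", {
  # curves follow the assay design: 12 concentrations in triplicate, 2% CV
  lig <- data.frame(ligand_id = "Lx", f_rep = 0.5, potency_log10_M = -6)
  hits <- vapply(1:200, function(i) {
    tab <- simulate_trfret_curve(lig, "NCoR1", noise_cv = 0.02, seed = i)
    fit <- fit_dose_response(tab)
    fit$converged && abs(fit$EC50 - 1e-6) / 1e-6 < 0.10
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("fixed-Bmax saturation fits recover Kd exactly on noiseless data", {
  x <- default_protein_series()
  tab <- data.frame(protein_M = x, response = 120 * x / (2e-6 + x) + 30)
  fit <- fit_saturation(tab, Bmax_fixed = 120)
  expect_equal(fit$Kd, 2e-6, tolerance = 1e-4)
  expect_equal(fit$background, 30, tolerance = 1e-4)
  # half-saturation identity on the fitted model
  yk <- 120 * fit$Kd / (fit$Kd + fit$Kd) + fit$background
  expect_equal(yk - fit$background, 120 / 2)
  expect_error(fit_saturation(tab, Bmax_fixed = -1), "Bmax")
})

test_that("non-saturating Kd is still recovered within 20 percent under noise", {
  x <- default_protein_series()
  kd <- 10 * max(x)
  ok <- vapply(1:100, function(i) {
    set.seed(3000 + i)
    tab <- data.frame(protein_M = x,
                      response = 120 * x / (kd + x) + rnorm(length(x), 0, 1.2))
    fit <- fit_saturation(tab, Bmax_fixed = 120)
    fit$converged && abs(fit$Kd - kd) / kd < 0.20
  }, logical(1))
  expect_gte(mean(ok), 0.90)
})

test_that("shared Bmax is estimated from the saturating curves only", {
  x <- default_protein_series()
  mk <- function(kd) data.frame(protein_M = x, response = 150 * x / (kd + x) + 10)
  tabs <- list(mk(1e-6), mk(3e-6), mk(500e-6))  # last one non-saturating
  est <- estimate_shared_bmax(tabs)
  expect_equal(est$qualifying, c(TRUE, TRUE, FALSE))
  expect_equal(est$Bmax, 150, tolerance = 0.02)
  # joint fit with one saturating + one non-saturating qualifier set
  est2 <- estimate_shared_bmax(tabs[c(1, 3)])
  expect_equal(est2$Bmax, 150, tolerance = 0.02)
  expect_error(estimate_shared_bmax(list(mk(900e-6))), "Bmax")
})

test_that("bias factors difference NCoR1 minus MED1 on the declared scale", {
  expect_equal(bias_factor(0.5, 0.2)$bias, 0.3)
  expect_equal(bias_factor(0.4, 0.4)$bias, 0)
  expect_equal(bias_factor(1e-6, 1e-5, scale = "log_affinity")$bias, 1)
  # antisymmetry
  expect_equal(bias_factor(0.7, 0.3)$bias, -bias_factor(0.3, 0.7)$bias)
  expect_error(bias_factor(NA, 1), "finite")
})

test_that("ddCt identities hold for the calibrator and simple shifts", {
  ct <- data.frame(condition = rep(c("DMSO", "T1"), each = 2),
                   gene = rep(c("aP2", "TBP"), 2),
                   replicate = 1,
                   ct = c(24, 18, 25, 18))  # ddCt = +1 for T1
  re <- relative_expression(ct, "aP2", "TBP", "DMSO")
  expect_equal(re$rq[re$condition == "DMSO"], 1)
  expect_equal(re$rq[re$condition == "T1"], 0.5)
  ct2 <- ct; ct2$ct[3] <- 22  # ddCt = -2
  expect_equal(relative_expression(ct2, "aP2", "TBP", "DMSO")$rq[2], 4)
  ct3 <- ct[ct$gene != "TBP" | ct$condition != "T1", ]
  expect_error(relative_expression(ct3, "aP2", "TBP", "DMSO"), "T1")
})
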