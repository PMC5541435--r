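test_that("noiseless data are fit back to machine precision", {
  truth <- hill_curve(emax = 1, d50 = 2, slope = 3)
  dat <- simulate_curve_data(truth, n_doses = 8, sigma = 0)
  fit <- fit_hill(dat)
  expect_lt(abs(fit$curve$emax - 1), 1e-6)
  expect_lt(abs(fit$curve$d50 - 2) / 2, 1e-6)
  expect_lt(abs(fit$curve$slope - 3) / 3, 1e-6)
  expect_lt(fit$rmse_fit, 1e-10)
  expect_true(fit$converged)
})

test_that("fit_hill validates its inputs", {
  dat <- simulate_curve_data(hill_curve(1, 1, 1), n_doses = 8, sigma = 0)
  expect_error(fit_hill(dat[1:3, ]), class = "hillsurf_domain_error")
  expect_error(fit_hill(dplyr::rename(dat, conc = dose)),
               class = "hillsurf_domain_error")
  expect_error(fit_hill(dat, fixed = list(ec50 = 1)),
               class = "hillsurf_domain_error")
  bad <- dat; bad$effect[2] <- 1.4
  expect_error(fit_hill(bad), class = "hillsurf_domain_error")
})

test_that("fixing the slope reproduces the unit-slope workflow and costs fit error", {
  truth <- hill_curve(emax = 1, d50 = 5, slope = 2)
  dat <- simulate_curve_data(truth, n_doses = 12, sigma = 0.01, seed = 4)
  free <- fit_hill(dat)
  constrained <- fit_hill(dat, fixed = list(slope = 1))
  expect_equal(constrained$curve$slope, 1)
  expect_true(tidy(constrained)$fixed[3])
  expect_gt(constrained$rmse_fit, free$rmse_fit)
})

test_that("tidy/glance/augment expose estimates, diagnostics and residuals", {
  truth <- hill_curve(emax = 0.9, d50 = 3, slope = 1.5)
  dat <- simulate_curve_data(truth, n_doses = 30, sigma = 0.02, seed = 9)
  fit <- fit_hill(dat)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "fixed"))
  expect_equal(td$term, c("emax", "d50", "slope"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 30L)
  expect_equal(gl$df_residual, 27L)
  au <- augment(fit)
  expect_equal(au$.resid, au$effect - au$.fitted)
  expect_lt(sqrt(mean(au$.resid^2)) - fit$rmse_fit, 1e-12)
})

test_that("estimates land within a few standard errors of the truth", {
  # interior truth: emax = 1 sits on the parameter bound and truncates the
  # estimator, which the linearised standard errors cannot describe
  truth <- hill_curve(emax = 0.9, d50 = 2, slope = 3)
  hits <- vapply(1:40, function(s) {
    dat <- simulate_curve_data(truth, n_doses = 50, sigma = 0.02, seed = 600 + s)
    td <- tidy(fit_hill(dat))
    all(abs(td$estimate - c(0.9, 2, 3)) <= 3 * td$std.error)
  }, logical(1))
  # nominal ~99.7% per parameter; demand >= 90% joint over 40 replicates
  expect_gte(mean(hits), 0.9)
})

test_that("prediction RMSE is invariant to record order and replicate grouping", {
  mix <- binary_example()
  tab <- simulate_mixture_grid(mix, sigma = 0.03, seed = 12)
  r1 <- glance(predict_mixture(tab, mix))$rmse
  r2 <- glance(predict_mixture(tab[sample(nrow(tab)), ], mix))$rmse
  expect_equal(r1, r2, tolerance = 1e-14)
  # duplicating every record leaves the RMSE unchanged
  r3 <- glance(predict_mixture(dplyr::bind_rows(tab, tab), mix))$rmse
  expect_equal(r1, r3, tolerance = 1e-14)
})

test_that("predict_mixture round-trips exact surfaces and flags model mismatch", {
  mix <- binary_example()
  exact <- simulate_mixture_grid(mix, sigma = 0)
  pred <- predict_mixture(exact, mix, method = "hill")
  expect_lt(glance(pred)$rmse, 1e-10)
  # single-agent rows inside the mixture table equal the 1-D curves
  edge <- exact[exact$dose_B == 0 & exact$dose_A > 0, ]
  expect_equal(predict_mixture(edge, mix)$.pred,
               hill_effect(edge$dose_A, mix$components[[1]]), tolerance = 1e-12)
  # Bliss-generated data scored against Hill: positive deviations below d50
  eq <- equal_model(2, d50 = 10)
  bl <- simulate_mixture_grid(eq, method = "bliss", sigma = 0,
                              doses = list(c(1, 2, 5), c(1, 2, 5)))
  ph <- predict_mixture(bl, eq, method = "hill")
  expect_gt(glance(ph)$rmse, 0)
  expect_gt(mean(ph$.resid), 0)
  expect_error(predict_mixture(exact, mix, method = "zip"))
})

test_that("synergy_report scores models side by side and flags disagreement", {
  mix <- binary_example()
  exact <- simulate_mixture_grid(mix, sigma = 0)
  rep0 <- synergy_report(exact, mix, methods = c("hill", "bliss"))
  expect_true(all(abs(rep0$dev_hill) < 1e-12))
  expect_lt(glance(rep0)$rmse[1], 1e-12)
  # flags appear exactly where hill and bliss disagree beyond the threshold
  gap <- abs(rep0$pred_hill - rep0$pred_bliss)
  expect_equal(rep0$flagged, gap > 0.05)
  expect_true(any(rep0$flagged))
  # an impossible threshold flags nothing
  rep1 <- synergy_report(exact, mix, methods = c("hill", "bliss"), threshold = 1)
  expect_false(any(rep1$flagged))
})
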