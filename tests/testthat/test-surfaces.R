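test_that("scaled doses divide by the median-effect doses, zeros stay zero", {
  mix <- binary_example()
  expect_equal(scaled_doses(c(100, 1), mix), c(1, 1))
  expect_equal(scaled_doses(c(0, 5), mixture_model(data.frame(
    emax = c(1, 1), d50 = c(2, 5), slope = c(1, 1)))), c(0, 1))
  expect_equal(scaled_doses(3, mixture_model(data.frame(
    emax = 1, d50 = 2, slope = 1))), 1.5)
  expect_error(scaled_doses(c(1, 2, 3), mix), class = "hillsurf_dimension_error")
  expect_error(scaled_doses(c(-1, 2), mix), class = "hillsurf_domain_error")
})

test_that("hill_effect matches the four-parameter logistic pointwise", {
  expect_equal(hill_effect(100, hill_curve(0.7, 100, 1)), 0.35)
  expect_equal(hill_effect(0, hill_curve(1, 1, 2)), 0)
  expect_equal(hill_effect(3, hill_curve(1, 1, 1)), 0.75)
  # asymptote and monotonicity
  crv <- hill_curve(0.6, 5, 3, e0 = 0.1)
  d <- 10^seq(-3, 6, length.out = 40)
  u <- hill_effect(d, crv)
  expect_true(all(diff(u) >= 0))
  expect_equal(hill_effect(1e12, crv), 0.7, tolerance = 1e-9)
  expect_error(hill_effect(-1, crv), class = "hillsurf_domain_error")
})

test_that("mixing functions are dose-weighted means of slope and emax", {
  mix <- binary_example()
  expect_equal(mix_gamma(c(1, 1), mix), 1.5)
  expect_equal(mix_umax(c(1, 1), mix), 0.85)
  # equal parameters: weighted mean collapses to the common value
  eq <- equal_model(3, emax = 0.4, slope = 2.5)
  expect_equal(mix_gamma(c(0.2, 3, 0.7), eq), 2.5)
  expect_equal(mix_umax(c(0.2, 3, 0.7), eq), 0.4)
  # single-component limit picks out that component
  tri <- mixture_model(data.frame(emax = c(0.8, 0.4, 1.0), d50 = c(1, 1, 1),
                                  slope = c(0.5, 5, 1)))
  expect_equal(mix_gamma(c(1, 0, 0), tri), 0.5)
  expect_equal(mix_umax(c(0, 0, 2), tri), 1.0)
  # bounds: always inside [min, max] of the component parameter
  set.seed(42)
  for (i in 1:20) {
    mdl <- random_model(n = sample(2:5, 1))
    m <- runif(n_agents(mdl), 0, 10)
    sl <- tidy(mdl)$slope
    expect_gte(mix_gamma(m, mdl), min(sl) - 1e-12)
    expect_lte(mix_gamma(m, mdl), max(sl) + 1e-12)
  }
  # degenerate all-zero input is NaN at this level
  expect_true(is.nan(mix_gamma(c(0, 0), mix)))
})

test_that("hill_surface_effect reproduces the hand-evaluated binary surface", {
  mix <- binary_example()
  # m = (1,1): S = 2, gamma = 1.5, u_max = 0.85
  expect_equal(hill_surface_effect(c(100, 1), mix),
               0.85 * 2^1.5 / (1 + 2^1.5), tolerance = 1e-14)
  # sham split of dose 1 at its d50 between identical agents
  expect_equal(hill_surface_effect(c(0.5, 0.5), equal_model(2)), 0.5)
  # all-zero doses give 0 by continuity
  expect_equal(hill_surface_effect(c(0, 0), mix), 0)
})

test_that("hill surface is numerically stable for extreme slopes and doses", {
  steep <- mixture_model(data.frame(emax = c(1, 1), d50 = c(1, 2),
                                    slope = c(106, 80)))
  u <- hill_surface_effect(rbind(c(1e8, 1e8), c(1e-8, 1e-8), c(5, 5)), steep)
  expect_true(all(is.finite(u)))
  expect_equal(u[1], 1, tolerance = 1e-12)
  expect_equal(u[2], 0, tolerance = 1e-12)
})

test_that("every model reduces to the single-agent curve on the axes", {
  mix <- binary_example()
  d <- 100 * 10^seq(-2, 2, length.out = 9)
  one_active <- cbind(d, 0)
  expected <- hill_effect(d, mix$components[[1]])
  for (method in c("hill", "bliss", "loewe")) {
    u <- evaluate_surface(as.data.frame(one_active), mix, method = method)$.effect
    expect_equal(u, expected, tolerance = 1e-10,
                 label = paste("pure-agent limit of", method))
  }
  # GCA as printed satisfies the pure-agent limit only for full agonists
  # (emax inside the denominator sum); exact at emax = 1, broken below it
  eq <- equal_model(2)
  d1 <- cbind(10^seq(-2, 2, length.out = 9), 0)
  expect_equal(gca_effect(d1, eq), hill_effect(d1[, 1], eq$components[[1]]),
               tolerance = 1e-12)
  expect_gt(max(abs(gca_effect(one_active, mix) - expected)), 0.01)
})

test_that("bliss_effect implements independent action", {
  mix <- binary_example()
  expect_equal(bliss_effect(c(100, 1), mix), 0.35 + 0.5 - 0.35 * 0.5)
  # component at dose zero contributes nothing
  expect_equal(bliss_effect(c(100, 0), mix), 0.35)
  # three agents at 0.5 each
  tri <- equal_model(3)
  expect_equal(bliss_effect(c(1, 1, 1), tri), 1 - 0.5^3)
  # monotone nondecreasing in every dose
  set.seed(7)
  for (i in 1:10) {
    mdl <- random_model(n = 2)
    base <- random_doses(mdl, rows = 1)
    for (j in 1:2) {
      up <- base; up[j] <- up[j] * 2
      expect_gte(bliss_effect(up, mdl), bliss_effect(base, mdl) - 1e-12)
    }
  }
})

test_that("gca_effect matches its explicit formula", {
  mix <- mixture_model(data.frame(emax = c(0.7, 1), d50 = c(100, 1),
                                  slope = c(1, 1)))
  expect_equal(gca_effect(c(50, 0.5), mix), 0.85 / 1.85, tolerance = 1e-14)
  expect_equal(gca_effect(c(0.5, 0.5), equal_model(2)), 0.5)
  expect_equal(gca_effect(c(0, 0), mix), 0)
})

test_that("Chou and Greco explicit forms match their hand evaluations", {
  expect_equal(chou_exclusive_effect(c(0.5, 0.5), umax = 1, gamma = 2), 0.5)
  expect_equal(chou_exclusive_effect(c(1, 1), umax = 0.85, gamma = 1.5),
               0.85 * 2^1.5 / (1 + 2^1.5), tolerance = 1e-14)
  expect_equal(chou_exclusive_effect(c(0, 0), umax = 1, gamma = 1), 0)
  expect_equal(chou_nonexclusive_effect(c(1, 1), umax = 1, gamma = 1), 0.75)
  expect_equal(chou_nonexclusive_effect(c(0, 2), umax = 0.8, gamma = 3),
               0.8 * 2^3 / (1 + 2^3), tolerance = 1e-14)
  expect_equal(chou_nonexclusive_effect(c(0, 0), umax = 1, gamma = 1), 0)
  expect_equal(greco_explicit_effect(c(1, 1), umax = 1, gamma = 1, alpha = 1), 0.75)
  expect_equal(greco_explicit_effect(c(1, 1), umax = 1, gamma = 1, alpha = 2), 4 / 5)
  expect_error(greco_explicit_effect(c(2, 2), umax = 1, gamma = 1, alpha = -2),
               class = "hillsurf_domain_error")
  expect_error(chou_nonexclusive_effect(c(1, 1, 1), umax = 1, gamma = 1),
               class = "hillsurf_dimension_error")
})

test_that("special-case equivalences hold on random grids", {
  set.seed(11)
  for (i in 1:10) {
    em <- runif(1, 0.3, 1); sl <- runif(1, 0.5, 5)
    mdl <- mixture_model(data.frame(emax = c(em, em), d50 = 10^runif(2, -1, 2),
                                    slope = c(sl, sl)))
    d <- random_doses(mdl, rows = 6)
    m <- scaled_doses(d, mdl)
    u_hill <- hill_surface_effect(d, mdl)
    # Hill == Chou exclusive for shared (emax, slope)
    expect_equal(chou_exclusive_effect(m, em, sl), u_hill, tolerance = 1e-10)
    # Greco(alpha = 0) == Chou exclusive; Greco(alpha = 1) == Chou non-exclusive
    expect_equal(greco_explicit_effect(m, em, sl, alpha = 0),
                 chou_exclusive_effect(m, em, sl), tolerance = 1e-10)
    expect_equal(greco_explicit_effect(m, em, sl, alpha = 1),
                 chou_nonexclusive_effect(m, em, sl), tolerance = 1e-10)
  }
  # Chou non-exclusive (gamma = 1, umax = 1) == Bliss of two slope-1 full agonists
  eq <- equal_model(2, d50 = 3)
  d <- cbind(10^runif(8, -2, 2) * 3, 10^runif(8, -2, 2) * 3)
  expect_equal(chou_nonexclusive_effect(scaled_doses(d, eq), 1, 1),
               bliss_effect(d, eq), tolerance = 1e-10)
  # Hill(all slopes 1, all emax 1) == GCA(all emax 1)
  expect_equal(hill_surface_effect(d, eq), gca_effect(d, eq), tolerance = 1e-10)
})

test_that("model outputs stay in range and are jointly permutation invariant", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(2:4, 1)
    mdl <- random_model(n = n)
    d <- random_doses(mdl, rows = 4)
    emax <- tidy(mdl)$emax
    for (method in c("hill", "bliss", "gca", "loewe")) {
      # loewe may warn when doses leave the classical CA domain; the cap
      # value is still well defined and must stay permutation invariant
      u <- suppressWarnings(
        evaluate_surface(as.data.frame(d), mdl, method = method)$.effect)
      expect_true(all(u >= 0 & u <= 1), label = paste(method, "in [0,1]"))
      if (method %in% c("hill", "loewe")) {
        expect_lte(max(u), max(emax) + 1e-9)
      }
      # permute components and dose columns together
      p <- sample(n)
      mdl_p <- mixture_model(tidy(mdl)[p, ])
      up <- suppressWarnings(
        evaluate_surface(as.data.frame(d[, p, drop = FALSE]), mdl_p,
                         method = method)$.effect)
      expect_equal(up, u, tolerance = 1e-10,
                   label = paste(method, "permutation invariance"))
    }
  }
})

test_that("hill surface u_max bound and shared-parameter monotonicity hold", {
  set.seed(31)
  for (i in 1:10) {
    mdl <- random_model(n = 3)
    d <- random_doses(mdl, rows = 3)
    m <- scaled_doses(d, mdl)
    emax <- tidy(mdl)$emax
    um <- mix_umax(m, mdl)
    expect_true(all(um >= min(emax) - 1e-12 & um <= max(emax) + 1e-12))
    expect_true(all(hill_surface_effect(d, mdl) <= max(emax) + 1e-12))
  }
  # shared (emax, slope): nondecreasing in every dose
  eq <- equal_model(2, emax = 0.8, slope = 3)
  d <- seq(0.2, 3, length.out = 10)
  u1 <- hill_surface_effect(cbind(d, 0.7), eq)
  u2 <- hill_surface_effect(cbind(0.7, d), eq)
  expect_true(all(diff(u1) > 0) && all(diff(u2) > 0))
})

test_that("evaluate_surface returns a tibble with .effect for data-frame input", {
  mix <- binary_example()
  grid <- expand.grid(dose_A = c(0, 100), dose_B = c(0, 1))
  out <- evaluate_surface(grid, mix, method = "hill")
  expect_s3_class(out, "tbl_df")
  expect_named(out, c("dose_A", "dose_B", ".effect"))
  expect_equal(out$.effect[1], 0)
  expect_equal(out$.effect[4], 0.85 * 2^1.5 / (1 + 2^1.5), tolerance = 1e-12)
  expect_error(evaluate_surface(grid, mix, method = "nope"))
})
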