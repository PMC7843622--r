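test_that("survival fractions normalise colony ratios to plating efficiency", {
  rec <- colony_records(arm = "xray",
                        dose_gy = c(0, 0, 2, 2),
                        cells_seeded = 200,
                        colonies = c(100, 100, 50, 50),
                        replicate = c(1, 2, 1, 2))
  sc <- survival_fractions(rec)
  expect_equal(attr(sc, "pe"), 0.5)
  expect_equal(sc$sf[sc$dose_gy == 0], 1)
  expect_equal(sc$sf[sc$dose_gy == 2], 0.5)
  # treated identical to control: SF = 1 everywhere
  rec2 <- colony_records("a", c(0, 1, 2), 100, c(40, 40, 40), 1)
  sc2 <- survival_fractions(rec2)
  expect_equal(sc2$sf, c(1, 1, 1))
})

test_that("missing controls and zero-colony doses are handled", {
  rec <- colony_records("a", c(1, 2, 3), 100, c(10, 5, 2), 1)
  expect_error(survival_fractions(rec), "0 Gy control")
  rec2 <- colony_records("a", c(0, 2, 4), 100, c(50, 10, 0), 1)
  sc <- survival_fractions(rec2)
  expect_true(sc$below_detection[sc$dose_gy == 4])
  expect_false(any(sc$below_detection[sc$dose_gy < 4]))
})

test_that("synthetic survival fractions are recovered within 3 SE", {
  # generator truth vs reduced SF, over many seeds and doses
  alpha <- 0.2; beta <- 0.0546
  doses <- c(0, 2.5, 5, 7.5)
  hits <- 0L; total <- 0L
  for (s in 1:200) {
    rec <- make_survival_dataset(alpha, beta, doses,
                                 cells_seeded = c(200, 800, 4000, 20000),
                                 replicates = 3, seed = s)
    sc <- survival_fractions(rec)
    for (i in which(sc$dose_gy > 0 & !sc$below_detection)) {
      truth <- exp(-(alpha * sc$dose_gy[i] + beta * sc$dose_gy[i]^2))
      total <- total + 1L
      if (abs(sc$sf[i] - truth) <= 3 * sc$sf_err[i]) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("LQ fit recovers noiseless parameters and the pure-exponential limit", {
  alpha <- 0.2; beta <- 0.0546
  d <- c(1, 2.5, 5, 7.5)
  curve <- survival_curve(d, exp(-(alpha * d + beta * d^2)))
  fit <- fit_lq(curve)
  expect_equal(fit$alpha, alpha, tolerance = 1e-9)
  expect_equal(fit$beta, beta, tolerance = 1e-9)
  expect_equal(fit$alpha_beta_ratio, alpha / beta, tolerance = 1e-6)
  # beta = 0 data yields beta ~ 0
  curve2 <- survival_curve(d, exp(-0.3 * d))
  fit2 <- fit_lq(curve2)
  expect_equal(fit2$beta, 0, tolerance = 1e-8)
  expect_equal(fit2$alpha, 0.3, tolerance = 1e-8)
})

test_that("LQ fit requires three distinct positive doses", {
  expect_error(fit_lq(survival_curve(c(0, 2, 4), c(1, 0.5, 0.2))),
               "3 distinct positive doses")
})

test_that("constrained fit pins negative components at zero", {
  # concave-up log survival (supra-exponential recovery) pushes beta < 0;
  # the constrained fit should return beta = 0 and alpha >= 0
  d <- c(2, 4, 6, 8)
  sf <- exp(-(0.4 * d - 0.01 * d^2))
  fit <- fit_lq(survival_curve(d, sf))
  expect_gte(fit$alpha, 0)
  expect_equal(fit$beta, 0)
  fit_u <- fit_lq(survival_curve(d, sf), constrain = FALSE)
  expect_lt(fit_u$beta, 0)
})

test_that("isoeffect dose solves the LQ quadratic", {
  fit_a <- structure(list(alpha = log(2), beta = 0), class = "lq_fit")
  expect_equal(dose_at_sf(fit_a, 0.5), 1)
  fit_b <- structure(list(alpha = 0, beta = log(2)), class = "lq_fit")
  expect_equal(dose_at_sf(fit_b, 0.5), 1)
  # generic parameters match a bisection root-finder
  for (p in list(c(0.2, 0.0546), c(0.05, 0.1), c(1.2, 0.01))) {
    fit <- structure(list(alpha = p[1], beta = p[2]), class = "lq_fit")
    for (sf in c(0.8, 0.5, 0.1, 0.01)) {
      expect_equal(dose_at_sf(fit, sf),
                   bisect_dose_at_sf(p[1], p[2], sf), tolerance = 1e-9)
    }
  }
  # monotone decreasing in the survival level
  fit <- structure(list(alpha = 0.2, beta = 0.0546), class = "lq_fit")
  lv <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  expect_true(all(diff(dose_at_sf(fit, lv)) > 0))
  expect_error(dose_at_sf(fit, 1.2), "strictly in")
})

test_that("RBE definition, trivial cases and dose-rescaling invariance", {
  d <- c(1, 2.5, 5, 7.5)
  sf <- exp(-(0.2 * d + 0.05 * d^2))
  fit <- fit_lq(survival_curve(d, sf))
  # identical fits give RBE exactly 1
  r1 <- rbe(fit, fit, sf_level = 0.5)
  expect_identical(r1$rbe, 1)
  # a test arm needing twice the dose has RBE 0.5
  sf_half <- exp(-(0.1 * d + 0.0125 * d^2))  # curve stretched 2x in dose
  fit_half <- fit_lq(survival_curve(d, sf_half))
  r2 <- rbe(fit, fit_half, sf_level = 0.5)
  expect_equal(r2$rbe, 0.5, tolerance = 1e-6)
  expect_equal(r2$dose_reference / r2$dose_test, r2$rbe)
  # rescaling both arms' doses by one factor leaves RBE unchanged
  c_ <- 3.7
  fit_s <- fit_lq(survival_curve(c_ * d, sf))
  fit_half_s <- fit_lq(survival_curve(c_ * d, sf_half))
  r3 <- rbe(fit_s, fit_half_s, sf_level = 0.5)
  expect_equal(r3$rbe, r2$rbe, tolerance = 1e-6)
})

test_that("interpolated isoeffect dose agrees with the fit on LQ data", {
  d <- c(0, 1, 2.5, 5, 7.5)
  sf <- exp(-(0.2 * d + 0.0546 * d^2))
  curve <- survival_curve(d, sf)
  fit <- fit_lq(curve)
  di <- dose_at_sf_interp(curve, 0.5)
  expect_false(di$extrapolated)
  # piecewise log-linear vs the smooth LQ root: close but not identical
  expect_equal(di$dose, dose_at_sf(fit, 0.5), tolerance = 0.05)
  # below the deepest measured point triggers the extrapolation flag
  di2 <- dose_at_sf_interp(curve, 1e-4)
  expect_true(di2$extrapolated)
  expect_warning(rbe(fit, curve, sf_level = 1e-4), "extrapolated")
})
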