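test_that("intensities convert to effective relaxation rates", {
  pr <- dispersion_profile("M1", nu = c(0, 50, 100, 200, 400, 800),
                           intensity = c(1, 1, 0.8, 0.9, 0.95, 1.05),
                           t_cpmg = 0.04)
  expect_warning(compute_r2eff(pr), "negative")
  r2 <- suppressWarnings(compute_r2eff(pr))
  expect_equal(r2$r2eff[r2$nu == 50], 0)            # I = I0
  expect_equal(r2$r2eff[r2$nu == 100], 5.5785888,   # ln(1.25)/0.04
               tolerance = 1e-6)
  expect_true(r2$negative[r2$nu == 800])            # I > I0, kept + flagged
  expect_error(dispersion_profile("M1", nu = c(50, 100, 200, 400, 600),
                                  intensity = rep(1, 5)),
               "reference")
})

test_that("non-positive intensities are dropped with a warning", {
  pr <- dispersion_profile("M2", nu = c(0, 50, 100, 200, 400, 800),
                           intensity = c(1, 0.9, -0.1, 0.8, 0.85, 0.9))
  expect_warning(r2 <- compute_r2eff(pr), "non-positive")
  expect_equal(nrow(r2), 4)
})

test_that("duplicate-based sigma follows the pooled-pair formula", {
  mk <- function(r2vals, nus) {
    # invert R2eff to intensities so the profile produces the wanted values
    dispersion_profile("M", nu = c(0, nus),
                       intensity = c(1, exp(-0.04 * r2vals)), t_cpmg = 0.04)
  }
  # identical duplicates
  expect_equal(estimate_errors(mk(c(10, 10, 12, 9, 8, 7),
                                  c(50, 50, 100, 200, 400, 800))), 0)
  # one pair differing by 1.0: sigma = sqrt(1/2)
  expect_equal(estimate_errors(mk(c(10, 11, 12, 9, 8, 7),
                                  c(50, 50, 100, 200, 400, 800))),
               0.7071068, tolerance = 1e-6)
  # two pairs differing by 1.0 and 0: sigma = sqrt(1/4)
  expect_equal(estimate_errors(mk(c(10, 11, 12, 12, 8, 7),
                                  c(50, 50, 300, 300, 400, 800))),
               0.5, tolerance = 1e-9)
  # no duplicates: fallback with warning
  expect_warning(s <- estimate_errors(mk(c(10, 12, 9, 8, 7),
                                         c(50, 100, 200, 400, 800)),
                                      fallback = 0.4),
                 "fallback")
  expect_equal(s, 0.4)
})

test_that("dispersion detection uses the low-minus-high amplitude rule", {
  flat <- data.frame(nu = c(50, 100, 200, 400, 800), r2eff = rep(10, 5))
  d <- detect_dispersion(flat)
  expect_equal(d$amplitude, 0)
  expect_false(d$dispersing)

  # hand-evaluated forward model, phi/kex = 5 at kex = 1000, default schedule
  pr <- gen_cpmg_profile(cpmg_preset(r2_0 = 12, kex = 1000, phi = 5000,
                                     noise_sd = 0), seed = 1)
  d2 <- detect_dispersion(compute_r2eff(pr))
  expect_equal(d2$amplitude, 3.5411738, tolerance = 1e-6)
  expect_true(d2$dispersing)

  # boundary: amplitude exactly at the threshold is NOT dispersing
  edge <- data.frame(nu = c(50, 100, 200, 400, 800),
                     r2eff = c(12, 12, 11, 10, 10))
  expect_false(detect_dispersion(edge)$dispersing)
  expect_equal(detect_dispersion(edge)$amplitude, 2)

  expect_error(detect_dispersion(flat[1:4, ]), "5 distinct")
})

test_that("two-state fit recovers noiseless truth to < 1%", {
  pr <- gen_cpmg_profile(cpmg_preset(r2_0 = 12, kex = 1500, phi = 3e5,
                                     noise_sd = 0), seed = 1)
  f <- fit_two_state(pr, sigma = 0.3)
  expect_lt(abs(f$r2_0 - 12) / 12, 0.01)
  expect_lt(abs(f$kex - 1500) / 1500, 0.01)
  expect_lt(abs(f$phi - 3e5) / 3e5, 0.01)
  expect_equal(f$model, "two-state-fast")
})

test_that("flat profiles choose no-exchange; ties break to parsimony", {
  pr <- gen_cpmg_profile(cpmg_preset(r2_0 = 15, kex = 1000, phi = 0,
                                     noise_sd = 0), seed = 1)
  f <- fit_two_state(pr, sigma = 0.3)
  expect_lt(f$aicc[["no-exchange"]], f$aicc[["two-state-fast"]])
  expect_equal(f$model, "no-exchange")
  expect_equal(select_model(c("no-exchange" = 5, "two-state-fast" = 5)),
               "no-exchange")
  expect_equal(select_model(c("no-exchange" = 5, "two-state-fast" = 4.9)),
               "two-state-fast")
})

test_that("optimizer chi-square matches a brute-force (kex, phi) grid", {
  pr <- gen_cpmg_profile(cpmg_preset(r2_0 = 12, kex = 1200, phi = 1.5e4,
                                     noise_sd = 0.01 * 1e6), seed = 5)
  sigma <- estimate_errors(pr)
  f <- fit_two_state(pr, sigma = sigma)
  r2 <- compute_r2eff(pr)
  w <- rep(1 / sigma^2, nrow(r2))
  grid_chi2 <- outer(
    10^seq(log10(100), log10(10000), length.out = 100),
    10^seq(log10(1e3), log10(1e6), length.out = 100),
    Vectorize(function(kex, phi) {
      shape <- oracle_luz_meiboom(r2$nu, 0, kex, phi)
      r2_0 <- sum(w * (r2$r2eff - shape)) / sum(w)  # profiled intercept
      sum(w * (r2$r2eff - shape - r2_0)^2)
    }))
  expect_lt(f$chi2, min(grid_chi2) * 1.001)
})

test_that("model curve is monotone in frequency with the right limits", {
  withr::with_seed(4, {
    for (i in 1:20) {
      r2_0 <- runif(1, 0, 30); kex <- 10^runif(1, 2, 4)
      phi <- 10^runif(1, 2, 6)
      nu <- sort(c(1e-6, 10^seq(0, 6, length.out = 50)))
      curve <- r2_dispersion_model(nu, r2_0, kex, phi)
      expect_true(all(diff(curve) <= 1e-9))
      expect_lt(abs(curve[1] - (r2_0 + phi / kex)), 1e-6 * (r2_0 + phi / kex))
      expect_lt(abs(curve[length(nu)] - r2_0), 1e-3)
    }
  })
})

test_that("exchange rate is recovered within 15% median error at sigma 0.3", {
  errs <- sapply(1:50, function(s) {
    kex <- withr::with_seed(s, runif(1, 500, 3000))
    pr <- gen_cpmg_profile(
      # intensity noise calibrated so sigma(R2eff) is about 0.3 1/s at the
      # typical measured intensity (~0.5 i_ref): sigma_I = 0.3 * T * I
      cpmg_preset(r2_0 = 12, kex = kex, phi = 8 * kex, i_ref = 1e6,
                  noise_sd = 0.3 * 0.04 * 0.5e6),
      seed = 1000 + s)
    f <- fit_two_state(pr, sigma = 0.3)
    abs(f$kex - kex) / kex
  })
  expect_lt(median(errs), 0.15)
})

test_that("strong dispersion is selected as exchange in almost every run", {
  sigma <- 0.3
  picks <- sapply(1:100, function(s) {
    pr <- gen_cpmg_profile(
      cpmg_preset(r2_0 = 12, kex = 1000, phi = 1000 * 10 * sigma,
                  i_ref = 1e6, noise_sd = sigma * 0.04 * 0.5e6),
      seed = 2000 + s)
    fit_two_state(pr, sigma = sigma)$model
  })
  expect_gte(sum(picks == "two-state-fast"), 95)
})
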