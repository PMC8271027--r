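make_trace <- function(k = 1e-3, y0 = 150, a = 150, noise = 0, seed = 1,
                       n = 40, t_end = 6 / k) {
  p <- fp_preset("X", "none", k_true = k, y0_true = y0, a_true = a,
                 noise_sd = noise, n_timepoints = n, t_end = t_end)
  gen_fp_trace(p, seed = seed)
}

test_that("baseline subtraction: identity, constant, and mean modes", {
  tr <- make_trace()$sample
  zero <- subtract_baseline(tr, 0)
  expect_equal(zero$fp, tr$fp)
  expect_true(zero$baseline_subtracted)

  shifted <- subtract_baseline(tr, 35)
  expect_equal(shifted$fp, tr$fp - 35)

  # baseline on a different grid: constant mode subtracts its hand-computed
  # mean; without the flag the grid mismatch is an error
  bl_vals <- c(34, 36, 35, 33, 37)
  bl <- fp_trace(seq(0, 4000, length.out = 8),
                 c(bl_vals, 35, 35, 35), role = "baseline")
  hand_mean <- sum(c(bl_vals, 35, 35, 35)) / 8
  expect_equal(subtract_baseline(tr, bl, constant = TRUE)$fp,
               tr$fp - hand_mean)
  expect_error(subtract_baseline(tr, bl), "grid")
})

test_that("association fit recovers noiseless truth and rejects flat traces", {
  tr <- make_trace(k = 1e-3)
  fit <- fit_association(subtract_baseline(tr$sample, 35))
  expect_true(fit$converged)
  expect_lt(abs(fit$k_on - 1e-3) / 1e-3, 1e-6)
  expect_lt(abs(fit$a - 150) / 150, 1e-6)

  flat <- fp_trace(seq(0, 1000, length.out = 20),
                   100 + rep(c(-0.1, 0.1), 10),
                   baseline_subtracted = TRUE)
  flat$baseline_subtracted <- TRUE
  expect_error(fit_association(flat), "no association detected")
})

test_that("replicate-mean rate stays within 5% of truth at assay noise", {
  k <- 1e-3
  khat <- sapply(1:9, function(s) {
    tr <- make_trace(k = k, noise = 2, seed = s)
    fit_association(subtract_baseline(tr$sample, tr$baseline,
                                      constant = TRUE))$k_on
  })
  means <- colMeans(matrix(khat, nrow = 3))
  expect_true(all(abs(means - k) / k < 0.05))
})

test_that("fold change and relative activity follow their definitions", {
  expect_equal(fold_change(2e-4, 2e-4), 1)
  expect_equal(fold_change(2e-4, 1e-4), 2)
  expect_error(fold_change(1e-4, 0), "k_uncat")

  expect_equal(relative_activity(5e-4, 5e-4, 1e-4), 1)
  expect_equal(relative_activity(1e-4, 5e-4, 1e-4), 0)
  expect_error(relative_activity(2e-4, 1e-4, 1e-4), "undefined")

  # invariance under common rescaling of all rates
  for (c in c(0.1, 3, 1e4)) {
    expect_equal(fold_change(c * 2e-4, c * 1e-4), 2)
    expect_equal(relative_activity(c * 3e-4, c * 5e-4, c * 1e-4),
                 relative_activity(3e-4, 5e-4, 1e-4))
  }
  # monotone in k_mut
  ra <- relative_activity(seq(1e-4, 9e-4, by = 1e-4), 5e-4, 1e-4)
  expect_true(all(diff(ra) > 0))
})

test_that("noiseless preset pairs reproduce the calibrated statistics", {
  tab <- preset_table(noise_sd = 0)
  pget <- function(al, cat) get_preset(al, cat, tab)
  kfit <- function(p) {
    fit_association(subtract_baseline(gen_fp_trace(p, 1)$sample,
                                      p$baseline_true))$k_on
  }
  expect_equal(fold_change(kfit(pget("A*03:01", "Tsn-WT")),
                           kfit(pget("A*03:01", "none"))),
               10.89, tolerance = 1e-5)
  expect_equal(relative_activity(kfit(pget("B*27:09", "K16L")),
                                 kfit(pget("B*27:09", "Tsn-WT")),
                                 kfit(pget("B*27:09", "none"))),
               1.26, tolerance = 1e-4)
})

test_that("Welch test matches the closed-form oracle and rejects degeneracy", {
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  # frozen from the hand-evaluated Welch formula for (1,2,3) vs (2,3,4)
  res <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -1.2247449, tolerance = 1e-6)
  expect_equal(res$dof, 4, tolerance = 1e-6)
  expect_equal(res$p_value, 0.2878641, tolerance = 1e-6)

  expect_error(welch_t_test(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welch_t_test(1, c(1, 2)), ">= 2")
})

test_that("condition summary handles replicates, SDs and missing baselines", {
  df <- data.frame(
    allotype = "A*03:01",
    catalyst = rep(c("none", "Tsn-WT", "L18G"), each = 3),
    replicate = rep(1:3, 3),
    k_on = c(1e-4, 1.1e-4, 0.9e-4, 1e-3, 1.1e-3, 1.05e-3,
             4e-4, 4.2e-4, 4.4e-4),
    converged = TRUE)
  s <- summarize_conditions(df)
  expect_equal(s$fold_change[s$catalyst == "none"], 1)
  expect_equal(s$relative_activity[s$catalyst == "Tsn-WT"], 1)
  expect_false(is.na(s$p_value[s$catalyst == "L18G"]))

  # single replicate: mean still reported, SD not available
  one <- summarize_conditions(df[c(1, 4), ])
  expect_true(all(is.na(one$k_on_sd)))
  expect_equal(one$fold_change[one$catalyst == "Tsn-WT"], 10)

  # identical replicates: SD exactly 0
  ident <- df; ident$k_on <- rep(c(1e-4, 1e-3, 4e-4), each = 3)
  expect_equal(summarize_conditions(ident)$k_on_sd, rep(0, 3))

  expect_error(summarize_conditions(df[df$catalyst != "none", ]), "none")
})

test_that("optimizer matches a dense grid with profiled linear parameters", {
  withr::with_seed(99, {
    for (i in 1:10) {
      k <- 10^runif(1, -4, -2.5)
      tr <- make_trace(k = k, y0 = runif(1, 100, 200),
                       a = runif(1, 80, 180), noise = 2, seed = i)
      d <- subtract_baseline(tr$sample, tr$baseline, constant = TRUE)
      fit <- fit_association(d)
      # grid oracle: profile (y0, a) by linear least squares for each k
      grid_rss <- sapply(k * 10^seq(-1, 1, length.out = 400), function(kk) {
        X <- cbind(1, -exp(-kk * d$time))
        sum(stats::lm.fit(X, d$fp)$residuals^2)
      })
      expect_lt(fit$rss, min(grid_rss) * 1.001)
    }
  })
})

test_that("Monte-Carlo SD of the rate estimate shrinks roughly as 1/sqrt(n)", {
  ks <- sapply(1:144, function(s) {
    tr <- make_trace(k = 1e-3, noise = 2, seed = 100 + s)
    fit_association(subtract_baseline(tr$sample, tr$baseline,
                                      constant = TRUE))$k_on
  })
  sd_of_mean <- function(n) {
    sd(colMeans(matrix(ks, nrow = n)))
  }
  s3 <- sd_of_mean(3); s12 <- sd_of_mean(12); s48 <- sd_of_mean(48)
  expect_gt(s3, s12)
  expect_gt(s12, s48)
})
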