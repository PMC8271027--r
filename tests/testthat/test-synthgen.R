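test_that("FP generator matches the closed form at t = 0 and at the plateau", {
  p <- fp_preset("X", "none", k_true = 1e-3, y0_true = 140, a_true = 120,
                 baseline_true = 30, noise_sd = 0, t_end = 20 / 1e-3)
  tr <- gen_fp_trace(p, seed = 1)$sample
  expect_equal(tr$fp[1], 30 + 140 - 120)
  expect_lt(abs(tr$fp[length(tr$fp)] - (30 + 140)), 1e-6 * 120)
})

test_that("FP generator is deterministic for a fixed seed", {
  p <- fp_preset("X", "Tsn-WT", k_true = 5e-4)
  a <- gen_fp_trace(p, seed = 7)
  b <- gen_fp_trace(p, seed = 7)
  expect_identical(a$sample$fp, b$sample$fp)
  expect_identical(a$baseline$fp, b$baseline$fp)
  c <- gen_fp_trace(p, seed = 8)
  expect_false(identical(a$sample$fp, c$sample$fp))
})

test_that("non-finite FP preset fields are rejected", {
  expect_error(fp_preset("X", "none", k_true = NaN), "non-finite")
  expect_error(fp_preset("X", "none", k_true = 1e-4, a_true = Inf),
               "non-finite")
  expect_error(fp_preset("X", "none", k_true = -1), "k_true")
  expect_error(fp_preset("X", "none", k_true = 1e-4, n_timepoints = 5),
               "n_timepoints")
})

test_that("CPMG generator emits the forward model exactly when noiseless", {
  # no exchange: constant intensity at every frequency
  p0 <- cpmg_preset(r2_0 = 8, kex = 1000, phi = 0, noise_sd = 0)
  pr0 <- gen_cpmg_profile(p0, seed = 1)
  meas <- pr0$nu > 0
  expect_equal(pr0$intensity[meas],
               rep(pr0$i_ref * exp(-0.04 * 8), sum(meas)))

  # hand evaluation at nu = 250: x = 1, R2 = 10 + 10 (1 - tanh 1)
  p <- cpmg_preset(r2_0 = 10, kex = 1000, phi = 1e4, noise_sd = 0)
  pr <- gen_cpmg_profile(p, seed = 1)
  i250 <- pr$intensity[pr$nu == 250]
  r2_back <- log(pr$i_ref / i250) / 0.04
  expect_equal(r2_back, 12.384058440, tolerance = 1e-9)

  # fast-pulsing limit
  expect_lt(abs(r2_dispersion_model(1e6, 10, 1000, 1e4) - 10), 1e-3)
  expect_error(r2_dispersion_model(-1, 10, 1000, 1e4), "nu")
})

test_that("peak-list pair generator honours attenuation, identity and seed", {
  ids <- sprintf("R%d", 1:8)
  ident <- gen_peaklist_pair(peakpair_preset(ids), seed = 3)
  expect_equal(ident$perturbed$intensity, ident$reference$intensity)
  expect_equal(ident$perturbed$delta_h, ident$reference$delta_h)

  att <- gen_peaklist_pair(
    peakpair_preset(ids, attenuation_map = c(R3 = 0.2)), seed = 3)
  tab <- intensity_ratios(match_peaks(att$reference, att$perturbed))
  expect_equal(tab$ratio[tab$assignment_id == "R3"], 0.2)
  expect_equal(tab$ratio[tab$assignment_id != "R3"], rep(1, 7))

  expect_error(peakpair_preset(c("A1", "A1")), "unique")

  # byte-identical files under a fixed seed
  f1 <- tempfile(); f2 <- tempfile()
  write_peaklist_tsv(gen_peaklist_pair(peakpair_preset(ids), 11)$perturbed, f1)
  write_peaklist_tsv(gen_peaklist_pair(peakpair_preset(ids), 11)$perturbed, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("melt generator hits the sigmoid midpoint and is monotone", {
  p <- melt_preset(tm_true = 65, slope_true = 1.5, f_min = 1000,
                   f_max = 9000, noise_sd = 0)
  cur <- gen_melt_curve(p, seed = 1)
  mid <- approx(cur$temperature, cur$fluorescence, xout = 65)$y
  expect_equal(mid, (1000 + 9000) / 2, tolerance = 1e-6)
  expect_true(all(diff(cur$fluorescence) >= 0))
  expect_error(melt_preset(65, step = 0), "step")
  expect_error(melt_preset(100), "t_range")
})

test_that("preset table encodes exactly the printed ratios", {
  tab <- preset_table()
  k_of <- function(al, cat) tab$k_true[tab$allotype == al & tab$catalyst == cat]
  # fold changes, ratio of encoded rates
  fc_expect <- list(c("A*03:01", "Tsn-WT", 10.89), c("B*27:05", "Tsn-WT", 5.83),
                    c("B*27:09", "Tsn-WT", 3.83), c("A*02:01", "Tsn-WT", 1.31),
                    c("A*02:01", "TAPBPR", 30.9), c("A*03:01", "TAPBPR", 34.28),
                    c("B*27:05", "TAPBPR", 1.48), c("B*27:09", "TAPBPR", 3.13))
  for (e in fc_expect)
    expect_equal(k_of(e[1], e[2]) / k_of(e[1], "none"), as.numeric(e[3]))
  # relative activities recovered by re-applying the formula
  ra_expect <- list(c("A*03:01", "L18G", 0.36), c("B*27:05", "L18G", 0.05),
                    c("B*27:09", "K16G", 0.95), c("B*27:05", "GGGGG", 0.02),
                    c("B*27:09", "K16L", 1.26), c("B*27:09", "GGGGL", 0.77),
                    c("A*03:01", "GGGGK", 0.23))
  for (e in ra_expect)
    expect_equal(relative_activity(k_of(e[1], e[2]), k_of(e[1], "Tsn-WT"),
                                   k_of(e[1], "none")),
                 as.numeric(e[3]))
  # identity: the uncatalyzed condition has fold change 1 against itself
  expect_equal(k_of("B*27:09", "none") / k_of("B*27:09", "none"), 1)
  expect_error(get_preset("A*03:01", "no-such-catalyst", tab), "no preset")
})

test_that("noiseless generator output round-trips through every fitter", {
  # FP
  p <- fp_preset("X", "none", k_true = 2e-4, noise_sd = 0)
  f <- fit_association(subtract_baseline(gen_fp_trace(p, 1)$sample,
                                         p$baseline_true))
  expect_lt(abs(f$k_on - 2e-4) / 2e-4, 1e-6)
  expect_lt(abs(f$y0 - p$y0_true) / p$y0_true, 1e-6)
  # CPMG (forward/backward consistency to 1e-9)
  cp <- cpmg_preset(r2_0 = 12, kex = 1500, phi = 3e5, noise_sd = 0)
  r2 <- compute_r2eff(gen_cpmg_profile(cp, 1))
  expect_equal(r2$r2eff, oracle_luz_meiboom(r2$nu, 12, 1500, 3e5),
               tolerance = 1e-9)
  # melt
  mp <- melt_preset(64.2, 1.1, noise_sd = 0)
  mf <- fit_boltzmann(gen_melt_curve(mp, 1))
  expect_lt(abs(mf$tm - 64.2), 1e-6)
})
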