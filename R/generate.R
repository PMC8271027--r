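#' Synthetic data generators
#'
#' Deterministic (seeded) forward simulators for the four assay types. Each
#' takes a preset holding the ground truth and emits the same container the
#' matching reader produces, so fitters can be validated end to end.
#'
#' @name synthgen
NULL

#' Simulate one FP association trace (plus its baseline well)
#'
#' Signal model: `baseline + y0 - a*exp(-k*t) + N(0, noise_sd)` on an even
#' time grid from 0 to `t_end`. A matching free-peptide-only baseline trace
#' (constant `baseline_true` plus independent noise) is generated alongside,
#' mirroring the baseline wells of the plate assay.
#'
#' @param preset an [fp_preset()].
#' @param seed integer seed; fixed seed gives identical traces.
#' @param replicate replicate index recorded in the condition metadata.
#' @return list with elements `sample` and `baseline`, both [fp_trace()]
#'   objects; `sample` carries `baseline_ref` pointing at `baseline`.
#' @export
gen_fp_trace <- function(preset, seed, replicate = 1L) {
  stopifnot(inherits(preset, "fp_preset"))
  t <- seq(0, preset$t_end, length.out = preset$n_timepoints)
  with_seed(seed, {
    mu <- preset$baseline_true + preset$y0_true -
      preset$a_true * exp(-preset$k_true * t)
    fp <- mu + stats::rnorm(length(t), 0, preset$noise_sd)
    bl <- preset$baseline_true + stats::rnorm(length(t), 0, preset$noise_sd)
    cond <- list(allotype = preset$allotype, catalyst = preset$catalyst,
                 replicate = as.integer(replicate))
    baseline <- fp_trace(t, bl, allotype = preset$allotype,
                         catalyst = preset$catalyst,
                         replicate = as.integer(replicate), role = "baseline")
    sample <- fp_trace(t, fp, allotype = preset$allotype,
                       catalyst = preset$catalyst,
                       replicate = as.integer(replicate), role = "sample",
                       baseline_ref = baseline)
    list(sample = sample, baseline = baseline)
  })
}

#' Two-state fast-exchange dispersion model
#'
#' Luz--Meiboom closed form
#' `r2_0 + (phi/kex) * (1 - (4*nu/kex) * tanh(kex/(4*nu)))`, with the
#' continuity value `r2_0 + phi/kex` at `nu = 0`.
#'
#' @param nu CPMG pulse frequency (Hz), >= 0.
#' @param r2_0,kex,phi model parameters (see [cpmg_preset()]).
#' @return effective relaxation rate (1/s).
#' @export
r2_dispersion_model <- function(nu, r2_0, kex, phi) {
  if (any(nu < 0)) stop_pepx("nu must be >= 0")
  out <- rep(r2_0 + phi / kex, length(nu))
  pos <- nu > 0
  x <- kex / (4 * nu[pos])
  out[pos] <- r2_0 + (phi / kex) * (1 - tanh(x) / x)
  out
}

#' Simulate one CPMG dispersion profile
#'
#' Peak intensities follow `i_ref * exp(-t_cpmg * R2(nu))` with additive
#' Gaussian noise; the `nu = 0` entry is the noise-free reference plane.
#' Duplicated frequencies (50 and 300 Hz in the default schedule) receive
#' independent noise, which is what duplicate-based error estimation relies
#' on.
#'
#' @param preset a [cpmg_preset()].
#' @param seed integer seed.
#' @return a [dispersion_profile()].
#' @export
gen_cpmg_profile <- function(preset, seed) {
  stopifnot(inherits(preset, "cpmg_preset"))
  nu <- preset$nu_schedule
  with_seed(seed, {
    r2 <- r2_dispersion_model(nu, preset$r2_0, preset$kex, preset$phi)
    intensity <- preset$i_ref * exp(-preset$t_cpmg * r2)
    meas <- nu > 0
    intensity[meas] <- intensity[meas] +
      stats::rnorm(sum(meas), 0, preset$noise_sd)
    intensity[!meas] <- preset$i_ref
    dispersion_profile(methyl_id = preset$methyl_id, nu = nu,
                       intensity = intensity, t_cpmg = preset$t_cpmg)
  })
}

#' Simulate a reference/perturbed HSQC peak-list pair
#'
#' Reference intensities are `intensity_scale` with a mild deterministic
#' spread across residues; perturbed intensities are attenuated by the true
#' I/I0 map plus noise, and peak positions are displaced by the shift map.
#'
#' @param preset a [peakpair_preset()].
#' @param seed integer seed.
#' @return list with `reference` and `perturbed` [peak_list()] objects.
#' @export
gen_peaklist_pair <- function(preset, seed) {
  stopifnot(inherits(preset, "peakpair_preset"))
  ids <- preset$residues
  n <- length(ids)
  with_seed(seed, {
    # reproducible per-residue base intensities around the scale
    base <- preset$intensity_scale * stats::runif(n, 0.8, 1.2)
    h <- stats::runif(n, 6.5, 10.5)
    nppm <- stats::runif(n, 105, 130)
    ref <- peak_list(ids, h, nppm, base, provenance = "reference")
    att <- preset$attenuation_map[ids]
    dh <- vapply(ids, function(i) (preset$shift_map[[i]] %||% c(0, 0))[1], 0)
    dn <- vapply(ids, function(i) (preset$shift_map[[i]] %||% c(0, 0))[2], 0)
    pint <- base * att + stats::rnorm(n, 0, preset$noise_sd)
    pert <- peak_list(ids, h + dh, nppm + dn, pmax(pint, 0),
                      provenance = "perturbed")
    list(reference = ref, perturbed = pert)
  })
}

#' Simulate one thermal-shift melt curve
#'
#' `F(T) = f_min + (f_max - f_min) / (1 + exp((tm_true - T)/slope_true))`
#' plus Gaussian noise, on the regular temperature grid of the preset.
#'
#' @param preset a [melt_preset()].
#' @param seed integer seed.
#' @param condition,replicate labels recorded on the curve.
#' @return a [melt_curve()].
#' @export
gen_melt_curve <- function(preset, seed, condition = "sample",
                           replicate = 1L) {
  stopifnot(inherits(preset, "melt_preset"))
  temp <- seq(preset$t_range[1], preset$t_range[2], by = preset$step)
  with_seed(seed, {
    f <- preset$f_min + (preset$f_max - preset$f_min) /
      (1 + exp((preset$tm_true - temp) / preset$slope_true))
    f <- f + stats::rnorm(length(temp), 0, preset$noise_sd)
    melt_curve(temp, f, condition = condition,
               replicate = as.integer(replicate))
  })
}
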