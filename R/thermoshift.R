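#' Melt curve container
#'
#' One well's dye fluorescence versus temperature from a thermal-shift
#' (DSF) run.
#'
#' @param temperature deg C, strictly increasing, >= 10 points.
#' @param fluorescence arbitrary units.
#' @param condition,replicate labels.
#' @return object of class `melt_curve`.
#' @export
melt_curve <- function(temperature, fluorescence, condition = "",
                       replicate = 1L) {
  if (length(temperature) != length(fluorescence))
    stop_pepx("temperature/fluorescence length mismatch")
  if (length(temperature) < 10) stop_pepx("melt_curve needs >= 10 points")
  if (any(diff(temperature) <= 0))
    stop_pepx("temperature must be strictly increasing")
  check_finite(fluorescence, "fluorescence")
  structure(list(temperature = as.numeric(temperature),
                 fluorescence = as.numeric(fluorescence),
                 condition = condition, replicate = as.integer(replicate)),
            class = "melt_curve")
}

#' Fit a Boltzmann sigmoid to a melt curve
#'
#' Least squares of
#' `F(T) = f_min + (f_max - f_min) / (1 + exp((tm - T)/slope))` on the
#' rising limb: points after the global fluorescence maximum are discarded
#' first, since dye curves quench after the transition. `tm` is initialized
#' at the temperature of the steepest rise (max dF/dT).
#'
#' @param curve a [melt_curve()].
#' @return object of class `tm_fit`: `tm`, `slope`, `f_min`, `f_max`, their
#'   standard errors, `rss`, `converged`, `truncated_at` (deg C) and the
#'   curve's labels.
#' @export
fit_boltzmann <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  rng_all <- max(curve$fluorescence) - min(curve$fluorescence)
  noise_all <- stats::sd(diff(curve$fluorescence)) / sqrt(2)
  if (rng_all < 3 * noise_all) stop_pepx("no melting transition detected")
  peak <- which.max(curve$fluorescence)
  temp <- curve$temperature[seq_len(peak)]
  f <- curve$fluorescence[seq_len(peak)]
  if (length(temp) < 10)
    stop_pepx("fewer than 10 points before the fluorescence maximum")
  df <- diff(f) / diff(temp)
  tm0 <- temp[which.max(df)]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ fmin + (fmax - fmin) / (1 + exp((tm - temp) / slope)),
      start = list(fmin = min(f), fmax = max(f), tm = tm0, slope = 1),
      lower = c(-Inf, -Inf, min(temp), 1e-3),
      upper = c(Inf, Inf, max(temp), Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(tm = NA_real_, slope = NA_real_, f_min = NA_real_,
                          f_max = NA_real_, tm_se = NA_real_,
                          slope_se = NA_real_, rss = NA_real_,
                          converged = FALSE, truncated_at = temp[length(temp)],
                          condition = curve$condition,
                          replicate = curve$replicate),
                     class = "tm_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4), names(cf)))
  structure(list(tm = unname(cf["tm"]), slope = unname(cf["slope"]),
                 f_min = unname(cf["fmin"]), f_max = unname(cf["fmax"]),
                 tm_se = unname(se["tm"]), slope_se = unname(se["slope"]),
                 rss = sum(stats::resid(fit)^2), converged = TRUE,
                 truncated_at = temp[length(temp)],
                 condition = curve$condition, replicate = curve$replicate),
            class = "tm_fit")
}

#' @export
print.tm_fit <- function(x, ...) {
  cat(sprintf("<tm_fit> %s rep %d: Tm = %.2f C (slope %.2f C)%s\n",
              x$condition, x$replicate, x$tm, x$slope,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Melting-temperature difference between two conditions
#'
#' @param fit_a,fit_b converged [fit_boltzmann()] results.
#' @return list with `delta_tm` (`tm_a - tm_b`, deg C) and `se` (propagated
#'   standard error).
#' @export
delta_tm <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "tm_fit"), inherits(fit_b, "tm_fit"))
  if (!fit_a$converged || !fit_b$converged)
    stop_pepx("delta_tm requires converged fits")
  list(delta_tm = fit_a$tm - fit_b$tm,
       se = sqrt(fit_a$tm_se^2 + fit_b$tm_se^2))
}
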