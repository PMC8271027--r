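#' CPMG dispersion profile container
#'
#' Peak intensities of one methyl group across the CPMG frequency schedule.
#' The `nu = 0` entries are the reference plane(s); duplicated frequencies
#' are kept as independent measurements.
#'
#' @param methyl_id assignment label, e.g. `"I124-CD1"`.
#' @param nu CPMG pulse frequencies (Hz), >= 0; must include 0.
#' @param intensity peak intensities, finite.
#' @param t_cpmg constant relaxation delay (s), > 0.
#' @return object of class `dispersion_profile`.
#' @export
dispersion_profile <- function(methyl_id, nu, intensity, t_cpmg = 0.040) {
  if (length(nu) != length(intensity)) stop_pepx("nu/intensity length mismatch")
  if (any(nu < 0)) stop_pepx("nu must be >= 0")
  if (!any(nu == 0)) stop_pepx("missing nu = 0 reference plane")
  if (t_cpmg <= 0) stop_pepx("t_cpmg must be > 0")
  check_finite(intensity, "intensity")
  i_ref <- mean(intensity[nu == 0])
  if (i_ref <= 0) stop_pepx("reference intensity must be > 0")
  structure(list(methyl_id = methyl_id, nu = as.numeric(nu),
                 intensity = as.numeric(intensity), i_ref = i_ref,
                 t_cpmg = t_cpmg),
            class = "dispersion_profile")
}

#' Convert peak intensities to effective relaxation rates
#'
#' `R2_eff(nu) = (1/T_CPMG) * log(I0 / I(nu))` for every measured frequency
#' `nu > 0`. Non-positive intensities cannot be converted and are dropped
#' with a warning; intensities above the reference give negative rates,
#' which are kept but flagged.
#'
#' @param profile a [dispersion_profile()].
#' @return data.frame with columns `nu`, `r2eff`, `negative` (flag);
#'   duplicated frequencies stay as separate rows. Attributes `methyl_id`
#'   and `t_cpmg` are carried along.
#' @export
compute_r2eff <- function(profile) {
  stopifnot(inherits(profile, "dispersion_profile"))
  meas <- profile$nu > 0
  nu <- profile$nu[meas]; int <- profile$intensity[meas]
  bad <- int <= 0
  if (any(bad)) {
    warning(sprintf("%d non-positive intensities dropped for %s",
                    sum(bad), profile$methyl_id))
    nu <- nu[!bad]; int <- int[!bad]
  }
  r2 <- log(profile$i_ref / int) / profile$t_cpmg
  neg <- r2 < 0
  if (any(neg))
    warning(sprintf("%d negative R2_eff values for %s (I > I0)",
                    sum(neg), profile$methyl_id))
  out <- data.frame(nu = nu, r2eff = r2, negative = neg)
  attr(out, "methyl_id") <- profile$methyl_id
  attr(out, "t_cpmg") <- profile$t_cpmg
  out
}

#' Duplicate-based error estimate for a dispersion profile
#'
#' Pooled standard deviation of R2_eff from repeated frequencies:
#' `sigma = sqrt( sum(delta^2) / (2 m) )` over the `m` duplicate pairs,
#' where `delta` is the R2_eff difference within a pair. The default
#' schedule repeats 50 and 300 Hz for exactly this purpose. One sigma is
#' returned per profile and applied to all its points.
#'
#' @param profile a [dispersion_profile()].
#' @param fallback sigma (1/s) used, with a warning, when the schedule has
#'   no duplicates; default 0.3.
#' @return single numeric sigma (1/s).
#' @export
estimate_errors <- function(profile, fallback = 0.3) {
  r2 <- compute_r2eff(profile)
  tab <- table(r2$nu)
  dups <- as.numeric(names(tab)[tab >= 2])
  if (!length(dups)) {
    warning("no duplicated frequencies; using fallback sigma")
    return(fallback)
  }
  deltas <- unlist(lapply(dups, function(v) {
    x <- r2$r2eff[r2$nu == v]
    # successive disjoint pairs if a frequency appears more than twice
    diff(x)[seq(1, length(x) - 1, by = 2)]
  }))
  sqrt(sum(deltas^2) / (2 * length(deltas)))
}

#' Detect dispersion in an R2_eff curve
#'
#' Dispersion amplitude = mean R2_eff over the two lowest distinct
#' frequencies minus the mean over the two highest. A methyl is flagged as
#' dispersing when the amplitude strictly exceeds the threshold (default
#' 2 1/s); for a two-state exchange curve the amplitude approximates the
#' exchange contribution to relaxation at slow pulsing.
#'
#' @param r2eff_curve data.frame from [compute_r2eff()] (columns nu, r2eff).
#' @param threshold amplitude threshold (1/s), default 2.
#' @return list with `amplitude` (1/s) and `dispersing` (logical).
#' @export
detect_dispersion <- function(r2eff_curve, threshold = 2) {
  nu <- r2eff_curve$nu; r2 <- r2eff_curve$r2eff
  dist <- sort(unique(nu))
  if (length(dist) < 5) stop_pepx("need >= 5 distinct frequencies")
  lo <- dist[1:2]; hi <- dist[(length(dist) - 1):length(dist)]
  amp <- mean(r2[nu %in% lo]) - mean(r2[nu %in% hi])
  list(amplitude = amp, dispersing = amp > threshold)
}

# dispersion model is linear in (r2_0, phi) given kex: profile them out
cpmg_linear_solve <- function(nu, r2, w, kex) {
  g <- vapply(nu, function(v) {
    if (v == 0) return(1 / kex)
    x <- kex / (4 * v)
    (1 - tanh(x) / x) / kex
  }, 0)
  X <- cbind(1, g)
  fit <- stats::lm.wfit(X, r2, w)
  beta <- fit$coefficients
  if (is.na(beta[2]) || beta[2] < 0) {
    # constrained boundary: no exchange contribution
    beta <- c(sum(w * r2) / sum(w), 0)
  }
  pred <- X %*% beta
  chi2 <- sum(w * (r2 - pred)^2)
  list(r2_0 = unname(beta[1]), phi = unname(beta[2]), chi2 = chi2)
}

aicc <- function(chi2, n, p) {
  if (n - p - 1 <= 0) return(Inf)
  chi2 + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Fit the two-state fast-exchange model to a dispersion profile
#'
#' Weighted least squares of
#' `R2_eff(nu) = r2_0 + (phi/kex) * (1 - (4 nu/kex) tanh(kex/(4 nu)))`
#' against the measured R2_eff values (duplicates kept as independent
#' observations, all weighted by `1/sigma^2`). The model is linear in
#' `(r2_0, phi)` for fixed `kex`, so those are profiled exactly and only
#' `kex` is optimized numerically, multi-started from 200, 1000 and
#' 5000 1/s. The flat no-exchange model `R2_eff = r2_0` is fitted alongside
#' and both models' AICc are reported.
#'
#' @param profile a [dispersion_profile()].
#' @param sigma R2_eff uncertainty (1/s), > 0; typically from
#'   [estimate_errors()].
#' @param kex_starts multi-start values for the exchange rate (1/s).
#' @return object of class `dispersion_fit`: `model` (selected label),
#'   `r2_0`, `kex`, `phi`, standard errors, `chi2`, `rss`, `aicc`
#'   (named vector for both models), `dispersion_amplitude`, `dispersing`.
#' @export
fit_two_state <- function(profile, sigma = NULL,
                          kex_starts = c(200, 1000, 5000)) {
  stopifnot(inherits(profile, "dispersion_profile"))
  sigma <- sigma %||% estimate_errors(profile)
  if (sigma <= 0) stop_pepx("sigma must be > 0")
  r2tab <- compute_r2eff(profile)
  nu <- r2tab$nu; r2 <- r2tab$r2eff
  n <- length(nu)
  if (n < 4) stop_pepx("fewer data points than free parameters")
  if (all(r2 < 0)) stop_pepx("all R2_eff values negative; cannot fit")
  w <- rep(1 / sigma^2, n)
  obj <- function(lk) cpmg_linear_solve(nu, r2, w, exp(lk))$chi2
  sols <- lapply(kex_starts, function(ks) {
    o <- tryCatch(stats::nlminb(log(ks), obj,
                                lower = log(1), upper = log(1e7)),
                  error = function(e) NULL)
    if (is.null(o)) return(NULL)
    kex <- exp(o$par)
    c(cpmg_linear_solve(nu, r2, w, kex), list(kex = kex))
  })
  sols <- Filter(Negate(is.null), sols)
  if (!length(sols)) stop_pepx("two-state fit failed from all starts")
  best <- sols[[which.min(vapply(sols, `[[`, 0, "chi2"))]]
  flat_r2_0 <- sum(w * r2) / sum(w)
  flat_chi2 <- sum(w * (r2 - flat_r2_0)^2)
  aic <- c("no-exchange" = aicc(flat_chi2, n, 1),
           "two-state-fast" = aicc(best$chi2, n, 3))
  model <- select_model(aic)
  # parameter covariance from the weighted Jacobian at the optimum
  se <- rep(NA_real_, 3)
  if (best$phi > 0) {
    eps <- 1e-6
    jac <- cbind(
      1,
      (r2_dispersion_model(nu, 0, best$kex * (1 + eps), best$phi) -
         r2_dispersion_model(nu, 0, best$kex * (1 - eps), best$phi)) /
        (2 * eps * best$kex),
      r2_dispersion_model(nu, 0, best$kex, 1))
    jw <- jac * sqrt(w)
    cov <- tryCatch(solve(crossprod(jw)), error = function(e) NULL)
    if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
  }
  disp <- detect_dispersion(r2tab)
  structure(list(methyl_id = profile$methyl_id, model = model,
                 r2_0 = best$r2_0, kex = best$kex, phi = best$phi,
                 r2_0_se = se[1], kex_se = se[2], phi_se = se[3],
                 chi2 = best$chi2, rss = best$chi2 * sigma^2,
                 sigma = sigma, aicc = aic,
                 flat_r2_0 = flat_r2_0, flat_chi2 = flat_chi2,
                 dispersion_amplitude = disp$amplitude,
                 dispersing = disp$dispersing),
            class = "dispersion_fit")
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat(sprintf(
    "<dispersion_fit> %s: model %s; r2_0 = %.3g, kex = %.4g, phi = %.4g; amplitude %.2f 1/s\n",
    x$methyl_id, x$model, x$r2_0, x$kex, x$phi, x$dispersion_amplitude))
  invisible(x)
}

#' Select between the no-exchange and two-state models
#'
#' Minimum AICc wins; on a tie the flat (no-exchange) model is kept for
#' parsimony.
#'
#' @param aicc_values named numeric vector with entries `"no-exchange"` and
#'   `"two-state-fast"` (as produced by [fit_two_state()]), or a
#'   `dispersion_fit`.
#' @return the chosen model label.
#' @export
select_model <- function(aicc_values) {
  if (inherits(aicc_values, "dispersion_fit")) aicc_values <- aicc_values$aicc
  stopifnot(all(c("no-exchange", "two-state-fast") %in% names(aicc_values)))
  if (aicc_values[["two-state-fast"]] < aicc_values[["no-exchange"]])
    "two-state-fast" else "no-exchange"
}
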