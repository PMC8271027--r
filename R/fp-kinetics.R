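#' FP trace container
#'
#' One well's fluorescence-polarization time series with condition metadata.
#'
#' @param time seconds, strictly increasing, length >= 8.
#' @param fp polarization values (arbitrary FP units).
#' @param allotype,catalyst,replicate condition labels.
#' @param role `"sample"` or `"baseline"` (free-FITC-peptide well).
#' @param baseline_ref optional linked baseline trace.
#' @param baseline_subtracted logical flag set by [subtract_baseline()].
#' @return object of class `fp_trace`.
#' @export
fp_trace <- function(time, fp, allotype = NA_character_,
                     catalyst = NA_character_, replicate = 1L,
                     role = "sample", baseline_ref = NULL,
                     baseline_subtracted = FALSE) {
  if (length(time) != length(fp)) stop_pepx("time and fp lengths differ")
  if (length(time) < 8) stop_pepx("fp_trace needs >= 8 points")
  if (any(diff(time) <= 0)) stop_pepx("time must be strictly increasing")
  check_finite(time, "time"); check_finite(fp, "fp")
  structure(list(time = as.numeric(time), fp = as.numeric(fp),
                 allotype = allotype, catalyst = catalyst,
                 replicate = as.integer(replicate), role = role,
                 baseline_ref = baseline_ref,
                 baseline_subtracted = isTRUE(baseline_subtracted)),
            class = "fp_trace")
}

#' @export
print.fp_trace <- function(x, ...) {
  cat(sprintf("<fp_trace> %s / %s rep %d, %d points over %.0f s%s\n",
              x$allotype, x$catalyst, x$replicate, length(x$time),
              max(x$time),
              if (x$baseline_subtracted) " (baseline-subtracted)" else ""))
  invisible(x)
}

#' Subtract the free-peptide baseline from an FP trace
#'
#' Reproduces the "dFP" signal: the polarization of wells containing only the
#' labeled peptide is removed from the sample well. When the baseline trace
#' shares the sample's time grid it is subtracted pointwise; otherwise (or
#' when `constant = TRUE`) its mean is subtracted as a constant.
#'
#' @param trace sample [fp_trace()].
#' @param baseline baseline [fp_trace()] (defaults to `trace$baseline_ref`),
#'   or a single number.
#' @param constant force constant-mode (mean of the baseline trace).
#' @return baseline-subtracted [fp_trace()].
#' @export
subtract_baseline <- function(trace, baseline = NULL, constant = FALSE) {
  stopifnot(inherits(trace, "fp_trace"))
  baseline <- baseline %||% trace$baseline_ref
  if (is.null(baseline)) stop_pepx("no baseline given or linked")
  if (is.numeric(baseline) && length(baseline) == 1) {
    adj <- trace$fp - baseline
  } else {
    stopifnot(inherits(baseline, "fp_trace"))
    same_grid <- length(baseline$time) == length(trace$time) &&
      all(abs(baseline$time - trace$time) < 1e-9 * max(1, max(trace$time)))
    if (same_grid && !constant) {
      adj <- trace$fp - baseline$fp
    } else if (constant) {
      adj <- trace$fp - mean(baseline$fp)
    } else {
      stop_pepx(paste("baseline grid does not match the sample grid;",
                      "use constant = TRUE to subtract its mean"))
    }
  }
  out <- trace
  out$fp <- adj
  out$baseline_subtracted <- TRUE
  out
}

# rough per-trace noise scale from lag-1 differences (signal is smooth on the
# sampling grid, so successive differences are dominated by noise)
estimate_fp_noise <- function(fp) {
  stats::sd(diff(fp)) / sqrt(2)
}

#' Fit the exponential association model to an FP trace
#'
#' Least-squares fit of `Y = Y0 - A * exp(-K * t)` where `Y0` is the plateau,
#' `A` the association amplitude and `K` the observed association rate
#' (reported as K_on). Starting values: `Y0 = max(fp)`,
#' `A = max(fp) - min(fp)`, and `K = log(2) / t_half` with `t_half` the first
#' crossing of the half-range; the fit is multi-started over
#' `K * c(0.1, 1, 10)` and the lowest-RSS solution kept.
#'
#' @param trace a baseline-subtracted [fp_trace()].
#' @param require_subtracted error if the trace is not marked
#'   baseline-subtracted (default TRUE).
#' @return object of class `kinetics_fit`: `y0`, `a`, `k_on`, standard
#'   errors (`y0_se`, `a_se`, `k_on_se`), `rss`, `converged`, and the
#'   condition metadata of the trace.
#' @export
fit_association <- function(trace, require_subtracted = TRUE) {
  stopifnot(inherits(trace, "fp_trace"))
  if (require_subtracted && !trace$baseline_subtracted)
    stop_pepx("trace is not baseline-subtracted (see subtract_baseline)")
  t <- trace$time; y <- trace$fp
  rng <- max(y) - min(y)
  noise <- estimate_fp_noise(y)
  if (rng < 3 * noise)
    stop_pepx("no association detected: signal range %.3g < 3 x noise %.3g",
              rng, noise)
  half <- (max(y) + min(y)) / 2
  idx <- which(y >= half)[1]
  t_half <- if (is.na(idx) || t[idx] <= 0) t[2] else t[idx]
  k0 <- log(2) / t_half
  fits <- lapply(k0 * c(0.1, 1, 10), function(ks) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ y0 - a * exp(-k * t),
        start = list(y0 = max(y), a = rng, k = ks),
        lower = c(-Inf, 1e-12, 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  cond <- list(allotype = trace$allotype, catalyst = trace$catalyst,
               replicate = trace$replicate)
  if (!length(fits)) {
    return(structure(c(list(y0 = NA_real_, a = NA_real_, k_on = NA_real_,
                            y0_se = NA_real_, a_se = NA_real_,
                            k_on_se = NA_real_, rss = NA_real_,
                            converged = FALSE,
                            diagnostics = "all starts failed"), cond),
                     class = "kinetics_fit"))
  }
  rss <- vapply(fits, function(f) sum(stats::resid(f)^2), 0)
  best <- fits[[which.min(rss)]]
  cf <- coef(best)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  structure(c(list(y0 = unname(cf["y0"]), a = unname(cf["a"]),
                   k_on = unname(cf["k"]),
                   y0_se = unname(se[1]), a_se = unname(se[2]),
                   k_on_se = unname(se[3]),
                   rss = min(rss), converged = TRUE, diagnostics = NULL),
              cond),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetics_fit> %s / %s rep %d: K_on = %.4g 1/s (Y0 = %.4g, A = %.4g)%s\n",
    x$allotype, x$catalyst, x$replicate, x$k_on, x$y0, x$a,
    if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Catalyst fold change of the observed association rate
#'
#' @param k_cat catalyzed rate(s) (1/s), > 0.
#' @param k_uncat uncatalyzed rate (1/s), > 0.
#' @return `k_cat / k_uncat`.
#' @export
fold_change <- function(k_cat, k_uncat) {
  if (any(k_uncat <= 0)) stop_pepx("k_uncat must be > 0")
  if (any(k_cat <= 0)) stop_pepx("k_cat must be > 0")
  k_cat / k_uncat
}

#' Relative catalytic activity of a catalyst mutant
#'
#' `(k_mut - k_none) / (k_wt - k_none)`: 1 for wild-type-like activity, 0 for
#' a mutant no better than the uncatalyzed reaction. Values below 0 or above
#' 1 are reported unclamped.
#'
#' @param k_mut,k_wt,k_none mutant-catalyzed, WT-catalyzed and uncatalyzed
#'   rates (1/s).
#' @return dimensionless relative activity.
#' @export
relative_activity <- function(k_mut, k_wt, k_none) {
  if (any(k_wt == k_none))
    stop_pepx("relative activity undefined: k_wt equals k_none")
  (k_mut - k_none) / (k_wt - k_none)
}

#' Welch's unequal-variance two-sample t test
#'
#' Two-sided Welch test with Welch--Satterthwaite degrees of freedom, used to
#' compare mutant and wild-type replicate rates.
#'
#' @param group_a,group_b numeric vectors, each with >= 2 values.
#' @return list with `t`, `dof`, `p_value`.
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_pepx("each group needs >= 2 values")
  if (var(group_a) == 0 && var(group_b) == 0)
    stop_pepx("both groups have zero variance; t test undefined")
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(tt$statistic), dof = unname(tt$parameter),
       p_value = unname(tt$p.value))
}

fits_to_frame <- function(fits) {
  if (is.data.frame(fits)) return(fits)
  do.call(rbind, lapply(fits, function(f) {
    stopifnot(inherits(f, "kinetics_fit"))
    data.frame(allotype = f$allotype, catalyst = f$catalyst,
               replicate = f$replicate, k_on = f$k_on,
               converged = f$converged, stringsAsFactors = FALSE)
  }))
}

#' Summarize replicate fits into fold changes and relative activities
#'
#' Groups per-trace fits by (allotype, catalyst), averages K_on over
#' replicates, and derives the downstream statistics: fold change of each
#' catalyst versus the uncatalyzed (`"none"`) condition of the same allotype,
#' relative catalytic activity versus the wild-type catalyst where one is
#' present, and Welch tests of mutant versus wild-type replicate rates.
#' Fold-change SDs come from first-order propagation of the two replicate
#' SDs; relative-activity SDs propagate all three.
#'
#' @param fits list of [fit_association()] results (or an equivalent
#'   data.frame with columns allotype, catalyst, replicate, k_on, converged).
#' @param wt_catalyst label of the wild-type catalyst condition used as the
#'   relative-activity reference, default `"Tsn-WT"`.
#' @return object of class `exchange_summary`: a data.frame with one row per
#'   condition (mean/SD of K_on, n, fold_change and its SD, relative_activity
#'   and its SD, Welch t/dof/p versus WT).
#' @export
summarize_conditions <- function(fits, wt_catalyst = "Tsn-WT") {
  df <- fits_to_frame(fits)
  df <- df[df$converged, , drop = FALSE]
  if (!nrow(df)) stop_pepx("no converged fits to summarize")
  key <- interaction(df$allotype, df$catalyst, drop = TRUE)
  agg <- do.call(rbind, lapply(split(df, key), function(g) {
    data.frame(allotype = g$allotype[1], catalyst = g$catalyst[1],
               n = nrow(g), k_on_mean = mean(g$k_on),
               k_on_sd = if (nrow(g) > 1) sd(g$k_on) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  out <- do.call(rbind, lapply(split(agg, agg$allotype), function(a) {
    none <- a[a$catalyst == "none", , drop = FALSE]
    if (!nrow(none))
      stop_pepx("allotype %s lacks an uncatalyzed ('none') condition",
                a$allotype[1])
    m0 <- none$k_on_mean; s0 <- none$k_on_sd
    a$fold_change <- a$k_on_mean / m0
    a$fold_change_sd <- a$fold_change *
      sqrt((a$k_on_sd / a$k_on_mean)^2 + (s0 / m0)^2)
    wt <- a[a$catalyst == wt_catalyst, , drop = FALSE]
    a$relative_activity <- NA_real_
    a$relative_activity_sd <- NA_real_
    a$t_statistic <- NA_real_; a$dof <- NA_real_; a$p_value <- NA_real_
    if (nrow(wt)) {
      mw <- wt$k_on_mean
      a$relative_activity <- (a$k_on_mean - m0) / (mw - m0)
      # d(ra)/dk terms; propagate replicate SDs of the three means
      denom <- mw - m0
      a$relative_activity_sd <- sqrt(
        (a$k_on_sd / denom)^2 +
          (wt$k_on_sd * (a$k_on_mean - m0) / denom^2)^2 +
          (s0 * (a$k_on_mean - mw) / denom^2)^2)
      wt_k <- df$k_on[df$allotype == a$allotype[1] &
                        df$catalyst == wt_catalyst]
      for (i in seq_len(nrow(a))) {
        ci <- a$catalyst[i]
        if (ci %in% c("none", wt_catalyst)) next
        gi <- df$k_on[df$allotype == a$allotype[1] & df$catalyst == ci]
        if (length(gi) >= 2 && length(wt_k) >= 2 &&
            (var(gi) > 0 || var(wt_k) > 0)) {
          wt_test <- welch_t_test(gi, wt_k)
          a$t_statistic[i] <- wt_test$t
          a$dof[i] <- wt_test$dof
          a$p_value[i] <- wt_test$p_value
        }
      }
    }
    a
  }))
  rownames(out) <- NULL
  class(out) <- c("exchange_summary", "data.frame")
  out
}

#' Fit every (sample, baseline) trace pair of a condition set
#'
#' Convenience wrapper: simulates `n_replicates` seeded trace pairs per
#' preset, subtracts baselines (constant mode: mean of the baseline well) and
#' fits each sample trace.
#'
#' @param presets list of [fp_preset()] objects.
#' @param seed integer base seed; replicate r of preset i uses a distinct
#'   sub-seed derived from it.
#' @return list of [fit_association()] results.
#' @export
fit_preset_conditions <- function(presets, seed) {
  fits <- list()
  for (i in seq_along(presets)) {
    p <- presets[[i]]
    for (r in seq_len(p$n_replicates)) {
      sub <- (as.integer(seed) + 7919L * i + 104729L * r) %% .Machine$integer.max
      tr <- gen_fp_trace(p, seed = sub, replicate = r)
      d <- subtract_baseline(tr$sample, tr$baseline, constant = TRUE)
      fits[[length(fits) + 1L]] <- fit_association(d)
    }
  }
  fits
}
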