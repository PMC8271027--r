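#' Ground-truth parameter presets for the synthetic generators
#'
#' Each preset constructor validates its fields and returns a plain list with a
#' class tag. Presets hold the *true* parameters from which synthetic data are
#' generated, so that every downstream fitter can be checked against known
#' ground truth. The catalog of FP presets calibrated to published summary
#' statistics lives in [preset_table()].
#'
#' @name presets
NULL

#' FP association-kinetics preset
#'
#' Truth for one (allotype, catalyst) condition of the FP peptide-exchange
#' assay. The generated signal is
#' \deqn{FP(t) = baseline + Y_0 - A e^{-K t} + \epsilon,}
#' i.e. an exponential association on top of the free-FITC-peptide baseline.
#'
#' @param allotype MHC-I allotype label, e.g. `"A*03:01"`.
#' @param catalyst catalyst label: `"none"`, `"Tsn-WT"`, `"TAPBPR"` or a
#'   tapasin scoop-loop mutant name.
#' @param k_true true observed association rate constant (1/s); must be > 0.
#' @param y0_true plateau (maximum) polarization above baseline, FP units.
#' @param a_true association amplitude, FP units; must be > 0.
#' @param baseline_true free-peptide polarization, FP units.
#' @param noise_sd Gaussian noise SD, FP units.
#' @param n_timepoints number of time points (>= 8).
#' @param t_end last time point (s). Default scales with the rate so the
#'   rise is resolved, bounded to the 1--5 h plate-reader window.
#' @param n_replicates replicate wells per condition.
#' @return object of class `fp_preset`.
#' @export
fp_preset <- function(allotype, catalyst, k_true,
                      y0_true = 150, a_true = 150, baseline_true = 35,
                      noise_sd = 2, n_timepoints = 40,
                      t_end = NULL, n_replicates = 3) {
  t_end <- t_end %||% min(18000, max(3600, 6 / k_true))
  num <- c(k_true = k_true, y0_true = y0_true, a_true = a_true,
           baseline_true = baseline_true, noise_sd = noise_sd,
           n_timepoints = n_timepoints, t_end = t_end,
           n_replicates = n_replicates)
  check_finite(num, "fp_preset fields")
  if (k_true <= 0) stop_pepx("k_true must be > 0")
  if (a_true <= 0) stop_pepx("a_true must be > 0")
  if (n_timepoints < 8) stop_pepx("n_timepoints must be >= 8")
  if (noise_sd < 0) stop_pepx("noise_sd must be >= 0")
  structure(list(allotype = allotype, catalyst = catalyst, k_true = k_true,
                 y0_true = y0_true, a_true = a_true,
                 baseline_true = baseline_true, noise_sd = noise_sd,
                 n_timepoints = as.integer(n_timepoints), t_end = t_end,
                 n_replicates = as.integer(n_replicates)),
            class = "fp_preset")
}

# 15-point constant-time CPMG schedule with duplicates at 50 and 300 Hz;
# the 0 Hz entry is the reference plane.
#' @export
#' @rdname cpmg_preset
default_nu_schedule <- function() {
  c(0, 950, 50, 300, 150, 800, 100, 250, 400, 600, 200, 50, 500, 300, 700)
}

#' CPMG relaxation-dispersion preset
#'
#' Truth for one methyl group's dispersion profile under the two-state
#' fast-exchange (Luz--Meiboom) model
#' \deqn{R_2(\nu) = R_{2,0} + \frac{\phi}{k_{ex}}
#'   \left(1 - \frac{4\nu}{k_{ex}} \tanh\frac{k_{ex}}{4\nu}\right)}
#' with \eqn{\phi = p_a p_b \Delta\omega^2}.
#'
#' @param r2_0 intrinsic transverse relaxation rate (1/s), >= 0.
#' @param kex exchange rate (1/s), > 0.
#' @param phi exchange amplitude (1/s^2), >= 0.
#' @param t_cpmg constant relaxation delay (s).
#' @param nu_schedule CPMG pulse frequencies (Hz); 0 marks the reference.
#' @param i_ref reference peak intensity at nu = 0.
#' @param noise_sd intensity noise SD.
#' @param methyl_id assignment label.
#' @return object of class `cpmg_preset`.
#' @export
cpmg_preset <- function(r2_0, kex, phi, t_cpmg = 0.040,
                        nu_schedule = default_nu_schedule(),
                        i_ref = 1e6, noise_sd = 0.01 * i_ref,
                        methyl_id = "M1") {
  check_finite(c(r2_0, kex, phi, t_cpmg, nu_schedule, i_ref, noise_sd),
               "cpmg_preset fields")
  if (r2_0 < 0) stop_pepx("r2_0 must be >= 0")
  if (kex <= 0) stop_pepx("kex must be > 0")
  if (phi < 0) stop_pepx("phi must be >= 0")
  if (t_cpmg <= 0) stop_pepx("t_cpmg must be > 0")
  if (any(nu_schedule < 0)) stop_pepx("nu_schedule values must be >= 0")
  if (i_ref <= 0) stop_pepx("i_ref must be > 0")
  structure(list(r2_0 = r2_0, kex = kex, phi = phi, t_cpmg = t_cpmg,
                 nu_schedule = nu_schedule, i_ref = i_ref,
                 noise_sd = noise_sd, methyl_id = methyl_id),
            class = "cpmg_preset")
}

#' Paired HSQC peak-list preset
#'
#' Truth for a reference/perturbed pair of amide peak lists: per-residue
#' intensity attenuations (true I/I0) and chemical-shift changes.
#'
#' @param residues character vector of unique assignment ids (e.g. "T143").
#' @param attenuation_map named numeric vector of true I/I0 per id (positive);
#'   ids not named keep ratio 1.
#' @param shift_map optional named list `id -> c(dH, dN)` in ppm.
#' @param intensity_scale base reference intensity.
#' @param noise_sd intensity noise SD.
#' @return object of class `peakpair_preset`.
#' @export
peakpair_preset <- function(residues, attenuation_map = NULL,
                            shift_map = NULL, intensity_scale = 1e5,
                            noise_sd = 0) {
  if (anyDuplicated(residues)) stop_pepx("residue ids must be unique")
  att <- setNames(rep(1, length(residues)), residues)
  if (!is.null(attenuation_map)) {
    bad <- setdiff(names(attenuation_map), residues)
    if (length(bad)) stop_pepx("attenuation for unknown id: %s", bad[1])
    if (any(attenuation_map < 0)) stop_pepx("attenuations must be >= 0")
    att[names(attenuation_map)] <- attenuation_map
  }
  structure(list(residues = residues, attenuation_map = att,
                 shift_map = shift_map %||% list(),
                 intensity_scale = intensity_scale, noise_sd = noise_sd),
            class = "peakpair_preset")
}

#' Thermal-shift melt-curve preset
#'
#' Truth for one Boltzmann melt:
#' \deqn{F(T) = F_{min} + \frac{F_{max}-F_{min}}{1+e^{(T_m - T)/s}}.}
#'
#' @param tm_true melting temperature (deg C), inside `t_range`.
#' @param slope_true transition width (deg C), > 0.
#' @param f_min,f_max pre-/post-transition fluorescence; `f_max > f_min`.
#' @param t_range temperature window (deg C), default 25--95.
#' @param step temperature step (deg C), > 0.
#' @param noise_sd fluorescence noise SD.
#' @return object of class `melt_preset`.
#' @export
melt_preset <- function(tm_true, slope_true = 1.5, f_min = 1000,
                        f_max = 9000, t_range = c(25, 95), step = 0.5,
                        noise_sd = 0) {
  check_finite(c(tm_true, slope_true, f_min, f_max, t_range, step, noise_sd),
               "melt_preset fields")
  if (step <= 0) stop_pepx("step must be > 0")
  if (slope_true <= 0) stop_pepx("slope_true must be > 0")
  if (f_max <= f_min) stop_pepx("f_max must exceed f_min")
  if (tm_true <= t_range[1] || tm_true >= t_range[2])
    stop_pepx("tm_true must lie inside t_range")
  structure(list(tm_true = tm_true, slope_true = slope_true,
                 f_min = f_min, f_max = f_max, t_range = t_range,
                 step = step, noise_sd = noise_sd),
            class = "melt_preset")
}

# Published summary statistics the FP presets are calibrated to: fold change
# of K_on vs the uncatalyzed reaction for WT catalysts, relative catalytic
# activity (K_mut - K_none)/(K_WT - K_none) for scoop-loop mutants.
# "Abolished"/"same as WT" qualitative calls are encoded as 0 / 1.
fp_calibration <- function() {
  fc <- data.frame(
    allotype = c("A*02:01", "A*03:01", "B*27:05", "B*27:09",
                 "A*02:01", "A*03:01", "B*27:05", "B*27:09"),
    catalyst = rep(c("Tsn-WT", "TAPBPR"), each = 4),
    fold_change = c(1.31, 10.89, 5.83, 3.83, 30.9, 34.28, 1.48, 3.13),
    fold_change_sd = c(0.08, 1.48, 1.06, 0.07, 1.12, 5.3, 0.23, 0.23),
    stringsAsFactors = FALSE
  )
  ra <- data.frame(
    allotype = c(rep("A*03:01", 9), rep("B*27:05", 3), rep("B*27:09", 9)),
    catalyst = c("L18G", "K16G", "GGGGG", "K16L", "L18K", "GGGGL", "GGGGK",
                 "GGKGG", "GGLGG",
                 "L18G", "K16G", "GGGGG",
                 "L18G", "K16G", "GGGGG", "K16L", "L18K", "GGGGL", "GGGGK",
                 "GGKGG", "GGLGG"),
    relative_activity = c(0.36, 0.77, 0.01, 0.93, 0.00, 0.40, 0.23,
                          1.00, 0.35,
                          0.05, 0.86, 0.02,
                          0.04, 0.95, 0.03, 1.26, 0.00, 0.77, 0.00,
                          0.00, 1.00),
    relative_activity_sd = c(0.06, 0.12, 0.01, 0.16, NA, 0.12, 0.05,
                             NA, 0.05,
                             0.02, 0.05, 0.01,
                             0.06, 0.15, 0.02, 0.06, NA, 0.14, NA,
                             NA, NA),
    stringsAsFactors = FALSE
  )
  list(fold_changes = fc, relative_activities = ra)
}

#' Catalog of calibrated FP presets
#'
#' Builds the full table of FP ground-truth presets for every (allotype,
#' catalyst) condition whose fold change or relative catalytic activity is
#' encoded in the calibration table. Rates are anchored to an arbitrary
#' uncatalyzed rate `k_none` (only *ratios* of rates are calibrated):
#' catalyzed rates are `k_none * fold_change`, and scoop-loop-mutant rates
#' invert the relative-activity formula,
#' `k_mut = k_none + activity * (k_wt - k_none)`.
#'
#' @param k_none uncatalyzed association rate (1/s), default 1e-4.
#' @param noise_sd FP noise SD passed to every preset.
#' @param n_replicates replicates per condition.
#' @return data.frame with one row per condition: allotype, catalyst,
#'   k_true, the calibrated fold_change / relative_activity (NA where not
#'   applicable) and their published SDs, plus generator settings. Attribute
#'   `"presets"` holds the corresponding list of [fp_preset()] objects keyed
#'   `"<allotype>|<catalyst>"`.
#' @export
preset_table <- function(k_none = 1e-4, noise_sd = 2, n_replicates = 3) {
  if (k_none <= 0) stop_pepx("k_none must be > 0")
  cal <- fp_calibration()
  rows <- data.frame(allotype = unique(c(cal$fold_changes$allotype,
                                         cal$relative_activities$allotype)),
                     stringsAsFactors = FALSE)
  out <- data.frame(allotype = rows$allotype, catalyst = "none",
                    k_true = k_none, fold_change = 1, fold_change_sd = NA_real_,
                    relative_activity = NA_real_,
                    relative_activity_sd = NA_real_,
                    stringsAsFactors = FALSE)
  fc <- cal$fold_changes
  fc$k_true <- k_none * fc$fold_change
  fc$relative_activity <- ifelse(fc$catalyst == "Tsn-WT", 1, NA_real_)
  fc$relative_activity_sd <- NA_real_
  ra <- cal$relative_activities
  k_wt <- setNames(fc$k_true[fc$catalyst == "Tsn-WT"],
                   fc$allotype[fc$catalyst == "Tsn-WT"])
  ra$k_true <- k_none + ra$relative_activity * (k_wt[ra$allotype] - k_none)
  ra$fold_change <- ra$k_true / k_none
  ra$fold_change_sd <- NA_real_
  cols <- c("allotype", "catalyst", "k_true", "fold_change", "fold_change_sd",
            "relative_activity", "relative_activity_sd")
  tab <- rbind(out[, cols], fc[, cols], ra[, cols])
  tab <- tab[order(tab$allotype, tab$catalyst != "none", tab$catalyst), ]
  rownames(tab) <- NULL
  tab$noise_sd <- noise_sd
  tab$n_replicates <- as.integer(n_replicates)
  presets <- lapply(seq_len(nrow(tab)), function(i) {
    fp_preset(tab$allotype[i], tab$catalyst[i], tab$k_true[i],
              noise_sd = noise_sd, n_replicates = n_replicates)
  })
  names(presets) <- paste(tab$allotype, tab$catalyst, sep = "|")
  attr(tab, "presets") <- presets
  class(tab) <- c("preset_table", "data.frame")
  tab
}

#' Look up one calibrated FP preset
#'
#' @param allotype,catalyst condition labels as in [preset_table()].
#' @param table optionally a precomputed [preset_table()].
#' @param ... passed to [preset_table()] when `table` is NULL.
#' @return an [fp_preset()].
#' @export
get_preset <- function(allotype, catalyst, table = NULL, ...) {
  table <- table %||% preset_table(...)
  key <- paste(allotype, catalyst, sep = "|")
  p <- attr(table, "presets")[[key]]
  if (is.null(p)) stop_pepx("no preset for condition %s", key)
  p
}
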