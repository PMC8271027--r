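#' Run configuration
#'
#' A single hierarchical configuration drives every pipeline stage. Defaults
#' encode the assay constants (40 ms CPMG constant-time delay, the 15-point
#' frequency schedule, the 2 1/s dispersion threshold, the mean - delta
#' attenuation rule) and can be overridden per key; unknown keys are
#' rejected by name.
#'
#' @param ... key = value overrides, or a single named list.
#' @param file optional YAML file read before applying `...` overrides.
#' @return object of class `pepx_config` (a named list).
#' @export
pepx_config <- function(..., file = NULL) {
  defaults <- list(
    seed = 1L,
    out_dir = "pepx-out",
    time_unit = "s",
    t_cpmg = 0.040,
    nu_schedule = default_nu_schedule(),
    dispersion_threshold = 2,
    sigma_fallback = 0.3,
    clamp_lo = 0.30,
    clamp_hi = 0.70,
    default_value = -1,
    chain = "A",
    wt_catalyst = "Tsn-WT",
    allotypes = c("A*02:01", "A*03:01", "B*27:05", "B*27:09"),
    catalysts = c("none", "Tsn-WT", "TAPBPR"),
    k_none = 1e-4,
    noise_sd = 2,
    n_replicates = 3L,
    inputs = list()
  )
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  if (!is.null(file)) over <- utils::modifyList(yaml::read_yaml(file), over)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop_pepx("unknown config key: %s", bad[1])
  cfg <- utils::modifyList(defaults, over)
  if (cfg$dispersion_threshold <= 0 || cfg$sigma_fallback <= 0)
    stop_pepx("thresholds must be positive")
  structure(cfg, class = "pepx_config")
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

manifest_add <- function(config, stage, paths) {
  mf <- file.path(config$out_dir, "manifest.jsonl")
  for (p in paths) {
    cat(jsonlite::toJSON(list(stage = stage, seed = config$seed, path = p),
                         auto_unbox = TRUE), "\n", file = mf, append = TRUE)
  }
  invisible(mf)
}

stage_synth <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- preset_table(k_none = config$k_none, noise_sd = config$noise_sd,
                      n_replicates = config$n_replicates)
  keep <- tab$allotype %in% config$allotypes &
    tab$catalyst %in% config$catalysts
  presets <- attr(tab, "presets")[keep]
  traces <- list()
  idx <- 0L
  for (p in presets) {
    idx <- idx + 1L
    for (r in seq_len(p$n_replicates)) {
      sub <- (config$seed + 7919L * idx + 104729L * r) %% .Machine$integer.max
      tr <- gen_fp_trace(p, seed = sub, replicate = r)
      traces <- c(traces, list(tr$sample, tr$baseline))
    }
  }
  fp_csv <- file.path(config$out_dir, "fp_traces.csv")
  fp_layout <- file.path(config$out_dir, "fp_layout.tsv")
  write_fp_plate(traces, fp_csv, fp_layout, time_unit = config$time_unit)

  cp <- cpmg_preset(r2_0 = 12, kex = 1500, phi = 1.2e4, t_cpmg = config$t_cpmg,
                    nu_schedule = config$nu_schedule, methyl_id = "I124-CD1")
  cp_flat <- cpmg_preset(r2_0 = 15, kex = 1000, phi = 0,
                         t_cpmg = config$t_cpmg,
                         nu_schedule = config$nu_schedule,
                         methyl_id = "L95-CD2")
  prof <- gen_cpmg_profile(cp, seed = config$seed + 11L)
  prof2 <- gen_cpmg_profile(cp_flat, seed = config$seed + 12L)
  cpmg_tsv <- file.path(config$out_dir, "cpmg_profiles.tsv")
  write_tsv_plain(rbind(
    data.frame(methyl_id = prof$methyl_id, nu_hz = prof$nu,
               intensity = prof$intensity),
    data.frame(methyl_id = prof2$methyl_id, nu_hz = prof2$nu,
               intensity = prof2$intensity)), cpmg_tsv)

  ids <- c("L95", "N97", "A117", "D120", "I124", "L126", "L130", "T143",
           "A151", "R79", "E76", "D77", "K146", "V152", "I23", "V34",
           "L40", "I52", "A69", "L78")
  pp <- peakpair_preset(ids,
                        attenuation_map = c(T143 = 0.2, N97 = 0.3,
                                            A117 = 0.35, R79 = 0.4),
                        intensity_scale = 1e5, noise_sd = 1e3)
  pair <- gen_peaklist_pair(pp, seed = config$seed + 21L)
  ref_tsv <- file.path(config$out_dir, "peaks_reference.tsv")
  pert_tsv <- file.path(config$out_dir, "peaks_perturbed.tsv")
  write_peaklist_tsv(pair$reference, ref_tsv)
  write_peaklist_tsv(pair$perturbed, pert_tsv)

  m_hi <- melt_preset(tm_true = 66, noise_sd = 80)
  m_lo <- melt_preset(tm_true = 60, noise_sd = 80)
  curves <- list()
  for (r in 1:3) {
    curves <- c(curves,
                list(gen_melt_curve(m_hi, seed = config$seed + 30L + r,
                                    condition = "photoRL9", replicate = r),
                     gen_melt_curve(m_lo, seed = config$seed + 40L + r,
                                    condition = "photoIF9", replicate = r)))
  }
  melt_csv <- file.path(config$out_dir, "melt_curves.csv")
  write_melt_csv(curves, melt_csv)

  paths <- c(fp_csv, fp_layout, cpmg_tsv, ref_tsv, pert_tsv, melt_csv)
  manifest_add(config, "synth", paths)
  stage_log("synth", "seed %d: wrote %d artifacts to %s", config$seed,
            length(paths), config$out_dir)
  invisible(paths)
}

stage_fitfp <- function(config) {
  fp_csv <- config$inputs$fp_csv %||% file.path(config$out_dir,
                                                "fp_traces.csv")
  fp_layout <- config$inputs$fp_layout %||% file.path(config$out_dir,
                                                      "fp_layout.tsv")
  traces <- read_fp_plate(fp_csv, fp_layout, time_unit = config$time_unit)
  samples <- Filter(function(t) t$role == "sample", traces)
  fits <- lapply(samples, function(t) {
    fit_association(subtract_baseline(t, constant = TRUE))
  })
  summary <- summarize_conditions(fits, wt_catalyst = config$wt_catalyst)
  fits_csv <- file.path(config$out_dir, "fp_fits.csv")
  sum_csv <- file.path(config$out_dir, "fp_summary.csv")
  write.csv(fits_to_frame(fits), fits_csv, row.names = FALSE, quote = FALSE)
  write.csv(as.data.frame(summary), sum_csv, row.names = FALSE, quote = FALSE)
  manifest_add(config, "fitfp", c(fits_csv, sum_csv))
  stage_log("fitfp", "%s: %d traces fitted", fp_csv, length(fits))
  invisible(c(fits_csv, sum_csv))
}

stage_cpmg <- function(config) {
  tsv <- config$inputs$cpmg_tsv %||% file.path(config$out_dir,
                                               "cpmg_profiles.tsv")
  profiles <- read_cpmg_tsv(tsv, t_cpmg = config$t_cpmg)
  rows <- lapply(profiles, function(p) {
    sigma <- tryCatch(estimate_errors(p, fallback = config$sigma_fallback),
                      warning = function(w) config$sigma_fallback)
    if (sigma <= 0) sigma <- config$sigma_fallback
    f <- fit_two_state(p, sigma = sigma)
    data.frame(methyl_id = p$methyl_id, model = f$model, r2_0 = f$r2_0,
               kex = f$kex, phi = f$phi,
               amplitude = f$dispersion_amplitude,
               dispersing = f$dispersion_amplitude >
                 config$dispersion_threshold,
               sigma = sigma, stringsAsFactors = FALSE)
  })
  out <- file.path(config$out_dir, "cpmg_fits.csv")
  write.csv(do.call(rbind, rows), out, row.names = FALSE, quote = FALSE)
  manifest_add(config, "cpmg", out)
  stage_log("cpmg", "%s: %d profiles fitted", tsv, length(profiles))
  invisible(out)
}

stage_ratio <- function(config) {
  ref <- config$inputs$peaklist_ref %||% file.path(config$out_dir,
                                                   "peaks_reference.tsv")
  pert <- config$inputs$peaklist_pert %||% file.path(config$out_dir,
                                                     "peaks_perturbed.tsv")
  tab <- flag_attenuated(intensity_ratios(match_peaks(
    read_peaklist_tsv(ref), read_peaklist_tsv(pert))))
  ratio_csv <- file.path(config$out_dir, "ratios.csv")
  value_csv <- file.path(config$out_dir, "residue_values.csv")
  write_ratio_csv(tab, ratio_csv, value_path = value_csv,
                  chain = config$chain)
  manifest_add(config, "ratio", c(ratio_csv, value_csv))
  stage_log("ratio", "%d residues, %d attenuated", nrow(tab),
            sum(tab$attenuated, na.rm = TRUE))
  invisible(c(ratio_csv, value_csv))
}

stage_map <- function(config) {
  pdb_in <- config$inputs$pdb
  if (is.null(pdb_in)) stop_pepx("map stage requires inputs$pdb")
  value_csv <- config$inputs$value_csv %||% file.path(config$out_dir,
                                                      "residue_values.csv")
  vmap <- read_value_csv(value_csv, lo = config$clamp_lo,
                         hi = config$clamp_hi,
                         default_value = config$default_value)
  mapped <- map_to_bfactor(read_structure(pdb_in), vmap)
  out <- file.path(config$out_dir, "mapped.pdb")
  write_structure(mapped, out)
  manifest_add(config, "map", out)
  stage_log("map", "%s -> %s", pdb_in, out)
  invisible(out)
}

stage_tm <- function(config) {
  melt_csv <- config$inputs$melt_csv %||% file.path(config$out_dir,
                                                    "melt_curves.csv")
  curves <- read_melt_csv(melt_csv)
  fits <- lapply(curves, fit_boltzmann)
  per <- do.call(rbind, lapply(fits, function(f) {
    data.frame(condition = f$condition, replicate = f$replicate, tm = f$tm,
               slope = f$slope, converged = f$converged,
               stringsAsFactors = FALSE)
  }))
  agg <- do.call(rbind, lapply(split(per[per$converged, ],
                                     per$condition[per$converged]),
                               function(g) {
    data.frame(condition = g$condition[1], n = nrow(g), tm_mean = mean(g$tm),
               tm_sd = if (nrow(g) > 1) sd(g$tm) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  out <- file.path(config$out_dir, "tm_table.csv")
  write.csv(agg, out, row.names = FALSE, quote = FALSE)
  manifest_add(config, "tm", out)
  stage_log("tm", "%d curves, %d conditions", length(curves), nrow(agg))
  invisible(out)
}

stage_report <- function(config) {
  out <- file.path(config$out_dir, "report.txt")
  con <- file(out, "w")
  on.exit(close(con))
  w <- function(...) cat(sprintf(...), "\n", sep = "", file = con)
  w("pepxkit run report (seed %d)", config$seed)
  sum_csv <- file.path(config$out_dir, "fp_summary.csv")
  if (file.exists(sum_csv)) {
    s <- read.csv(sum_csv, stringsAsFactors = FALSE)
    w("\n== FP exchange kinetics: fold changes ==")
    for (i in which(s$catalyst != "none"))
      w("  %-8s %-8s fold change %6.2f (sd %s)  relative activity %s",
        s$allotype[i], s$catalyst[i], s$fold_change[i],
        formatC(s$fold_change_sd[i], format = "f", digits = 2),
        ifelse(is.na(s$relative_activity[i]), "-",
               formatC(s$relative_activity[i], format = "f", digits = 2)))
  }
  cp_csv <- file.path(config$out_dir, "cpmg_fits.csv")
  if (file.exists(cp_csv)) {
    cp <- read.csv(cp_csv, stringsAsFactors = FALSE)
    w("\n== CPMG: dispersing methyls (amplitude > %g 1/s) ==",
      config$dispersion_threshold)
    for (i in which(cp$dispersing))
      w("  %-10s model %-15s kex %8.0f 1/s  amplitude %5.2f",
        cp$methyl_id[i], cp$model[i], cp$kex[i], cp$amplitude[i])
  }
  ratio_csv <- file.path(config$out_dir, "ratios.csv")
  if (file.exists(ratio_csv)) {
    rt <- read.csv(ratio_csv, stringsAsFactors = FALSE)
    w("\n== HSQC I/I0: attenuated residues (below mean - delta) ==")
    w("  mean ratio %.3f, delta %.3f", rt$mean_ratio[1], rt$delta[1])
    for (i in which(rt$attenuated %in% TRUE))
      w("  %-6s I/I0 = %.3f", rt$assignment_id[i], rt$ratio[i])
  }
  tm_csv <- file.path(config$out_dir, "tm_table.csv")
  if (file.exists(tm_csv)) {
    tm <- read.csv(tm_csv, stringsAsFactors = FALSE)
    w("\n== Thermal shift: Tm per condition ==")
    for (i in seq_len(nrow(tm)))
      w("  %-10s Tm = %.2f C (sd %s, n = %d)", tm$condition[i],
        tm$tm_mean[i], formatC(tm$tm_sd[i], format = "f", digits = 2),
        tm$n[i])
    if (nrow(tm) == 2)
      w("  delta Tm = %.2f C", tm$tm_mean[1] - tm$tm_mean[2])
  }
  manifest_add(config, "report", out)
  stage_log("report", "wrote %s", out)
  invisible(out)
}

#' Run one pipeline stage
#'
#' Subcommands: `synth` (generate all synthetic inputs), `fitfp` (FP fits and
#' exchange summary), `cpmg` (dispersion fits), `ratio` (I/I0 table),
#' `map` (paint ratios into PDB B-factors), `tm` (melt fits), `report`
#' (aggregate the stage CSVs into one plain-text summary). Each stage reads
#' and writes the documented formats under `config$out_dir`, logs to stderr
#' and appends to the run manifest (JSON-lines, one record per artifact).
#' For a fixed config and seed the outputs are byte-identical.
#'
#' @param name subcommand name.
#' @param config a [pepx_config()].
#' @return invisibly, the paths of the artifacts written.
#' @export
pepx_run <- function(name, config = pepx_config()) {
  stopifnot(inherits(config, "pepx_config"))
  stages <- list(synth = stage_synth, fitfp = stage_fitfp,
                 cpmg = stage_cpmg, ratio = stage_ratio, map = stage_map,
                 tm = stage_tm, report = stage_report)
  if (!name %in% names(stages))
    stop_pepx("unknown subcommand '%s' (expected one of: %s)", name,
              paste(names(stages), collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages[[name]](config)
}

#' Run the full pipeline
#'
#' `synth` through `report` in order (the `map` stage only when a PDB input
#' is configured).
#'
#' @param config a [pepx_config()].
#' @return invisibly, the report path.
#' @export
pepx_run_all <- function(config = pepx_config()) {
  for (s in c("synth", "fitfp", "cpmg", "ratio", "tm")) pepx_run(s, config)
  if (!is.null(config$inputs$pdb)) pepx_run("map", config)
  pepx_run("report", config)
}
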