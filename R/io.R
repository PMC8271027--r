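#' File readers and writers
#'
#' The on-disk dialects are small plain-text formats:
#' \itemize{
#'   \item FP: long CSV with columns `time, value, well`, plus a plate-layout
#'     TSV mapping `well` to `allotype, catalyst, replicate, role`
#'     (`role` is `sample` or `baseline`).
#'   \item CPMG: TSV with columns `methyl_id, nu_hz, intensity`; rows with
#'     `nu_hz = 0` are the reference plane.
#'   \item Peak lists: TSV with columns `assignment_id, h_ppm, n_ppm,
#'     intensity`; missing positions are tolerated.
#'   \item Melt curves: long CSV with columns `temperature, fluorescence,
#'     condition, replicate`.
#'   \item Per-residue value file for structure mapping: CSV with columns
#'     `chain, resnum, value`.
#' }
#' @name pepx_io
NULL

#' Read FP plate data
#'
#' @param csv_path long-format CSV (`time, value, well`); time in the unit
#'   named by `time_unit`.
#' @param layout_path plate-layout TSV (`well, allotype, catalyst, replicate,
#'   role`).
#' @param time_unit `"s"`, `"min"` or `"h"`; converted to seconds.
#' @return list of [fp_trace()] objects; sample traces carry their matching
#'   baseline (same allotype/catalyst/replicate if present, otherwise the
#'   first baseline well) as `baseline_ref`.
#' @export
read_fp_plate <- function(csv_path, layout_path, time_unit = "s") {
  mult <- switch(time_unit, s = 1, min = 60, h = 3600,
                 stop_pepx("unknown time unit '%s'", time_unit))
  dat <- read.csv(csv_path, stringsAsFactors = FALSE)
  lay <- read.delim(layout_path, stringsAsFactors = FALSE)
  need <- c("time", "value", "well")
  if (!all(need %in% names(dat)))
    stop_pepx("FP CSV must have columns: %s", paste(need, collapse = ", "))
  need_l <- c("well", "allotype", "catalyst", "replicate", "role")
  if (!all(need_l %in% names(lay)))
    stop_pepx("layout TSV must have columns: %s",
              paste(need_l, collapse = ", "))
  traces <- lapply(split(dat, dat$well), function(w) {
    m <- lay[lay$well == w$well[1], , drop = FALSE]
    if (!nrow(m)) stop_pepx("well '%s' missing from layout", w$well[1])
    o <- order(w$time)
    fp_trace(w$time[o] * mult, w$value[o], allotype = m$allotype,
             catalyst = m$catalyst, replicate = m$replicate, role = m$role)
  })
  is_base <- vapply(traces, function(t) t$role == "baseline", TRUE)
  for (i in which(!is_base)) {
    t <- traces[[i]]
    match_b <- which(is_base & vapply(traces, function(b) {
      identical(b$allotype, t$allotype) && identical(b$catalyst, t$catalyst) &&
        b$replicate == t$replicate
    }, TRUE))
    if (!length(match_b)) match_b <- which(is_base)
    if (length(match_b)) traces[[i]]$baseline_ref <- traces[[match_b[1]]]
  }
  unname(traces)
}

#' Write FP traces as long CSV plus plate layout TSV
#'
#' @param traces list of [fp_trace()] objects.
#' @param csv_path,layout_path output paths.
#' @param time_unit unit for the time column (`"s"`, `"min"`, `"h"`).
#' @return invisibly, the two paths.
#' @export
write_fp_plate <- function(traces, csv_path, layout_path, time_unit = "s") {
  mult <- switch(time_unit, s = 1, min = 60, h = 3600,
                 stop_pepx("unknown time unit '%s'", time_unit))
  wells <- sprintf("W%03d", seq_along(traces))
  long <- do.call(rbind, Map(function(t, w) {
    data.frame(time = t$time / mult, value = t$fp, well = w,
               stringsAsFactors = FALSE)
  }, traces, wells))
  lay <- do.call(rbind, Map(function(t, w) {
    data.frame(well = w, allotype = t$allotype, catalyst = t$catalyst,
               replicate = t$replicate, role = t$role,
               stringsAsFactors = FALSE)
  }, traces, wells))
  write.csv(long, csv_path, row.names = FALSE, quote = FALSE)
  write_tsv_plain(lay, layout_path)
  invisible(c(csv_path, layout_path))
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read CPMG profiles from TSV
#'
#' @param path TSV with columns `methyl_id, nu_hz, intensity`.
#' @param t_cpmg constant relaxation delay (s).
#' @return list of [dispersion_profile()] objects, one per methyl id.
#' @export
read_cpmg_tsv <- function(path, t_cpmg = 0.040) {
  dat <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("methyl_id", "nu_hz", "intensity")
  if (!all(need %in% names(dat)))
    stop_pepx("CPMG TSV must have columns: %s", paste(need, collapse = ", "))
  unname(lapply(split(dat, dat$methyl_id), function(g) {
    dispersion_profile(g$methyl_id[1], g$nu_hz, g$intensity, t_cpmg = t_cpmg)
  }))
}

#' Write a CPMG profile to TSV
#'
#' @param profile a [dispersion_profile()].
#' @param path output TSV.
#' @export
write_cpmg_tsv <- function(profile, path) {
  write_tsv_plain(data.frame(methyl_id = profile$methyl_id,
                             nu_hz = profile$nu, intensity = profile$intensity),
                  path)
  invisible(path)
}

#' Read a peak list from TSV
#'
#' @param path TSV with columns `assignment_id, h_ppm, n_ppm, intensity`;
#'   empty position fields are kept as NA.
#' @param provenance label attached to the list.
#' @return a [peak_list()].
#' @export
read_peaklist_tsv <- function(path, provenance = basename(path)) {
  dat <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("assignment_id", "h_ppm", "n_ppm", "intensity")
  if (!all(need %in% names(dat)))
    stop_pepx("peak list TSV must have columns: %s",
              paste(need, collapse = ", "))
  peak_list(dat$assignment_id, dat$h_ppm, dat$n_ppm, dat$intensity,
            provenance = provenance)
}

#' Write a peak list to TSV
#'
#' @param peaks a [peak_list()].
#' @param path output TSV.
#' @export
write_peaklist_tsv <- function(peaks, path) {
  write_tsv_plain(data.frame(assignment_id = peaks$assignment_id,
                             h_ppm = peaks$delta_h, n_ppm = peaks$delta_n,
                             intensity = peaks$intensity), path)
  invisible(path)
}

#' Read melt curves from long CSV
#'
#' @param path CSV with columns `temperature, fluorescence, condition,
#'   replicate`.
#' @return list of [melt_curve()] objects.
#' @export
read_melt_csv <- function(path) {
  dat <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature", "fluorescence", "condition", "replicate")
  if (!all(need %in% names(dat)))
    stop_pepx("melt CSV must have columns: %s", paste(need, collapse = ", "))
  key <- interaction(dat$condition, dat$replicate, drop = TRUE)
  unname(lapply(split(dat, key), function(g) {
    o <- order(g$temperature)
    melt_curve(g$temperature[o], g$fluorescence[o],
               condition = g$condition[1], replicate = g$replicate[1])
  }))
}

#' Write melt curves to long CSV
#'
#' @param curves list of [melt_curve()] objects.
#' @param path output CSV.
#' @export
write_melt_csv <- function(curves, path) {
  long <- do.call(rbind, lapply(curves, function(c) {
    data.frame(temperature = c$temperature, fluorescence = c$fluorescence,
               condition = c$condition, replicate = c$replicate,
               stringsAsFactors = FALSE)
  }))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-residue value CSV into a residue value map
#'
#' @param path CSV with columns `chain, resnum, value` (single chain).
#' @param lo,hi,default_value see [residue_value_map()].
#' @return a [residue_value_map()].
#' @export
read_value_csv <- function(path, lo = 0.30, hi = 0.70, default_value = -1) {
  dat <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("chain", "resnum", "value")
  if (!all(need %in% names(dat)))
    stop_pepx("value CSV must have columns: %s", paste(need, collapse = ", "))
  if (length(unique(dat$chain)) != 1)
    stop_pepx("value CSV must reference a single chain")
  residue_value_map(dat$chain[1], dat$resnum, dat$value, lo = lo, hi = hi,
                    default_value = default_value)
}

#' Write a ratio table (and its value-file companion) to CSV
#'
#' @param table a [intensity_ratios()]/[flag_attenuated()] result.
#' @param path output CSV for the ratio table.
#' @param value_path optional per-residue value CSV (`chain, resnum, value`)
#'   consumable by [read_value_csv()]; requires `chain`.
#' @param chain chain id recorded in the value file.
#' @export
write_ratio_csv <- function(table, path, value_path = NULL, chain = "A") {
  out <- as.data.frame(table)
  out$mean_ratio <- attr(table, "mean_ratio")
  out$delta <- attr(table, "delta")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(value_path)) {
    keep <- table$quantified & !is.na(table$ratio)
    resnum <- suppressWarnings(
      as.integer(sub("^[A-Za-z]+", "", table$assignment_id[keep])))
    write.csv(data.frame(chain = chain, resnum = resnum,
                         value = table$ratio[keep]),
              value_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
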