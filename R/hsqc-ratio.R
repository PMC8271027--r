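#' HSQC peak list container
#'
#' Quantified amide peaks of one spectrum: assignment id, 1H and 15N
#' chemical shifts and peak intensity.
#'
#' @param assignment_id residue labels (e.g. "T143"), unique.
#' @param delta_h,delta_n chemical shifts (ppm); may be NA for rows whose
#'   position was not quantified.
#' @param intensity peak intensities, >= 0.
#' @param provenance label for the spectrum, e.g. `"no-uv"` or `"+Tsn-WT"`.
#' @return object of class `peak_list` (a data.frame).
#' @export
peak_list <- function(assignment_id, delta_h, delta_n, intensity,
                      provenance = "") {
  if (anyDuplicated(assignment_id))
    stop_pepx("duplicated assignment id: %s",
              assignment_id[duplicated(assignment_id)][1])
  if (any(intensity < 0, na.rm = TRUE)) stop_pepx("intensities must be >= 0")
  out <- data.frame(assignment_id = as.character(assignment_id),
                    delta_h = as.numeric(delta_h),
                    delta_n = as.numeric(delta_n),
                    intensity = as.numeric(intensity),
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Pair two peak lists on assignment id
#'
#' Inner join on `assignment_id`; ids present in only one list are returned
#' separately (those residues are typically plotted as unassigned).
#'
#' @param reference,perturbed [peak_list()] objects.
#' @return list with `paired` (data.frame with reference/perturbed shifts and
#'   intensities) and `unmatched` (data.frame: id and which list it came
#'   from).
#' @export
match_peaks <- function(reference, perturbed) {
  stopifnot(inherits(reference, "peak_list"), inherits(perturbed, "peak_list"))
  shared <- intersect(reference$assignment_id, perturbed$assignment_id)
  if (!length(shared)) stop_pepx("peak lists share no assignment ids")
  ri <- match(shared, reference$assignment_id)
  pi <- match(shared, perturbed$assignment_id)
  paired <- data.frame(
    assignment_id = shared,
    h_ref = reference$delta_h[ri], n_ref = reference$delta_n[ri],
    i_ref = reference$intensity[ri],
    h_pert = perturbed$delta_h[pi], n_pert = perturbed$delta_n[pi],
    i_pert = perturbed$intensity[pi],
    stringsAsFactors = FALSE)
  only_ref <- setdiff(reference$assignment_id, shared)
  only_pert <- setdiff(perturbed$assignment_id, shared)
  unmatched <- data.frame(
    assignment_id = c(only_ref, only_pert),
    present_in = rep(c("reference", "perturbed"),
                     c(length(only_ref), length(only_pert))),
    stringsAsFactors = FALSE)
  list(paired = paired, unmatched = unmatched)
}

#' Per-residue intensity ratios I/I0
#'
#' `ratio = I_perturbed / I_reference` per shared assignment id, with the
#' summary statistics the attenuation rule needs: the mean ratio and its
#' standard deviation (delta) over quantified ids. Ids with zero reference
#' intensity cannot be quantified; they are flagged and excluded from the
#' summary. Ids whose perturbed peak vanished (intensity 0) get ratio 0 and
#' remain in the summary.
#'
#' @param paired output of [match_peaks()] (the list or its `paired` element).
#' @return object of class `ratio_table`: data.frame with `assignment_id`,
#'   `ratio`, `csp` (ppm), `quantified`, `attenuated`, `vanished`;
#'   attributes `mean_ratio` and `delta` (SD of ratios).
#' @export
intensity_ratios <- function(paired) {
  if (is.list(paired) && !is.data.frame(paired)) paired <- paired$paired
  quantified <- paired$i_ref > 0
  ratio <- ifelse(quantified, paired$i_pert / paired$i_ref, NA_real_)
  out <- data.frame(assignment_id = paired$assignment_id,
                    ratio = ratio,
                    csp = chemical_shift_perturbation(paired)$csp,
                    quantified = quantified,
                    vanished = quantified & paired$i_pert == 0,
                    attenuated = NA,
                    stringsAsFactors = FALSE)
  attr(out, "mean_ratio") <- mean(ratio[quantified])
  attr(out, "delta") <- sd(ratio[quantified])
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Flag significantly attenuated residues
#'
#' A residue is attenuated when its ratio falls strictly below
#' `mean(I/I0) - delta`, delta being one standard deviation of the ratio
#' distribution over quantified residues. Vanished peaks (ratio 0) are
#' always flagged.
#'
#' @param table a [intensity_ratios()] result.
#' @return the table with the `attenuated` column filled and attribute
#'   `threshold` set to `mean - delta`.
#' @export
flag_attenuated <- function(table) {
  stopifnot(inherits(table, "ratio_table"))
  if (sum(table$quantified) < 3)
    stop_pepx("need >= 3 quantified residues for the mean - delta rule")
  thr <- attr(table, "mean_ratio") - attr(table, "delta")
  table$attenuated <- ifelse(table$quantified,
                             table$ratio < thr | table$vanished, NA)
  attr(table, "threshold") <- thr
  table
}

#' Weighted amide chemical-shift perturbation
#'
#' `csp = sqrt(dH^2 + (dN/5)^2)` in ppm, the conventional amide weighting.
#' Rows with a missing position in either list are skipped (NA) and flagged.
#'
#' @param paired output of [match_peaks()] (the list or its `paired`
#'   element).
#' @return data.frame with `assignment_id`, `csp`, `position_missing`.
#' @export
chemical_shift_perturbation <- function(paired) {
  if (is.list(paired) && !is.data.frame(paired)) paired <- paired$paired
  dh <- paired$h_pert - paired$h_ref
  dn <- paired$n_pert - paired$n_ref
  missing <- is.na(dh) | is.na(dn)
  csp <- ifelse(missing, NA_real_, sqrt(dh^2 + (dn / 5)^2))
  data.frame(assignment_id = paired$assignment_id, csp = csp,
             position_missing = missing, stringsAsFactors = FALSE)
}
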