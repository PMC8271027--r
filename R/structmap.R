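#' Per-residue value map for B-factor painting
#'
#' Values (e.g. I/I0 ratios) keyed by author residue number on one chain,
#' with the display clamp range and the sentinel written to unmapped
#' residues so viewers can color "unassigned" distinctly.
#'
#' @param chain single chain id (e.g. "A").
#' @param resnum positive integer residue numbers.
#' @param value numeric values, same length as `resnum`.
#' @param lo,hi clamp range; `lo < hi`. The published display conventions are
#'   e.g. 0--0.58 (zero to the mean ratio) or 0.30--0.70.
#' @param default_value B-factor for residues absent from the map; default
#'   -1 as an "unassigned" sentinel.
#' @return object of class `residue_value_map`.
#' @export
residue_value_map <- function(chain, resnum, value, lo = 0.30, hi = 0.70,
                              default_value = -1) {
  if (length(resnum) != length(value)) stop_pepx("resnum/value length mismatch")
  if (any(resnum != as.integer(resnum)) || any(resnum <= 0))
    stop_pepx("residue numbers must be positive integers")
  if (anyDuplicated(resnum)) stop_pepx("duplicated residue number")
  if (!(lo < hi)) stop_pepx("clamp range requires lo < hi")
  structure(list(chain = chain, resnum = as.integer(resnum),
                 value = as.numeric(value), lo = lo, hi = hi,
                 default_value = default_value),
            class = "residue_value_map")
}

pdb_num_field <- function(lines, idx, from, to, what) {
  raw <- substr(lines[idx], from, to)
  val <- suppressWarnings(as.numeric(raw))
  bad <- is.na(val) & trimws(raw) != ""
  if (any(bad))
    stop_pepx("malformed %s field in PDB line %d: '%s'",
              what, idx[bad][1], raw[bad][1])
  if (any(trimws(raw) == ""))
    stop_pepx("empty %s field in PDB line %d", what, idx[trimws(raw) == ""][1])
  val
}

#' Read a PDB structure, preserving the file verbatim
#'
#' Parses the fixed-width ATOM/HETATM records (chain, residue number,
#' insertion code, atom name, coordinates, occupancy, B-factor) and keeps
#' every line of the file untouched, so that writing the structure back
#' reproduces the input byte for byte. All non-coordinate records pass
#' through verbatim.
#'
#' @param pdb path to a PDB file, or a character vector of its lines.
#' @return object of class `pdb_structure`: `lines` (verbatim) and `atoms`
#'   (data.frame with one row per ATOM/HETATM record, including the line
#'   index it came from).
#' @export
read_structure <- function(pdb) {
  lines <- if (length(pdb) == 1 && file.exists(pdb)) readLines(pdb) else pdb
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(idx)) stop_pepx("no ATOM/HETATM records found")
  short <- idx[nchar(lines[idx]) < 66]
  if (length(short))
    stop_pepx("ATOM record shorter than 66 columns at line %d", short[1])
  atoms <- data.frame(
    line = idx,
    record = trimws(rec[idx]),
    name = trimws(substr(lines[idx], 13, 16)),
    resname = trimws(substr(lines[idx], 18, 20)),
    chain = substr(lines[idx], 22, 22),
    resnum = as.integer(pdb_num_field(lines, idx, 23, 26, "residue number")),
    icode = substr(lines[idx], 27, 27),
    x = pdb_num_field(lines, idx, 31, 38, "x"),
    y = pdb_num_field(lines, idx, 39, 46, "y"),
    z = pdb_num_field(lines, idx, 47, 54, "z"),
    occupancy = pdb_num_field(lines, idx, 55, 60, "occupancy"),
    bfactor = pdb_num_field(lines, idx, 61, 66, "B-factor"),
    stringsAsFactors = FALSE)
  structure(list(lines = lines, atoms = atoms), class = "pdb_structure")
}

#' Write a structure back to PDB text
#'
#' @param structure a [pdb_structure()][read_structure()].
#' @param path output file; omit to return the lines invisibly.
#' @return the character lines, invisibly.
#' @export
write_structure <- function(structure, path = NULL) {
  stopifnot(inherits(structure, "pdb_structure"))
  if (!is.null(path)) writeLines(structure$lines, path)
  invisible(structure$lines)
}

#' Paint per-residue values into the B-factor column
#'
#' Every atom of a mapped residue on the map's chain receives
#' `clamp(value, lo, hi)`; residues of that chain absent from the map get
#' the sentinel `default_value`. Values are written in PDB fixed width
#' (`%6.2f`, columns 61-66); atoms on other chains, atom order, coordinates
#' and all non-ATOM records are untouched. Mapping is idempotent.
#'
#' @param structure a [pdb_structure()][read_structure()].
#' @param map a [residue_value_map()].
#' @return the modified `pdb_structure`.
#' @export
map_to_bfactor <- function(structure, map) {
  stopifnot(inherits(structure, "pdb_structure"),
            inherits(map, "residue_value_map"))
  atoms <- structure$atoms
  sel <- atoms$chain == map$chain
  if (!any(sel)) stop_pepx("chain '%s' not found in structure", map$chain)
  if (any(atoms$icode[sel] != " "))
    stop_pepx("insertion codes on chain '%s' are not supported", map$chain)
  pos <- match(atoms$resnum[sel], map$resnum)
  b <- ifelse(is.na(pos), map$default_value,
              pmin(pmax(map$value[pos], map$lo), map$hi))
  newfield <- sprintf("%6.2f", b)
  over <- nchar(newfield) > 6
  if (any(over)) stop_pepx("B-factor value does not fit PDB width: %s",
                           newfield[over][1])
  lines <- structure$lines
  li <- atoms$line[sel]
  substr(lines[li], 61, 66) <- newfield
  structure$lines <- lines
  structure$atoms$bfactor[sel] <- round(b, 2)
  structure
}

#' Build a residue value map from a ratio table
#'
#' Convenience bridge from [flag_attenuated()] output to
#' [map_to_bfactor()]: assignment ids of the form `<AA><number>` (e.g.
#' "T143") are parsed for the residue number.
#'
#' @param table a [intensity_ratios()] result.
#' @param chain chain id to map onto.
#' @param lo,hi,default_value see [residue_value_map()].
#' @return a [residue_value_map()].
#' @export
ratio_value_map <- function(table, chain, lo = 0.30, hi = 0.70,
                            default_value = -1) {
  stopifnot(inherits(table, "ratio_table"))
  keep <- table$quantified & !is.na(table$ratio)
  resnum <- suppressWarnings(
    as.integer(sub("^[A-Za-z]+", "", table$assignment_id[keep])))
  if (any(is.na(resnum)))
    stop_pepx("cannot parse residue number from id '%s'",
              table$assignment_id[keep][is.na(resnum)][1])
  residue_value_map(chain, resnum, table$ratio[keep], lo = lo, hi = hi,
                    default_value = default_value)
}
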