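# Structure / trajectory / table IO.  PDB parsing and writing are
# delegated to bio3d; a light pre-scan enforces the contracts the
# analysis relies on (per-MODEL atom counts, coordinate field sanity
# with line numbers, insertion-code rejection, first-altloc policy).

.pdb_atom_lines <- function(lines) {
  which(substr(lines, 1L, 6L) %in% c("ATOM  ", "HETATM"))
}

# per-MODEL atom counts; files without MODEL records count as one model
.pdb_model_counts <- function(lines) {
  rec <- substr(lines, 1L, 6L)
  starts <- which(rec == "MODEL ")
  if (!length(starts)) {
    return(length(.pdb_atom_lines(lines)))
  }
  ends <- which(rec == "ENDMDL")
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  vapply(seq_along(starts), function(i) {
    block <- lines[starts[i]:ends[i]]
    length(.pdb_atom_lines(block))
  }, integer(1))
}

.pdb_scan <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  al <- .pdb_atom_lines(lines)
  if (!length(al))
    stop("no ATOM/HETATM records in ", path, call. = FALSE)
  for (i in al) {
    ln <- lines[i]
    if (nchar(ln) < 54L)
      stop(sprintf("malformed coordinate record at line %d of %s", i, path),
           call. = FALSE)
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop(sprintf("malformed coordinate field at line %d of %s", i, path),
           call. = FALSE)
    icode <- substr(ln, 27, 27)
    if (icode != " " && nzchar(trimws(icode)))
      stop(sprintf("insertion code '%s' at line %d of %s is not supported",
                   icode, i, path), call. = FALSE)
  }
  lines
}

.bio3d_to_atoms <- function(pdb) {
  a <- pdb$atom
  elem <- trimws(a$elesy)
  # fall back to the first letter of the atom name when ELEMENT is blank
  blank <- is.na(elem) | !nzchar(elem)
  elem[blank] <- substr(gsub("[0-9']", "", a$elety[blank]), 1L, 1L)
  data.frame(serial = as.integer(a$eleno), name = trimws(a$elety),
             resname = trimws(a$resid), chain = as.character(a$chain),
             resno = as.integer(a$resno),
             x = a$x, y = a$y, z = a$z,
             element = toupper(elem), stringsAsFactors = FALSE)
}

# keep the first altloc per (chain, resno, name); drop the rest
.filter_altloc <- function(pdb) {
  alt <- pdb$atom$alt
  if (all(is.na(alt) | !nzchar(trimws(alt)))) return(pdb)
  key <- paste(pdb$atom$chain, pdb$atom$resno, trimws(pdb$atom$elety))
  keep <- !duplicated(key)
  pdb$atom <- pdb$atom[keep, , drop = FALSE]
  cols <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1,
                          3 * which(keep)))
  pdb$xyz <- pdb$xyz[, cols, drop = FALSE]
  pdb
}

#' Read a structure from a PDB-dialect file
#'
#' Reads ATOM/HETATM records of the first MODEL into a
#' [MolStructure-class].  TER/REMARK and other records are ignored.
#' When alternate locations are present only the first altloc of each
#' atom is kept; insertion codes are rejected.
#'
#' @param path path to a PDB file.
#' @param label structure label; defaults to the file name.
#' @return A [MolStructure-class].
#' @export
readStructure <- function(path, label = basename(path)) {
  .pdb_scan(path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  pdb <- .filter_altloc(pdb)
  atoms <- .bio3d_to_atoms(pdb)
  atoms$x <- pdb$xyz[1, seq(1, by = 3, length.out = nrow(atoms))]
  atoms$y <- pdb$xyz[1, seq(2, by = 3, length.out = nrow(atoms))]
  atoms$z <- pdb$xyz[1, seq(3, by = 3, length.out = nrow(atoms))]
  MolStructure(atoms, label = label)
}

#' Read a multi-model trajectory
#'
#' Reads a multi-model PDB file whose every MODEL has the same atom
#' count and order as `topology`.  Frames are returned in MODEL order;
#' times default to `frame index * timeStep` starting at 0 unless given
#' explicitly.
#'
#' @param path path to a multi-model PDB file.
#' @param topology the [MolStructure-class] the frames share.
#' @param times optional numeric vector of frame times, ns.
#' @param timeStep frame spacing in ns when `times` is missing.
#' @return A [MolTrajectory-class].
#' @export
readTrajectory <- function(path, topology, times = NULL, timeStep = 0.1) {
  lines <- .pdb_scan(path)
  counts <- .pdb_model_counts(lines)
  bad <- which(counts != nAtoms(topology))
  if (length(bad))
    stop(sprintf(
      "MODEL %d in %s has %d atoms; topology has %d",
      bad[1L], path, counts[bad[1L]], nAtoms(topology)), call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- unclass(pdb$xyz)
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  MolTrajectory(topology, xyz, times = times, timeStep = timeStep)
}

.write_pdb_frames <- function(path, atoms, xyz) {
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   type = rep("ATOM", nrow(atoms)),
                   resno = atoms$resno, resid = atoms$resname,
                   eleno = atoms$serial, elety = atoms$name,
                   chain = atoms$chain, elesy = atoms$element)
  invisible(path)
}

#' Write a structure to a PDB-dialect file
#'
#' Atom order is the stored file order; coordinates are written with the
#' fixed-width PDB precision of 1e-3 Angstrom.
#'
#' @param structure a [MolStructure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(structure, path) {
  xyz <- as.vector(t(coords(structure)))
  .write_pdb_frames(path, structure@atoms, matrix(xyz, nrow = 1L))
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a [MolTrajectory-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path) {
  .write_pdb_frames(path, traj@topology@atoms, traj@coords)
}

#' Read a per-atom nonbonded parameter table
#'
#' The table is a CSV with header
#' `residue_name,atom_name,charge_e,epsilon_kcal,rmin_half_A`: partial
#' charge in elementary-charge units, Lennard-Jones well depth in
#' kcal/mol (non-negative) and the LJ minimum-distance half parameter
#' Rmin/2 in Angstrom (positive).
#'
#' @param path CSV file path.
#' @return data.frame keyed by `(residue_name, atom_name)`.
#' @export
readNonbondParams <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         comment.char = "#")
  need <- c("residue_name", "atom_name", "charge_e", "epsilon_kcal",
            "rmin_half_A")
  if (!all(need %in% names(tab)))
    stop("parameter table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(tab$epsilon_kcal < 0)) stop("epsilon must be >= 0")
  if (any(tab$rmin_half_A <= 0)) stop("Rmin/2 must be > 0")
  if (anyDuplicated(paste(tab$residue_name, tab$atom_name)))
    stop("duplicate (residue_name, atom_name) rows in parameter table")
  tab
}

#' Write a nonbonded parameter table
#' @param params data.frame as returned by [readNonbondParams()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeNonbondParams <- function(params, path) {
  utils::write.csv(params, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a results series as delimited text
#'
#' Comma-separated with a mandatory header row and `"."` decimal marks.
#' Numeric columns are written with 9 significant digits so that a
#' write/read round-trip is lossless at that precision.  An optional
#' units table is emitted as `#`-prefixed comment lines above the
#' header.
#'
#' @param table data.frame of equal-length columns.
#' @param path output file path.
#' @param units optional named character vector mapping column names to
#'   unit strings, echoed in the header comments.
#' @return `path`, invisibly.
#' @export
writeSeries <- function(table, path, units = NULL) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(units)) {
    for (nm in names(units))
      writeLines(sprintf("# units: %s = %s", nm, units[[nm]]), con)
  }
  writeLines(paste(names(table), collapse = ","), con)
  if (nrow(table)) {
    cols <- lapply(table, function(col) {
      if (is.numeric(col)) sprintf("%.9g", col) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(path)
}

#' Read a series written by [writeSeries()]
#'
#' @param path CSV path; `#` comment lines are skipped.
#' @return data.frame.
#' @export
readSeries <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}
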