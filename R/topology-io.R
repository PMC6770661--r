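# Structure / trajectory / configuration I/O.
#
# A deliberately small reader for the subset of PDB and GRO actually used
# here (ATOM/HETATM/MODEL/ENDMDL/CRYST1; fixed-width GRO), written so the
# error contracts can name offending lines and model indices and so
# triclinic boxes are rejected explicitly.  Only orthorhombic boxes are
# supported: the systems this package targets are orthorhombic membrane
# slabs.

.parsePdbAtomLines <- function(lines, lineNumbers, path) {
  short <- nchar(lines) < 54L
  if (any(short))
    .stopf("parse error in '%s': truncated ATOM/HETATM record at line %d",
           path, lineNumbers[which(short)[1]])
  num <- function(from, to, what) {
    s <- substr(lines, from, to)
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v))
      .stopf("parse error in '%s': unreadable %s field at line %d",
             path, what, lineNumbers[which(is.na(v))[1]])
    v
  }
  atoms <- data.frame(
    atom_name = trimws(substr(lines, 13, 16)),
    residue_number = as.integer(num(23, 26, "residue number")),
    residue_name = trimws(substr(lines, 18, 20)),
    segment_id = trimws(substr(lines, 22, 22)),
    stringsAsFactors = FALSE
  )
  coords <- cbind(num(31, 38, "x"), num(39, 46, "y"), num(47, 54, "z"))
  list(atoms = atoms, coords = coords)
}

.parseCryst1 <- function(line, path, lineNumber) {
  len <- suppressWarnings(as.numeric(c(substr(line, 7, 15),
                                       substr(line, 16, 24),
                                       substr(line, 25, 33))))
  ang <- suppressWarnings(as.numeric(c(substr(line, 34, 40),
                                       substr(line, 41, 47),
                                       substr(line, 48, 54))))
  if (anyNA(len))
    .stopf("parse error in '%s': unreadable CRYST1 record at line %d",
           path, lineNumber)
  if (!anyNA(ang) && any(abs(ang - 90) > 0.01))
    .stopf("unsupported box in '%s': triclinic cell (angles %s); only orthorhombic boxes are supported",
           path, paste(format(ang), collapse = ", "))
  len
}

#' Read a single-frame structure file
#'
#' Reads a PDB (first model if several) or GRO coordinate file into a
#' [MemFrame-class], preserving author residue numbering and atom names
#' verbatim.  GRO coordinates (nm) are converted to Angstrom.  Triclinic
#' boxes are rejected; a missing box is allowed and flagged \code{NA}
#' (box-requiring operations will then fail with a configuration error).
#'
#' @param path file path.
#' @param format \code{"pdb"} or \code{"gro"}; default guessed from the
#'   file extension.
#' @return a [MemFrame-class].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  if (!file.exists(path)) .stopf("file not found: '%s'", path)
  if (format == "gro") return(.readGro(path))
  traj <- readTrajectory(path, format = "pdb")
  getFrame(traj, 1L)
}

#' Read a trajectory from a multi-model PDB file
#'
#' Each MODEL/ENDMDL block becomes one frame; a file without MODEL records
#' yields a single-frame trajectory.  All models must share the atom count
#' and ordering.
#'
#' @param path file path.
#' @param format only \code{"pdb"} (multi-model) is built in; XTC/DCD
#'   readers can be plugged in by converting to a [MemTrajectory-class]
#'   with the constructor.
#' @return a [MemTrajectory-class].
#' @export
readTrajectory <- function(path, format = c("pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  isAtom <- rec %in% c("ATOM  ", "HETATM")
  box <- rep(NA_real_, 3)
  cry <- which(rec == "CRYST1")
  if (length(cry)) box <- .parseCryst1(lines[cry[1]], path, cry[1])
  modelStarts <- which(trimws(rec) == "MODEL")
  if (length(modelStarts) == 0L) {
    if (!any(isAtom)) .stopf("no frames in '%s'", path)
    p <- .parsePdbAtomLines(lines[isAtom], which(isAtom), path)
    return(MemTrajectory(p$atoms, array(p$coords, c(nrow(p$coords), 3, 1)),
                         box))
  }
  ends <- which(trimws(rec) == "ENDMDL")
  if (length(ends) < length(modelStarts))
    ends <- c(ends, length(lines) + 1L)
  frames <- vector("list", length(modelStarts))
  atoms <- NULL
  for (m in seq_along(modelStarts)) {
    span <- seq(modelStarts[m] + 1L, ends[m] - 1L)
    sel <- span[isAtom[span]]
    if (!length(sel)) .stopf("model %d of '%s' contains no atoms", m, path)
    p <- .parsePdbAtomLines(lines[sel], sel, path)
    if (is.null(atoms)) {
      atoms <- p$atoms
    } else if (nrow(p$atoms) != nrow(atoms)) {
      .stopf("atom-count mismatch in '%s': model %d has %d atoms, model 1 has %d",
             path, m, nrow(p$atoms), nrow(atoms))
    } else if (!identical(p$atoms$atom_name, atoms$atom_name) ||
               !identical(p$atoms$residue_number, atoms$residue_number)) {
      .stopf("atom-order mismatch in '%s' at model %d", path, m)
    }
    frames[[m]] <- p$coords
  }
  arr <- array(unlist(frames), c(nrow(atoms), 3, length(frames)))
  MemTrajectory(atoms, arr, box)
}

.readGro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) .stopf("no frames in '%s'", path)
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms))
    .stopf("parse error in '%s': unreadable atom count at line 2", path)
  if (length(lines) < 2L + natoms + 1L)
    .stopf("parse error in '%s': expected %d atom lines", path, natoms)
  al <- lines[3:(2 + natoms)]
  short <- nchar(al) < 44L
  if (any(short))
    .stopf("parse error in '%s': truncated atom record at line %d",
           path, 2L + which(short)[1])
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(al, from, to)))
    if (anyNA(v))
      .stopf("parse error in '%s': unreadable %s field at line %d",
             path, what, 2L + which(is.na(v))[1])
    v
  }
  atoms <- data.frame(
    atom_name = trimws(substr(al, 11, 15)),
    residue_number = as.integer(num(1, 5, "residue number")),
    residue_name = trimws(substr(al, 6, 10)),
    segment_id = "",
    stringsAsFactors = FALSE
  )
  coords <- cbind(num(21, 28, "x"), num(29, 36, "y"), num(37, 44, "z")) * 10
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + natoms]),
                                               "[[:space:]]+")[[1]]))
  if (length(boxv) > 3 && any(abs(boxv[-(1:3)]) > 1e-9))
    .stopf("unsupported box in '%s': triclinic cell; only orthorhombic boxes are supported",
           path)
  box <- if (length(boxv) >= 3 && !anyNA(boxv[1:3])) boxv[1:3] * 10 else
    rep(NA_real_, 3)
  MemFrame(atoms, coords, box)
}

.pdbAtomLine <- function(serial, name, resname, chain, resno, xyz) {
  nm <- ifelse(nchar(name) <= 3, sprintf(" %-3s", name), sprintf("%-4s", name))
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial %% 100000L, nm, substr(resname, 1, 3),
          substr(ifelse(nzchar(chain), chain, "A"), 1, 1),
          resno %% 10000L, xyz[1], xyz[2], xyz[3])
}

.pdbBody <- function(atoms, coords) {
  n <- nrow(atoms)
  nm <- ifelse(nchar(atoms$atom_name) <= 3,
               sprintf(" %-3s", atoms$atom_name),
               sprintf("%-4s", atoms$atom_name))
  ch <- ifelse(nzchar(atoms$segment_id), substr(atoms$segment_id, 1, 1), "A")
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          seq_len(n) %% 100000L, nm, substr(atoms$residue_name, 1, 3), ch,
          atoms$residue_number %% 10000L,
          coords[, 1], coords[, 2], coords[, 3])
}

#' Write a frame or trajectory as (multi-model) PDB
#'
#' Frames are written as MODEL/ENDMDL blocks with a CRYST1 record when box
#' dimensions are known.  Coordinates are written at the PDB precision of
#' 1e-3 Angstrom.
#'
#' @param x a [MemFrame-class] or [MemTrajectory-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePDB <- function(x, path) {
  if (is(x, "MemFrame")) x <- MemTrajectory(x@atoms, x@coords, x@box)
  stopifnot(is(x, "MemTrajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  box <- x@box[1, ]
  if (!anyNA(box))
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      box[1], box[2], box[3], 90, 90, 90), con)
  nf <- nFrames(x)
  for (f in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(.pdbBody(x@atoms, x@coords[, , f]), con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a frame in GRO format
#'
#' Coordinates are converted to nm and written at the GRO precision of
#' 1e-3 nm (1e-2 Angstrom).
#'
#' @param x a [MemFrame-class].
#' @param path output file path.
#' @param title header line.
#' @return \code{path}, invisibly.
#' @export
writeGRO <- function(x, path, title = "memOrient frame") {
  stopifnot(is(x, "MemFrame"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(sprintf("%5d", nrow(x@coords)), con)
  nm <- x@coords / 10
  writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     x@atoms$residue_number %% 100000L,
                     substr(x@atoms$residue_name, 1, 5),
                     substr(x@atoms$atom_name, 1, 5),
                     seq_len(nrow(x@coords)) %% 100000L,
                     nm[, 1], nm[, 2], nm[, 3]), con)
  box <- if (anyNA(x@box)) c(0, 0, 0) else x@box / 10
  writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  invisible(path)
}

#' Validate a segment map against a frame
#'
#' Checks that every configured residue range matches at least one
#' non-lipid particle of the frame and that the heme selection matches
#' exactly four particles, and errors otherwise, naming the offending
#' ranges.
#'
#' @param frame a [MemFrame-class].
#' @param segmap a [SegmentMap-class].
#' @return the validated segment map, invisibly, with attribute
#'   \code{matchedCounts}.
#' @export
resolveSegments <- function(frame, segmap) {
  stopifnot(is(frame, "MemFrame"), is(segmap, "SegmentMap"))
  at <- frame@atoms
  lipid <- at$atom_name %in% c(segmap@lipidHead, segmap@lipidTail)
  counts <- integer(0)
  bad <- character(0)
  for (nm in names(segmap@segments)) {
    r <- segmap@segments[[nm]]
    n <- sum(!lipid & at$residue_number >= r[1] & at$residue_number <= r[2])
    counts[nm] <- n
    if (n == 0L)
      bad <- c(bad, sprintf("%s (%d-%d)", nm, as.integer(r[1]),
                            as.integer(r[2])))
  }
  if (length(bad))
    .stopf("segment range(s) match no particles: %s",
           paste(bad, collapse = "; "))
  if (length(segmap@hemeResidue)) {
    nh <- sum(at$residue_name %in% segmap@hemeResidue &
                at$atom_name %in% segmap@hemeAtoms)
    if (nh != 4L)
      .stopf("heme nitrogen selection matched %d particles; exactly 4 are required",
             nh)
    counts["heme_nitrogens"] <- nh
  }
  attr(segmap, "matchedCounts") <- counts
  invisible(segmap)
}

.segmentMapToList <- function(segmap) {
  list(
    segments = lapply(segmap@segments, function(r) as.integer(r)),
    heme_residue = segmap@hemeResidue,
    heme_atoms = segmap@hemeAtoms,
    lipid_head = segmap@lipidHead,
    lipid_tail = segmap@lipidTail,
    backbone = segmap@backboneNames
  )
}

.segmentMapFromList <- function(x) {
  segs <- lapply(x$segments, function(r) as.numeric(unlist(r)))
  do.call(SegmentMap, c(segs, list(
    hemeResidue = as.character(unlist(x$heme_residue)),
    hemeAtoms = if (is.null(x$heme_atoms)) c("NA", "NB", "NC", "ND") else
      as.character(unlist(x$heme_atoms)),
    lipidHead = as.character(unlist(x$lipid_head)),
    lipidTail = as.character(unlist(x$lipid_tail)),
    backboneNames = if (is.null(x$backbone)) c("CA", "BB") else
      as.character(unlist(x$backbone))
  )))
}

#' Read or write a segment-map configuration file (YAML or JSON)
#'
#' The file holds the residue ranges and particle name sets of a
#' [SegmentMap-class] under the keys \code{segments}, \code{heme_residue},
#' \code{heme_atoms}, \code{lipid_head}, \code{lipid_tail},
#' \code{backbone}.
#'
#' @param path configuration file (\code{.yaml}/\code{.yml} or
#'   \code{.json}).
#' @return [readSegmentConfig()] returns a [SegmentMap-class].
#' @export
readSegmentConfig <- function(path) {
  if (!file.exists(path)) .stopf("file not found: '%s'", path)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path) else yaml::read_yaml(path)
  .segmentMapFromList(x)
}

#' @rdname readSegmentConfig
#' @param segmap a [SegmentMap-class] to serialize.
#' @export
writeSegmentConfig <- function(segmap, path) {
  x <- .segmentMapToList(segmap)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = FALSE, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
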