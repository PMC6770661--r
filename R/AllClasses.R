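#' @import methods
NULL

#' Named residue-range segment annotations for a membrane-protein system
#'
#' A \code{SegmentMap} declares, by author residue numbering, the structural
#' segments that drive every geometric construction in the package: the
#' transmembrane anchor helix, the flexible linker, the globular (catalytic)
#' domain, the C-, F- and I-helices used for the orientation axis vectors,
#' the F'-G' membrane-binding region, the heme nitrogen selection, and the
#' lipid head/tail particle name sets.
#'
#' Residue ranges are inclusive \code{c(first, last)} pairs in the numbering
#' of the input files; no renumbering is ever applied.  Helix segments used
#' for terminal-residue axis vectors (\code{tm_helix}, \code{c_helix},
#' \code{f_helix}, \code{i_helix}) must span at least 8 residues so the
#' four-residue terminal centers of mass do not overlap.
#'
#' @slot segments named list of inclusive integer ranges; recognized names
#'   are \code{tm_helix}, \code{linker}, \code{globular}, \code{c_helix},
#'   \code{f_helix}, \code{i_helix}, \code{fprime_gprime}.
#' @slot hemeResidue residue name(s) of the heme group (e.g. \code{"HEM"});
#'   empty when the system carries no heme (coarse-grained runs).
#' @slot hemeAtoms atom names of the four heme nitrogens coordinating the
#'   iron (default \code{NA, NB, NC, ND}).
#' @slot lipidHead atom/bead names counted as lipid head-group (phosphate)
#'   particles.
#' @slot lipidTail atom/bead names counted as lipid hydrophobic-tail
#'   particles.
#' @slot backboneNames atom names accepted as backbone particles for axis
#'   vectors (default \code{CA} for atomistic and \code{BB} for
#'   coarse-grained input).
#' @seealso [SegmentMap()], [resolveSegments()]
#' @export
setClass("SegmentMap",
  representation(
    segments = "list",
    hemeResidue = "character",
    hemeAtoms = "character",
    lipidHead = "character",
    lipidTail = "character",
    backboneNames = "character"
  )
)

setValidity("SegmentMap", function(object) {
  msgs <- character(0)
  segs <- object@segments
  if (length(segs) && (is.null(names(segs)) || any(!nzchar(names(segs)))))
    msgs <- c(msgs, "all segments must be named")
  for (nm in names(segs)) {
    r <- segs[[nm]]
    if (!is.numeric(r) || length(r) != 2L || anyNA(r))
      msgs <- c(msgs, sprintf("segment '%s' is not a c(first, last) range", nm))
    else if (r[2] < r[1])
      msgs <- c(msgs, sprintf("segment '%s' range is empty (%g-%g)", nm, r[1], r[2]))
    else if (r[1] < 1)
      msgs <- c(msgs, sprintf("segment '%s' starts below residue 1", nm))
    else if (nm %in% c("tm_helix", "c_helix", "f_helix", "i_helix") &&
             (r[2] - r[1] + 1) < 8)
      msgs <- c(msgs, sprintf(
        "helix segment '%s' spans %d residues; at least 8 are required so terminal four-residue centers of mass do not overlap",
        nm, as.integer(r[2] - r[1] + 1)))
  }
  if (length(object@hemeResidue) && length(object@hemeAtoms) != 4L)
    msgs <- c(msgs, "hemeAtoms must name exactly 4 nitrogen particles")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SegmentMap
#'
#' @param ... named inclusive residue ranges, each a \code{c(first, last)}
#'   pair, e.g. \code{tm_helix = c(3, 21)}, \code{globular = c(50, 490)}.
#' @param hemeResidue residue name(s) of the heme group; \code{character(0)}
#'   for heme-less (coarse-grained) systems.
#' @param hemeAtoms the four heme nitrogen atom names.
#' @param lipidHead,lipidTail lipid head-group and tail particle name sets.
#' @param backboneNames backbone particle names used for axis vectors.
#' @return a validated [SegmentMap-class] object.
#' @examples
#' sm <- SegmentMap(
#'   tm_helix = c(3, 21), linker = c(22, 49), globular = c(50, 490),
#'   c_helix = c(118, 135), f_helix = c(190, 209), i_helix = c(286, 316),
#'   fprime_gprime = c(210, 220),
#'   hemeResidue = "HEM",
#'   lipidHead = "PO4", lipidTail = c("C1A", "C2A")
#' )
#' @export
SegmentMap <- function(..., hemeResidue = character(0),
                       hemeAtoms = c("NA", "NB", "NC", "ND"),
                       lipidHead = character(0), lipidTail = character(0),
                       backboneNames = c("CA", "BB")) {
  segs <- list(...)
  segs <- lapply(segs, function(r) as.numeric(r))
  new("SegmentMap",
    segments = segs,
    hemeResidue = as.character(hemeResidue),
    hemeAtoms = as.character(hemeAtoms),
    lipidHead = as.character(lipidHead),
    lipidTail = as.character(lipidTail),
    backboneNames = as.character(backboneNames)
  )
}

#' Single frame of particle coordinates
#'
#' Holds one configuration of the system: a particle table (atom name,
#' residue number/name, segment id) plus an \code{n x 3} coordinate matrix
#' in Angstrom and an orthorhombic box.  Author residue numbering from the
#' input file is preserved verbatim.
#'
#' @slot atoms data.frame with columns \code{atom_name},
#'   \code{residue_number}, \code{residue_name}, \code{segment_id}.
#' @slot coords numeric matrix, one row per particle, columns x/y/z in
#'   Angstrom.
#' @slot box numeric(3) orthorhombic box lengths in Angstrom, or
#'   \code{NA} when the input supplied none.
#' @export
setClass("MemFrame",
  representation(atoms = "data.frame", coords = "matrix", box = "numeric")
)

setValidity("MemFrame", function(object) {
  msgs <- character(0)
  need <- c("atom_name", "residue_number", "residue_name", "segment_id")
  if (!all(need %in% names(object@atoms)))
    msgs <- c(msgs, paste("atoms table must have columns",
                          paste(need, collapse = ", ")))
  if (ncol(object@coords) != 3L)
    msgs <- c(msgs, "coords must have 3 columns")
  if (nrow(object@coords) != nrow(object@atoms))
    msgs <- c(msgs, "coords and atoms row counts differ")
  if (!all(is.finite(object@coords)))
    msgs <- c(msgs, "coordinates must be finite")
  if ("residue_number" %in% names(object@atoms) &&
      nrow(object@atoms) > 0 && any(object@atoms$residue_number < 1))
    msgs <- c(msgs, "residue numbers must be >= 1")
  if (length(object@box) != 3L)
    msgs <- c(msgs, "box must be numeric(3)")
  else if (!anyNA(object@box) && any(object@box <= 0))
    msgs <- c(msgs, "box lengths must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MemFrame
#' @param atoms particle table (see [MemFrame-class]).
#' @param coords n x 3 coordinate matrix in Angstrom.
#' @param box orthorhombic box lengths in Angstrom (\code{NA} if absent).
#' @return a [MemFrame-class] object.
#' @export
MemFrame <- function(atoms, coords, box = rep(NA_real_, 3)) {
  coords <- as.matrix(coords)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  new("MemFrame", atoms = as.data.frame(atoms), coords = coords,
      box = as.numeric(box))
}

#' Time-ordered trajectory of frames with a fixed particle list
#'
#' All frames share one particle table and atom ordering; coordinates are
#' stored as an \code{n_atoms x 3 x n_frames} array.
#'
#' @slot atoms shared particle table (as in [MemFrame-class]).
#' @slot coords numeric array \code{n_atoms x 3 x n_frames}, Angstrom.
#' @slot box numeric matrix \code{n_frames x 3} of box lengths.
#' @export
setClass("MemTrajectory",
  representation(atoms = "data.frame", coords = "array", box = "matrix")
)

setValidity("MemTrajectory", function(object) {
  msgs <- character(0)
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msgs <- c(msgs, "coords must be an n_atoms x 3 x n_frames array")
  else {
    if (d[1] != nrow(object@atoms))
      msgs <- c(msgs, "coords atom dimension does not match atoms table")
    if (nrow(object@box) != d[3])
      msgs <- c(msgs, "box must have one row per frame")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MemTrajectory
#' @param atoms shared particle table.
#' @param coords n_atoms x 3 x n_frames array (Angstrom).
#' @param box either numeric(3) applied to all frames or an
#'   n_frames x 3 matrix.
#' @return a [MemTrajectory-class] object.
#' @export
MemTrajectory <- function(atoms, coords, box = rep(NA_real_, 3)) {
  coords <- as.array(coords)
  if (length(dim(coords)) == 2L) dim(coords) <- c(dim(coords), 1L)
  nf <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  new("MemTrajectory", atoms = as.data.frame(atoms), coords = coords,
      box = as.matrix(box))
}

#' Synthetic membrane-protein system with analytic ground truth
#'
#' Bundles a generated trajectory, the segment map describing it, the
#' per-frame ground-truth orientation record computed in closed form from
#' the applied rigid-body transforms (independently of the analysis
#' kernels), and the generating parameters.
#'
#' @slot trajectory the generated [MemTrajectory-class].
#' @slot segmentMap the [SegmentMap-class] describing the pseudo-protein.
#' @slot groundTruth data.frame, one row per frame, columns \code{frame},
#'   \code{alpha}, \code{beta}, \code{gamma}, \code{heme_tilt},
#'   \code{d_globular}, \code{d_linker}, \code{d_fg}.
#' @slot spec list of generator parameters, including the seed.
#' @export
setClass("SyntheticSystem",
  representation(trajectory = "MemTrajectory", segmentMap = "SegmentMap",
                 groundTruth = "data.frame", spec = "list")
)

# ---- generics & accessors ---------------------------------------------------

#' @describeIn MemTrajectory-class number of frames
#' @param x object
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @describeIn MemTrajectory-class number of particles
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' Particle metadata table
#' @param x a MemFrame, MemTrajectory or SyntheticSystem
#' @export
setGeneric("particles", function(x) standardGeneric("particles"))
#' Coordinates (matrix for a frame, array for a trajectory)
#' @param x a MemFrame or MemTrajectory
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' Box dimensions in Angstrom
#' @param x a MemFrame or MemTrajectory
#' @export
setGeneric("boxDims", function(x) standardGeneric("boxDims"))
#' Extract one frame of a trajectory as a MemFrame
#' @param x a MemTrajectory
#' @param i frame index (1-based)
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' Residue-range segment list of a SegmentMap
#' @param x a SegmentMap
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' Ground-truth orientation series of a synthetic system
#' @param x a SyntheticSystem
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' Segment map of a synthetic system
#' @param x a SyntheticSystem
#' @export
setGeneric("segmentMap", function(x) standardGeneric("segmentMap"))
#' Trajectory of a synthetic system
#' @param x a SyntheticSystem
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' @rdname nFrames
#' @aliases nFrames,MemTrajectory-method
setMethod("nFrames", "MemTrajectory", function(x) dim(x@coords)[3])
#' @rdname nFrames
setMethod("nFrames", "MemFrame", function(x) 1L)
#' @rdname nAtoms
setMethod("nAtoms", "MemTrajectory", function(x) dim(x@coords)[1])
#' @rdname nAtoms
setMethod("nAtoms", "MemFrame", function(x) nrow(x@coords))
#' @rdname particles
setMethod("particles", "MemFrame", function(x) x@atoms)
#' @rdname particles
setMethod("particles", "MemTrajectory", function(x) x@atoms)
#' @rdname particles
setMethod("particles", "SyntheticSystem", function(x) x@trajectory@atoms)
#' @rdname coords
setMethod("coords", "MemFrame", function(x) x@coords)
#' @rdname coords
setMethod("coords", "MemTrajectory", function(x) x@coords)
#' @rdname boxDims
setMethod("boxDims", "MemFrame", function(x) x@box)
#' @rdname boxDims
setMethod("boxDims", "MemTrajectory", function(x) x@box)
#' @rdname getFrame
setMethod("getFrame", "MemTrajectory", function(x, i) {
  i <- as.integer(i)
  if (i < 1L || i > nFrames(x))
    .stopf("frame index %d out of range (trajectory has %d frames)",
           i, nFrames(x))
  MemFrame(x@atoms, x@coords[, , i], x@box[i, ])
})
#' @rdname segments
setMethod("segments", "SegmentMap", function(x) x@segments)
#' @rdname groundTruth
setMethod("groundTruth", "SyntheticSystem", function(x) x@groundTruth)
#' @rdname segmentMap
setMethod("segmentMap", "SyntheticSystem", function(x) x@segmentMap)
#' @rdname segmentMap
setMethod("segmentMap", "SegmentMap", function(x) x)
#' @rdname trajectory
setMethod("trajectory", "SyntheticSystem", function(x) x@trajectory)

setMethod("show", "SegmentMap", function(object) {
  cat("SegmentMap with", length(object@segments), "residue segments\n")
  for (nm in names(object@segments)) {
    r <- object@segments[[nm]]
    cat(sprintf("  %-14s %d-%d\n", nm, as.integer(r[1]), as.integer(r[2])))
  }
  if (length(object@hemeResidue))
    cat("  heme:", paste(object@hemeResidue, collapse = ","),
        "atoms", paste(object@hemeAtoms, collapse = ","), "\n")
  cat("  lipid head: {", paste(object@lipidHead, collapse = ", "), "}\n")
  cat("  lipid tail: {", paste(object@lipidTail, collapse = ", "), "}\n")
})

setMethod("show", "MemFrame", function(object) {
  cat("MemFrame:", nrow(object@coords), "particles,",
      length(unique(object@atoms$residue_number)), "residues")
  if (!anyNA(object@box))
    cat(sprintf(", box %.1f x %.1f x %.1f A", object@box[1], object@box[2],
                object@box[3]))
  cat("\n")
})

setMethod("show", "MemTrajectory", function(object) {
  cat("MemTrajectory:", nFrames(object), "frames x", nAtoms(object),
      "particles\n")
})

setMethod("show", "SyntheticSystem", function(object) {
  cat("SyntheticSystem:", nFrames(object@trajectory), "frames,",
      nAtoms(object@trajectory), "particles (seed",
      object@spec$seed, ")\n")
  gt <- object@groundTruth[1, ]
  cat(sprintf("  frame-1 truth: alpha %.2f, beta %.2f, gamma %.2f, heme %.2f, d_glob %.2f A\n",
              gt$alpha, gt$beta, gt$gamma, gt$heme_tilt, gt$d_globular))
})
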