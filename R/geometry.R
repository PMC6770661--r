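# Pure geometric kernels: centers of mass, axis vectors, angles to the
# membrane normal (+z), heme plane, axial distances, Kabsch superposition,
# RMSD and RMSF-derived B-factors.
#
# Conventions: the membrane normal is the +z axis.  Angles to the normal
# are reported unfolded in [0, 180] for the orientation vectors v1/v2
# (alpha, beta) and folded to [0, 90] for the TM tilt (gamma) and the
# heme tilt.

#' Center of mass of a particle selection
#'
#' @param frame a [MemFrame-class].
#' @param select logical or integer particle index; default all particles.
#' @param weighting \code{"uniform"} (every particle weight 1; appropriate
#'   for coarse-grained beads) or \code{"element"} (atomic masses inferred
#'   from atom names; appropriate for atomistic input).
#' @return numeric(3) position in Angstrom.
#' @export
centerOfMass <- function(frame, select = NULL,
                         weighting = c("uniform", "element")) {
  weighting <- match.arg(weighting)
  stopifnot(is(frame, "MemFrame"))
  xyz <- frame@coords
  nms <- frame@atoms$atom_name
  if (!is.null(select)) {
    xyz <- xyz[select, , drop = FALSE]
    nms <- nms[select]
  }
  if (nrow(xyz) == 0L) stop("center of mass of an empty particle set")
  w <- if (weighting == "element") .atomMasses(nms) else NULL
  .comMat(xyz, w)
}

.backboneIdx <- function(atoms, segmap) {
  atoms$atom_name %in% segmap@backboneNames
}

# CoM of the backbone particles of `terminalN` residues at one end of a
# residue range; residues ordered by residue number
.terminalCom <- function(frame, resnos, which = c("first", "last"),
                         terminalN, weighting) {
  which <- match.arg(which)
  resnos <- sort(unique(resnos))
  take <- if (which == "first") utils::head(resnos, terminalN) else
    utils::tail(resnos, terminalN)
  sel <- frame@atoms$residue_number %in% take
  centerOfMass(frame, sel, weighting)
}

#' Axis vector of a helical segment
#'
#' The vector from the center of mass of the backbone particles of the
#' first \code{terminalN} residues of the range to the center of mass of
#' the backbone particles of the last \code{terminalN} residues.  This is
#' the construction behind the orientation vectors: v1 along the I-helix,
#' v2 from the C-helix start to the F-helix end, v3 along the TM-helix.
#'
#' @param frame a [MemFrame-class].
#' @param range inclusive residue range \code{c(first, last)}.
#' @param segmap a [SegmentMap-class] (supplies backbone particle names).
#' @param terminalN residues averaged at each end (default 4).
#' @param weighting CoM weighting, see [centerOfMass()].
#' @return numeric(3) vector (Angstrom, not normalized).
#' @export
axisVector <- function(frame, range, segmap, terminalN = 4L,
                       weighting = c("uniform", "element")) {
  weighting <- match.arg(weighting)
  bb <- .backboneIdx(frame@atoms, segmap)
  inR <- frame@atoms$residue_number >= range[1] &
    frame@atoms$residue_number <= range[2]
  resnos <- frame@atoms$residue_number[bb & inR]
  nres <- length(unique(resnos))
  if (nres < 2L * terminalN)
    .stopf("residue range %d-%d has %d backbone residues; at least %d are needed for terminal %d-residue centers of mass",
           as.integer(range[1]), as.integer(range[2]), nres,
           2L * terminalN, terminalN)
  keep <- bb & inR
  fr <- MemFrame(frame@atoms[keep, , drop = FALSE],
                 frame@coords[keep, , drop = FALSE], frame@box)
  .terminalCom(fr, fr@atoms$residue_number, "last", terminalN, weighting) -
    .terminalCom(fr, fr@atoms$residue_number, "first", terminalN, weighting)
}

#' Angle between a vector and the membrane normal
#'
#' Unfolded angle in degrees, \code{acos(v.z / |v|)}, in [0, 180].  Used
#' for the orientation angles alpha (v1) and beta (v2).
#'
#' @param v numeric(3) vector.
#' @return angle in degrees.
#' @export
angleToNormal <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("zero-length vector has no angle to the normal")
  .deg(acos(min(1, max(-1, v[3] / nv))))
}

#' Tilt angle of an axis (folded to [0, 90])
#'
#' \code{min(theta, 180 - theta)} of [angleToNormal()]: the tilt of an
#' undirected axis such as the TM-helix (gamma).
#'
#' @param v numeric(3) vector.
#' @return angle in degrees in [0, 90].
#' @export
tiltAngle <- function(v) {
  th <- angleToNormal(v)
  min(th, 180 - th)
}

.hemeIdx <- function(atoms, segmap) {
  if (!length(segmap@hemeResidue)) return(integer(0))
  which(atoms$residue_name %in% segmap@hemeResidue &
          atoms$atom_name %in% segmap@hemeAtoms)
}

#' Heme-tilt angle
#'
#' The angle between the heme plane -- the least-squares plane through the
#' four nitrogen atoms coordinating the iron -- and the membrane normal
#' axis, folded to [0, 90].  Geometrically this is the plane-line angle
#' \code{90 - fold(angle(n, z))} where \code{n} is the plane normal: a heme
#' lying flat in the membrane plane gives 90 degrees, a heme standing
#' perpendicular to it gives 0.
#'
#' @param frame a [MemFrame-class].
#' @param segmap a [SegmentMap-class] with a heme selection.
#' @return angle in degrees in [0, 90].
#' @export
hemeTilt <- function(frame, segmap) {
  idx <- .hemeIdx(frame@atoms, segmap)
  if (length(idx) != 4L)
    .stopf("heme selection matched %d particles; exactly 4 nitrogen atoms are required",
           length(idx))
  pts <- frame@coords[idx, , drop = FALSE]
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12))
    stop("degenerate heme geometry: the four nitrogens are collinear")
  n <- sv$v[, 3]
  90 - tiltAngle(n)
}

#' Axial center-of-mass distances to the bilayer midplane
#'
#' Absolute z distances of the centers of mass of the globular domain, the
#' linker, and the F'-G' region from the center of mass of all lipid
#' particles.
#'
#' @param frame a [MemFrame-class].
#' @param segmap a [SegmentMap-class]; lipid particles are those whose
#'   atom name is in the head or tail sets.
#' @param weighting CoM weighting, see [centerOfMass()].
#' @return named numeric: \code{d_globular}, \code{d_linker}, \code{d_fg}
#'   in Angstrom (\code{NA} for segments absent from the map).
#' @export
axialDistances <- function(frame, segmap,
                           weighting = c("uniform", "element")) {
  weighting <- match.arg(weighting)
  at <- frame@atoms
  lipid <- at$atom_name %in% c(segmap@lipidHead, segmap@lipidTail)
  if (!any(lipid))
    stop("no lipid particles found: axial distances need a bilayer (configuration error)")
  zLip <- unname(centerOfMass(frame, lipid, weighting)[3])
  segZ <- function(nm) {
    r <- segmap@segments[[nm]]
    if (is.null(r)) return(NA_real_)
    sel <- !lipid & at$residue_number >= r[1] & at$residue_number <= r[2]
    if (!any(sel)) return(NA_real_)
    unname(abs(centerOfMass(frame, sel, weighting)[3] - zLip))
  }
  c(d_globular = segZ("globular"), d_linker = segZ("linker"),
    d_fg = segZ("fprime_gprime"))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of the selected particles of a mobile frame
#' onto a reference; the returned RMSD is minimal over all rigid
#' transforms.
#'
#' @param mobile,reference [MemFrame-class] objects with matching
#'   selections.
#' @param select logical or integer particle index applied to both frames
#'   (default: all particles).
#' @return list with \code{R} (3x3 rotation), \code{t} (translation),
#'   \code{rmsd} (Angstrom), and \code{coords} (all mobile coordinates
#'   after the fit).  The transform maps mobile coordinates as
#'   \code{x R + t}.
#' @export
superposeFrames <- function(mobile, reference, select = NULL) {
  stopifnot(is(mobile, "MemFrame"), is(reference, "MemFrame"))
  mAll <- mobile@coords
  m <- if (is.null(select)) mAll else mAll[select, , drop = FALSE]
  r <- if (is.null(select)) reference@coords else
    reference@coords[select, , drop = FALSE]
  if (nrow(m) != nrow(r))
    .stopf("selection sizes differ: %d mobile vs %d reference particles",
           nrow(m), nrow(r))
  if (nrow(m) < 3L)
    stop("superposition needs at least 3 particles")
  mc <- colMeans(m); rc <- colMeans(r)
  M <- sweep(m, 2, mc); Rf <- sweep(r, 2, rc)
  sv <- svd(crossprod(M, Rf))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12))
    stop("superposition needs at least 3 non-collinear particles")
  d <- sign(det(sv$v %*% t(sv$u)))
  Rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t <- rc - mc %*% Rot
  fitSel <- sweep(M %*% Rot, 2, rc, "+")
  rmsd <- sqrt(mean(rowSums((fitSel - r)^2)))
  fitAll <- sweep(sweep(mAll, 2, mc) %*% Rot, 2, rc, "+")
  list(R = Rot, t = as.numeric(t), rmsd = rmsd, coords = fitAll)
}

#' C-alpha (backbone) RMSD time series of a trajectory
#'
#' Per-frame minimal RMSD of the selected particles against a reference
#' frame after optimal superposition; the standard structural-stability
#' readout of a simulation.
#'
#' @param traj a [MemTrajectory-class].
#' @param reference a [MemFrame-class] (default: first frame).
#' @param select particle selection (default: backbone particles per
#'   \code{segmap}; if \code{segmap} is NULL, all particles).
#' @param segmap optional [SegmentMap-class] used for the default
#'   backbone selection.
#' @return numeric vector of RMSD (Angstrom), one per frame.
#' @export
rmsdSeries <- function(traj, reference = NULL, select = NULL, segmap = NULL) {
  stopifnot(is(traj, "MemTrajectory"))
  if (is.null(reference)) reference <- getFrame(traj, 1L)
  if (is.null(select) && !is.null(segmap))
    select <- .backboneIdx(traj@atoms, segmap)
  vapply(seq_len(nFrames(traj)), function(f) {
    superposeFrames(getFrame(traj, f), reference, select)$rmsd
  }, numeric(1))
}

#' Per-residue B-factors from trajectory fluctuations
#'
#' Computes \code{B_i = (8 pi^2 / 3) <|r_i - <r_i>|^2>} from the positional
#' fluctuations about the mean structure, averaged over the selected
#' particles of each residue: the quantity compared against
#' crystallographic B-factors.  Frames are assumed pre-superposed onto a
#' common reference; set \code{fit = TRUE} to superpose each frame onto
#' the first frame beforehand.
#'
#' @param traj a [MemTrajectory-class] with at least 2 frames.
#' @param select particle selection (default: all particles).
#' @param fit superpose frames onto frame 1 before measuring fluctuations.
#' @return data.frame with \code{residue_number} and \code{bfactor}
#'   (Angstrom squared).
#' @export
rmsfBfactor <- function(traj, select = NULL, fit = FALSE) {
  stopifnot(is(traj, "MemTrajectory"))
  nf <- nFrames(traj)
  if (nf < 2L) stop("B-factor computation needs at least 2 frames")
  idx <- if (is.null(select)) seq_len(nAtoms(traj)) else
    if (is.logical(select)) which(select) else as.integer(select)
  xyz <- traj@coords[idx, , , drop = FALSE]
  if (fit) {
    ref <- getFrame(traj, 1L)
    for (f in seq_len(nf)) {
      fitted <- superposeFrames(getFrame(traj, f), ref, idx)$coords
      xyz[, , f] <- fitted[idx, ]
    }
  }
  mean3 <- apply(xyz, c(1, 2), mean)
  dev2 <- sweep(xyz, c(1, 2), mean3)^2
  msf <- apply(dev2, 1, sum) / nf          # <|r - <r>|^2> per particle
  resno <- traj@atoms$residue_number[idx]
  agg <- tapply(msf, resno, mean)
  data.frame(residue_number = as.integer(names(agg)),
             bfactor = as.numeric(agg) * (8 * pi^2 / 3),
             row.names = NULL)
}
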