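# Per-residue protein-lipid contact occupancy split into head-group and
# tail interactions.

#' Per-residue lipid contact occupancy
#'
#' For each protein residue, the percentage of analyzed frames in which
#' any of its particles lies within the cutoff of any lipid head-group
#' (phosphate) particle, and separately of any lipid tail particle.
#' Distances use the minimal-image convention in x and y only (the
#' membrane is periodic in-plane; the protein does not wrap in z in these
#' systems).  Hydrogens are excluded from the protein side by default so
#' the cutoff is calibrated on heavy atoms; coarse-grained beads are
#' unaffected.
#'
#' @param traj a [MemTrajectory-class].
#' @param segmap a [SegmentMap-class] with disjoint, non-empty lipid head
#'   and tail particle name sets.
#' @param cutoff contact distance cutoff in Angstrom (default 5).
#' @param window analysis window, see [summarizeOrientation()].
#' @param stride keep every stride-th frame of the window.
#' @param excludeHydrogens drop protein particles whose inferred element
#'   is H.
#' @return data.frame (an occupancy table) with \code{residue_number},
#'   \code{residue_name}, \code{head_pct}, \code{tail_pct}; attribute
#'   \code{n_frames}.
#' @export
contactOccupancy <- function(traj, segmap, cutoff = 5, window = NULL,
                             stride = 1L, excludeHydrogens = TRUE) {
  stopifnot(is(traj, "MemTrajectory"), is(segmap, "SegmentMap"))
  if (!length(segmap@lipidHead) || !length(segmap@lipidTail))
    stop("configuration error: lipid head and tail particle sets must be non-empty")
  overlap <- intersect(segmap@lipidHead, segmap@lipidTail)
  if (length(overlap))
    .stopf("configuration error: lipid head and tail sets overlap (%s)",
           paste(overlap, collapse = ", "))
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  at <- traj@atoms
  headIdx <- which(at$atom_name %in% segmap@lipidHead)
  tailIdx <- which(at$atom_name %in% segmap@lipidTail)
  if (!length(headIdx) || !length(tailIdx))
    stop("no lipid head or tail particles found in the trajectory")
  protIdx <- which(!(at$atom_name %in% c(segmap@lipidHead,
                                         segmap@lipidTail)))
  if (excludeHydrogens)
    protIdx <- protIdx[.elementFromName(at$atom_name[protIdx]) != "H"]
  if (!length(protIdx)) stop("no protein particles found")
  frames <- .windowIdx(nFrames(traj), window, stride)
  resno <- at$residue_number[protIdx]
  resLevels <- sort(unique(resno))
  resFac <- factor(resno, levels = resLevels)
  headHits <- tailHits <- integer(length(resLevels))
  cut2 <- cutoff^2
  for (f in frames) {
    xyz <- traj@coords[, , f]
    box <- traj@box[f, ]
    if (anyNA(box))
      stop("configuration error: contact analysis needs box dimensions for the in-plane minimal-image convention")
    p <- xyz[protIdx, , drop = FALSE]
    hc <- .anyContactPerAtom(p, xyz[headIdx, , drop = FALSE], box, cut2)
    tc <- .anyContactPerAtom(p, xyz[tailIdx, , drop = FALSE], box, cut2)
    headHits <- headHits + as.logical(tapply(hc, resFac, any))
    tailHits <- tailHits + as.logical(tapply(tc, resFac, any))
  }
  nf <- length(frames)
  out <- data.frame(
    residue_number = resLevels,
    residue_name = at$residue_name[protIdx][match(resLevels, resno)],
    head_pct = 100 * headHits / nf,
    tail_pct = 100 * tailHits / nf,
    stringsAsFactors = FALSE
  )
  attr(out, "n_frames") <- nf
  attr(out, "cutoff") <- cutoff
  out
}

# for each row of p, whether any row of l lies within sqrt(cut2), with
# minimal image applied in x and y
.anyContactPerAtom <- function(p, l, box, cut2) {
  dx <- outer(p[, 1], l[, 1], "-")
  dx <- dx - box[1] * round(dx / box[1])
  dy <- outer(p[, 2], l[, 2], "-")
  dy <- dy - box[2] * round(dy / box[2])
  dz <- outer(p[, 3], l[, 3], "-")
  rowSums(dx * dx + dy * dy + dz * dz <= cut2) > 0
}

#' Annotate an occupancy table with structural-region labels
#'
#' Attaches overlapping region labels (e.g. substrate-recognition sites or
#' secondary-structure elements given as residue ranges) to each residue
#' row, keeps only residues with non-zero occupancy, and sorts by residue
#' number.
#'
#' @param table occupancy table from [contactOccupancy()].
#' @param annotations named list of inclusive residue ranges, e.g.
#'   \code{list("F'-G'" = c(210, 226))}; \code{NULL} or empty passes the
#'   table through unlabeled.
#' @return the filtered, annotated occupancy table (column
#'   \code{annotation}, comma-separated labels).
#' @export
occupancyReport <- function(table, annotations = NULL) {
  keep <- table$head_pct > 0 | table$tail_pct > 0
  out <- table[keep, , drop = FALSE]
  out <- out[order(out$residue_number), , drop = FALSE]
  lab <- character(nrow(out))
  if (length(annotations)) {
    for (nm in names(annotations)) {
      r <- annotations[[nm]]
      hit <- out$residue_number >= r[1] & out$residue_number <= r[2]
      lab[hit] <- ifelse(nzchar(lab[hit]), paste(lab[hit], nm, sep = ","),
                         nm)
    }
  }
  out$annotation <- lab
  rownames(out) <- NULL
  out
}
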