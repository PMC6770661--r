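# Synthetic pseudo CYP-membrane systems with analytic ground truth.
#
# A rigid two-part body -- a globular scaffold carrying labeled I-, C-,
# F-helices, an F'-G' stub and a planar 4-point heme, plus a TM anchor
# helix joined by a straight linker -- is posed over a planar two-leaflet
# pseudo-bilayer at requested orientation targets.  Ground truth is
# computed in closed form from the applied rotation and the constructed
# coordinates (plain arithmetic, independent of the analysis kernels), so
# parameter-recovery tests are not self-fulfilling.

#' Specification of a synthetic membrane-protein system
#'
#' Defaults reproduce the class-A regime of a full-length drug-metabolizing
#' CYP over a phosphocholine bilayer: alpha 90, beta 112, TM tilt 15,
#' heme tilt 40 degrees, globular-domain CoM 43 Angstrom above the bilayer
#' midplane, bilayer half-thickness 19 Angstrom.
#'
#' @param alpha,beta orientation angles of the v1/v2 axes to the membrane
#'   normal, degrees (unfolded).
#' @param gamma TM-helix tilt, degrees in [0, 90).
#' @param hemeTilt heme-plane tilt target, degrees in (0, 90].
#' @param dGlobular axial distance of the globular-domain CoM from the
#'   bilayer midplane, Angstrom.
#' @param nFrames number of trajectory frames.
#' @param jitter per-coordinate Gaussian positional noise sigma, Angstrom.
#' @param drift optional list \code{(alpha, beta, gamma, hemeTilt,
#'   dGlobular, switchFrame)}: the orientation is interpolated
#'   (spherically, as rigid-body poses) from the primary targets to these
#'   final targets over frames 1..switchFrame and held constant after.
#' @param halfThickness bilayer leaflet half-thickness, Angstrom
#'   (head-group plane at +/- this z).
#' @param gridSpacing in-plane lipid grid spacing, Angstrom (default 8,
#'   approximating the area per phosphocholine lipid).
#' @param gridN lipids per box edge (gridN x gridN per leaflet).
#' @param boxZ box height, Angstrom.
#' @param v12Angle fixed body-frame angle between v1 and v2, degrees; it
#'   bounds the reachable (alpha, beta) combinations.
#' @param seed RNG seed recorded in the output.
#' @param iHelix,cHelix,fHelix,fgRegion,tmHelix,linker,globular residue
#'   ranges of the pseudo-protein segments.
#' @return a validated list of class \code{SyntheticSpec}.
#' @export
syntheticSpec <- function(alpha = 90, beta = 112, gamma = 15,
                          hemeTilt = 40, dGlobular = 43,
                          nFrames = 1L, jitter = 0, drift = NULL,
                          halfThickness = 19, gridSpacing = 8,
                          gridN = 12L, boxZ = 140, v12Angle = 85,
                          seed = 1L,
                          iHelix = c(286, 316), cHelix = c(118, 135),
                          fHelix = c(190, 209), fgRegion = c(210, 220),
                          tmHelix = c(3, 21), linker = c(22, 49),
                          globular = c(50, 490)) {
  spec <- list(alpha = alpha, beta = beta, gamma = gamma,
               hemeTilt = hemeTilt, dGlobular = dGlobular,
               nFrames = as.integer(nFrames), jitter = jitter,
               drift = drift, halfThickness = halfThickness,
               gridSpacing = gridSpacing, gridN = as.integer(gridN),
               boxZ = boxZ, v12Angle = v12Angle, seed = as.integer(seed),
               iHelix = iHelix, cHelix = cHelix, fHelix = fHelix,
               fgRegion = fgRegion, tmHelix = tmHelix, linker = linker,
               globular = globular)
  if (alpha < 0 || alpha > 180 || beta < 0 || beta > 180)
    stop("alpha and beta must lie in [0, 180] degrees")
  if (gamma < 0 || gamma >= 90) stop("gamma must lie in [0, 90) degrees")
  if (hemeTilt < 0 || hemeTilt > 90)
    stop("heme tilt must lie in [0, 90] degrees")
  if (halfThickness <= 0) stop("bilayer half-thickness must be positive")
  if (gridSpacing <= 0) stop("grid spacing must be positive")
  if (jitter < 0) stop("jitter sigma must be non-negative")
  if (spec$nFrames < 1L) stop("nFrames must be >= 1")
  if (!is.null(drift)) {
    need <- c("alpha", "beta", "switchFrame")
    if (!all(need %in% names(drift)))
      stop("drift needs at least alpha, beta and switchFrame")
    if (is.null(drift$gamma)) spec$drift$gamma <- gamma
    if (is.null(drift$dGlobular)) spec$drift$dGlobular <- dGlobular
    if (drift$switchFrame < 1 || drift$switchFrame > spec$nFrames)
      stop("drift switchFrame outside the trajectory")
  }
  class(spec) <- "SyntheticSpec"
  spec
}

# rotation taking the body-frame v1 (+z) and v2 (at delta degrees from v1
# in the xz-plane) to lab directions at polar angles alpha and beta; the
# azimuth of the posed v2 follows from the spherical law of cosines
.poseRotation <- function(alpha, beta, delta) {
  a <- alpha / .RAD2DEG; b <- beta / .RAD2DEG; d <- delta / .RAD2DEG
  lo <- abs(alpha - delta)
  hi <- min(alpha + delta, 360 - alpha - delta)
  v1b <- c(0, 0, 1)
  v2b <- c(sin(d), 0, cos(d))
  if (sin(a) < 1e-12 || sin(b) < 1e-12) {
    # pole cases: the v2 polar angle is forced to alpha -/+ delta
    if (abs(beta - lo) > 1e-9 && abs(beta - hi) > 1e-9)
      .stopf("unreachable orientation: with alpha = %g and a v1-v2 separation of %g degrees, beta must lie in [%g, %g]",
             alpha, delta, lo, hi)
    phi <- 0
  } else {
    cphi <- (cos(d) - cos(a) * cos(b)) / (sin(a) * sin(b))
    if (cphi > 1 + 1e-9 || cphi < -1 - 1e-9)
      .stopf("unreachable orientation: with alpha = %g and a v1-v2 separation of %g degrees, beta must lie in [%g, %g]",
             alpha, delta, lo, hi)
    phi <- acos(min(1, max(-1, cphi)))
  }
  u1 <- c(sin(a), 0, cos(a))
  u2 <- c(sin(b) * cos(phi), sin(b) * sin(phi), cos(b))
  frameOf <- function(p, q) {
    e1 <- p / sqrt(sum(p^2))
    q2 <- q - sum(q * e1) * e1
    n2 <- sqrt(sum(q2^2))
    if (n2 < 1e-12)
      stop("degenerate geometry: v1 and v2 are parallel")
    e2 <- q2 / n2
    cbind(e1, e2, c(e1[2] * e2[3] - e1[3] * e2[2],
                    e1[3] * e2[1] - e1[1] * e2[3],
                    e1[1] * e2[2] - e1[2] * e2[1]))
  }
  frameOf(u1, u2) %*% t(frameOf(v1b, v2b))
}

# golden-angle spiral on a sphere: deterministic filler positions
.spherePoints <- function(n, radius) {
  j <- seq_len(n)
  zs <- 1 - 2 * (j - 0.5) / n
  r <- sqrt(pmax(0, 1 - zs^2))
  th <- j * 2.399963229728653
  radius * cbind(r * cos(th), r * sin(th), zs)
}

#' Build the rigid pseudo-protein body (body frame)
#'
#' Constructs a one-bead-per-residue scaffold whose I-helix axis is the
#' body-frame v1 (+z), whose C-to-F helix vector realizes v2 at the fixed
#' \code{v12Angle}, with an F'-G' stub, globular filler residues on a
#' sphere, and four heme pseudo-nitrogens in a plane whose normal is
#' chosen so the initial pose meets the heme-tilt target.
#'
#' @param spec a [syntheticSpec()].
#' @return list with \code{frame} (body-frame [MemFrame-class], protein +
#'   heme only), \code{segmap} ([SegmentMap-class]), \code{v1}, \code{v2},
#'   \code{hemeNormal} (body-frame unit vectors) and \code{spec}.
#' @export
buildBody <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  d <- spec$v12Angle / .RAD2DEG
  v1b <- c(0, 0, 1)
  v2b <- c(sin(d), 0, cos(d))
  segmap <- SegmentMap(
    tm_helix = spec$tmHelix, linker = spec$linker,
    globular = spec$globular, c_helix = spec$cHelix,
    f_helix = spec$fHelix, i_helix = spec$iHelix,
    fprime_gprime = spec$fgRegion,
    hemeResidue = "HEM",
    lipidHead = "PO4", lipidTail = c("C1A", "C2A"),
    backboneNames = c("CA", "BB")
  )
  rise <- 1.5
  seg <- function(range) seq.int(range[1], range[2])
  iRes <- seg(spec$iHelix); cRes <- seg(spec$cHelix)
  fRes <- seg(spec$fHelix); gRes <- seg(spec$fgRegion)
  # I-helix along +z, centered at the origin
  iPos <- cbind(0, 0, (seq_along(iRes) - (length(iRes) + 1) / 2) * rise)
  # C-helix along +x; F-helix along +x positioned so that the CoM of the
  # first four C residues to the CoM of the last four F residues is
  # exactly 30 A along v2
  pC <- c(-15, 8, -12)
  cPos <- cbind(pC[1] + (seq_along(cRes) - 1) * rise, pC[2], pC[3])
  c1 <- pC + c((0 + 1 + 2 + 3) / 4 * rise, 0, 0)
  pF <- c1 + 30 * v2b - c((length(fRes) - 1 - 1.5) * rise, 0, 0)
  fPos <- cbind(pF[1] + (seq_along(fRes) - 1) * rise, pF[2], pF[3])
  # F'-G' stub along +y, low on the body so it sits membrane-proximal
  gPos <- cbind(10, -15 + (seq_along(gRes) - (length(gRes) + 1) / 2) * rise,
                -18)
  used <- c(iRes, cRes, fRes, gRes)
  fill <- setdiff(seg(spec$globular), used)
  fPosFill <- .spherePoints(length(fill), 18)
  resno <- c(iRes, cRes, fRes, gRes, fill)
  xyz <- rbind(iPos, cPos, fPos, gPos, fPosFill)
  ord <- order(resno)
  resno <- resno[ord]
  xyz <- xyz[ord, , drop = FALSE]
  atoms <- data.frame(atom_name = "BB", residue_number = resno,
                      residue_name = "GLY", segment_id = "P",
                      stringsAsFactors = FALSE)
  # heme: 4 nitrogens on a square in a plane whose body-frame normal is
  # chosen so that the initial pose meets the heme-tilt target
  R0 <- .poseRotation(spec$alpha, spec$beta, spec$v12Angle)
  h <- spec$hemeTilt / .RAD2DEG
  nLab <- c(cos(h), 0, sin(h))   # polar angle 90 - hemeTilt
  nB <- as.numeric(t(R0) %*% nLab)
  ref <- if (abs(nB[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * nB) * nB
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nB[2] * e1[3] - nB[3] * e1[2],
          nB[3] * e1[1] - nB[1] * e1[3],
          nB[1] * e1[2] - nB[2] * e1[1])
  hemeCtr <- c(0, 5, 0)
  hemeXyz <- rbind(hemeCtr + 2.05 * e1, hemeCtr + 2.05 * e2,
                   hemeCtr - 2.05 * e1, hemeCtr - 2.05 * e2)
  hemeAtoms <- data.frame(atom_name = c("NA", "NB", "NC", "ND"),
                          residue_number = 999L, residue_name = "HEM",
                          segment_id = "P", stringsAsFactors = FALSE)
  frame <- MemFrame(rbind(atoms, hemeAtoms), rbind(xyz, hemeXyz))
  list(frame = frame, segmap = segmap, v1 = v1b, v2 = v2b,
       hemeNormal = nB, spec = spec)
}

#' Build the planar two-leaflet pseudo-bilayer
#'
#' Head beads (\code{PO4}) on a square grid at z = +/- half-thickness;
#' two tail beads per lipid between them.  The lipid z-CoM is 0 by
#' construction.
#'
#' @param spec a [syntheticSpec()].
#' @return a [MemFrame-class] of lipid particles with the box set.
#' @export
buildBilayer <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  s <- spec$gridSpacing; n <- spec$gridN; h <- spec$halfThickness
  off <- (seq_len(n) - (n + 1) / 2) * s
  g <- expand.grid(x = off, y = off)
  nl <- nrow(g)
  mk <- function(zH, resBase) {
    z <- c(zH, zH * 2 / 3, zH / 3)
    nm <- c("PO4", "C1A", "C2A")
    data.frame(
      atom_name = rep(nm, nl),
      residue_number = rep(resBase + seq_len(nl) - 1L, each = 3L),
      residue_name = "POP", segment_id = "M",
      x = rep(g$x, each = 3L), y = rep(g$y, each = 3L),
      z = rep(z, nl), stringsAsFactors = FALSE
    )
  }
  up <- mk(h, 1001L)
  dn <- mk(-h, 1001L + nl)
  all <- rbind(up, dn)
  MemFrame(all[c("atom_name", "residue_number", "residue_name",
                 "segment_id")],
           as.matrix(all[c("x", "y", "z")]),
           box = c(n * s, n * s, spec$boxZ))
}

# pose the body at a given rotation/tilt/height and attach TM + linker;
# returns coordinates (protein+heme, body atom order, then TM, then
# linker) plus closed-form ground truth
.poseAt <- function(body, R, gamma, dGlob) {
  spec <- body$spec
  rise <- 1.5
  at <- body$frame@atoms
  xyz <- body$frame@coords %*% t(R)
  glob <- at$residue_number >= spec$globular[1] &
    at$residue_number <= spec$globular[2]
  shift <- c(-colMeans(xyz[glob, 1:2, drop = FALSE]),
             dGlob - mean(xyz[glob, 3]))
  xyz <- sweep(xyz, 2, shift, "+")
  # TM helix through the membrane center at tilt gamma
  g <- gamma / .RAD2DEG
  uTm <- c(sin(g), 0, cos(g))
  tmRes <- seq.int(spec$tmHelix[1], spec$tmHelix[2])
  k <- seq_along(tmRes) - (length(tmRes) + 1) / 2
  tmXyz <- t(vapply(k, function(kk) kk * rise * uTm, numeric(3)))
  tmAtoms <- data.frame(atom_name = "BB", residue_number = tmRes,
                        residue_name = "GLY", segment_id = "P",
                        stringsAsFactors = FALSE)
  # straight linker from the TM top to the first globular residue
  lkRes <- seq.int(spec$linker[1], spec$linker[2])
  pTop <- tmXyz[nrow(tmXyz), ]
  p50 <- xyz[which(at$residue_number == spec$globular[1])[1], ]
  tt <- seq_along(lkRes) / (length(lkRes) + 1)
  lkXyz <- t(vapply(tt, function(s) pTop + s * (p50 - pTop), numeric(3)))
  lkAtoms <- data.frame(atom_name = "BB", residue_number = lkRes,
                        residue_name = "GLY", segment_id = "P",
                        stringsAsFactors = FALSE)
  allAtoms <- rbind(at, tmAtoms, lkAtoms)
  allXyz <- rbind(xyz, tmXyz, lkXyz)
  # closed-form ground truth from R and the constructed coordinates
  ang <- function(v) .deg(acos(min(1, max(-1, v[3] / sqrt(sum(v^2))))))
  fold <- function(x) min(x, 180 - x)
  nLab <- as.numeric(R %*% body$hemeNormal)
  fg <- allAtoms$residue_number >= spec$fgRegion[1] &
    allAtoms$residue_number <= spec$fgRegion[2] &
    allAtoms$residue_name != "HEM"
  lk <- allAtoms$residue_number %in% lkRes & allAtoms$residue_name != "HEM"
  truth <- c(
    alpha = ang(as.numeric(R %*% body$v1)),
    beta = ang(as.numeric(R %*% body$v2)),
    gamma = fold(ang(uTm)),
    heme_tilt = 90 - fold(ang(nLab)),
    d_globular = abs(dGlob),
    d_linker = abs(mean(allXyz[lk, 3])),
    d_fg = abs(mean(allXyz[fg, 3]))
  )
  list(atoms = allAtoms, xyz = allXyz, truth = truth)
}

#' Pose the body at orientation targets (lab frame)
#'
#' Rotates the rigid body so the v1/v2 axes meet the alpha/beta targets
#' (erroring, with the feasible beta interval, when the fixed v1-v2
#' separation makes the combination unreachable), raises the globular CoM
#' to the target height, and attaches the TM helix at the target tilt
#' with a straight linker.  Ground truth is computed in closed form from
#' the rotation and the constructed coordinates.
#'
#' @param body from [buildBody()].
#' @param alpha,beta,gamma,dGlobular orientation targets (defaults: the
#'   body's spec).
#' @return list with \code{frame} (lab-frame protein [MemFrame-class])
#'   and \code{truth} (named numeric ground-truth record).
#' @export
poseBody <- function(body, alpha = body$spec$alpha, beta = body$spec$beta,
                     gamma = body$spec$gamma,
                     dGlobular = body$spec$dGlobular) {
  R <- .poseRotation(alpha, beta, body$spec$v12Angle)
  p <- .poseAt(body, R, gamma, dGlobular)
  list(frame = MemFrame(p$atoms, p$xyz), truth = p$truth)
}

#' Emit a synthetic trajectory with per-frame ground truth
#'
#' Poses the body over the bilayer for each frame, applying spherical
#' interpolation between the initial and final orientations when a drift
#' is configured (intermediate frames remain rigid-body poses, held at the
#' final target after the switch frame), then adds iid Gaussian jitter to
#' every coordinate.  All randomness comes from the recorded seed; equal
#' seeds give bit-identical trajectories.
#'
#' @param spec a [syntheticSpec()].
#' @return a [SyntheticSystem-class].
#' @export
emitTrajectory <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  body <- buildBody(spec)
  bil <- buildBilayer(spec)
  R0 <- .poseRotation(spec$alpha, spec$beta, spec$v12Angle)
  drift <- spec$drift
  R1 <- if (!is.null(drift))
    .poseRotation(drift$alpha, drift$beta, spec$v12Angle) else R0
  nf <- spec$nFrames
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec$seed)
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                  envir = globalenv())
  })
  frames <- vector("list", nf)
  truths <- vector("list", nf)
  atoms <- NULL
  for (f in seq_len(nf)) {
    if (is.null(drift)) {
      R <- R0; g <- spec$gamma; dG <- spec$dGlobular
    } else {
      s <- if (drift$switchFrame <= 1L) 1 else
        min(1, (f - 1) / (drift$switchFrame - 1))
      R <- .slerpRot(R0, R1, s)
      g <- (1 - s) * spec$gamma + s * spec$drift$gamma
      dG <- (1 - s) * spec$dGlobular + s * spec$drift$dGlobular
    }
    p <- .poseAt(body, R, g, dG)
    if (is.null(atoms)) atoms <- rbind(p$atoms, bil@atoms)
    xyz <- rbind(p$xyz, bil@coords)
    if (spec$jitter > 0)
      xyz <- xyz + stats::rnorm(length(xyz), sd = spec$jitter)
    frames[[f]] <- xyz
    truths[[f]] <- p$truth
  }
  arr <- array(unlist(frames), c(nrow(atoms), 3, nf))
  gt <- as.data.frame(do.call(rbind, truths))
  gt <- cbind(frame = seq_len(nf), gt)
  traj <- MemTrajectory(atoms, arr, bil@box)
  new("SyntheticSystem", trajectory = traj, segmentMap = body$segmap,
      groundTruth = gt, spec = unclass(spec))
}

#' Synthetic isoform-like sequence pair
#'
#' A deterministic pair of 490-residue sequences standing in for a highly
#' similar drug-metabolizing isoform pair: 43 substitutions (447/490 =
#' 91.2 percent positional identity) including the six
#' membrane-interface swaps G46D, K72E, P73R, I99H, S220P and P221T.
#' These are synthetic sequences for exercising the comparison module,
#' not database entries.
#'
#' @return a named \code{AAStringSet} of two sequences
#'   (\code{synthetic_2C9_like}, \code{synthetic_2C19_like}).
#' @export
syntheticIsoformPair <- function() {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n <- 490L
  # deterministic base sequence from a small multiplicative generator
  state <- 104729
  nxt <- function() {
    state <<- (state * 48271) %% 2147483647
    state
  }
  base <- vapply(seq_len(n), function(i) aa[nxt() %% 20L + 1L],
                 character(1))
  interfacePos <- c(46L, 72L, 73L, 99L, 220L, 221L)
  base[interfacePos] <- c("G", "K", "P", "I", "S", "P")
  other <- base
  other[interfacePos] <- c("D", "E", "R", "H", "P", "T")
  extra <- setdiff(round(seq(12, 480, length.out = 45L)), interfacePos)
  extra <- utils::head(unique(extra), 37L)
  for (p in extra) {
    cur <- other[p]
    other[p] <- aa[(match(cur, aa) %% 20L) + 1L]
  }
  stopifnot(sum(base != other) == 43L)
  Biostrings::AAStringSet(c(
    synthetic_2C9_like = paste(base, collapse = ""),
    synthetic_2C19_like = paste(other, collapse = "")
  ))
}
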