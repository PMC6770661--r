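# Fixtures and independent oracles used across the test files.

# a bare frame from residue numbers / atom names / coordinates
makeFrame <- function(resno, coords, atomName = "BB", resName = "GLY",
                      box = rep(NA_real_, 3)) {
  n <- length(resno)
  MemFrame(
    data.frame(atom_name = rep_len(atomName, n),
               residue_number = as.integer(resno),
               residue_name = rep_len(resName, n),
               segment_id = "A", stringsAsFactors = FALSE),
    coords, box
  )
}

# straight pseudo-helix: one backbone bead per residue along `dir`
makeHelixFrame <- function(resRange, dir = c(0, 0, 1), origin = c(0, 0, 0),
                           rise = 1.5, atomName = "BB") {
  resno <- seq.int(resRange[1], resRange[2])
  dir <- dir / sqrt(sum(dir^2))
  xyz <- t(vapply(seq_along(resno) - 1,
                  function(k) origin + k * rise * dir, numeric(3)))
  makeFrame(resno, xyz, atomName = atomName)
}

# independent O(N^2) contact-occupancy oracle: explicit loops, minimal
# image in x and y only
bruteOccupancy <- function(traj, headNames, tailNames, cutoff,
                           frames = seq_len(nFrames(traj))) {
  at <- particles(traj)
  isHead <- at$atom_name %in% headNames
  isTail <- at$atom_name %in% tailNames
  isProt <- !(isHead | isTail)
  resnos <- sort(unique(at$residue_number[isProt]))
  headHits <- tailHits <- setNames(integer(length(resnos)),
                                   as.character(resnos))
  for (f in frames) {
    xyz <- coords(traj)[, , f]
    box <- boxDims(traj)[f, ]
    for (r in resnos) {
      pIdx <- which(isProt & at$residue_number == r)
      hFound <- tFound <- FALSE
      for (i in pIdx) {
        for (j in which(isHead | isTail)) {
          dx <- xyz[i, 1] - xyz[j, 1]; dx <- dx - box[1] * round(dx / box[1])
          dy <- xyz[i, 2] - xyz[j, 2]; dy <- dy - box[2] * round(dy / box[2])
          dz <- xyz[i, 3] - xyz[j, 3]
          if (sqrt(dx^2 + dy^2 + dz^2) <= cutoff) {
            if (isHead[j]) hFound <- TRUE else tFound <- TRUE
          }
          if (hFound && tFound) break
        }
        if (hFound && tFound) break
      }
      key <- as.character(r)
      headHits[key] <- headHits[key] + hFound
      tailHits[key] <- tailHits[key] + tFound
    }
  }
  data.frame(residue_number = resnos,
             head_pct = 100 * unname(headHits) / length(frames),
             tail_pct = 100 * unname(tailHits) / length(frames))
}

# a tiny membrane-plus-protein trajectory with hand-placed residues;
# protein beads sit at controlled depths relative to head planes at +/- h
makeSlabSystem <- function(depths, nFramesOut = 1L, box = c(40, 40, 120),
                           h = 19) {
  headXY <- expand.grid(x = c(-16, -8, 0, 8, 16), y = c(-16, -8, 0, 8, 16))
  lipAtoms <- data.frame(
    atom_name = rep(c("PO4", "C1A"), each = nrow(headXY) * 2),
    residue_number = 1000L + seq_len(nrow(headXY) * 4),
    residue_name = "POP", segment_id = "M", stringsAsFactors = FALSE)
  lipXyz <- rbind(
    cbind(headXY$x, headXY$y, h), cbind(headXY$x, headXY$y, -h),
    cbind(headXY$x, headXY$y, h / 3), cbind(headXY$x, headXY$y, -h / 3))
  protAtoms <- data.frame(
    atom_name = "BB", residue_number = seq_along(depths),
    residue_name = "GLY", segment_id = "P", stringsAsFactors = FALSE)
  protXyz <- cbind(0, 0, depths)
  atoms <- rbind(protAtoms, lipAtoms)
  xyz <- rbind(protXyz, lipXyz)
  arr <- array(rep(xyz, nFramesOut), c(nrow(xyz), 3, nFramesOut))
  MemTrajectory(atoms, arr, box)
}

slabSegmentMap <- function() {
  SegmentMap(lipidHead = "PO4", lipidTail = "C1A")
}

# random rotation matrix from a seeded stream (QR of a Gaussian matrix,
# sign-fixed to a proper rotation)
randomRotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

applyRotation <- function(frame, R, center = c(0, 0, 0)) {
  fr <- frame
  fr@coords <- sweep(sweep(frame@coords, 2, center) %*% t(R), 2, center, "+")
  fr
}
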