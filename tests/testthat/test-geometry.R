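# Geometric kernels: centers of mass, axis vectors, angles, heme plane,
# axial distances, superposition, fluctuation B-factors.

test_that("center of mass matches hand-computed means under both weightings", {
  fr <- makeFrame(1:2, rbind(c(0, 0, 0), c(0, 0, 2)))
  expect_equal(unname(centerOfMass(fr)), c(0, 0, 1))
  one <- makeFrame(1, rbind(c(3, -2, 7)))
  expect_equal(unname(centerOfMass(one)), c(3, -2, 7))
  # masses 12, 12, 14, 16 (C, C, N, O): weighted mean along z
  fr4 <- makeFrame(1:4, cbind(0, 0, c(0, 1, 2, 3)),
                   atomName = c("C1", "C2", "N1", "O1"))
  zExp <- (12.011 * 0 + 12.011 * 1 + 14.007 * 2 + 15.999 * 3) /
    (12.011 + 12.011 + 14.007 + 15.999)
  expect_equal(centerOfMass(fr4, weighting = "element")[3], zExp,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(centerOfMass(fr, select = logical(2)), "empty")
})

test_that("axis vectors follow terminal four-residue CoMs and applied rotations", {
  sm <- SegmentMap(backboneNames = "BB")
  helix <- makeHelixFrame(c(1, 12))   # 16.5 A long, along +z
  v <- axisVector(helix, c(1, 12), sm)
  expect_equal(v / sqrt(sum(v^2)), c(0, 0, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  # rotate 90 degrees about x: +z maps to +y
  R <- matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3)
  vR <- axisVector(applyRotation(helix, R), c(1, 12), sm)
  expect_equal(vR / sqrt(sum(vR^2)), as.numeric(R %*% c(0, 0, 1)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # random rotation oracle, seeded
  set.seed(42)
  for (i in 1:5) {
    Q <- randomRotation()
    vQ <- axisVector(applyRotation(helix, Q), c(1, 12), sm)
    expect_equal(vQ / sqrt(sum(vQ^2)), as.numeric(Q %*% c(0, 0, 1)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(axisVector(makeHelixFrame(c(1, 5)), c(1, 5), sm),
               "at least 8")
})

test_that("angles to the membrane normal unfold and fold as defined", {
  expect_equal(angleToNormal(c(0, 0, 1)), 0)
  expect_equal(angleToNormal(c(1, 0, 0)), 90)
  expect_equal(angleToNormal(c(0, 1, 1)), 45)
  expect_equal(angleToNormal(c(0, 0, -1)), 180)
  expect_equal(tiltAngle(c(0, 0, -1)), 0)
  expect_equal(tiltAngle(c(1, 0, 1)), 45)
  expect_equal(tiltAngle(c(1, 0, 0)), 90)
  expect_error(angleToNormal(c(0, 0, 0)), "zero")
  # antipode identity and fold invariance, property-style
  set.seed(7)
  for (i in 1:25) {
    v <- rnorm(3)
    expect_equal(angleToNormal(v) + angleToNormal(-v), 180,
                 tolerance = 1e-9)
    expect_equal(tiltAngle(v), tiltAngle(-v), tolerance = 1e-9)
    expect_gte(tiltAngle(v), 0); expect_lte(tiltAngle(v), 90)
  }
})

test_that("heme tilt is the plane-line angle of the nitrogen plane", {
  sm <- SegmentMap(hemeResidue = "HEM")
  hemeFrame <- function(xyz) makeFrame(rep(999L, 4), xyz,
                                       atomName = c("NA", "NB", "NC", "ND"),
                                       resName = "HEM")
  sq <- rbind(c(2, 0, 5), c(0, 2, 5), c(-2, 0, 5), c(0, -2, 5))
  expect_equal(hemeTilt(hemeFrame(sq), sm), 90)            # flat in xy
  xz <- rbind(c(2, 0, 0), c(0, 0, 2), c(-2, 0, 0), c(0, 0, -2))
  expect_equal(hemeTilt(hemeFrame(xz), sm), 0)             # standing plane
  # xy-square rotated 30 degrees about x tilts the plane to 60
  th <- 30 * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  expect_equal(hemeTilt(hemeFrame(sq %*% t(Rx)), sm), 60, tolerance = 1e-9)
  col <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_error(hemeTilt(hemeFrame(col), sm), "collinear")
})

test_that("axial distances measure segment CoM z offsets from the lipid CoM", {
  sm <- SegmentMap(globular = c(50, 490), lipidHead = "PO4",
                   lipidTail = "C1A")
  atoms <- data.frame(
    atom_name = c(rep("BB", 2), "PO4", "PO4", "C1A", "C1A"),
    residue_number = c(100L, 101L, 1001L, 1002L, 1003L, 1004L),
    residue_name = c("GLY", "GLY", rep("POP", 4)),
    segment_id = "A", stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 42), c(0, 0, 44),
               c(0, 0, 19), c(0, 0, -19), c(0, 0, 6), c(0, 0, -6))
  fr <- MemFrame(atoms, xyz, c(40, 40, 120))
  d <- axialDistances(fr, sm)
  expect_equal(unname(d["d_globular"]), 43)
  expect_true(is.na(d["d_linker"]))     # linker not configured
  noLip <- MemFrame(atoms[1:2, ], xyz[1:2, ], c(40, 40, 120))
  expect_error(axialDistances(noLip, sm), "lipid")
})

test_that("angles and distances are invariant to z-rotation and xy-translation", {
  sys <- emitTrajectory(syntheticSpec(gridN = 4))
  traj <- trajectory(sys)
  ser0 <- orientationSeries(traj, segmentMap(sys))
  set.seed(13)
  for (i in 1:3) {
    th <- runif(1, 0, 2 * pi)
    Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), 0 + cos(th), 0, 0, 0, 1),
                 3, 3)
    shift <- c(runif(2, -5, 5), 0)
    xyz <- sweep(coords(traj)[, , 1] %*% t(Rz), 2, shift, "+")
    tr2 <- MemTrajectory(particles(traj), array(xyz, c(nrow(xyz), 3, 1)),
                         boxDims(traj)[1, ])
    ser <- orientationSeries(tr2, segmentMap(sys))
    expect_equal(unlist(ser[1, -1]), unlist(ser0[1, -1]),
                 tolerance = 1e-9)
  }
})

test_that("Kabsch superposition recovers rigid transforms and minimizes RMSD", {
  sys <- emitTrajectory(syntheticSpec(gridN = 4))
  fr <- getFrame(trajectory(sys), 1)
  expect_equal(superposeFrames(fr, fr)$rmsd, 0, tolerance = 1e-10)
  shifted <- MemFrame(particles(fr), sweep(coords(fr), 2, c(5, -3, 8), "+"),
                      boxDims(fr))
  expect_equal(superposeFrames(shifted, fr)$rmsd, 0, tolerance = 1e-9)
  set.seed(21)
  Q <- randomRotation()
  rot <- MemFrame(particles(fr), coords(fr) %*% t(Q), boxDims(fr))
  fit <- superposeFrames(rot, fr)
  expect_lt(fit$rmsd, 1e-9)
  # fitted RMSD never exceeds the raw RMSD
  jit <- MemFrame(particles(fr),
                  coords(fr) %*% t(Q) + rnorm(length(coords(fr)), sd = 0.5),
                  boxDims(fr))
  raw <- sqrt(mean(rowSums((coords(jit) - coords(fr))^2)))
  expect_lte(superposeFrames(jit, fr)$rmsd, raw + 1e-12)
  expect_error(superposeFrames(
    makeFrame(1:2, rbind(c(0, 0, 0), c(1, 0, 0))),
    makeFrame(1:2, rbind(c(0, 0, 0), c(0, 1, 0)))), "at least 3")
})

test_that("superposition RMSD agrees with the bio3d fitting oracle", {
  sys <- emitTrajectory(syntheticSpec(nFrames = 2, jitter = 0.8,
                                      gridN = 4, seed = 5))
  f1 <- getFrame(trajectory(sys), 1)
  f2 <- getFrame(trajectory(sys), 2)
  ours <- superposeFrames(f2, f1)
  fixed <- as.numeric(t(coords(f1)))
  mob <- as.numeric(t(coords(f2)))
  fitted <- bio3d::fit.xyz(fixed, mob, 1:length(fixed), 1:length(mob))
  ref <- bio3d::rmsd(fixed, fitted)
  expect_equal(ours$rmsd, ref, tolerance = 1e-4)
})

test_that("RMSF-derived B-factors vanish for static input and follow the jitter variance", {
  sys0 <- emitTrajectory(syntheticSpec(nFrames = 5, jitter = 0, gridN = 4))
  b0 <- rmsfBfactor(trajectory(sys0))
  expect_true(all(b0$bfactor < 1e-18))
  # isotropic jitter sigma: <|dr|^2> = 3 sigma^2, B -> 8 pi^2 sigma^2
  sigma <- 0.4
  nF <- 400L
  set.seed(31)
  base <- matrix(rnorm(60, sd = 10), 20, 3)
  arr <- array(rep(base, nF), c(20, 3, nF)) +
    array(rnorm(20 * 3 * nF, sd = sigma), c(20, 3, nF))
  tr <- MemTrajectory(data.frame(atom_name = "BB",
                                 residue_number = 1:20,
                                 residue_name = "GLY", segment_id = "A"),
                      arr, c(100, 100, 100))
  b <- rmsfBfactor(tr)
  expect_equal(mean(b$bfactor), 8 * pi^2 * sigma^2, tolerance = 0.05)
  # doubling sigma quadruples B (asymptotically)
  arr2 <- array(rep(base, nF), c(20, 3, nF)) +
    array(rnorm(20 * 3 * nF, sd = 2 * sigma), c(20, 3, nF))
  b2 <- rmsfBfactor(MemTrajectory(data.frame(atom_name = "BB",
                                             residue_number = 1:20,
                                             residue_name = "GLY",
                                             segment_id = "A"),
                                  arr2, c(100, 100, 100)))
  expect_equal(mean(b2$bfactor) / mean(b$bfactor), 4, tolerance = 0.15)
  expect_error(rmsfBfactor(MemTrajectory(particles(tr),
                                         arr[, , 1, drop = FALSE],
                                         c(100, 100, 100))),
               "at least 2")
})

test_that("backbone RMSD series is zero for a rigidly moving trajectory", {
  sys <- emitTrajectory(syntheticSpec(
    nFrames = 6, gridN = 4,
    drift = list(alpha = 100, beta = 137, dGlobular = 47, switchFrame = 6)))
  # the globular body moves rigidly: superposed RMSD of its beads is 0
  at <- particles(trajectory(sys))
  glob <- at$residue_number >= 50 & at$residue_number <= 490 &
    at$atom_name == "BB"
  r <- rmsdSeries(trajectory(sys), select = glob)
  expect_true(all(r < 1e-9))
})
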