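# Structure/trajectory I/O and segment resolution.

test_that("PDB reading preserves particle count, names and numbering", {
  fr <- makeHelixFrame(c(1, 10))
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(fr, f)
  rd <- readStructure(f)
  expect_equal(nAtoms(rd), 10L)
  expect_identical(particles(rd)$residue_number, 1:10)
  expect_identical(particles(rd)$atom_name, rep("BB", 10))
  expect_equal(coords(rd), coords(fr), tolerance = 1e-8)
})

test_that("truncated and malformed PDB records are rejected with the line number", {
  fr <- makeHelixFrame(c(1, 5))
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(fr, f)
  lines <- readLines(f)
  lines[3] <- substr(lines[3], 1, 40)   # truncate an ATOM record
  writeLines(lines, f)
  expect_error(readStructure(f), "line 3")
  expect_error(readTrajectory(withr::local_tempfile(fileext = ".pdb",
                                                    lines = character(0))),
               "no frames")
})

test_that("multi-model PDB round trips bit-comparably and frame count equals model count", {
  sys <- emitTrajectory(syntheticSpec(nFrames = 5, jitter = 0.2,
                                      gridN = 4, seed = 7))
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(trajectory(sys), f)
  rd <- readTrajectory(f)
  expect_equal(nFrames(rd), 5L)
  # PDB stores 3 decimals: agreement at format precision
  expect_lt(max(abs(coords(rd) - coords(trajectory(sys)))), 1e-3 + 1e-9)
  expect_identical(particles(rd)$residue_number,
                   particles(trajectory(sys))$residue_number)
})

test_that("our PDB writer/reader agrees with the bio3d parser", {
  sys <- emitTrajectory(syntheticSpec(nFrames = 2, jitter = 0.1,
                                      gridN = 4, seed = 3))
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(trajectory(sys), f)
  rd <- readTrajectory(f)
  ref <- suppressWarnings(bio3d::read.pdb(f, multi = TRUE))
  for (m in 1:2) {
    b <- matrix(ref$xyz[m, ], ncol = 3, byrow = TRUE)
    expect_equal(unname(coords(rd)[, , m]), unname(b), tolerance = 1e-9)
  }
  expect_identical(particles(rd)$residue_number, ref$atom$resno)
})

test_that("atom-count mismatch between models names the model index", {
  fr <- makeHelixFrame(c(1, 10))
  f <- withr::local_tempfile(fileext = ".pdb")
  con <- file(f, "w")
  body <- readLines(writePDB(fr, withr::local_tempfile(fileext = ".pdb")))
  atomLines <- grep("^ATOM", body, value = TRUE)
  writeLines(c("MODEL     1", atomLines, "ENDMDL",
               "MODEL     2", atomLines[1:9], "ENDMDL"), con)
  close(con)
  expect_error(readTrajectory(f), "model 2")
})

test_that("GRO round trip holds at format precision and converts nm to Angstrom", {
  sys <- emitTrajectory(syntheticSpec(nFrames = 1, jitter = 0.3,
                                      gridN = 4, seed = 11))
  fr <- getFrame(trajectory(sys), 1)
  f <- withr::local_tempfile(fileext = ".gro")
  writeGRO(fr, f)
  rd <- readStructure(f)
  expect_lt(max(abs(coords(rd) - coords(fr))), 1e-2 + 1e-9)
  expect_equal(boxDims(rd), boxDims(fr), tolerance = 1e-6)
  # hand-written single-atom file: 1.5 nm becomes 15 Angstrom
  g <- withr::local_tempfile(fileext = ".gro", lines = c(
    "one atom", "    1",
    "    1GLY     BB    1   1.500   0.200   0.000",
    "   4.00000   4.00000   4.00000"))
  one <- readStructure(g)
  expect_equal(unname(coords(one)[1, ]), c(15, 2, 0))
  expect_equal(boxDims(one), c(40, 40, 40))
})

test_that("triclinic boxes are rejected as unsupported", {
  fr <- makeHelixFrame(c(1, 5))
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(MemFrame(particles(fr), coords(fr), c(40, 40, 40)), f)
  lines <- readLines(f)
  lines[1] <- "CRYST1   40.000   40.000   40.000  90.00  90.00  60.00 P 1"
  writeLines(lines, f)
  expect_error(readStructure(f), "triclinic")
  g <- withr::local_tempfile(fileext = ".gro", lines = c(
    "tric", "    1",
    "    1GLY     BB    1   1.000   1.000   1.000",
    "   4.0   4.0   4.0   0.0   0.0   1.2"))
  expect_error(readStructure(g), "triclinic")
})

test_that("segment resolution validates ranges and the heme selection", {
  sys <- emitTrajectory(syntheticSpec(gridN = 4))
  fr <- getFrame(trajectory(sys), 1)
  sm <- segmentMap(sys)
  expect_invisible(resolveSegments(fr, sm))
  bad <- SegmentMap(globular = c(900, 910))
  expect_error(resolveSegments(fr, bad), "900-910")
  # duplicate the heme: 8 matched nitrogens must be rejected
  at <- particles(fr); xyz <- coords(fr)
  hIdx <- which(at$residue_name == "HEM")
  fr2 <- MemFrame(rbind(at, at[hIdx, ]), rbind(xyz, xyz[hIdx, ] + 30),
                  boxDims(fr))
  expect_error(resolveSegments(fr2, sm), "8 particles")
})

test_that("SegmentMap validity enforces helix spans and range sanity", {
  expect_error(SegmentMap(i_helix = c(286, 290)), "at least 8")
  expect_error(SegmentMap(globular = c(50, 40)), "empty")
  expect_silent(SegmentMap(i_helix = c(286, 316), linker = c(22, 49)))
})

test_that("segment configuration files round trip through YAML and JSON", {
  sm <- SegmentMap(tm_helix = c(3, 21), globular = c(50, 490),
                   i_helix = c(286, 316), hemeResidue = "HEM",
                   lipidHead = "PO4", lipidTail = c("C1A", "C2A"))
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    writeSegmentConfig(sm, f)
    rd <- readSegmentConfig(f)
    expect_equal(segments(rd), segments(sm))
    expect_equal(rd@lipidHead, sm@lipidHead)
    expect_equal(rd@hemeResidue, sm@hemeResidue)
  }
})
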