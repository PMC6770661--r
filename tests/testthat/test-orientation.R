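# Orientation series, classification, summaries, convergence,
# representative frames and distributions.

test_that("orientation records reproduce generator ground truth on a class-A frame", {
  sys <- emitTrajectory(syntheticSpec(alpha = 90, beta = 112, gamma = 15,
                                      hemeTilt = 40, dGlobular = 43,
                                      gridN = 4))
  ser <- orientationSeries(trajectory(sys), segmentMap(sys))
  gt <- groundTruth(sys)
  expect_lt(max(abs(unlist(ser[1, -1]) - unlist(gt[1, -1]))), 1e-6)
})

test_that("a heme-less coarse-grained-style system yields NA heme tilt, not zero", {
  sys <- emitTrajectory(syntheticSpec(gridN = 4))
  traj <- trajectory(sys)
  at <- particles(traj)
  keep <- at$residue_name != "HEM"
  tr2 <- MemTrajectory(at[keep, ],
                       coords(traj)[keep, , , drop = FALSE],
                       boxDims(traj)[1, ])
  smNoHeme <- segmentMap(sys)
  smNoHeme@hemeResidue <- character(0)
  ser <- orientationSeries(tr2, smNoHeme)
  expect_true(all(is.na(ser$heme_tilt)))
  expect_false(anyNA(ser$beta))
})

test_that("a static trajectory yields identical records and a z-flipped frame is restored", {
  sys <- emitTrajectory(syntheticSpec(nFrames = 10, jitter = 0, gridN = 4))
  ser <- orientationSeries(trajectory(sys), segmentMap(sys))
  expect_equal(nrow(ser), 10L)
  for (cl in c("alpha", "beta", "gamma", "heme_tilt", "d_globular"))
    expect_equal(length(unique(round(ser[[cl]], 9))), 1L)
  # flip the whole frame upside down: analysis must restore the convention
  traj <- trajectory(sys)
  xyz <- coords(traj)[, , 1]
  xyz[, 2:3] <- -xyz[, 2:3]            # 180-degree rotation about x
  flipped <- MemTrajectory(particles(traj),
                           array(xyz, c(nrow(xyz), 3, 1)),
                           boxDims(traj)[1, ])
  expect_message(serF <- orientationSeries(flipped, segmentMap(sys)),
                 "z-flip")
  expect_equal(unlist(serF[1, -1]), unlist(ser[1, -1]), tolerance = 1e-9)
  expect_equal(attr(serF, "flipped"), 1L)
})

test_that("beta classification reproduces the published class partition", {
  expect_equal(as.character(classifyOrientation(112)), "A")
  expect_equal(as.character(classifyOrientation(137)), "B")
  expect_equal(as.character(classifyOrientation(129)), "A/B")
  expect_equal(as.character(classifyOrientation(c(125, 130))),
               c("A/B", "A/B"))   # closed boundaries
  expect_error(classifyOrientation(190), "out of range")
  expect_error(classifyOrientation(-1), "out of range")
  # total monotone partition of [0, 180]
  beta <- seq(0, 180, by = 0.5)
  cls <- classifyOrientation(beta)
  expect_false(anyNA(cls))
  expect_true(all(diff(as.integer(cls)) >= 0))
  expect_equal(as.integer(table(cls)), c(250, 11, 100))
})

test_that("summaries equal brute-force means/SDs and honor windows and strides", {
  con <- data.frame(frame = 1:10, alpha = 90, beta = 112, gamma = 15,
                    heme_tilt = 40, d_globular = 43, d_linker = 25,
                    d_fg = 28)
  s <- summarizeOrientation(con)
  expect_equal(s$beta_mean, 112); expect_equal(s$beta_sd, 0)
  expect_equal(s$class, "A")
  # window = last 90% of 10 frames uses 9 frames
  expect_equal(summarizeOrientation(con, window = 0.9)$n_frames, 9L)
  expect_equal(summarizeOrientation(con, stride = 2)$n_frames, 5L)
  # brute-force oracle on a seeded Gaussian series
  set.seed(19)
  x <- rnorm(9000, 137, 10)
  ser <- data.frame(frame = seq_along(x), alpha = 100, beta = x,
                    gamma = 13, heme_tilt = 52, d_globular = 47,
                    d_linker = 21, d_fg = 26)
  s2 <- summarizeOrientation(ser)
  expect_equal(s2$beta_mean, sum(x) / length(x), tolerance = 1e-12)
  expect_equal(s2$beta_sd,
               sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
               tolerance = 1e-12)
  expect_lt(abs(s2$beta_mean - 137), 3 * 10 / sqrt(9000))
  expect_equal(s2$class, "B")
  expect_error(summarizeOrientation(con, window = c(20, 30)), "outside")
})

test_that("convergence detection localizes a step change and rejects drift", {
  mk <- function(beta) data.frame(frame = seq_along(beta), beta = beta,
                                  d_globular = 43)
  con <- detectConvergence(mk(rep(112, 400)), windowSize = 50)
  expect_true(con$converged)
  expect_equal(con$startFrame, 1L)
  step <- mk(c(rep(160, 500), rep(112, 500)))
  cs <- detectConvergence(step, windowSize = 100, tol = c(beta = 2))
  expect_true(cs$converged)
  expect_gte(cs$startFrame, 501L)
  expect_lte(cs$startFrame, 600L)
  drift <- mk(seq(160, 112, length.out = 1000))
  expect_false(detectConvergence(drift, windowSize = 100)$converged)
  expect_error(detectConvergence(mk(rep(1, 10)), windowSize = 50),
               "too short")
})

test_that("representative-frame selection applies the 1% rule", {
  con <- data.frame(frame = 1:10, alpha = 90, beta = 112, gamma = 15,
                    d_globular = 43, d_fg = 28)
  r <- selectRepresentativeFrame(con)
  expect_equal(r$frame, 1L)
  expect_equal(r$maxRelDev, 0)
  expect_true(r$withinTol)
  # constructed series where exactly one frame satisfies every 1% bound;
  # verified by brute force over all frames
  n <- 20
  ser <- data.frame(frame = 1:n,
                    alpha = c(rep(c(88, 92), 9), 90.05, 95),
                    beta = 112, gamma = 15, d_globular = 43, d_fg = 28)
  mu <- vapply(c("alpha", "beta", "gamma", "d_globular", "d_fg"),
               function(f) mean(ser[[f]]), numeric(1))
  ok <- vapply(1:n, function(i) {
    all(vapply(names(mu), function(f)
      abs(ser[[f]][i] - mu[[f]]) / abs(mu[[f]]) <= 0.01, logical(1)))
  }, logical(1))
  expect_equal(which(ok), 19L)
  r2 <- selectRepresentativeFrame(ser)
  expect_equal(r2$frame, 19L)
  expect_true(r2$withinTol)
  # no frame within tolerance: minimizer returned with a warning
  far <- data.frame(frame = 1:4, alpha = c(50, 130, 50, 130),
                    beta = c(90, 150, 90, 150), gamma = 15,
                    d_globular = 43, d_fg = 28)
  expect_warning(r3 <- selectRepresentativeFrame(far), "closest")
  expect_false(r3$withinTol)
  devs <- vapply(1:4, function(i) max(abs(far$alpha[i] - mean(far$alpha)) /
                                        mean(far$alpha),
                                      abs(far$beta[i] - mean(far$beta)) /
                                        mean(far$beta)), numeric(1))
  expect_equal(r3$frame, which.min(devs))
})

test_that("distribution tables are normalized and locate mixture modes", {
  ser <- data.frame(beta = rep(112.3, 50))
  h <- distributionTable(ser, "beta", 2)
  expect_equal(sum(h$density * 2), 1)
  expect_equal(max(h$density), 1 / 2)
  set.seed(9)
  u <- data.frame(beta = runif(20000, 100, 140))
  hu <- distributionTable(u, "beta", 5)
  inner <- hu$density[hu$lower >= 100 & hu$upper <= 140]
  expect_true(all(abs(inner - 1 / 40) < 0.15 / 40))
  mix <- data.frame(beta = c(rnorm(5000, 112, 2), rnorm(5000, 137, 2)))
  hm <- distributionTable(mix, "beta", 2)
  top2 <- hm$mid[order(hm$density, decreasing = TRUE)[1:2]]
  expect_true(any(abs(top2 - 112) <= 2))
  expect_true(any(abs(top2 - 137) <= 2))
  expect_error(distributionTable(mix, "beta", 0), "positive")
})
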