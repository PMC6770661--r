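# Per-frame orientation records, time-series summaries, orientation-class
# assignment, convergence detection, representative-frame selection and
# distribution tables.

#' Per-frame orientation record of a trajectory
#'
#' For every frame, computes the orientation of the globular domain above
#' the bilayer: alpha (angle of the I-helix axis v1 to the membrane
#' normal), beta (angle of the C-helix-start to F-helix-end vector v2),
#' gamma (TM-helix tilt, folded to [0, 90]), the heme-tilt angle (NA when
#' the segment map declares no heme, as in coarse-grained models without
#' the cofactor), and the axial CoM distances of the globular domain,
#' linker and F'-G' region from the bilayer midplane.
#'
#' The membrane normal is +z with z oriented so the globular domain lies
#' above the bilayer: frames whose globular-domain CoM sits below the
#' lipid CoM are rotated 180 degrees about x (a proper rotation taking z
#' to -z) before analysis, and the flip is recorded in the
#' \code{"flipped"} attribute.  This keeps the unfolded alpha/beta values
#' comparable across inputs.
#'
#' @param traj a [MemTrajectory-class].
#' @param segmap a [SegmentMap-class]; must provide \code{i_helix},
#'   \code{c_helix}, \code{f_helix} and lipid particle sets;
#'   \code{tm_helix}, \code{linker}, \code{fprime_gprime} and the heme are
#'   optional (absent fields yield NA columns).
#' @param weighting CoM weighting, see [centerOfMass()].
#' @param terminalN residues averaged at segment ends for axis vectors.
#' @return data.frame with columns \code{frame}, \code{alpha},
#'   \code{beta}, \code{gamma}, \code{heme_tilt}, \code{d_globular},
#'   \code{d_linker}, \code{d_fg}; attribute \code{flipped} lists frames
#'   that were z-flipped.
#' @export
orientationSeries <- function(traj, segmap,
                              weighting = c("uniform", "element"),
                              terminalN = 4L) {
  weighting <- match.arg(weighting)
  stopifnot(is(traj, "MemTrajectory"), is(segmap, "SegmentMap"))
  segs <- segmap@segments
  for (need in c("i_helix", "c_helix", "f_helix", "globular"))
    if (is.null(segs[[need]]))
      .stopf("segment map lacks required segment '%s'", need)
  at <- traj@atoms
  lipid <- at$atom_name %in% c(segmap@lipidHead, segmap@lipidTail)
  if (!any(lipid))
    stop("no lipid particles found: orientation analysis needs a bilayer")
  glob <- segs$globular
  globSel <- !lipid & at$residue_number >= glob[1] &
    at$residue_number <= glob[2]
  hasHeme <- length(segmap@hemeResidue) > 0 &&
    length(.hemeIdx(at, segmap)) == 4L
  nf <- nFrames(traj)
  out <- data.frame(frame = seq_len(nf), alpha = NA_real_, beta = NA_real_,
                    gamma = NA_real_, heme_tilt = NA_real_,
                    d_globular = NA_real_, d_linker = NA_real_,
                    d_fg = NA_real_)
  flipped <- logical(nf)
  flipR <- .rotAxis(c(1, 0, 0), pi)
  for (f in seq_len(nf)) {
    fr <- getFrame(traj, f)
    zG <- centerOfMass(fr, globSel, weighting)[3]
    zL <- centerOfMass(fr, lipid, weighting)[3]
    if (zG < zL) {
      flipped[f] <- TRUE
      ctr <- c(0, 0, zL)
      fr@coords <- sweep(sweep(fr@coords, 2, ctr) %*% t(flipR), 2, ctr, "+")
    }
    v1 <- axisVector(fr, segs$i_helix, segmap, terminalN, weighting)
    ccom <- .terminalComOfRange(fr, segs$c_helix, segmap, "first",
                                terminalN, weighting)
    fcom <- .terminalComOfRange(fr, segs$f_helix, segmap, "last",
                                terminalN, weighting)
    v2 <- fcom - ccom
    out$alpha[f] <- angleToNormal(v1)
    out$beta[f] <- angleToNormal(v2)
    if (!is.null(segs$tm_helix))
      out$gamma[f] <- tiltAngle(axisVector(fr, segs$tm_helix, segmap,
                                           terminalN, weighting))
    if (hasHeme) out$heme_tilt[f] <- hemeTilt(fr, segmap)
    d <- axialDistances(fr, segmap, weighting)
    out$d_globular[f] <- d["d_globular"]
    out$d_linker[f] <- d["d_linker"]
    out$d_fg[f] <- d["d_fg"]
  }
  if (any(flipped))
    message("z-flip applied to ", sum(flipped),
            " frame(s) so the globular domain lies above the bilayer")
  attr(out, "flipped") <- which(flipped)
  attr(out, "hemePresent") <- hasHeme
  out
}

# CoM of the backbone particles of terminalN residues at one end of a range
.terminalComOfRange <- function(frame, range, segmap, which, terminalN,
                                weighting) {
  bb <- .backboneIdx(frame@atoms, segmap)
  inR <- frame@atoms$residue_number >= range[1] &
    frame@atoms$residue_number <= range[2]
  resnos <- frame@atoms$residue_number[bb & inR]
  if (length(unique(resnos)) < terminalN)
    .stopf("residue range %d-%d has fewer than %d backbone residues",
           as.integer(range[1]), as.integer(range[2]), terminalN)
  keep <- bb & inR
  fr <- MemFrame(frame@atoms[keep, , drop = FALSE],
                 frame@coords[keep, , drop = FALSE], frame@box)
  .terminalCom(fr, fr@atoms$residue_number, which, terminalN, weighting)
}

#' Orientation class from the beta angle
#'
#' Class A for beta below the lower threshold (125 degrees by default),
#' class A/B inside the closed interval between the thresholds, class B
#' above the upper threshold (130 degrees).  The A/B interval is closed on
#' both sides because the class-A definition is strictly "below".
#'
#' @param beta beta angle(s) in degrees, in [0, 180].
#' @param thresholds strictly increasing numeric(2), degrees.
#' @return factor with levels \code{A}, \code{A/B}, \code{B}.
#' @export
classifyOrientation <- function(beta, thresholds = c(125, 130)) {
  if (length(thresholds) != 2L || diff(thresholds) <= 0)
    stop("thresholds must be strictly increasing numeric(2)")
  ok <- is.na(beta) | (beta >= 0 & beta <= 180)
  if (!all(ok))
    .stopf("beta angle out of range [0, 180]: %s",
           paste(format(beta[!ok]), collapse = ", "))
  lab <- ifelse(is.na(beta), NA_character_,
                ifelse(beta < thresholds[1], "A",
                       ifelse(beta <= thresholds[2], "A/B", "B")))
  factor(lab, levels = c("A", "A/B", "B"))
}

# resolve a window spec into frame indices of a series of length n:
# NULL = all; single value in (0,1] = last fraction; length-2 = explicit
# inclusive frame range
.windowIdx <- function(n, window, stride = 1L) {
  idx <- if (is.null(window)) {
    seq_len(n)
  } else if (length(window) == 1L) {
    if (window <= 0 || window > 1)
      stop("fractional window must lie in (0, 1]")
    seq.int(n - floor(window * n) + 1L, n)
  } else if (length(window) == 2L) {
    if (window[1] < 1 || window[2] > n || window[2] < window[1])
      .stopf("window %d-%d outside series of length %d",
             as.integer(window[1]), as.integer(window[2]), n)
    seq.int(window[1], window[2])
  } else stop("window must be NULL, a fraction, or a frame range")
  idx <- idx[seq.int(1L, length(idx), by = as.integer(stride))]
  if (!length(idx)) stop("empty analysis window")
  idx
}

#' Summarize an orientation series over an analysis window
#'
#' Sample mean and standard deviation of every orientation field over a
#' (possibly strided) window, with the orientation class assigned from
#' the mean beta angle -- the per-system summary row reported for each
#' simulation set.
#'
#' @param series data.frame from [orientationSeries()].
#' @param window \code{NULL} (all frames), a fraction in (0, 1] (last
#'   fraction of the series, e.g. 0.9 for the production tail), or an
#'   explicit inclusive frame range \code{c(first, last)}.
#' @param stride keep every \code{stride}-th frame of the window.
#' @param thresholds class thresholds, see [classifyOrientation()].
#' @return one-row data.frame of \code{<field>_mean} / \code{<field>_sd}
#'   plus \code{class}, \code{n_frames}, \code{window_start},
#'   \code{window_end}.
#' @export
summarizeOrientation <- function(series, window = NULL, stride = 1L,
                                 thresholds = c(125, 130)) {
  idx <- .windowIdx(nrow(series), window, stride)
  fields <- c("alpha", "beta", "gamma", "heme_tilt", "d_globular",
              "d_linker", "d_fg")
  fields <- intersect(fields, names(series))
  out <- list()
  for (fl in fields) {
    x <- series[[fl]][idx]
    out[[paste0(fl, "_mean")]] <- if (all(is.na(x))) NA_real_ else
      mean(x, na.rm = TRUE)
    out[[paste0(fl, "_sd")]] <- if (all(is.na(x))) NA_real_ else
      stats::sd(x, na.rm = TRUE)
  }
  out$class <- as.character(classifyOrientation(out$beta_mean, thresholds))
  out$n_frames <- length(idx)
  out$window_start <- idx[1]
  out$window_end <- idx[length(idx)]
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Detect convergence of an orientation series
#'
#' The series is tiled into non-overlapping windows of
#' \code{windowSize} frames.  It is declared converged from the earliest
#' window from which every subsequent window's mean of each monitored
#' field stays within the per-field tolerance of the final complete
#' window's mean; at least the penultimate window must agree with the
#' final one, otherwise the series is reported unconverged.  This
#' operationalizes "no further significant change in orientation" at the
#' scale of the tolerances (defaults: 2 degrees for angles, 1 Angstrom
#' for distances, matching the scale of typical run-to-run standard
#' deviations).
#'
#' @param series data.frame from [orientationSeries()].
#' @param fields monitored column names (default \code{beta},
#'   \code{d_globular}).
#' @param windowSize frames per window; default 10\% of the series length
#'   (at least 2 frames).
#' @param tol named per-field tolerances; unnamed fields fall back to 2
#'   (angles) or 1 (distance fields, names starting \code{d_}).
#' @return list of class \code{ConvergenceReport}: \code{converged},
#'   \code{startFrame} (first frame of the earliest stable window, or NA),
#'   \code{monitored}, \code{windowSize}, \code{tolerances},
#'   \code{windowMeans}.
#' @export
detectConvergence <- function(series, fields = c("beta", "d_globular"),
                              windowSize = NULL, tol = NULL) {
  n <- nrow(series)
  if (is.null(windowSize)) windowSize <- max(2L, floor(n / 10))
  windowSize <- as.integer(windowSize)
  if (n < 2L * windowSize)
    .stopf("series of %d frames is too short for window size %d (need at least %d)",
           n, windowSize, 2L * windowSize)
  missingF <- setdiff(fields, names(series))
  if (length(missingF))
    .stopf("monitored field(s) not in series: %s",
           paste(missingF, collapse = ", "))
  tolFor <- function(fl) {
    if (!is.null(tol) && fl %in% names(tol)) return(tol[[fl]])
    if (!is.null(tol) && is.null(names(tol)) && length(tol) == 1L)
      return(tol[[1]])
    if (startsWith(fl, "d_")) 1 else 2
  }
  tols <- vapply(fields, tolFor, numeric(1))
  K <- n %/% windowSize
  starts <- (seq_len(K) - 1L) * windowSize + 1L
  wm <- sapply(fields, function(fl) {
    vapply(starts, function(s) {
      mean(series[[fl]][s:(s + windowSize - 1L)], na.rm = TRUE)
    }, numeric(1))
  })
  wm <- matrix(wm, nrow = K, dimnames = list(NULL, fields))
  finalMeans <- wm[K, ]
  okWin <- vapply(seq_len(K), function(k) {
    all(abs(wm[k, ] - finalMeans) <= tols)
  }, logical(1))
  # earliest window from which all later windows (and itself) agree
  stableFrom <- NA_integer_
  for (k in seq_len(K)) {
    if (all(okWin[k:K])) { stableFrom <- k; break }
  }
  converged <- !is.na(stableFrom) && stableFrom <= K - 1L
  structure(list(
    converged = converged,
    startFrame = if (converged) starts[stableFrom] else NA_integer_,
    monitored = fields,
    windowSize = windowSize,
    tolerances = tols,
    windowMeans = wm
  ), class = "ConvergenceReport")
}

#' @export
print.ConvergenceReport <- function(x, ...) {
  cat("ConvergenceReport:",
      if (x$converged) sprintf("converged from frame %d", x$startFrame)
      else "not converged", "\n")
  cat("  monitored:", paste(x$monitored, collapse = ", "),
      "| window:", x$windowSize, "frames\n")
  invisible(x)
}

#' Select a representative frame from a converged window
#'
#' Returns the frame whose monitored orientation values all lie within a
#' relative tolerance (1\% by default) of their means over the window --
#' the rule used to pick a single structure for downstream modeling.  If
#' several frames qualify, the one minimizing the maximum relative
#' deviation is chosen; if none does, that minimizer is returned with
#' \code{withinTol = FALSE} and a warning.
#'
#' @param series data.frame from [orientationSeries()].
#' @param window inclusive frame range \code{c(first, last)} of the
#'   converged part (default: whole series).
#' @param fields monitored fields (default alpha, beta, gamma,
#'   d_globular, d_fg; fields that are all-NA in the window are dropped).
#' @param relTol relative deviation bound (default 0.01).
#' @return list: \code{frame} (absolute index), \code{maxRelDev},
#'   \code{withinTol}, \code{means}.
#' @export
selectRepresentativeFrame <- function(series, window = NULL,
                                      fields = c("alpha", "beta", "gamma",
                                                 "d_globular", "d_fg"),
                                      relTol = 0.01) {
  idx <- .windowIdx(nrow(series), window)
  fields <- intersect(fields, names(series))
  fields <- fields[vapply(fields,
                          function(fl) !all(is.na(series[[fl]][idx])),
                          logical(1))]
  if (!length(fields)) stop("no monitored fields with data in the window")
  mu <- vapply(fields, function(fl) mean(series[[fl]][idx]), numeric(1))
  dev <- sapply(fields, function(fl) {
    x <- series[[fl]][idx]
    ifelse(x == mu[[fl]], 0, abs(x - mu[[fl]]) / abs(mu[[fl]]))
  })
  dev <- matrix(dev, nrow = length(idx), dimnames = list(NULL, fields))
  maxDev <- apply(dev, 1, max)
  best <- which.min(maxDev)
  withinTol <- maxDev[best] <= relTol
  if (!withinTol)
    warning(sprintf(
      "no frame lies within %.1f%% of the window means; returning the closest (max relative deviation %.3f)",
      100 * relTol, maxDev[best]))
  list(frame = idx[best], maxRelDev = unname(maxDev[best]),
       withinTol = withinTol, means = mu)
}

#' Normalized distribution table of an orientation field
#'
#' Histogram with fixed bin width whose densities integrate to 1: the
#' tabular form of the angle/distance distribution plots used to compare
#' orientations between systems.
#'
#' @param series data.frame from [orientationSeries()] (or any data.frame).
#' @param field column to histogram.
#' @param binWidth bin width in the field's units (degrees or Angstrom).
#' @return data.frame with \code{lower}, \code{upper}, \code{mid},
#'   \code{count}, \code{density}.
#' @export
distributionTable <- function(series, field, binWidth) {
  if (!is.numeric(binWidth) || binWidth <= 0)
    stop("bin width must be positive")
  x <- series[[field]]
  x <- x[!is.na(x)]
  if (!length(x)) stop("no values to histogram")
  lo <- floor(min(x) / binWidth) * binWidth
  hi <- ceiling(max(x) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  breaks <- seq(lo, hi, by = binWidth)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = FALSE)
  data.frame(lower = utils::head(h$breaks, -1),
             upper = h$breaks[-1],
             mid = h$mids,
             count = h$counts,
             density = h$counts / (length(x) * binWidth))
}
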