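# internal helpers shared across modules

.RAD2DEG <- 180 / pi

.deg <- function(x) x * .RAD2DEG

# element masses used for mass-by-element weighting (Da)
.ELEMENT_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
  S = 32.06, FE = 55.845, MG = 24.305, ZN = 65.38, CL = 35.45,
  BR = 79.904, K = 39.098
)

# infer an element symbol from an atom name; two-letter metals are
# recognized explicitly, otherwise the first alphabetic character wins
.elementFromName <- function(name) {
  up <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", name)))
  two <- substr(up, 1, 2)
  ifelse(two %in% c("FE", "MG", "ZN", "CL", "BR"), two, substr(up, 1, 1))
}

.atomMasses <- function(atomNames) {
  el <- .elementFromName(atomNames)
  m <- .ELEMENT_MASS[el]
  if (anyNA(m)) {
    bad <- unique(atomNames[is.na(m)])
    stop("cannot infer element mass for atom name(s): ",
         paste(bad, collapse = ", "))
  }
  unname(m)
}

# weighted mean position of an n x 3 coordinate matrix
.comMat <- function(xyz, w = NULL) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  if (nrow(xyz) == 0L) stop("center of mass of an empty particle set")
  if (is.null(w)) {
    colMeans(xyz)
  } else {
    colSums(xyz * w) / sum(w)
  }
}

# rotation matrix about a unit axis by angle (radians), Rodrigues form
.rotAxis <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# axis-angle decomposition of a proper rotation matrix
.axisAngle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  theta <- acos(ct)
  if (theta < 1e-12) return(list(axis = c(0, 0, 1), angle = 0))
  if (abs(theta - pi) < 1e-6) {
    # near 180 degrees: axis from the symmetric part
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    # fix signs from off-diagonals
    if (axis[1] > 1e-8) {
      axis[2] <- sign(B[1, 2]) * abs(axis[2])
      axis[3] <- sign(B[1, 3]) * abs(axis[3])
    } else if (axis[2] > 1e-8) {
      axis[3] <- sign(B[2, 3]) * abs(axis[3])
    }
    return(list(axis = axis / sqrt(sum(axis^2)), angle = pi))
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  list(axis = axis, angle = theta)
}

# spherical interpolation between two rotation matrices, s in [0, 1]
.slerpRot <- function(R0, R1, s) {
  aa <- .axisAngle(R1 %*% t(R0))
  .rotAxis(aa$axis, s * aa$angle) %*% R0
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
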