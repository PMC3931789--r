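# Deterministic near-uniform covering of SO(3), built on the Hopf
# decomposition: a golden-angle (Fibonacci) lattice of axis directions
# on S2 crossed with a uniform grid of spin angles about each direction.
# The first sample is always the identity.

#' Generate a deterministic near-uniform rotation set
#'
#' Produces a covering of rotation space such that every rotation lies
#' within about the requested angular resolution of some sample. The
#' construction crosses a Fibonacci lattice of \code{max(10,
#' round(11/a^2))} axis directions with \code{max(4, round(2*pi/a))}
#' spin angles (\code{a} the resolution in radians); at the 5.6 degree
#' docking default this yields 73664 rotations, bracketing the
#' conventional ~60000-rotation exhaustive search. Deterministic for a
#' fixed resolution.
#'
#' @param resolutionDeg angular resolution in degrees, in (0, 180].
#' @return numeric matrix (n x 4) of unit quaternions (w, x, y, z) with
#'   attribute \code{resolution}.
#' @export
generateRotations <- function(resolutionDeg) {
  if (!is.finite(resolutionDeg) || resolutionDeg <= 0 ||
      resolutionDeg > 180)
    stop("resolution must be in (0, 180] degrees")
  a <- resolutionDeg * pi / 180
  n1 <- max(4L, as.integer(round(2 * pi / a)))
  n2 <- max(10L, as.integer(round(11 / a^2)))
  u <- fibonacciSphere(n2)
  psi <- (seq_len(n1) - 1) * 2 * pi / n1
  qz <- cbind(cos(psi / 2), 0, 0, sin(psi / 2))
  Q <- matrix(0, n1 * n2, 4)
  k <- 1L
  for (j in seq_len(n2)) {
    qa <- alignZQuat(u[j, ])
    for (i in seq_len(n1)) {
      Q[k, ] <- quatMultiply(qa, qz[i, ])
      k <- k + 1L
    }
  }
  colnames(Q) <- c("w", "x", "y", "z")
  attr(Q, "resolution") <- resolutionDeg
  Q
}

#' Angular distance between rotations
#'
#' @param q a unit quaternion (length 4) or n x 4 matrix.
#' @param ref a unit quaternion.
#' @return rotation-angle distance(s) in degrees.
#' @export
rotationDistance <- function(q, ref) {
  if (is.null(dim(q))) q <- matrix(q, 1)
  d <- abs(as.vector(q %*% ref))
  2 * acos(pmin(1, d)) * 180 / pi
}
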