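# Internal helpers: seeded RNG scopes, quaternion algebra, sphere lattices.

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring
# the caller's .Random.seed afterwards.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Quaternion (w,x,y,z) product a * b.
quatMultiply <- function(a, b) {
  c(a[1]*b[1] - a[2]*b[2] - a[3]*b[3] - a[4]*b[4],
    a[1]*b[2] + a[2]*b[1] + a[3]*b[4] - a[4]*b[3],
    a[1]*b[3] - a[2]*b[4] + a[3]*b[1] + a[4]*b[2],
    a[1]*b[4] + a[2]*b[3] - a[3]*b[2] + a[4]*b[1])
}

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q numeric length-4 quaternion (w, x, y, z); normalised
#'   internally.
#' @return 3x3 proper rotation matrix.
#' @export
quat2mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
    2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
    2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' @param R 3x3 proper rotation matrix.
#' @return numeric length-4 quaternion (w, x, y, z) with w >= 0.
#' @export
mat2quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

# Near-uniform n-point lattice on the unit sphere (golden-angle spiral);
# the first point is exactly +z.
fibonacciSphere <- function(n) {
  i <- seq_len(n)
  z <- 1 - 2 * (i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (i - 1) * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Rotation matrix about a named axis.
axisRotation <- function(axis = c("x", "y", "z"), angleRad) {
  axis <- match.arg(axis)
  cth <- cos(angleRad); sth <- sin(angleRad)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, cth, -sth, 0, sth, cth), 3, 3, byrow = TRUE),
    y = matrix(c(cth, 0, sth, 0, 1, 0, -sth, 0, cth), 3, 3, byrow = TRUE),
    z = matrix(c(cth, -sth, 0, sth, cth, 0, 0, 0, 1), 3, 3, byrow = TRUE))
}

# Minimal rotation taking +z onto unit vector u, as a quaternion.
alignZQuat <- function(u) {
  uz <- max(-1, min(1, u[3]))
  ax <- c(-u[2], u[1], 0)
  na <- sqrt(sum(ax^2))
  if (na < 1e-12) {
    if (uz > 0) c(1, 0, 0, 0) else c(0, 1, 0, 0)   # flip about x
  } else {
    ang <- acos(uz)
    c(cos(ang / 2), sin(ang / 2) * ax / na)
  }
}

# All-pairs squared distances between row-matrices a (n x 3), b (m x 3).
crossDist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}
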