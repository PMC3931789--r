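# Shrake-Rupley solvent-accessible surface area and the relative-SASA
# (A_rel) predictor of unbound docking success. A protein whose
# accessible area exceeds that expected for a folded protein of its
# molecular weight by more than 10 percent (A_rel > 1.1) is likely to
# undergo large binding-induced conformational change, which defeats
# rigid-body docking.

# Element van der Waals radii (Angstrom), Bondi-type values.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               H = 1.20, SE = 1.90)

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's sphere of radius (vdW + probe) is sampled with a
#' deterministic spherical point lattice; points not buried inside any
#' neighbour's probe-expanded sphere count as accessible.
#'
#' @param s a non-empty \code{TypedStructure}.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param nPoints sample points per atom sphere (default 960).
#' @return total accessible area in square Angstrom, with per-atom
#'   areas as attribute \code{"perAtom"}.
#' @export
sasa <- function(s, probe = 1.4, nPoints = 960) {
  if (nAtoms(s) == 0) stop("empty structure")
  ele <- toupper(s@atoms$element)
  radii <- VDW_RADII[ele]
  if (anyNA(radii))
    stop("no van der Waals radius for element(s): ",
         paste(unique(ele[is.na(radii)]), collapse = ", "))
  radii <- unname(radii) + probe
  xyz <- atomCoords(s)
  n <- nrow(xyz)
  pts <- fibonacciSphere(nPoints)
  # neighbour lists: spheres that can occlude each other
  d2 <- crossDist2(xyz, xyz)
  perAtom <- numeric(n)
  for (i in seq_len(n)) {
    ri <- radii[i]
    nb <- which(d2[i, ] < (ri + radii)^2 & seq_len(n) != i)
    sp <- sweep(pts * ri, 2, xyz[i, ], "+")
    accessible <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(accessible)) break
      dj <- rowSums(sweep(sp, 2, xyz[j, ])^2)
      accessible <- accessible & dj >= radii[j]^2
    }
    perAtom[i] <- 4 * pi * ri^2 * mean(accessible)
  }
  structure(sum(perAtom), perAtom = perAtom)
}

#' Relative solvent-accessible surface area
#'
#' A_rel is the measured accessible area divided by the area expected
#' for a folded protein of the same molecular weight, via the power
#' law \eqn{A_{expected} = c M^e} (defaults c = 6.3, e = 0.73, Miller-type
#' relation with M in Dalton and areas in square Angstrom; calibrated
#' against the package's heavy-atom molecular weight convention).
#'
#' @param s a \code{TypedStructure}.
#' @param coeff,expo power-law constants.
#' @param probe,nPoints passed to \code{\link{sasa}}.
#' @return an \code{ArelReport}.
#' @export
aRel <- function(s, coeff = 6.3, expo = 0.73, probe = 1.4,
                 nPoints = 960) {
  mw <- molecularWeight(s)
  if (mw <= 0) stop("zero molecular weight")
  area <- as.numeric(sasa(s, probe = probe, nPoints = nPoints))
  expected <- coeff * mw^expo
  new("ArelReport", sasa = area, expectedSasa = expected,
      arel = area / expected, mw = mw)
}

setMethod("show", "ArelReport", function(object) {
  cat(sprintf(
    "ArelReport: SASA %.1f A^2, expected %.1f A^2 (M %.0f Da), A_rel %.3f\n",
    object@sasa, object@expectedSasa, object@mw, object@arel))
})

#' Predict whether unbound docking will succeed
#'
#' Success is predicted if and only if both partners have A_rel
#' strictly below the threshold (1.1 by default): partners with larger
#' relative accessible area are extended/flexible and tend to change
#' conformation on binding, defeating rigid docking.
#'
#' @param receptorUnbound,ligandUnbound unbound partner structures.
#' @param threshold A_rel threshold (default 1.1).
#' @param ... passed to \code{\link{aRel}}.
#' @return list with \code{prediction} (\code{"success"} or
#'   \code{"failure"}), \code{success} (logical) and the two
#'   \code{ArelReport}s.
#' @export
predictSuccess <- function(receptorUnbound, ligandUnbound,
                           threshold = 1.1, ...) {
  rr <- aRel(receptorUnbound, ...)
  rl <- aRel(ligandUnbound, ...)
  ok <- rr@arel < threshold && rl@arel < threshold
  list(prediction = if (ok) "success" else "failure", success = ok,
       receptor = rr, ligand = rl)
}
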