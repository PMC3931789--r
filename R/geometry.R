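# Geometric primitives: rmsd with optional least-squares superposition,
# centre of mass, molecular weight, rigid poses.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# Resolve a selection argument to a logical mask over atoms.
resolveSelection <- function(s, selection) {
  a <- s@atoms
  if (is.character(selection) && length(selection) == 1) {
    switch(selection,
      all = rep(TRUE, nrow(a)),
      backbone = a$name %in% BACKBONE_ATOMS,
      calpha = a$name == "CA",
      stop("unknown selection keyword: ", selection))
  } else if (is.logical(selection)) {
    stopifnot(length(selection) == nrow(a))
    selection
  } else if (is.numeric(selection)) {
    seq_len(nrow(a)) %in% selection
  } else stop("selection must be a keyword, logical mask or index vector")
}

# Check that two selected atom sets correspond atom-by-atom.
checkCorrespondence <- function(a, b) {
  if (nrow(a) != nrow(b))
    stop("selections do not correspond: ", nrow(a), " vs ", nrow(b),
         " atoms")
  if (!all(a$name == b$name) || !all(a$resname == b$resname))
    stop("selections do not correspond: atom identities differ")
  invisible(TRUE)
}

#' Root-mean-square deviation between two structures
#'
#' The structures must correspond atom-by-atom under the selection
#' (same atom count, names and residue names, in order). With
#' \code{superpose = TRUE} the deviation is measured after optimal
#' least-squares superposition of the selected atoms.
#'
#' @param a,b \code{TypedStructure} objects.
#' @param selection \code{"all"} (default), \code{"backbone"},
#'   \code{"calpha"}, or a logical/index vector over the atoms of both
#'   structures.
#' @param superpose logical; superpose before measuring.
#' @return rmsd in Angstrom.
#' @export
rmsdStructures <- function(a, b, selection = "all", superpose = FALSE) {
  ma <- resolveSelection(a, selection)
  mb <- resolveSelection(b, selection)
  aa <- a@atoms[ma, , drop = FALSE]
  ab <- b@atoms[mb, , drop = FALSE]
  checkCorrespondence(aa, ab)
  xa <- as.matrix(aa[, c("x", "y", "z")])
  xb <- as.matrix(ab[, c("x", "y", "z")])
  if (superpose) xb <- kabschFit(xa, xb)$coords
  rmsdCoords(xa, xb)
}

# Plain rmsd between corresponding coordinate matrices.
rmsdCoords <- function(xa, xb) {
  sqrt(mean(rowSums((xa - xb)^2)))
}

# Least-squares superposition of mobile onto fixed (both n x 3).
# Returns the transformed mobile coordinates plus rotation/translation
# so the same transform can be applied to other coordinates.
kabschFit <- function(fixed, mobile) {
  cf <- colMeans(fixed)
  cm <- colMeans(mobile)
  H <- crossprod(sweep(mobile, 2, cm), sweep(fixed, 2, cf))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cf - as.vector(R %*% cm)
  coords <- sweep(tcrossprod(mobile, R), 2, trans, "+")
  list(coords = coords, rotation = R, translation = trans)
}

# Apply a kabschFit transform to arbitrary coordinates.
applyFit <- function(fit, coords) {
  sweep(tcrossprod(coords, fit$rotation), 2, fit$translation, "+")
}

# bio3d's periodic-table data, cached after first use.
bio3dElements <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("elements", package = "bio3d", envir = e)
      cache <<- get("elements", envir = e)
    }
    cache
  }
})

# Atomic masses for the element column; errors on unknown elements.
atomMasses <- function(s) {
  ele <- s@atoms$element
  tab <- bio3dElements()
  m <- tab$mass[match(toupper(ele), toupper(tab$symb))]
  if (any(is.na(m) | m == 0))
    stop("unknown element(s): ",
         paste(unique(ele[is.na(m) | m == 0]), collapse = ", "))
  m
}

#' Mass-weighted centre of mass
#'
#' @param s a non-empty \code{TypedStructure}.
#' @return numeric 3-vector in Angstrom.
#' @export
centerOfMass <- function(s) {
  if (nAtoms(s) == 0) stop("empty structure")
  m <- atomMasses(s)
  as.vector(crossprod(atomCoords(s), m) / sum(m))
}

#' Heavy-atom molecular weight
#'
#' Sum of the atomic masses of the retained heavy atoms (hydrogens are
#' excluded throughout the package, so this is the package's molecular
#' weight convention; the expected-SASA power law is calibrated against
#' the same convention).
#'
#' @param s a \code{TypedStructure}.
#' @return mass in Dalton (0 for an empty structure).
#' @export
molecularWeight <- function(s) {
  if (nAtoms(s) == 0) return(0)
  sum(atomMasses(s))
}

#' Construct a rigid pose
#'
#' @param rotation 3x3 proper rotation matrix (default identity).
#' @param translation numeric 3-vector in Angstrom (default zero).
#' @return a \code{Pose}.
#' @export
pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("Pose", rotation = rotation, translation = as.numeric(translation))
}

#' Invert a pose
#' @param p a \code{Pose}.
#' @return the inverse \code{Pose}.
#' @export
invertPose <- function(p) {
  Rt <- t(p@rotation)
  pose(Rt, -as.vector(Rt %*% p@translation))
}

setMethod("show", "Pose", function(object) {
  q <- mat2quat(object@rotation)
  ang <- 2 * acos(min(1, abs(q[1]))) * 180 / pi
  cat(sprintf("Pose: rotation %.1f deg, translation (%.2f, %.2f, %.2f) A\n",
              ang, object@translation[1], object@translation[2],
              object@translation[3]))
})

#' Apply a rigid pose to a structure
#'
#' Coordinates are rotated then translated (x' = R x + t); all
#' intra-structure distances are preserved.
#'
#' @param s a \code{TypedStructure}.
#' @param p a \code{Pose}.
#' @return the transformed \code{TypedStructure}.
#' @export
applyPose <- function(s, p) {
  validObject(p)
  xyz <- atomCoords(s)
  setCoords(s, sweep(tcrossprod(xyz, p@rotation), 2, p@translation, "+"))
}
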