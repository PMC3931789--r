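# Scoring of complex configurations: direct pair summation over all
# inter-partner heavy-atom pairs below 5 Angstrom, and the fast path via
# receptor potential grids (one scalar field per ligand atom type).

# Look up binned potential values for (typeIndexA, typeIndexB, d).
potentialLookup <- function(p, ia, ib, d, interpolate = FALSE) {
  nb <- length(p@breaks) - 1
  bw <- p@breaks[2] - p@breaks[1]
  if (!interpolate) {
    bin <- pmin(nb, floor(d / bw) + 1L)
    return(p@values[cbind(ia, ib, bin)])
  }
  centers <- binCenters(p)
  pos <- (d - centers[1]) / bw
  k0 <- pmax(1L, pmin(nb - 1L, floor(pos) + 1L))
  f <- pmin(1, pmax(0, pos - (k0 - 1)))
  v0 <- p@values[cbind(ia, ib, k0)]
  v1 <- p@values[cbind(ia, ib, k0 + 1L)]
  v0 * (1 - f) + v1 * f
}

#' Score a complex configuration by direct pair summation
#'
#' Sums the pair potential over every inter-partner heavy-atom pair at a
#' distance below 5 Angstrom. Pairs at or beyond the cutoff contribute
#' nothing. The score is symmetric in the two partners and lower values
#' are more favourable.
#'
#' @param receptor,ligand typed \code{TypedStructure}s.
#' @param p a \code{PairPotentialSet}.
#' @param interpolate logical; linear interpolation between bin centres
#'   instead of the piecewise-constant (containing-bin) lookup that
#'   matches the derivation's binning (default FALSE).
#' @return list with \code{value} (the summed score) and \code{nPairs}
#'   (number of contributing atom pairs).
#' @export
scoreDirect <- function(receptor, ligand, p, interpolate = FALSE) {
  tr <- atomTypes(receptor); tl <- atomTypes(ligand)
  if (any(tr == "untyped") || any(tl == "untyped"))
    stop("untyped atoms; run assignAtomTypes first")
  ir <- match(tr, p@alphabet); il <- match(tl, p@alphabet)
  if (anyNA(ir) || anyNA(il))
    stop("atom types outside the potential alphabet")
  xr <- atomCoords(receptor); xl <- atomCoords(ligand)
  d2 <- crossDist2(xr, xl)
  hit <- which(d2 < (PAIR_DISTANCE_CUTOFF + 0.01)^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(list(value = 0, nPairs = 0L))
  # recompute exact distances for the candidates (bin-edge robustness)
  d <- sqrt(rowSums((xr[hit[, 1], , drop = FALSE] -
                       xl[hit[, 2], , drop = FALSE])^2))
  keep <- d < PAIR_DISTANCE_CUTOFF
  if (!any(keep)) return(list(value = 0, nPairs = 0L))
  hit <- hit[keep, , drop = FALSE]
  d <- d[keep]
  v <- potentialLookup(p, ir[hit[, 1]], il[hit[, 2]], d, interpolate)
  list(value = sum(v), nPairs = nrow(hit))
}

#' Precompute receptor potential grids
#'
#' Builds one rectangular scalar field per atom type of the alphabet
#' (11 by default). Each node holds the sum over receptor atoms of the
#' pair potential between the receptor atom's type and the grid's type
#' at the node-atom distance, for distances below 5 Angstrom. The box is
#' centred at the receptor centre of mass and leaves \code{margin}
#' Angstrom beyond the receptor extent on every face so the full
#' interaction shell is representable.
#'
#' @param receptor typed \code{TypedStructure}.
#' @param p a \code{PairPotentialSet}.
#' @param spacing node spacing in Angstrom (default 1, matching the
#'   translational search step).
#' @param margin box margin per face in Angstrom (default 5, the
#'   interaction cutoff).
#' @return a \code{PotentialGridSet}.
#' @export
buildGrids <- function(receptor, p, spacing = 1, margin = 5) {
  if (spacing <= 0) stop("spacing must be > 0")
  tr <- atomTypes(receptor)
  if (any(tr == "untyped")) stop("untyped receptor atoms")
  ir <- match(tr, p@alphabet)
  if (anyNA(ir)) stop("receptor types outside the potential alphabet")
  xyz <- atomCoords(receptor)
  com <- centerOfMass(receptor)
  ext <- apply(xyz, 2, function(v) max(v) - min(v))
  half <- ext / 2 + margin
  dims <- as.integer(ceiling(2 * half / spacing)) + 1L
  origin <- com - (dims - 1) * spacing / 2
  # node axes
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(dims[k]) - 1) * spacing)
  nt <- length(p@alphabet)
  grids <- lapply(seq_len(nt), function(g) array(0, dims))
  names(grids) <- p@alphabet
  cut2 <- PAIR_DISTANCE_CUTOFF^2
  for (i in seq_len(nrow(xyz))) {
    at <- xyz[i, ]
    rng <- lapply(1:3, function(k) {
      w <- which(abs(ax[[k]] - at[k]) <= PAIR_DISTANCE_CUTOFF)
      w
    })
    if (any(lengths(rng) == 0)) next
    dx2 <- (ax[[1]][rng[[1]]] - at[1])^2
    dy2 <- (ax[[2]][rng[[2]]] - at[2])^2
    dz2 <- (ax[[3]][rng[[3]]] - at[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    inside <- d2 < cut2
    if (!any(inside)) next
    d <- sqrt(d2[inside])
    nbins <- length(p@breaks) - 1
    bw <- p@breaks[2] - p@breaks[1]
    bin <- pmin(nbins, floor(d / bw) + 1L)
    for (g in seq_len(nt)) {
      block <- grids[[g]][rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
      block[inside] <- block[inside] + p@values[ir[i], g, ][bin]
      grids[[g]][rng[[1]], rng[[2]], rng[[3]]] <- block
    }
  }
  new("PotentialGridSet", alphabet = p@alphabet, origin = com -
        (dims - 1) * spacing / 2, spacing = spacing, dims = dims,
      grids = grids)
}

setMethod("show", "PotentialGridSet", function(object) {
  cat("PotentialGridSet:", length(object@grids), "grids,",
      paste(object@dims, collapse = " x "), "nodes at",
      object@spacing, "A spacing\n")
  cat(sprintf("  origin (%.2f, %.2f, %.2f) A\n", object@origin[1],
              object@origin[2], object@origin[3]))
})

#' Score a posed ligand on precomputed grids
#'
#' Sums, over the ligand atoms, the value of the grid matching each
#' atom's type at the atom's posed position. Atoms posed outside the
#' grid box contribute zero and are counted (they are beyond the
#' interaction shell by the box-size rule).
#'
#' @param grids a \code{PotentialGridSet}.
#' @param ligand typed \code{TypedStructure}.
#' @param pose a \code{Pose} applied to the ligand (default identity).
#' @param interpolation \code{"trilinear"} (default) or
#'   \code{"nearest"} node lookup.
#' @return list with \code{value}, \code{nAtoms} and \code{nOutside}
#'   (atoms outside the box).
#' @export
scoreOnGrid <- function(grids, ligand, pose = NULL,
                        interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  tl <- atomTypes(ligand)
  if (any(tl == "untyped")) stop("untyped ligand atoms")
  gi <- match(tl, grids@alphabet)
  if (anyNA(gi))
    stop("ligand types missing from the grid set: ",
         paste(unique(tl[is.na(gi)]), collapse = ", "))
  if (!is.null(pose)) ligand <- applyPose(ligand, pose)
  xyz <- atomCoords(ligand)
  u <- sweep(xyz, 2, grids@origin) / grids@spacing   # grid coordinates
  dims <- grids@dims
  total <- 0; outside <- 0L
  for (i in seq_len(nrow(u))) {
    g <- grids@grids[[gi[i]]]
    if (interpolation == "nearest") {
      idx <- round(u[i, ]) + 1
      if (any(idx < 1) || any(idx > dims)) { outside <- outside + 1L; next }
      total <- total + g[idx[1], idx[2], idx[3]]
    } else {
      i0 <- floor(u[i, ]) + 1
      f <- u[i, ] - (i0 - 1)
      if (any(i0 < 1) || any(i0 + 1 > dims)) {
        # clamp onto a face only if still inside; otherwise outside
        if (any(u[i, ] < 0) || any(u[i, ] > dims - 1)) {
          outside <- outside + 1L; next
        }
        i0 <- pmin(i0, dims - 1)
        f <- u[i, ] - (i0 - 1)
      }
      acc <- 0
      for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
        w <- (if (cx) f[1] else 1 - f[1]) *
             (if (cy) f[2] else 1 - f[2]) *
             (if (cz) f[3] else 1 - f[3])
        if (w > 0)
          acc <- acc + w * g[i0[1] + cx, i0[2] + cy, i0[3] + cz]
      }
      total <- total + acc
    }
  }
  list(value = total, nAtoms = nrow(u), nOutside = outside)
}
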