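#' @import methods
NULL

#' Typed protein structure
#'
#' Container for the heavy atoms of one protein (or one docking partner):
#' coordinates in Angstrom, chain/residue identity, element, and a
#' Sybyl-style atom type label (\code{"untyped"} until
#' \code{\link{assignAtomTypes}} has been run).
#'
#' @slot atoms data.frame with one row per heavy atom and columns
#'   \code{serial}, \code{name}, \code{resname}, \code{chain},
#'   \code{resno}, \code{insert}, \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{type}.
#' @slot provenance character notes on where the atoms came from (source
#'   path, records dropped while parsing).
#'
#' @seealso \code{\link{readPDB}}, \code{\link{assignAtomTypes}}
#' @export
setClass("TypedStructure",
  representation(atoms = "data.frame", provenance = "character"),
  prototype(atoms = data.frame(), provenance = character())
)

setValidity("TypedStructure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "resname", "chain", "resno", "insert",
            "element", "x", "y", "z", "type")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) > 0) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      return("non-finite coordinates")
    if (any(!nzchar(a$element)))
      return("empty element symbols")
  }
  TRUE
})

#' Residue/atom to Sybyl-type lookup table
#'
#' Maps (residue name, atom name) pairs of the 20 canonical amino acids
#' to one of the atom-type labels of the alphabet (11 labels by default,
#' giving 121 ordered type pairs).
#'
#' @slot table data.frame with columns \code{resname}, \code{atom},
#'   \code{type}.
#' @slot alphabet character vector of type labels.
#'
#' @seealso \code{\link{defaultAtomTypeTable}}
#' @export
setClass("AtomTypeTable",
  representation(table = "data.frame", alphabet = "character")
)

setValidity("AtomTypeTable", function(object) {
  t <- object@table
  if (!all(c("resname", "atom", "type") %in% names(t)))
    return("table must have columns resname, atom, type")
  if (!all(t$type %in% object@alphabet))
    return("table contains types outside the alphabet")
  TRUE
})

#' Symmetric inter-partner distance histograms per type pair
#'
#' Raw counts of inter-partner heavy-atom distances below the 5 Angstrom
#' cutoff, binned on a shared partition, one histogram per unordered
#' type pair (stored symmetrically).
#'
#' @slot alphabet character type labels.
#' @slot breaks numeric bin edges covering [0, 5) Angstrom.
#' @slot counts 3-d array [type, type, bin], symmetric in the first two
#'   dimensions.
#' @export
setClass("PairHistogramSet",
  representation(alphabet = "character", breaks = "numeric",
                 counts = "array")
)

setValidity("PairHistogramSet", function(object) {
  nt <- length(object@alphabet)
  nb <- length(object@breaks) - 1L
  if (!all(dim(object@counts) == c(nt, nt, nb)))
    return("counts dimensions do not match alphabet/breaks")
  if (any(object@counts < 0)) return("negative counts")
  for (k in seq_len(nb))
    if (!isTRUE(all.equal(object@counts[, , k], t(object@counts[, , k]))))
      return("counts not symmetric under type-pair swap")
  TRUE
})

#' Distance-dependent pair potentials
#'
#' Binned potential values for every ordered type pair over [0, 5)
#' Angstrom, anchored to zero in the final bin, with per-pair interaction
#' counts and the statistical-significance threshold.
#'
#' @slot alphabet character type labels.
#' @slot breaks numeric shared bin edges.
#' @slot values 3-d array [type, type, bin] of potential values
#'   (dimensionless; lower = more favourable).
#' @slot counts matrix [type, type] of total interaction counts per pair.
#' @slot sigThreshold minimum count for a statistically significant pair
#'   potential (500 by default).
#' @slot repulsionApplied logical; TRUE once the short-range Gaussian
#'   repulsion has been added.
#' @export
setClass("PairPotentialSet",
  representation(alphabet = "character", breaks = "numeric",
                 values = "array", counts = "matrix",
                 sigThreshold = "numeric", repulsionApplied = "logical"),
  prototype(sigThreshold = 500, repulsionApplied = FALSE)
)

setValidity("PairPotentialSet", function(object) {
  nt <- length(object@alphabet)
  nb <- length(object@breaks) - 1L
  if (!all(dim(object@values) == c(nt, nt, nb)))
    return("values dimensions do not match alphabet/breaks")
  if (!all(is.finite(object@values))) return("non-finite potential values")
  if (!all(dim(object@counts) == c(nt, nt)))
    return("counts dimensions do not match alphabet")
  TRUE
})

#' Short-range Gaussian repulsion parameters
#'
#' @slot height value added at d = 0 (default 280000).
#' @slot width Gaussian sigma in Angstrom (default 0.8, which decays the
#'   term below 0.1 percent of its height by 3 Angstrom).
#' @slot onsetOffset Angstrom added to the first-maximum location to set
#'   the repulsion onset (default 0.1).
#' @export
setClass("RepulsionParams",
  representation(height = "numeric", width = "numeric",
                 onsetOffset = "numeric"),
  prototype(height = 280000, width = 0.8, onsetOffset = 0.1)
)

setValidity("RepulsionParams", function(object) {
  if (object@height <= 0) return("height must be > 0")
  if (object@width <= 0) return("width must be > 0")
  TRUE
})

#' Precomputed receptor potential grids
#'
#' One rectangular scalar field per atom type of the alphabet, each node
#' holding the summed pair-potential contribution of all receptor atoms
#' within the 5 Angstrom interaction range. The box is centred at the
#' receptor centre of mass and leaves a 5 Angstrom margin on every face.
#'
#' @slot alphabet character type labels (one grid per label).
#' @slot origin coordinates of the first node, Angstrom.
#' @slot spacing node spacing, Angstrom.
#' @slot dims integer grid dimensions (nx, ny, nz).
#' @slot grids named list of 3-d arrays of node values.
#' @export
setClass("PotentialGridSet",
  representation(alphabet = "character", origin = "numeric",
                 spacing = "numeric", dims = "integer", grids = "list")
)

setValidity("PotentialGridSet", function(object) {
  if (object@spacing <= 0) return("spacing must be > 0")
  if (length(object@dims) != 3 || any(object@dims < 1))
    return("dims must be three integers >= 1")
  if (!identical(names(object@grids), object@alphabet))
    return("grids must be named by the alphabet, in order")
  for (g in object@grids)
    if (!all(dim(g) == object@dims)) return("grid dims mismatch")
  TRUE
})

#' Rigid-body pose
#'
#' A proper rotation plus translation applied to atomic coordinates as
#' x' = R x + t.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation 3-vector, Angstrom.
#' @export
setClass("Pose",
  representation(rotation = "matrix", translation = "numeric")
)

setValidity("Pose", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation matrix is not orthonormal")
  if (abs(det(R) - 1) > 1e-6)
    return("rotation matrix determinant is not +1")
  if (length(object@translation) != 3 || !all(is.finite(object@translation)))
    return("translation must be a finite 3-vector")
  TRUE
})

#' Ranked docking solutions
#'
#' Ordered rigid-body solutions with scores, ranks and (after
#' clustering) cluster assignments. Rotations are stored as unit
#' quaternions (w, x, y, z); translations are the plain affine offsets
#' so that \code{applyPose} reproduces the posed ligand.
#'
#' @slot solutions data.frame with columns \code{rank}, \code{score},
#'   \code{qw}, \code{qx}, \code{qy}, \code{qz}, \code{tx}, \code{ty},
#'   \code{tz}, \code{cluster} (NA before clustering).
#' @slot metadata list of search settings (resolution, step,
#'   restriction, seed, potential-table checksum).
#' @export
setClass("SolutionList",
  representation(solutions = "data.frame", metadata = "list"),
  prototype(metadata = list())
)

setValidity("SolutionList", function(object) {
  s <- object@solutions
  need <- c("rank", "score", "qw", "qx", "qy", "qz",
            "tx", "ty", "tz", "cluster")
  if (!all(need %in% names(s)))
    return(paste("solutions must have columns:", paste(need, collapse = ", ")))
  if (nrow(s) > 0) {
    if (!identical(as.integer(s$rank), seq_len(nrow(s))))
      return("ranks must be contiguous 1..n in order")
  }
  TRUE
})

#' CAPRI-style quality report
#'
#' @slot fnat fraction of reference contacts reproduced by the model.
#' @slot fnot fraction of the model's contacts absent from the reference.
#' @slot irmsd interface backbone rmsd, Angstrom.
#' @slot lrmsd ligand backbone rmsd after receptor superposition,
#'   Angstrom.
#' @slot qualityClass one of \code{"high"}, \code{"medium"},
#'   \code{"acceptable"}, \code{"incorrect"}.
#' @slot mode index of the reference binding mode the report refers to.
#' @export
setClass("QualityReport",
  representation(fnat = "numeric", fnot = "numeric", irmsd = "numeric",
                 lrmsd = "numeric", qualityClass = "character",
                 mode = "integer")
)

setValidity("QualityReport", function(object) {
  if (object@fnat < 0 || object@fnat > 1) return("fnat outside [0,1]")
  if (object@fnot < 0 || object@fnot > 1) return("fnot outside [0,1]")
  if (object@irmsd < 0 || object@lrmsd < 0) return("negative rmsd")
  if (!object@qualityClass %in%
        c("high", "medium", "acceptable", "incorrect"))
    return("unknown quality class")
  TRUE
})

#' Quality class of a QualityReport
#' @param x a \code{QualityReport}.
#' @return character class label.
#' @export
qualityClass <- function(x) x@qualityClass

#' Relative solvent-accessible surface area report
#'
#' @slot sasa measured accessible area, square Angstrom.
#' @slot expectedSasa area expected for a folded protein of the same
#'   molecular weight (power law), square Angstrom.
#' @slot arel ratio sasa / expectedSasa.
#' @slot mw heavy-atom molecular weight, Dalton.
#' @export
setClass("ArelReport",
  representation(sasa = "numeric", expectedSasa = "numeric",
                 arel = "numeric", mw = "numeric")
)

setValidity("ArelReport", function(object) {
  if (object@sasa <= 0) return("sasa must be > 0")
  if (object@arel <= 0) return("arel must be > 0")
  TRUE
})
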