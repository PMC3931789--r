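# PDB input/output and TypedStructure accessors. Parsing and writing of
# the fixed-column PDB dialect go through bio3d; this layer enforces the
# package's conventions: heavy atoms only, single conformer per atom,
# protein ATOM records only.

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

# Construct a TypedStructure from an atoms data.frame.
newTypedStructure <- function(atoms, provenance = character()) {
  rownames(atoms) <- NULL
  new("TypedStructure", atoms = atoms, provenance = provenance)
}

#' Number of atoms in a structure
#' @param x a \code{TypedStructure}.
#' @return integer atom count.
#' @export
nAtoms <- function(x) nrow(x@atoms)

#' Atom table of a structure
#' @param x a \code{TypedStructure}.
#' @return data.frame with one row per atom.
#' @export
atomData <- function(x) x@atoms

#' Atom coordinates
#' @param x a \code{TypedStructure}.
#' @return numeric matrix (n x 3) of coordinates in Angstrom.
#' @export
atomCoords <- function(x) {
  as.matrix(x@atoms[, c("x", "y", "z"), drop = FALSE])
}

#' Atom types
#' @param x a \code{TypedStructure}.
#' @return character vector of type labels (\code{"untyped"} before
#'   typing).
#' @export
atomTypes <- function(x) x@atoms$type

#' Chain identifiers present in a structure
#' @param x a \code{TypedStructure}.
#' @return character vector of unique chain ids, in order of appearance.
#' @export
chainIds <- function(x) unique(x@atoms$chain)

# Replace coordinates, preserving all other columns.
setCoords <- function(x, coords) {
  stopifnot(nrow(coords) == nAtoms(x))
  x@atoms$x <- coords[, 1]
  x@atoms$y <- coords[, 2]
  x@atoms$z <- coords[, 3]
  x
}

# Residue keys "chain/resno/insert" per atom.
residueKeys <- function(x) {
  a <- x@atoms
  paste(a$chain, a$resno, a$insert, sep = "/")
}

#' Subset a structure by chain
#' @param x a \code{TypedStructure}.
#' @param chain chain id(s) to keep.
#' @return a \code{TypedStructure} with only the selected chains.
#' @export
selectChains <- function(x, chain) {
  keep <- x@atoms$chain %in% chain
  newTypedStructure(x@atoms[keep, , drop = FALSE], x@provenance)
}

setMethod("show", "TypedStructure", function(object) {
  a <- object@atoms
  nres <- length(unique(residueKeys(object)))
  typed <- sum(a$type != "untyped")
  cat("TypedStructure:", nrow(a), "heavy atoms,", nres, "residues,",
      length(unique(a$chain)), "chain(s)\n")
  cat("  typed atoms:", typed, "/", nrow(a), "\n")
  if (length(object@provenance))
    cat("  provenance:", object@provenance[1], "\n")
})

#' Read a protein structure from a PDB file
#'
#' Reads ATOM records only: HETATM groups, waters and hydrogens are
#' dropped, and alternate locations are resolved to a single conformer
#' (highest occupancy, ties broken by the alphabetically first altloc
#' label). Atom types are left as \code{"untyped"}; run
#' \code{\link{assignAtomTypes}} afterwards.
#'
#' @param path path to a PDB file.
#' @return a \code{TypedStructure}.
#' @export
readPDB <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("could not parse PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% WATER_RESIDUES), ,
           drop = FALSE]
  if (nrow(at) == 0) stop("no protein ATOM records in ", path)
  ele <- at$elesy
  miss <- is.na(ele) | !nzchar(trimws(ele))
  if (any(miss))
    ele[miss] <- suppressWarnings(bio3d::atom2ele(at$elety[miss]))
  ele <- trimws(ele)
  hyd <- toupper(ele) %in% c("H", "D")
  at <- at[!hyd, , drop = FALSE]
  ele <- ele[!hyd]
  if (nrow(at) == 0) stop("no protein heavy atoms in ", path)

  ins <- at$insert
  ins[is.na(ins)] <- ""
  ch <- at$chain
  ch[is.na(ch)] <- " "
  key <- paste(ch, at$resno, ins, at$elety, sep = "\r")
  occ <- at$o
  occ[is.na(occ)] <- 1
  alt <- at$alt
  alt[is.na(alt)] <- ""
  nAll <- nrow(at)
  # altloc rule: highest occupancy wins, ties -> first altloc label
  ord <- order(key, -occ, alt)
  keep <- ord[!duplicated(key[ord])]
  keep <- sort(keep)               # restore file order
  at <- at[keep, , drop = FALSE]
  ele <- ele[keep]
  ch <- ch[keep]
  ins <- ins[keep]

  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = at$elety,
    resname = at$resid,
    chain = ch,
    resno = as.integer(at$resno),
    insert = ins,
    element = ele,
    x = at$x, y = at$y, z = at$z,
    type = "untyped",
    stringsAsFactors = FALSE)
  prov <- c(paste0("source: ", path),
            if (nAll > nrow(at))
              paste0("altloc records collapsed: ", nAll - nrow(at)))
  newTypedStructure(atoms, prov)
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column ATOM records readable by \code{\link{readPDB}}.
#'
#' @param x a \code{TypedStructure}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writePDB <- function(x, path) {
  a <- x@atoms
  if (nrow(a) == 0) stop("cannot write an empty structure")
  xyz <- as.vector(t(atomCoords(x)))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
                   eleno = a$serial, elety = a$name, resid = a$resname,
                   chain = a$chain, resno = a$resno,
                   insert = ifelse(nzchar(a$insert), a$insert, NA),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   elesy = a$element)
  invisible(path)
}
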