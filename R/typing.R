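# Sybyl-style atom typing. The residue/atom -> type table ships as an
# editable tab-separated configuration file; the default covers all
# heavy atoms of the 20 canonical amino acids with an 11-label alphabet
# (C.2, C.3, C.ar, N.3, N.am, N.ar, N.pl3, O.2, O.3, O.co2, S.3),
# giving 121 ordered type pairs.

#' Read an atom-type configuration table
#'
#' @param path tab-separated file with columns \code{resname},
#'   \code{atom}, \code{type}; lines starting with \code{#} are
#'   comments.
#' @return an \code{AtomTypeTable}.
#' @export
readAtomTypeTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("resname", "atom", "type") %in% names(tab)))
    stop("atom-type table needs columns resname, atom, type")
  new("AtomTypeTable", table = tab, alphabet = sort(unique(tab$type)))
}

#' The default atom-type table
#'
#' Reads the table bundled with the package
#' (\code{inst/extdata/atom_types.tsv}).
#'
#' @return an \code{AtomTypeTable} with an 11-label alphabet.
#' @export
defaultAtomTypeTable <- function() {
  readAtomTypeTable(system.file("extdata", "atom_types.tsv",
                                package = "ppdock", mustWork = TRUE))
}

#' Type alphabet of an AtomTypeTable
#' @param table an \code{AtomTypeTable}.
#' @return character vector of type labels, sorted.
#' @export
typeAlphabet <- function(table) table@alphabet

setMethod("show", "AtomTypeTable", function(object) {
  cat("AtomTypeTable:", nrow(object@table), "residue/atom entries,",
      length(object@alphabet), "types\n")
  cat("  alphabet:", paste(object@alphabet, collapse = " "), "\n")
})

#' Assign atom types to a structure
#'
#' Every heavy atom of a canonical residue receives the type given by
#' the table. Atoms without a table entry (non-canonical residues,
#' non-standard atom names) are dropped with a warning reporting the
#' count. The operation is idempotent.
#'
#' @param s a \code{TypedStructure}.
#' @param table an \code{AtomTypeTable}; defaults to
#'   \code{\link{defaultAtomTypeTable}()}.
#' @return a \code{TypedStructure} whose remaining atoms all carry a
#'   type from the table's alphabet.
#' @export
assignAtomTypes <- function(s, table = defaultAtomTypeTable()) {
  a <- s@atoms
  if (nrow(a) == 0) return(s)
  key <- paste(a$resname, a$name, sep = "\r")
  tkey <- paste(table@table$resname, table@table$atom, sep = "\r")
  idx <- match(key, tkey)
  unknown <- is.na(idx)
  if (any(unknown)) {
    bad <- unique(paste(a$resname[unknown], a$name[unknown]))
    warning(sum(unknown), " atom(s) without a type assignment dropped (",
            paste(utils::head(bad, 5), collapse = ", "),
            if (length(bad) > 5) ", ..." else "", ")")
    a <- a[!unknown, , drop = FALSE]
    idx <- idx[!unknown]
  }
  if (nrow(a) == 0) stop("no typeable atoms remain after typing")
  a$type <- table@table$type[idx]
  newTypedStructure(a, c(s@provenance,
                         if (any(unknown))
                           paste0("untypeable atoms dropped: ",
                                  sum(unknown))))
}
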