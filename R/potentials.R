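# Derivation, augmentation and persistence of the distance-dependent
# pair potentials. The potential for a type pair is the negative log
# ratio of the pair's inter-partner distance density to a pooled
# (type-averaged) reference density, binned on [0, 5) Angstrom and
# anchored to zero in the final bin. Any distance-volume correction
# cancels in the ratio because both densities share the same bins.

PAIR_DISTANCE_CUTOFF <- 5.0

#' Count inter-partner atom-pair distances
#'
#' Accumulates symmetric per-type-pair distance histograms over a
#' collection of typed complexes. Only inter-partner heavy-atom pairs at
#' distances below 5 Angstrom are counted; intra-partner pairs never
#' contribute.
#'
#' @param complexes list of complexes, each a list with elements
#'   \code{receptor} and \code{ligand} (typed \code{TypedStructure}s).
#' @param binWidth bin width in Angstrom; must divide 5 evenly
#'   (default 0.1, giving 50 bins).
#' @param alphabet type alphabet; defaults to the bundled 11-label
#'   alphabet.
#' @return a \code{PairHistogramSet}.
#' @export
countPairDistances <- function(complexes, binWidth = 0.1,
                               alphabet = typeAlphabet(defaultAtomTypeTable())) {
  nb <- PAIR_DISTANCE_CUTOFF / binWidth
  if (abs(nb - round(nb)) > 1e-9)
    stop("binWidth must divide 5 Angstrom evenly")
  nb <- as.integer(round(nb))
  nt <- length(alphabet)
  counts <- array(0, dim = c(nt, nt, nb),
                  dimnames = list(alphabet, alphabet, NULL))
  for (ci in seq_along(complexes)) {
    cx <- complexes[[ci]]
    r <- cx$receptor; l <- cx$ligand
    tr <- atomTypes(r); tl <- atomTypes(l)
    if (any(tr == "untyped") || any(tl == "untyped"))
      stop("untyped atoms in complex ", ci, "; run assignAtomTypes first")
    ir <- match(tr, alphabet); il <- match(tl, alphabet)
    if (anyNA(ir) || anyNA(il))
      stop("complex ", ci, " contains types outside the alphabet")
    xr <- atomCoords(r); xl <- atomCoords(l)
    d2 <- crossDist2(xr, xl)
    hit <- which(d2 < (PAIR_DISTANCE_CUTOFF + 0.01)^2, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    # exact distances for the candidate pairs: the expanded quadratic
    # form above loses a few ulps, which matters at bin edges
    d <- sqrt(rowSums((xr[hit[, 1], , drop = FALSE] -
                         xl[hit[, 2], , drop = FALSE])^2))
    keep <- d < PAIR_DISTANCE_CUTOFF
    hit <- hit[keep, , drop = FALSE]
    d <- d[keep]
    if (length(d) == 0) next
    bin <- pmin(nb, floor(d / binWidth) + 1L)
    a <- ir[hit[, 1]]; b <- il[hit[, 2]]
    # accumulate symmetrically: off-diagonal interactions feed both
    # ordered cells, diagonal interactions one cell, so each slice stays
    # symmetric and counts[a, b, ] sums to the pair's interaction count
    tab <- table(factor(a, levels = seq_len(nt)),
                 factor(b, levels = seq_len(nt)),
                 factor(bin, levels = seq_len(nb)))
    tab <- unclass(tab)
    for (k in seq_len(nb)) {
      s <- tab[, , k]
      counts[, , k] <- counts[, , k] + s + t(s) - diag(diag(s), nt)
    }
  }
  new("PairHistogramSet", alphabet = alphabet,
      breaks = seq(0, PAIR_DISTANCE_CUTOFF, by = binWidth), counts = counts)
}

setMethod("show", "PairHistogramSet", function(object) {
  nt <- length(object@alphabet)
  tot <- sum(object@counts) -
    sum(apply(object@counts, 3, function(s) sum(diag(s)))) / 2
  cat("PairHistogramSet:", nt, "types,",
      length(object@breaks) - 1, "bins,",
      round(sum(pairCounts(object))), "interactions\n")
})

# Total interaction count per unordered pair, from a histogram set or
# potential set.
pairCounts <- function(object) {
  if (is(object, "PairHistogramSet")) {
    m <- apply(object@counts, c(1, 2), sum)
  } else m <- object@counts
  m[upper.tri(m, diag = TRUE)]
}

#' Derive pair potentials from distance histograms
#'
#' For each type pair the potential is
#' \deqn{W(a, b, bin) = -ln[g_{ab}(bin) / g_{ref}(bin)]}
#' where \eqn{g_{ab}} is the pair's normalised distance density and
#' \eqn{g_{ref}} the pooled density over all pairs (type-averaged
#' reference). Pair densities are smoothed toward the reference with a
#' Dirichlet pseudo-count of \code{pseudoCount} observations,
#' \deqn{g_{ab} = (n_{ab} + \lambda g_{ref}) / (N_{ab} + \lambda),}
#' which keeps log ratios finite and makes bins never observed for a
#' pair mildly repulsive (\eqn{ln[(N_{ab}+\lambda)/\lambda]}) rather
#' than artificially attractive — short distances absent from the
#' knowledge base carry no attractive information. Every pair potential
#' is shifted so its final bin (at 5 Angstrom) is exactly zero; a pair
#' with no observations at all gets a flat zero potential.
#'
#' @param hist a \code{PairHistogramSet}.
#' @param pseudoCount Dirichlet smoothing weight \eqn{\lambda} in
#'   observations (default 1; 0 disables smoothing).
#' @param sigThreshold minimum interactions per pair for a
#'   statistically significant potential (default 500, about 10 per
#'   0.1 Angstrom bin).
#' @param reference \code{"pooled"} (default) or a numeric vector of
#'   per-bin reference densities (an alternative reference state).
#' @return a \code{PairPotentialSet} (repulsion not yet applied).
#' @export
derivePotentials <- function(hist, pseudoCount = 1, sigThreshold = 500,
                             reference = "pooled") {
  counts <- hist@counts
  if (sum(counts) == 0) stop("all histograms are empty")
  nt <- length(hist@alphabet)
  nb <- dim(counts)[3]
  if (is.character(reference) && identical(reference, "pooled")) {
    pooled <- rep(0, nb)
    for (a in seq_len(nt)) for (b in a:nt)
      pooled <- pooled + counts[a, b, ]
    gref <- (pooled + max(pseudoCount, 1e-12)) /
      sum(pooled + max(pseudoCount, 1e-12))
  } else {
    gref <- as.numeric(reference)
    if (length(gref) != nb || any(gref <= 0))
      stop("reference must be 'pooled' or ", nb, " positive densities")
    gref <- gref / sum(gref)
  }
  values <- array(0, dim = dim(counts),
                  dimnames = dimnames(counts))
  for (a in seq_len(nt)) for (b in a:nt) {
    n <- counts[a, b, ]
    if (sum(n) + pseudoCount == 0) next         # no data, no smoothing
    g <- (n + pseudoCount * gref) / (sum(n) + pseudoCount)
    w <- -log(g / gref)
    w <- w - w[nb]                              # zero anchor at 5 A
    values[a, b, ] <- w
    values[b, a, ] <- w
  }
  new("PairPotentialSet", alphabet = hist@alphabet, breaks = hist@breaks,
      values = values, counts = apply(counts, c(1, 2), sum),
      sigThreshold = sigThreshold, repulsionApplied = FALSE)
}

setMethod("show", "PairPotentialSet", function(object) {
  nt <- length(object@alphabet)
  cat("PairPotentialSet:", nt, "types (", nt * nt, "ordered pairs ),",
      length(object@breaks) - 1, "bins on [0,",
      max(object@breaks), ") A\n")
  cat("  repulsion applied:", object@repulsionApplied,
      "| significant pairs:",
      sum(pairCounts(object) >= object@sigThreshold), "/",
      nt * (nt + 1) / 2, "\n")
})

# Bin centres of a potential/histogram set.
binCenters <- function(object) {
  b <- object@breaks
  (b[-1] + b[-length(b)]) / 2
}

# First local maximum of a binned potential scanning from d = 0.
# Plateaus (runs of exactly equal values, as produced by
# zero-information bins under Dirichlet smoothing) are treated as one
# point: a run is the first maximum if it strictly exceeds the next
# run and either strictly exceeds the previous run or is an initial
# plateau (length >= 2, the zero-information wall at the origin). The
# location reported is the last bin of the run. When no such maximum
# precedes the global minimum the fallback is (global minimum location
# - bin width); a strictly decreasing potential therefore always takes
# the fallback.
firstMaximumLocation <- function(values, centers) {
  nb <- length(values)
  kmin <- which.min(values)
  runEnd <- c(which(diff(values) != 0), nb)    # last index of each run
  runVal <- values[runEnd]
  for (r in seq_along(runEnd)) {
    if (runEnd[r] >= kmin) break
    aboveNext <- r < length(runEnd) && runVal[r] > runVal[r + 1]
    abovePrev <- if (r == 1) runEnd[1] >= 2 else runVal[r] > runVal[r - 1]
    if (aboveNext && abovePrev) return(centers[runEnd[r]])
  }
  centers[kmin] - (centers[2] - centers[1])
}

#' Add the short-range Gaussian repulsion term
#'
#' For each pair potential, all bins below the location of its first
#' maximum (scanning from d = 0) plus the onset offset receive an added
#' Gaussian \eqn{h \exp(-d^2 / (2 \sigma^2))} evaluated at the bin's
#' lower edge, so the d = 0 bin receives exactly the full height. This
#' penalises inter-partner distances shorter than any observed in the
#' knowledge base.
#'
#' @param p a derived \code{PairPotentialSet} without repulsion.
#' @param params a \code{RepulsionParams} (height 280000, sigma 0.8 A,
#'   onset offset 0.1 A by default).
#' @return the augmented \code{PairPotentialSet}.
#' @export
addRepulsion <- function(p, params = new("RepulsionParams")) {
  if (p@repulsionApplied) stop("repulsion already applied")
  validObject(params)
  centers <- binCenters(p)
  edges <- p@breaks[-length(p@breaks)]
  nt <- length(p@alphabet)
  values <- p@values
  for (a in seq_len(nt)) for (b in a:nt) {
    v <- values[a, b, ]
    onset <- firstMaximumLocation(v, centers) + params@onsetOffset
    sel <- centers < onset
    v[sel] <- v[sel] +
      params@height * exp(-edges[sel]^2 / (2 * params@width^2))
    values[a, b, ] <- v
    values[b, a, ] <- v
  }
  initialize(p, values = values, repulsionApplied = TRUE)
}

#' Statistical-significance report per type pair
#'
#' One row per unordered type pair with its total interaction count and
#' whether it reaches the significance threshold (count >= 500 by
#' default).
#'
#' @param p a \code{PairPotentialSet}.
#' @return data.frame with columns \code{typeA}, \code{typeB},
#'   \code{count}, \code{significant}.
#' @export
significanceReport <- function(p) {
  nt <- length(p@alphabet)
  out <- do.call(rbind, lapply(seq_len(nt), function(a)
    data.frame(typeA = p@alphabet[a], typeB = p@alphabet[a:nt],
               count = p@counts[a, a:nt],
               stringsAsFactors = FALSE)))
  out$significant <- out$count >= p@sigThreshold
  rownames(out) <- NULL
  out
}

#' Save pair potentials as tab-separated text
#'
#' Canonical ordering (typeA <= typeB, ascending bins) so files diff
#' bit-exactly; metadata lines carry the significance threshold and the
#' repulsion state.
#'
#' @param p a \code{PairPotentialSet}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
savePotentials <- function(p, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# ppdock pair potentials"),
    paste0("# sig_threshold\t", format(p@sigThreshold)),
    paste0("# repulsion_applied\t", as.integer(p@repulsionApplied)),
    paste("type_a", "type_b", "bin_lo", "bin_hi", "count", "delta_w",
          "repulsion_flag", sep = "\t")), con)
  nt <- length(p@alphabet)
  nb <- length(p@breaks) - 1
  lo <- p@breaks[-(nb + 1)]; hi <- p@breaks[-1]
  for (a in seq_len(nt)) for (b in a:nt) {
    writeLines(paste(p@alphabet[a], p@alphabet[b],
                     sprintf("%.17g", lo), sprintf("%.17g", hi),
                     sprintf("%.17g", p@counts[a, b]),
                     sprintf("%.17g", p@values[a, b, ]),
                     as.integer(p@repulsionApplied), sep = "\t"), con)
  }
  invisible(path)
}

#' Load pair potentials saved by \code{\link{savePotentials}}
#'
#' @param path path to a potential table.
#' @return a \code{PairPotentialSet}.
#' @export
loadPotentials <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- which(!startsWith(lines, "#"))
  if (length(body) < 2) stop("malformed potential file: no data rows")
  header <- strsplit(lines[body[1]], "\t", fixed = TRUE)[[1]]
  need <- c("type_a", "type_b", "bin_lo", "bin_hi", "count", "delta_w",
            "repulsion_flag")
  if (!identical(header, need))
    stop("malformed potential file at line ", body[1],
         ": unexpected header")
  fields <- strsplit(lines[body[-1]], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 7)
  if (length(bad))
    stop("malformed potential file at line ", body[1 + bad[1]],
         ": expected 7 fields")
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- need
  for (cc in c("bin_lo", "bin_hi", "count", "delta_w"))
    tab[[cc]] <- as.numeric(tab[[cc]])
  if (anyNA(tab$delta_w) || anyNA(tab$bin_lo))
    stop("malformed potential file: non-numeric values")

  alphabet <- sort(unique(c(tab$type_a, tab$type_b)))
  breaks <- sort(unique(c(tab$bin_lo, tab$bin_hi)))
  nt <- length(alphabet); nb <- length(breaks) - 1
  values <- array(NA_real_, c(nt, nt, nb),
                  dimnames = list(alphabet, alphabet, NULL))
  counts <- matrix(0, nt, nt, dimnames = list(alphabet, alphabet))
  bin <- match(tab$bin_lo, breaks[-(nb + 1)])
  a <- match(tab$type_a, alphabet); b <- match(tab$type_b, alphabet)
  values[cbind(a, b, bin)] <- tab$delta_w
  values[cbind(b, a, bin)] <- tab$delta_w
  counts[cbind(a, b)] <- tab$count
  counts[cbind(b, a)] <- tab$count
  if (anyNA(values)) {
    miss <- which(is.na(values[, , 1]), arr.ind = TRUE)[1, ]
    stop("potential file is missing pair ", alphabet[miss[1]], "-",
         alphabet[miss[2]])
  }
  sig <- 500; rep <- any(tab$repulsion_flag == "1")
  for (m in meta) {
    f <- strsplit(sub("^#\\s*", "", m), "\t")[[1]]
    if (f[1] == "sig_threshold") sig <- as.numeric(f[2])
    if (f[1] == "repulsion_applied") rep <- f[2] == "1"
  }
  new("PairPotentialSet", alphabet = alphabet, breaks = breaks,
      values = values, counts = counts, sigThreshold = sig,
      repulsionApplied = rep)
}
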