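# Greedy leader clustering of docking solutions and decoy ensembles,
# cluster-based ranking, the antibody Tyr-interface re-ranking rule,
# and solution-file round-tripping.

# Greedy leader clustering over flattened coordinate rows (one row per
# member, 3k columns), in input order: each member joins the first
# (earliest-created) leader within the rmsd threshold, else founds a
# new cluster. Returns integer cluster ids in creation order.
greedyLeaderCluster <- function(coordMat, threshold) {
  n <- nrow(coordMat)
  natom <- ncol(coordMat) / 3
  thr2 <- threshold^2 * natom
  ids <- integer(n)
  leaders <- matrix(0, 0, ncol(coordMat))
  lnorm <- numeric(0)
  for (i in seq_len(n)) {
    v <- coordMat[i, ]
    if (nrow(leaders)) {
      d2 <- lnorm - 2 * as.vector(leaders %*% v) + sum(v^2)
      j <- which(d2 <= thr2)
      if (length(j)) { ids[i] <- j[1]; next }
    }
    leaders <- rbind(leaders, v)
    lnorm <- c(lnorm, sum(v^2))
    ids[i] <- nrow(leaders)
  }
  ids
}

# Shared cluster-and-rank core. Members must arrive in score order
# (best first). Returns a data.frame in the final ranked order:
# representatives of all clusters first (cluster order by `orderBy`),
# then remaining members.
clusterRankCore <- function(coordMat, scores, threshold, orderBy) {
  n <- nrow(coordMat)
  if (n == 0)
    return(data.frame(origIndex = integer(0), score = numeric(0),
                      cluster = integer(0), isRep = logical(0),
                      rank = integer(0)))
  ids <- greedyLeaderCluster(coordMat, threshold)
  sizes <- tabulate(ids)
  repOf <- match(seq_along(sizes), ids)       # first member = best score
  clusterOrder <- if (orderBy == "size") {
    order(-sizes, repOf)                      # ties: better representative
  } else {
    order(scores[repOf], repOf)
  }
  newId <- match(ids, clusterOrder)           # renumber clusters
  isRep <- seq_len(n) %in% repOf
  ord <- order(!isRep, newId, seq_len(n))     # reps first, then members
  data.frame(origIndex = ord, score = scores[ord], cluster = newId[ord],
             isRep = isRep[ord], rank = seq_len(n))
}

#' Cluster and re-rank docking solutions
#'
#' Greedy leader clustering of the ranked solutions at an rmsd
#' threshold on the posed ligand coordinates (backbone by default, the
#' docking protocol; 5 Angstrom threshold by default). The
#' representative of each cluster is its best-scored member. Clusters
#' are ordered by representative score (docking protocol) or by size,
#' largest first (decoy protocol); the returned list places all cluster
#' representatives before the remaining members.
#'
#' @param sol a score-ranked \code{SolutionList}.
#' @param ligand the ligand \code{TypedStructure} the solutions pose.
#' @param threshold rmsd threshold in Angstrom (default 5).
#' @param orderBy \code{"score"} (default) or \code{"size"}.
#' @param selection atom selection used for the rmsd
#'   (default \code{"backbone"}).
#' @return a \code{SolutionList} with cluster assignments, reordered so
#'   representatives come first.
#' @export
clusterSolutions <- function(sol, ligand, threshold = 5,
                             orderBy = c("score", "size"),
                             selection = "backbone") {
  orderBy <- match.arg(orderBy)
  s <- sol@solutions
  if (nrow(s) == 0) return(sol)
  mask <- resolveSelection(ligand, selection)
  X <- atomCoords(ligand)[mask, , drop = FALSE]
  coordMat <- matrix(0, nrow(s), 3 * nrow(X))
  for (i in seq_len(nrow(s))) {
    R <- quat2mat(c(s$qw[i], s$qx[i], s$qy[i], s$qz[i]))
    coordMat[i, ] <- as.vector(t(sweep(tcrossprod(X, R), 2,
                                       c(s$tx[i], s$ty[i], s$tz[i]),
                                       "+")))
  }
  res <- clusterRankCore(coordMat, s$score, threshold, orderBy)
  out <- s[res$origIndex, ]
  out$rank <- res$rank
  out$cluster <- res$cluster
  rownames(out) <- NULL
  initialize(sol, solutions = out,
             metadata = c(sol@metadata,
                          list(clusterThreshold = threshold,
                               clusterOrderBy = orderBy)))
}

#' Score, cluster and rank a decoy ensemble
#'
#' The decoy-rescoring protocol: each decoy ligand is scored against
#' the receptor by direct pair summation, decoys are ranked by score,
#' clustered by greedy leader clustering at an all-atom ligand rmsd
#' threshold (2.5 Angstrom by default) and the clusters sorted by size,
#' largest first; the best-scored member represents each cluster.
#'
#' @param receptor typed \code{TypedStructure}.
#' @param decoys list of typed ligand \code{TypedStructure}s sharing
#'   one atom correspondence.
#' @param p a \code{PairPotentialSet}.
#' @param threshold clustering rmsd threshold in Angstrom (default
#'   2.5).
#' @param orderBy \code{"size"} (default, decoy protocol) or
#'   \code{"score"}.
#' @param selection rmsd atom selection (default \code{"all"}).
#' @return data.frame in final ranked order with columns \code{rank},
#'   \code{decoy} (index into \code{decoys}), \code{score},
#'   \code{cluster}, \code{isRep}.
#' @export
rescoreDecoys <- function(receptor, decoys, p, threshold = 2.5,
                          orderBy = c("size", "score"),
                          selection = "all") {
  orderBy <- match.arg(orderBy)
  scores <- vapply(decoys, function(d) scoreDirect(receptor, d, p)$value,
                   numeric(1))
  scoreOrder <- order(scores, seq_along(scores))
  mask <- resolveSelection(decoys[[1]], selection)
  coordMat <- t(vapply(decoys[scoreOrder], function(d)
    as.vector(t(atomCoords(d)[mask, , drop = FALSE])),
    numeric(3 * sum(mask))))
  res <- clusterRankCore(coordMat, scores[scoreOrder], threshold, orderBy)
  data.frame(rank = res$rank, decoy = scoreOrder[res$origIndex],
             score = res$score, cluster = res$cluster, isRep = res$isRep)
}

#' Re-rank top solutions by antibody interface tyrosines
#'
#' Reorders the first \code{topN} solutions by the descending number of
#' tyrosine residues the antibody partner contributes to the 10
#' Angstrom interface of each pose (stable on ties; the remaining
#' solutions are untouched). Tyr is the most abundant residue of
#' antibody paratopes, so this is a cheap post-filter for
#' antigen-antibody targets.
#'
#' @param sol a \code{SolutionList}.
#' @param receptor,ligand the partners the solutions pose.
#' @param antibody which partner is the antibody: \code{"receptor"} or
#'   \code{"ligand"}.
#' @param topN solutions to reorder (default 100).
#' @param cutoff interface cutoff in Angstrom (default 10).
#' @return the re-ranked \code{SolutionList}.
#' @export
rerankByTyr <- function(sol, receptor, ligand,
                        antibody = c("receptor", "ligand"),
                        topN = 100, cutoff = 10) {
  antibody <- match.arg(antibody)
  s <- sol@solutions
  k <- min(topN, nrow(s))
  if (k == 0) return(sol)
  counts <- integer(k)
  for (i in seq_len(k)) {
    posed <- applyPose(ligand, solutionPose(sol, i))
    ir <- interfaceResidues(receptor, posed, cutoff = cutoff)
    side <- if (antibody == "receptor") receptor else posed
    keys <- if (antibody == "receptor") ir$receptor else ir$ligand
    resn <- atomData(side)$resname[match(keys, residueKeys(side))]
    counts[i] <- sum(resn == "TYR")
  }
  ord <- order(-counts, seq_len(k))
  out <- s
  out[seq_len(k), ] <- s[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  initialize(sol, solutions = out,
             metadata = c(sol@metadata, list(tyrReranked = k)))
}

#' Write solutions to a tab-separated file
#'
#' Columns rank, score, quaternion (w x y z), translation (x y z),
#' cluster; full double precision so read/write round-trips exactly.
#'
#' @param sol a \code{SolutionList}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSolutions <- function(sol, path) {
  s <- sol@solutions
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("rank", "score", "qw", "qx", "qy", "qz",
                   "tx", "ty", "tz", "cluster", sep = "\t"), con)
  writeLines(paste(s$rank, sprintf("%.17g", s$score),
                   sprintf("%.17g", s$qw), sprintf("%.17g", s$qx),
                   sprintf("%.17g", s$qy), sprintf("%.17g", s$qz),
                   sprintf("%.17g", s$tx), sprintf("%.17g", s$ty),
                   sprintf("%.17g", s$tz),
                   ifelse(is.na(s$cluster), "NA", s$cluster),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a solutions file written by \code{\link{writeSolutions}}
#'
#' @param path path to a solutions file.
#' @return a \code{SolutionList}.
#' @export
readSolutions <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("rank", "score", "qw", "qx", "qy", "qz", "tx", "ty", "tz",
            "cluster")
  if (!identical(names(tab), need))
    stop("malformed solutions file: unexpected columns")
  tab$rank <- as.integer(tab$rank)
  tab$cluster <- as.integer(tab$cluster)
  new("SolutionList", solutions = tab, metadata = list(source = path))
}
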