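# CAPRI-style quality assessment of predicted complexes against one or
# more reference binding modes, benchmark difficulty classification,
# decoy-set summary statistics with random-selection baselines, and
# funnel (score vs rmsd) analysis.

#' Interface residues of a complex
#'
#' A receptor or ligand residue is in the interface if any of its heavy
#' atoms lies within \code{cutoff} Angstrom of any heavy atom of the
#' other partner (10 Angstrom by default).
#'
#' @param receptor,ligand \code{TypedStructure}s in a shared frame.
#' @param cutoff distance cutoff in Angstrom (default 10).
#' @return list with character vectors \code{receptor} and
#'   \code{ligand} of residue keys (\code{"chain/resno/insert"}).
#' @export
interfaceResidues <- function(receptor, ligand, cutoff = 10) {
  d2 <- crossDist2(atomCoords(receptor), atomCoords(ligand))
  hit <- d2 <= cutoff^2
  rk <- residueKeys(receptor); lk <- residueKeys(ligand)
  list(receptor = unique(rk[rowSums(hit) > 0]),
       ligand = unique(lk[colSums(hit) > 0]))
}

#' Residue-residue contacts of a complex
#'
#' A receptor residue and a ligand residue are in contact if any pair
#' of their heavy atoms lies within \code{cutoff} Angstrom (5 Angstrom
#' by default).
#'
#' @param receptor,ligand \code{TypedStructure}s in a shared frame.
#' @param cutoff distance cutoff in Angstrom (default 5).
#' @return character vector of contact keys
#'   \code{"receptorResidue|ligandResidue"}.
#' @export
contactPairs <- function(receptor, ligand, cutoff = 5) {
  d2 <- crossDist2(atomCoords(receptor), atomCoords(ligand))
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(character(0))
  rk <- residueKeys(receptor); lk <- residueKeys(ligand)
  unique(paste(rk[hit[, 1]], lk[hit[, 2]], sep = "|"))
}

# CAPRI quality class from (fnat, lrmsd, irmsd). The printed criteria
# double-assign the boundaries fnat = 0.3 and 0.5; classes are
# evaluated in precedence order high > medium > acceptable, with
# everything else incorrect, so exactly one class fires per triple.
capriClass <- function(fnat, lrmsd, irmsd) {
  if (fnat >= 0.5 && (lrmsd <= 1.0 || irmsd <= 1.0)) return("high")
  if ((fnat >= 0.3 && fnat <= 0.5 && (lrmsd <= 5.0 || irmsd <= 2.0)) ||
      (fnat > 0.5 && lrmsd > 1.0 && irmsd > 1.0)) return("medium")
  if ((fnat >= 0.1 && fnat <= 0.3 && (lrmsd <= 10.0 || irmsd <= 4.0)) ||
      (fnat > 0.3 && lrmsd > 5.0 && irmsd > 2.0)) return("acceptable")
  "incorrect"
}

# Atom keys "chain/resno/insert/name" for correspondence matching.
atomKeys <- function(x) paste(residueKeys(x), x@atoms$name, sep = "/")

# Indices of corresponding atoms (pred -> ref) restricted to a
# selection mask on the prediction side.
matchAtoms <- function(pred, ref, mask = NULL) {
  kp <- atomKeys(pred); kr <- atomKeys(ref)
  ip <- seq_along(kp)
  if (!is.null(mask)) ip <- ip[mask]
  ir <- match(kp[ip], kr)
  keep <- !is.na(ir)
  if (!any(keep)) stop("no atom correspondence between prediction and reference")
  list(pred = ip[keep], ref = ir[keep])
}

# Quality of one prediction against one reference mode.
assessOneMode <- function(predR, predL, refR, refL, contactCutoff,
                          interfaceCutoff) {
  refContacts <- contactPairs(refR, refL, contactCutoff)
  predContacts <- contactPairs(predR, predL, contactCutoff)
  fnat <- if (length(refContacts) == 0) 0 else
    sum(predContacts %in% refContacts) / length(refContacts)
  fnot <- if (length(predContacts) == 0) 0 else
    sum(!(predContacts %in% refContacts)) / length(predContacts)

  # l_rmsd: superpose receptors on all backbone atoms, measure ligand
  # backbone rmsd without refit (CAPRI convention)
  mR <- matchAtoms(predR, refR, resolveSelection(predR, "backbone"))
  fit <- kabschFit(atomCoords(refR)[mR$ref, , drop = FALSE],
                   atomCoords(predR)[mR$pred, , drop = FALSE])
  mL <- matchAtoms(predL, refL, resolveSelection(predL, "backbone"))
  lpred <- applyFit(fit, atomCoords(predL)[mL$pred, , drop = FALSE])
  lrmsd <- rmsdCoords(atomCoords(refL)[mL$ref, , drop = FALSE], lpred)

  # i_rmsd: backbone of reference-interface residues, least-squares fit
  # on those same atoms; a reference without any interface (degenerate
  # binding mode) has no defined i_rmsd
  iface <- interfaceResidues(refR, refL, interfaceCutoff)
  irmsd <- if (length(iface$receptor) == 0 &&
               length(iface$ligand) == 0) Inf else {
    mRf <- resolveSelection(predR, "backbone") &
      residueKeys(predR) %in% iface$receptor
    mLf <- resolveSelection(predL, "backbone") &
      residueKeys(predL) %in% iface$ligand
    iR <- matchAtoms(predR, refR, mRf)
    iL <- matchAtoms(predL, refL, mLf)
    px <- rbind(atomCoords(predR)[iR$pred, , drop = FALSE],
                atomCoords(predL)[iL$pred, , drop = FALSE])
    rx <- rbind(atomCoords(refR)[iR$ref, , drop = FALSE],
                atomCoords(refL)[iL$ref, , drop = FALSE])
    rmsdCoords(rx, kabschFit(rx, px)$coords)
  }
  list(fnat = fnat, fnot = fnot, irmsd = irmsd, lrmsd = lrmsd,
       class = capriClass(fnat, lrmsd, irmsd))
}

#' CAPRI-style quality assessment of a predicted complex
#'
#' Computes f_nat (fraction of reference residue contacts reproduced),
#' f_not (fraction of the prediction's contacts absent from the
#' reference), the ligand rmsd after receptor superposition (l_rmsd),
#' the interface backbone rmsd (i_rmsd), and the CAPRI quality class.
#' With several reference binding modes the best-scoring class is
#' reported (ties resolved by lowest i_rmsd) together with the matched
#' mode index.
#'
#' @param prediction list with elements \code{receptor} and
#'   \code{ligand}.
#' @param reference a list like \code{prediction}, or a list of such
#'   lists (multiple binding modes).
#' @param contactCutoff contact distance, Angstrom (default 5).
#' @param interfaceCutoff interface distance, Angstrom (default 10).
#' @return a \code{QualityReport}.
#' @export
assessQuality <- function(prediction, reference, contactCutoff = 5,
                          interfaceCutoff = 10) {
  if (!is.null(reference$receptor)) reference <- list(reference)
  reports <- lapply(reference, function(ref)
    assessOneMode(prediction$receptor, prediction$ligand,
                  ref$receptor, ref$ligand, contactCutoff,
                  interfaceCutoff))
  rankOf <- c(high = 1, medium = 2, acceptable = 3, incorrect = 4)
  cls <- vapply(reports, function(r) rankOf[[r$class]], numeric(1))
  irs <- vapply(reports, function(r) r$irmsd, numeric(1))
  best <- order(cls, irs)[1]
  r <- reports[[best]]
  new("QualityReport", fnat = r$fnat, fnot = r$fnot, irmsd = r$irmsd,
      lrmsd = r$lrmsd, qualityClass = r$class, mode = as.integer(best))
}

setMethod("show", "QualityReport", function(object) {
  cat(sprintf(
    "QualityReport: %s (f_nat %.3f, f_not %.3f, i_rmsd %.2f A, l_rmsd %.2f A; mode %d)\n",
    object@qualityClass, object@fnat, object@fnot, object@irmsd,
    object@lrmsd, object@mode))
})

#' Benchmark difficulty class of an unbound/bound complex pair
#'
#' Each unbound partner is superposed onto its bound counterpart
#' (backbone least squares) to assemble an unbound-conformer complex in
#' the bound frame; difficulty follows the conventional thresholds on
#' the interface C-alpha rmsd and the fraction of non-native contacts:
#' easy (i_rmsd < 1.5 A and f_not < 0.4), medium (1.5 < i_rmsd <= 2.2,
#' or i_rmsd < 1.5 and f_not > 0.4), difficult (i_rmsd > 2.2).
#'
#' @param bound list with \code{receptor}, \code{ligand} (bound forms).
#' @param unbound list with \code{receptor}, \code{ligand} (unbound
#'   forms, atom-matchable to the bound forms).
#' @param interfaceCutoff interface cutoff, Angstrom (default 10).
#' @return list with \code{class} (\code{"easy"}, \code{"medium"} or
#'   \code{"difficult"}), \code{caIrmsd} and \code{fnot}.
#' @export
classifyDifficulty <- function(bound, unbound, interfaceCutoff = 10) {
  superposed <- lapply(c("receptor", "ligand"), function(part) {
    m <- matchAtoms(unbound[[part]], bound[[part]],
                    resolveSelection(unbound[[part]], "backbone"))
    fit <- kabschFit(atomCoords(bound[[part]])[m$ref, , drop = FALSE],
                     atomCoords(unbound[[part]])[m$pred, , drop = FALSE])
    setCoords(unbound[[part]], applyFit(fit, atomCoords(unbound[[part]])))
  })
  names(superposed) <- c("receptor", "ligand")

  iface <- interfaceResidues(bound$receptor, bound$ligand,
                             interfaceCutoff)
  caI <- local({
    mR <- matchAtoms(superposed$receptor, bound$receptor,
                     resolveSelection(superposed$receptor, "calpha") &
                       residueKeys(superposed$receptor) %in% iface$receptor)
    mL <- matchAtoms(superposed$ligand, bound$ligand,
                     resolveSelection(superposed$ligand, "calpha") &
                       residueKeys(superposed$ligand) %in% iface$ligand)
    px <- rbind(atomCoords(superposed$receptor)[mR$pred, , drop = FALSE],
                atomCoords(superposed$ligand)[mL$pred, , drop = FALSE])
    bx <- rbind(atomCoords(bound$receptor)[mR$ref, , drop = FALSE],
                atomCoords(bound$ligand)[mL$ref, , drop = FALSE])
    rmsdCoords(bx, kabschFit(bx, px)$coords)
  })
  refContacts <- contactPairs(bound$receptor, bound$ligand)
  ubContacts <- contactPairs(superposed$receptor, superposed$ligand)
  fnot <- if (length(ubContacts) == 0) 0 else
    sum(!(ubContacts %in% refContacts)) / length(ubContacts)
  class <- if (caI < 1.5 && fnot < 0.4) "easy"
    else if (caI > 2.2) "difficult"
    else "medium"
  list(class = class, caIrmsd = caI, fnot = fnot)
}

#' Decoy-set summary statistics
#'
#' Percentages of targets whose top-ranked decoys reach the
#' conventional rmsd thresholds: \code{R5} / \code{R10} — at least one
#' of the top \code{topK} below 5 / 10 Angstrom; \code{N10} — at least
#' three of the top \code{topK} below 10 Angstrom; \code{bestRmsd} —
#' at least one of the top \code{topK} below 10 Angstrom. The
#' perturbation-rescoring protocol uses the top 5 decoys, the
#' docking protocol the top 10 cluster representatives.
#'
#' @param rankedRmsds list with one numeric vector per target: decoy
#'   rmsds in final rank order.
#' @param topK ranks considered per target (default 5).
#' @return list with \code{R5}, \code{R10}, \code{N10},
#'   \code{bestRmsd} (percent over targets) and a per-target
#'   \code{detail} data.frame.
#' @export
decoySetMetrics <- function(rankedRmsds, topK = 5) {
  stopifnot(length(rankedRmsds) > 0)
  detail <- do.call(rbind, lapply(seq_along(rankedRmsds), function(i) {
    top <- utils::head(rankedRmsds[[i]], topK)
    data.frame(target = i,
               r5 = any(top < 5), r10 = any(top < 10),
               n10 = sum(top < 10) >= 3, best = any(top < 10))
  }))
  list(R5 = 100 * mean(detail$r5), R10 = 100 * mean(detail$r10),
       N10 = 100 * mean(detail$n10), bestRmsd = 100 * mean(detail$best),
       detail = detail)
}

#' Random-selection baseline probability
#'
#' Probability that random selection places at least \code{kMin}
#' acceptable solutions in the top \code{nTop}, with acceptable
#' fraction \code{p} in the pool: the binomial tail
#' P(X >= kMin), X ~ Binomial(nTop, p).
#'
#' @param p fraction of acceptable decoys in the pool, in [0, 1].
#' @param nTop size of the top rank window.
#' @param kMin minimum number of acceptable solutions.
#' @return list with \code{probability} and \code{percent} (rounded to
#'   integer percent, as such baselines are conventionally quoted).
#' @export
randomBaseline <- function(p, nTop, kMin = 1) {
  if (!is.finite(p) || p < 0 || p > 1) stop("p must be in [0, 1]")
  stopifnot(kMin >= 1, kMin <= nTop)
  prob <- stats::pbinom(kMin - 1, nTop, p, lower.tail = FALSE)
  list(probability = prob, percent = round(100 * prob))
}

#' Funnel correlation between scores and rmsds
#'
#' Spearman rank correlation (average-rank ties) between docking
#' scores and rmsds to the native structure; +1 when better (lower)
#' scores coincide with lower rmsds, the signature of a funnel-shaped
#' binding energy landscape.
#'
#' @param scores,rmsds paired numeric vectors, length >= 3.
#' @return list with \code{rs} and \code{n}.
#' @export
funnelSpearman <- function(scores, rmsds) {
  stopifnot(length(scores) == length(rmsds))
  if (length(scores) < 3) stop("need at least 3 points")
  if (stats::sd(scores) == 0 || stats::sd(rmsds) == 0)
    stop("correlation undefined for constant input")
  list(rs = stats::cor(scores, rmsds, method = "spearman"),
       n = length(scores))
}

#' Binary classifier metrics
#'
#' Sensitivity, specificity and accuracy of success/failure
#' predictions, with success as the positive class.
#'
#' @param predictions,outcomes logical vectors (TRUE = success).
#' @return list with \code{sensitivity}, \code{specificity},
#'   \code{accuracy}.
#' @export
classifierMetrics <- function(predictions, outcomes) {
  stopifnot(length(predictions) == length(outcomes))
  if (length(predictions) == 0) stop("empty input")
  tp <- sum(predictions & outcomes)
  tn <- sum(!predictions & !outcomes)
  fp <- sum(predictions & !outcomes)
  fn <- sum(!predictions & outcomes)
  list(sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
       accuracy = (tp + tn) / length(predictions))
}
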