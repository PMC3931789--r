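# Deterministic synthetic fixtures: toy complexes with a known native
# pose, rigid decoy ensembles with exact rmsd tags, and mini knowledge
# bases with prescribed inter-partner distance laws. Residues are
# placed from idealised templates (no backbone realism): downstream
# code only consumes typed atoms and distances.
#
# Toy-complex geometry: the receptor is a bowl of alanines (chain A)
# whose inner surface carries a few aspartate "sockets" at irregular,
# asymmetric directions; the ligand (chain B) sits in the bowl and
# carries matching lysine "spokes" whose terminal amines sit
# equidistant (~2.9 Angstrom) from both carboxylate oxygens of their
# socket. One amine cannot reach two sockets (the sockets are ~8
# Angstrom apart), so the per-spoke score is maximal exactly when the
# spoke faces its socket, and the irregular socket pattern makes the
# native orientation the unique pose that maximises all spokes at
# once: potentials with a short-range attractive well for N.3/O.co2
# plus clash repulsion have their global optimum at the native pose.

#' Fixture specification
#'
#' @slot nResReceptor receptor residues (bowl alanines + sockets).
#' @slot nResLigand ligand residues (spoke arginines + core alanines).
#' @slot contactTarget number of salt-bridge socket/spoke pairs, also
#'   the minimum residue-contact count the construction must reach
#'   (default 4, maximum 6).
#' @slot rotScale decoy rotation perturbation scale, degrees.
#' @slot transScale decoy translation perturbation scale, Angstrom.
#' @slot nDecoys decoy ensemble size.
#' @slot jitter coordinate jitter s.d., Angstrom.
#' @slot seed integer seed (mandatory; fixtures are pure functions of
#'   spec + seed).
#' @export
setClass("FixtureSpec",
  representation(nResReceptor = "integer", nResLigand = "integer",
                 contactTarget = "integer", rotScale = "numeric",
                 transScale = "numeric", nDecoys = "integer",
                 jitter = "numeric", seed = "integer"),
  prototype(nResReceptor = 24L, nResLigand = 8L, contactTarget = 4L,
            rotScale = 50, transScale = 15, nDecoys = 200L,
            jitter = 0.06, seed = 1L)
)

setValidity("FixtureSpec", function(object) {
  if (object@nResReceptor < object@contactTarget + 1)
    return("receptor too small for the requested sockets")
  if (object@nResLigand < object@contactTarget)
    return("ligand too small for the requested spokes")
  if (object@contactTarget < 1 || object@contactTarget > 6)
    return("contactTarget must be in 1..6")
  if (object@nDecoys < 2) return("need at least 2 decoys")
  TRUE
})

#' Construct a FixtureSpec
#' @param nResReceptor,nResLigand residues per chain.
#' @param contactTarget salt-bridge pairs (1..6).
#' @param rotScale,transScale decoy perturbation scales (deg, A).
#' @param nDecoys decoys per ensemble.
#' @param jitter coordinate jitter s.d., A.
#' @param seed integer seed.
#' @return a \code{FixtureSpec}.
#' @export
fixtureSpec <- function(nResReceptor = 24, nResLigand = 8,
                        contactTarget = 4, rotScale = 50,
                        transScale = 15, nDecoys = 200, jitter = 0.06,
                        seed = 1) {
  new("FixtureSpec", nResReceptor = as.integer(nResReceptor),
      nResLigand = as.integer(nResLigand),
      contactTarget = as.integer(contactTarget), rotScale = rotScale,
      transScale = transScale, nDecoys = as.integer(nDecoys),
      jitter = jitter, seed = as.integer(seed))
}

# Idealised residue templates: CA at the origin, side chain along +z.
residueTemplate <- function(resname) {
  bb <- rbind(N = c(-1.20, 0.77, -0.30), CA = c(0, 0, 0),
              C = c(1.25, 0.64, -0.30), O = c(1.35, 1.80, -0.55))
  sc <- switch(resname,
    ALA = rbind(CB = c(0, -0.70, 1.25)),
    SER = rbind(CB = c(0, -0.70, 1.25), OG = c(0, -0.20, 2.65)),
    ASP = rbind(CB = c(0, -0.70, 1.25), CG = c(0, -0.20, 2.70),
                OD1 = c(1.05, 0, 3.45), OD2 = c(-1.05, 0, 3.45)),
    ARG = rbind(CB = c(0, -0.70, 1.25), CG = c(0.45, -0.20, 2.60),
                CD = c(0, 0.20, 3.95), NE = c(0.35, -0.10, 5.30),
                CZ = c(0, 0, 6.60), NH1 = c(1.10, 0, 7.30),
                NH2 = c(-1.10, 0, 7.30)),
    LYS = rbind(CB = c(0, -0.70, 1.25), CG = c(0.45, -0.20, 2.60),
                CD = c(0, 0.20, 3.95), CE = c(0.35, -0.10, 5.25),
                NZ = c(0, 0, 6.55)),
    stop("no template for ", resname))
  rbind(bb, sc)
}

ELEMENT_FROM_NAME <- function(name) substr(name, 1, 1)

# Orthonormal frame whose third column is the unit vector zdir.
frameWithZ <- function(zdir) {
  z <- zdir / sqrt(sum(zdir^2))
  ref <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- ref - sum(ref * z) * z
  x <- x / sqrt(sum(x^2))
  cbind(x, pracmaCross(z, x), z)
}

pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Irregular, asymmetric socket directions (unit vectors, lower
# hemisphere-ish): all 15 pairwise angles are distinct (>= 8 degrees
# apart, minimum separation ~43 degrees), so no non-identity rotation
# maps the direction pattern onto itself even approximately — the
# native spoke-to-socket assignment is unique.
socketDirections <- function(n) {
  sph <- function(theta, phi) {
    t <- theta * pi / 180; p <- phi * pi / 180
    c(sin(t) * cos(p), sin(t) * sin(p), -cos(t))
  }
  d <- rbind(sph(0, 0), sph(45, 0), sph(70, 140), sph(55, 250),
             sph(85, 60), sph(62, 310))
  d[seq_len(n), , drop = FALSE]
}

# Place one residue: CA at caPos, side chain (+z of the template)
# along zdir, or in an explicitly given orthonormal frame.
placeResidue <- function(resname, caPos, zdir, chain, resno, serialFrom,
                         frame = NULL) {
  tpl <- residueTemplate(resname)
  Rf <- if (is.null(frame)) frameWithZ(zdir) else frame
  xyz <- sweep(tcrossprod(tpl, Rf), 2, caPos, "+")
  data.frame(serial = serialFrom + seq_len(nrow(tpl)) - 1L,
             name = rownames(tpl), resname = resname, chain = chain,
             resno = resno, insert = "",
             element = ELEMENT_FROM_NAME(rownames(tpl)),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             type = "untyped", stringsAsFactors = FALSE)
}

#' Generate a toy receptor/ligand complex
#'
#' Builds the bowl-and-spokes complex described in the module notes:
#' guaranteed at least \code{contactTarget} inter-chain residue
#' contacts below 5 Angstrom, no inter-chain heavy-atom pair below the
#' 2 Angstrom clash floor, receptor strictly larger than the ligand,
#' and byte-identical output for a fixed spec.
#'
#' @param spec a \code{FixtureSpec}.
#' @return list with typed \code{receptor} and \code{ligand}
#'   \code{TypedStructure}s.
#' @export
makeToyComplex <- function(spec = fixtureSpec()) {
  validObject(spec)
  nS <- spec@contactTarget
  dirs <- socketDirections(nS)
  Rb <- 12                       # bowl CA radius, Angstrom
  # per-socket radii: the spoke-tip constellation is then NOT a scaled
  # copy of the socket constellation, so no permuted spoke-to-socket
  # assignment is rigidly congruent with the native one; all pairwise
  # radius differences are >= 1.8 A (several times the salt-bridge
  # well width), so even a single swapped assignment forfeits bridges
  sockR <- Rb + c(-2.7, -0.9, 0.9, 2.7, -1.8, 1.8)[seq_len(nS)]
  # NZ lands 2.9 A from both OD1 and OD2: OD plane at sockR - 3.45 with
  # +-1.05 tangential spread, so the radial gap is sqrt(2.9^2 - 1.05^2)
  spokeCA <- (sockR - 3.45) - sqrt(2.9^2 - 1.05^2) - 6.55
  withSeed(spec@seed, {
    rows <- list(); serial <- 1L; resno <- 0L
    # receptor sockets
    for (k in seq_len(nS)) {
      resno <- resno + 1L
      r <- placeResidue("ASP", sockR[k] * dirs[k, ], -dirs[k, ], "A",
                        resno, serial)
      rows[[length(rows) + 1]] <- r; serial <- serial + nrow(r)
    }
    # receptor bowl alanines: lower-hemisphere lattice directions kept
    # clear of the sockets
    cand <- fibonacciSphere(6 * spec@nResReceptor)
    cand <- cand[cand[, 3] < -0.05, , drop = FALSE]
    ang <- tcrossprod(cand, dirs)
    ang[ang > 1] <- 1; ang[ang < -1] <- -1
    ang <- acos(ang)
    cand <- cand[apply(ang, 1, min) > 25 * pi / 180, , drop = FALSE]
    nAla <- spec@nResReceptor - nS
    if (nrow(cand) < nAla) stop("unsatisfiable fixture spec: bowl too dense")
    for (k in seq_len(nAla)) {
      resno <- resno + 1L
      r <- placeResidue("ALA", Rb * cand[k, ], -cand[k, ], "A", resno,
                        serial)
      rows[[length(rows) + 1]] <- r; serial <- serial + nrow(r)
    }
    receptor <- do.call(rbind, rows)

    rows <- list(); serial <- 1L; resno <- 0L
    # ligand spokes, in frames complementary to the sockets
    for (k in seq_len(nS)) {
      resno <- resno + 1L
      fr <- frameWithZ(-dirs[k, ])             # the socket's frame
      frL <- cbind(fr[, 1], -fr[, 2], dirs[k, ])
      r <- placeResidue("LYS", spokeCA[k] * dirs[k, ], dirs[k, ], "B",
                        resno, serial, frame = frL)
      rows[[length(rows) + 1]] <- r; serial <- serial + nrow(r)
    }
    # ligand core alanines on the upper side
    nCore <- spec@nResLigand - nS
    if (nCore > 0) {
      up <- fibonacciSphere(4 * max(4, nCore))
      up <- up[up[, 3] > 0.35, , drop = FALSE]
      for (k in seq_len(nCore)) {
        resno <- resno + 1L
        r <- placeResidue("ALA", 3.0 * up[k, ], up[k, ], "B", resno,
                          serial)
        rows[[length(rows) + 1]] <- r; serial <- serial + nrow(r)
      }
    }
    ligand <- do.call(rbind, rows)

    # deterministic jitter
    jit <- function(df) {
      df$x <- df$x + stats::rnorm(nrow(df), 0, spec@jitter)
      df$y <- df$y + stats::rnorm(nrow(df), 0, spec@jitter)
      df$z <- df$z + stats::rnorm(nrow(df), 0, spec@jitter)
      df
    }
    receptor <- jit(receptor); ligand <- jit(ligand)

    r <- assignAtomTypes(newTypedStructure(receptor,
                                           "synthetic toy receptor"))
    l <- assignAtomTypes(newTypedStructure(ligand,
                                           "synthetic toy ligand"))
    d2 <- crossDist2(atomCoords(r), atomCoords(l))
    if (min(d2) < 2^2)
      stop("unsatisfiable fixture spec: inter-chain clash below 2 A")
    if (min(d2) >= 5^2)
      stop("unsatisfiable fixture spec: no inter-chain contact below 5 A")
    if (length(contactPairs(r, l)) < spec@contactTarget)
      stop("unsatisfiable fixture spec: contact target not reached")
    list(receptor = r, ligand = l)
  })
}

#' Generate a rigid decoy ensemble around a native complex
#'
#' Rigid perturbations of the native ligand pose with magnitudes
#' ramping from zero (the first decoy is the native pose) up to the
#' spec's rotation/translation scales, in randomised directions; each
#' decoy is tagged with its exact all-atom ligand rmsd from the
#' native.
#'
#' @param native list with \code{receptor} and \code{ligand}.
#' @param spec a \code{FixtureSpec}.
#' @return list with \code{ligands} (list of posed ligand structures),
#'   \code{rmsd} (numeric vector) and \code{receptor} (unchanged).
#' @export
makeDecoys <- function(native, spec = fixtureSpec()) {
  validObject(spec)
  lig <- native$ligand
  com <- centerOfMass(lig)
  n <- spec@nDecoys
  withSeed(spec@seed + 1L, {
    ligands <- vector("list", n)
    rmsd <- numeric(n)
    for (i in seq_len(n)) {
      frac <- (i - 1) / (n - 1)
      axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
      ang <- spec@rotScale * frac * pi / 180
      K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                    -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
      R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      t <- com - as.vector(R %*% com) + dir * spec@transScale * frac
      ligands[[i]] <- applyPose(lig, pose(R, t))
      rmsd[i] <- rmsdStructures(lig, ligands[[i]], "all")
    }
    list(ligands = ligands, rmsd = rmsd, receptor = native$receptor)
  })
}

#' Distance laws for synthetic knowledge bases
#'
#' @param min,max support bounds within (0, 5) Angstrom.
#' @return a law object (quantile function plus description).
#' @export
uniformLaw <- function(min = 0, max = 5) {
  if (min < 0 || max > 5 || min >= max)
    stop("law support must lie within (0, 5) Angstrom")
  list(kind = "uniform",
       qfun = function(p) min + p * (max - min))
}

#' @rdname uniformLaw
#' @param mean,sd Gaussian location and width, Angstrom (truncated to
#'   [min, max]).
#' @export
gaussianLaw <- function(mean, sd, min = 0, max = 5) {
  if (mean <= min || mean >= max || sd <= 0 || min < 0 || max > 5)
    stop("gaussian law must be centred inside its (min, max) support",
         " within (0, 5) Angstrom")
  p0 <- stats::pnorm(min, mean, sd); p1 <- stats::pnorm(max, mean, sd)
  list(kind = "gaussian", mean = mean, sd = sd,
       qfun = function(p) stats::qnorm(p0 + p * (p1 - p0), mean, sd))
}

#' Potentials matched to the toy complexes
#'
#' Derives a repulsion-augmented potential set from a synthetic
#' knowledge base covering all type pairs that occur in the toy
#' complexes: the salt-bridge pair N.3/O.co2 follows a Gaussian law
#' centred at 3 Angstrom (the planted attractive well), every other
#' pair a uniform contact law on (1.8, 5) Angstrom; the salt-bridge
#' pair mixes the Gaussian with the same uniform floor. The potentials
#' are derived against the uniform reference state (the reference is a
#' pluggable strategy; with a pool this small and deliberately biased,
#' the pooled reference would tilt every generic pair by the planted
#' pair's composition), which leaves generic pairs exactly flat inside
#' their support. Distances below 1.8 Angstrom are never observed, so
#' the derivation makes them repulsive and the Gaussian repulsion term
#' is anchored below the observed range — together this gives the toy
#' system a scoring function whose global optimum is the native
#' bowl-and-spokes pose.
#'
#' @param nPerPair distance samples per type pair (default 4000; large
#'   enough that integerised histogram counts leave generic pairs flat
#'   to a few thousandths).
#' @param seed integer seed.
#' @param sampling passed to \code{\link{makeKnowledgeBase}}.
#' @return a repulsion-augmented \code{PairPotentialSet}.
#' @export
toyPotentials <- function(nPerPair = 4000, seed = 1,
                          sampling = "stratified") {
  types <- c("C.2", "C.3", "N.am", "N.3", "O.2", "O.co2")
  pairs <- list(); laws <- list()
  for (i in seq_along(types)) for (j in i:length(types)) {
    pairs[[length(pairs) + 1]] <- c(types[i], types[j])
    laws[[length(laws) + 1]] <- uniformLaw(1.8, 5)
  }
  pairs[[length(pairs) + 1]] <- c("N.3", "O.co2")
  laws[[length(laws) + 1]] <- gaussianLaw(3.0, 0.35, min = 2.0, max = 4.2)
  n <- c(rep(nPerPair, length(pairs) - 1), 2 * nPerPair)
  kb <- makeKnowledgeBase(pairs, laws, nPerPair = n, seed = seed,
                          sampling = sampling)
  h <- countPairDistances(kb)
  addRepulsion(derivePotentials(h, reference = rep(1, length(h@breaks) - 1)))
}

# type -> representative (resname, atom) whose table type is `type`
REPRESENTATIVE_ATOM <- list(
  C.2 = c("GLY", "C"), C.3 = c("ALA", "CB"), C.ar = c("PHE", "CZ"),
  N.3 = c("LYS", "NZ"), N.am = c("GLY", "N"), N.ar = c("HIS", "ND1"),
  N.pl3 = c("ARG", "NH1"), O.2 = c("GLY", "O"), O.3 = c("SER", "OG"),
  O.co2 = c("ASP", "OD1"), S.3 = c("CYS", "SG"))

#' Generate a mini knowledge base with prescribed distance laws
#'
#' Builds typed complexes whose inter-partner pair distances follow
#' the stated law for each requested type pair: every sampled distance
#' becomes one receptor/ligand atom pair on a well-separated station
#' lattice (20 Angstrom spacing), so no unintended pair falls below
#' the 5 Angstrom counting cutoff. Distances are drawn by inverse-CDF
#' stratified sampling by default so the empirical histograms converge
#' to the laws at desk-scale sample counts; iid sampling is available.
#'
#' @param pairs list of length-2 character vectors of type labels; a
#'   pair may appear several times with different laws (its overall law
#'   is then the sample-weighted mixture).
#' @param laws one law (recycled) or a list of laws parallel to
#'   \code{pairs}; see \code{\link{uniformLaw}},
#'   \code{\link{gaussianLaw}}.
#' @param nPerPair distance samples per entry of \code{pairs}
#'   (recycled).
#' @param seed integer seed.
#' @param sampling \code{"stratified"} (default) or \code{"random"}.
#' @param pairsPerComplex stations bundled into one complex.
#' @return list of complexes (lists with \code{receptor},
#'   \code{ligand}).
#' @export
makeKnowledgeBase <- function(pairs, laws = uniformLaw(),
                              nPerPair = 2000, seed = 1,
                              sampling = c("stratified", "random"),
                              pairsPerComplex = 400) {
  sampling <- match.arg(sampling)
  if (!is.null(laws$qfun)) laws <- rep(list(laws), length(pairs))
  stopifnot(length(laws) == length(pairs))
  nPerPair <- rep_len(nPerPair, length(pairs))
  # sample all distances
  samples <- withSeed(seed, {
    do.call(rbind, lapply(seq_along(pairs), function(k) {
      q <- laws[[k]]$qfun
      n <- nPerPair[k]
      d <- if (sampling == "stratified")
        q((seq_len(n) - 0.5) / n)
      else q(stats::runif(n))
      if (any(!is.finite(d)) || any(d < 0) || any(d > 5))
        stop("invalid law: support must lie within (0, 5) Angstrom")
      data.frame(a = pairs[[k]][1], b = pairs[[k]][2], d = d,
                 stringsAsFactors = FALSE)
    }))
  })
  nTot <- nrow(samples)
  bad <- setdiff(unique(c(samples$a, samples$b)),
                 names(REPRESENTATIVE_ATOM))
  if (length(bad))
    stop("no representative atom for type(s): ",
         paste(bad, collapse = ", "))
  repinfo <- function(types) {
    ra <- do.call(rbind, REPRESENTATIVE_ATOM[types])
    list(resname = ra[, 1], name = ra[, 2],
         element = ELEMENT_FROM_NAME(ra[, 2]))
  }
  # station lattice, 20 A spacing
  side <- ceiling(pairsPerComplex^(1 / 3))
  starts <- seq(1, nTot, by = pairsPerComplex)
  lapply(starts, function(s0) {
    idx <- s0:min(nTot, s0 + pairsPerComplex - 1)
    m <- seq_along(idx) - 1L
    st <- cbind(m %% side, (m %/% side) %% side,
                m %/% (side * side)) * 20
    one <- function(types, xyz) {
      info <- repinfo(types)
      newTypedStructure(data.frame(
        serial = seq_along(types), name = info$name,
        resname = info$resname, chain = NA_character_,
        resno = seq_along(types), insert = "",
        element = info$element, x = xyz[, 1], y = xyz[, 2],
        z = xyz[, 3], type = types, stringsAsFactors = FALSE),
        "synthetic KB partner")
    }
    r <- one(samples$a[idx], st); r@atoms$chain <- "A"
    l <- one(samples$b[idx], st + cbind(samples$d[idx], 0, 0))
    l@atoms$chain <- "B"
    list(receptor = r, ligand = l)
  })
}
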