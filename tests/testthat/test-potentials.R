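# Pair-distance counting, potential derivation, repulsion
# augmentation and persistence.

test_that("pair-distance counting is exact, symmetric, cutoff-bounded", {
  mk <- function(type, x) {
    ra <- ppdock:::REPRESENTATIVE_ATOM[[type]]
    s <- miniStructure(matrix(c(x, 0, 0), 1), name = ra[2],
                       resname = ra[1])
    s@atoms$type <- type
    s
  }
  cx <- list(receptor = mk("N.pl3", 0), ligand = mk("O.co2", 3.05))
  h <- countPairDistances(list(cx))
  expect_equal(h@counts["N.pl3", "O.co2", 31], 1)   # bin [3.0, 3.1)
  expect_equal(h@counts["O.co2", "N.pl3", 31], 1)   # symmetric storage
  expect_equal(sum(h@counts), 2)

  far <- list(receptor = mk("N.pl3", 0), ligand = mk("O.co2", 6))
  expect_equal(sum(countPairDistances(list(far))@counts), 0)

  expect_error(countPairDistances(list(list(
    receptor = miniStructure(matrix(0, 1, 3)),
    ligand = mk("O.co2", 3)))), "untyped")
  expect_error(countPairDistances(list(cx), binWidth = 0.3), "evenly")

  # synthetic mini knowledge base vs brute-force double loop
  kb <- makeKnowledgeBase(list(c("C.3", "O.3"), c("N.am", "N.am")),
                          uniformLaw(1, 5), nPerPair = 150, seed = 4)
  h2 <- countPairDistances(kb)
  brute <- array(0, dim(h2@counts), dimnames = dimnames(h2@counts))
  for (cx in kb) {
    xr <- atomCoords(cx$receptor); xl <- atomCoords(cx$ligand)
    tr <- atomTypes(cx$receptor); tl <- atomTypes(cx$ligand)
    for (i in seq_len(nrow(xr))) for (j in seq_len(nrow(xl))) {
      d <- sqrt(sum((xr[i, ] - xl[j, ])^2))
      if (d < 5) {
        b <- min(50, floor(d / 0.1) + 1)
        brute[tr[i], tl[j], b] <- brute[tr[i], tl[j], b] + 1
        if (tr[i] != tl[j])
          brute[tl[j], tr[i], b] <- brute[tl[j], tr[i], b] + 1
      }
    }
  }
  expect_identical(unname(h2@counts), unname(brute))
})

test_that("derivation reproduces analytic log ratios and the zero anchor", {
  ab <- c("N.3", "O.co2")
  counts <- array(0, c(2, 2, 50), dimnames = list(ab, ab, NULL))
  # pair 1-2: 48 counts per bin except bin 15 with 98, total 2450, so
  # the bin-15 density is exactly twice the uniform reference (0.04)
  c12 <- rep(48, 50); c12[15] <- 98
  counts[1, 2, ] <- c12; counts[2, 1, ] <- c12
  counts[1, 1, ] <- rep(10, 50)
  counts[2, 2, ] <- rep(10, 50)
  h <- new("PairHistogramSet", alphabet = ab,
           breaks = seq(0, 5, by = 0.1), counts = counts)

  p <- derivePotentials(h, pseudoCount = 0, reference = rep(1, 50))
  # pre-shift value at the doubled bin is exactly -ln 2; the stored
  # value carries the zero anchor on top
  w <- -log((c12 / sum(c12)) / 0.02)
  expect_equal(w[15], -log(2))
  expect_equal(p@values["N.3", "O.co2", ], w - w[50])
  expect_equal(p@values["N.3", "O.co2", 50], 0)        # anchored
  expect_equal(p@values["N.3", "N.3", ], rep(0, 50))   # flat = reference
  expect_identical(p@values, aperm(p@values, c(2, 1, 3)))  # symmetry

  # pooled reference: every distribution identical -> all zero
  counts2 <- counts
  counts2[1, 2, ] <- rep(10, 50); counts2[2, 1, ] <- rep(10, 50)
  h2 <- new("PairHistogramSet", alphabet = ab,
            breaks = seq(0, 5, by = 0.1), counts = counts2)
  p2 <- derivePotentials(h2, pseudoCount = 0)
  expect_equal(max(abs(p2@values)), 0)

  # Dirichlet smoothing keeps values finite with empty bins and makes
  # unobserved bins repulsive relative to the anchor
  counts3 <- counts
  c3 <- c(rep(0, 19), rep(60, 31))          # nothing observed below 1.9 A
  counts3[1, 2, ] <- c3; counts3[2, 1, ] <- c3
  h3 <- new("PairHistogramSet", alphabet = ab,
            breaks = seq(0, 5, by = 0.1), counts = counts3)
  p3 <- derivePotentials(h3, pseudoCount = 1)
  expect_true(all(is.finite(p3@values)))
  expect_gt(p3@values["N.3", "O.co2", 10], 0)

  expect_error(derivePotentials(new("PairHistogramSet", alphabet = ab,
                                    breaks = seq(0, 5, by = 0.1),
                                    counts = array(0, c(2, 2, 50)))),
               "empty")
})

test_that("planted over-represented distance yields the potential minimum there", {
  kb <- makeKnowledgeBase(
    list(c("N.pl3", "O.co2"), c("C.3", "C.3"), c("C.3", "N.pl3"),
         c("C.3", "O.co2")),
    list(gaussianLaw(2.8, 0.3), uniformLaw(), uniformLaw(),
         uniformLaw()),
    nPerPair = 3000, seed = 5)
  h <- countPairDistances(kb)
  p <- derivePotentials(h)
  v <- p@values["N.pl3", "O.co2", ]
  centers <- ppdock:::binCenters(p)
  expect_lte(abs(centers[which.min(v)] - 2.8), 0.1)

  # values match an independently coded density-ratio oracle
  pooled <- rep(0, 50)
  ab <- h@alphabet; nt <- length(ab)
  for (a in seq_len(nt)) for (b in a:nt) pooled <- pooled + h@counts[a, b, ]
  gref <- (pooled + 1) / sum(pooled + 1)
  n <- h@counts["N.pl3", "O.co2", ]
  g <- (n + gref) / (sum(n) + 1)
  w <- -log(g / gref); w <- w - w[50]
  expect_equal(v, w, tolerance = 1e-12)
})

test_that("Gaussian repulsion: exact height at d=0, onset rule, monotone decay", {
  ab <- c("N.3", "O.co2")
  counts <- array(10, c(2, 2, 50), dimnames = list(ab, ab, NULL))
  h <- new("PairHistogramSet", alphabet = ab,
           breaks = seq(0, 5, by = 0.1), counts = counts)
  p <- derivePotentials(h, pseudoCount = 0)
  # hand-shape one pair: barrier at bin 8, well at bin 28
  v <- rep(0, 50); v[1:7] <- 2; v[8] <- 3; v[9:27] <- -seq(0.1, 1.9, 0.1)
  v[28] <- -2; v[29:49] <- seq(-1.9, 0.1, 0.1)[1:21]; v[50] <- 0
  vals <- p@values; vals[1, 2, ] <- v; vals[2, 1, ] <- v
  vals[1, 1, ] <- rev(seq_len(50)) / 10       # strictly decreasing
  vals[1, 1, 50] <- 0; vals[2, 2, 50] <- 0
  p <- initialize(p, values = vals)

  aug <- addRepulsion(p)
  params <- new("RepulsionParams")
  centers <- ppdock:::binCenters(p)
  edges <- p@breaks[-51]

  # pair (1,2): first maximum at bin 8 (centre 0.75), onset 0.85
  v12 <- aug@values["N.3", "O.co2", ]
  expect_equal(v12[1], v[1] + 280000)          # Gaussian at edge 0 = height
  sel <- centers < centers[8] + 0.1
  expect_equal(v12[!sel], v[!sel])             # beyond onset unchanged
  added <- v12[sel] - v[sel]
  expect_equal(added, 280000 * exp(-edges[sel]^2 / (2 * 0.8^2)))
  expect_true(all(diff(added) < 0))            # strictly decreasing

  # strictly decreasing potential: fallback onset at global min - width
  v11 <- aug@values["N.3", "N.3", ]
  onset <- (centers[50] - 0.1) + 0.1
  sel11 <- centers < onset
  expect_equal(v11[!sel11], vals[1, 1, ][!sel11])
  expect_equal(v11[sel11] - vals[1, 1, ][sel11],
               280000 * exp(-edges[sel11]^2 / (2 * 0.8^2)))

  expect_error(addRepulsion(aug), "already")
  expect_true(aug@repulsionApplied)
})

test_that("significance report flags the 500-interaction rule over 66 pairs", {
  pot <- sharedPotentials()
  rep <- significanceReport(pot)
  expect_equal(nrow(rep), 11 * 12 / 2)         # 66 unordered pairs
  expect_equal(length(pot@alphabet)^2, 121)    # 121 ordered pairs

  pot2 <- pot
  pot2@counts["C.3", "C.3"] <- 499
  pot2@counts["C.3", "C.ar"] <- 500
  r2 <- significanceReport(pot2)
  expect_false(r2$significant[r2$typeA == "C.3" & r2$typeB == "C.3"])
  expect_true(r2$significant[r2$typeA == "C.3" & r2$typeB == "C.ar"])
})

test_that("potential tables round-trip losslessly and reject damage", {
  pot <- sharedPotentials()
  f <- withr::local_tempfile(fileext = ".tsv")
  savePotentials(pot, f)
  back <- loadPotentials(f)
  expect_equal(back@values, pot@values)
  expect_equal(back@counts, pot@counts)
  expect_equal(back@breaks, pot@breaks)
  expect_equal(back@sigThreshold, pot@sigThreshold)
  expect_equal(back@repulsionApplied, pot@repulsionApplied)

  # hand-written 2-type table loads verbatim
  f2 <- withr::local_tempfile(fileext = ".tsv")
  lines <- c("type_a\ttype_b\tbin_lo\tbin_hi\tcount\tdelta_w\trepulsion_flag")
  bw <- 2.5
  for (pair in list(c("A", "A"), c("A", "B"), c("B", "B")))
    for (k in 0:1)
      lines <- c(lines, paste(pair[1], pair[2], k * bw, (k + 1) * bw,
                              7, -0.25 * k, 0, sep = "\t"))
  writeLines(lines, f2)
  tiny <- loadPotentials(f2)
  expect_equal(tiny@values["A", "B", ], c(0, -0.25))
  expect_equal(tiny@counts["B", "B"], 7)

  # missing pair -> error naming it
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines[1:5], f3)
  expect_error(loadPotentials(f3), "missing pair")

  # truncated row -> error with line number
  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(lines[1:3], "A\tB\t0"), f4)
  expect_error(loadPotentials(f4), "line")
})

test_that("leave-out consistency: zero-contribution complexes change nothing", {
  kb <- makeKnowledgeBase(list(c("C.3", "O.3")), uniformLaw(1, 4.5),
                          nPerPair = 400, seed = 8)
  # a complex whose partners are > 5 A apart contributes no counts
  silent <- list(
    receptor = {
      s <- miniStructure(matrix(c(0, 0, 0), 1), name = "CB")
      s@atoms$type <- "C.3"; s
    },
    ligand = {
      s <- miniStructure(matrix(c(30, 0, 0), 1), name = "OG",
                         resname = "SER")
      s@atoms$type <- "O.3"; s
    })
  pA <- derivePotentials(countPairDistances(kb))
  pB <- derivePotentials(countPairDistances(c(kb, list(silent))))
  expect_equal(pA@values, pB@values)
  expect_equal(pA@counts, pB@counts)
})
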