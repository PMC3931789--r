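# Interfaces, contacts, CAPRI quality, difficulty classes, decoy-set
# statistics, baselines, funnel correlation, classifier metrics.

test_that("interface residues and contacts follow the 10/5 A cutoffs", {
  rec <- miniStructure(matrix(c(0, 0, 0), 1))
  ligNear <- miniStructure(matrix(c(9.5, 0, 0), 1), chain = "B")
  ligFar <- miniStructure(matrix(c(50, 0, 0), 1), chain = "B")

  far <- interfaceResidues(rec, ligFar)
  expect_length(far$receptor, 0)
  expect_length(far$ligand, 0)

  near <- interfaceResidues(rec, ligNear)
  expect_length(near$receptor, 1)
  expect_length(near$ligand, 1)

  lig49 <- miniStructure(matrix(c(4.9, 0, 0), 1), chain = "B")
  lig51 <- miniStructure(matrix(c(5.1, 0, 0), 1), chain = "B")
  expect_length(contactPairs(rec, lig49), 1)
  expect_length(contactPairs(rec, lig51), 0)

  # toy complex vs brute-force residue-pair minimum-distance scan
  cx <- sharedToy()
  got <- contactPairs(cx$receptor, cx$ligand)
  rk <- ppdock:::residueKeys(cx$receptor)
  lk <- ppdock:::residueKeys(cx$ligand)
  want <- character(0)
  for (r in unique(rk)) for (l in unique(lk)) {
    dr <- atomCoords(cx$receptor)[rk == r, , drop = FALSE]
    dl <- atomCoords(cx$ligand)[lk == l, , drop = FALSE]
    if (sqrt(min(ppdock:::crossDist2(dr, dl))) <= 5)
      want <- c(want, paste(r, l, sep = "|"))
  }
  expect_setequal(got, want)
  gotI <- interfaceResidues(cx$receptor, cx$ligand)
  wantR <- character(0); wantL <- character(0)
  for (r in unique(rk)) {
    dr <- atomCoords(cx$receptor)[rk == r, , drop = FALSE]
    if (sqrt(min(ppdock:::crossDist2(dr, atomCoords(cx$ligand)))) <= 10)
      wantR <- c(wantR, r)
  }
  for (l in unique(lk)) {
    dl <- atomCoords(cx$ligand)[lk == l, , drop = FALSE]
    if (sqrt(min(ppdock:::crossDist2(dl, atomCoords(cx$receptor)))) <= 10)
      wantL <- c(wantL, l)
  }
  expect_setequal(gotI$receptor, wantR)
  expect_setequal(gotI$ligand, wantL)
})

test_that("CAPRI classes fire exactly once per triple and match worked cases", {
  cls <- ppdock:::capriClass
  expect_equal(cls(0.05, 0.5, 0.5), "incorrect")
  expect_equal(cls(0.2, 12, 3.0), "acceptable")
  expect_equal(cls(1.0, 0.0, 0.0), "high")
  expect_equal(cls(0.4, 4.0, 1.5), "medium")
  expect_equal(cls(0.6, 2.0, 3.0), "medium")   # high-fnat, off-geometry
  expect_equal(cls(0.35, 6.0, 3.0), "acceptable")
  expect_equal(cls(0.15, 20, 20), "incorrect")

  # dense sweep: the classifier always returns exactly one valid label
  fn <- c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.8, 1)
  lr <- c(0, 0.5, 1, 2, 5, 7.5, 10, 15, 30)
  ir <- c(0, 0.5, 1, 1.5, 2, 3, 4, 6, 12)
  for (f in fn) for (l in lr) for (i in ir) {
    got <- cls(f, l, i)
    expect_true(got %in% c("high", "medium", "acceptable", "incorrect"))
  }
  # boundary precedence: fnat = 0.5 prefers high when geometry allows
  expect_equal(cls(0.5, 0.8, 5), "high")
  expect_equal(cls(0.3, 4, 5), "medium")
})

test_that("assessQuality: identity is high accuracy; displaced ligand incorrect", {
  cx <- sharedToy()
  q <- assessQuality(cx, cx)
  expect_equal(q@fnat, 1)
  expect_equal(q@fnot, 0)
  expect_equal(q@irmsd, 0, tolerance = 1e-9)
  expect_equal(q@lrmsd, 0, tolerance = 1e-9)
  expect_equal(qualityClass(q), "high")

  pred <- list(receptor = cx$receptor,
               ligand = applyPose(cx$ligand, pose(translation = c(40, 0, 0))))
  q2 <- assessQuality(pred, cx)
  expect_equal(q2@fnat, 0)
  expect_equal(qualityClass(q2), "incorrect")

  # a mild rigid shift keeps most contacts: fnat high, small rmsds
  pred3 <- list(receptor = cx$receptor,
                ligand = applyPose(cx$ligand, pose(translation = c(0.4, 0, 0))))
  q3 <- assessQuality(pred3, cx)
  expect_gt(q3@fnat, 0.5)
  expect_equal(q3@lrmsd, 0.4, tolerance = 1e-6)
})

test_that("multiple binding modes report the best class with its mode index", {
  cx <- sharedToy()
  shifted <- list(receptor = cx$receptor,
                  ligand = applyPose(cx$ligand, pose(translation = c(35, 0, 0))))
  q <- assessQuality(cx, list(shifted, cx))
  expect_equal(qualityClass(q), "high")
  expect_equal(q@mode, 2L)
})

test_that("difficulty classes follow the interface-rmsd / fnot thresholds", {
  cx <- sharedToy()
  # unbound = bound rigidly moved: superposition recovers it -> easy
  rigid <- list(receptor = applyPose(cx$receptor,
                                     pose(quat2mat(c(1, 1, 0, 0)), c(20, 0, 0))),
                ligand = applyPose(cx$ligand,
                                   pose(quat2mat(c(1, 0, 1, 0)), c(-15, 5, 0))))
  d0 <- classifyDifficulty(cx, rigid)
  expect_equal(d0$class, "easy")
  expect_lt(d0$caIrmsd, 1e-6)

  # alternating +-v displacement of ligand interface CA atoms survives
  # superposition; magnitude controls the class
  deform <- function(v) {
    iface <- interfaceResidues(cx$receptor, cx$ligand)$ligand
    lig <- cx$ligand
    sel <- which(ppdock:::residueKeys(lig) %in% iface &
                   atomData(lig)$name == "CA")
    co <- atomCoords(lig)
    co[sel, 1] <- co[sel, 1] + v * (-1)^seq_along(sel)
    list(receptor = cx$receptor, ligand = ppdock:::setCoords(lig, co))
  }
  d1 <- classifyDifficulty(cx, deform(6))
  expect_equal(d1$class, "difficult")
  expect_gt(d1$caIrmsd, 2.2)
  d2 <- classifyDifficulty(cx, deform(4))
  expect_equal(d2$class, "medium")
  expect_true(d2$caIrmsd > 1.5 && d2$caIrmsd <= 2.2)
  # class is always consistent with the returned numbers
  for (d in list(d0, d1, d2)) {
    want <- if (d$caIrmsd < 1.5 && d$fnot < 0.4) "easy"
      else if (d$caIrmsd > 2.2) "difficult" else "medium"
    expect_equal(d$class, want)
  }
})

test_that("decoy-set statistics reproduce hand-counted percentages", {
  # every target's rank-1 decoy under 10 A
  all10 <- replicate(6, c(runif(1, 0, 9), runif(9, 12, 40)),
                     simplify = FALSE)
  m <- decoySetMetrics(all10, topK = 5)
  expect_equal(m$bestRmsd, 100)
  expect_equal(m$N10, 0)

  none <- replicate(4, runif(8, 12, 50), simplify = FALSE)
  m0 <- decoySetMetrics(none, topK = 5)
  expect_equal(m0$R5, 0); expect_equal(m0$R10, 0)
  expect_equal(m0$N10, 0); expect_equal(m0$bestRmsd, 0)

  # 10 synthetic targets, hand-counted
  rl <- list(c(3, 20, 20, 20, 20),  # r5, r10, best
             c(8, 9, 9.5, 20, 20),  # r10, n10, best
             c(12, 12, 12, 12, 4),  # r5 (rank 5), r10, best
             c(11, 11, 11, 11, 11), # nothing
             c(4, 4, 4, 30, 30),    # r5, r10, n10, best
             c(20, 6, 20, 20, 20),  # r10, best
             c(9, 9, 11, 11, 9),    # r10, n10, best
             c(30, 30, 30, 2, 30),  # r5, r10, best
             c(15, 15, 9, 9, 15),   # r10, best
             c(5.5, 20, 20, 20, 20))# r10, best
  m10 <- decoySetMetrics(rl, topK = 5)
  expect_equal(m10$R5, 40)
  expect_equal(m10$R10, 90)
  expect_equal(m10$N10, 30)
  expect_equal(m10$bestRmsd, 90)
})

test_that("random baselines: binomial tails, printed percentages, MC agreement", {
  expect_equal(randomBaseline(0.28, 5, 1)$percent, 81)
  expect_equal(randomBaseline(0.28, 5, 3)$percent, 14)
  expect_equal(randomBaseline(0.19, 10, 1)$percent, 88)
  expect_equal(randomBaseline(1, 7, 3)$percent, 100)
  expect_error(randomBaseline(1.2, 5, 1), "p must")

  # Monte-Carlo agreement within 3 standard errors on a (p, n, k) grid
  set.seed(99)
  nmc <- 1e5
  for (p in c(0.1, 0.28, 0.6)) for (nk in list(c(5, 1), c(5, 3), c(10, 2))) {
    draws <- rbinom(nmc, nk[1], p)
    mc <- mean(draws >= nk[2])
    exact <- randomBaseline(p, nk[1], nk[2])$probability
    se <- sqrt(exact * (1 - exact) / nmc)
    expect_lte(abs(mc - exact), 3 * se + 1e-12)
  }
})

test_that("funnel correlation: signs, oracle, monotone-transform invariance", {
  expect_equal(funnelSpearman(1:10, (1:10)^2)$rs, 1)
  expect_equal(funnelSpearman(1:10, -(1:10))$rs, -1)

  set.seed(7)
  sc <- rnorm(40); rm <- 0.5 * sc + rnorm(40)
  got <- funnelSpearman(sc, rm)$rs
  oracle <- {
    rs <- rank(sc); rr <- rank(rm)
    sum((rs - mean(rs)) * (rr - mean(rr))) /
      sqrt(sum((rs - mean(rs))^2) * sum((rr - mean(rr))^2))
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(funnelSpearman(exp(sc), rm^3 + rm)$rs,
               funnelSpearman(sc, rm)$rs)

  expect_error(funnelSpearman(rep(1, 5), 1:5), "constant")
  expect_error(funnelSpearman(1:2, 1:2), "3 points")
})

test_that("classifier metrics reproduce confusion-matrix ratios", {
  allRight <- classifierMetrics(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(allRight$sensitivity, 1)
  expect_equal(allRight$specificity, 1)
  expect_equal(allRight$accuracy, 1)

  m <- classifierMetrics(predictions = c(FALSE, FALSE, FALSE, FALSE),
                         outcomes = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 1)

  set.seed(12)
  pred <- sample(c(TRUE, FALSE), 20, replace = TRUE)
  out <- sample(c(TRUE, FALSE), 20, replace = TRUE)
  m20 <- classifierMetrics(pred, out)
  tp <- sum(pred & out); fn <- sum(!pred & out)
  tn <- sum(!pred & !out); fp <- sum(pred & !out)
  expect_equal(m20$sensitivity, tp / (tp + fn))
  expect_equal(m20$specificity, tn / (tn + fp))
  expect_equal(m20$accuracy, (tp + tn) / 20)
  expect_error(classifierMetrics(logical(0), logical(0)), "empty")
})
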