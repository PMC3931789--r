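# Structure reading, typing and geometric primitives.

test_that("readPDB parses coordinates, drops hydrogens/HETATM, resolves altlocs", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), f)
  s <- readPDB(f)
  expect_equal(nAtoms(s), 1)
  expect_equal(as.vector(atomCoords(s)), c(1, 2, 3))

  # altloc A (occupancy 0.6) vs B (0.4): conformer A kept
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  N   ALA A   1       0.000   1.000   0.000  1.00  0.00           N",
    "ATOM      4  H   ALA A   1       0.000   2.000   0.000  1.00  0.00           H",
    "HETATM    5  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "END"), f2)
  s2 <- readPDB(f2)
  expect_equal(nAtoms(s2), 2)            # CA (altloc A) + N
  expect_equal(unname(atomCoords(s2)[1, 1]), 1.0)

  # equal occupancy: first altloc label alphabetically wins
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA BALA A   1       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "END"), f3)
  expect_equal(unname(atomCoords(readPDB(f3))[1, 1]), 1.0)

  expect_error(readPDB(withr::local_tempfile()), "not found")
  f4 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f4)
  expect_error(readPDB(f4), "parse|ATOM")
})

test_that("fixture round trip: written PDB re-reads to identical atoms", {
  cx <- sharedToy()
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(cx$receptor, f)
  back <- readPDB(f)
  expect_equal(nAtoms(back), nAtoms(cx$receptor))
  expect_equal(atomData(back)$name, atomData(cx$receptor)$name)
  # PDB fixed columns carry 3 decimals
  expect_equal(atomCoords(back), atomCoords(cx$receptor),
               tolerance = 1e-3)
})

test_that("atom typing follows the Sybyl-style table and is idempotent", {
  tab <- defaultAtomTypeTable()
  expect_length(typeAlphabet(tab), 11)
  lookup <- function(res, atom) {
    t <- tab@table
    t$type[t$resname == res & t$atom == atom]
  }
  expect_equal(lookup("ARG", "NH1"), "N.pl3")
  expect_equal(lookup("ASP", "OD1"), "O.co2")
  expect_equal(lookup("SER", "OG"), "O.3")
  expect_equal(lookup("PHE", "CZ"), "C.ar")

  cx <- sharedToy()
  again <- assignAtomTypes(cx$receptor)
  expect_identical(atomTypes(again), atomTypes(cx$receptor))
  # every heavy atom of every canonical residue is covered
  expect_false(any(atomTypes(cx$receptor) == "untyped"))

  # non-canonical residues are dropped with a warning
  s <- miniStructure(matrix(c(0, 0, 0), 1), name = "X1",
                     resname = "LIG")
  both <- rbind(atomData(s),
                atomData(miniStructure(matrix(c(3, 0, 0), 1))))
  both$serial <- seq_len(nrow(both))
  s2 <- ppdock:::newTypedStructure(both)
  expect_warning(typed <- assignAtomTypes(s2), "dropped")
  expect_equal(nAtoms(typed), 1)
})

test_that("rmsd matches direct formula, superposition never increases it", {
  co <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3,
               byrow = TRUE)
  a <- miniStructure(co)
  expect_equal(rmsdStructures(a, a), 0)

  co2 <- co; co2[1, ] <- co2[1, ] + c(2, 0, 0)
  b <- miniStructure(co2)
  expect_equal(rmsdStructures(a, b), 1)   # sqrt(4/4)

  # random 20-atom pair vs brute-force sum of squares
  set.seed(11)
  xa <- matrix(rnorm(60), 20, 3); xb <- matrix(rnorm(60), 20, 3)
  sa <- miniStructure(xa); sb <- miniStructure(xb)
  brute <- sqrt(sum((xa - xb)^2) / 20)
  expect_equal(rmsdStructures(sa, sb), brute, tolerance = 1e-12)

  # superposed rmsd <= raw rmsd, and matches the bio3d fit
  for (seed in 1:5) {
    set.seed(seed)
    xa <- matrix(rnorm(45), 15, 3)
    xb <- xa %*% ppdock:::axisRotation("z", 0.4) +
      matrix(rnorm(45, sd = 0.3), 15, 3)
    sa <- miniStructure(xa); sb <- miniStructure(xb)
    rFit <- rmsdStructures(sa, sb, superpose = TRUE)
    expect_lte(rFit, rmsdStructures(sa, sb) + 1e-12)
    oracle <- bio3d::rmsd(as.vector(t(xa)), as.vector(t(xb)),
                          fit = TRUE)          # bio3d prints 3 decimals
    expect_lt(abs(rFit - oracle), 6e-4)
  }

  expect_error(rmsdStructures(a, miniStructure(co[1:2, ])),
               "correspond")
})

test_that("center of mass and molecular weight use element masses", {
  s1 <- miniStructure(matrix(c(1, 2, 3), 1))
  expect_equal(centerOfMass(s1), c(1, 2, 3))

  s2 <- miniStructure(matrix(c(0, 0, 0, 2, 0, 0), 2, byrow = TRUE))
  expect_equal(centerOfMass(s2), c(1, 0, 0))

  # mixed elements: mass-weighted mean, hand-computed
  co <- matrix(c(0, 0, 0, 1, 0, 0), 2, byrow = TRUE)
  s3 <- miniStructure(co, element = c("C", "O"))
  mC <- 12.0107; mO <- 15.9994
  expect_equal(centerOfMass(s3),
               c(mO / (mC + mO), 0, 0), tolerance = 1e-6)
  expect_equal(molecularWeight(s3), mC + mO, tolerance = 1e-6)

  expect_equal(molecularWeight(s1), 12.0107, tolerance = 1e-3)
  empty <- ppdock:::newTypedStructure(atomData(s1)[0, ])
  expect_equal(molecularWeight(empty), 0)
  expect_error(centerOfMass(empty), "empty")
  bad <- miniStructure(matrix(0, 1, 3), element = "Qq")
  expect_error(molecularWeight(bad), "unknown element")
})

test_that("poses are rigid: distances preserved, inverse recovers input", {
  s <- miniStructure(matrix(c(1, 0, 0), 1))
  expect_equal(atomCoords(applyPose(s, pose())), atomCoords(s))

  flip <- pose(ppdock:::axisRotation("z", pi))
  expect_equal(as.vector(atomCoords(applyPose(s, flip))),
               c(-1, 0, 0), tolerance = 1e-12)

  set.seed(3)
  cloud <- miniStructure(matrix(rnorm(30), 10, 3))
  p <- pose(quat2mat(c(0.3, 0.5, -0.2, 0.4)), c(3, -1, 2))
  moved <- applyPose(cloud, p)
  d0 <- dist(atomCoords(cloud)); d1 <- dist(atomCoords(moved))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
  back <- applyPose(moved, invertPose(p))
  expect_equal(atomCoords(back), atomCoords(cloud), tolerance = 1e-9)

  expect_error(pose(diag(c(1, 1, -1))), "determinant")
  expect_error(pose(matrix(1:9, 3)), "orthonormal")
})
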