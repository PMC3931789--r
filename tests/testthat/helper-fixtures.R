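# Shared test fixtures, built once per test run.

# A bare structure from explicit atom fields (untyped by default).
miniStructure <- function(coords, name = "CA", resname = "ALA",
                          chain = "A", resno = seq_len(nrow(coords)),
                          element = "C", type = "untyped",
                          insert = "") {
  n <- nrow(coords)
  ppdock:::newTypedStructure(data.frame(
    serial = seq_len(n), name = rep_len(name, n),
    resname = rep_len(resname, n), chain = rep_len(chain, n),
    resno = rep_len(resno, n), insert = rep_len(insert, n),
    element = rep_len(element, n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    type = rep_len(type, n), stringsAsFactors = FALSE))
}

# A tiny hand-made potential set over a 2-type alphabet: every pair's
# potential is known in closed form for single-term scoring tests.
miniPotentials <- function(alphabet = c("N.3", "O.co2"),
                           fill = 0) {
  nb <- 50L
  values <- array(fill, c(2, 2, nb),
                  dimnames = list(alphabet, alphabet, NULL))
  new("PairPotentialSet", alphabet = alphabet,
      breaks = seq(0, 5, by = 0.1), values = values,
      counts = matrix(1000, 2, 2, dimnames = list(alphabet, alphabet)),
      sigThreshold = 500, repulsionApplied = FALSE)
}

# An all-zero potential set over the full default alphabet.
zeroPotentials <- function() {
  ab <- typeAlphabet(defaultAtomTypeTable())
  nt <- length(ab)
  new("PairPotentialSet", alphabet = ab, breaks = seq(0, 5, by = 0.1),
      values = array(0, c(nt, nt, 50),
                     dimnames = list(ab, ab, NULL)),
      counts = matrix(0, nt, nt, dimnames = list(ab, ab)),
      sigThreshold = 500, repulsionApplied = FALSE)
}

# Memoised shared toy complex and matched potentials (the expensive
# fixtures used across test files).
sharedToy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makeToyComplex(fixtureSpec(seed = 1))
    cache
  }
})

sharedPotentials <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- toyPotentials(seed = 99)
    cache
  }
})

# Brute-force direct score: independent double loop over atom pairs.
bruteForceScore <- function(receptor, ligand, p) {
  xr <- atomCoords(receptor); xl <- atomCoords(ligand)
  tr <- atomTypes(receptor); tl <- atomTypes(ligand)
  bw <- p@breaks[2] - p@breaks[1]
  nb <- length(p@breaks) - 1
  total <- 0; npairs <- 0L
  for (i in seq_len(nrow(xr))) for (j in seq_len(nrow(xl))) {
    d <- sqrt(sum((xr[i, ] - xl[j, ])^2))
    if (d < 5) {
      bin <- min(nb, floor(d / bw) + 1)
      total <- total + p@values[tr[i], tl[j], bin]
      npairs <- npairs + 1L
    }
  }
  list(value = total, nPairs = npairs)
}

# A random typed mini-complex for oracle comparisons: two clouds of
# typed atoms a few Angstrom apart.
randomTypedComplex <- function(seed, nR = 12, nL = 8,
                               alphabet = typeAlphabet(defaultAtomTypeTable())) {
  ppdock:::withSeed(seed, {
    mk <- function(n, offset, chain) {
      co <- matrix(stats::rnorm(3 * n, sd = 3), n, 3)
      co[, 1] <- co[, 1] + offset
      s <- miniStructure(co, chain = chain)
      s@atoms$type <- sample(alphabet, n, replace = TRUE)
      s
    }
    list(receptor = mk(nR, 0, "A"), ligand = mk(nL, 4, "B"))
  })
}
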