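.mkTab <- function(O2, restype = "ALA", siteClass = "backbone", sd = 0.01) {
  orderParameterTable(seq_along(O2), rep(restype, length.out = length(O2)),
                      O2, sd = sd, siteClass = siteClass)
}

test_that("backbone entropy difference is zero for identical tables and antisymmetric", {
  set.seed(5)
  O2 <- runif(50, 0.7, 0.95)
  tab <- .mkTab(O2)
  expect_identical(backboneEntropyDiff(tab, tab), 0)
  O2b <- pmin(O2 + rnorm(50, 0, 0.02), 0.99)
  tabB <- .mkTab(O2b)
  expect_equal(backboneEntropyDiff(tab, tabB),
               -backboneEntropyDiff(tabB, tab))
})

test_that("backbone entropy matches a term-by-term oracle on 116 residues", {
  set.seed(6)
  O2a <- runif(116, 0.72, 0.96)
  O2b <- pmin(pmax(O2a + rnorm(116, 0.01, 0.015), 0.1), 0.995)
  v <- backboneEntropyDiff(.mkTab(O2a), .mkTab(O2b), temperature = 301)
  oracle <- 0
  for (k in seq_len(116)) {
    oracle <- oracle +
      log((3 - sqrt(1 + 8 * O2a[k])) / (3 - sqrt(1 + 8 * O2b[k])))
  }
  oracle <- -301 * 8.314 * oracle / 1000
  expect_equal(v, oracle, tolerance = 1e-12)
})

test_that("entropy differences are additive over disjoint residue subsets", {
  set.seed(7)
  O2a <- runif(40, 0.7, 0.95); O2b <- runif(40, 0.7, 0.95)
  full <- backboneEntropyDiff(.mkTab(O2a), .mkTab(O2b))
  part1 <- backboneEntropyDiff(.mkTab(O2a[1:17]), .mkTab(O2b[1:17]))
  part2 <- backboneEntropyDiff(.mkTab(O2a[18:40]), .mkTab(O2b[18:40]))
  expect_equal(full, part1 + part2, tolerance = 1e-12)
})

test_that("site-set mismatches and out-of-range O2 are rejected", {
  tabA <- .mkTab(c(0.8, 0.9))
  tabB <- orderParameterTable(2:3, c("ALA", "ALA"), c(0.8, 0.9))
  expect_error(backboneEntropyDiff(tabA, tabB), "mismatch")
  expect_warning(orderParameterTable(1, "ALA", 1.01), "clipped")
})

test_that("side-chain contributions scale with the residue-type coefficients", {
  mk <- function(ty, O2) .mkTab(O2, restype = ty, siteClass = "methyl")
  dIle <- sidechainEntropyDiff(mk("ILE", 0.7), mk("ILE", 0.8))
  dThr <- sidechainEntropyDiff(mk("THR", 0.7), mk("THR", 0.8))
  expect_equal(dIle / dThr, 3.1 / 1.32, tolerance = 1e-12)
  dVal <- sidechainEntropyDiff(mk("VAL", 0.7), mk("VAL", 0.8))
  dMet <- sidechainEntropyDiff(mk("MET", 0.7), mk("MET", 0.8))
  expect_equal(dVal / dThr, 1, tolerance = 1e-12)
  expect_equal(dMet / dThr, 2.31 / 1.32, tolerance = 1e-12)
  ## identical tables give exactly zero
  expect_identical(sidechainEntropyDiff(mk("LEU", 0.7), mk("LEU", 0.7)), 0)
  ## alanine goes through the log-ratio form
  dAla <- sidechainEntropyDiff(mk("ALA", 0.7), mk("ALA", 0.8))
  expect_equal(dAla, backboneEntropyDiff(.mkTab(0.7), .mkTab(0.8)),
               tolerance = 1e-12)
  expect_error(sidechainEntropyDiff(mk("GLY", 0.7), mk("GLY", 0.8)),
               "coefficient")
})

test_that("side-chain sums match an independent per-type oracle on 73 methyls", {
  set.seed(8)
  types <- sample(c("VAL", "THR", "ILE", "LEU", "MET", "ALA"), 73,
                  replace = TRUE)
  O2a <- runif(73, 0.3, 0.95)
  O2b <- pmin(pmax(O2a + rnorm(73, 0, 0.05), 0.05), 0.99)
  tabA <- orderParameterTable(1:73, types, O2a, siteClass = "methyl")
  tabB <- orderParameterTable(1:73, types, O2b, siteClass = "methyl")
  v <- sidechainEntropyDiff(tabA, tabB)
  cm <- c(VAL = 1.32, THR = 1.32, ILE = 3.1, LEU = 3.1, MET = 2.31)
  oracle <- 0
  for (k in 1:73) {
    oracle <- oracle + if (types[k] == "ALA") {
      8.314 * log((3 - sqrt(1 + 8 * O2a[k])) / (3 - sqrt(1 + 8 * O2b[k])))
    } else {
      -8.314 * cm[[types[k]]] * (O2a[k] - O2b[k])
    }
  }
  expect_equal(v, -301 * oracle / 1000, tolerance = 1e-12)
})

test_that("the intercomplex statistic is zero-sum with the factor-1.5 identity", {
  expect_equal(unname(intercomplexDelta(c(1, 1, 1))), c(0, 0, 0))
  expect_equal(unname(intercomplexDelta(c(4, 2, 2))), c(2, -1, -1))
  set.seed(9)
  for (i in 1:25) {
    v <- rnorm(3, 0, 10)
    d <- intercomplexDelta(v)
    expect_lt(abs(sum(d)), 1e-9)
    expect_equal(unname(d), unname(1.5 * (v - mean(v))), tolerance = 1e-12)
  }
  expect_error(intercomplexDelta(c(1, 2)), "three values")
})

test_that("monte-carlo entropy errors scale with the input uncertainties", {
  ## O2 kept away from 1 so the log-ratio term stays in its linear regime
  set.seed(10)
  O2 <- runif(116, 0.65, 0.88)
  mk <- function(sd) .mkTab(pmin(O2 + rnorm(116, 0, 0.01), 0.9), sd = sd)
  set.seed(11); tabs0 <- list(M = mk(0), P = mk(0), O = mk(0))
  e0 <- entropyMcErrors(tabs0, "backbone", nMc = 50, seed = 1)
  expect_equal(unname(e0), c(0, 0, 0))

  set.seed(11); tabs1 <- list(M = mk(0.01), P = mk(0.01), O = mk(0.01))
  set.seed(11); tabs2 <- list(M = mk(0.02), P = mk(0.02), O = mk(0.02))
  e1 <- entropyMcErrors(tabs1, "backbone", nMc = 400, seed = 2)
  e2 <- entropyMcErrors(tabs2, "backbone", nMc = 400, seed = 2)
  expect_equal(unname(e2 / e1), rep(2, 3), tolerance = 0.25)
})

test_that("mc error estimates stabilize between seeds at 500 samples", {
  set.seed(12)
  O2 <- runif(116, 0.65, 0.9)
  tabs <- list(M = .mkTab(O2, sd = 0.012),
               P = .mkTab(pmin(O2 + 0.01, 0.95), sd = 0.012),
               O = .mkTab(pmax(O2 - 0.01, 0.1), sd = 0.012))
  eA <- entropyMcErrors(tabs, "backbone", nMc = 500, seed = 100)
  eB <- entropyMcErrors(tabs, "backbone", nMc = 500, seed = 200)
  expect_true(all(abs(eA - eB) / eA < 0.1))
})

test_that("intercomplex entropy deltas sum to zero regardless of reference", {
  set.seed(13)
  O2 <- runif(30, 0.7, 0.95)
  tabs <- list(M = .mkTab(O2), P = .mkTab(pmin(O2 + 0.02, 0.99)),
               O = .mkTab(pmax(O2 - 0.02, 0.1)))
  d <- intercomplexEntropy(tabs, "backbone")
  expect_lt(abs(sum(d)), 1e-9)
  ## permuting the list relabels but keeps the same values per complex
  d2 <- intercomplexEntropy(tabs[c(2, 3, 1)], "backbone")
  expect_equal(sort(unname(d)), sort(unname(d2)), tolerance = 1e-9)
})

test_that("per-residue entropy decreases strictly with O2", {
  tab <- .mkTab(seq(0.5, 0.95, length.out = 10))
  v <- perResidueEntropy(tab)
  expect_true(all(diff(v) < 0))
  tabC <- .mkTab(rep(0.8, 5))
  expect_equal(unname(diff(perResidueEntropy(tabC))), rep(0, 4))
  ## matches the closed form against a fixed reference
  ref <- 0.8
  single <- perResidueEntropy(.mkTab(c(0.9)))
  relative <- single - 301 * 8.314 * log(3 - sqrt(1 + 8 * ref)) / 1000
  pair <- backboneEntropyDiff(.mkTab(0.9), .mkTab(ref))
  expect_equal(unname(-relative), pair, tolerance = 1e-12)
})

test_that("order parameter tables round-trip through CSV", {
  set.seed(14)
  tab <- orderParameterTable(c(5, 5, 9), c("VAL", "VAL", "ILE"),
                             c(0.8, 0.7, 0.6), sd = c(0.01, 0.02, 0.01),
                             siteClass = "methyl")
  fp <- tempfile(fileext = ".csv")
  writeOrderParameterTable(tab, fp)
  back <- readOrderParameterTable(fp)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})
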