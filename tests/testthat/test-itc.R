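## independent stepwise mass-balance oracle for the perfusion model and the
## differential heat, written as an explicit per-injection loop
.stepwiseOracle <- function(scheme, n, Kd, dH, Qoff, heatUnit = 1e9) {
  M <- 0; X <- scheme@cellConc; Qprev <- 0
  ni <- nInjections(scheme)
  q <- Mv <- Xv <- numeric(ni)
  for (i in seq_len(ni)) {
    f <- scheme@injectionVolumes[i] / scheme@V0
    M <- M * (1 - f) + scheme@syringeConc * f
    X <- X * (1 - f)
    al <- n * M + X + Kd
    PL <- (al - sqrt(al^2 - 4 * n * M * X)) / 2
    Q <- scheme@V0 * dH * PL * heatUnit
    q[i] <- Q - Qprev + f * (Q + Qprev) / 2 + Qoff
    Qprev <- Q
    Mv[i] <- M; Xv[i] <- X
  }
  list(q = q, M = Mv, X = Xv)
}

test_that("cell concentrations follow the perfusion model", {
  sch <- titrationScheme(V0 = 200e-6, injectionVolumes = 2e-6,
                         syringeConc = 100e-6, cellConc = 1000e-6,
                         nInjections = 10)
  expect_equal(unname(cellConcentrations(sch, 0)), c(0, 1000e-6))
  ## closed forms for constant injection volume
  f <- 2e-6 / 200e-6
  cc <- cellConcentrations(sch, 10)
  expect_equal(cc[["M"]], 100e-6 * (1 - (1 - f)^10), tolerance = 1e-12)
  expect_equal(cc[["X"]], 1000e-6 * (1 - f)^10, tolerance = 1e-12)
  ## stepwise oracle agreement and monotonicity along the titration
  or <- .stepwiseOracle(sch, 1, 1e-6, -50, 0)
  Ms <- sapply(1:10, function(i) cellConcentrations(sch, i)[["M"]])
  Xs <- sapply(1:10, function(i) cellConcentrations(sch, i)[["X"]])
  expect_equal(Ms, or$M, tolerance = 1e-12)
  expect_equal(Xs, or$X, tolerance = 1e-12)
  expect_true(all(diff(Ms) > 0) && all(diff(Xs) < 0))
  expect_error(cellConcentrations(sch, 11), "out of range")
})

test_that("complex concentration obeys mass-action limits and a bisection oracle", {
  ## stoichiometric limit
  p <- bindingParams(n = 1, Kd = 1e-15, dH = -50)
  expect_equal(complexConcentration(1e-4, 1e-4, p), 1e-4, tolerance = 1e-5)
  expect_equal(complexConcentration(0, 1e-4, p), 0)
  ## bisection oracle at M = X = Kd
  Kd <- 2e-6
  p2 <- bindingParams(n = 1, Kd = Kd, dH = -50)
  froot <- function(PL, M, X) (M - PL) * (X - PL) / PL - Kd
  or <- uniroot(froot, c(1e-18, min(Kd, Kd) * (1 - 1e-12)), M = Kd, X = Kd,
                tol = 1e-18)$root
  expect_equal(complexConcentration(Kd, Kd, p2), or, tolerance = 1e-9)
  ## monotonicity in each argument
  Ms <- seq(1e-6, 1e-4, length.out = 15)
  expect_true(all(diff(complexConcentration(Ms, 5e-5, p2)) > 0))
  expect_true(all(diff(complexConcentration(5e-5, Ms, p2)) > 0))
  Kds <- 10^seq(-8, -4, length.out = 10)
  pls <- sapply(Kds, function(k)
    complexConcentration(5e-5, 5e-5, bindingParams(1, k, -50)))
  expect_true(all(diff(pls) < 0))
})

test_that("predicted heats match the stepwise oracle and its limits", {
  ## the quoted reference conditions: 20 x 2 uL into 250 uL, 100 uM titrant
  ## into 1000 uM cell, Kd 2 uM, dH -50 kJ/mol
  sch <- titrationScheme(V0 = 250e-6, injectionVolumes = 2e-6,
                         syringeConc = 100e-6, cellConc = 1000e-6,
                         nInjections = 20)
  p <- bindingParams(n = 1, Kd = 2e-6, dH = -50, Qoff = 0.25)
  q <- predictedHeats(sch, p)
  or <- .stepwiseOracle(sch, 1, 2e-6, -50, 0.25)$q
  expect_equal(q, or, tolerance = 1e-6)

  ## dH = 0 -> all heats equal the offset
  expect_equal(predictedHeats(sch, bindingParams(1, 2e-6, 0, 0.7)),
               rep(0.7, 20))
  ## Kd -> infinity -> offset only
  expect_equal(predictedHeats(sch, bindingParams(1, 1e6, -50, 0.7)),
               rep(0.7, 20), tolerance = 1e-6)
})

test_that("heat conservation holds over the titration", {
  sch <- referenceScheme()
  p <- bindingParams(n = 0.95, Kd = 2.5e-6, dH = -47, Qoff = 0.4)
  q <- predictedHeats(sch, p)
  conc <- sapply(1:20, function(i) cellConcentrations(sch, i))
  PL <- complexConcentration(conc[1, ], conc[2, ], p)
  Q <- sch@V0 * p@dH * PL * 1e9
  v <- sch@injectionVolumes / sch@V0
  Qprev <- c(0, Q[-20])
  lhs <- sum(q - p@Qoff)
  rhs <- Q[20] + sum(v * (Q + Qprev) / 2)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("global fit inverts noiseless synthetic thermograms", {
  truth <- bindingParams(n = 0.92, Kd = 2e-6, dH = -50.4, Qoff = 0.3)
  g <- genItc(truth, nReplicates = 2, noiseFrac = 0, seed = 5)
  f <- fitGlobal(g$thermograms, init = bindingParams(1.05, 5e-6, -30, 0))
  expect_lt(abs(f$params@Kd - 2e-6) / 2e-6, 1e-4)
  expect_lt(abs(f$params@dH - (-50.4)) / 50.4, 1e-4)
  expect_lt(abs(f$params@n - 0.92) / 0.92, 1e-4)
})

test_that("global fit recovers truth within errors at realistic noise", {
  truth <- bindingParams(n = 1, Kd = 2e-6, dH = -50.4, Qoff = 0.3)
  g <- genItc(truth, nReplicates = 2, noiseFrac = 0.02, seed = 42)
  f <- fitGlobal(g$thermograms)
  expect_lt(abs(f$params@Kd - truth@Kd), 3 * f$sd["Kd"])
  expect_lt(abs(f$params@dH - truth@dH), 3 * f$sd["dH"])
  expect_lt(abs(f$params@n - truth@n), 3 * f$sd["n"])
})

test_that("a sign-flipped replicate yields a sign-consistent fit or misfit flag", {
  truth <- bindingParams(n = 1, Kd = 2e-6, dH = -50, Qoff = 0)
  g <- genItc(truth, nReplicates = 2, noiseFrac = 0.01, seed = 8)
  flipped <- g$thermograms
  flipped[[2]]@heats <- -flipped[[2]]@heats
  f <- tryCatch(fitGlobal(flipped), error = function(e) e)
  if (!inherits(f, "error")) {
    ## converged: the shared dH has one sign and the misfit is large
    expect_gt(f$chisq / f$dof, 10)
  } else {
    expect_match(conditionMessage(f), "fit failure")
  }
})

test_that("derived thermodynamics reproduce the standard-state identities", {
  s <- deriveThermodynamics(1, -10, temperature = 300)
  expect_equal(s@dG, 0)
  s2 <- deriveThermodynamics(2e-6, -50.4, KdSd = 0.29e-6, dHSd = 1.2)
  expect_equal(s2@dG, s2@dH + s2@mTdS)
  expect_gte(s2@sd[["mTdS"]], max(s2@sd[["dG"]], s2@sd[["dH"]]))
  expect_error(deriveThermodynamics(-1, -50), "positive")
})

test_that("saturation behaves in the tight-binding and excess-ligand limits", {
  expect_equal(saturation(1e-4, 1e-4, bindingParams(1, 1e-15, -50)), 1,
               tolerance = 1e-5)
  ## excess ligand: saturation ~ X / (X + Kd)
  Kd <- 2e-6
  X <- 1e-3
  s <- saturation(1e-7, X, bindingParams(1, Kd, -50))
  expect_equal(s, X / (X + Kd), tolerance = 1e-3)
  ## bisection oracle at NMR-sample-like concentrations
  M <- 0.9e-3; X2 <- 1.05 * M
  p <- bindingParams(1, 2e-6, -50)
  froot <- function(PL) (M - PL) * (X2 - PL) / PL - 2e-6
  or <- uniroot(froot, c(1e-12, M * (1 - 1e-9)), tol = 1e-16)$root
  expect_equal(saturation(M, X2, p), or / M, tolerance = 1e-6)
  expect_error(saturation(0, 0, p), "both totals")
})

test_that("thermogram and scheme files round-trip", {
  sch <- referenceScheme()
  truth <- bindingParams(1, 2e-6, -50, 0.2)
  tg <- genItc(truth, sch, nReplicates = 1, noiseFrac = 0.02,
               seed = 3)$thermograms[[1]]
  fp <- tempfile(fileext = ".csv")
  writeThermogram(tg, fp)
  back <- readThermogram(fp, sch)
  expect_equal(back@heats, tg@heats, tolerance = 1e-10)
  expect_equal(back@scheme@injectionVolumes, sch@injectionVolumes)

  yml <- tempfile(fileext = ".yml")
  writeLines(c("V0_uL: 250", "syringe_uM: 1000", "cell_uM: 100",
               "temperature_K: 301.1", "injection_uL: 2",
               "n_injections: 20"), yml)
  sch2 <- readTitrationScheme(yml)
  expect_equal(sch2@V0, sch@V0)
  expect_equal(sch2@syringeConc, sch@syringeConc)
  expect_equal(nInjections(sch2), 20L)
})
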