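test_that("rigid-rotor and degenerate-tensor limits of the spectral density", {
  tens <- isotropicTensor(7e-9)
  expect_equal(spectralDensity(0, list(O2 = 1), tens), 0.4 * 7e-9,
               tolerance = 1e-12)
  ## axial tensor with DZZ = DXX reduces to the isotropic value
  ax <- axialTensor(7e-9, 1)
  u <- c(0.3, 0.4, sqrt(1 - 0.25))
  p <- list(O2 = 0.8, taue = 50e-12)
  for (w in c(0, 5e8, 3e9)) {
    expect_equal(spectralDensity(w, p, ax, u),
                 spectralDensity(w, p, tens), tolerance = 1e-12)
  }
  expect_error(spectralDensity(0, list(O2 = 0.8, taue = -1), tens),
               "invalid input")
})

test_that("woessner weights sum to one and J decreases with frequency", {
  set.seed(20)
  for (i in 1:20) {
    D <- sort(runif(3, 1e7, 4e7))
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    w <- BindEntropy:::.woessner(D, u)
    expect_equal(sum(w$A), 1, tolerance = 1e-12)
    tens <- diffusionTensor(D)
    J <- spectralDensity(10^seq(6, 10, length.out = 12),
                         list(O2 = 0.85, taue = 30e-12), tens, u)
    expect_true(all(diff(J) <= 1e-18))
    expect_true(all(J >= 0))
  }
})

test_that("rhombic spectral density equals quadrature of the correlation function", {
  ## independent oracle: J(w) = 2 * int_0^inf C(t) cos(wt) dt with
  ## C(t) = sum_j A_j [O2 + (1-O2) exp(-t/taue)] exp(-k_j t) evaluated by
  ## adaptive quadrature
  D <- c(1.2e7, 1.9e7, 3.1e7)
  u <- c(0.48, -0.36, sqrt(1 - 0.48^2 - 0.36^2))
  O2 <- 0.82; taue <- 40e-12
  tens <- diffusionTensor(D)
  w <- BindEntropy:::.woessner(D, u)
  Ct <- function(t) {
    ov <- sapply(t, function(tt) sum(w$A * exp(-w$k * tt)))
    ov * (O2 + (1 - O2) * exp(-t / taue))
  }
  for (om in c(0, 3e8, 1.2e9)) {
    or <- 0.4 * integrate(function(t) Ct(t) * cos(om * t), 0, Inf,
                          rel.tol = 1e-10)$value
    expect_equal(spectralDensity(om, list(O2 = O2, taue = taue), tens, u),
                 or, tolerance = 1e-6)
  }
})

test_that("15N rates match a closed-form single-Lorentzian evaluation", {
  ## O2 = 1, no internal motion: J(w) = 0.4 tauc / (1 + (w tauc)^2)
  tauc <- 7e-9
  tens <- isotropicTensor(tauc)
  cst <- spinConstants()
  B0 <- 14.1
  wH <- cst$gammaH * B0; wN <- abs(cst$gammaN) * B0
  d <- cst$mu0 * cst$hbar * cst$gammaH * abs(cst$gammaN) /
    (4 * pi * cst$rNH^3)
  cc <- wN * cst$csaN / sqrt(3)
  J <- function(w) 0.4 * tauc / (1 + (w * tauc)^2)
  R1or <- (d^2 / 4) * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) +
    cc^2 * J(wN)
  R2or <- (d^2 / 8) * (4 * J(0) + J(wH - wN) + 3 * J(wN) + 6 * J(wH) +
                       6 * J(wH + wN)) + (cc^2 / 6) * (4 * J(0) + 3 * J(wN))
  NOEor <- 1 + (cst$gammaH / cst$gammaN) * (d^2 / 4) *
    (6 * J(wH + wN) - J(wH - wN)) / R1or
  r <- rates15N(list(O2 = 1), tens, B0 = B0)
  expect_equal(unname(r), c(R1or, R2or, NOEor), tolerance = 1e-10)
})

test_that("Rex adds only to R2, scaled by the square of the field", {
  tens <- isotropicTensor(7e-9)
  for (B0 in c(11.7, 14.1, 18.8)) {
    r0 <- rates15N(list(O2 = 0.85), tens, B0 = B0)
    r2 <- rates15N(list(O2 = 0.85, Rex = 2), tens, B0 = B0)
    expect_equal(r2[["R2"]] - r0[["R2"]], 2 * (B0 / 11.7)^2,
                 tolerance = 1e-10)
    expect_equal(r2[["R1"]], r0[["R1"]])
    expect_equal(r2[["NOE"]], r0[["NOE"]])
  }
})

test_that("extreme narrowing gives R1 close to R2", {
  r <- rates15N(list(O2 = 1), isotropicTensor(1e-13), B0 = 14.1)
  expect_equal(r[["R1"]], r[["R2"]], tolerance = 1e-3)
})

test_that("2H methyl rates obey the quadrupolar scaling and slow-tumbling order", {
  tens <- isotropicTensor(7e-9)
  p <- list(O2 = 0.6, tauf = 30e-12)
  h1 <- rates2HMethyl(p, tens, 14.1)
  h2 <- rates2HMethyl(p, tens, 14.1, spinConstants(qcc = 2 * 167e3))
  expect_equal(unname(h2 / h1), rep(4, 4), tolerance = 1e-12)
  expect_gt(h1[["R2Dplus"]], h1[["R1Dz"]])

  ## hand-evaluated J combinations at both fields
  cst <- spinConstants()
  for (B0 in c(11.7, 14.1)) {
    wD <- abs(cst$gammaD) * B0
    wq <- 2 * pi * cst$qcc
    Jm <- function(w) {
      tc <- 7e-9; tf <- 30e-12
      tp <- 1 / (1 / tc + 1 / tf)
      0.4 * ((0.6 / 9) * tc / (1 + (w * tc)^2) +
               (1 - 0.6 / 9) * tp / (1 + (w * tp)^2))
    }
    r <- rates2HMethyl(p, tens, B0)
    expect_equal(r[["R1Dz"]], (3 / 40) * wq^2 * (Jm(wD) + 4 * Jm(2 * wD)),
                 tolerance = 1e-10)
    expect_equal(r[["R3Dz2"]], (9 / 40) * wq^2 * Jm(wD), tolerance = 1e-10)
    expect_equal(r[["R2Dplus"]],
                 (1 / 80) * wq^2 * (9 * Jm(0) + 15 * Jm(wD) + 6 * Jm(2 * wD)),
                 tolerance = 1e-10)
    expect_equal(r[["RDplusDz"]],
                 (1 / 80) * wq^2 * (9 * Jm(0) + 3 * Jm(wD) + 6 * Jm(2 * wD)),
                 tolerance = 1e-10)
  }
})

test_that("fast free-rotor methyl limit gives small, narrowing-limit rates", {
  r <- rates2HMethyl(list(O2 = 0, tauf = 1e-12), isotropicTensor(7e-9), 14.1)
  expect_true(all(r < 1))
  expect_equal(r[["R1Dz"]], r[["R2Dplus"]], tolerance = 0.01)
})

test_that("anisotropy and rhombicity definitions evaluate as printed", {
  expect_equal(unname(anisotropyRhombicity(1, 1, 1)), c(1, 0))
  expect_equal(unname(anisotropyRhombicity(1, 2, 3)), c(2, 1))
  expect_equal(unname(anisotropyRhombicity(1, 1, 2)), c(2, 0))
  expect_error(anisotropyRhombicity(3, 2, 1), "ascending")
})

test_that("fitSite recovers noiseless extended data and selects m2", {
  tens <- isotropicTensor(7e-9)
  gen <- genRelaxation(nSites = 1, tensor = tens, noiseFrac = 1e-6,
                       truth = data.frame(site = "res001", model = "m2",
                                          O2 = 0.85, taue = 50e-12,
                                          Rex = NA), seed = 3)
  f <- fitSite(gen$records, tens)
  expect_equal(f$model, "m2")
  expect_lt(abs(f$params$O2 - 0.85), 1e-3)
  expect_lt(abs(f$params$taue - 50e-12) / 50e-12, 0.05)
})

test_that("fitSite is invariant to record ordering and flags underdetermined sites", {
  tens <- isotropicTensor(7e-9)
  gen <- genRelaxation(nSites = 1, tensor = tens, noiseFrac = 0.015,
                       seed = 17)
  rec <- gen$records
  f1 <- fitSite(rec, tens)
  f2 <- fitSite(rec[sample(nrow(rec)), ], tens)
  expect_equal(f1$params, f2$params, tolerance = 1e-10)
  expect_equal(f1$model, f2$model)

  single <- rec[rec$field_T == 11.7 & rec$rate_type == "R1", ]
  f3 <- fitSite(single, tens)
  expect_true(f3$underdetermined)
})

test_that("monte-carlo errors from fitSite calibrate against truth", {
  tens <- isotropicTensor(7e-9)
  gen <- genRelaxation(nSites = 1, tensor = tens, noiseFrac = 0.015,
                       seed = 23)
  f <- fitSite(gen$records, tens, nMc = 100, seed = 1)
  expect_false(is.null(f$sd))
  expect_lt(abs(f$params$O2 - gen$truth$O2), 4 * f$sd[["O2"]])
})

test_that("back-calculated rates reproduce the input data (self-consistency)", {
  tens <- isotropicTensor(7e-9)
  gen <- genRelaxation(nSites = 6, tensor = tens, noiseFrac = 0.015,
                       seed = 29)
  for (s in unique(gen$records$site)) {
    rec <- gen$records[gen$records$site == s, ]
    rec <- rec[order(rec$field_T, rec$rate_type), ]
    f <- fitSite(rec, tens)
    pred <- numeric(nrow(rec))
    for (B0 in unique(rec$field_T)) {
      r <- rates15N(f$params, tens, B0 = B0)
      sel <- rec$field_T == B0
      pred[sel] <- r[rec$rate_type[sel]]
    }
    ## within ~3 sd of every datum
    expect_true(all(abs(rec$value - pred) < 4 * rec$sd))
  }
})

test_that("fitDiffusionTensor recovers an isotropic tensor on a small protein", {
  gen <- genRelaxation(nSites = 24, tensor = isotropicTensor(7e-9),
                       noiseFrac = 0.015, seed = 31)
  tf <- fitDiffusionTensor(gen$records, gen$vectors, shape = "isotropic")
  expect_lt(abs(tf$tauc - 7e-9) / 7e-9, 0.01)
  expect_equal(tf$zeta, 1)
  expect_equal(tf$eta, 0)
})

test_that("exactly isotropic principal values give zeta 1 and eta 0", {
  tens <- diffusionTensor(rep(1 / (6 * 7e-9), 3))
  ze <- anisotropyRhombicity(tens@D[1], tens@D[2], tens@D[3])
  expect_identical(unname(ze), c(1, 0))
})
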