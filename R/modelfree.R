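## Lipari-Szabo model-free analysis: spectral densities under isotropic,
## axially symmetric, or rhombic rotational diffusion (Woessner
## multi-exponential weighting), 15N backbone and 2H methyl relaxation rate
## expressions, nested-model fitting with F-test selection, and diffusion
## tensor optimization.

#' Spin-system constants for relaxation rate expressions
#'
#' @param rNH N-H bond length, metres (default 1.02 A).
#' @param csaN 15N chemical shift anisotropy (default -172 ppm).
#' @param qcc 2H quadrupolar coupling constant e^2qQ/h, Hz (default 167 kHz).
#' @return named list including the gyromagnetic ratios of 1H, 15N and 2H
#'   (rad s^-1 T^-1).
#' @export
spinConstants <- function(rNH = 1.02e-10, csaN = -172e-6, qcc = 167e3) {
  list(rNH = rNH, csaN = csaN, qcc = qcc,
       gammaH = 2.6752218744e8, gammaN = -2.7126e7, gammaD = 4.10662791e7,
       hbar = 1.054571817e-34, mu0 = 4e-7 * pi)
}

#' Anisotropy and rhombicity of a diffusion tensor
#'
#' zeta = 2 DZZ / (DXX + DYY) and
#' eta = 1.5 (DYY - DXX) / (DZZ - (DXX + DYY)/2), with principal values
#' sorted ascending.  At the isotropic singularity eta is defined as 0.
#'
#' @param Dxx,Dyy,Dzz principal values, ascending.
#' @return named numeric c(zeta, eta).
#' @examples
#' anisotropyRhombicity(1, 2, 3)  # zeta 2, eta 1
#' @export
anisotropyRhombicity <- function(Dxx, Dyy, Dzz) {
  if (is.unsorted(c(Dxx, Dyy, Dzz)))
    stop("principal values must be sorted ascending")
  zeta <- 2 * Dzz / (Dxx + Dyy)
  den <- Dzz - 0.5 * (Dxx + Dyy)
  eta <- if (abs(den) < .Machine$double.eps * Dzz) 0 else 1.5 * (Dyy - Dxx) / den
  c(zeta = zeta, eta = eta)
}

## Woessner decomposition of the rigid-rotor correlation function for a unit
## vector with direction cosines u (in the tensor PAS):
## C(t) = sum_j A_j exp(-k_j t), 5 exponentials in general, validated against
## Brownian-dynamics simulation.  sum(A) = 1 for any u.
.woessner <- function(D, u) {
  Dx <- D[1]; Dy <- D[2]; Dz <- D[3]
  if (max(D) - min(D) < 1e-9 * max(D)) {
    return(list(k = 6 * mean(D), A = 1))
  }
  Diso <- mean(D)
  L2 <- (Dx * Dy + Dx * Dz + Dy * Dz) / 3
  mu <- sqrt(max(Diso^2 - L2, 0))
  k <- c(4 * Dx + Dy + Dz,
         Dx + 4 * Dy + Dz,
         Dx + Dy + 4 * Dz,
         6 * Diso + 6 * mu,
         6 * Diso - 6 * mu)
  dx <- u[1]; dy <- u[2]; dz <- u[3]
  A1 <- 3 * dy^2 * dz^2
  A2 <- 3 * dx^2 * dz^2
  A3 <- 3 * dx^2 * dy^2
  d <- 0.25 * (3 * (dx^4 + dy^4 + dz^4) - 1)
  e <- if (mu > 0) {
    (1 / (12 * mu)) * ((Dx - Diso) * (3 * dx^4 + 6 * dy^2 * dz^2 - 1) +
                       (Dy - Diso) * (3 * dy^4 + 6 * dx^2 * dz^2 - 1) +
                       (Dz - Diso) * (3 * dz^4 + 6 * dx^2 * dy^2 - 1))
  } else 0
  list(k = k, A = c(A1, A2, A3, d - e, d + e))
}

## Internal-motion decomposition: list of (amplitude, internal tau; Inf for
## the rigid plateau).  Backbone simple LS and extended forms; methyl forms
## carry the 1/9 factor from fast rotation about the methyl symmetry axis.
.mfComponents <- function(params, siteClass = c("backbone", "methyl")) {
  siteClass <- match.arg(siteClass)
  gp <- function(x, d = NULL) if (is.null(params[[x]])) d else params[[x]]
  if (siteClass == "backbone") {
    Of2 <- gp("Of2"); Os2 <- gp("Os2")
    if (!is.null(Of2) && !is.null(Os2)) {
      tf <- gp("tauf", 0); ts <- gp("taus", 0)
      amp <- c(Of2 * Os2, Of2 * (1 - Os2), 1 - Of2)
      tau <- c(Inf, ts, tf)
    } else {
      O2 <- gp("O2")
      te <- gp("taue", 0)
      amp <- c(O2, 1 - O2)
      tau <- c(Inf, te)
    }
  } else {
    ## methyl axis: fast methyl spinning scales the plateau by
    ## P2(cos 109.47)^2 = 1/9 and contributes an 8/9 fast term
    Of2 <- gp("Of2"); Os2 <- gp("Os2")
    if (is.null(Of2) || is.null(Os2)) {
      Os2 <- gp("O2")
      Of2 <- 1
      if (!is.null(gp("taus")) || !is.null(gp("taueff"))) {
        ## {O2, tauf, taueff}: slow axis motion present
      } else {
        Of2 <- gp("O2"); Os2 <- 1  # {O2, tauf}: single internal time
      }
    }
    tf <- gp("tauf", 0); ts <- gp("taus", 0)
    amp <- c(Of2 * Os2 / 9, Of2 * (1 - Os2) / 9, 1 - Of2 / 9)
    tau <- c(Inf, ts, tf)
  }
  ## a zero internal time means infinitely fast motion: that component
  ## contributes nothing to J and is dropped (m1-style models)
  keep <- amp > 0 & (is.infinite(tau) | tau > 0)
  list(amp = amp[keep], tau = tau[keep])
}

#' Lipari-Szabo spectral density
#'
#' J(omega) for a bond vector undergoing internal motion (simple or extended
#' model-free) on a molecule tumbling with an isotropic, axial, or rhombic
#' rotational diffusion tensor.  Anisotropic overall motion uses the
#' Woessner multi-exponential weighting (3 exponentials for axial, 5 for
#' rhombic); each internal component combines with each overall exponential
#' through 1/tau_eff = k_j + 1/tau_int.
#'
#' @param omega angular frequency, rad/s (vectorized, >= 0).
#' @param params named list of model-free parameters: \code{O2} and optional
#'   \code{taue} (simple), or \code{Of2}, \code{Os2}, \code{tauf},
#'   \code{taus} (extended); times in seconds.
#' @param tensor a \code{\link{diffusionTensor}}.
#' @param orientation unit bond vector in the tensor principal axis system
#'   (ignored for isotropic tensors).
#' @param siteClass "backbone" or "methyl"; methyl applies the 1/9 geometric
#'   factor of fast methyl rotation to the plateau.
#' @return J(omega) in s/rad.
#' @examples
#' ## rigid rotor: J(0) = (2/5) tauc
#' spectralDensity(0, list(O2 = 1), isotropicTensor(7e-9))
#' @export
spectralDensity <- function(omega, params, tensor,
                            orientation = c(0, 0, 1),
                            siteClass = "backbone") {
  stopifnot(all(omega >= 0))
  tchk <- unlist(params[c("taue", "tauf", "taus")])
  if (any(tchk < 0)) stop("invalid input: internal correlation times must be >= 0")
  w <- .woessner(tensor@D, orientation / sqrt(sum(orientation^2)))
  comp <- .mfComponents(params, siteClass)
  J <- numeric(length(omega))
  for (j in seq_along(w$k)) {
    for (c in seq_along(comp$amp)) {
      keff <- w$k[j] + if (is.finite(comp$tau[c]) && comp$tau[c] > 0)
        1 / comp$tau[c] else 0
      if (!is.finite(keff) || keff <= 0) next
      te <- 1 / keff
      J <- J + w$A[j] * comp$amp[c] * te / (1 + (omega * te)^2)
    }
  }
  0.4 * J
}

#' 15N relaxation rates from model-free parameters
#'
#' Standard dipolar + CSA expressions for amide 15N R1, R2 and the
#' heteronuclear {1H}-15N NOE.  An exchange term Rex (defined at the
#' reference field) is added to R2 scaled by (B0/Bref)^2.
#'
#' @param params model-free parameter list (see
#'   \code{\link{spectralDensity}}); may include \code{Rex} (s^-1 at
#'   \code{Bref}).
#' @param tensor a \code{\link{diffusionTensor}}.
#' @param orientation NH unit vector in the tensor frame.
#' @param B0 static field, tesla.
#' @param constants \code{\link{spinConstants}}.
#' @param Bref reference field for Rex, tesla (default 11.7).
#' @return named numeric c(R1, R2, NOE); R1/R2 in s^-1, NOE dimensionless.
#' @export
rates15N <- function(params, tensor, orientation = c(0, 0, 1), B0,
                     constants = spinConstants(), Bref = 11.7) {
  wH <- constants$gammaH * B0
  wN <- abs(constants$gammaN) * B0
  d <- constants$mu0 * constants$hbar * constants$gammaH *
    abs(constants$gammaN) / (4 * pi * constants$rNH^3)
  cc <- wN * constants$csaN / sqrt(3)
  J <- function(w) spectralDensity(abs(w), params, tensor, orientation)
  Rex <- if (is.null(params$Rex)) 0 else params$Rex * (B0 / Bref)^2
  R1 <- (d^2 / 4) * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) + cc^2 * J(wN)
  R2 <- (d^2 / 8) * (4 * J(0) + J(wH - wN) + 3 * J(wN) + 6 * J(wH) +
                     6 * J(wH + wN)) +
    (cc^2 / 6) * (4 * J(0) + 3 * J(wN)) + Rex
  sigma <- (d^2 / 4) * (6 * J(wH + wN) - J(wH - wN))
  NOE <- 1 + (constants$gammaH / constants$gammaN) * sigma / R1
  c(R1 = R1, R2 = R2, NOE = NOE)
}

#' 2H methyl relaxation rates from model-free parameters
#'
#' Quadrupolar rates of the four deuterium coherences R1(Dz), R(3Dz^2-2),
#' R2(D+) and R(D+Dz + DzD+), evaluated from J(0), J(wD) and J(2wD) with
#' omega_Q = 2 pi QCC:
#' R1(Dz) = (3/40) wQ^2 [J(wD) + 4 J(2wD)],
#' R(3Dz^2-2) = (9/40) wQ^2 J(wD),
#' R2(D+) = (1/80) wQ^2 [9 J(0) + 15 J(wD) + 6 J(2wD)],
#' R(D+Dz+DzD+) = (1/80) wQ^2 [9 J(0) + 3 J(wD) + 6 J(2wD)].
#'
#' @param params model-free parameters for the methyl axis: \code{O2} plus
#'   \code{tauf} (and optionally \code{taus} or extended \code{Of2},
#'   \code{Os2}).
#' @param tensor a \code{\link{diffusionTensor}}.
#' @param B0 static field, tesla.
#' @param constants \code{\link{spinConstants}} (uses \code{qcc}).
#' @param orientation methyl-axis unit vector in the tensor frame.
#' @return named numeric of the four rates, s^-1.
#' @export
rates2HMethyl <- function(params, tensor, B0, constants = spinConstants(),
                          orientation = c(0, 0, 1)) {
  wD <- abs(constants$gammaD) * B0
  wq <- 2 * pi * constants$qcc
  J <- function(w) spectralDensity(w, params, tensor, orientation,
                                   siteClass = "methyl")
  J0 <- J(0); J1 <- J(wD); J2 <- J(2 * wD)
  c(R1Dz = (3 / 40) * wq^2 * (J1 + 4 * J2),
    R3Dz2 = (9 / 40) * wq^2 * J1,
    R2Dplus = (1 / 80) * wq^2 * (9 * J0 + 15 * J1 + 6 * J2),
    RDplusDz = (1 / 80) * wq^2 * (9 * J0 + 3 * J1 + 6 * J2))
}

## ---- model fitting ---------------------------------------------------------

.thetaToParams <- function(model, theta) {
  switch(model,
    m1 = list(O2 = theta[1]),
    m2 = list(O2 = theta[1], taue = theta[2]),
    m3 = list(O2 = theta[1], Rex = theta[2]),
    m4 = list(O2 = theta[1], taue = theta[2], Rex = theta[3]),
    s2 = list(O2 = theta[1], tauf = theta[2]),
    s3 = list(O2 = theta[1], tauf = theta[2], taus = theta[3]),
    s4 = list(Of2 = theta[1], Os2 = theta[2], tauf = theta[3],
              taus = theta[4]),
    stop("unknown model ", model))
}

## Build a fast predictor for one site: precomputes the Woessner
## decomposition, per-field frequency tables and interaction constants, and
## returns function(model, theta) -> predicted rates in the row order of
## `records`.  Semantically identical to calling rates15N / rates2HMethyl
## row by row (checked in the test suite).
.makePredictor <- function(records, tensor, orientation, constants,
                           siteClass, Bref = 11.7) {
  w <- .woessner(tensor@D, orientation / sqrt(sum(orientation^2)))
  kk <- w$k; AA <- w$A
  Jfun <- function(omega, amp, tau) {
    ## omega vector; amp/tau internal components (tau Inf = plateau)
    J <- numeric(length(omega))
    for (j in seq_along(kk)) {
      for (c in seq_along(amp)) {
        keff <- kk[j] + if (is.finite(tau[c])) 1 / tau[c] else 0
        te <- 1 / keff
        J <- J + AA[j] * amp[c] * te / (1 + (omega * te)^2)
      }
    }
    0.4 * J
  }
  fields <- unique(records$field_T)
  if (siteClass == "backbone") {
    d <- constants$mu0 * constants$hbar * constants$gammaH *
      abs(constants$gammaN) / (4 * pi * constants$rNH^3)
    gr <- constants$gammaH / constants$gammaN
    ftab <- lapply(fields, function(B0) {
      wH <- constants$gammaH * B0
      wN <- abs(constants$gammaN) * B0
      list(om = c(0, wN, wH - wN, wH, wH + wN),
           cc = wN * constants$csaN / sqrt(3),
           rexScale = (B0 / Bref)^2,
           rows = which(records$field_T == B0),
           types = records$rate_type[records$field_T == B0])
    })
    function(model, theta) {
      p <- .thetaToParams(model, theta)
      comp <- .mfComponents(p, "backbone")
      Rex <- if (is.null(p$Rex)) 0 else p$Rex
      pred <- numeric(nrow(records))
      for (ft in ftab) {
        J <- Jfun(ft$om, comp$amp, comp$tau)
        ## J: [J0, JN, JHmN, JH, JHpN]
        R1 <- (d^2 / 4) * (J[3] + 3 * J[2] + 6 * J[5]) + ft$cc^2 * J[2]
        R2 <- (d^2 / 8) * (4 * J[1] + J[3] + 3 * J[2] + 6 * J[4] +
                           6 * J[5]) +
          (ft$cc^2 / 6) * (4 * J[1] + 3 * J[2]) + Rex * ft$rexScale
        NOE <- 1 + gr * (d^2 / 4) * (6 * J[5] - J[3]) / R1
        r <- c(R1 = R1, R2 = R2, NOE = NOE)
        pred[ft$rows] <- r[ft$types]
      }
      pred
    }
  } else {
    wq <- 2 * pi * constants$qcc
    ftab <- lapply(fields, function(B0) {
      wD <- abs(constants$gammaD) * B0
      list(om = c(0, wD, 2 * wD),
           rows = which(records$field_T == B0),
           types = records$rate_type[records$field_T == B0])
    })
    function(model, theta) {
      p <- .thetaToParams(model, theta)
      comp <- .mfComponents(p, "methyl")
      pred <- numeric(nrow(records))
      for (ft in ftab) {
        J <- Jfun(ft$om, comp$amp, comp$tau)
        r <- c(R1Dz = (3 / 40) * wq^2 * (J[2] + 4 * J[3]),
               R3Dz2 = (9 / 40) * wq^2 * J[2],
               R2Dplus = (1 / 80) * wq^2 * (9 * J[1] + 15 * J[2] + 6 * J[3]),
               RDplusDz = (1 / 80) * wq^2 * (9 * J[1] + 3 * J[2] + 6 * J[3]))
        pred[ft$rows] <- r[ft$types]
      }
      pred
    }
  }
}

.predictSite <- function(theta, model, records, tensor, orientation,
                         constants, siteClass) {
  .makePredictor(records, tensor, orientation, constants,
                 siteClass)(model, theta)
}

.modelInfo <- function(siteClass) {
  if (siteClass == "backbone") {
    list(models = c("m1", "m2", "m3", "m4"),
         npar = c(m1 = 1, m2 = 2, m3 = 2, m4 = 3),
         lower = list(m1 = 0, m2 = c(0, 0), m3 = c(0, 0), m4 = c(0, 0, 0)),
         upper = list(m1 = 1, m2 = c(1, 5e-9), m3 = c(1, 100),
                      m4 = c(1, 5e-9, 100)),
         starts = list(
           m1 = lapply(c(0.5, 0.8, 0.95), function(x) x),
           m2 = do.call(c, lapply(c(0.5, 0.8, 0.95), function(o)
             lapply(c(20e-12, 200e-12, 1e-9), function(t) c(o, t)))),
           m3 = do.call(c, lapply(c(0.5, 0.8, 0.95), function(o)
             lapply(c(0.5, 3), function(r) c(o, r)))),
           m4 = do.call(c, lapply(c(0.6, 0.9), function(o)
             lapply(c(50e-12, 500e-12), function(t)
               lapply(c(0.5, 3), function(r) c(o, t, r)))))))
  } else {
    list(models = c("s2", "s3", "s4"),
         npar = c(s2 = 2, s3 = 3, s4 = 4),
         lower = list(s2 = c(0, 1e-14), s3 = c(0, 1e-14, 1e-12),
                      s4 = c(0, 0, 1e-14, 1e-12)),
         upper = list(s2 = c(1, 1e-9), s3 = c(1, 1e-9, 5e-8),
                      s4 = c(1, 1, 1e-9, 5e-8)),
         starts = list(
           s2 = do.call(c, lapply(c(0.4, 0.65, 0.9), function(o)
             lapply(c(10e-12, 50e-12), function(t) c(o, t)))),
           s3 = do.call(c, lapply(c(0.4, 0.7), function(o)
             lapply(c(30e-12), function(t)
               lapply(c(1e-9, 5e-9), function(s) c(o, t, s))))),
           s4 = do.call(c, lapply(c(0.6, 0.9), function(f)
             lapply(c(0.6, 0.9), function(s)
               lapply(c(30e-12), function(t) c(f, s, t, 2e-9)))))))
  }
}

.flattenStarts <- function(x, np) {
  ## nested lapply lists above can nest one level deep per parameter
  out <- list()
  rec <- function(e) {
    if (is.numeric(e) && length(e) == np) out[[length(out) + 1L]] <<- e
    else if (is.list(e)) for (ee in e) rec(ee)
    else if (is.numeric(e) && np == 1) out[[length(out) + 1L]] <<- e
  }
  rec(x)
  out
}

.fitOneModel <- function(model, records, predictor, info) {
  obs <- records$value; sd <- records$sd
  chisqFun <- function(theta) {
    p <- predictor(model, theta)
    s <- sum(((obs - p) / sd)^2)
    if (!is.finite(s)) 1e30 else s
  }
  np <- info$npar[[model]]
  lo <- info$lower[[model]]; hi <- info$upper[[model]]
  if (np == 1L) {
    o <- stats::optimize(function(x) chisqFun(x), lower = lo, upper = hi,
                         tol = 1e-10)
    return(list(model = model, theta = o$minimum, chisq = o$objective,
                npar = np))
  }
  best <- NULL
  for (st in .flattenStarts(info$starts[[model]], np)) {
    ## scale parameters so optim sees O(1) magnitudes
    sc <- pmax(abs(st), c(0.1, 1e-11, 0.1, 1e-10)[seq_len(np)])
    f <- function(z) chisqFun(pmin(pmax(z * sc, lo), hi))
    o <- stats::optim(st / sc, f, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) {
      best <- o; best$theta <- pmin(pmax(o$par * sc, lo), hi)
    }
  }
  list(model = model, theta = best$theta, chisq = best$value, npar = np)
}

#' Model-free fit of one site with nested-model selection
#'
#' Fits the nested model ladder (backbone: {O2}, {O2, taue}, {O2, Rex},
#' {O2, taue, Rex}; methyl: {O2, tauf}, {O2, tauf, taus}, {Of2, Os2, tauf,
#' taus}) by weighted least squares with multi-start optimization, then
#' selects a model.  With the default F-test criterion a larger model is
#' promoted only when it improves the fit significantly at alpha = 0.95
#' (p < 0.05); AIC selection is available as an option.  Monte-Carlo errors
#' come from refitting noise-resampled synthetic data.
#'
#' @param records data.frame of rate records (one site): columns
#'   \code{field_T}, \code{rate_type}, \code{value}, \code{sd}.
#' @param tensor a \code{\link{diffusionTensor}}.
#' @param orientation bond unit vector in the tensor frame.
#' @param siteClass "backbone" or "methyl".
#' @param criterion "ftest" (default) or "aic".
#' @param alpha significance threshold of the F-test (default 0.05).
#' @param nMc Monte-Carlo samples for parameter errors (0 = skip).
#' @param constants \code{\link{spinConstants}}.
#' @param seed optional seed for the Monte-Carlo resampling.
#' @return list of class \code{modelFreeFit}: \code{model}, \code{params}
#'   (named list), \code{sd} (MC standard deviations, if computed),
#'   \code{chisq}, \code{dof}, \code{allModels}, \code{underdetermined}.
#' @export
fitSite <- function(records, tensor, orientation = c(0, 0, 1),
                    siteClass = c("backbone", "methyl"),
                    criterion = c("ftest", "aic"), alpha = 0.05,
                    nMc = 0, constants = spinConstants(), seed = NULL) {
  siteClass <- match.arg(siteClass)
  criterion <- match.arg(criterion)
  records <- records[order(records$field_T, records$rate_type), , drop = FALSE]
  info <- .modelInfo(siteClass)
  n <- nrow(records)
  if (n < max(info$npar)) {
    return(structure(list(model = NA_character_, params = NULL, sd = NULL,
                          chisq = NA_real_, dof = NA_integer_,
                          allModels = NULL, underdetermined = TRUE),
                     class = "modelFreeFit"))
  }
  predictor <- .makePredictor(records, tensor, orientation, constants,
                              siteClass)
  fits <- lapply(info$models, .fitOneModel, records = records,
                 predictor = predictor, info = info)
  names(fits) <- info$models

  pick <- fits[[1]]
  if (criterion == "aic") {
    aic <- vapply(fits, function(f) f$chisq + 2 * f$npar, 0)
    pick <- fits[[which.min(aic)]]
  } else {
    repeat {
      cand <- Filter(function(f) f$npar > pick$npar && n > f$npar, fits)
      if (!length(cand)) break
      pv <- vapply(cand, function(f) {
        d1 <- f$npar - pick$npar
        d2 <- n - f$npar
        if (f$chisq <= .Machine$double.eps * n) {
          ## perfect fit of the larger model: promote only if the smaller
          ## model misfits
          return(if (pick$chisq > 1e-8 * n) 0 else 1)
        }
        F <- ((pick$chisq - f$chisq) / d1) / (f$chisq / d2)
        stats::pf(F, d1, d2, lower.tail = FALSE)
      }, 0)
      if (min(pv) < alpha) {
        pick <- cand[[which.min(pv)]]
      } else break
    }
  }

  sdOut <- NULL
  if (nMc > 0) {
    if (!is.null(seed)) set.seed(seed)
    pred <- predictor(pick$model, pick$theta)
    draws <- vapply(seq_len(nMc), function(i) {
      rr <- records
      rr$value <- pred + stats::rnorm(n, 0, records$sd)
      f <- .fitOneModel(pick$model, rr, predictor, info)
      f$theta
    }, numeric(length(pick$theta)))
    sdOut <- apply(matrix(draws, nrow = length(pick$theta)), 1, stats::sd)
    names(sdOut) <- names(.thetaToParams(pick$model, pick$theta))
  }
  structure(list(model = pick$model,
                 params = .thetaToParams(pick$model, pick$theta),
                 sd = sdOut, chisq = pick$chisq, dof = n - pick$npar,
                 allModels = lapply(fits, function(f)
                   list(model = f$model, chisq = f$chisq, npar = f$npar)),
                 underdetermined = FALSE),
            class = "modelFreeFit")
}

#' @export
print.modelFreeFit <- function(x, ...) {
  if (isTRUE(x$underdetermined)) {
    cat("modelFreeFit: under-determined site, no fit\n")
    return(invisible(x))
  }
  cat("modelFreeFit: model", x$model, "| chisq =", signif(x$chisq, 4),
      "dof =", x$dof, "\n  ")
  cat(paste(names(x$params), signif(unlist(x$params), 4), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

## zyz Euler rotation matrix (maps PAS coordinates to lab coordinates)
.eulerZYZ <- function(a, b, g) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  matrix(c(ca * cb * cg - sa * sg, sa * cb * cg + ca * sg, -sb * cg,
           -ca * cb * sg - sa * cg, -sa * cb * sg + ca * cg, sb * sg,
           ca * sb, sa * sb, cb), 3, 3)
}

## lab-frame unit vectors -> tensor PAS
.toPAS <- function(vectors, angles) {
  Rm <- .eulerZYZ(angles[1], angles[2], angles[3])
  t(crossprod(Rm, t(vectors)))
}

#' Fit the rotational diffusion tensor from multi-site relaxation data
#'
#' Alternating refinement: per-site local model-free fits (with model
#' selection) given the current tensor, then tensor optimization given the
#' local parameters, iterated to convergence of the global chi-square.
#' Rigid-site preselection keeps sites with NOE above a threshold at the
#' highest field and no exchange-model preference.
#'
#' @param records data.frame of rate records for many sites: columns
#'   \code{site}, \code{field_T}, \code{rate_type}, \code{value}, \code{sd}.
#' @param vectors matrix (nSites x 3) of NH unit vectors in the lab frame,
#'   rownames matching the site labels; see \code{\link{nhVectors}}.
#' @param shape "isotropic", "axial" or "rhombic".
#' @param preselect apply the rigid-site filter (default TRUE).
#' @param noeThreshold NOE cutoff at the highest field (default 0.65).
#' @param constants \code{\link{spinConstants}}.
#' @param maxIter maximum alternating-refinement rounds.
#' @return list of class \code{tensorFit}: \code{tensor}
#'   (a \code{\link{diffusionTensor}}), \code{tauc}, \code{zeta}, \code{eta},
#'   \code{chisq}, \code{sites} (site labels used), \code{localFits}.
#' @export
fitDiffusionTensor <- function(records, vectors,
                               shape = c("isotropic", "axial", "rhombic"),
                               preselect = TRUE, noeThreshold = 0.65,
                               constants = spinConstants(), maxIter = 10) {
  shape <- match.arg(shape)
  sites <- intersect(unique(records$site), rownames(vectors))
  if (preselect) {
    hiField <- max(records$field_T)
    noe <- records[records$rate_type == "NOE" & records$field_T == hiField, ]
    rigid <- noe$site[noe$value > noeThreshold]
    sites <- intersect(sites, rigid)
  }
  if (length(sites) < 10)
    stop("need at least 10 rigid sites for tensor fitting (have ",
         length(sites), ")")
  V <- vectors[sites, , drop = FALSE]
  ## degenerate geometry: warn and fall back to isotropic
  if (shape != "isotropic") {
    sv <- svd(scale(V, scale = FALSE))$d
    if (sv[2] < 1e-3 * sv[1]) {
      warning("NH vectors nearly parallel; falling back to isotropic tensor")
      shape <- "isotropic"
    }
  }
  recBySite <- split(records[records$site %in% sites, ],
                     records$site[records$site %in% sites])
  recBySite <- recBySite[sites]

  globalChisq <- function(tensor, locals) {
    U <- .toPAS(V, tensor@angles)
    s <- 0
    for (i in seq_along(sites)) {
      f <- locals[[i]]
      if (isTRUE(f$underdetermined)) next
      pr <- .makePredictor(recBySite[[i]], tensor, U[i, ], constants,
                           "backbone")
      pred <- pr(f$model, unlist(f$params, use.names = FALSE))
      s <- s + sum(((recBySite[[i]]$value - pred) / recBySite[[i]]$sd)^2)
    }
    s
  }
  refitLocals <- function(tensor) {
    U <- .toPAS(V, tensor@angles)
    lapply(seq_along(sites), function(i)
      fitSite(recBySite[[i]], tensor, U[i, ], "backbone",
              constants = constants))
  }

  ## analytic tau_c start from the R2/R1 ratio at the highest field
  hiF <- max(records$field_T)
  r1 <- records[records$site %in% sites & records$field_T == hiF &
                  records$rate_type == "R1", c("site", "value")]
  r2 <- records[records$site %in% sites & records$field_T == hiF &
                  records$rate_type == "R2", c("site", "value")]
  m <- merge(r1, r2, by = "site")
  wN <- abs(constants$gammaN) * hiF
  ratio <- stats::median(m$value.y / m$value.x)
  tauc0 <- sqrt(max(6 * ratio - 7, 0.5)) / (2 * wN)
  if (!is.finite(tauc0) || tauc0 < 1e-9 || tauc0 > 3e-8) tauc0 <- 7e-9

  makeTensor <- function(p) {
    switch(shape,
      isotropic = isotropicTensor(p[1]),
      axial = axialTensor(p[1], p[2], c(p[3], p[4], 0)),
      rhombic = {
        Diso <- 1 / (6 * p[1])
        ## parametrize by (tauc, zeta, eta-like spread, angles)
        Dz <- Diso * 3 * p[2] / (2 + p[2])
        Dper <- (3 * Diso - Dz) / 2
        delta <- p[5] * Dper * 0.999
        diffusionTensor(c(Dper - delta, Dper + delta, Dz),
                        c(p[3], p[4], p[6]))
      })
  }
  p0 <- switch(shape,
    isotropic = tauc0,
    axial = c(tauc0, 1.1, 0.5, 0.5),
    rhombic = c(tauc0, 1.1, 0.5, 0.5, 0.1, 0.5))

  tensor <- makeTensor(p0)
  locals <- refitLocals(tensor)
  chi <- globalChisq(tensor, locals)
  for (it in seq_len(maxIter)) {
    obj <- function(p) {
      if (p[1] <= 1e-10 || p[1] > 5e-8) return(1e30)
      if (length(p) >= 2 && (p[2] <= 0.2 || p[2] > 5)) return(1e30)
      if (length(p) >= 5 && (p[5] < 0 || p[5] >= 1)) return(1e30)
      globalChisq(makeTensor(p), locals)
    }
    if (shape == "isotropic") {
      op <- stats::optimize(function(tc) obj(tc),
                            interval = c(0.5 * p0[1], 2 * p0[1]),
                            tol = 1e-13)
      p0 <- op$minimum
    } else {
      ## several axis starts guard against orientation local minima
      bestp <- NULL; bestv <- Inf
      axStarts <- if (it == 1) list(c(0.3, 0.3), c(1.2, 0.8), c(0.8, 2.2),
                                    c(p0[3], p0[4]))
                  else list(c(p0[3], p0[4]))
      for (ax in axStarts) {
        pTry <- p0; pTry[3] <- ax[1]; pTry[4] <- ax[2]
        o <- stats::optim(pTry, obj, method = "Nelder-Mead",
                          control = list(maxit = 800, reltol = 1e-10,
                                         parscale = abs(pTry) + 1e-10))
        if (o$value < bestv) { bestv <- o$value; bestp <- o$par }
      }
      p0 <- bestp
    }
    tensor <- makeTensor(p0)
    locals <- refitLocals(tensor)
    newChi <- globalChisq(tensor, locals)
    if (abs(chi - newChi) < 1e-6 * max(chi, 1)) { chi <- newChi; break }
    chi <- newChi
  }
  ze <- anisotropyRhombicity(tensor@D[1], tensor@D[2], tensor@D[3])
  names(locals) <- sites
  structure(list(tensor = tensor, tauc = tauC(tensor),
                 zeta = unname(ze["zeta"]), eta = unname(ze["eta"]),
                 chisq = chi, sites = sites, localFits = locals),
            class = "tensorFit")
}

#' @export
print.tensorFit <- function(x, ...) {
  cat(sprintf("Diffusion tensor fit: tauc = %.3f ns, zeta = %.3f, eta = %.3f (%d sites, chisq %.3g)\n",
              x$tauc * 1e9, x$zeta, x$eta, length(x$sites), x$chisq))
  invisible(x)
}

#' NH bond unit vectors from a PDB structure
#'
#' Extracts amide N-H unit vectors from a protonated structure read with
#' \code{bio3d::read.pdb}.
#'
#' @param pdb a \code{bio3d} pdb object (must contain amide protons named
#'   H or HN).
#' @param chain optional chain identifier.
#' @return matrix (nResidues x 3) of unit vectors, rownames = residue numbers.
#' @export
nhVectors <- function(pdb, chain = NULL) {
  a <- pdb$atom
  if (!is.null(chain)) a <- a[a$chain %in% chain, ]
  out <- list()
  for (res in unique(a$resno)) {
    sub <- a[a$resno == res, ]
    iN <- which(sub$elety == "N")
    iH <- which(sub$elety %in% c("H", "HN"))
    if (length(iN) == 1 && length(iH) >= 1) {
      v <- c(sub$x[iH[1]] - sub$x[iN], sub$y[iH[1]] - sub$y[iN],
             sub$z[iH[1]] - sub$z[iN])
      out[[as.character(res)]] <- v / sqrt(sum(v^2))
    }
  }
  do.call(rbind, out)
}
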