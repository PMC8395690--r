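## Single-site ITC binding model: perfusion dilution bookkeeping, Wiseman-type
## per-injection heats, global replicate fitting, and derived thermodynamics.
##
## Conventions: volumes in litres, concentrations in mol/L, enthalpies in
## kJ/mol, heats in the unit the thermograms are recorded in (microjoules in
## all shipped examples; Qoff shares that unit).

#' Total cell concentrations after a number of injections
#'
#' Perfusion (overfill) model: each injection displaces its own volume of
#' well-mixed cell contents, so every injection of volume v dilutes the
#' current contents by (1 - v/V0) and delivers syringe material at v/V0.
#' For constant injection volume v this gives the familiar closed forms
#' X_i = X0 (1 - v/V0)^i and M_i = Msyr [1 - (1 - v/V0)^i], with the protein
#' (titrant) M in the syringe and the ligand X in the cell.
#'
#' @param scheme a \code{\link{titrationScheme}}.
#' @param injectionIndex number of completed injections, 0..nInjections;
#'   0 returns the pre-titration state (0, cellConc).
#' @return named numeric c(M = ..., X = ...) in mol/L.
#' @export
cellConcentrations <- function(scheme, injectionIndex) {
  ni <- nInjections(scheme)
  if (injectionIndex < 0 || injectionIndex > ni)
    stop("injectionIndex out of range 0..", ni)
  M <- 0; X <- scheme@cellConc
  if (injectionIndex > 0) {
    for (i in seq_len(injectionIndex)) {
      f <- scheme@injectionVolumes[i] / scheme@V0
      M <- M * (1 - f) + scheme@syringeConc * f
      X <- X * (1 - f)
    }
  }
  c(M = M, X = X)
}

.cellConcProfile <- function(scheme) {
  ni <- nInjections(scheme)
  M <- numeric(ni); X <- numeric(ni)
  m <- 0; x <- scheme@cellConc
  for (i in seq_len(ni)) {
    f <- scheme@injectionVolumes[i] / scheme@V0
    m <- m * (1 - f) + scheme@syringeConc * f
    x <- x * (1 - f)
    M[i] <- m; X[i] <- x
  }
  list(M = M, X = X)
}

#' Equilibrium complex concentration under single-site binding
#'
#' Solves the mass-action quadratic for the complex concentration:
#' [PL] = (alpha - sqrt(alpha^2 - 4 n M X)) / 2 with
#' alpha = n M + X + Kd, evaluated in a cancellation-safe form.
#'
#' @param Mtot total protein concentration, mol/L (vectorized).
#' @param Xtot total ligand concentration, mol/L (vectorized).
#' @param params a \code{\link{bindingParams}} object.
#' @return complex concentration, mol/L; bounded by min(n Mtot, Xtot).
#' @export
complexConcentration <- function(Mtot, Xtot, params) {
  stopifnot(all(Mtot >= 0), all(Xtot >= 0))
  n <- params@n; Kd <- params@Kd
  alpha <- n * Mtot + Xtot + Kd
  disc <- pmax(alpha^2 - 4 * n * Mtot * Xtot, 0)
  ## (alpha - sqrt(disc))/2 rewritten to avoid cancellation when Kd is small
  2 * n * Mtot * Xtot / (alpha + sqrt(disc))
}

#' Predicted per-injection heats (Wiseman isotherm)
#'
#' Cumulative heat after injection i is Q_i = V0 * dH * [PL]_i (converted to
#' microjoule-scale heat units); the observed differential heat corrects for
#' the displaced volume:
#' q_i = Q_i - Q_{i-1} + (V_i/V0) * (Q_i + Q_{i-1})/2 + Qoff.
#'
#' @param scheme a \code{\link{titrationScheme}}.
#' @param params a \code{\link{bindingParams}}; \code{dH} in kJ/mol,
#'   \code{Qoff} in heat units (first element used).
#' @param heatUnit multiplicative conversion from kJ to the heat unit of the
#'   thermogram; default 1e9 (microjoules).
#' @return numeric vector of per-injection heats.
#' @export
predictedHeats <- function(scheme, params, heatUnit = 1e9) {
  conc <- .cellConcProfile(scheme)
  PL <- complexConcentration(conc$M, conc$X, params)
  Q <- scheme@V0 * params@dH * PL * heatUnit
  Qprev <- c(0, Q[-length(Q)])
  v <- scheme@injectionVolumes / scheme@V0
  Q - Qprev + v * (Q + Qprev) / 2 + params@Qoff[1]
}

#' Global single-site fit over replicate titrations
#'
#' Fits one shared set of (n, Kd, dH) plus one heat offset Qoff per replicate
#' to all thermograms simultaneously, by weighted least squares
#' (Levenberg-Marquardt on log Kd).  Parameter standard deviations come from
#' the fit covariance, scaled by the reduced chi-square.
#'
#' @param thermograms list of \code{\link{thermogram}} objects (>= 1).
#' @param init optional \code{\link{bindingParams}} start values; a heuristic
#'   start is derived from the data when omitted.
#' @param excludeFirst drop injection 1 of each replicate from the fit
#'   (common practice for the diffusion-compromised first injection).
#' @param heatUnit see \code{\link{predictedHeats}}.
#' @return list of class \code{itcFit}: \code{params} (a
#'   \code{BindingParams} with per-replicate Qoff), \code{sd} (named vector
#'   for n, Kd, dH, Qoff...), \code{chisq}, \code{dof}, \code{residuals},
#'   \code{converged}.
#' @export
fitGlobal <- function(thermograms, init = NULL, excludeFirst = FALSE,
                      heatUnit = 1e9) {
  if (is(thermograms, "Thermogram")) thermograms <- list(thermograms)
  nrep <- length(thermograms)
  stopifnot(nrep >= 1)
  keep <- lapply(thermograms, function(tg) {
    k <- seq_along(tg@heats)
    if (excludeFirst) k[-1] else k
  })
  nobs <- sum(lengths(keep))
  if (nobs < 5L) stop("need at least 5 informative injections in total")

  if (is.null(init)) {
    sch <- thermograms[[1]]@scheme
    dH0 <- sum(thermograms[[1]]@heats - stats::median(thermograms[[1]]@heats[
      max(1, length(thermograms[[1]]@heats) - 2):length(thermograms[[1]]@heats)])) /
      (sch@V0 * min(sch@syringeConc, sch@cellConc) * heatUnit)
    if (!is.finite(dH0) || dH0 == 0) dH0 <- -40
    init <- bindingParams(n = 1, Kd = 1e-6, dH = dH0,
                          Qoff = rep(0, nrep))
  }
  q0 <- if (length(init@Qoff) == nrep) init@Qoff else rep(init@Qoff[1], nrep)
  par0 <- c(n = init@n, lKd = log(init@Kd), dH = init@dH,
            stats::setNames(q0, paste0("Qoff", seq_len(nrep))))

  residFun <- function(p) {
    unlist(lapply(seq_len(nrep), function(r) {
      tg <- thermograms[[r]]
      bp <- new("BindingParams", n = min(max(p[["n"]], 1e-3), 2),
                Kd = exp(p[["lKd"]]), dH = p[["dH"]],
                Qoff = p[[paste0("Qoff", r)]])
      pred <- predictedHeats(tg@scheme, bp, heatUnit)
      ((tg@heats - pred) / pmax(tg@sd, .Machine$double.eps))[keep[[r]]]
    }))
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = residFun,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0, 5) || any(!is.finite(fit$par)))
    stop("fit failure: global ITC fit did not converge; final residual norm ",
         signif(sqrt(fit$deviance), 4))
  p <- fit$par
  dof <- nobs - length(p)
  redchi <- fit$deviance / max(dof, 1)
  cv <- tryCatch(solve(fit$hessian) * redchi * 2,
                 error = function(e) matrix(NA_real_, length(p), length(p)))
  ## nls.lm hessian ~ 2 J'J; vcov = redchi * (J'J)^-1
  sds <- sqrt(pmax(diag(cv), 0))
  names(sds) <- names(p)
  KdHat <- exp(p[["lKd"]])
  sd <- c(n = unname(sds["n"]), Kd = KdHat * unname(sds["lKd"]),
          dH = unname(sds["dH"]),
          stats::setNames(unname(sds[paste0("Qoff", seq_len(nrep))]),
                          paste0("Qoff", seq_len(nrep))))
  params <- new("BindingParams", n = p[["n"]], Kd = KdHat, dH = p[["dH"]],
                Qoff = unname(p[paste0("Qoff", seq_len(nrep))]))
  structure(list(params = params, sd = sd, chisq = fit$deviance, dof = dof,
                 residuals = fit$fvec, converged = TRUE),
            class = "itcFit")
}

#' @export
print.itcFit <- function(x, ...) {
  p <- x$params
  cat("Global single-site ITC fit\n")
  cat(sprintf("  n    = %.4f +/- %.4f\n", p@n, x$sd["n"]))
  cat(sprintf("  Kd   = %.3g +/- %.2g M\n", p@Kd, x$sd["Kd"]))
  cat(sprintf("  dH   = %.2f +/- %.2f kJ/mol\n", p@dH, x$sd["dH"]))
  cat(sprintf("  Qoff = %s\n", paste(signif(p@Qoff, 3), collapse = ", ")))
  cat(sprintf("  chisq/dof = %.3f (dof %d)\n", x$chisq / max(x$dof, 1), x$dof))
  invisible(x)
}

#' Derived binding thermodynamics
#'
#' dG = R T ln(Kd) with Kd in mol/L (standard state 1 M) and
#' -T dS = dG - dH; errors propagated assuming independence.
#'
#' @param Kd dissociation constant, mol/L.
#' @param dH binding enthalpy, kJ/mol.
#' @param temperature kelvin (default 301.1, the ITC temperature of the
#'   experiments this package was built around).
#' @param KdSd,dHSd standard deviations of Kd (mol/L) and dH (kJ/mol).
#' @return a \code{\link{ThermoSummary-class}} object.
#' @examples
#' deriveThermodynamics(2.0e-6, -50.4)   # dG = -32.9, -TdS = 17.5 kJ/mol
#' @export
deriveThermodynamics <- function(Kd, dH, temperature = 301.1,
                                 KdSd = 0, dHSd = 0) {
  if (!is.finite(Kd) || Kd <= 0) stop("invalid input: Kd must be positive")
  if (temperature <= 0) stop("invalid input: temperature must be positive")
  Kd <- unname(Kd); dH <- unname(dH); KdSd <- unname(KdSd); dHSd <- unname(dHSd)
  dG <- .R_GAS * temperature * log(Kd) / 1000
  mTdS <- dG - dH
  dGsd <- .R_GAS * temperature * (KdSd / Kd) / 1000
  sd <- c(dG = dGsd, dH = dHSd, mTdS = sqrt(dGsd^2 + dHSd^2))
  new("ThermoSummary", dG = dG, dH = dH, mTdS = mTdS, Kd = Kd,
      temperature = temperature, sd = sd)
}

#' Fractional saturation of the limiting species
#'
#' Complex concentration divided by min(n Mtot, Xtot).
#'
#' @inheritParams complexConcentration
#' @return saturation in [0, 1].
#' @export
saturation <- function(Mtot, Xtot, params) {
  if (all(Mtot == 0) && all(Xtot == 0))
    stop("invalid input: both totals are zero")
  lim <- pmin(params@n * Mtot, Xtot)
  complexConcentration(Mtot, Xtot, params) / lim
}

#' Read a titration scheme from a YAML config
#'
#' Expected keys: \code{V0_uL}, \code{syringe_uM}, \code{cell_uM},
#' \code{temperature_K}, and either \code{injection_uL} (scalar plus
#' \code{n_injections}, or a list).
#'
#' @param path YAML file path.
#' @return a \code{\link{titrationScheme}}.
#' @export
readTitrationScheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  vol <- unlist(cfg$injection_uL) * 1e-6
  if (length(vol) == 1L && !is.null(cfg$n_injections))
    vol <- rep(vol, cfg$n_injections)
  titrationScheme(V0 = cfg$V0_uL * 1e-6, injectionVolumes = vol,
                  syringeConc = cfg$syringe_uM * 1e-6,
                  cellConc = cfg$cell_uM * 1e-6,
                  temperature = cfg$temperature_K)
}

#' Read / write thermogram CSVs
#'
#' Columns \code{injection,volume_uL,heat_uJ} plus optional \code{sd}.  The
#' scheme supplies cell volume, concentrations and temperature; injection
#' volumes are taken from the CSV.
#'
#' @param path CSV path.
#' @param scheme a \code{\link{titrationScheme}} carrying V0, concentrations
#'   and temperature (its injection volumes are replaced by the CSV's).
#' @return a \code{\link{thermogram}}.
#' @export
readThermogram <- function(path, scheme) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("injection", "volume_uL", "heat_uJ")
  if (!all(need %in% names(df)))
    stop("thermogram CSV must have columns: ", paste(need, collapse = ","))
  df <- df[order(df$injection), ]
  sch <- titrationScheme(V0 = scheme@V0,
                         injectionVolumes = df$volume_uL * 1e-6,
                         syringeConc = scheme@syringeConc,
                         cellConc = scheme@cellConc,
                         temperature = scheme@temperature)
  thermogram(df$heat_uJ, sch, sd = if ("sd" %in% names(df)) df$sd else 1)
}

#' @rdname readThermogram
#' @param tg a \code{\link{thermogram}} to write.
#' @export
writeThermogram <- function(tg, path) {
  df <- data.frame(injection = seq_along(tg@heats),
                   volume_uL = tg@scheme@injectionVolumes * 1e6,
                   heat_uJ = tg@heats, sd = tg@sd)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
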