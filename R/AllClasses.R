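#' @import methods
NULL

## Gas constant, J mol^-1 K^-1, used throughout.
.R_GAS <- 8.314

## Rate types understood by the measurement layer.  The four deuterium entries
## are the standard methyl 2H coherences: R1(Dz), R(3Dz^2-2), R2(D+) and
## R(D+Dz + DzD+).
.RATE_TYPES <- c("R1", "R2", "NOE", "R1Dz", "R3Dz2", "R2Dplus", "RDplusDz")

#' TitrationScheme: injection bookkeeping for an ITC experiment
#'
#' Holds the cell volume, the per-injection volumes, the syringe and initial
#' cell concentrations, and the temperature.  In the experiments this package
#' was built around, the titrant in the syringe is the protein and the cell
#' holds the ligand.
#'
#' @slot V0 cell volume in litres.
#' @slot injectionVolumes numeric vector of injection volumes in litres.
#' @slot syringeConc syringe (titrant, protein) concentration in mol/L.
#' @slot cellConc initial cell (ligand) concentration in mol/L.
#' @slot temperature temperature in kelvin.
#' @exportClass TitrationScheme
setClass("TitrationScheme",
  representation(
    V0 = "numeric",
    injectionVolumes = "numeric",
    syringeConc = "numeric",
    cellConc = "numeric",
    temperature = "numeric"
  )
)

setValidity("TitrationScheme", function(object) {
  msg <- character()
  if (length(object@V0) != 1L || !is.finite(object@V0) || object@V0 <= 0)
    msg <- c(msg, "V0 must be a single positive number (litres)")
  if (length(object@injectionVolumes) < 1L || any(!is.finite(object@injectionVolumes)) ||
      any(object@injectionVolumes <= 0))
    msg <- c(msg, "injectionVolumes must all be positive")
  if (object@syringeConc < 0 || object@cellConc < 0)
    msg <- c(msg, "concentrations must be non-negative")
  if (object@temperature <= 0)
    msg <- c(msg, "temperature must be positive (kelvin)")
  if (length(msg)) msg else TRUE
})

#' Construct a TitrationScheme
#'
#' @param V0 cell volume, litres.
#' @param injectionVolumes injection volumes, litres; a scalar is recycled to
#'   \code{nInjections}.
#' @param syringeConc syringe (protein) concentration, mol/L.
#' @param cellConc initial cell (ligand) concentration, mol/L.
#' @param temperature temperature, K.
#' @param nInjections number of injections when \code{injectionVolumes} is a
#'   scalar.
#' @return a \code{TitrationScheme} object.
#' @examples
#' sch <- titrationScheme(V0 = 250e-6, injectionVolumes = 2e-6,
#'                        syringeConc = 100e-6, cellConc = 1000e-6,
#'                        temperature = 301.1, nInjections = 20)
#' @export
titrationScheme <- function(V0, injectionVolumes, syringeConc, cellConc,
                            temperature = 301.1, nInjections = NULL) {
  if (length(injectionVolumes) == 1L && !is.null(nInjections))
    injectionVolumes <- rep(injectionVolumes, nInjections)
  new("TitrationScheme", V0 = V0, injectionVolumes = injectionVolumes,
      syringeConc = syringeConc, cellConc = cellConc, temperature = temperature)
}

#' @describeIn titrationScheme number of injections in a scheme.
#' @param scheme a \code{TitrationScheme}.
#' @export
nInjections <- function(scheme) length(scheme@injectionVolumes)

setMethod("show", "TitrationScheme", function(object) {
  cat("TitrationScheme:", length(object@injectionVolumes), "injections,",
      sprintf("V0 = %.1f uL,", object@V0 * 1e6),
      sprintf("syringe %.1f uM -> cell %.1f uM,", object@syringeConc * 1e6,
              object@cellConc * 1e6),
      sprintf("T = %.1f K\n", object@temperature))
})

#' BindingParams: single-site binding model parameters
#'
#' @slot n fraction of binding-competent protein (dimensionless, in (0, 2]).
#' @slot Kd dissociation constant, mol/L.
#' @slot dH binding enthalpy, kJ/mol.
#' @slot Qoff per-replicate heat offset(s), same units as the measured heats.
#' @exportClass BindingParams
setClass("BindingParams",
  representation(n = "numeric", Kd = "numeric", dH = "numeric", Qoff = "numeric")
)

setValidity("BindingParams", function(object) {
  msg <- character()
  if (!is.finite(object@Kd) || object@Kd <= 0)
    msg <- c(msg, "Kd must be positive")
  if (!is.finite(object@n) || object@n <= 0 || object@n > 2)
    msg <- c(msg, "n must lie in (0, 2]")
  if (length(msg)) msg else TRUE
})

#' Construct BindingParams
#'
#' @param n fraction of binding-competent protein.
#' @param Kd dissociation constant, mol/L.
#' @param dH binding enthalpy, kJ/mol.
#' @param Qoff heat offset (one value per replicate), units of the heats.
#' @return a \code{BindingParams} object.
#' @export
bindingParams <- function(n = 1, Kd, dH, Qoff = 0) {
  new("BindingParams", n = n, Kd = Kd, dH = dH, Qoff = Qoff)
}

setMethod("show", "BindingParams", function(object) {
  cat(sprintf("BindingParams: n = %.3f, Kd = %.3g M, dH = %.2f kJ/mol, Qoff = %s\n",
              object@n, object@Kd, object@dH,
              paste(signif(object@Qoff, 3), collapse = ", ")))
})

#' Thermogram: per-injection heats with uncertainties
#'
#' @slot heats numeric vector of per-injection heats (units chosen by the
#'   user; microjoules in the shipped examples).
#' @slot sd per-injection standard deviations, same units.
#' @slot scheme the \code{TitrationScheme} the heats were recorded under.
#' @exportClass Thermogram
setClass("Thermogram",
  representation(heats = "numeric", sd = "numeric", scheme = "TitrationScheme")
)

setValidity("Thermogram", function(object) {
  msg <- character()
  if (length(object@heats) != length(object@scheme@injectionVolumes))
    msg <- c(msg, "length(heats) must match the scheme's injection count")
  if (length(object@sd) != length(object@heats))
    msg <- c(msg, "length(sd) must match length(heats)")
  if (any(object@sd < 0)) msg <- c(msg, "sd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a Thermogram
#'
#' @param heats per-injection heats.
#' @param scheme a \code{TitrationScheme}.
#' @param sd per-injection standard deviations (scalar recycled).
#' @return a \code{Thermogram}.
#' @export
thermogram <- function(heats, scheme, sd = 1) {
  if (length(sd) == 1L) sd <- rep(sd, length(heats))
  new("Thermogram", heats = heats, sd = sd, scheme = scheme)
}

setMethod("show", "Thermogram", function(object) {
  cat("Thermogram:", length(object@heats), "injections, heat range",
      sprintf("[%.3g, %.3g]\n", min(object@heats), max(object@heats)))
})

#' ThermoSummary: derived binding thermodynamics
#'
#' Construction enforces the identity dG = dH + mTdS (mTdS denotes -T*dS).
#'
#' @slot dG binding free energy, kJ/mol.
#' @slot dH binding enthalpy, kJ/mol.
#' @slot mTdS entropic term -T*dS, kJ/mol.
#' @slot Kd dissociation constant, mol/L.
#' @slot temperature kelvin.
#' @slot sd named numeric vector of standard deviations (dG, dH, mTdS).
#' @exportClass ThermoSummary
setClass("ThermoSummary",
  representation(dG = "numeric", dH = "numeric", mTdS = "numeric",
                 Kd = "numeric", temperature = "numeric", sd = "numeric")
)

setValidity("ThermoSummary", function(object) {
  if (abs(object@dG - (object@dH + object@mTdS)) > 1e-9)
    "dG must equal dH + mTdS (construction identity)"
  else TRUE
})

setMethod("show", "ThermoSummary", function(object) {
  cat(sprintf("ThermoSummary at %.1f K: Kd = %.3g M\n", object@temperature, object@Kd))
  cat(sprintf("  dG   = %7.2f +/- %.2f kJ/mol\n", object@dG, object@sd["dG"]))
  cat(sprintf("  dH   = %7.2f +/- %.2f kJ/mol\n", object@dH, object@sd["dH"]))
  cat(sprintf("  -TdS = %7.2f +/- %.2f kJ/mol\n", object@mTdS, object@sd["mTdS"]))
})

#' DiffusionTensor: rotational diffusion tensor
#'
#' Principal values are stored sorted ascending (DXX <= DYY <= DZZ); the
#' orientation maps the laboratory frame onto the tensor principal axis
#' system by three z-y-z Euler angles.
#'
#' @slot D numeric length-3, principal values in s^-1, ascending.
#' @slot angles numeric length-3, z-y-z Euler angles in radians.
#' @exportClass DiffusionTensor
setClass("DiffusionTensor",
  representation(D = "numeric", angles = "numeric")
)

setValidity("DiffusionTensor", function(object) {
  msg <- character()
  if (length(object@D) != 3L || any(!is.finite(object@D)) || any(object@D <= 0))
    msg <- c(msg, "D must be three positive principal values")
  if (is.unsorted(object@D)) msg <- c(msg, "principal values must be ascending")
  if (length(object@angles) != 3L) msg <- c(msg, "angles must have length 3")
  if (length(msg)) msg else TRUE
})

#' Construct a DiffusionTensor
#'
#' @param D principal values (s^-1), any order; sorted ascending internally.
#' @param angles z-y-z Euler angles (radians) carrying the principal axis
#'   system orientation; default aligned with the laboratory frame.
#' @return a \code{DiffusionTensor}.
#' @seealso \code{\link{isotropicTensor}}, \code{\link{axialTensor}}
#' @export
diffusionTensor <- function(D, angles = c(0, 0, 0)) {
  new("DiffusionTensor", D = sort(D), angles = angles)
}

#' Isotropic diffusion tensor from a correlation time
#'
#' @param tauc overall rotational correlation time, seconds.
#' @return a \code{DiffusionTensor} with DXX = DYY = DZZ = 1/(6 tauc).
#' @export
isotropicTensor <- function(tauc) {
  D <- 1 / (6 * tauc)
  diffusionTensor(c(D, D, D))
}

#' Axially symmetric diffusion tensor
#'
#' @param tauc correlation time 1/(6 Diso), seconds.
#' @param zeta anisotropy 2 DZZ / (DXX + DYY).
#' @param angles z-y-z Euler angles of the unique axis, radians.
#' @return a \code{DiffusionTensor} with DXX = DYY.
#' @export
axialTensor <- function(tauc, zeta, angles = c(0, 0, 0)) {
  Diso <- 1 / (6 * tauc)
  ## Diso = (2 Dperp + Dpar)/3 and zeta = Dpar/Dperp
  Dperp <- 3 * Diso / (2 + zeta)
  Dpar <- zeta * Dperp
  diffusionTensor(c(Dperp, Dperp, Dpar), angles)
}

#' Overall rotational correlation time of a tensor
#'
#' @param tensor a \code{DiffusionTensor}.
#' @return tau_c = 1/(6 Diso) in seconds, Diso the mean principal value.
#' @export
tauC <- function(tensor) 1 / (6 * mean(tensor@D))

setMethod("show", "DiffusionTensor", function(object) {
  ze <- anisotropyRhombicity(object@D[1], object@D[2], object@D[3])
  cat(sprintf("DiffusionTensor: tauc = %.3g ns, zeta = %.3f, eta = %.3f\n",
              tauC(object) * 1e9, ze[["zeta"]], ze[["eta"]]))
})

#' OrderParameterTable: per-site generalized order parameters
#'
#' @slot residue integer residue numbers.
#' @slot restype three-letter residue types (upper case).
#' @slot siteClass "backbone" (amide NH) or "methyl" (methyl symmetry axis).
#' @slot O2 generalized order parameters in [0, 1).
#' @slot sd standard deviations of O2.
#' @slot site character site labels (residue + methyl identifier), unique.
#' @exportClass OrderParameterTable
setClass("OrderParameterTable",
  representation(residue = "integer", restype = "character",
                 siteClass = "character", O2 = "numeric", sd = "numeric",
                 site = "character")
)

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

setValidity("OrderParameterTable", function(object) {
  n <- length(object@residue)
  msg <- character()
  if (any(lengths(list(object@restype, object@siteClass, object@O2,
                       object@sd, object@site)) != n))
    msg <- c(msg, "all slots must have equal length")
  if (!all(object@restype %in% .AA3))
    msg <- c(msg, paste("unknown residue type(s):",
                        paste(unique(setdiff(object@restype, .AA3)), collapse = ", ")))
  if (!all(object@siteClass %in% c("backbone", "methyl")))
    msg <- c(msg, "siteClass must be 'backbone' or 'methyl'")
  if (any(object@O2 < 0 | object@O2 >= 1))
    msg <- c(msg, "O2 must lie in [0, 1) for entropy evaluation")
  if (any(object@sd < 0)) msg <- c(msg, "sd must be non-negative")
  if (anyDuplicated(object@site)) msg <- c(msg, "site labels must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct an OrderParameterTable
#'
#' Order parameters equal to or above 1 (possible from fit noise) are clipped
#' to 1 - 1e-6 with a warning, so that the log-ratio entropy stays finite
#' while flagging the suspect sites.
#'
#' @param residue integer residue numbers.
#' @param restype three-letter residue codes.
#' @param O2 order parameters.
#' @param sd standard deviations (default 0).
#' @param siteClass "backbone" or "methyl" (scalar recycled).
#' @param site optional site labels; defaults to residue numbers (plus an
#'   index suffix for duplicated residues, e.g. two methyls of one residue).
#' @return an \code{OrderParameterTable}.
#' @export
orderParameterTable <- function(residue, restype, O2, sd = 0,
                                siteClass = "backbone", site = NULL) {
  n <- length(residue)
  restype <- toupper(restype)
  if (length(sd) == 1L) sd <- rep(sd, n)
  if (length(siteClass) == 1L) siteClass <- rep(siteClass, n)
  if (is.null(site)) {
    site <- as.character(residue)
    if (anyDuplicated(site))
      site <- make.unique(site, sep = "_")
  }
  bad <- O2 >= 1
  if (any(bad)) {
    warning("O2 >= 1 clipped to 1 - 1e-6 at site(s): ",
            paste(site[bad], collapse = ", "))
    O2[bad] <- 1 - 1e-6
  }
  new("OrderParameterTable", residue = as.integer(residue), restype = restype,
      siteClass = siteClass, O2 = O2, sd = sd, site = site)
}

setMethod("show", "OrderParameterTable", function(object) {
  cat(sprintf("OrderParameterTable: %d sites (%d backbone, %d methyl), <O2> = %.3f\n",
              length(object@O2), sum(object@siteClass == "backbone"),
              sum(object@siteClass == "methyl"), mean(object@O2)))
})

setMethod("length", "OrderParameterTable", function(x) length(x@O2))

#' @export
as.data.frame.OrderParameterTable <- function(x, ...) {
  data.frame(site = x@site, residue = x@residue, restype = x@restype,
             site_class = x@siteClass, O2 = x@O2, sd = x@sd,
             stringsAsFactors = FALSE)
}

#' ShellScheme: radial shell edges around the ligand
#'
#' The default follows the analysis this package reimplements: 1 A-thick
#' shells from 2 to 9 A and 2 A-thick shells from 9 to 27 A.
#'
#' @slot edges strictly increasing shell edges in angstrom.
#' @exportClass ShellScheme
setClass("ShellScheme", representation(edges = "numeric"))

setValidity("ShellScheme", function(object) {
  if (length(object@edges) < 2L || any(diff(object@edges) <= 0))
    "edges must be strictly increasing with at least two values"
  else TRUE
})

#' Construct a ShellScheme
#'
#' @param edges shell edges, angstrom; default \code{c(2:9, seq(11, 27, 2))}.
#' @return a \code{ShellScheme}.
#' @export
shellScheme <- function(edges = c(2:9, seq(11, 27, by = 2))) {
  new("ShellScheme", edges = edges)
}

#' @describeIn shellScheme shell midpoints in angstrom.
#' @param scheme a \code{ShellScheme}.
#' @export
shellMidpoints <- function(scheme) {
  e <- scheme@edges
  (e[-length(e)] + e[-1]) / 2
}

setMethod("show", "ShellScheme", function(object) {
  cat("ShellScheme:", length(object@edges) - 1L, "shells spanning",
      sprintf("[%g, %g] A\n", min(object@edges), max(object@edges)))
})
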