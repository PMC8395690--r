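## Dihedral-histogram conformational entropy and iRED order parameters from
## trajectory time series (plain angle / bond-vector tables).

.wrapAngle <- function(x) ((x + 180) %% 360) - 180

#' Histogram entropy of a dihedral-angle distribution
#'
#' S = -R sum p ln p over occupied bins of the empirical angle distribution,
#' with 5 degree bins by default (72 bins per dihedral; 72 x 72 for a 2-D
#' phi/psi distribution).  Bins originate at -180 degrees; ties at bin edges
#' go to the upper bin; empty bins contribute zero.  Angles outside
#' [-180, 180) are wrapped with a warning.
#'
#' @param angles numeric vector of dihedral angles, degrees.
#' @param angles2 optional second angle vector (2-D phi/psi histogram).
#' @param binWidth bin width in degrees; must divide 360 (default 5).
#' @return entropy in J mol^-1 K^-1.
#' @examples
#' histogramEntropy(rep(10, 100))                       # 0
#' histogramEntropy(seq(-180, 175, by = 5))             # R ln 72
#' @export
histogramEntropy <- function(angles, angles2 = NULL, binWidth = 5) {
  if (360 %% binWidth != 0) stop("binWidth must divide 360")
  if (any(angles < -180 | angles >= 180)) {
    warning("angles outside [-180, 180) wrapped")
    angles <- .wrapAngle(angles)
  }
  nb <- as.integer(360 / binWidth)
  ix <- pmin(floor((angles + 180) / binWidth), nb - 1L)
  if (!is.null(angles2)) {
    if (any(angles2 < -180 | angles2 >= 180)) {
      warning("angles outside [-180, 180) wrapped")
      angles2 <- .wrapAngle(angles2)
    }
    iy <- pmin(floor((angles2 + 180) / binWidth), nb - 1L)
    ix <- ix * nb + iy
  }
  p <- tabulate(ix + 1L, nbins = if (is.null(angles2)) nb else nb * nb)
  p <- p[p > 0] / length(angles)
  -.R_GAS * sum(p * log(p))
}

#' Normalize a histogram entropy to the free rotor
#'
#' Referenced to the uniform (maximally disordered) distribution over the
#' same bins: -T dS = -T (S - S_free) with S_free = R ln(nbins) per
#' dihedral (R ln 72 for 5 degree bins; R ln 72^2 for a 2-D distribution).
#' The result is >= 0 in this -T dS convention and is 0 exactly for the
#' uniform distribution.
#'
#' @param S raw entropy, J mol^-1 K^-1 (from
#'   \code{\link{histogramEntropy}}).
#' @param dimensionality 1 or 2.
#' @param temperature kelvin (default 301).
#' @param binWidth bin width in degrees used for \code{S}.
#' @return -T dS in kJ/mol.
#' @examples
#' normalizeFreeRotor(0)  # single-bin distribution: R T ln 72 = 10.70
#' @export
normalizeFreeRotor <- function(S, dimensionality = 1, temperature = 301,
                               binWidth = 5) {
  nb <- 360 / binWidth
  Sfree <- .R_GAS * log(nb^dimensionality)
  -temperature * (S - Sfree) / 1000
}

#' Block-averaged dihedral entropy with standard errors
#'
#' Splits an angle time series into consecutive windows (default 5 ns of
#' 10 ps-sampled data, i.e. 500 snapshots per block), evaluates the
#' free-rotor-normalized entropy per block, and reports mean and standard
#' error over blocks.  A trailing partial window is truncated with a
#' warning.
#'
#' @param angles dihedral angle series, degrees.
#' @param angles2 optional second series (2-D phi/psi).
#' @param windowNs block length, ns (default 5).
#' @param samplingPs sampling interval, ps (default 10).
#' @param temperature kelvin.
#' @param binWidth degrees.
#' @return list with \code{value} (-T dS, kJ/mol), \code{sem},
#'   \code{nBlocks}, \code{perBlock}.
#' @export
blockAverage <- function(angles, angles2 = NULL, windowNs = 5,
                         samplingPs = 10, temperature = 301, binWidth = 5) {
  blockLen <- round(windowNs * 1000 / samplingPs)
  n <- length(angles)
  nb <- n %/% blockLen
  if (nb < 1) stop("series shorter than one block")
  if (n %% blockLen != 0)
    warning("truncating ", n %% blockLen, " trailing snapshot(s)")
  per <- vapply(seq_len(nb), function(b) {
    ix <- ((b - 1) * blockLen + 1):(b * blockLen)
    S <- histogramEntropy(angles[ix],
                          if (is.null(angles2)) NULL else angles2[ix],
                          binWidth)
    normalizeFreeRotor(S, if (is.null(angles2)) 1 else 2, temperature,
                       binWidth)
  }, 0)
  sem <- if (nb >= 2) stats::sd(per) / sqrt(nb) else NA_real_
  if (nb < 2) warning("fewer than 2 blocks: sem undefined")
  list(value = mean(per), sem = sem, nBlocks = nb, perBlock = per)
}

#' iRED order parameters from bond-vector series
#'
#' Isotropic reorientational eigenmode dynamics: builds the second-rank
#' covariance matrix M_ij = <P2(u_i . u_j)> across sites (averaged over
#' snapshots), eigendecomposes it, and computes per-site order parameters
#' O2_i = 1 - sum_m lambda_m |m_i|^2 with the sum over all but the five
#' largest eigenmodes (which carry overall reorientation).
#'
#' @param vectors numeric array (nSites x nSnapshots x 3) of unit bond
#'   vectors, or a list of nSites matrices (nSnapshots x 3).
#' @return numeric vector of per-site O2 values, clamped to [0, 1]; names
#'   taken from the input when present.
#' @export
iredOrderParameters <- function(vectors) {
  if (is.list(vectors)) {
    vectors <- simplify2array(vectors)      # snap x 3 x site
    vectors <- aperm(vectors, c(3, 1, 2))   # site x snap x 3
  }
  stopifnot(length(dim(vectors)) == 3L, dim(vectors)[3] == 3L)
  ns <- dim(vectors)[1]; nt <- dim(vectors)[2]
  if (ns < 6) stop("rank requirement: need at least 6 bond vectors")
  nrm <- sqrt(vectors[, , 1]^2 + vectors[, , 2]^2 + vectors[, , 3]^2)
  if (any(abs(nrm - 1) > 1e-6)) stop("bond vectors must be unit length")
  ## M_ij = <P2(u_i . u_j)>_t ; accumulate over snapshots
  M <- matrix(0, ns, ns)
  for (t in seq_len(nt)) {
    U <- vectors[, t, ]
    dot <- tcrossprod(U)
    M <- M + 0.5 * (3 * dot^2 - 1)
  }
  M <- M / nt
  eg <- eigen(M, symmetric = TRUE)
  internal <- seq(6, ns)  # eigenvalues sorted decreasing; drop 5 largest
  contrib <- (eg$vectors[, internal, drop = FALSE]^2) %*%
    eg$values[internal]
  O2 <- 1 - as.vector(contrib)
  O2 <- pmin(pmax(O2, 0), 1)
  names(O2) <- dimnames(vectors)[[1]]
  O2
}

#' Read angle / vector time-series tables
#'
#' Angle tables: CSV \code{site,time_ps,angle_deg[,angle2_deg]}.
#' Vector tables: CSV \code{site,time_ps,x,y,z}.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readAngleTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site", "time_ps", "angle_deg") %in% names(df)))
    stop("angle table must have columns site,time_ps,angle_deg")
  df
}

#' @rdname readAngleTable
#' @export
readVectorTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site", "time_ps", "x", "y", "z") %in% names(df)))
    stop("vector table must have columns site,time_ps,x,y,z")
  df
}
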