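## Seeded generators producing every input the pipeline consumes, with the
## ground truth recorded alongside.  All randomness flows through one
## explicitly seeded stream per invocation; identical seeds give identical
## output.  Default sizes and noise levels mirror the study conditions this
## package was built around: duplicate ITC titrations of 100 uM protein into
## 1000 uM ligand at 301.1 K with ~2% heat noise, 116 backbone amides and 73
## methyls at fields 11.7/14.1/18.8 T with 1-2% rate noise, tau_c near 7 ns,
## and 100 ns trajectories sampled every 10 ps.

#' Reference titration scheme of the emulated experiments
#'
#' 20 injections of 2 uL of 1 mM titrant into a 250 uL cell held at 100 uM
#' and 301.1 K.  With a low-micromolar Kd this gives a Wiseman c-value near
#' 50, a final molar ratio of about 1.7, and a final saturation of the cell
#' species of about 97 percent -- matching the saturation levels reported
#' for the titrations this package emulates, and making (n, Kd, dH) well
#' identifiable from duplicate runs.
#'
#' @param nInjections number of injections (default 20).
#' @return a \code{\link{titrationScheme}}.
#' @export
referenceScheme <- function(nInjections = 20) {
  titrationScheme(V0 = 250e-6, injectionVolumes = 2e-6,
                  syringeConc = 1000e-6, cellConc = 100e-6,
                  temperature = 301.1, nInjections = nInjections)
}

#' Generate synthetic ITC thermogram replicates
#'
#' Heats are the single-site model prediction plus Gaussian noise with sd
#' equal to \code{noiseFrac} of the largest-magnitude model heat.
#'
#' @param truth a \code{\link{bindingParams}} object (the ground truth).
#' @param scheme a \code{\link{titrationScheme}}.
#' @param nReplicates number of replicate thermograms (default 2).
#' @param noiseFrac Gaussian heat noise as a fraction of the maximum
#'   absolute model heat (default 0.02).
#' @param seed integer seed.
#' @return list with \code{thermograms} (list of \code{Thermogram}) and
#'   \code{truth}.
#' @export
genItc <- function(truth, scheme = referenceScheme(), nReplicates = 2,
                   noiseFrac = 0.02, seed = 1) {
  set.seed(seed)
  pred <- predictedHeats(scheme, truth)
  sdAbs <- noiseFrac * max(abs(pred - truth@Qoff[1]))
  tgs <- lapply(seq_len(nReplicates), function(r) {
    noise <- if (sdAbs > 0) stats::rnorm(length(pred), 0, sdAbs) else 0
    thermogram(pred + noise, scheme, sd = max(sdAbs, 1e-12))
  })
  list(thermograms = tgs, truth = truth, noiseSd = sdAbs)
}

#' Generate synthetic backbone 15N relaxation tables
#'
#' Per-site model-free truths are sampled (unless supplied): O2 from a
#' Beta-shaped distribution centred near 0.84 (matching the observed
#' backbone mean), a fraction of sites carrying tau_e and/or Rex terms.
#' Rates at every field are computed from the model-free machinery and
#' perturbed with Gaussian noise of sd = \code{noiseFrac} * rate (NOE: an
#' absolute sd of \code{noiseFrac/2}).
#'
#' @param nSites number of residues (default 116).
#' @param fields static fields in tesla (default 11.7, 14.1, 18.8).
#' @param tensor a \code{\link{diffusionTensor}} (default isotropic 7 ns).
#' @param truth optional data.frame (site, O2, taue, Rex) overriding the
#'   sampled truths.
#' @param modelMix probabilities of generating models m1/m2/m3 per site
#'   (default pure m1).
#' @param noiseFrac relative rate noise (default 0.015).
#' @param vectors optional (nSites x 3) bond vectors in the lab frame; drawn
#'   uniformly on the sphere when omitted.
#' @param constants \code{\link{spinConstants}}.
#' @param seed integer seed.
#' @return list with \code{records} (rate table data.frame), \code{truth}
#'   (per-site data.frame), \code{vectors}, \code{tensor}.
#' @export
genRelaxation <- function(nSites = 116, fields = c(11.7, 14.1, 18.8),
                          tensor = isotropicTensor(7e-9), truth = NULL,
                          modelMix = c(m1 = 1, m2 = 0, m3 = 0),
                          noiseFrac = 0.015, vectors = NULL,
                          constants = spinConstants(), seed = 1) {
  set.seed(seed)
  siteIds <- sprintf("res%03d", seq_len(nSites))
  if (is.null(vectors)) {
    v <- matrix(stats::rnorm(3 * nSites), ncol = 3)
    vectors <- v / sqrt(rowSums(v^2))
  }
  rownames(vectors) <- siteIds
  if (is.null(truth)) {
    ## Beta-shaped O2 with mean 0.837 (matching the observed backbone mean)
    ## and spread ~0.06
    O2 <- 0.60 + 0.38 * stats::rbeta(nSites, 5, 3)
    O2 <- pmin(O2, 0.98)
    mdl <- sample(names(modelMix), nSites, replace = TRUE, prob = modelMix)
    taue <- ifelse(mdl %in% c("m2"), stats::runif(nSites, 20e-12, 100e-12), NA)
    Rex <- ifelse(mdl %in% c("m3"), stats::runif(nSites, 1, 4), NA)
    truth <- data.frame(site = siteIds, model = mdl, O2 = O2,
                        taue = taue, Rex = Rex, stringsAsFactors = FALSE)
  }
  U <- .toPAS(vectors, tensor@angles)
  rec <- list()
  for (i in seq_len(nSites)) {
    p <- list(O2 = truth$O2[i])
    if (!is.na(truth$taue[i])) p$taue <- truth$taue[i]
    if (!is.na(truth$Rex[i])) p$Rex <- truth$Rex[i]
    for (B0 in fields) {
      r <- rates15N(p, tensor, U[i, ], B0, constants)
      sdv <- c(noiseFrac * abs(r[["R1"]]), noiseFrac * abs(r[["R2"]]),
               noiseFrac / 2)
      val <- r + stats::rnorm(3, 0, sdv)
      rec[[length(rec) + 1L]] <- data.frame(
        site = truth$site[i], field_T = B0,
        rate_type = c("R1", "R2", "NOE"), value = unname(val),
        sd = sdv, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rec)
  rownames(records) <- NULL
  list(records = records, truth = truth, vectors = vectors, tensor = tensor)
}

#' Generate synthetic 2H methyl relaxation tables
#'
#' @param nSites number of methyl sites (default 73).
#' @param fields tesla (default 11.7, 14.1).
#' @param tensor \code{\link{diffusionTensor}}.
#' @param noiseFrac relative rate noise.
#' @param constants \code{\link{spinConstants}}.
#' @param seed integer seed.
#' @return list with \code{records} and per-site \code{truth} (O2 of the
#'   methyl axis and tau_f).
#' @export
genMethylRelaxation <- function(nSites = 73, fields = c(11.7, 14.1),
                                tensor = isotropicTensor(7e-9),
                                noiseFrac = 0.015,
                                constants = spinConstants(), seed = 1) {
  set.seed(seed)
  siteIds <- sprintf("met%03d", seq_len(nSites))
  O2 <- stats::runif(nSites, 0.3, 0.95)
  tauf <- stats::runif(nSites, 10e-12, 60e-12)
  rec <- list()
  for (i in seq_len(nSites)) {
    p <- list(O2 = O2[i], tauf = tauf[i])
    for (B0 in fields) {
      r <- rates2HMethyl(p, tensor, B0, constants)
      sdv <- noiseFrac * abs(r)
      val <- r + stats::rnorm(length(r), 0, sdv)
      rec[[length(rec) + 1L]] <- data.frame(
        site = siteIds[i], field_T = B0, rate_type = names(r),
        value = unname(val), sd = unname(sdv), stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rec)
  rownames(records) <- NULL
  list(records = records,
       truth = data.frame(site = siteIds, O2 = O2, tauf = tauf,
                          stringsAsFactors = FALSE))
}

## analytic binned entropy of a von Mises mixture: integrate the density
## over each bin, then -R sum p ln p
.vonMisesBinnedEntropy <- function(means, kappas, weights, binWidth = 5) {
  dens <- function(x) {
    ## x in degrees; exponentials kept scaled so large kappa stays finite
    xr <- x * pi / 180
    out <- 0
    for (j in seq_along(means)) {
      mu <- means[j] * pi / 180
      out <- out + weights[j] *
        exp(kappas[j] * (cos(xr - mu) - 1)) /
        (2 * pi * besselI(kappas[j], 0, expon.scaled = TRUE))
    }
    out * pi / 180  # density per degree
  }
  edges <- seq(-180, 180, by = binWidth)
  p <- vapply(seq_len(length(edges) - 1L), function(i)
    stats::integrate(dens, edges[i], edges[i + 1L],
                     rel.tol = 1e-10)$value, 0)
  p <- p / sum(p)
  p <- p[p > 0]
  -.R_GAS * sum(p * log(p))
}

#' Generate a dihedral-angle series from a von Mises mixture
#'
#' Samples wrapped angles from a mixture of von Mises components and
#' records the analytic binned entropy of the mixture as the ground truth.
#'
#' @param n number of snapshots.
#' @param means component means, degrees.
#' @param kappas component concentrations (0 = uniform).
#' @param weights component weights (normalized internally).
#' @param binWidth degrees, for the recorded analytic truth (default 5).
#' @param seed integer seed.
#' @return list with \code{angles} (degrees in [-180, 180)),
#'   \code{truthEntropy} (J mol^-1 K^-1, binned analytic) and the mixture
#'   definition.
#' @export
genDihedral <- function(n, means = c(-60, 60), kappas = c(4, 4),
                        weights = c(0.5, 0.5), binWidth = 5, seed = 1) {
  set.seed(seed)
  weights <- weights / sum(weights)
  comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
  ## von Mises sampling by rejection from a wrapped Cauchy envelope
  ## (Best & Fisher); kappa = 0 falls back to uniform
  rvm1 <- function(m, kappa) {
    if (kappa < 1e-12) return(stats::runif(1, -pi, pi))
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        return(((if (u[3] > 0.5) 1 else -1) * acos(f) + m * pi / 180))
      }
    }
  }
  ang <- vapply(comp, function(j) rvm1(means[j], kappas[j]), 0) * 180 / pi
  ang <- .wrapAngle(ang)
  list(angles = ang,
       truthEntropy = .vonMisesBinnedEntropy(means, kappas, weights,
                                             binWidth),
       means = means, kappas = kappas, weights = weights)
}

#' Generate cone-model bond-vector series
#'
#' Each site's unit vector is drawn uniformly within a cone of the given
#' semi-angle about a site-specific mean axis; the analytic order parameter
#' [cos(theta) (1 + cos(theta)) / 2]^2 is recorded as the truth.
#'
#' @param nSites number of sites.
#' @param nSnapshots snapshots per site.
#' @param theta cone semi-angle(s), degrees (scalar recycled).
#' @param seed integer seed.
#' @return list with \code{vectors} (nSites x nSnapshots x 3 array) and
#'   \code{truthO2} per site.
#' @export
genBondVectors <- function(nSites, nSnapshots, theta = 30, seed = 1) {
  set.seed(seed)
  theta <- rep(theta, length.out = nSites)
  thr <- theta * pi / 180
  axes <- matrix(stats::rnorm(3 * nSites), ncol = 3)
  axes <- axes / sqrt(rowSums(axes^2))
  out <- array(0, c(nSites, nSnapshots, 3))
  for (i in seq_len(nSites)) {
    ## uniform in the spherical cap: cos(t) ~ U[cos(thr), 1]
    ct <- stats::runif(nSnapshots, cos(thr[i]), 1)
    st <- sqrt(1 - ct^2)
    ph <- stats::runif(nSnapshots, 0, 2 * pi)
    loc <- cbind(st * cos(ph), st * sin(ph), ct)
    ## rotate cap axis (0,0,1) onto axes[i,]
    z <- c(0, 0, 1); a <- axes[i, ]
    v <- c(z[2] * a[3] - z[3] * a[2], z[3] * a[1] - z[1] * a[3],
           z[1] * a[2] - z[2] * a[1])
    cth <- sum(z * a)
    Rm <- if (abs(cth + 1) < 1e-12) diag(c(1, -1, -1)) else {
      vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
      diag(3) + vx + vx %*% vx / (1 + cth)
    }
    out[i, , ] <- loc %*% t(Rm)
  }
  ct0 <- cos(thr)
  truth <- (ct0 * (1 + ct0) / 2)^2
  list(vectors = out, truthO2 = truth, theta = theta)
}

#' Generate a toy protein-ligand complex as PDB text
#'
#' A single-atom "ligand" sits at the origin; each residue is a small
#' three-atom cluster placed along a randomly chosen coordinate axis so that
#' its minimum distance to the ligand equals the prescription exactly at PDB
#' coordinate precision (prescriptions are rounded to 0.001 A).  The PDB is
#' written through bio3d so it is valid input for any standard parser.
#'
#' @param distances numeric vector of prescribed minimum residue-ligand
#'   distances, angstrom (one residue per value; rounded to 0.001 A).
#' @param path optional output path; a temporary file is used when omitted.
#' @param seed integer seed (placement directions).
#' @return list with \code{path}, \code{pdb} (bio3d object re-read from the
#'   file) and \code{truth} (named prescribed distances).
#' @export
genToyComplex <- function(distances, path = tempfile(fileext = ".pdb"),
                          seed = 1) {
  set.seed(seed)
  distances <- round(distances, 3)
  nres <- length(distances)
  ## axis-aligned placement keeps coordinates exact in the fixed-point PDB
  ## fields; the nearest atom sits at dir * d, the other two strictly
  ## further out
  axes <- diag(3)
  pick <- sample.int(3, nres, replace = TRUE)
  sgn <- sample(c(-1, 1), nres, replace = TRUE)
  xyz <- list(); resno <- c(); resid <- c(); elety <- c()
  for (i in seq_len(nres)) {
    away <- sgn[i] * axes[pick[i], ]
    base <- away * distances[i]
    perp <- axes[(pick[i] %% 3) + 1L, ]
    cluster <- rbind(base,
                     base + 1.5 * away,
                     base + 1.2 * away + 1.0 * perp)
    xyz[[i]] <- cluster
    resno <- c(resno, rep(i, 3))
    resid <- c(resid, rep("ALA", 3))
    elety <- c(elety, c("CA", "CB", "C"))
  }
  co <- do.call(rbind, xyz)
  ## ligand atom at the origin, own residue
  co <- rbind(co, c(0, 0, 0))
  resno <- c(resno, nres + 1L)
  resid <- c(resid, "LIG")
  elety <- c(elety, "C1")
  pdb <- bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(co)),
    resno = resno, resid = resid, eleno = seq_len(nrow(co)),
    elety = elety, chain = rep("A", nrow(co)),
    o = rep(1, nrow(co)), b = rep(0, nrow(co))
  )
  list(path = path, pdb = bio3d::read.pdb(path),
       truth = stats::setNames(distances, as.character(seq_len(nres))))
}
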