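## Conformational entropy from NMR order parameters: per-residue backbone
## log-ratio terms (diffusion-in-a-cone entropy), linear side-chain terms
## with residue-type coefficients, the three-complex comparison statistic,
## and Monte-Carlo error propagation.

#' Side-chain entropy coefficients per residue type
#'
#' Slopes C_m of the linear relation between methyl-axis order parameter and
#' side-chain conformational entropy: 1.32 for Val and Thr, 3.1 for Ile and
#' Leu, 2.31 for Met.  Ala is not listed here: its single methyl reports
#' directly on motion of the Calpha-Cbeta axis and is routed through the
#' backbone log-ratio form instead.
#'
#' @return named numeric vector of C_m values.
#' @export
cmCoefficients <- function() {
  c(VAL = 1.32, THR = 1.32, ILE = 3.1, LEU = 3.1, MET = 2.31)
}

## per-site backbone entropy kernel: S/R = ln(3 - sqrt(1 + 8 O2)),
## finite for O2 in [0, 1)
.coneLog <- function(O2) log(3 - sqrt(1 + 8 * O2))

.checkO2 <- function(tab) {
  bad <- tab@O2 >= 1
  if (any(bad))
    stop("invalid input: O2 >= 1 at site(s) ",
         paste(tab@site[bad], collapse = ", "))
}

.matchSites <- function(tabA, tabB) {
  if (!setequal(tabA@site, tabB@site)) {
    missA <- setdiff(tabB@site, tabA@site)
    missB <- setdiff(tabA@site, tabB@site)
    stop("site-set mismatch; missing in A: ",
         paste(missA, collapse = ", "), "; missing in B: ",
         paste(missB, collapse = ", "))
  }
  match(tabA@site, tabB@site)
}

#' Backbone conformational entropy difference from order parameters
#'
#' -T dS_bb(A relative to B) computed as
#' -T * R * sum_k ln[(3 - sqrt(1 + 8 O2_Ak)) / (3 - sqrt(1 + 8 O2_Bk))],
#' antisymmetric under swapping the two tables.  Reported in kJ/mol.
#'
#' @param tableA,tableB \code{\link{orderParameterTable}} objects covering
#'   the same sites.
#' @param temperature kelvin (default 301).
#' @return -T dS in kJ/mol.
#' @export
backboneEntropyDiff <- function(tableA, tableB, temperature = 301) {
  .checkO2(tableA); .checkO2(tableB)
  idx <- .matchSites(tableA, tableB)
  dS <- .R_GAS * sum(.coneLog(tableA@O2) - .coneLog(tableB@O2[idx]))
  -temperature * dS / 1000
}

#' Side-chain (methyl) conformational entropy difference
#'
#' -T dS_sc(A relative to B) from methyl-axis order parameters with the
#' linear per-type form dS = -R * C_m * dO2 summed over all methyls of each
#' type; Ala sites use the backbone log-ratio form.
#'
#' @param tableA,tableB \code{\link{orderParameterTable}} objects (methyl
#'   sites) covering the same sites.
#' @param coeffs named C_m coefficients, see \code{\link{cmCoefficients}}.
#' @param temperature kelvin (default 301).
#' @return -T dS in kJ/mol.
#' @export
sidechainEntropyDiff <- function(tableA, tableB, coeffs = cmCoefficients(),
                                 temperature = 301) {
  .checkO2(tableA); .checkO2(tableB)
  idx <- .matchSites(tableA, tableB)
  O2A <- tableA@O2; O2B <- tableB@O2[idx]
  ty <- tableA@restype
  known <- ty %in% c(names(coeffs), "ALA")
  if (!all(known))
    stop("no side-chain coefficient for residue type(s): ",
         paste(unique(ty[!known]), collapse = ", "))
  dS <- 0
  ala <- ty == "ALA"
  if (any(ala))
    dS <- dS + .R_GAS * sum(.coneLog(O2A[ala]) - .coneLog(O2B[ala]))
  if (any(!ala)) {
    cm <- coeffs[ty[!ala]]
    ## entropy decreases as the order parameter grows: dS = -R C_m dO2
    dS <- dS - .R_GAS * sum(cm * (O2A[!ala] - O2B[!ala]))
  }
  -temperature * dS / 1000
}

#' Intercomplex comparison statistic
#'
#' For three labelled values, dP(A) = P(A) - (P(B) + P(C))/2 and cyclically;
#' the three deltas sum to zero and equal 1.5 times the deviation from the
#' three-way mean.
#'
#' @param values named numeric vector of exactly three values.
#' @return named numeric vector of the three deltas.
#' @examples
#' intercomplexDelta(c(M = 4, P = 2, O = 2))  # c(2, -1, -1)
#' @export
intercomplexDelta <- function(values) {
  if (length(values) != 3L)
    stop("invalid input: exactly three values required")
  tot <- sum(values)
  out <- values - (tot - values) / 2
  out
}

#' Monte-Carlo errors of entropy differences
#'
#' Resamples every order parameter from a normal distribution with its
#' stated sd (clipped to [0, 1)), recomputes the three intercomplex entropy
#' deltas, and reports the standard deviation over resamples.
#'
#' @param tables named list of exactly three \code{orderParameterTable}s
#'   (one per complex) with per-site sds.
#' @param what "backbone" or "sidechain".
#' @param nMc number of Monte-Carlo samples (default 500).
#' @param seed optional integer seed.
#' @param temperature kelvin.
#' @param coeffs side-chain coefficients (used when
#'   \code{what = "sidechain"}).
#' @return named numeric vector: sd of each complex's intercomplex delta,
#'   kJ/mol.
#' @export
entropyMcErrors <- function(tables, what = c("backbone", "sidechain"),
                            nMc = 500, seed = NULL, temperature = 301,
                            coeffs = cmCoefficients()) {
  what <- match.arg(what)
  stopifnot(length(tables) == 3L)
  if (!is.null(seed)) set.seed(seed)
  labs <- names(tables)
  if (is.null(labs)) labs <- c("A", "B", "C")
  resample <- function(tab) {
    O2 <- tab@O2 + stats::rnorm(length(tab@O2), 0, tab@sd)
    O2 <- pmin(pmax(O2, 0), 1 - 1e-6)
    new("OrderParameterTable", residue = tab@residue, restype = tab@restype,
        siteClass = tab@siteClass, O2 = O2, sd = tab@sd, site = tab@site)
  }
  draws <- vapply(seq_len(nMc), function(i) {
    tt <- lapply(tables, resample)
    intercomplexEntropy(tt, what = what, temperature = temperature,
                        coeffs = coeffs)
  }, numeric(3))
  out <- apply(draws, 1, stats::sd)
  names(out) <- labs
  out
}

#' Intercomplex entropy deltas for three complexes
#'
#' Convenience wrapper: sums the pairwise entropy machinery into the
#' three-complex comparison -T ddS(A) = -T [dS(A) - (dS(B) + dS(C))/2]
#' evaluated per complex over the common site set.
#'
#' @inheritParams entropyMcErrors
#' @return named numeric vector of the three -T ddS values, kJ/mol; they
#'   sum to zero.
#' @export
intercomplexEntropy <- function(tables, what = c("backbone", "sidechain"),
                                temperature = 301,
                                coeffs = cmCoefficients()) {
  what <- match.arg(what)
  stopifnot(length(tables) == 3L)
  labs <- names(tables)
  if (is.null(labs)) labs <- c("A", "B", "C")
  ## per-complex entropy sums on a common reference: use complex 1 as the
  ## pairwise reference; intercomplexDelta removes the reference choice
  ref <- tables[[1]]
  P <- vapply(tables, function(tab) {
    if (what == "backbone") backboneEntropyDiff(tab, ref, temperature)
    else sidechainEntropyDiff(tab, ref, coeffs, temperature)
  }, 0)
  names(P) <- labs
  intercomplexDelta(P)
}

#' Per-residue conformational entropy values
#'
#' Per-site backbone entropy in energy units, T * R * ln(3 - sqrt(1 + 8 O2))
#' (kJ/mol), higher for more mobile residues; strictly decreasing in O2.
#' Only relative values are meaningful: downstream radial-shell analysis
#' re-references them to the minimum shell.
#'
#' @param table an \code{\link{orderParameterTable}}.
#' @param temperature kelvin (default 301).
#' @return named numeric vector (names = site labels), kJ/mol.
#' @export
perResidueEntropy <- function(table, temperature = 301) {
  .checkO2(table)
  stats::setNames(temperature * .R_GAS * .coneLog(table@O2) / 1000,
                  table@site)
}

#' Read / write order-parameter tables
#'
#' CSV with header \code{residue,restype,site_class,O2,sd} (an optional
#' \code{site} column carries methyl identifiers).
#'
#' @param path CSV path.
#' @return an \code{\link{orderParameterTable}}.
#' @export
readOrderParameterTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue", "restype", "site_class", "O2", "sd")
  if (!all(need %in% names(df)))
    stop("order-parameter CSV must have columns: ",
         paste(need, collapse = ","))
  orderParameterTable(df$residue, df$restype, df$O2, df$sd, df$site_class,
                      site = if ("site" %in% names(df)) df$site else NULL)
}

#' @rdname readOrderParameterTable
#' @param table an \code{\link{orderParameterTable}} to write.
#' @export
writeOrderParameterTable <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
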