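## Radial distribution of per-residue conformational entropy around the
## bound ligand.

#' Minimum residue-ligand distances from a structure
#'
#' For every protein residue, the shortest distance between any of its atoms
#' and any ligand atom.  Distances use the atoms present in the file (heavy
#' atoms plus any modelled hydrogens); no hydrogens are added.
#'
#' @param pdb a \code{bio3d} pdb object (\code{bio3d::read.pdb}).
#' @param ligandResname residue name(s) identifying the ligand.
#' @param ligandChain optional chain restriction for the ligand.
#' @return named numeric vector of distances in angstrom, names = residue
#'   numbers of the protein residues.
#' @export
residueLigandDistances <- function(pdb, ligandResname, ligandChain = NULL) {
  a <- pdb$atom
  isLig <- a$resid %in% ligandResname
  if (!is.null(ligandChain)) isLig <- isLig & a$chain %in% ligandChain
  if (!any(isLig)) stop("empty ligand selection: no atoms with resid ",
                        paste(ligandResname, collapse = "/"))
  lig <- as.matrix(a[isLig, c("x", "y", "z")])
  prot <- a[!isLig & a$resid %in% .AA3, ]
  if (!nrow(prot)) stop("no protein residues found")
  out <- vapply(split(seq_len(nrow(prot)), prot$resno), function(idx) {
    xyz <- as.matrix(prot[idx, c("x", "y", "z")])
    ## min over all atom pairs
    d2 <- outer(rowSums(xyz^2), rowSums(lig^2), "+") -
      2 * tcrossprod(xyz, lig)
    sqrt(max(min(d2), 0))
  }, 0)
  out[order(as.integer(names(out)))]
}

#' Radial shell profile of per-residue entropy
#'
#' Sorts residues into distance shells (half-open [lower, upper)), averages
#' the member residues' entropy values per shell, subtracts the minimum
#' shell mean (so the least-entropic shell sits at 0), and computes the
#' cumulative residue-weighted mean entropy as a function of distance,
#' evaluated at shell midpoints.  Residues beyond the outer edge are
#' excluded; residues closer than the inner edge are assigned to the
#' innermost shell with a warning.  Empty shells are recorded as missing,
#' not zero.
#'
#' @param entropy named numeric vector of per-residue entropy values
#'   (kJ/mol), names = residue identifiers.
#' @param distances named numeric vector of residue-ligand distances
#'   (angstrom) covering the same residues.
#' @param scheme a \code{\link{shellScheme}}.
#' @return data.frame of class \code{shellProfile} with columns
#'   \code{shell_lo}, \code{shell_hi}, \code{midpoint}, \code{n_residues},
#'   \code{mean_raw}, \code{mean_mTdS} (referenced) and \code{cumulative}.
#' @export
buildProfile <- function(entropy, distances, scheme = shellScheme()) {
  common <- intersect(names(entropy), names(distances))
  if (!length(common)) stop("entropy and distances share no residues")
  e <- entropy[common]; d <- distances[common]
  edges <- scheme@edges
  below <- d < edges[1]
  if (any(below)) {
    warning(sum(below), " residue(s) closer than ", edges[1],
            " A assigned to the innermost shell")
    d[below] <- edges[1]
  }
  keep <- d < edges[length(edges)]
  e <- e[keep]; d <- d[keep]
  bin <- findInterval(d, edges)  # [lower, upper): interval i means edge i <= d < edge i+1
  ns <- length(edges) - 1L
  mean_raw <- vapply(seq_len(ns), function(i) {
    if (any(bin == i)) mean(e[bin == i]) else NA_real_
  }, 0)
  counts <- tabulate(bin, nbins = ns)
  mids <- shellMidpoints(scheme)
  ref <- min(mean_raw, na.rm = TRUE)
  ## cumulative mean is residue-weighted and on the raw scale
  cumu <- vapply(mids, function(m) {
    inside <- d <= m
    if (any(inside)) mean(e[inside]) else NA_real_
  }, 0)
  out <- data.frame(shell_lo = edges[-length(edges)], shell_hi = edges[-1],
                    midpoint = mids, n_residues = counts,
                    mean_raw = mean_raw, mean_mTdS = mean_raw - ref,
                    cumulative = cumu)
  class(out) <- c("shellProfile", "data.frame")
  out
}

#' @export
print.shellProfile <- function(x, ...) {
  cat("Radial entropy profile:", sum(x$n_residues), "residues in",
      nrow(x), "shells\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a shell profile as CSV
#'
#' @param profile a \code{shellProfile} from \code{\link{buildProfile}}.
#' @param path output CSV path.
#' @export
writeShellProfile <- function(profile, path) {
  utils::write.csv(profile[, c("shell_lo", "shell_hi", "midpoint",
                               "n_residues", "mean_mTdS", "cumulative")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
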