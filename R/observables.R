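## Shared measurement layer: relaxation decay fitting, chemical shift
## perturbations, and rate-table I/O.

#' Fit a monoexponential relaxation decay
#'
#' Fits I(t) = I0 * exp(-R t) to a relaxation decay by least squares.  The fit
#' is unweighted unless per-point noise standard deviations are supplied, in
#' which case it is inverse-variance weighted.  Duplicate delays (recorded in
#' relaxation experiments as e.g. "8 (x2)") are kept as separate points.
#'
#' Uncertainties come either from a leave-one-out jackknife or from
#' Monte-Carlo refits of noise-resampled data (the latter requires
#' \code{noiseSd}).
#'
#' @param delays relaxation delays, seconds (>= 3 distinct values).
#' @param intensities peak intensities, arbitrary units.
#' @param noiseSd optional per-point noise standard deviation (scalar or
#'   vector); enables weighting and the Monte-Carlo error method.
#' @param errorMethod "jackknife" (default) or "montecarlo".
#' @param nMc number of Monte-Carlo resamples when
#'   \code{errorMethod = "montecarlo"}.
#' @param seed optional integer seed for the Monte-Carlo resampling.
#' @return a list of class \code{decayFit} with elements \code{rate} (s^-1),
#'   \code{amplitude}, \code{rateSd}, \code{amplitudeSd}, \code{residuals},
#'   \code{degenerate} (TRUE when the decay carries no information and the
#'   rate is pinned near zero).
#' @examples
#' f <- fitMonoexponential(c(0, 0.1, 0.2), 100 * exp(-10 * c(0, 0.1, 0.2)))
#' f$rate  # 10
#' @export
fitMonoexponential <- function(delays, intensities,
                               noiseSd = NULL,
                               errorMethod = c("jackknife", "montecarlo"),
                               nMc = 200, seed = NULL) {
  errorMethod <- match.arg(errorMethod)
  if (length(delays) != length(intensities))
    stop("delays and intensities must have equal length")
  if (length(unique(delays)) < 3L)
    stop("invalid input: need at least 3 distinct delays")
  if (any(!is.finite(intensities)) || any(!is.finite(delays)) || any(delays < 0))
    stop("invalid input: delays must be non-negative and intensities finite")
  w <- if (is.null(noiseSd)) rep(1, length(delays)) else {
    if (length(noiseSd) == 1L) noiseSd <- rep(noiseSd, length(delays))
    1 / noiseSd^2
  }

  core <- function(t, y, w) {
    if (diff(range(y)) < .Machine$double.eps * max(abs(y), 1)) {
      ## constant intensities: no decay information
      return(list(rate = 0, amplitude = y[1], degenerate = TRUE))
    }
    ## log-linear start values (positive intensities only)
    pos <- y > 0
    if (sum(pos) >= 2) {
      cf <- stats::lm.wfit(cbind(1, t[pos]), log(y[pos]), w[pos])$coefficients
      start <- c(I0 = exp(cf[1]), R = max(-cf[2], 1e-6))
    } else {
      start <- c(I0 = max(abs(y)), R = 1 / max(t[t > 0]))
    }
    fit <- minpack.lm::nls.lm(
      par = start,
      fn = function(p, t, y, w) sqrt(w) * (y - p[1] * exp(-p[2] * t)),
      t = t, y = y, w = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    if (fit$info == 0 || any(!is.finite(fit$par)))
      stop("fit failure: monoexponential did not converge; final deviance ",
           signif(fit$deviance, 4))
    list(rate = unname(fit$par[2]), amplitude = unname(fit$par[1]),
         degenerate = FALSE)
  }

  base <- core(delays, intensities, w)
  n <- length(delays)

  rateSd <- NA_real_; ampSd <- NA_real_
  if (!base$degenerate) {
    if (errorMethod == "jackknife") {
      jr <- vapply(seq_len(n), function(i) {
        f <- core(delays[-i], intensities[-i], w[-i])
        c(f$rate, f$amplitude)
      }, numeric(2))
      rateSd <- sqrt((n - 1) / n * sum((jr[1, ] - mean(jr[1, ]))^2))
      ampSd <- sqrt((n - 1) / n * sum((jr[2, ] - mean(jr[2, ]))^2))
    } else {
      if (is.null(noiseSd))
        stop("montecarlo errors require noiseSd")
      if (!is.null(seed)) set.seed(seed)
      pred <- base$amplitude * exp(-base$rate * delays)
      mc <- vapply(seq_len(nMc), function(i) {
        yy <- pred + stats::rnorm(n, 0, noiseSd)
        f <- tryCatch(core(delays, yy, w), error = function(e) NULL)
        if (is.null(f)) c(NA_real_, NA_real_) else c(f$rate, f$amplitude)
      }, numeric(2))
      rateSd <- stats::sd(mc[1, ], na.rm = TRUE)
      ampSd <- stats::sd(mc[2, ], na.rm = TRUE)
    }
  }
  structure(list(rate = base$rate, amplitude = base$amplitude,
                 rateSd = rateSd, amplitudeSd = ampSd,
                 residuals = intensities - base$amplitude * exp(-base$rate * delays),
                 degenerate = base$degenerate),
            class = "decayFit")
}

#' @export
print.decayFit <- function(x, ...) {
  cat(sprintf("Monoexponential decay fit: R = %.4g +/- %.3g s^-1, I0 = %.4g%s\n",
              x$rate, x$rateSd, x$amplitude,
              if (x$degenerate) " [degenerate: no decay]" else ""))
  invisible(x)
}

#' Chemical shift perturbation
#'
#' Weighted Euclidean combination of the proton and heteronuclear chemical
#' shift changes, sqrt(dH^2 + (w * dX)^2).  The conventional weights are 0.16
#' for 15N (backbone amides) and 0.25 for 13C (methyl groups).
#'
#' @param deltaH 1H shift change, ppm.
#' @param deltaX heteronuclear (15N or 13C) shift change, ppm.
#' @param weight scaling of the heteronuclear axis; default 0.16.
#' @return the perturbation in ppm (vectorized).
#' @examples
#' chemicalShiftPerturbation(0.1, 0.5)          # backbone amide
#' chemicalShiftPerturbation(0.1, 0.5, 0.25)    # methyl
#' @export
chemicalShiftPerturbation <- function(deltaH, deltaX, weight = 0.16) {
  stopifnot(all(is.finite(deltaH)), all(is.finite(deltaX)))
  sqrt(deltaH^2 + (weight * deltaX)^2)
}

#' Read / write relaxation rate tables
#'
#' Delimited text with header \code{site,field_T,rate_type,value,sd}.
#' Round-trips are lossless.  Unknown rate types and duplicated
#' (site, field, type) combinations are rejected.
#'
#' @param path file path.
#' @param sep field separator (default comma; use "\t" for TSV).
#' @return \code{readRateTable} returns a data.frame with columns
#'   \code{site}, \code{field_T}, \code{rate_type}, \code{value}, \code{sd}.
#' @export
readRateTable <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("site", "field_T", "rate_type", "value", "sd")
  if (!all(need %in% names(df)))
    stop("rate table must have header columns: ", paste(need, collapse = ","))
  df <- df[, need]
  validateRateTable(df)
  df
}

#' @rdname readRateTable
#' @param records data.frame of rate records as returned by
#'   \code{readRateTable}.
#' @export
writeRateTable <- function(records, path, sep = ",") {
  validateRateTable(records)
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname readRateTable
#' @export
validateRateTable <- function(records) {
  bad <- !records$rate_type %in% .RATE_TYPES
  if (any(bad)) {
    stop("parse error at row(s) ", paste(which(bad), collapse = ", "),
         ": unknown rate_type ",
         paste(unique(records$rate_type[bad]), collapse = ", "))
  }
  if (any(!is.finite(records$value)) || any(!is.finite(records$sd)))
    stop("parse error: non-finite value/sd at row(s) ",
         paste(which(!is.finite(records$value) | !is.finite(records$sd)),
               collapse = ", "))
  if (any(records$sd <= 0))
    stop("sd must be positive at row(s) ",
         paste(which(records$sd <= 0), collapse = ", "))
  key <- paste(records$site, records$field_T, records$rate_type)
  if (anyDuplicated(key))
    stop("duplicated (site, field, type): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  invisible(TRUE)
}

#' Read a decay table
#'
#' Delimited text with header \code{site,delay_s,intensity} and an optional
#' \code{sd} column; one block of rows per site.
#'
#' @param path file path.
#' @param sep field separator.
#' @return a data.frame with one row per (site, delay) point.
#' @export
readDecayTable <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("site", "delay_s", "intensity")
  if (!all(need %in% names(df)))
    stop("decay table must have header columns: ", paste(need, collapse = ","))
  df
}

#' Fit monoexponential decays for every site in a decay table
#'
#' @param decays data.frame from \code{\link{readDecayTable}}.
#' @param ... passed to \code{\link{fitMonoexponential}}.
#' @return data.frame with columns \code{site}, \code{rate}, \code{rateSd},
#'   \code{amplitude}, \code{degenerate}.
#' @export
fitDecayTable <- function(decays, ...) {
  out <- lapply(split(decays, decays$site), function(d) {
    f <- fitMonoexponential(d$delay_s, d$intensity,
                            noiseSd = if ("sd" %in% names(d)) d$sd else NULL,
                            ...)
    data.frame(site = d$site[1], rate = f$rate, rateSd = f$rateSd,
               amplitude = f$amplitude, degenerate = f$degenerate,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
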