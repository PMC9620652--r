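#' Refit signature exposures to a spectrum by maximum likelihood
#'
#' Estimates the fraction of a sample's mutations attributable to each
#' signature of a fixed catalog ("contribution scores"), by maximising the
#' multinomial log-likelihood over the exposure simplex with a monotone
#' expectation-maximisation update from uniform initialisation. The fit is
#' deterministic: the same spectrum and catalog always give identical
#' exposures.
#'
#' The GCVsig contribution score of a sample is
#' `fitExposures(spec, catalog)$exposures[["GCVsig"]]`.
#'
#' @param spectrum 96-channel count vector (named vector from
#'   [buildSpectrum()]; total must be >= 1).
#' @param catalog A [SignatureCatalog-class].
#' @param maxIter Iteration cap (default 10000; cheap at 96 channels).
#' @param tol Convergence tolerance on the max absolute exposure change
#'   (default 1e-8).
#' @return A list: `exposures` (named, non-negative, sums to 1), `logLik`,
#'   `n` (total mutations used) and `iterations`.
#' @export
fitExposures <- function(spectrum, catalog, maxIter = 10000L, tol = 1e-8) {
  stopifnot(is(catalog, "SignatureCatalog"))
  x <- asSpectrumMatrix(spectrum)
  if (sum(x) < 1) stop("unfittable: spectrum has no mutations")
  fit <- .em_fit_batch(x, catalog@probs, as.integer(maxIter), tol)
  e <- fit$exposures[, 1L]
  names(e) <- signatureNames(catalog)
  list(exposures = e, logLik = fit$loglik[1L], n = sum(x),
       iterations = fit$iterations[1L])
}

#' Refit a batch of spectra
#'
#' Vectorised form of [fitExposures()] used by the FDR calibration, where
#' hundreds of thousands of simulated spectra are refit.
#'
#' @param spectra 96 x m count matrix (spectra in columns).
#' @inheritParams fitExposures
#' @return K x m exposure matrix (signatures in rows); all-zero spectra give
#'   NA columns.
#' @export
fitExposuresMatrix <- function(spectra, catalog, maxIter = 10000L, tol = 1e-8) {
  stopifnot(is(catalog, "SignatureCatalog"))
  x <- asSpectrumMatrix(spectra)
  fit <- .em_fit_batch(x, catalog@probs, as.integer(maxIter), tol)
  expo <- fit$exposures
  rownames(expo) <- signatureNames(catalog)
  colnames(expo) <- colnames(x)
  expo
}

# coerce vector / matrix spectra to a 96 x m double matrix in canonical order
asSpectrumMatrix <- function(spectra) {
  if (is.null(dim(spectra))) spectra <- matrix(spectra, ncol = 1L,
                                               dimnames = list(names(spectra), NULL))
  spectra <- as.matrix(spectra)
  if (nrow(spectra) != 96L)
    stop(sprintf("spectra must have 96 channel rows, found %d", nrow(spectra)))
  if (!is.null(rownames(spectra))) {
    if (!setequal(rownames(spectra), SBS96_CHANNELS))
      stop("spectrum channel labels do not match the canonical SBS96 set")
    spectra <- spectra[SBS96_CHANNELS, , drop = FALSE]
  }
  storage.mode(spectra) <- "double"
  spectra
}

#' Simulate a spectrum from a signature mixture
#'
#' One multinomial draw of `n` mutations from the channel distribution
#' `sum_k w_k * P[, k]` implied by a named mixture of catalog signatures.
#'
#' @param weights Named numeric mixture weights over catalog signatures
#'   (must sum to 1; unnamed signatures get weight 0).
#' @param catalog A [SignatureCatalog-class].
#' @param n Number of mutations to draw (>= 0).
#' @param seed Optional integer seed for reproducibility.
#' @return Named integer 96-vector.
#' @export
simulateSpectrum <- function(weights, catalog, n, seed = NULL) {
  stopifnot(is(catalog, "SignatureCatalog"))
  if (n < 0) stop("n must be non-negative")
  p <- mixtureProbs(weights, catalog)
  if (!is.null(seed)) set.seed(seed)
  s <- emptySpectrum()
  if (n > 0) s[] <- as.integer(stats::rmultinom(1L, size = n, prob = p))
  s
}

mixtureProbs <- function(weights, catalog) {
  missing <- setdiff(names(weights), signatureNames(catalog))
  if (length(missing))
    stop("mixture names absent from catalog: ", paste(missing, collapse = ", "))
  if (abs(sum(weights) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (any(weights < 0)) stop("mixture weights must be non-negative")
  as.numeric(catalog@probs[, names(weights), drop = FALSE] %*% weights)
}
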