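#' SignatureCatalog: a fixed set of SBS96 mutational signatures
#'
#' A 96 x K column-stochastic matrix of channel probabilities with named
#' signatures, in canonical COSMIC channel order. This is the fixed reference
#' against which sample spectra are refit; no de novo extraction is done.
#'
#' @slot probs numeric matrix, 96 rows (canonical channels as rownames) by K
#'   signature columns; every column sums to 1 and all entries are >= 0.
#'
#' @seealso [readSignatureCatalog()], [makeSignatureCatalog()],
#'   [fitExposures()]
#' @export
setClass("SignatureCatalog", representation(probs = "matrix"))

setValidity("SignatureCatalog", function(object) {
  p <- object@probs
  msgs <- character(0)
  if (nrow(p) != 96L)
    msgs <- c(msgs, sprintf("catalog must have 96 rows, found %d", nrow(p)))
  else if (!identical(rownames(p), SBS96_CHANNELS))
    msgs <- c(msgs, "rownames must be the 96 canonical SBS channels in COSMIC order")
  if (is.null(colnames(p)) || anyDuplicated(colnames(p)))
    msgs <- c(msgs, "signature columns must have unique names")
  if (any(p < 0))
    msgs <- c(msgs, "signature probabilities must be non-negative")
  cs <- colSums(p)
  if (any(abs(cs - 1) > 1e-8))
    msgs <- c(msgs, sprintf("column sums must equal 1 (max deviation %.3g)",
                            max(abs(cs - 1))))
  if (length(msgs)) msgs else TRUE
})

#' Construct a SignatureCatalog from a probability matrix
#'
#' @param probs 96 x K numeric matrix; rownames must be SBS96 channel labels
#'   (any order; rows are reordered canonically), colnames the signature names.
#' @return A [SignatureCatalog-class] object.
#' @export
SignatureCatalog <- function(probs) {
  probs <- as.matrix(probs)
  if (is.null(rownames(probs)))
    stop("probs must carry SBS channel labels as rownames")
  if (nrow(probs) != 96L)
    stop(sprintf("expected 96 channel rows, found %d", nrow(probs)))
  if (anyDuplicated(rownames(probs)))
    stop("duplicate channel label in probs")
  missing <- setdiff(SBS96_CHANNELS, rownames(probs))
  if (length(missing))
    stop("missing channel(s): ", paste(utils::head(missing, 3), collapse = ", "))
  probs <- probs[SBS96_CHANNELS, , drop = FALSE]
  storage.mode(probs) <- "double"
  new("SignatureCatalog", probs = probs)
}

#' @describeIn SignatureCatalog-class names of the signatures in the catalog
#' @param x,object A `SignatureCatalog`.
#' @export
signatureNames <- function(x) colnames(x@probs)

#' @describeIn SignatureCatalog-class the 96 x K probability matrix
#' @export
signatureProbs <- function(x) x@probs

#' @describeIn SignatureCatalog-class number of signatures
#' @export
setMethod("length", "SignatureCatalog", function(x) ncol(x@probs))

setMethod("show", "SignatureCatalog", function(object) {
  cat("SignatureCatalog with", ncol(object@probs), "signatures over 96 SBS channels\n")
  cat("signatures:", paste(colnames(object@probs), collapse = ", "), "\n")
})

#' @describeIn SignatureCatalog-class subset signatures by name or index
#' @param i signature names or indices.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SignatureCatalog", function(x, i, j, ..., drop = FALSE) {
  SignatureCatalog(x@probs[, i, drop = FALSE])
})

#' CutoffCurve: simulation-calibrated 1% FDR score cutoffs by mutation count
#'
#' Holds the 99th-percentile GCVsig contribution score among spectra simulated
#' from a fixed null mixture (by default 0.95 focal signature + 0.05 SBS5),
#' evaluated over a grid of mutation counts. Queries at off-grid counts are
#' linearly interpolated in log(count) and held constant beyond the grid ends.
#'
#' @slot nullSignature name of the focal null signature (e.g. "SBS18").
#' @slot mixture named numeric mixture weights used in the null simulation.
#' @slot countsGrid strictly increasing integer mutation counts.
#' @slot cutoffs score cutoffs in `[0, 1]`, one per grid count.
#' @slot reps simulations per grid count.
#' @slot percentile percentile used (default 99).
#' @slot seed root seed of the simulation.
#' @seealso [buildCutoffCurve()], [cutoffAt()]
#' @export
setClass("CutoffCurve", representation(
  nullSignature = "character", mixture = "numeric",
  countsGrid = "integer", cutoffs = "numeric",
  reps = "integer", percentile = "numeric", seed = "integer"
))

setValidity("CutoffCurve", function(object) {
  msgs <- character(0)
  if (length(object@countsGrid) != length(object@cutoffs))
    msgs <- c(msgs, "countsGrid and cutoffs lengths differ")
  if (is.unsorted(object@countsGrid, strictly = TRUE))
    msgs <- c(msgs, "countsGrid must be strictly increasing")
  if (any(object@cutoffs < 0 | object@cutoffs > 1))
    msgs <- c(msgs, "cutoffs must lie in [0, 1]")
  if (abs(sum(object@mixture) - 1) > 1e-8)
    msgs <- c(msgs, "mixture weights must sum to 1")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CutoffCurve", function(object) {
  cat(sprintf("CutoffCurve: %g%%ile %s-null cutoffs at %d counts in [%d, %d] (%d reps)\n",
              object@percentile, object@nullSignature,
              length(object@countsGrid), min(object@countsGrid),
              max(object@countsGrid), object@reps))
})

#' CutoffRegression: regression surface for per-sample 1% FDR cutoffs
#'
#' Fitted coefficients of the cutoff model
#' `cutoff = b0 + b1*count + b2*log(count) + b3*contrib + b4*contrib*log(count)`
#' trained on a simulated (contribution, count) cutoff surface, so a sample's
#' cutoff can be predicted from its mutation count and estimated null-signature
#' contribution without fresh simulation.
#'
#' @slot nullSignature focal null signature name.
#' @slot beta named numeric of length 5 (b0..b4).
#' @slot rSquared coefficient of determination on the training surface.
#' @slot surface the training data.frame (contrib, count, cutoff).
#' @seealso [fitCutoffRegression()], [predictCutoff()]
#' @export
setClass("CutoffRegression", representation(
  nullSignature = "character", beta = "numeric",
  rSquared = "numeric", surface = "data.frame"
))

setValidity("CutoffRegression", function(object) {
  msgs <- character(0)
  if (length(object@beta) != 5L)
    msgs <- c(msgs, "beta must have length 5")
  if (length(object@rSquared) != 1L ||
      is.na(object@rSquared) || object@rSquared < 0 || object@rSquared > 1)
    msgs <- c(msgs, "rSquared must be a single value in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CutoffRegression", function(object) {
  cat(sprintf("CutoffRegression (%s null): R^2 = %.4f\n",
              object@nullSignature, object@rSquared))
  print(signif(object@beta, 4))
})
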