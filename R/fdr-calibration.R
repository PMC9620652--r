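#' Derive a reproducible child seed
#'
#' Hashes a root seed together with an arbitrary tag (e.g. null signature,
#' mixture contribution, mutation count) into a 31-bit integer, so every
#' simulation cell gets an independent, rerun-stable stream.
#'
#' @param root Integer root seed.
#' @param ... Tag components (coerced to character).
#' @return Integer in `[0, 2^31)`.
#' @export
deriveSeed <- function(root, ...) {
  parts <- paste(c(as.character(root), vapply(list(...), as.character,
                                              character(1L))), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483563
  as.integer(h)
}

#' Simulate null-model GCVsig contribution scores
#'
#' Draws `reps` spectra of `n` mutations from the null mixture
#' `contrib * nullSignature + (1 - contrib) * SBS5`, refits each against the
#' full detection catalog, and returns the GCVsig contribution score of every
#' draw. These scores are the null distribution from which FDR cutoffs are
#' taken.
#'
#' @param nullSignature Name of the focal null signature ("SBS18" or
#'   "SBS38").
#' @param contrib Focal signature weight in `(0, 1]` (remainder is SBS5).
#' @param n Mutations per simulated spectrum (>= 1).
#' @param reps Number of simulations.
#' @param catalog Detection [SignatureCatalog-class]; must contain
#'   `nullSignature`, "SBS5" and "GCVsig".
#' @param seed Optional integer seed.
#' @param scoreSignature Signature whose contribution is scored (default
#'   "GCVsig").
#' @return Numeric vector of `reps` scores in `[0, 1]`.
#' @export
simulateNullScores <- function(nullSignature, contrib, n, reps, catalog,
                               seed = NULL, scoreSignature = "GCVsig") {
  stopifnot(is(catalog, "SignatureCatalog"))
  if (contrib <= 0 || contrib > 1) stop("contrib must be in (0, 1]")
  if (n < 1) stop("n must be >= 1")
  for (nm in c(nullSignature, "SBS5", scoreSignature))
    if (!nm %in% signatureNames(catalog))
      stop("catalog lacks signature: ", nm)
  w <- c(contrib, 1 - contrib)
  names(w) <- c(nullSignature, "SBS5")
  if (nullSignature == "SBS5") w <- c(SBS5 = 1)
  p <- mixtureProbs(w, catalog)
  if (!is.null(seed)) set.seed(seed)
  draws <- stats::rmultinom(reps, size = n, prob = p)
  rownames(draws) <- SBS96_CHANNELS
  expo <- fitExposuresMatrix(draws, catalog)
  as.numeric(expo[scoreSignature, ])
}

#' Nearest-rank percentile
#'
#' The `percentile`-th percentile of `scores` by the nearest-rank
#' definition: after sorting ascending, the value at 1-based index
#' `ceiling(percentile/100 * length(scores))`. Exact for 1000 scores at the
#' 99th percentile (rank 990); percentile 100 gives the maximum.
#'
#' @param scores Non-empty numeric vector.
#' @param percentile Percentile in `(0, 100]`.
#' @return A single score value.
#' @export
percentileCutoff <- function(scores, percentile = 99) {
  if (length(scores) == 0L) stop("empty score list")
  if (percentile <= 0 || percentile > 100) stop("percentile must be in (0, 100]")
  sorted <- sort(scores)
  idx <- max(1L, as.integer(ceiling(percentile / 100 * length(sorted))))
  sorted[idx]
}

#' Default mutation-count grid for cutoff curves
#'
#' Log-spaced integer counts spanning 1 to 10,000 (the mutation-count range
#' of panel cohorts); cutoff queries between grid points interpolate in
#' log(count), where the curve is close to linear.
#'
#' @param from,to Grid range (defaults 1 and 10000).
#' @param length.out Number of grid points before deduplication (default 40).
#' @return Increasing integer vector.
#' @export
defaultCountsGrid <- function(from = 1L, to = 10000L, length.out = 40L) {
  sort(unique(as.integer(round(10 ^ seq(log10(from), log10(to),
                                        length.out = length.out)))))
}

#' Build the simulation-calibrated 1% FDR cutoff curve
#'
#' For each mutation count on the grid, simulates `reps` null spectra from
#' the dominant-process mixture (default 0.95 focal null signature + 0.05
#' SBS5 background), refits them, and records the 99th-percentile GCVsig
#' contribution score: the score above which an observed spectrum has a
#' `<= 1%` chance of having arisen from the null process. Off-grid counts
#' are served by linear interpolation in log(count) (see [cutoffAt()]).
#'
#' @inheritParams simulateNullScores
#' @param countsGrid Increasing integer mutation counts in `[1, 10000]`
#'   (default: 40 log-spaced values).
#' @param reps Simulations per grid count (default 1000).
#' @param percentile Cutoff percentile (default 99, i.e. 1% FDR).
#' @param contrib Focal-signature weight of the null mixture (default 0.95).
#' @param seed Root seed; each grid count uses a derived child seed.
#' @return A [CutoffCurve-class].
#' @export
buildCutoffCurve <- function(nullSignature, catalog,
                             countsGrid = defaultCountsGrid(),
                             reps = 1000L, percentile = 99, contrib = 0.95,
                             seed = 1L) {
  countsGrid <- sort(unique(as.integer(countsGrid)))
  if (any(countsGrid < 1L) || any(countsGrid > 10000L))
    stop("countsGrid must lie within [1, 10000]")
  cutoffs <- vapply(countsGrid, function(n) {
    scores <- simulateNullScores(nullSignature, contrib, n, reps, catalog,
                                 seed = deriveSeed(seed, nullSignature,
                                                   contrib, n))
    percentileCutoff(scores, percentile)
  }, numeric(1L))
  mix <- c(contrib, 1 - contrib)
  names(mix) <- c(nullSignature, "SBS5")
  new("CutoffCurve", nullSignature = nullSignature, mixture = mix,
      countsGrid = countsGrid, cutoffs = unname(cutoffs),
      reps = as.integer(reps), percentile = percentile,
      seed = as.integer(seed))
}

#' Query a cutoff curve at arbitrary mutation counts
#'
#' Linear interpolation in log(count) between grid points; constant
#' extrapolation beyond the grid ends.
#'
#' @param curve A [CutoffCurve-class].
#' @param n Integer mutation count(s), >= 1.
#' @return Cutoff value(s) in `[0, 1]`.
#' @export
cutoffAt <- function(curve, n) {
  stopifnot(is(curve, "CutoffCurve"))
  if (any(n < 1)) stop("count must be >= 1")
  if (length(curve@countsGrid) == 1L)
    return(rep(curve@cutoffs, length(n)))
  stats::approx(log(curve@countsGrid), curve@cutoffs, xout = log(n),
                rule = 2)$y
}

#' Simulate the (contribution, count) cutoff training surface
#'
#' One 99th-percentile null cutoff per combination of focal-signature
#' contribution and mutation count, each cell from `reps` simulations. The
#' default grid spans contributions 0.05-0.95 (step 0.05) and counts 5-250
#' (step 5): 950 cells. This surface trains the regression cutoff model for
#' samples whose mutations come from several processes at once.
#'
#' @inheritParams buildCutoffCurve
#' @param contribs Focal contributions in `[0.05, 0.95]`.
#' @param counts Mutation counts in `[5, 250]`.
#' @return data.frame with columns `contrib`, `count`, `cutoff`.
#' @export
buildTrainingSurface <- function(nullSignature, catalog,
                                 contribs = seq(0.05, 0.95, by = 0.05),
                                 counts = seq(5L, 250L, by = 5L),
                                 reps = 1000L, percentile = 99, seed = 1L) {
  if (any(contribs < 0.05 - 1e-9) || any(contribs > 0.95 + 1e-9))
    stop("contribs must lie within [0.05, 0.95]")
  if (any(counts < 5L) || any(counts > 250L))
    stop("counts must lie within [5, 250]")
  grid <- expand.grid(count = as.integer(counts), contrib = contribs,
                      KEEP.OUT.ATTRS = FALSE)
  grid$cutoff <- mapply(function(ct, cb) {
    scores <- simulateNullScores(nullSignature, cb, ct, reps, catalog,
                                 seed = deriveSeed(seed, nullSignature, cb, ct))
    percentileCutoff(scores, percentile)
  }, grid$count, grid$contrib)
  grid[, c("contrib", "count", "cutoff")]
}

#' Fit the regression cutoff surface
#'
#' Ordinary least squares of the simulated cutoffs on mutation count,
#' log(count), focal contribution, and the contribution x log(count)
#' interaction:
#' `cutoff = b0 + b1*count + b2*log(count) + b3*contrib + b4*contrib*log(count)`.
#' The fitted model predicts a sample's 1% FDR cutoff without fresh
#' simulation.
#'
#' @param surface Training data.frame from [buildTrainingSurface()] (needs
#'   >= 5 distinct rows).
#' @param nullSignature Focal null signature name recorded on the model.
#' @return A [CutoffRegression-class] with coefficients `b0..b4` and the
#'   training R^2 (defined as 1 when the surface is fit with zero residuals).
#' @export
fitCutoffRegression <- function(surface, nullSignature) {
  stopifnot(all(c("contrib", "count", "cutoff") %in% names(surface)))
  if (nrow(unique(surface[, c("contrib", "count")])) < 5L)
    stop("need at least 5 distinct (contrib, count) rows")
  d <- data.frame(cutoff = surface$cutoff, count = surface$count,
                  logn = log(surface$count), contrib = surface$contrib)
  d$contrib_logn <- d$contrib * d$logn
  fit <- stats::lm(cutoff ~ count + logn + contrib + contrib_logn, data = d)
  beta <- stats::coef(fit)
  if (anyNA(beta)) stop("rank-deficient cutoff design (degenerate surface grid)")
  beta <- unname(beta[c("(Intercept)", "count", "logn", "contrib",
                        "contrib_logn")])
  names(beta) <- paste0("b", 0:4)
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  tss <- sum((d$cutoff - mean(d$cutoff))^2)
  r2 <- if (tss <= .Machine$double.eps * length(res)) {
    if (rss <= 1e-12) 1 else 0
  } else max(0, min(1, 1 - rss / tss))
  new("CutoffRegression", nullSignature = nullSignature, beta = beta,
      rSquared = r2, surface = surface)
}

#' Predict a 1% FDR cutoff from the regression surface
#'
#' Evaluates the fitted cutoff model at a sample's mutation count and
#' estimated null-signature contribution; predictions are clamped into
#' `[0, 1]`.
#'
#' @param model A [CutoffRegression-class].
#' @param count Mutation count(s), >= 1 (log is taken).
#' @param contrib Estimated focal contribution(s) in `[0, 1]`.
#' @return Predicted cutoff(s) in `[0, 1]`.
#' @export
predictCutoff <- function(model, count, contrib) {
  stopifnot(is(model, "CutoffRegression"))
  if (any(count < 1)) stop("count must be >= 1 (log undefined below 1)")
  if (any(contrib < 0 | contrib > 1)) stop("contrib must be in [0, 1]")
  b <- model@beta
  raw <- b[1L] + b[2L] * count + b[3L] * log(count) + b[4L] * contrib +
    b[5L] * contrib * log(count)
  pmin(1, pmax(0, unname(raw)))
}

#' Calibrate GCVsig detection for a catalog
#'
#' Convenience driver building, for each null signature, the dominant-process
#' cutoff curve and the regression cutoff surface. SBS18 is the default null
#' (the COSMIC signature most similar to GCVsig); the SBS38 calibration is
#' applied only to skin malignancies, where UV-associated SBS38 is an
#' alternative explanation of C>A enrichment.
#'
#' @inheritParams buildCutoffCurve
#' @param nullSignatures Null signatures to calibrate (default SBS18 and
#'   SBS38).
#' @param surfaceReps Simulations per training-surface cell (default
#'   `reps`).
#' @param contribs,counts Training-surface grid (see
#'   [buildTrainingSurface()]).
#' @return A list with elements `curves` and `regressions` (named by null
#'   signature), plus `seed` and `signatures` (the catalog signature names,
#'   used to verify calibration/catalog consistency at call time).
#' @export
calibrateDetection <- function(catalog, nullSignatures = c("SBS18", "SBS38"),
                               countsGrid = defaultCountsGrid(),
                               reps = 1000L, surfaceReps = reps,
                               contribs = seq(0.05, 0.95, by = 0.05),
                               counts = seq(5L, 250L, by = 5L), seed = 1L) {
  curves <- lapply(nullSignatures, function(ns)
    buildCutoffCurve(ns, catalog, countsGrid = countsGrid, reps = reps,
                     seed = seed))
  regressions <- lapply(nullSignatures, function(ns)
    fitCutoffRegression(
      buildTrainingSurface(ns, catalog, contribs = contribs, counts = counts,
                           reps = surfaceReps, seed = seed), ns))
  names(curves) <- names(regressions) <- nullSignatures
  list(curves = curves, regressions = regressions, seed = as.integer(seed),
       signatures = signatureNames(catalog))
}

#' Write / read calibration artifacts as JSON
#'
#' Serialises the cutoff curves and regression coefficients (with grids,
#' reps and seeds) so cohort runs can reuse a calibration.
#'
#' @param calibration Result of [calibrateDetection()].
#' @param path JSON file path.
#' @return `path` invisibly; `readCalibration` returns the calibration list.
#' @export
writeCalibration <- function(calibration, path) {
  enc <- list(
    seed = calibration$seed,
    signatures = calibration$signatures,
    curves = lapply(calibration$curves, function(cv) list(
      nullSignature = cv@nullSignature, mixture = as.list(cv@mixture),
      countsGrid = cv@countsGrid, cutoffs = cv@cutoffs, reps = cv@reps,
      percentile = cv@percentile, seed = cv@seed)),
    regressions = lapply(calibration$regressions, function(rg) list(
      nullSignature = rg@nullSignature, beta = as.list(rg@beta),
      rSquared = rg@rSquared))
  )
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  curves <- lapply(enc$curves, function(cv)
    new("CutoffCurve", nullSignature = cv$nullSignature,
        mixture = unlist(cv$mixture), countsGrid = as.integer(cv$countsGrid),
        cutoffs = as.numeric(cv$cutoffs), reps = as.integer(cv$reps),
        percentile = as.numeric(cv$percentile), seed = as.integer(cv$seed)))
  regressions <- lapply(enc$regressions, function(rg)
    new("CutoffRegression", nullSignature = rg$nullSignature,
        beta = unlist(rg$beta), rSquared = as.numeric(rg$rSquared),
        surface = data.frame()))
  list(curves = curves, regressions = regressions,
       seed = as.integer(enc$seed), signatures = enc$signatures)
}
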