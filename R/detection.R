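#' Call GCVsig status for a batch of sample spectra
#'
#' Applies the per-sample decision logic to every column of a spectrum
#' matrix:
#' \enumerate{
#'   \item samples with fewer than 10 mutations are not evaluable (the score
#'     cutoffs are unreliable below this count) and are never called
#'     positive;
#'   \item the GCVsig contribution score is estimated by maximum-likelihood
#'     refitting against the catalog;
#'   \item samples with more than 10 CA>AA mutations take their 1% FDR
#'     cutoff from the regression surface, using the CA>AA fraction as the
#'     estimated null-signature contribution; all other samples fall back to
#'     the dominant-process (0.95-mixture) cutoff curve at their mutation
#'     count;
#'   \item a sample is positive when its score exceeds the SBS18 cutoff and,
#'     for skin malignancies only, also the SBS38 cutoff.
#' }
#'
#' @param spectra 96 x m count matrix, samples in columns.
#' @param groups Character vector of cancer groups (length m); "SKIN"
#'   triggers the dual-cutoff rule.
#' @param catalog Detection [SignatureCatalog-class].
#' @param calibration Calibration from [calibrateDetection()] (or
#'   [readCalibration()]); must have been built from the same catalog.
#' @return data.frame with one row per sample: `n`, `gcv_score`,
#'   `ca_aa_count`, `ca_aa_fraction`, `cutoff_sbs18`, `cutoff_sbs38`,
#'   `evaluable`, `positive`.
#' @export
callSamples <- function(spectra, groups, catalog, calibration) {
  stopifnot(is(catalog, "SignatureCatalog"))
  if (!identical(as.character(calibration$signatures),
                 signatureNames(catalog)))
    stop("calibration was built from a different catalog (signature sets differ)")
  spectra <- asSpectrumMatrix(spectra)
  m <- ncol(spectra)
  groups <- as.character(groups)
  if (length(groups) == 1L) groups <- rep(groups, m)
  stopifnot(length(groups) == m)
  curve18 <- calibration$curves[["SBS18"]]
  reg18 <- calibration$regressions[["SBS18"]]
  curve38 <- calibration$curves[["SBS38"]]
  reg38 <- calibration$regressions[["SBS38"]]
  if (is.null(curve18) || is.null(reg18))
    stop("calibration lacks the SBS18 curve/regression")

  n <- colSums(spectra)
  score <- rep(NA_real_, m)
  fitted <- n >= 1
  if (any(fitted)) {
    expo <- fitExposuresMatrix(spectra[, fitted, drop = FALSE], catalog)
    if (!"GCVsig" %in% rownames(expo))
      score[fitted] <- 0
    else
      score[fitted] <- as.numeric(expo["GCVsig", ])
  }
  caaa <- colSums(spectra[CA_AA_CHANNELS, , drop = FALSE])
  frac <- ifelse(n > 0, caaa / n, 0)
  regpath <- fitted & caaa > 10

  cutoff18 <- rep(NA_real_, m)
  if (any(regpath))
    cutoff18[regpath] <- predictCutoff(reg18, n[regpath], frac[regpath])
  if (any(fitted & !regpath))
    cutoff18[fitted & !regpath] <- cutoffAt(curve18, n[fitted & !regpath])

  skin <- groups == "SKIN"
  cutoff38 <- rep(NA_real_, m)
  if (any(skin & fitted)) {
    if (is.null(curve38) || is.null(reg38))
      stop("cohort contains SKIN samples but calibration lacks SBS38 artifacts")
    i <- skin & regpath
    if (any(i)) cutoff38[i] <- predictCutoff(reg38, n[i], frac[i])
    i <- skin & fitted & !regpath
    if (any(i)) cutoff38[i] <- cutoffAt(curve38, n[i])
  }

  evaluable <- n >= 10
  positive <- evaluable & !is.na(score) & score > cutoff18 &
    (!skin | (!is.na(cutoff38) & score > cutoff38))
  data.frame(
    n = as.integer(n), gcv_score = score, ca_aa_count = as.integer(caaa),
    ca_aa_fraction = frac, cutoff_sbs18 = cutoff18, cutoff_sbs38 = cutoff38,
    evaluable = evaluable, positive = positive,
    row.names = colnames(spectra), stringsAsFactors = FALSE
  )
}

#' @rdname callSamples
#' @param spectrum A single 96-channel spectrum.
#' @param group Cancer group of the sample.
#' @return `callSample` returns a one-row data.frame.
#' @export
callSample <- function(spectrum, group, catalog, calibration) {
  callSamples(matrix(spectrum, ncol = 1L,
                     dimnames = list(names(spectrum), NULL)),
              group, catalog, calibration)
}

#' Chi-square test of observed versus expected GCVsig frequency
#'
#' Compares the mutation frequencies attributed to GCVsig and to everything
#' else, `(score * n, (1 - score) * n)`, against the expectation under the
#' cohort null, `(expected * n, (1 - expected) * n)`, with the 1-df
#' goodness-of-fit statistic `sum((O - E)^2 / E)`. Frequencies are used
#' as-is (not rounded to integers).
#'
#' @param gcvScore Observed GCVsig contribution score in `[0, 1]`.
#' @param n Sample mutation count.
#' @param expectedScore Expected score under the cohort null, in `(0, 1)`.
#' @return Upper-tail p-value.
#' @export
chisqPvalue <- function(gcvScore, n, expectedScore) {
  if (expectedScore <= 0 || expectedScore >= 1)
    stop("expectedScore must be in (0, 1)")
  O <- c(gcvScore * n, (1 - gcvScore) * n)
  E <- c(expectedScore * n, (1 - expectedScore) * n)
  if (any(E < 1e-12)) stop("degenerate expectation (category below 1e-12)")
  stat <- sum((O - E)^2 / E)
  stats::pchisq(stat, df = 1L, lower.tail = FALSE)
}

#' Expected GCVsig score under the cohort-wide null
#'
#' Mean GCVsig contribution score over `reps` multinomial draws of `n`
#' mutations from the cohort-wide average spectrum, each refit against the
#' catalog. This is the expectation used by [chisqPvalue()].
#'
#' @param avgSpectrum Probability 96-vector from [cohortAverageSpectrum()].
#' @param n Mutation count of the sample under test (>= 1).
#' @param catalog Detection [SignatureCatalog-class].
#' @param reps Number of simulated refits (default 1000).
#' @param seed Optional seed.
#' @return Mean score in `[0, 1]`.
#' @export
expectedScoreFromCohort <- function(avgSpectrum, n, catalog, reps = 1000L,
                                    seed = NULL) {
  stopifnot(length(avgSpectrum) == 96L, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  draws <- stats::rmultinom(reps, size = n, prob = avgSpectrum)
  rownames(draws) <- SBS96_CHANNELS
  expo <- fitExposuresMatrix(draws, catalog)
  if (!"GCVsig" %in% rownames(expo)) return(0)
  mean(expo["GCVsig", ])
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted p-values, returned in input order.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values (same length and order).
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cohort-wide permutation estimate of the false discovery rate
#'
#' Replaces every sample's spectrum by a multinomial draw of the same size
#' from the cohort-wide average spectrum, re-runs the full calling logic,
#' and counts positives; repeated `repeats` times. The estimated FDR is the
#' mean permutation positive count divided by the observed positive count
#' (at least 1).
#'
#' @inheritParams callSamples
#' @param repeats Number of whole-cohort permutations (default 10).
#' @param seed Optional root seed.
#' @return A list: `permutation_positive_counts` (length `repeats`),
#'   `observed_positive_count`, `estimated_fdr`.
#' @export
cohortPermutationFdr <- function(spectra, groups, catalog, calibration,
                                 repeats = 10L, seed = NULL) {
  spectra <- asSpectrumMatrix(spectra)
  n <- colSums(spectra)
  if (!any(n >= 10)) stop("no evaluable samples (all below 10 mutations)")
  observed <- callSamples(spectra, groups, catalog, calibration)
  avg <- cohortAverageSpectrum(spectra)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  counts <- vapply(seq_len(repeats), function(r) {
    set.seed(deriveSeed(seed, "perm", r))
    null_spectra <- vapply(n, function(ni) {
      if (ni > 0) as.numeric(stats::rmultinom(1L, size = ni, prob = avg))
      else numeric(96L)
    }, numeric(96L))
    rownames(null_spectra) <- SBS96_CHANNELS
    sum(callSamples(null_spectra, groups, catalog, calibration)$positive)
  }, integer(1L))
  list(permutation_positive_counts = counts,
       observed_positive_count = sum(observed$positive),
       estimated_fdr = mean(counts) / max(sum(observed$positive), 1L))
}

#' Default cohort-run configuration
#'
#' @param seed Root seed for every stochastic step of the run.
#' @param expectedReps Simulated refits behind each expected score
#'   (default 1000).
#' @param permutationRepeats Whole-cohort permutations for the FDR estimate
#'   (default 10).
#' @param columns Column mapping for the mutation table.
#' @return Config list for [runCohort()].
#' @export
cohortConfig <- function(seed = 1L, expectedReps = 1000L,
                         permutationRepeats = 10L,
                         columns = defaultColumnMapping()) {
  list(seed = as.integer(seed), expectedReps = as.integer(expectedReps),
       permutationRepeats = as.integer(permutationRepeats), columns = columns)
}

#' Run the full cohort screening pipeline
#'
#' End-to-end driver: read (or take) a mutation table, keep each patient's
#' most recent sample, build per-sample spectra, call every sample against
#' the calibration, compute chi-square p-values from the cohort-expected
#' score at each sample's count, Benjamini-Hochberg adjust across evaluable
#' samples, and estimate the cohort permutation FDR.
#'
#' @param mutations Mutation table path or data.frame
#'   (see [readMutationTable()]).
#' @param catalog Signature catalog path or [SignatureCatalog-class].
#' @param calibration Calibration list or JSON path
#'   (see [calibrateDetection()]).
#' @param config Configuration from [cohortConfig()].
#' @param reference Optional reference FASTA path / DNAStringSet for records
#'   without a context column.
#' @param out Optional output TSV path for the calls table.
#' @return A list: `calls` (data.frame sorted by gcv_score descending,
#'   with p_value / p_adjusted), `fdr` (see [cohortPermutationFdr()]),
#'   `avg_spectrum`, and `n_samples`.
#' @export
runCohort <- function(mutations, catalog, calibration,
                      config = cohortConfig(), reference = NULL, out = NULL) {
  if (is.character(mutations))
    mutations <- readMutationTable(mutations, columns = config$columns)
  if (is.character(catalog)) catalog <- readSignatureCatalog(catalog)
  if (is.character(calibration)) calibration <- readCalibration(calibration)
  if (nrow(mutations) == 0L) stop("empty cohort: no mutation records")
  mutations <- dedupLatestSample(mutations)

  ids <- sort(unique(mutations$sample_id))
  bysample <- split(mutations, mutations$sample_id)[ids]
  spectra <- vapply(bysample, function(df) as.numeric(buildSpectrum(df, reference)),
                    numeric(96L))
  rownames(spectra) <- SBS96_CHANNELS
  colnames(spectra) <- ids
  groups <- vapply(bysample, function(df) df$cancer_group[1L], character(1L))

  calls <- callSamples(spectra, groups, catalog, calibration)
  calls <- cbind(sample_id = rownames(calls), cancer_group = unname(groups),
                 calls)
  rownames(calls) <- NULL

  avg <- cohortAverageSpectrum(spectra)
  calls$p_value <- NA_real_
  ev <- which(calls$evaluable)
  if (length(ev)) {
    uniq_n <- sort(unique(calls$n[ev]))
    exp_by_n <- vapply(uniq_n, function(ni)
      expectedScoreFromCohort(avg, ni, catalog, reps = config$expectedReps,
                              seed = deriveSeed(config$seed, "expected", ni)),
      numeric(1L))
    names(exp_by_n) <- uniq_n
    calls$expected_score <- NA_real_
    calls$expected_score[ev] <- exp_by_n[as.character(calls$n[ev])]
    calls$p_value[ev] <- vapply(ev, function(i)
      chisqPvalue(calls$gcv_score[i], calls$n[i], calls$expected_score[i]),
      numeric(1L))
  } else {
    calls$expected_score <- NA_real_
  }
  calls$p_adjusted <- NA_real_
  if (length(ev)) calls$p_adjusted[ev] <- bhAdjust(calls$p_value[ev])

  fdr <- cohortPermutationFdr(spectra, groups, catalog, calibration,
                              repeats = config$permutationRepeats,
                              seed = deriveSeed(config$seed, "permfdr"))

  ord <- order(-calls$gcv_score, calls$sample_id)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  if (!is.null(out)) writeCalls(calls, out)
  list(calls = calls, fdr = fdr, avg_spectrum = avg, n_samples = ncol(spectra))
}

#' Write a calls table
#'
#' Tab-separated, one row per sample, floats with 6 significant digits.
#'
#' @param calls Calls data.frame from [runCohort()] or [callSamples()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeCalls <- function(calls, path) {
  out <- calls
  num <- vapply(out, is.double, logical(1L))
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
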