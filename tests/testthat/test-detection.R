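# a hand-built calibration with known constant cutoffs, for decision-logic
# tests that must not depend on simulation noise
fixedCalibration <- function(cut18, cut38, reg18 = cut18, reg38 = cut38,
                             signatures = signatureNames(catCosmic)) {
  mkCurve <- function(ns, cut) new("CutoffCurve", nullSignature = ns,
                                   mixture = setNames(c(0.95, 0.05), c(ns, "SBS5")),
                                   countsGrid = c(1L, 10000L),
                                   cutoffs = c(cut, cut), reps = 1L,
                                   percentile = 99, seed = 0L)
  mkReg <- function(ns, cut) new("CutoffRegression", nullSignature = ns,
                                 beta = setNames(c(cut, 0, 0, 0, 0),
                                                 paste0("b", 0:4)),
                                 rSquared = 1, surface = data.frame())
  list(curves = list(SBS18 = mkCurve("SBS18", cut18),
                     SBS38 = mkCurve("SBS38", cut38)),
       regressions = list(SBS18 = mkReg("SBS18", reg18),
                          SBS38 = mkReg("SBS38", reg38)),
       seed = 0L, signatures = signatures)
}

test_that("samples below 10 mutations are never evaluable or positive", {
  calib <- fixedCalibration(0, 0)  # cutoffs that anything would pass
  s <- simulateSpectrum(c(GCVsig = 1), catCosmic, 9, seed = 1)
  call <- callSample(s, "GI", catCosmic, calib)
  expect_false(call$evaluable)
  expect_false(call$positive)
  s10 <- simulateSpectrum(c(GCVsig = 1), catCosmic, 10, seed = 1)
  expect_true(callSample(s10, "GI", catCosmic, calib)$evaluable)
})

test_that("skin samples must clear both the SBS18 and SBS38 cutoffs", {
  s <- simulateSpectrum(c(GCVsig = 0.9, SBS5 = 0.1), catCosmic, 100, seed = 2)
  sc <- callSample(s, "GI", catCosmic, fixedCalibration(0.5, 0.99, 0.5, 0.99))
  expect_gt(sc$gcv_score, 0.5)
  expect_true(sc$positive)

  # same spectrum as SKIN: SBS38 cutoff of 0.99 blocks the call
  skin <- callSample(s, "SKIN", catCosmic,
                     fixedCalibration(0.5, 0.99, 0.5, 0.99))
  expect_false(skin$positive)
  expect_equal(skin$cutoff_sbs38, 0.99)
  # non-skin samples carry no SBS38 cutoff
  expect_true(is.na(sc$cutoff_sbs38))
})

test_that("the regression path engages only above 10 CA>AA mutations", {
  calib <- fixedCalibration(0.2, 0.2, reg18 = 0.8, reg38 = 0.8)
  # heavy CA>AA spectrum: regression cutoff (0.8) applies
  s <- integer(96); names(s) <- sbs96Channels()
  s["A[C>A]A"] <- 30L; s["A[C>T]A"] <- 20L
  call <- callSample(s, "GI", catCosmic, calib)
  expect_equal(call$ca_aa_count, 30L)
  expect_equal(call$cutoff_sbs18, 0.8)
  # few CA>AA mutations: dominant-process curve (0.2) applies
  s2 <- integer(96); names(s2) <- sbs96Channels()
  s2["A[C>A]A"] <- 5L; s2["A[C>T]A"] <- 45L
  expect_equal(callSample(s2, "GI", catCosmic, calib)$cutoff_sbs18, 0.2)
})

test_that("calibration built from a different catalog is rejected", {
  calib <- fixedCalibration(0.5, 0.5, signatures = c("A", "B"))
  s <- simulateSpectrum(c(SBS5 = 1), catCosmic, 20, seed = 3)
  expect_error(callSample(s, "GI", catCosmic, calib), "different catalog")
})

test_that("seeded spike-in and background samples call as expected", {
  calib <- lightCalibration()
  spike <- simulateSpectrum(c(GCVsig = 0.9, SBS5 = 0.1), catCosmic, 100,
                            seed = 71)
  expect_true(callSample(spike, "GI", catCosmic, calib)$positive)
  null5 <- simulateSpectrum(c(SBS5 = 1), catCosmic, 100, seed = 72)
  call5 <- callSample(null5, "GI", catCosmic, calib)
  expect_false(call5$positive)
  expect_lt(call5$gcv_score, 0.1)
})

test_that("chi-square p-values follow the 1-df goodness-of-fit formula", {
  expect_equal(chisqPvalue(0.3, 50, 0.3), 1)
  # observed (30, 70) vs expected (20, 80): statistic 10^2/20 + 10^2/80
  stat <- 100 / 20 + 100 / 80
  expect_equal(stat, 6.25)
  expect_equal(chisqPvalue(0.3, 100, 0.2),
               pchisq(6.25, df = 1, lower.tail = FALSE))
  # category-order symmetry: scores s vs 1-s with mirrored expectation
  expect_equal(chisqPvalue(0.3, 100, 0.2), chisqPvalue(0.7, 100, 0.8))
  expect_error(chisqPvalue(0.3, 100, 0), "\\(0, 1\\)")
  expect_error(chisqPvalue(0.3, 100, 1), "\\(0, 1\\)")
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(c(0.001, 0.5)), c(0.002, 0.5))
  p <- c(0.04, 0.001, 0.9)
  adj <- bhAdjust(p)
  expect_equal(adj[order(p)], sort(adj))  # monotone in p order
  expect_true(all(adj >= p))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("expected cohort score concentrates and is reproducible", {
  # cohort average orthogonal to GCVsig support (disjoint catalog)
  avg <- rep(0, 96); names(avg) <- sbs96Channels()
  avg[1:24] <- 1 / 24  # pure SBS5 block
  expect_equal(expectedScoreFromCohort(avg, 50, catDisjoint, reps = 20,
                                       seed = 1), 0)

  one <- expectedScoreFromCohort(avg, 50, catCosmic, reps = 1, seed = 4)
  expect_identical(one,
                   expectedScoreFromCohort(avg, 50, catCosmic, reps = 1,
                                           seed = 4))

  # at large n the sampled expectation matches the exact-average fit
  w <- c(SBS5 = 0.7, SBS18 = 0.3)
  mix <- as.numeric(signatureProbs(catCosmic)[, names(w)] %*% w)
  names(mix) <- sbs96Channels()
  exp_score <- expectedScoreFromCohort(mix, 10000, catCosmic, reps = 50,
                                       seed = 5)
  exact <- fitExposures(mix * 10000, catCosmic)
  expect_lt(abs(exp_score - exact$exposures[["GCVsig"]]), 0.02)
})

test_that("permutation FDR is zero for GCVsig-free cohorts and reproducible", {
  set.seed(61)
  spectra <- vapply(1:30, function(i) {
    v <- rep(0, 96); v[1:24] <- rmultinom(1, 40, rep(1 / 24, 24)); v
  }, numeric(96))
  rownames(spectra) <- sbs96Channels()
  calib <- fixedCalibration(0.05, 0.05,
                            signatures = signatureNames(catDisjoint))
  fdr <- cohortPermutationFdr(spectra, rep("GI", 30), catDisjoint, calib,
                              repeats = 5, seed = 7)
  expect_equal(fdr$permutation_positive_counts, rep(0L, 5))
  expect_equal(fdr$estimated_fdr, 0)

  fdr2 <- cohortPermutationFdr(spectra, rep("GI", 30), catDisjoint, calib,
                               repeats = 5, seed = 7)
  expect_identical(fdr$permutation_positive_counts,
                   fdr2$permutation_positive_counts)

  low <- spectra; low[] <- 0; low[1, ] <- 5
  expect_error(cohortPermutationFdr(low, rep("GI", 30), catDisjoint, calib,
                                    repeats = 2, seed = 1), "evaluable")
})

test_that("run_cohort produces a complete, deterministic calls table", {
  spec <- cohortSimSpec(nSamples = 120L, spikeInFraction = 2 / 120,
                        spikeInExposure = 0.85, seed = 33L)
  cohort <- makeCohort(spec, catCosmic)
  calib <- lightCalibration()
  cfg <- cohortConfig(seed = 5L, expectedReps = 200L,
                      permutationRepeats = 3L)
  res <- runCohort(cohort$mutations, catCosmic, calib, config = cfg)

  expect_equal(res$n_samples, length(unique(cohort$mutations$sample_id)))
  expect_true(all(c("sample_id", "n", "gcv_score", "ca_aa_fraction",
                    "cutoff_sbs18", "evaluable", "positive", "p_value",
                    "p_adjusted") %in% names(res$calls)))
  # sorted by score descending
  expect_true(all(diff(res$calls$gcv_score) <= 1e-12 |
                    is.na(diff(res$calls$gcv_score))))
  # every spiked sample is recovered
  spiked <- cohort$truth$sample_id[cohort$truth$spiked]
  expect_true(all(spiked %in% res$calls$sample_id[res$calls$positive]))
  # false positives among evaluable nulls stay within the 1% calibration
  nulls <- res$calls[!res$calls$sample_id %in% spiked & res$calls$evaluable, ]
  expect_lte(sum(nulls$positive), qbinom(0.995, nrow(nulls), 0.01))
  # adjusted p-values are BH of the evaluable p-values
  ev <- res$calls[res$calls$evaluable, ]
  expect_equal(ev$p_adjusted, bhAdjust(ev$p_value))
  expect_true(all(ev$p_adjusted >= ev$p_value))

  # reruns with the same config are byte-identical
  out1 <- withr::local_tempfile(fileext = ".tsv")
  out2 <- withr::local_tempfile(fileext = ".tsv")
  writeCalls(res$calls, out1)
  res2 <- runCohort(cohort$mutations, catCosmic, calib, config = cfg,
                    out = out2)
  expect_identical(readLines(out1), readLines(out2))

  expect_error(runCohort(cohort$mutations[0, ], catCosmic, calib,
                         config = cfg), "empty")
})
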