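# Shared fixtures. Catalogs are deterministic; the light calibration is
# built once per test run and reused by detection tests (modest reps keep
# the suite fast; acceptance tests build their own full-reps calibration).

catDisjoint <- makeSignatureCatalog("disjoint")
catCosmic <- makeSignatureCatalog("cosmic_like")
catOverlap <- makeSignatureCatalog("overlapping", seed = 42L)

lightCalibration <- local({
  cached <- NULL
  function() {
    if (is.null(cached))
      cached <<- calibrateDetection(
        catCosmic,
        countsGrid = c(1L, 3L, 10L, 30L, 100L, 300L, 1000L, 3000L, 10000L),
        reps = 300L, surfaceReps = 150L,
        contribs = seq(0.05, 0.95, by = 0.15),
        counts = c(5L, 10L, 25L, 50L, 100L, 175L, 250L),
        seed = 11L)
    cached
  }
})

# independent per-record channel lookup used as the spectrum oracle: builds
# the channel label from scratch with its own complement table
oracleChannel <- function(context, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mid <- substr(context, 2, 2)
  if (mid %in% c("A", "G")) {
    cx <- strsplit(context, "")[[1]]
    context <- paste0(comp[cx[3]], comp[cx[2]], comp[cx[1]])
    alt <- comp[alt]
    mid <- substr(context, 2, 2)
  }
  paste0(substr(context, 1, 1), "[", mid, ">", alt, "]",
         substr(context, 3, 3))
}

randomRecords <- function(n, seed, with_context = TRUE) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ctx <- replicate(n, paste(sample(bases, 3, replace = TRUE), collapse = ""))
  ref <- substr(ctx, 2, 2)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  data.frame(
    sample_id = sprintf("s%02d", sample.int(5, n, replace = TRUE)),
    patient_id = sprintf("p%02d", sample.int(5, n, replace = TRUE)),
    chrom = "chr1", pos = sample.int(10000, n, replace = TRUE),
    ref = ref, alt = unname(alt), cancer_group = "OTHER",
    age = 50, context = if (with_context) ctx else NA_character_,
    stringsAsFactors = FALSE)
}
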