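#' Synthetic SBS96 signature catalogs
#'
#' Builds a four-signature catalog (SBS5, SBS18, SBS38, GCVsig) with a
#' chosen support structure:
#' \describe{
#'   \item{disjoint}{each signature occupies its own block of 24 channels,
#'     uniformly — exposures are then exactly the count split, useful for
#'     closed-form tests;}
#'   \item{overlapping}{random Dirichlet-style columns sharing all 96
#'     channels, drawn reproducibly from `seed`;}
#'   \item{cosmic_like}{deterministic emulations of the real processes:
#'     a flat clock-like SBS5, a C>A-heavy SBS18 (reactive oxygen damage),
#'     an SBS38 with C>A mass concentrated at 5'-T contexts (indirect UV),
#'     and a GCVsig placing >= 60% of its mass on the four CA>AA channels.}
#' }
#' These are synthetic stand-ins with the qualitative structure of the real
#' COSMIC signatures, not copies of them.
#'
#' @param style One of "cosmic_like", "disjoint", "overlapping".
#' @param seed Integer seed (used by the "overlapping" style).
#' @return A [SignatureCatalog-class] with signatures SBS5, SBS18, SBS38,
#'   GCVsig.
#' @export
makeSignatureCatalog <- function(style = c("cosmic_like", "disjoint",
                                           "overlapping"), seed = 1L) {
  style <- match.arg(style)
  probs <- matrix(0, nrow = 96L, ncol = 4L,
                  dimnames = list(SBS96_CHANNELS,
                                  c("SBS5", "SBS18", "SBS38", "GCVsig")))
  if (style == "disjoint") {
    for (k in 1:4) probs[(k - 1L) * 24L + 1:24, k] <- 1 / 24
  } else if (style == "overlapping") {
    set.seed(seed)
    raw <- matrix(stats::rgamma(96L * 4L, shape = 0.5), nrow = 96L)
    raw <- raw + 1e-4  # keep all channels in the support
    probs[] <- sweep(raw, 2L, colSums(raw), "/")
  } else {
    parts <- channelParts(SBS96_CHANNELS)
    ca <- parts$ref == "C" & parts$alt == "A"
    caaa <- ca & parts$p3 == "A"
    # SBS5: flat clock-like background over all channels, mildly favouring
    # C>T and T>C as pyrimidine transitions
    w5 <- rep(1, 96L)
    w5[parts$ref == "C" & parts$alt == "T"] <- 2
    w5[parts$ref == "T" & parts$alt == "C"] <- 2
    # SBS18: dominated by C>A broadly across contexts (8-oxo-G damage),
    # strongest at 5'-flanks C/G/T, with a small non-C>A floor
    w18 <- rep(0.05, 96L)
    w18[ca] <- 1
    w18[ca & parts$p5 %in% c("C", "G", "T")] <- 1.6
    w18[caaa] <- 2.2
    # SBS38: C>A concentrated at 5'-T / 3'-T contexts, little CA>AA overlap
    w38 <- rep(0.04, 96L)
    w38[ca & (parts$p5 == "T" | parts$p3 == "T")] <- 1.8
    w38[ca & parts$p5 == "T" & parts$p3 == "T"] <- 3
    # GCVsig: >= 60% of mass on the four CA>AA channels, remainder mostly
    # on the other C>A channels
    wg <- rep(0.02, 96L)
    wg[ca] <- 0.5
    wg[caaa] <- 96 * 0.75 / 4  # 75% of total weight before normalisation
    probs[, "SBS5"] <- w5 / sum(w5)
    probs[, "SBS18"] <- w18 / sum(w18)
    probs[, "SBS38"] <- w38 / sum(w38)
    probs[, "GCVsig"] <- wg / sum(wg)
  }
  SignatureCatalog(probs)
}

#' Specification of a synthetic panel cohort
#'
#' Defaults emulate a GENIE-like panel cohort: per-sample mutation counts
#' drawn from a rounded lognormal with mean about 8 (counts observed in such
#' cohorts range from 0 to several thousand), truncated at `maxCount`.
#' `preset = "fm"` narrows the tail to a Foundation-Medicine-like cohort
#' (mean about 7, max a few hundred).
#'
#' @param nSamples Number of samples.
#' @param preset "genie" or "fm" count-distribution preset.
#' @param meanlog,sdlog,maxCount Lognormal count parameters (override the
#'   preset).
#' @param backgroundMixtures List of named mixture weight vectors; one is
#'   sampled per sample with probabilities `backgroundWeights`.
#' @param backgroundWeights Sampling weights for the background mixtures.
#' @param spikeInFraction Fraction of samples receiving a GCVsig spike-in.
#' @param spikeInExposure GCVsig weight in spiked samples (the background
#'   mixture is scaled to the remainder).
#' @param spikeMinCount Minimum mutation count forced on spiked samples
#'   (spike-ins are only meaningful in evaluable samples; default 50).
#' @param skinFraction Fraction of samples labelled SKIN (default 0.1);
#'   others are drawn from the remaining cancer groups.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A cohort spec list for [makeCohort()].
#' @export
cohortSimSpec <- function(nSamples = 500L, preset = c("genie", "fm"),
                          meanlog = NULL, sdlog = NULL, maxCount = NULL,
                          backgroundMixtures = list(
                            c(SBS5 = 1),
                            c(SBS5 = 0.5, SBS18 = 0.5),
                            c(SBS5 = 0.6, SBS38 = 0.4)),
                          backgroundWeights = c(0.5, 0.3, 0.2),
                          spikeInFraction = 0, spikeInExposure = 0.8,
                          spikeMinCount = 50L, skinFraction = 0.1,
                          seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(meanlog)) meanlog <- if (preset == "genie") 1.55 else 1.5
  if (is.null(sdlog)) sdlog <- if (preset == "genie") 1.1 else 1.0
  if (is.null(maxCount)) maxCount <- if (preset == "genie") 10000L else 400L
  stopifnot(spikeInFraction >= 0, spikeInFraction <= 1,
            spikeInExposure > 0, spikeInExposure <= 1,
            abs(sum(backgroundWeights) - 1) < 1e-8)
  list(nSamples = as.integer(nSamples), meanlog = meanlog, sdlog = sdlog,
       maxCount = as.integer(maxCount),
       backgroundMixtures = backgroundMixtures,
       backgroundWeights = backgroundWeights,
       spikeInFraction = spikeInFraction, spikeInExposure = spikeInExposure,
       spikeMinCount = as.integer(spikeMinCount),
       skinFraction = skinFraction, seed = as.integer(seed))
}

# draw a trinucleotide context + ref/alt representation for each channel
# index; half the records are emitted on the purine strand to exercise the
# reverse-complement path
channelToRecord <- function(channelIdx, flip) {
  parts <- channelParts(SBS96_CHANNELS)
  ctx <- paste0(parts$p5, parts$ref, parts$p3)
  ref <- parts$ref
  alt <- parts$alt
  out <- data.frame(context = ctx[channelIdx], ref = ref[channelIdx],
                    alt = alt[channelIdx], stringsAsFactors = FALSE)
  if (any(flip)) {
    out$context[flip] <- revcompSeq(out$context[flip])
    out$ref[flip] <- unname(revcompBase(out$ref[flip]))
    out$alt[flip] <- unname(revcompBase(out$alt[flip]))
  }
  out
}

#' Generate a synthetic panel cohort with known truth
#'
#' Per sample: draws a mutation count from the spec's truncated lognormal,
#' picks a background signature mixture, optionally blends in GCVsig at the
#' spike-in exposure, draws the mutations' channels from the resulting
#' distribution, and emits MAF-like records (contexts included; half the
#' records are written on the purine strand). The truth table records each
#' sample's mixture and spike flag. Everything is reproducible from the spec
#' seed.
#'
#' @param spec Cohort spec from [cohortSimSpec()].
#' @param catalog A [SignatureCatalog-class] containing every signature
#'   named in the spec mixtures plus "GCVsig".
#' @return A list: `mutations` (record data.frame) and `truth`
#'   (per-sample data.frame: sample_id, n, cancer_group, spiked,
#'   gcv_exposure, background).
#' @export
makeCohort <- function(spec, catalog) {
  stopifnot(is(catalog, "SignatureCatalog"))
  set.seed(spec$seed)
  m <- spec$nSamples
  ids <- sprintf("S%04d", seq_len(m))
  counts <- pmin(spec$maxCount,
                 as.integer(round(stats::rlnorm(m, spec$meanlog, spec$sdlog))))
  # exact spike count: round(fraction * n) samples, chosen at random
  nspike <- as.integer(round(spec$spikeInFraction * m))
  spiked <- rep(FALSE, m)
  if (nspike > 0L) spiked[sample.int(m, nspike)] <- TRUE
  counts[spiked] <- pmax(counts[spiked], spec$spikeMinCount)
  bg_idx <- sample.int(length(spec$backgroundMixtures), m, replace = TRUE,
                       prob = spec$backgroundWeights)
  nonskin <- setdiff(CANCER_GROUPS, "SKIN")
  groups <- ifelse(stats::runif(m) < spec$skinFraction, "SKIN",
                   sample(nonskin, m, replace = TRUE))
  ages <- round(stats::runif(m, 30, 85))

  muts <- vector("list", m)
  truth <- data.frame(sample_id = ids, n = counts, cancer_group = groups,
                      spiked = spiked, gcv_exposure = ifelse(
                        spiked, spec$spikeInExposure, 0),
                      background = vapply(bg_idx, function(i)
                        paste(names(spec$backgroundMixtures[[i]]),
                              spec$backgroundMixtures[[i]],
                              sep = ":", collapse = ","), character(1L)),
                      stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    n <- counts[i]
    if (n == 0L) next
    w <- spec$backgroundMixtures[[bg_idx[i]]]
    if (spiked[i]) {
      w <- w * (1 - spec$spikeInExposure)
      if ("GCVsig" %in% names(w))
        w[["GCVsig"]] <- w[["GCVsig"]] + spec$spikeInExposure
      else
        w <- c(w, GCVsig = spec$spikeInExposure)
    }
    p <- mixtureProbs(w / sum(w), catalog)
    chan <- sample.int(96L, n, replace = TRUE, prob = p)
    flip <- stats::runif(n) < 0.5
    rec <- channelToRecord(chan, flip)
    muts[[i]] <- data.frame(
      sample_id = ids[i], patient_id = paste0("P", substring(ids[i], 2L)),
      chrom = "chr1", pos = seq_len(n) * 5L + 10L,
      ref = rec$ref, alt = rec$alt, cancer_group = groups[i],
      age = ages[i], context = rec$context, stringsAsFactors = FALSE)
  }
  mutations <- do.call(rbind, muts[!vapply(muts, is.null, logical(1L))])
  rownames(mutations) <- NULL
  list(mutations = mutations, truth = truth)
}

#' Alternating replication-direction annotation
#'
#' Tiles a sequence with alternating left- and right-replicating segments
#' (disjoint, sorted), emulating replication timing domains around origins.
#'
#' @param sequenceLength Total length to tile.
#' @param segmentLength Length of each segment (>= 1).
#' @param chrom Chromosome name (default "chr1").
#' @param startDirection Direction of the first segment (default "right").
#' @return data.frame with `chrom`, `start`, `end`, `direction`.
#' @export
makeReplicationAnnotation <- function(sequenceLength, segmentLength,
                                      chrom = "chr1",
                                      startDirection = "right") {
  stopifnot(segmentLength >= 1L, sequenceLength >= 1L)
  starts <- seq(1L, sequenceLength, by = segmentLength)
  ends <- pmin(starts + segmentLength - 1L, sequenceLength)
  dirs <- rep(c(startDirection, setdiff(c("left", "right"), startDirection)),
              length.out = length(starts))
  data.frame(chrom = chrom, start = as.integer(starts),
             end = as.integer(ends), direction = dirs,
             stringsAsFactors = FALSE)
}

#' Synthetic COSMIC-style hotspot table
#'
#' Emulates a census export: `nGenes` genes with a handful of hotspot sites
#' each, occurrence counts straddling the 100-occurrence threshold, contexts
#' drawn over all 96 channels, plus a TP53 decoy with by far the highest
#' count variance (which downstream selection must drop).
#'
#' @param nGenes Number of non-TP53 genes.
#' @param hotspotsPerGene Hotspot sites per gene (default 4).
#' @param seed Integer seed.
#' @return data.frame with `gene`, `position`, `label`, `context`, `alt`,
#'   `occurrences`.
#' @export
makeHotspotTable <- function(nGenes, hotspotsPerGene = 4L, seed = 1L) {
  stopifnot(nGenes >= 1L)
  set.seed(seed)
  parts <- channelParts(SBS96_CHANNELS)
  genes <- c(sprintf("GENE%03d", seq_len(nGenes)), "TP53")
  rows <- lapply(seq_along(genes), function(gi) {
    g <- genes[gi]
    k <- if (g == "TP53") 12L else hotspotsPerGene
    chan <- sample.int(96L, k, replace = TRUE)
    occ <- if (g == "TP53") {
      # decoy: one enormous hotspot amid tiny ones -> maximal variance
      c(50000L, rep(5L, k - 1L))
    } else {
      # straddle the 100-occurrence threshold, variance scaling with index
      as.integer(round(stats::rlnorm(k, meanlog = 4 + 2 * gi / length(genes),
                                     sdlog = 1)))
    }
    data.frame(gene = g, position = sort(sample.int(2000L, k)),
               label = sprintf("%s.%d", g, seq_len(k)),
               context = paste0(parts$p5[chan], parts$ref[chan],
                                parts$p3[chan]),
               alt = parts$alt[chan], occurrences = occ,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Random reference sequence fixture
#'
#' A small uniform-random DNA sequence for exercising the FASTA context
#' lookup path of [buildSpectrum()].
#'
#' @param length Sequence length.
#' @param chrom Sequence name (default "chr1").
#' @param seed Integer seed.
#' @return A [Biostrings::DNAStringSet] of one sequence.
#' @export
makeReferenceSequence <- function(length, chrom = "chr1", seed = 1L) {
  set.seed(seed)
  seq <- paste(sample(BASES, length, replace = TRUE), collapse = "")
  out <- Biostrings::DNAStringSet(seq)
  names(out) <- chrom
  out
}
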