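emptySpectrum <- function() {
  s <- integer(96L)
  names(s) <- SBS96_CHANNELS
  s
}

#' Build an SBS96 trinucleotide substitution spectrum
#'
#' Maps each somatic SNV to one of the 96 pyrimidine-strand trinucleotide
#' substitution channels and counts them. Purine-reference mutations are
#' reverse complemented (ref, alt and flanking context) before lookup.
#' Contexts are taken from the records' `context` column when present,
#' otherwise looked up in `reference`.
#'
#' Records are rejected (with a message listing how many, and why) when the
#' context middle base disagrees with the recorded ref, or the context
#' contains a non-ACGT base.
#'
#' @param records Mutation record data.frame (see [readMutationTable()]).
#' @param reference Optional reference sequence: a [Biostrings::DNAStringSet]
#'   (names matching `chrom`) or a FASTA file path. Only needed for records
#'   without a `context` value.
#' @return Named integer vector of length 96 in canonical channel order;
#'   `sum(spectrum)` is the number of usable records.
#' @examples
#' rec <- data.frame(sample_id = "s", patient_id = "p", chrom = "1", pos = 5,
#'                   ref = "C", alt = "A", cancer_group = "OTHER",
#'                   age = NA, context = "ACA")
#' buildSpectrum(rec)[["A[C>A]A"]]
#' @export
buildSpectrum <- function(records, reference = NULL) {
  spec <- emptySpectrum()
  if (nrow(records) == 0L) return(spec)
  ctx <- if ("context" %in% names(records)) as.character(records$context)
         else rep(NA_character_, nrow(records))
  need <- is.na(ctx) | ctx == ""
  if (any(need)) {
    if (is.null(reference))
      stop(sum(need), " record(s) lack a context and no reference was given")
    if (is.character(reference))
      reference <- Biostrings::readDNAStringSet(reference)
    nm <- names(reference)
    # FASTA headers may carry descriptions; match on the first word
    names(reference) <- sub("\\s.*$", "", nm)
    idx <- which(need)
    chrom <- records$chrom[idx]
    bad_chr <- !chrom %in% names(reference)
    if (any(bad_chr))
      stop("chromosome(s) absent from reference: ",
           paste(unique(chrom[bad_chr]), collapse = ", "))
    pos <- records$pos[idx]
    lens <- Biostrings::width(reference)[match(chrom, names(reference))]
    inb <- pos >= 2L & pos + 1L <= lens
    if (any(inb)) {
      got <- as.character(Biostrings::subseq(
        reference[chrom[inb]], start = pos[inb] - 1L, width = 3L))
      ctx[idx[inb]] <- got
    }
    if (any(!inb))
      message(sum(!inb), " record(s) too close to a sequence end dropped")
  }
  ctx <- toupper(ctx)
  usable <- !is.na(ctx) & ctx != ""
  hasN <- usable & grepl("[^ACGT]", ctx)
  if (any(hasN)) {
    message(sum(hasN), " record(s) with ambiguous context dropped")
    usable <- usable & !hasN
  }
  mism <- usable & substr(ctx, 2L, 2L) != records$ref
  if (any(mism)) {
    message(sum(mism), " record(s) rejected: context middle base != ref (rows ",
            paste(utils::head(which(mism), 5L), collapse = ", "), ")")
    usable <- usable & !mism
  }
  if (!any(usable)) return(spec)
  chan <- contextToChannel(ctx[usable], records$alt[usable])
  chan <- chan[!is.na(chan)]
  tab <- table(factor(chan, levels = SBS96_CHANNELS))
  spec[] <- as.integer(tab)
  spec
}

#' Count CA>AA mutations in a spectrum
#'
#' CA>AA mutations are C>A substitutions with a 3' adenine on the pyrimidine
#' strand (equivalently G>T with a 5' thymine on the opposite strand): the
#' four channels `A[C>A]A, C[C>A]A, G[C>A]A, T[C>A]A`. These dominate the
#' ganciclovir signature.
#'
#' @param spectrum A 96-channel spectrum (named vector from
#'   [buildSpectrum()]).
#' @return A list with `ca_aa_count`, `total`, `fraction` (0 when the
#'   spectrum is empty) and `defined` (FALSE when total is 0).
#' @export
caAaFraction <- function(spectrum) {
  stopifnot(length(spectrum) == 96L)
  if (is.null(names(spectrum))) names(spectrum) <- SBS96_CHANNELS
  total <- sum(spectrum)
  caaa <- sum(spectrum[CA_AA_CHANNELS])
  list(ca_aa_count = as.integer(caaa), total = as.integer(total),
       fraction = if (total > 0) caaa / total else 0,
       defined = total > 0)
}

#' Cohort-wide average mutational spectrum
#'
#' Pools counts over all samples and normalizes: the probability that a
#' mutation drawn uniformly from the cohort falls in each channel.
#'
#' @param spectra A list of 96-vectors, or a 96 x n matrix with samples in
#'   columns.
#' @return Named numeric 96-vector summing to 1.
#' @export
cohortAverageSpectrum <- function(spectra) {
  if (is.list(spectra)) spectra <- do.call(cbind, spectra)
  spectra <- as.matrix(spectra)
  stopifnot(nrow(spectra) == 96L)
  pooled <- rowSums(spectra)
  gt <- sum(pooled)
  if (gt <= 0) stop("cohort is empty: no mutations to average")
  avg <- pooled / gt
  names(avg) <- SBS96_CHANNELS
  avg
}

#' Compare two CA>AA fractions by Fisher's exact test
#'
#' Tests whether two samples (or conditions) differ in their fraction of
#' CA>AA mutations, via the two-sided Fisher's exact test on the 2x2 table of
#' CA>AA versus other mutations.
#'
#' @param a,b CA>AA summaries from [caAaFraction()].
#' @return Two-sided p-value.
#' @export
compareCaFractions <- function(a, b) {
  if (a$total <= 0 || b$total <= 0) stop("both totals must be positive")
  tab <- matrix(c(a$ca_aa_count, a$total - a$ca_aa_count,
                  b$ca_aa_count, b$total - b$ca_aa_count),
                nrow = 2L, byrow = TRUE)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Ratio paired t-test on contribution scores
#'
#' Paired comparison of positive scores (e.g. GCVsig contribution under two
#' treatments) on the ratio scale: a one-sample t-test of `log(b/a)` against
#' mean zero.
#'
#' @param a,b Numeric vectors of paired scores in `(0, 1]` (same length,
#'   n >= 2).
#' @return Two-sided p-value.
#' @export
ratioTTest <- function(a, b) {
  if (length(a) != length(b)) stop("paired scores must have equal length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  if (any(a <= 0) || any(b <= 0)) stop("ratio t-test requires positive scores")
  lr <- log(b / a)
  if (stats::sd(lr) == 0) {
    # all ratios identical: t is 0 (p = 1) when the common log-ratio is 0
    return(if (all(lr == 0)) 1 else 0)
  }
  stats::t.test(lr, mu = 0)$p.value
}
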