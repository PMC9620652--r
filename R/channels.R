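#' @useDynLib sparsesig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

BASES <- c("A", "C", "G", "T")
PYRIMIDINE_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Canonical SBS96 channel labels
#'
#' The 96 single-base-substitution classes on the pyrimidine strand in the
#' standard COSMIC order: substitutions `C>A, C>G, C>T, T>A, T>C, T>G`, each
#' expanded over the 16 combinations of 5' and 3' flanking bases in
#' alphabetical order. Labels look like `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @examples
#' head(sbs96Channels())
#' @export
sbs96Channels <- function() {
  unlist(lapply(PYRIMIDINE_SUBS, function(sub) {
    ref <- substr(sub, 1L, 1L)
    unlist(lapply(BASES, function(p5) {
      paste0(p5, "[", sub, "]", BASES)
    }))
  }), use.names = FALSE)
}

SBS96_CHANNELS <- sbs96Channels()

# the four C>A channels with a 3' adenine: the CA>AA dinucleotide change
CA_AA_CHANNELS <- paste0(BASES, "[C>A]A")

revcompBase <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]
}

revcompSeq <- function(s) {
  vapply(s, function(x) {
    paste(rev(unname(revcompBase(strsplit(x, "")[[1L]]))), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Map a trinucleotide substitution to its SBS96 channel
#'
#' Resolves a reference trinucleotide context plus alternate base to the
#' canonical pyrimidine-strand channel label. Purine-centred contexts (middle
#' base A or G) are reverse complemented — context, reference and alternate
#' alike — before lookup, so either strand representation of the same event
#' maps to the same channel.
#'
#' @param context Character vector of 3-base reference contexts (the middle
#'   base is the mutated reference base).
#' @param alt Character vector of single alternate bases.
#' @return Character vector of channel labels (NA where the context contains
#'   a non-ACGT base).
#' @examples
#' contextToChannel("ACA", "A")  # "A[C>A]A"
#' contextToChannel("TGT", "T")  # same channel, opposite strand
#' @export
contextToChannel <- function(context, alt) {
  stopifnot(length(context) == length(alt))
  context <- toupper(context)
  alt <- toupper(alt)
  out <- rep(NA_character_, length(context))
  ok <- nchar(context) == 3L & alt %in% BASES &
    !grepl("[^ACGT]", context)
  if (!any(ok)) return(out)
  ctx <- context[ok]
  a <- alt[ok]
  mid <- substr(ctx, 2L, 2L)
  flip <- mid %in% c("A", "G")
  ctx[flip] <- revcompSeq(ctx[flip])
  a[flip] <- unname(revcompBase(a[flip]))
  mid <- substr(ctx, 2L, 2L)
  lab <- paste0(substr(ctx, 1L, 1L), "[", mid, ">", a, "]", substr(ctx, 3L, 3L))
  lab[mid == a] <- NA_character_
  lab[!lab %in% SBS96_CHANNELS] <- NA_character_
  out[ok] <- lab
  out
}

# channel label -> (pyrimidine) ref base, alt base, 5'/3' flanks
channelParts <- function(channels) {
  data.frame(
    p5 = substr(channels, 1L, 1L),
    ref = substr(channels, 3L, 3L),
    alt = substr(channels, 5L, 5L),
    p3 = substr(channels, 7L, 7L),
    stringsAsFactors = FALSE
  )
}
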