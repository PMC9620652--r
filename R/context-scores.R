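#' Classify C>A mutations by replication strand
#'
#' Assigns each C>A-class mutation (C>A on the reference strand, or its G>T
#' complement) to the leading or lagging strand given an annotation of local
#' replication direction. Convention: a pyrimidine-strand C>A event in a
#' right-replicating region (fork moving in the direction of increasing
#' coordinates) is "leading"; the G>T representation of the same event flips
#' class. Loci outside the annotation, and non-C>A mutations, are "unknown".
#'
#' @param records Mutation record data.frame (see [readMutationTable()]).
#' @param annotation Replication-direction intervals: a data.frame with
#'   columns `chrom`, `start`, `end` (1-based, inclusive) and `direction`
#'   ("left" or "right"), or a `GRanges` with a `direction` metadata column.
#'   Intervals must not overlap.
#' @return `records` with an added `replication_class` column
#'   (`leading` / `lagging` / `unknown`).
#' @export
classifyReplicationStrand <- function(records, annotation) {
  if (is.data.frame(annotation)) {
    gr <- GenomicRanges::GRanges(
      seqnames = annotation$chrom,
      ranges = IRanges::IRanges(start = annotation$start,
                                end = annotation$end),
      direction = annotation$direction)
  } else {
    gr <- annotation
  }
  if (!all(gr$direction %in% c("left", "right")))
    stop("annotation direction must be 'left' or 'right'")
  if (length(gr) > 1L) {
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                        drop.redundant = TRUE)
    if (length(hits) > 0L) stop("replication annotation intervals overlap")
  }
  cls <- rep("unknown", nrow(records))
  isCA <- records$ref == "C" & records$alt == "A"
  isGT <- records$ref == "G" & records$alt == "T"
  idx <- which(isCA | isGT)
  if (length(idx)) {
    q <- GenomicRanges::GRanges(
      seqnames = records$chrom[idx],
      ranges = IRanges::IRanges(start = records$pos[idx], width = 1L))
    ov <- GenomicRanges::findOverlaps(q, gr, select = "first")
    hit <- !is.na(ov)
    dirn <- rep(NA_character_, length(idx))
    dirn[hit] <- gr$direction[ov[hit]]
    # right-replicating + pyrimidine-strand C>A -> leading; G>T flips
    lead <- (dirn == "right" & isCA[idx]) | (dirn == "left" & isGT[idx])
    cls[idx[hit & lead]] <- "leading"
    cls[idx[hit & !lead]] <- "lagging"
  }
  records$replication_class <- cls
  records
}

#' Replication strand asymmetry test
#'
#' Counts leading- versus lagging-strand C>A mutations, reports the
#' pseudocounted log2 ratio `log2((leading + 0.5) / (lagging + 0.5))`, and
#' the two-sided exact binomial p-value against an even split.
#'
#' @param annotated Output of [classifyReplicationStrand()] (at least one
#'   classified mutation required).
#' @return A list: `leading`, `lagging`, `log2_ratio`, `p_value`.
#' @export
strandAsymmetryTest <- function(annotated) {
  lead <- sum(annotated$replication_class == "leading")
  lag <- sum(annotated$replication_class == "lagging")
  if (lead + lag == 0L) stop("no classified C>A mutations")
  list(leading = lead, lagging = lag,
       log2_ratio = log2((lead + 0.5) / (lag + 0.5)),
       p_value = stats::binom.test(lead, lead + lag, p = 0.5)$p.value)
}

#' Select high-variance hotspot genes
#'
#' Ranks genes by the variance of their mutation counts across annotated
#' positions (a gene with a few dominant hotspots has high variance), drops
#' TP53 (its volume of hotspot sites dominates any ranking), keeps the top
#' `topN` genes, and within them retains hotspots with at least
#' `minOccurrences` recorded occurrences.
#'
#' @param hotspots data.frame with at least `gene`, `position` (or `label`)
#'   and `occurrences` columns, one row per hotspot site.
#' @param topN Number of genes to keep (default 50).
#' @param minOccurrences Minimum occurrence count for a retained hotspot
#'   (default 100).
#' @return A list: `genes` (selected gene symbols, variance-descending) and
#'   `hotspots` (the filtered hotspot rows for those genes).
#' @export
selectHotspotGenes <- function(hotspots, topN = 50L, minOccurrences = 100L) {
  if (nrow(hotspots) == 0L) stop("empty hotspot table")
  byGene <- split(hotspots$occurrences, hotspots$gene)
  v <- vapply(byGene, function(x) if (length(x) > 1L) stats::var(x) else 0,
              numeric(1L))
  v <- v[names(v) != "TP53"]
  genes <- names(sort(v, decreasing = TRUE))
  genes <- utils::head(genes, topN)
  keep <- hotspots$gene %in% genes & hotspots$occurrences >= minOccurrences
  list(genes = genes, hotspots = hotspots[keep, , drop = FALSE])
}

#' Accessibility of a hotspot to a mutational signature
#'
#' The probability mass the signature places on the exact trinucleotide
#' substitution channel needed to create the hotspot mutation. Contexts
#' given on the purine strand are reverse complemented first, so the score
#' is strand-invariant.
#'
#' @param context 3-base reference context of the hotspot site.
#' @param alt Alternate base creating the hotspot mutation.
#' @param signature Named 96-vector of channel probabilities (one catalog
#'   column, e.g. `signatureProbs(cat)[, "GCVsig"]`).
#' @return The signature probability of that channel.
#' @export
hotspotAccessibility <- function(context, alt, signature) {
  stopifnot(length(signature) == 96L)
  if (is.null(names(signature))) names(signature) <- SBS96_CHANNELS
  if (toupper(alt) == toupper(substr(context, 2L, 2L)))
    stop("alt equals the reference middle base: not a substitution")
  chan <- contextToChannel(context, alt)
  if (is.na(chan)) stop("unresolvable hotspot context: ", context, ">", alt)
  unname(signature[chan])
}

#' Gene-level accessibility
#'
#' Sum of [hotspotAccessibility()] over a gene's retained hotspots:
#' the total signature mass pointed at that gene's driver sites.
#'
#' @param hotspots data.frame of hotspots for one gene, with `context` and
#'   `alt` columns.
#' @param signature Named 96-vector of channel probabilities.
#' @return Summed accessibility (0 for an empty table).
#' @export
geneAccessibility <- function(hotspots, signature) {
  if (nrow(hotspots) == 0L) return(0)
  if (length(unique(hotspots$gene)) > 1L)
    stop("hotspots must all belong to one gene")
  sum(vapply(seq_len(nrow(hotspots)), function(i)
    hotspotAccessibility(hotspots$context[i], hotspots$alt[i], signature),
    numeric(1L)))
}

#' Rank genes by signature accessibility
#'
#' Applies [selectHotspotGenes()] then scores every selected gene with
#' [geneAccessibility()], returning genes in descending accessibility order.
#'
#' @inheritParams selectHotspotGenes
#' @param signature Named 96-vector of channel probabilities.
#' @return data.frame with `gene` and `accessibility`, sorted descending.
#' @export
rankGeneAccessibility <- function(hotspots, signature, topN = 50L,
                                  minOccurrences = 100L) {
  sel <- selectHotspotGenes(hotspots, topN = topN,
                            minOccurrences = minOccurrences)
  acc <- vapply(sel$genes, function(g)
    geneAccessibility(sel$hotspots[sel$hotspots$gene == g, , drop = FALSE],
                      signature), numeric(1L))
  out <- data.frame(gene = sel$genes, accessibility = unname(acc),
                    stringsAsFactors = FALSE)
  out[order(-out$accessibility, out$gene), , drop = FALSE]
}
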