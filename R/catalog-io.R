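#' Default column mapping for mutation tables
#'
#' Panel exports name their columns differently; the reader takes a mapping
#' from internal field names to file column names. `context` and `age` are
#' optional fields.
#'
#' @return Named character vector mapping internal names to column names.
#' @export
defaultColumnMapping <- function() {
  c(sample_id = "sample_id", patient_id = "patient_id", chrom = "chrom",
    pos = "pos", ref = "ref", alt = "alt", cancer_group = "cancer_group",
    age = "age", context = "context")
}

CANCER_GROUPS <- c("BLCA", "GI", "HEME", "HNSC", "SARC", "SKIN", "OTHER")

#' Read a MAF-like somatic SNV table
#'
#' Reads a tab-separated mutation table with one row per somatic single
#' nucleotide variant. Rows whose ref or alt is not a single A/C/G/T base
#' (indels, dinucleotides, ambiguity codes) are dropped with a message giving
#' the count. Positions are 1-based in the file.
#'
#' @param path Path to a TSV file with a header row.
#' @param columns Named mapping from internal field names to file column
#'   names; see [defaultColumnMapping()]. Required fields: sample_id,
#'   patient_id, chrom, pos, ref, alt, cancer_group. Optional: age, context.
#' @return A data.frame of validated mutation records with the internal
#'   column names (`context` is `NA` where absent).
#' @export
readMutationTable <- function(path, columns = defaultColumnMapping()) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty mutation table: ", path)
  # read as character throughout: allele columns of all "T" would otherwise
  # be parsed as logical
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0L) stop("mutation table has no data rows: ", path)
  required <- c("sample_id", "patient_id", "chrom", "pos", "ref", "alt",
                "cancer_group")
  mapped <- function(field)
    if (field %in% names(columns)) columns[[field]] else NULL
  for (field in required) {
    col <- mapped(field)
    if (is.null(col) || !col %in% names(raw))
      stop(sprintf("missing required column '%s' (field %s)",
                   if (is.null(col)) field else col, field))
  }
  getcol <- function(field, default = NULL) {
    col <- mapped(field)
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else default
  }
  df <- data.frame(
    sample_id = as.character(getcol("sample_id")),
    patient_id = as.character(getcol("patient_id")),
    chrom = as.character(getcol("chrom")),
    pos = as.integer(getcol("pos")),
    ref = toupper(as.character(getcol("ref"))),
    alt = toupper(as.character(getcol("alt"))),
    cancer_group = as.character(getcol("cancer_group")),
    age = as.numeric(getcol("age", default = rep(NA_real_, nrow(raw)))),
    context = toupper(as.character(getcol("context",
                                          default = rep(NA_character_, nrow(raw))))),
    stringsAsFactors = FALSE
  )
  snv <- df$ref %in% BASES & df$alt %in% BASES & df$ref != df$alt
  dropped <- sum(!snv)
  if (dropped > 0L)
    message(dropped, " non-SNV row(s) dropped")
  df <- df[snv, , drop = FALSE]
  bad_pos <- !is.na(df$pos) & df$pos < 1L
  if (any(bad_pos)) stop("positions must be >= 1")
  bad_grp <- !df$cancer_group %in% CANCER_GROUPS
  if (any(bad_grp)) {
    message(sum(bad_grp), " record(s) with unrecognised cancer group set to OTHER")
    df$cancer_group[bad_grp] <- "OTHER"
  }
  has_ctx <- !is.na(df$context) & df$context != ""
  if (any(has_ctx & nchar(df$context) != 3L))
    stop("context column must contain 3-base strings")
  mism <- has_ctx & substr(df$context, 2L, 2L) != df$ref
  if (any(mism))
    stop(sum(mism), " record(s) whose context middle base does not match ref")
  rownames(df) <- NULL
  df
}

#' Write a mutation table
#'
#' Inverse of [readMutationTable()] under the default column mapping;
#' the round trip preserves every field.
#'
#' @param records Mutation record data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeMutationTable <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a COSMIC-layout SBS96 signature catalog
#'
#' First column: channel labels like `"A[C>A]A"`; remaining columns: one
#' numeric column per signature. Rows may be in any order and are reordered
#' canonically. Columns are renormalized to unit sum only when the deviation
#' is below `1e-4`; larger deviations indicate a malformed file and raise an
#' error.
#'
#' @param path Path to the signature TSV.
#' @return A [SignatureCatalog-class].
#' @export
readSignatureCatalog <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) < 2L) stop("signature catalog needs a label column plus >= 1 signature")
  labels <- as.character(raw[[1L]])
  if (nrow(raw) != 96L)
    stop(sprintf("signature catalog must have 96 rows, found %d", nrow(raw)))
  if (anyDuplicated(labels))
    stop("duplicate channel label: ",
         labels[duplicated(labels)][1L])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- labels
  cs <- colSums(mat)
  off <- abs(cs - 1)
  if (any(off >= 1e-4))
    stop(sprintf("column '%s' sums to %.6f (must be within 1e-4 of 1)",
                 colnames(mat)[which.max(off)], cs[which.max(off)]))
  mat <- sweep(mat, 2L, cs, "/")
  SignatureCatalog(mat)
}

#' Write a signature catalog in COSMIC SBS96 text layout
#'
#' @param catalog A [SignatureCatalog-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeSignatureCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "SignatureCatalog"))
  df <- data.frame(Type = rownames(catalog@probs),
                   signif(catalog@probs, 6), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep only each patient's most recent sample
#'
#' For patients with several samples, retains the mutations of the sample
#' with the greatest participant age; earlier samples are removed entirely.
#' Age ties are broken deterministically by lexicographic sample_id (smallest
#' wins). Samples with missing age are never preferred over one with a known
#' age; patients whose samples all lack age keep their first-listed sample,
#' with a message.
#'
#' @param records Mutation record data.frame (see [readMutationTable()]).
#' @return The filtered data.frame: one sample_id per patient_id.
#' @export
dedupLatestSample <- function(records) {
  if (nrow(records) == 0L) return(records)
  samp <- unique(records[, c("patient_id", "sample_id", "age")])
  samp$age_key <- ifelse(is.na(samp$age), -Inf, samp$age)
  samp$order <- seq_len(nrow(samp))
  keep <- vapply(split(samp, samp$patient_id), function(g) {
    best <- g[g$age_key == max(g$age_key), , drop = FALSE]
    if (nrow(best) > 1L) {
      if (all(is.infinite(best$age_key))) {
        message("patient ", best$patient_id[1L],
                ": no age metadata; keeping first-listed sample")
        best <- best[order(best$order), , drop = FALSE]
      } else {
        best <- best[order(best$sample_id), , drop = FALSE]
      }
    }
    best$sample_id[1L]
  }, character(1L))
  out <- records[records$sample_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
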