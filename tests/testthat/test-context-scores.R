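mkRec <- function(chrom, pos, ref, alt) {
  data.frame(sample_id = "s", patient_id = "p", chrom = chrom, pos = pos,
             ref = ref, alt = alt, cancer_group = "OTHER", age = NA,
             context = NA_character_, stringsAsFactors = FALSE)
}

test_that("replication strand classes follow direction and strand", {
  ann <- data.frame(chrom = "chr1", start = c(1L, 101L), end = c(100L, 200L),
                    direction = c("right", "left"))
  rec <- mkRec("chr1", c(50L, 50L, 150L, 150L, 500L, 60L),
               c("C", "G", "C", "G", "C", "C"),
               c("A", "T", "A", "T", "A", "T"))
  out <- classifyReplicationStrand(rec, ann)
  # pyrimidine C>A in right-replicating region: leading; G>T flips
  expect_equal(out$replication_class[1:4],
               c("leading", "lagging", "lagging", "leading"))
  expect_equal(out$replication_class[5], "unknown")  # outside annotation
  expect_equal(out$replication_class[6], "unknown")  # C>T is not C>A class

  overlapping <- data.frame(chrom = "chr1", start = c(1L, 50L),
                            end = c(100L, 150L),
                            direction = c("right", "left"))
  expect_error(classifyReplicationStrand(rec, overlapping), "overlap")
})

test_that("classification agrees with a brute-force interval scan", {
  ann <- makeReplicationAnnotation(10000L, 500L)
  set.seed(71)
  n <- 200
  rec <- mkRec("chr1", sample.int(12000L, n, replace = TRUE),
               sample(c("C", "G"), n, replace = TRUE), "A")
  rec$alt <- ifelse(rec$ref == "C", "A", "T")
  out <- classifyReplicationStrand(rec, ann)
  brute <- vapply(seq_len(n), function(i) {
    hit <- which(ann$start <= rec$pos[i] & ann$end >= rec$pos[i])
    if (!length(hit)) return("unknown")
    d <- ann$direction[hit]
    if ((d == "right") == (rec$ref[i] == "C")) "leading" else "lagging"
  }, character(1))
  expect_equal(out$replication_class, brute)
})

test_that("the asymmetry test reports counts, log2 ratio and binomial p", {
  ann <- data.frame(chrom = "chr1", start = 1L, end = 1000L,
                    direction = "right")
  even <- classifyReplicationStrand(
    mkRec("chr1", 1:20, rep(c("C", "G"), 10), rep(c("A", "T"), 10)), ann)
  res <- strandAsymmetryTest(even)
  expect_equal(res$leading, 10)
  expect_equal(res$lagging, 10)
  expect_equal(res$log2_ratio, 0)
  expect_equal(res$p_value, 1)

  allLead <- classifyReplicationStrand(
    mkRec("chr1", 1:10, rep("C", 10), rep("A", 10)), ann)
  res10 <- strandAsymmetryTest(allLead)
  expect_equal(res10$p_value, 2 * 0.5^10)

  # aggregation over samples equals the sum of per-sample counts
  both <- rbind(even, allLead)
  agg <- strandAsymmetryTest(both)
  expect_equal(agg$leading, res$leading + res10$leading)
  expect_equal(agg$lagging, res$lagging + res10$lagging)

  expect_error(strandAsymmetryTest(
    classifyReplicationStrand(mkRec("chr1", 5000L, "C", "A"), ann[0, ])),
    "classified")
})

test_that("a planted 2:1 leading bias is recovered", {
  ann <- makeReplicationAnnotation(100000L, 1000L)
  set.seed(55)
  n <- 1000
  pos <- sample.int(100000L, n, replace = TRUE)
  seg <- ((pos - 1) %/% 1000)  # even: right-replicating, odd: left
  dirn <- ifelse(seg %% 2 == 0, "right", "left")
  lead <- runif(n) < 2 / 3
  # choose the strand representation that realises the wanted class
  useC <- (dirn == "right") == lead
  rec <- mkRec("chr1", pos, ifelse(useC, "C", "G"), ifelse(useC, "A", "T"))
  res <- strandAsymmetryTest(classifyReplicationStrand(rec, ann))
  expect_lt(abs(res$log2_ratio - 1), 0.3)
  expect_lt(res$p_value, 0.001)
})

test_that("hotspot gene selection ranks by variance and drops TP53", {
  single <- data.frame(gene = "KRAS", position = 1:2, occurrences = c(500, 40))
  sel <- selectHotspotGenes(single)
  expect_equal(sel$genes, "KRAS")
  expect_equal(nrow(sel$hotspots), 1L)  # the 40-occurrence site is filtered

  withTP53 <- rbind(single,
                    data.frame(gene = "TP53", position = 1:3,
                               occurrences = c(100000, 1, 1)))
  expect_false("TP53" %in% selectHotspotGenes(withTP53)$genes)

  # 60 genes with known variances: selection equals sort-then-slice
  set.seed(77)
  tab <- do.call(rbind, lapply(1:60, function(g) data.frame(
    gene = sprintf("G%02d", g), position = 1:5,
    occurrences = round(rlnorm(5, 5, 0.5 + g / 30)))))
  sel60 <- selectHotspotGenes(tab, topN = 50)
  vars <- sapply(split(tab$occurrences, tab$gene), var)
  oracle <- names(sort(vars, decreasing = TRUE))[1:50]
  expect_equal(sel60$genes, oracle)
  expect_true(all(sel60$hotspots$occurrences >= 100))
  expect_error(selectHotspotGenes(tab[0, ]), "empty")
})

test_that("hotspot accessibility reads the signature mass of the exact channel", {
  gcv <- signatureProbs(catCosmic)[, "GCVsig"]
  uniform <- rep(1 / 96, 96); names(uniform) <- sbs96Channels()
  expect_equal(hotspotAccessibility("ACG", "T", uniform), 1 / 96)

  zero <- rep(0, 96); names(zero) <- sbs96Channels(); zero[1] <- 1
  expect_equal(hotspotAccessibility("TCT", "G", zero), 0)

  # strand invariance: the purine-strand representation scores identically
  expect_equal(hotspotAccessibility("CCA", "A", gcv),
               hotspotAccessibility("TGG", "T", gcv))

  # a KRAS-G12C-like C>A hotspot in CCA context sits in the top decile of
  # channels under a CA>AA-concentrated signature
  score <- hotspotAccessibility("CCA", "A", gcv)
  expect_gte(sum(gcv <= score), 87)  # rank within the top 10 of 96

  expect_error(hotspotAccessibility("ACA", "C", gcv), "reference middle")
})

test_that("gene accessibility is additive and order-invariant", {
  gcv <- signatureProbs(catCosmic)[, "GCVsig"]
  hs <- data.frame(gene = "KRAS", context = c("CCA", "TCT"), alt = c("A", "A"),
                   occurrences = c(200, 150), stringsAsFactors = FALSE)
  expect_equal(geneAccessibility(hs, gcv),
               hotspotAccessibility("CCA", "A", gcv) +
                 hotspotAccessibility("TCT", "A", gcv))
  expect_equal(geneAccessibility(hs[2:1, ], gcv), geneAccessibility(hs, gcv))
  expect_equal(geneAccessibility(hs[0, ], gcv), 0)

  # ranking equals a brute-force per-gene summation
  tab <- makeHotspotTable(8, seed = 91)
  tab <- selectHotspotGenes(tab, topN = 8)$hotspots
  ranked <- rankGeneAccessibility(makeHotspotTable(8, seed = 91), gcv,
                                  topN = 8)
  brute <- sapply(split(tab, tab$gene), function(g)
    sum(mapply(function(cx, al) gcv[[oracleChannel(cx, al)]],
               g$context, g$alt)))
  brute <- sort(brute, decreasing = TRUE)
  common <- intersect(ranked$gene, names(brute))
  expect_equal(ranked$accessibility[match(common, ranked$gene)],
               unname(brute[common]))
})
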