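mkFeatures <- function(starts, widths, strands, biotypes) {
  gr <- GRanges("chrI", IRanges(starts, width = widths), strand = strands,
                seqinfo = smallSeqinfo(50000L))
  gr$featureId <- paste0("f", seq_along(gr))
  gr$biotype <- biotypes
  gr
}

test_that("the upstream window is strand-relative and strictly bounded", {
  gene <- mkFeatures(1001, 500, "+", "gene")
  nearPeak <- GRanges("chrI", IRanges(801, 850))   # ends 150 bp before TSS
  farPeak <- GRanges("chrI", IRanges(601, 750))    # ends 250 bp before TSS
  ann <- annotatePeaks(c(nearPeak, farPeak), gene)
  expect_equal(ann$relation, c("upstream", "unannotated"))

  # same geometry on the minus strand: upstream flips to the right
  geneM <- mkFeatures(1001, 500, "-", "gene")
  rightPeak <- GRanges("chrI", IRanges(1651, 1700))  # 150 bp past gene end
  ann2 <- annotatePeaks(rightPeak, geneM)
  expect_equal(ann2$relation, "upstream")
})

test_that("a peak may annotate to several features; fractions follow", {
  feats <- mkFeatures(c(1001, 1601, 5001, 9001), c(500, 500, 100, 80),
                      c("+", "+", "+", "+"),
                      c("gene", "gene", "gene", "tRNA_gene"))
  peaks <- GRanges("chrI", IRanges(c(1201, 1602, 9010, 20001),
                                   width = c(500, 100, 40, 100)))
  ann <- annotatePeaks(peaks, feats)
  # first peak spans gene 1 and reaches the upstream window of gene 2
  expect_gte(sum(ann$peakId == "peak00001"), 2L)
  fr <- featureClassFractions(ann)
  expect_equal(fr[["protein-coding"]], 0.5)
  expect_equal(fr[["tRNA"]], 0.25)
  expect_equal(fr[["unannotated"]], 0.25)
  expect_error(featureClassFractions(ann[0, ]), "empty")
})

test_that("annotation equals the brute-force all-pairs scan", {
  set.seed(11)
  for (rep in 1:5) {
    nf <- 40
    feats <- GRanges("chrI", IRanges(sample.int(40000, nf),
                                     width = sample(100:800, nf, TRUE)),
                     strand = sample(c("+", "-"), nf, TRUE),
                     seqinfo = smallSeqinfo(50000L))
    feats$featureId <- paste0("f", seq_len(nf))
    feats$biotype <- "gene"
    peaks <- GRanges("chrI", IRanges(sample.int(40000, 30),
                                     width = sample(50:400, 30, TRUE)),
                     seqinfo = smallSeqinfo(50000L))
    ann <- annotatePeaks(peaks, feats)
    ann <- ann[ann$relation != "unannotated", ]
    oracle <- bfAnnotate(peaks, feats)
    gotPairs <- paste(match(ann$peakId, sprintf("peak%05d", seq_len(30))),
                      match(ann$featureId, feats$featureId))
    oraclePairs <- if (is.null(oracle)) character(0)
                   else unique(paste(oracle$peak, oracle$feature))
    expect_setequal(gotPairs, oraclePairs)
  }
})

test_that("mirroring the genome leaves annotation counts invariant", {
  set.seed(12)
  L <- 50000L
  nf <- 30
  feats <- GRanges("chrI", IRanges(sample.int(40000, nf),
                                   width = sample(100:600, nf, TRUE)),
                   strand = sample(c("+", "-"), nf, TRUE),
                   seqinfo = smallSeqinfo(L))
  feats$featureId <- paste0("f", seq_len(nf)); feats$biotype <- "gene"
  peaks <- GRanges("chrI", IRanges(sample.int(40000, 20),
                                   width = sample(50:300, 20, TRUE)),
                   seqinfo = smallSeqinfo(L))
  mirror <- function(gr) {
    out <- GRanges("chrI", IRanges(L + 1L - end(gr), L + 1L - start(gr)),
                   strand = chartr("+-", "-+", as.character(strand(gr))),
                   seqinfo = smallSeqinfo(L))
    mcols(out) <- mcols(gr)
    out
  }
  a1 <- annotatePeaks(peaks, feats)
  a2 <- annotatePeaks(mirror(peaks), mirror(feats))
  expect_equal(table(a1$relation), table(a2$relation))
})

test_that("RPKM follows its formula and scales inversely with depth", {
  expect_equal(rpkm(10, 500, 1e6), 20)
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_equal(rpkm(7, 300, 2e6), rpkm(7, 300, 1e6) / 2)
  expect_error(rpkm(1, 0, 1e6), "length")
  expect_error(rpkm(1, 100, 0), "library")
})

test_that("gain-gene property comparison detects planted expression bias", {
  truth <- generateAnnotation(smallTruthConfig(seed = 21))
  genes <- truthGenes(truth)
  expr <- setNames(genes$expression, genes$geneId)
  # identical sets: ratios exactly one
  same <- compareGeneProperties(genes, genes, expr)
  expect_equal(unname(same$medianLength[["ratio"]]), 1)
  expect_equal(unname(same$medianExpression[["ratio"]]), 1)
  # planting in the top expression tercile shifts the expression median
  top <- genes[expr >= quantile(expr, 2 / 3)]
  biased <- compareGeneProperties(top, genes, expr)
  expect_gt(biased$medianExpression[["ratio"]], 1)
  expect_lt(biased$pExpression, 0.01)
  expect_error(compareGeneProperties(genes[0], genes, expr), "empty")
})

test_that("random gain sets give calibrated rank-sum p-values", {
  # a small gain sample from a large gene pool keeps the sample/population
  # overlap negligible, so the null p-values are near-uniform
  truth <- generateAnnotation(truthConfig(seed = 22))
  genes <- truthGenes(truth)
  expr <- setNames(genes$expression, genes$geneId)
  set.seed(99)
  hits <- replicate(200, {
    g <- genes[sample(length(genes), 20)]
    compareGeneProperties(g, genes, expr)$pExpression < 0.05
  })
  # the sampled set is a subset of the comparison population, which makes
  # the rank-sum test mildly conservative; the key property is that it
  # never rejects above the nominal band
  expect_gte(mean(hits), 0.01)
  expect_lte(mean(hits), 0.08)
})
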