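test_that("RPKM coverage follows its formula and conserves read counts", {
  si <- smallSeqinfo(1000L)
  bins <- GRanges("chrI", IRanges(seq(1, by = 10, length.out = 100),
                                  width = 10), seqinfo = si)
  cts <- integer(100); cts[5] <- 1L
  bc <- BinnedCounts(bins, cbind(s = cts), librarySizes = 1e6, binWidth = 10L)
  tr <- coverageRpkm(bc)
  expect_equal(trackValues(tr)$chrI[5], 100)   # 1 read / 10 bp bin / 1e6
  expect_equal(normalization(tr), "RPKM")

  set.seed(1)
  cts2 <- as.integer(rpois(100, 4))
  bc2 <- BinnedCounts(bins, cbind(s = cts2), librarySizes = 123456,
                      binWidth = 10L)
  tr2 <- coverageRpkm(bc2)
  recovered <- sum(trackValues(tr2)$chrI * (10 / 1000) * (123456 / 1e6))
  expect_equal(recovered, sum(cts2))
  expect_true(all(trackValues(coverageRpkm(bc2, totalReads = 1))$chrI >= 0))
  expect_error(coverageRpkm(bc2, totalReads = 0), "positive")
})

test_that("RNase-H scaling multiplies by the unique/total ratio", {
  tr <- constantTrack(5)
  expect_equal(trackValues(scaleRnh(tr, 100, 100))$chrI,
               trackValues(tr)$chrI)
  sc <- scaleRnh(tr, 80, 100)
  expect_equal(trackValues(sc)$chrI, rep(4, 1000))
  expect_equal(normalization(sc), "RNH-scaled")
  # multiplying back by the reciprocal factor restores the input
  expect_equal(trackValues(sc)$chrI * (100 / 80), trackValues(tr)$chrI,
               tolerance = 1e-12)
  expect_error(scaleRnh(tr, 101, 100), "exceed")
})

test_that("wild-type subtraction is elementwise, unclamped and linear", {
  set.seed(2)
  a <- constantTrack(0); b <- constantTrack(0)
  a@values$chrI <- rnorm(1000, 5); b@values$chrI <- rnorm(1000, 6)
  d <- subtractWt(a, b)
  expect_true(any(trackValues(d)$chrI < 0))   # negatives preserved
  expect_equal(trackValues(subtractWt(a, a))$chrI, rep(0, 1000))
  expect_equal(trackValues(subtractWt(a, constantTrack(0)))$chrI,
               trackValues(a)$chrI)
  # region means commute with subtraction
  expect_equal(mean(trackValues(d)$chrI[11:40]),
               mean(trackValues(a)$chrI[11:40]) -
                 mean(trackValues(b)$chrI[11:40]))
  expect_error(subtractWt(a, constantTrack(0, bw = 20L)), "bin widths")
})

test_that("reference-point profiles are flat for constant signal and peaked for a delta", {
  tr <- constantTrack(3, len = 20000L)
  anchors <- GRanges("chrI", IRanges(c(9001, 12001), width = 200),
                     strand = "+", seqinfo = smallSeqinfo(20000L))
  mm <- metaplotReferencePoint(tr, anchors, flankBp = 2000, nBins = 40)
  prof <- meanProfile(mm)
  expect_lt(max(prof) - min(prof), 1e-9)

  delta <- constantTrack(0, len = 20000L)
  mid <- 9100
  delta@values$chrI[(mid - 1) %/% 10 + 1] <- 50
  mm2 <- metaplotReferencePoint(delta, anchors[1], flankBp = 2000, nBins = 40)
  expect_equal(which.max(meanProfile(mm2)), 20, tolerance = 1)

  # fully off-chromosome windows (anchor beyond the chromosome end) are
  # dropped with a notice; partial windows pad with NaN instead
  edge <- suppressWarnings(GRanges("chrI", IRanges(25001, 25010),
                                   strand = "+",
                                   seqinfo = smallSeqinfo(20000L)))
  withEdge <- suppressWarnings(c(anchors, edge))
  expect_message(
    mm3 <- metaplotReferencePoint(tr, withEdge, flankBp = 2000,
                                  nBins = 10),
    "dropped")
  expect_equal(nrow(mm3@values), 2L)
  nearEdge <- GRanges("chrI", IRanges(501, 600), strand = "+",
                      seqinfo = smallSeqinfo(20000L))
  mm4 <- metaplotReferencePoint(tr, nearEdge, flankBp = 2000, nBins = 40)
  expect_true(anyNA(mm4@values))
})

test_that("scaled-region rows reverse exactly with region strand", {
  set.seed(3)
  tr <- constantTrack(0, len = 20000L)
  tr@values$chrI <- rnorm(2000)
  plusGene <- GRanges("chrI", IRanges(5001, 6500), strand = "+",
                      seqinfo = smallSeqinfo(20000L))
  minusGene <- plusGene; strand(minusGene) <- "-"
  mp <- metaplotScaledRegions(tr, plusGene, bodyBins = 50, flankBp = 500,
                              flankBinWidth = 10)
  mq <- metaplotScaledRegions(tr, minusGene, bodyBins = 50, flankBp = 500,
                              flankBinWidth = 10)
  expect_equal(mp@values[1, ], rev(mq@values[1, ]))
  # constant track -> flat profile; a short region interpolates, no error
  flat <- metaplotScaledRegions(constantTrack(2, len = 20000L),
                                c(plusGene,
                                  GRanges("chrI", IRanges(100, 120),
                                          strand = "+",
                                          seqinfo = smallSeqinfo(20000L))),
                                bodyBins = 50)
  expect_lt(max(flat@values[1, ]) - min(flat@values[1, ]), 1e-9)
  expect_false(anyNA(flat@values[1, ]))
})

test_that("sense plus antisense equals the pooled-track profile", {
  truth <- generateAnnotation(smallTruthConfig(seed = 31))
  bc <- simulateDripCounts(truth, "WT", "S", 1)
  plus <- coverageRpkm(bc, strand = "+")
  minus <- coverageRpkm(bc, strand = "-")
  genes <- truthGenes(truth)[1:10]
  sas <- senseAntisenseSplit(plus, minus, genes, bodyBins = 40,
                             flankBp = 500, flankBinWidth = 50)
  pooled <- plus
  pooled@values <- Map(`+`, trackValues(plus), trackValues(minus))
  mmPooled <- metaplotScaledRegions(pooled, genes, bodyBins = 40,
                                    flankBp = 500, flankBinWidth = 50)
  expect_equal(sas$sense@values + sas$antisense@values, mmPooled@values,
               tolerance = 1e-9)
})

test_that("the sense-strand gene profile ramps toward the 3' end", {
  truth <- generateAnnotation(smallTruthConfig(seed = 32))
  bc <- simulateDripCounts(truth, "WT", "S", 1)
  plus <- coverageRpkm(bc, strand = "+")
  minus <- coverageRpkm(bc, strand = "-")
  genes <- truthGenes(truth)
  sas <- senseAntisenseSplit(plus, minus, genes, bodyBins = 90,
                             flankBp = 500, flankBinWidth = 50)
  body <- meanProfile(sas$sense)[11:100]   # body columns
  terciles <- split(body, rep(1:3, each = 30))
  expect_gt(mean(terciles[[3]]), mean(terciles[[1]]))
})

test_that("replicate averaging commutes with metaplotting", {
  set.seed(4)
  t1 <- constantTrack(0, len = 20000L); t2 <- constantTrack(0, len = 20000L)
  t1@values$chrI <- rnorm(2000); t2@values$chrI <- rnorm(2000)
  anchors <- GRanges("chrI", IRanges(c(7001, 11001), width = 100),
                     strand = "+", seqinfo = smallSeqinfo(20000L))
  mAvg <- metaplotReferencePoint(list(t1, t2), anchors, flankBp = 1000,
                                 nBins = 20)
  m1 <- metaplotReferencePoint(t1, anchors, flankBp = 1000, nBins = 20)
  m2 <- metaplotReferencePoint(t2, anchors, flankBp = 1000, nBins = 20)
  expect_equal(mAvg@values, (m1@values + m2@values) / 2, tolerance = 1e-12)
})

test_that("the asymmetry index hits its closed-form extremes", {
  # all signal strictly downstream of a plus-strand anchor: AI = 1
  tr <- constantTrack(0, len = 20000L)
  tr@values$chrI[1101:1200] <- 10   # bp 11001..12000
  anchor <- GRanges("chrI", IRanges(9901, 10100), strand = "+",
                    seqinfo = smallSeqinfo(20000L))
  mm <- metaplotReferencePoint(tr, anchor, flankBp = 3000, nBins = 60)
  ai <- asymmetryIndex(mm, coreExclusionBp = 300, nBoot = 100)
  expect_equal(ai@mean, 1)
  # flipping the anchor strand flips the sign
  minus <- anchor; strand(minus) <- "-"
  mmM <- metaplotReferencePoint(tr, minus, flankBp = 3000, nBins = 60)
  expect_equal(asymmetryIndex(mmM, 300, nBoot = 100)@mean, -1)
  expect_error(asymmetryIndex(mm, coreExclusionBp = 5000), "flank")
})

test_that("mirroring the genome leaves scaled profiles unchanged", {
  set.seed(5)
  L <- 20000L
  tr <- constantTrack(0, len = L)
  tr@values$chrI <- rnorm(L / 10)
  genes <- GRanges("chrI", IRanges(c(4001, 9001), width = c(1500, 800)),
                   strand = c("+", "-"), seqinfo = smallSeqinfo(L))
  mirTrack <- constantTrack(0, len = L)
  mirTrack@values$chrI <- rev(tr@values$chrI)
  mirGenes <- GRanges("chrI", IRanges(L + 1L - end(genes),
                                      L + 1L - start(genes)),
                      strand = chartr("+-", "-+", as.character(strand(genes))),
                      seqinfo = smallSeqinfo(L))
  m1 <- metaplotScaledRegions(tr, genes, bodyBins = 40, flankBp = 500,
                              flankBinWidth = 10)
  m2 <- metaplotScaledRegions(mirTrack, mirGenes, bodyBins = 40,
                              flankBp = 500, flankBinWidth = 10)
  expect_equal(m1@values, m2@values, tolerance = 1e-9)
})
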