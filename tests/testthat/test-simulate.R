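test_that("annotation generation is deterministic and respects constraints", {
  cfg <- smallTruthConfig(seed = 11)
  t1 <- generateAnnotation(cfg)
  t2 <- generateAnnotation(cfg)
  expect_identical(granges(truthGenes(t1)), granges(truthGenes(t2)))
  expect_identical(truthGainRegions(t1)$label, truthGainRegions(t2)$label)
  expect_identical(start(truthArs(t1)), start(truthArs(t2)))

  genes <- truthGenes(t1)
  expect_true(all(countOverlaps(genes, genes) == 1L))   # non-overlapping
  for (chr in seqlevels(truthSeqinfo(t1))) {
    mids <- start(truthArs(t1))[as.character(seqnames(truthArs(t1))) == chr]
    if (length(mids) > 1L) expect_true(all(diff(sort(mids)) >= 20000))
  }
  # every planted region lies inside a gene body, labels exclusive
  gains <- truthGainRegions(t1)
  expect_true(all(countOverlaps(gains, genes, type = "equal") == 1L))
  expect_true(all(gains$label %in%
                    c("hpr1-specific", "sen1-specific", "common")))
})

test_that("head-on placement honours the configured fraction", {
  truth <- generateAnnotation(truthConfig(seed = 3, nChrom = 2L,
    chromLength = 150000L, nGenes = 60L, nEarlyArs = 8L,
    nGainHpr1 = 5L, nGainSen1 = 5L, nGainCommon = 2L, piHO = 1.0))
  gains <- truthGainRegions(truth)
  sen1 <- gains[gains$label == "sen1-specific"]
  genes <- truthGenes(truth)
  ori <- genes$orientation[match(sen1$geneId, genes$geneId)]
  expect_true(all(ori == "HO"))

  truthDefault <- generateAnnotation(truthConfig(seed = 5))
  g <- truthGainRegions(truthDefault)
  s <- g[g$label == "sen1-specific"]
  genesD <- truthGenes(truthDefault)
  frac <- mean(genesD$orientation[match(s$geneId, genesD$geneId)] == "HO")
  # binomial 99% CI around 0.8 at n = 24
  expect_true(abs(frac - 0.8) < 2.58 * sqrt(0.8 * 0.2 / length(s)))
})

test_that("hybrid mean surface encodes condition/phase logic", {
  truth <- generateAnnotation(smallTruthConfig(seed = 2))
  # sen1-type gains are S-only: the G1 mean surface equals wild type
  expect_identical(dripExpectedMeans(truth, "sen1", "G1"),
                   dripExpectedMeans(truth, "WT", "G1"))
  # hpr1-type gains act in both phases
  muH <- dripExpectedMeans(truth, "hpr1", "G1")
  muW <- dripExpectedMeans(truth, "WT", "G1")
  expect_false(identical(muH, muW))
  # RNase-H control is pure background
  muR <- dripExpectedMeans(truth, "RNH", "S")
  cfg <- truthConfigOf(truth)
  expect_true(all(unlist(muR) == cfg@muBg))
  expect_error(dripExpectedMeans(truth, "nope", "S"), "condition")
  expect_error(simulateDripCounts(truth, "WT", "M"), "phase")
})

test_that("RNase-H counts average to background within 3 standard errors", {
  truth <- generateAnnotation(smallTruthConfig(seed = 4))
  cfg <- truthConfigOf(truth)
  bc <- simulateDripCounts(truth, "RNH", "S")
  x <- as.numeric(counts(bc))
  se <- sqrt((cfg@muBg + cfg@alphaBg * cfg@muBg^2) / length(x))
  expect_lt(abs(mean(x) - cfg@muBg), 3 * se)
})

test_that("planted gains recover the configured fold within 20%", {
  truth <- generateAnnotation(truthConfig(seed = 1))
  cfg <- truthConfigOf(truth)
  gains <- truthGainRegions(truth)
  active <- gains[gains$label %in% c("hpr1-specific", "common")]
  mut <- simulateDripCounts(truth, "hpr1", "S", 1)
  wt <- simulateDripCounts(truth, "WT", "S", 1)
  hit <- overlapsAny(rowRanges(mut), active, ignore.strand = FALSE)
  ratio <- mean(counts(mut)[hit, 1]) / mean(counts(wt)[hit, 1])
  expect_lt(abs(ratio - cfg@fGain) / cfg@fGain, 0.2)
})

test_that("expected gain log-fold-change grows strictly with the gain fold", {
  lfc <- vapply(c(1.5, 3, 6), function(fg) {
    truth <- generateAnnotation(smallTruthConfig(seed = 9, fGain = fg))
    gains <- truthGainRegions(truth)
    act <- gains[gains$label %in% c("hpr1-specific", "common")]
    muM <- dripExpectedMeans(truth, "hpr1", "S")
    muW <- dripExpectedMeans(truth, "WT", "S")
    bins <- genomeBins(truthSeqinfo(truth), truthConfigOf(truth)@callBin,
                      stranded = TRUE)
    hit <- overlapsAny(bins, act, ignore.strand = FALSE)
    mVec <- c(unlist(muM[["+"]], use.names = FALSE),
              unlist(muM[["-"]], use.names = FALSE))
    wVec <- c(unlist(muW[["+"]], use.names = FALSE),
              unlist(muW[["-"]], use.names = FALSE))
    log2(mean(mVec[hit]) / mean(wVec[hit]))
  }, numeric(1))
  expect_true(all(diff(lfc) > 0))
})

test_that("replicates share truth but differ in noise; seeds reproduce", {
  truth <- generateAnnotation(smallTruthConfig(seed = 6))
  a <- simulateDripCounts(truth, "WT", "S", 1)
  b <- simulateDripCounts(truth, "WT", "S", 1)
  c2 <- simulateDripCounts(truth, "WT", "S", 2)
  expect_identical(counts(a), counts(b))
  expect_false(identical(counts(a), counts(c2)))
})

test_that("damage mass splits by fork direction as configured", {
  # zero baseline isolates the planted damage
  truth <- generateAnnotation(smallTruthConfig(seed = 8,
                                               h2apBaselineMean = 1e-9))
  cfg <- truthConfigOf(truth)
  gains <- truthGainRegions(truth)
  anchors <- gains[gains$label %in% c("sen1-specific", "common")]
  sideMass <- function(track, a) {
    v <- trackValues(track)
    up <- dn <- 0
    for (i in seq_along(a)) {
      chr <- as.character(seqnames(a))[i]
      mid <- floor((start(a)[i] + end(a)[i]) / 2)
      cb <- (mid - 1) %/% cfg@covBin + 1
      n <- length(v[[chr]])
      w <- 500L
      lo <- sum(v[[chr]][max(1, cb - w):(cb - 1)])
      hi <- sum(v[[chr]][(cb + 1):min(n, cb + w)])
      if (a$forkDirection[i] == "+") { dn <- dn + hi; up <- up + lo }
      else { dn <- dn + lo; up <- up + hi }
    }
    c(up = up, down = dn)
  }
  symm <- sideMass(simulateH2apTrack(truth, "sen1", aDam = 0.5), anchors)
  expect_lt(abs(symm[["down"]] / symm[["up"]] - 1), 0.05)
  extreme <- sideMass(simulateH2apTrack(truth, "sen1", aDam = 1), anchors)
  expect_equal(extreme[["up"]], 0)
  expect_gt(extreme[["down"]], 0)
  expect_error(simulateH2apTrack(truth, "RNH"), "condition")
})
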