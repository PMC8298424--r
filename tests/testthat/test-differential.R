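mkCounts <- function(y, libs = NULL, bw = 200L, pitch = bw) {
  y <- as.matrix(y)
  bins <- GRanges("chrI", IRanges(seq(1L, by = pitch, length.out = nrow(y)),
                                  width = bw),
                  seqinfo = smallSeqinfo(pitch * nrow(y) + 1000L))
  BinnedCounts(bins, y, libs %||% rep(1e6, ncol(y)), bw)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("TMM factors are exactly one for identical samples", {
  set.seed(1)
  base <- rnbinom(2000, mu = 30, size = 10) + 1L
  bc <- mkCounts(cbind(s1 = base, s2 = base))
  f <- normFactors(tmmFactors(bc))
  expect_equal(unname(f), c(1, 1), tolerance = 1e-12)
  expect_error(tmmFactors(mkCounts(cbind(a = rep(0L, 50), b = rep(0L, 50)))),
               "insufficient data")
})

test_that("a pure depth change is fully absorbed by effective sizes", {
  set.seed(2)
  base <- rnbinom(2000, mu = 30, size = 10) + 1L
  bc <- mkCounts(cbind(s1 = base, s2 = 2L * base),
                 libs = c(sum(base), sum(2L * base)))
  fac <- tmmFactors(bc)
  regions <- GRanges("chrI", IRanges(c(1, 100001), width = 5000),
                     seqinfo = seqinfo(rowRanges(bc)))
  res <- testRegions(regions, bc, c("A", "B"), fac, dispersion = 0.05)
  expect_lt(max(abs(res$meanNorm1 - res$meanNorm2)), 1e-6 * max(res$meanNorm1))
})

test_that("trimming shields the factors from a planted composition shift", {
  set.seed(3)
  n <- 4000
  base <- rnbinom(n, mu = 50, size = 20) + 1L
  pert <- base
  idx <- sample(n, n / 10)
  pert[idx] <- 5L * pert[idx]   # 10% of bins gain 5x in sample 2
  bc <- mkCounts(cbind(s1 = base, s2 = pert),
                 libs = c(sum(base), sum(pert)))
  f <- normFactors(tmmFactors(bc))
  # depth-only oracle from the unperturbed 90% of bins
  clean <- mkCounts(cbind(s1 = base[-idx], s2 = pert[-idx]),
                    libs = c(sum(base), sum(pert)))
  f0 <- normFactors(tmmFactors(clean))
  expect_lt(max(abs(f / f0 - 1)), 0.03)
})

test_that("the NB test reproduces the stated pseudocount fold change", {
  bc <- mkCounts(matrix(c(10L, 12L, 30L, 28L), 1),
                 libs = rep(1e6, 4))
  regions <- rowRanges(bc)
  res <- testRegions(regions, bc, c("w", "w", "m", "m"), dispersion = 0.05)
  expect_equal(res$log2FC, log2(29.5 / 11.5), tolerance = 1e-12)

  same <- mkCounts(matrix(c(20L, 20L), 1), libs = rep(1e6, 2))
  res0 <- testRegions(rowRanges(same), same, c("a", "b"), dispersion = 0.05)
  expect_equal(res0$log2FC, 0)
  expect_equal(res0$pvalue, 1)

  zero <- mkCounts(matrix(0L, 1, 4), libs = rep(1e6, 4))
  resz <- testRegions(rowRanges(zero), zero, c("a", "a", "b", "b"),
                      dispersion = 0.05)
  expect_equal(resz$log2FC, 0)
  expect_equal(resz$pvalue, 1)
})

test_that("swapping condition labels negates fold changes and keeps p-values", {
  set.seed(4)
  y <- matrix(rnbinom(400, mu = 25, size = 15), 100, 4)
  bc <- mkCounts(y)
  regions <- rowRanges(bc)
  grp <- c("A", "A", "B", "B")
  fwd <- testRegions(regions, bc, grp, dispersion = 0.05, ref = "A")
  rev <- testRegions(regions, bc, grp, dispersion = 0.05, ref = "B")
  expect_equal(rev$log2FC, -fwd$log2FC, tolerance = 1e-9)
  expect_equal(rev$pvalue, fwd$pvalue, tolerance = 1e-9)
})

test_that("enrichment thresholds are strict and G1 is uniformly stricter", {
  gr <- GRanges("chrI", IRanges(c(1, 201, 401), width = 100))
  gr$log2FC <- log2(c(1.5, 1.2, 1.5))
  gr$negLog10P <- c(0.8, 5, 2)
  s <- classifyEnriched(gr, "S")
  expect_equal(s$enriched, c(TRUE, FALSE, TRUE))   # FC = 1.2 exactly fails
  g1 <- classifyEnriched(gr, "G1")
  expect_equal(g1$enriched, c(FALSE, FALSE, FALSE)) # all fail the 2x bar
  expect_error(classifyEnriched(gr, "M"), "phase")

  set.seed(5)
  rnd <- GRanges("chrI", IRanges(seq(1, by = 200, length.out = 200),
                                 width = 100))
  rnd$log2FC <- rnorm(200); rnd$negLog10P <- rexp(200)
  expect_true(all(classifyEnriched(rnd, "G1")$enriched <=
                    classifyEnriched(rnd, "S")$enriched))
})

test_that("specific/common classification follows the planted contrast", {
  set.seed(6)
  n <- 60
  # region-level sums: high counts, low dispersion, as after summing the
  # 50 bp calling bins over a gene-sized region
  muH <- rep(200, n); muS <- rep(200, n)
  muH[1:20] <- 1000                       # hpr1-only regions
  muH[21:40] <- 600; muS[21:40] <- 600    # equal 3x in both: common
  muS[41:60] <- 1000                      # sen1-only regions
  y <- cbind(s1 = rnbinom(n, mu = muS, size = 500),
             s2 = rnbinom(n, mu = muS, size = 500),
             h1 = rnbinom(n, mu = muH, size = 500),
             h2 = rnbinom(n, mu = muH, size = 500))
  # regions separated by > fuseDist so classification keeps them apart
  bc <- mkCounts(y, pitch = 1000L)
  regions <- rowRanges(bc)
  cls <- classifySpecificCommon(regions[1:40], regions[21:60], bc,
                                c("sen1", "sen1", "hpr1", "hpr1"))
  lab <- cls$class[match(start(regions), start(cls))]
  expect_true(mean(lab[1:20] == "hpr1-specific") >= 0.9)
  expect_true(mean(lab[21:40] == "common") >= 0.9)
  expect_true(mean(lab[41:60] == "sen1-specific") >= 0.9)

  # with an empty sen1 set nothing can be sen1-specific
  cls2 <- classifySpecificCommon(regions[1:20], GRanges(), bc,
                                 c("sen1", "sen1", "hpr1", "hpr1"))
  expect_false(any(cls2$class == "sen1-specific"))
  expect_length(classifySpecificCommon(GRanges(), GRanges(), bc,
                                       c("sen1", "sen1", "hpr1", "hpr1")), 0L)
})

test_that("phase overlap categories partition the gain sets", {
  g1 <- GRanges("chrI", IRanges(101, 300))
  s <- GRanges("chrI", IRanges(251, 400))
  out <- phaseOverlapCategories(g1, s)
  expect_equal(out$category, "G1-S R-loop-gain")

  g1b <- GRanges("chrI", IRanges(c(101, 1001), width = 100))
  sb <- GRanges("chrI", IRanges(5001, width = 100))
  outb <- phaseOverlapCategories(g1b, sb)
  expect_equal(sort(table(outb$category), decreasing = TRUE)[["G1 R-loop-gain"]], 2L)
  expect_equal(table(outb$category)[["S R-loop-gain"]], 1L)

  set.seed(7)
  for (i in 1:10) {
    a <- reduce(randomIntervals(20)); b <- reduce(randomIntervals(20))
    cats <- phaseOverlapCategories(a, b)
    nG1 <- sum(cats$category %in% c("G1 R-loop-gain", "G1-S R-loop-gain"))
    expect_equal(nG1, length(a))   # conservation of the G1 set
  }
})
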