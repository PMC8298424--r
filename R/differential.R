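# Differential R-loop-gain analysis: TMM scaling on genome-wide bins,
# per-region NB likelihood-ratio tests with a common method-of-moments
# dispersion, threshold-based enrichment calls, mutant-specific / common
# classification, and G1/S overlap categories.

#' TMM normalization factors from genome-wide binned counts
#'
#' Computes trimmed-mean-of-M-values scale factors (trim 30% by log-ratio
#' M, 5% by abundance A, precision weights) on genome-wide bins via
#' [edgeR::calcNormFactors()].  Bins with a zero count in any sample are
#' excluded from factor estimation; factors are rescaled to geometric
#' mean 1.
#'
#' @param bc a multi-sample [BinnedCounts-class] of genome-wide bins
#'   (typically 200 bp).
#' @param refSample optional reference column (default: edgeR's choice).
#' @return a [NormalizationFactors-class].
#' @export
tmmFactors <- function(bc, refSample = NULL) {
  cts <- counts(bc)
  stopIfNot(ncol(cts) >= 2L, "TMM needs at least 2 samples")
  keep <- rowSums(cts == 0) == 0L
  stopIfNot(sum(keep) >= 100L, "insufficient data for normalization (< 100 usable bins)")
  refCol <- if (is.null(refSample)) NULL else match(refSample, colnames(cts))
  f <- edgeR::calcNormFactors(cts[keep, , drop = FALSE], method = "TMM",
                              lib.size = librarySizes(bc),
                              refColumn = refCol,
                              logratioTrim = 0.30, sumTrim = 0.05,
                              doWeighting = TRUE)
  f <- f / exp(mean(log(f)))
  new("NormalizationFactors",
      factors = stats::setNames(f, colnames(cts)),
      refSample = if (is.null(refSample)) NA_character_ else refSample,
      trimM = 0.30, trimA = 0.05)
}

#' Sum bin counts over regions
#'
#' @param regions `GRanges` of regions.
#' @param bc a [BinnedCounts-class] whose bins overlap the regions (strand
#'   respected; `*` matches both).
#' @return integer matrix, regions x samples.
#' @export
regionCounts <- function(regions, bc) {
  hits <- GenomicRanges::findOverlaps(rowRanges(bc), regions,
                                      ignore.strand = FALSE)
  out <- matrix(0L, length(regions), ncol(bc),
                dimnames = list(NULL, colnames(bc)))
  if (length(hits)) {
    cts <- counts(bc)[S4Vectors::queryHits(hits), , drop = FALSE]
    agg <- rowsum(cts, S4Vectors::subjectHits(hits))
    out[as.integer(rownames(agg)), ] <- agg
  }
  out
}

# Intercept-only NB GLM with offsets and known dispersion, vectorised
# across regions via Fisher scoring.  y: regions x samples; N: effective
# library sizes (length = ncol(y)).  Returns the fitted rate lambda and
# the per-region log-likelihood.
.nbMeanFit <- function(y, N, alpha, iter = 30L) {
  size <- 1 / max(alpha, 1e-8)
  lambda <- (rowSums(y) + 0.1) / sum(N)
  for (it in seq_len(iter)) {
    muMat <- outer(lambda, N)
    wMat <- muMat / (1 + alpha * muMat)
    num <- rowSums(wMat * (y - muMat) / pmax(muMat, 1e-12))
    den <- pmax(rowSums(wMat), 1e-12)
    lambda <- lambda * exp(num / den)
    lambda <- pmin(pmax(lambda, 1e-12), 1e9)
  }
  muMat <- outer(lambda, N)
  ll <- rowSums(stats::dnbinom(y, mu = pmax(muMat, 1e-12), size = size,
                               log = TRUE))
  list(lambda = lambda, logLik = ll)
}

# Common method-of-moments dispersion across all regions and groups with
# replicates: pooled excess variance of library-size-normalised counts.
.momDispersion <- function(y, N, group) {
  num <- 0; den <- 0
  for (g in unique(group)) {
    cols <- which(group == g)
    if (length(cols) < 2L) next
    z <- sweep(y[, cols, drop = FALSE], 2, N[cols] / mean(N[cols]), "/")
    m <- rowMeans(z)
    v <- apply(z, 1, stats::var)
    keep <- m > 0
    # on the count scale var(z) ~ m + alpha * m^2 for near-equal sizes
    num <- num + sum(v[keep] - m[keep])
    den <- den + sum(m[keep]^2)
  }
  if (den <= 0) return(NA_real_)
  max(num / den, 1e-6)
}

#' Per-region differential NB test
#'
#' For each region, counts are summed per sample; effective library sizes
#' are `librarySize * TMM factor`; the log2 fold change is
#' `log2((mean normalized count of condition 2 + 0.5) /
#'        (mean normalized count of condition 1 + 0.5))`;
#' the p-value comes from a negative-binomial likelihood-ratio test
#' (chi-square, 1 df) of a common rate against per-condition rates, with a
#' common dispersion estimated by method of moments across all regions
#' (replicated designs) or a fixed value when a condition has a single
#' replicate.  Regions with zero counts in every sample get `log2FC = 0`,
#' `p = 1`.
#'
#' @param regions `GRanges` of regions to test (typically the merged/fused
#'   peaks of the two conditions).
#' @param bc a [BinnedCounts-class] holding all samples of both conditions.
#' @param group character/factor of length `ncol(bc)` with exactly two
#'   levels; condition 1 (the fold-change denominator) is `ref` when
#'   given, else the first level encountered.
#' @param ref optional name of the reference condition (denominator);
#'   swapping `ref` between the two levels negates every `log2FC` and
#'   leaves p-values unchanged.
#' @param factors a [NormalizationFactors-class] or numeric vector of
#'   per-sample factors (default all 1).
#' @param dispersion fixed common dispersion; `NULL` (default) estimates
#'   it by method of moments, falling back to `fallbackDispersion` for
#'   unreplicated designs.
#' @param fallbackDispersion dispersion used when no group has replicates.
#' @return the `regions` with mcols `meanNorm1`, `meanNorm2`, `log2FC`,
#'   `pvalue`, `negLog10P`.
#' @export
testRegions <- function(regions, bc, group, factors = NULL,
                        dispersion = NULL, fallbackDispersion = 0.05,
                        ref = NULL) {
  group <- as.character(group)
  stopIfNot(length(group) == ncol(bc), "one group label per sample required")
  lev <- unique(group)
  stopIfNot(length(lev) == 2L, "exactly two conditions required")
  if (!is.null(ref)) {
    stopIfNot(ref %in% lev, "ref must be one of the two conditions")
    lev <- c(ref, setdiff(lev, ref))
  }
  f <- if (is.null(factors)) rep(1, ncol(bc))
       else if (is(factors, "NormalizationFactors")) normFactors(factors)
       else as.numeric(factors)
  N <- librarySizes(bc) * f
  y <- regionCounts(regions, bc)

  if (is.null(dispersion)) {
    dispersion <- if (max(table(group)) >= 2L) .momDispersion(y, N, group)
                  else NA_real_
    if (!is.finite(dispersion)) dispersion <- fallbackDispersion
  }

  Nbar <- mean(N)
  cols1 <- which(group == lev[1]); cols2 <- which(group == lev[2])
  norm <- sweep(y, 2, N / Nbar, "/")
  m1 <- rowMeans(norm[, cols1, drop = FALSE])
  m2 <- rowMeans(norm[, cols2, drop = FALSE])
  log2FC <- log2((m2 + 0.5) / (m1 + 0.5))

  fitNull <- .nbMeanFit(y, N, dispersion)
  fit1 <- .nbMeanFit(y[, cols1, drop = FALSE], N[cols1], dispersion)
  fit2 <- .nbMeanFit(y[, cols2, drop = FALSE], N[cols2], dispersion)
  dev <- pmax(2 * (fit1$logLik + fit2$logLik - fitNull$logLik), 0)
  p <- stats::pchisq(dev, df = 1, lower.tail = FALSE)

  allZero <- rowSums(y) == 0L
  log2FC[allZero] <- 0
  p[allZero] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  out <- granges(regions)
  out$meanNorm1 <- m1
  out$meanNorm2 <- m2
  out$log2FC <- log2FC
  out$pvalue <- p
  out$negLog10P <- -log10(p)
  S4Vectors::metadata(out)$dispersion <- dispersion
  S4Vectors::metadata(out)$conditions <- lev
  out
}

#' Phase-specific enrichment thresholds
#'
#' A region is enriched when its linear fold change and -log10 p-value
#' strictly exceed the phase's thresholds: FC > 1.2 and -log10 p > 0.6 for
#' S-phase comparisons, FC > 2 and -log10 p > 1 for G1 data sets.
#'
#' @param results `GRanges` from [testRegions()].
#' @param phase `"G1"` or `"S"`.
#' @return `results` with an added logical mcol `enriched`.
#' @export
classifyEnriched <- function(results, phase) {
  stopIfNot(phase %in% c("G1", "S"), sprintf("unknown phase '%s'", phase))
  fcThr <- if (phase == "G1") 2 else 1.2
  lpThr <- if (phase == "G1") 1 else 0.6
  results$enriched <- (2^results$log2FC > fcThr) & (results$negLog10P > lpThr)
  results
}

#' @rdname classifyEnriched
#' @export
enrichedRegions <- function(results, phase) {
  res <- classifyEnriched(results, phase)
  res[res$enriched]
}

#' Mutant-specific versus common gain regions
#'
#' The union of the two mutants' enriched regions is merged/fused
#' (< `fuseDist` bp) and re-tested mutant against mutant with
#' [testRegions()]: a region enriched in the hpr1-type condition over the
#' sen1-type condition (by the same phase thresholds) is labelled
#' `hpr1-specific`, the reverse `sen1-specific`, anything else `common`.
#'
#' @param hpr1Enriched,sen1Enriched enriched region `GRanges` of the two
#'   mutants (same phase).
#' @param bc [BinnedCounts-class] holding the two mutants' samples.
#' @param group character vector with levels `"sen1"` and `"hpr1"`
#'   matching `colnames(bc)` (condition 1 = sen1, so positive log2FC means
#'   higher in hpr1).
#' @param factors normalization factors for `bc`.
#' @param phase thresholds to apply (default `"S"`).
#' @param fuseDist fuse distance for the region union.
#' @param dispersion optional fixed dispersion passed to [testRegions()].
#' @return `GRanges` of the merged regions with mcols `log2FC`, `pvalue`
#'   and `class` in hpr1-specific / sen1-specific / common.
#' @export
classifySpecificCommon <- function(hpr1Enriched, sen1Enriched, bc, group,
                                   factors = NULL, phase = "S",
                                   fuseDist = 200, dispersion = NULL) {
  un <- suppressWarnings(c(granges(hpr1Enriched), granges(sen1Enriched)))
  if (length(un) == 0L) return(GRanges())
  regions <- mergeAndFuse(un, fuseDist)
  res <- testRegions(regions, bc, group, factors, dispersion = dispersion)
  lev <- S4Vectors::metadata(res)$conditions   # lev[1] = denominator
  fcThr <- if (phase == "G1") 2 else 1.2
  lpThr <- if (phase == "G1") 1 else 0.6
  upIn2 <- (2^res$log2FC > fcThr) & (res$negLog10P > lpThr)
  upIn1 <- (2^(-res$log2FC) > fcThr) & (res$negLog10P > lpThr)
  cls <- rep("common", length(res))
  cls[upIn2] <- paste0(lev[2], "-specific")
  cls[upIn1] <- paste0(lev[1], "-specific")
  res$class <- cls
  res
}

#' G1/S overlap categories of R-loop-gain peaks
#'
#' Gain peaks detected in the two phases of the same mutant are compared
#' by overlap: a G1 peak overlapping any S peak is a `G1-S R-loop-gain`
#' region, a G1 peak with no S overlap is `G1 R-loop-gain`, and an S peak
#' with no G1 overlap is `S R-loop-gain`.  Counts conserve:
#' `|G1 set| = |G1-only| + |G1-S|`.
#'
#' @param g1Gain,sGain gain-region `GRanges` of the two phases.
#' @param ignoreStrand ignore strand when overlapping.
#' @return `GRanges` with mcol `category`.
#' @export
phaseOverlapCategories <- function(g1Gain, sGain, ignoreStrand = FALSE) {
  g1Hit <- IRanges::overlapsAny(g1Gain, sGain,
                                      ignore.strand = ignoreStrand)
  sHit <- IRanges::overlapsAny(sGain, g1Gain,
                                     ignore.strand = ignoreStrand)
  out1 <- granges(g1Gain)
  out1$category <- ifelse(g1Hit, "G1-S R-loop-gain", "G1 R-loop-gain")
  out2 <- granges(sGain)[!sHit]
  out2$category <- rep("S R-loop-gain", sum(!sHit))
  suppressWarnings(c(out1, out2))
}
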