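#' @describeIn CoverageTrack-class bin width in bp.
#' @export
setMethod("binWidth", "CoverageTrack", function(x) x@binWidth)

#' @describeIn BinnedCounts-class counting bin width in bp.
#' @export
setMethod("binWidth", "BinnedCounts", function(x) metadata(x)$binWidth)

#' @describeIn CoverageTrack-class named list of per-chromosome value vectors.
#' @export
setMethod("trackValues", "CoverageTrack", function(x) x@values)

#' @describeIn CoverageTrack-class normalization tag.
#' @export
setMethod("normalization", "CoverageTrack", function(x) x@normalization)

#' @describeIn CoverageTrack-class genome description.
#' @importMethodsFrom GenomeInfoDb seqinfo
#' @export
setMethod("seqinfo", "CoverageTrack", function(x) x@seqinfo)

#' @describeIn CoverageTrack-class track strand.
#' @importMethodsFrom BiocGenerics strand
#' @export
setMethod("strand", "CoverageTrack", function(x) x@strand)

#' @describeIn BinnedCounts-class total mapped reads per sample.
#' @export
setMethod("librarySizes", "BinnedCounts", function(x) {
  stats::setNames(colData(x)$librarySize, colnames(x))
})

#' @describeIn BinnedCounts-class the counts matrix.
#' @importMethodsFrom BiocGenerics counts
#' @export
setMethod("counts", "BinnedCounts", function(object) assay(object, "counts"))

#' @describeIn NBHMMFit-class per-bin posterior probability of the enriched
#'   state.
#' @export
setMethod("enrichedPosterior", "NBHMMFit", function(x) x@posterior)

#' @describeIn MetaplotMatrix-class the position axis.
#' @export
setMethod("profilePositions", "MetaplotMatrix", function(x) x@positions)

#' @describeIn MetaplotMatrix-class column-wise mean signal over anchors
#'   (`NaN` windows ignored).
#' @export
setMethod("meanProfile", "MetaplotMatrix", function(x) {
  colMeans(x@values, na.rm = TRUE)
})

setMethod("show", "CoverageTrack", function(object) {
  sl <- seqlengths(object@seqinfo)
  cat(sprintf("CoverageTrack: %d chromosome(s), bin %d bp, strand %s, %s\n",
              length(sl), object@binWidth, object@strand,
              object@normalization))
  tot <- sum(vapply(object@values, function(v) sum(v, na.rm = TRUE), numeric(1)))
  cat(sprintf("  genome %s bp, total signal %.4g\n",
              format(sum(as.numeric(sl)), big.mark = ","), tot))
})

setMethod("show", "NBHMMFit", function(object) {
  cat("Two-state NB HMM fit\n")
  cat(sprintf("  mu (background, enriched): %.3f, %.3f\n",
              object@mu[1], object@mu[2]))
  cat(sprintf("  alpha: %.4f, %.4f\n", object@alpha[1], object@alpha[2]))
  cat(sprintf("  logLik %.2f after %d iteration(s)%s%s\n",
              object@logLik[length(object@logLik)], object@iterations,
              if (object@converged) "" else " (not converged)",
              if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "MetaplotMatrix", function(object) {
  cat(sprintf("MetaplotMatrix (%s): %d anchor(s) x %d position(s)%s\n",
              object@mode, nrow(object@values), ncol(object@values),
              if (object@oriented) ", oriented" else ""))
})

setMethod("show", "AsymmetryIndex", function(object) {
  cat(sprintf("AsymmetryIndex: mean %.3f [95%% CI %.3f, %.3f], n = %d (%d excluded)\n",
              object@mean, object@ciLower, object@ciUpper,
              length(object@ai), object@nExcluded))
})

setMethod("show", "NormalizationFactors", function(object) {
  cat("TMM normalization factors (trim M", object@trimM, ", A", object@trimA, ")\n")
  print(round(object@factors, 4))
})

setMethod("show", "RLoopTruth", function(object) {
  cat(sprintf("RLoopTruth: %d chromosome(s), %d genes, %d features, %d origins\n",
              length(seqlengths(object@seqinfo)), length(object@genes),
              length(object@features), length(object@ars)))
  print(table(object@gainRegions$label))
})

#' @describeIn AsymmetryIndex-class per-anchor AI values.
#' @param x an `AsymmetryIndex`.
#' @export
asymmetryValues <- function(x) x@ai

#' @describeIn AsymmetryIndex-class summary of the mean AI and its CI.
#' @export
asymmetrySummary <- function(x) {
  c(mean = x@mean, ciLower = x@ciLower, ciUpper = x@ciUpper)
}

#' @describeIn NormalizationFactors-class the per-sample factors.
#' @param x a `NormalizationFactors`.
#' @export
normFactors <- function(x) x@factors

#' Accessors for RLoopTruth components
#'
#' @param x an [RLoopTruth-class] object.
#' @return the requested component.
#' @name truth-accessors
NULL

#' @rdname truth-accessors
#' @export
truthGenes <- function(x) x@genes

#' @rdname truth-accessors
#' @export
truthFeatures <- function(x) x@features

#' @rdname truth-accessors
#' @export
truthArs <- function(x) x@ars

#' @rdname truth-accessors
#' @export
truthGainRegions <- function(x) x@gainRegions

#' @rdname truth-accessors
#' @export
truthConfigOf <- function(x) x@config

#' @rdname truth-accessors
#' @export
truthSeqinfo <- function(x) x@seqinfo
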