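#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges granges
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb Seqinfo seqinfo seqnames seqlengths seqlevels
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData assay
NULL

#' CoverageTrack: fixed-bin-width genomic signal
#'
#' Dense per-chromosome signal vectors at a fixed bin width, as produced by
#' binned coverage counting (bamCoverage-style).  The `normalization` tag
#' records what the values mean: raw counts, RPKM, a mutant-minus-wild-type
#' difference (which may be negative), or RNase-H scaled signal.
#'
#' @slot values named list of numeric vectors, one per chromosome; vector
#'   `j` holds the signal of bin `j`, covering base pairs
#'   `[(j-1)*binWidth + 1, j*binWidth]`.
#' @slot seqinfo a [GenomeInfoDb::Seqinfo] describing the genome.
#' @slot binWidth bin width in bp.
#' @slot strand one of `"+"`, `"-"`, `"*"`.
#' @slot normalization one of `"raw"`, `"RPKM"`, `"WT-subtracted"`,
#'   `"RNH-scaled"`.
#' @slot totalReads,uniqueReads library sizes backing the track (may be NA).
#' @exportClass CoverageTrack
setClass("CoverageTrack",
  representation(
    values = "list",
    seqinfo = "Seqinfo",
    binWidth = "integer",
    strand = "character",
    normalization = "character",
    totalReads = "numeric",
    uniqueReads = "numeric"
  )
)

setValidity("CoverageTrack", function(object) {
  msg <- character()
  sl <- seqlengths(object@seqinfo)
  if (!identical(sort(names(object@values)), sort(names(sl))))
    msg <- c(msg, "value vectors must be named by chromosome, one per chromosome")
  if (length(object@binWidth) != 1L || object@binWidth < 1L)
    msg <- c(msg, "binWidth must be a single positive integer")
  else {
    expected <- ceiling(sl / object@binWidth)
    for (chr in names(object@values)) {
      if (length(object@values[[chr]]) != expected[[chr]])
        msg <- c(msg, sprintf("chromosome %s: %d bins, expected %d",
                              chr, length(object@values[[chr]]), expected[[chr]]))
    }
  }
  if (!object@strand %in% c("+", "-", "*"))
    msg <- c(msg, "strand must be one of '+', '-', '*'")
  if (!object@normalization %in% c("raw", "RPKM", "WT-subtracted", "RNH-scaled"))
    msg <- c(msg, "unknown normalization tag")
  if (object@normalization == "RPKM" &&
      any(vapply(object@values, function(v) any(v < 0, na.rm = TRUE), logical(1))))
    msg <- c(msg, "RPKM tracks must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a CoverageTrack
#'
#' @param values named list of per-chromosome numeric vectors.
#' @param seqinfo genome description ([GenomeInfoDb::Seqinfo]).
#' @param binWidth bin width in bp.
#' @param strand `"+"`, `"-"` or `"*"` (unstranded).
#' @param normalization normalization tag, see [CoverageTrack-class].
#' @param totalReads,uniqueReads optional library sizes.
#' @return a `CoverageTrack`.
#' @examples
#' si <- GenomeInfoDb::Seqinfo("chrI", 100)
#' CoverageTrack(list(chrI = rep(0, 10)), si, binWidth = 10L)
#' @export
CoverageTrack <- function(values, seqinfo, binWidth, strand = "*",
                          normalization = "raw",
                          totalReads = NA_real_, uniqueReads = NA_real_) {
  new("CoverageTrack",
      values = values[seqlevels(seqinfo)], seqinfo = seqinfo,
      binWidth = as.integer(binWidth), strand = strand,
      normalization = normalization,
      totalReads = as.numeric(totalReads), uniqueReads = as.numeric(uniqueReads))
}

#' BinnedCounts: regions-by-samples integer counts
#'
#' A thin [SummarizedExperiment::RangedSummarizedExperiment] holding
#' non-negative integer counts for a set of (possibly stranded) genomic
#' regions across samples, with one library size per sample in
#' `colData()$librarySize` and the bin width in `metadata()$binWidth`.
#'
#' @exportClass BinnedCounts
setClass("BinnedCounts", contains = "RangedSummarizedExperiment")

setValidity("BinnedCounts", function(object) {
  msg <- character()
  cts <- assay(object, "counts")
  if (any(cts < 0) || any(cts != round(cts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (!"librarySize" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a librarySize column")
  else if (any(is.na(colData(object)$librarySize)))
    msg <- c(msg, "one library size is required per sample")
  if (is.null(metadata(object)$binWidth))
    msg <- c(msg, "metadata must record binWidth")
  if (length(msg)) msg else TRUE
})

#' Construct a BinnedCounts object
#'
#' @param regions [GenomicRanges::GRanges] of counted regions (bins).
#' @param counts numeric matrix, `length(regions)` rows x samples columns.
#' @param librarySizes total mapped reads per sample (recycled names from
#'   `colnames(counts)`).
#' @param binWidth the counting bin width in bp.
#' @return a `BinnedCounts`.
#' @examples
#' gr <- GenomicRanges::GRanges("chrI", IRanges::IRanges(c(1, 201), width = 200))
#' BinnedCounts(gr, cbind(s1 = c(3L, 5L)), librarySizes = c(s1 = 8), binWidth = 200L)
#' @export
BinnedCounts <- function(regions, counts, librarySizes, binWidth) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowRanges = regions,
    colData = DataFrame(librarySize = as.numeric(librarySizes),
                        row.names = colnames(counts)))
  metadata(se)$binWidth <- as.integer(binWidth)
  new("BinnedCounts", se)
}

#' Two-state negative-binomial HMM fit
#'
#' Emission and transition parameters of the background/enriched two-state
#' NB HMM together with the per-bin posterior probability of the enriched
#' state and the EM log-likelihood trajectory.
#'
#' @slot mu,alpha length-2 numeric: state means and dispersions, ordered
#'   `(background, enriched)` with `mu[2] > mu[1]` (up to degeneracy).
#' @slot transition 2x2 row-stochastic transition matrix.
#' @slot initProb initial state distribution.
#' @slot logLik log-likelihood at each EM iteration (non-decreasing).
#' @slot iterations number of EM iterations used.
#' @slot converged logical; `FALSE` triggers a warning at fit time.
#' @slot degenerate logical; `TRUE` when the two state means are
#'   indistinguishable (within 5%).
#' @slot bins the binned regions the fit refers to.
#' @slot posterior per-bin posterior probability of the enriched state.
#' @exportClass NBHMMFit
setClass("NBHMMFit",
  representation(
    mu = "numeric", alpha = "numeric",
    transition = "matrix", initProb = "numeric",
    logLik = "numeric", iterations = "integer",
    converged = "logical", degenerate = "logical",
    bins = "GRanges", posterior = "numeric"
  )
)

setValidity("NBHMMFit", function(object) {
  msg <- character()
  if (length(object@mu) != 2L || length(object@alpha) != 2L)
    msg <- c(msg, "mu and alpha must have length 2")
  if (any(abs(rowSums(object@transition) - 1) > 1e-12))
    msg <- c(msg, "transition matrix rows must sum to 1")
  if (length(object@bins) > 0L &&
      length(object@posterior) != length(object@bins))
    msg <- c(msg, "one posterior value per bin required")
  if (any(object@posterior < -1e-12 | object@posterior > 1 + 1e-12))
    msg <- c(msg, "posteriors must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Metaplot matrix: anchors-by-positions oriented signal
#'
#' @slot values anchors x positions matrix of average signal; `NaN` only
#'   where a window exceeded chromosome bounds.
#' @slot positions position axis: bp offsets from the anchor point
#'   (reference-point mode) or scaled coordinates (scaled-region mode).
#' @slot mode `"refpoint"` or `"scaled"`.
#' @slot oriented logical: rows flipped so the axis runs 5'->3' (or fork
#'   upstream -> downstream).
#' @exportClass MetaplotMatrix
setClass("MetaplotMatrix",
  representation(values = "matrix", positions = "numeric",
                 mode = "character", oriented = "logical")
)

setValidity("MetaplotMatrix", function(object) {
  if (ncol(object@values) != length(object@positions))
    "one position per matrix column required" else TRUE
})

#' Damage asymmetry index around anchors
#'
#' Per-anchor `AI = (D - U) / (D + U)` where `D` and `U` are the mean
#' signals of the downstream and upstream flanks (core excluded); anchors
#' with `D + U = 0` are excluded.
#'
#' @slot ai per-anchor asymmetry indices in `[-1, 1]`.
#' @slot mean mean AI over anchors.
#' @slot ciLower,ciUpper bootstrap 95% confidence interval of the mean.
#' @slot nExcluded anchors dropped for zero or undefined flank signal.
#' @exportClass AsymmetryIndex
setClass("AsymmetryIndex",
  representation(ai = "numeric", mean = "numeric",
                 ciLower = "numeric", ciUpper = "numeric",
                 nExcluded = "integer")
)

#' TMM normalization factors
#'
#' @slot factors per-sample scale factors, geometric mean 1.
#' @slot refSample reference sample used by the trimmed-mean computation.
#' @slot trimM,trimA trim fractions on log-ratios (M) and abundance (A).
#' @exportClass NormalizationFactors
setClass("NormalizationFactors",
  representation(factors = "numeric", refSample = "character",
                 trimM = "numeric", trimA = "numeric")
)

setValidity("NormalizationFactors", function(object) {
  msg <- character()
  if (any(object@factors <= 0)) msg <- c(msg, "factors must be positive")
  if (abs(mean(log(object@factors))) > 1e-9)
    msg <- c(msg, "factors must have geometric mean 1")
  if (length(msg)) msg else TRUE
})

#' Synthetic-truth configuration
#'
#' All parameters of the synthetic genome, annotation and signal generator.
#' Defaults are the package's reference study conditions; see the methods
#' vignette for rationale.
#'
#' @slot seed master seed; every stochastic stage derives its own stream.
#' @slot nChrom,chromLength genome shape (bp).
#' @slot nGenes number of protein-coding genes.
#' @slot geneLenMeanlog,geneLenSdlog log-normal gene length parameters (bp).
#' @slot fracTrna,fracSnorna tRNA / snoRNA feature counts as fractions of
#'   `nGenes`.
#' @slot telomereLength terminal telomere length per chromosome end (bp).
#' @slot nEarlyArs number of early replication origins (midpoints >= 20 kb
#'   apart); each origin gets one flanking gene per side within 1 kb.
#' @slot muBg,alphaBg background NB mean and dispersion per calling bin.
#' @slot hybridScale mean gene-body hybrid signal per bin at expression 1.
#' @slot exprSdlog log-normal sd of per-gene expression (meanlog 0).
#' @slot fGain hybrid gain fold at planted regions (> 1).
#' @slot nGainHpr1,nGainSen1,nGainCommon planted gain region counts.
#' @slot piHO fraction of sen1-type gain regions placed on head-on
#'   ARS-proximal genes (the rest go to codirectional ARS-proximal genes).
#' @slot sigmaDam Gaussian damage-spread kernel width (bp).
#' @slot aDam fraction of sen1-type damage mass placed downstream of the
#'   fork (hpr1-type damage always uses 0.5).
#' @slot damageMass expected damage counts added per anchor.
#' @slot h2apBaselineMean,h2apBaselineDisp NB baseline of the damage track
#'   per coverage bin.
#' @slot nReplicates replicates per condition.
#' @slot callBin,countBin,covBin bin widths (bp) for peak calling,
#'   genome-wide counting and coverage.
#' @exportClass TruthConfig
setClass("TruthConfig",
  representation(
    seed = "integer",
    nChrom = "integer", chromLength = "integer",
    nGenes = "integer",
    geneLenMeanlog = "numeric", geneLenSdlog = "numeric",
    fracTrna = "numeric", fracSnorna = "numeric",
    telomereLength = "integer",
    nEarlyArs = "integer",
    muBg = "numeric", alphaBg = "numeric",
    hybridScale = "numeric", exprSdlog = "numeric",
    fGain = "numeric",
    nGainHpr1 = "integer", nGainSen1 = "integer", nGainCommon = "integer",
    piHO = "numeric",
    sigmaDam = "numeric", aDam = "numeric", damageMass = "numeric",
    h2apBaselineMean = "numeric", h2apBaselineDisp = "numeric",
    nReplicates = "integer",
    callBin = "integer", countBin = "integer", covBin = "integer"
  )
)

setValidity("TruthConfig", function(object) {
  msg <- character()
  probs <- c(object@fracTrna, object@fracSnorna, object@piHO, object@aDam)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  cnt <- c(object@nChrom, object@chromLength, object@nGenes, object@nEarlyArs,
           object@nGainHpr1, object@nGainSen1, object@nGainCommon,
           object@nReplicates)
  if (any(cnt < 0)) msg <- c(msg, "counts must be >= 0")
  if (object@fGain <= 1) msg <- c(msg, "fGain must exceed 1")
  if (any(c(object@muBg, object@alphaBg, object@sigmaDam) <= 0))
    msg <- c(msg, "muBg, alphaBg and sigmaDam must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a TruthConfig
#'
#' @param seed master seed (integer).
#' @param nChrom,chromLength,nGenes,geneLenMeanlog,geneLenSdlog,fracTrna,fracSnorna,telomereLength,nEarlyArs,muBg,alphaBg,hybridScale,exprSdlog,fGain,nGainHpr1,nGainSen1,nGainCommon,piHO,sigmaDam,aDam,damageMass,h2apBaselineMean,h2apBaselineDisp,nReplicates,callBin,countBin,covBin
#'   see [TruthConfig-class].
#' @return a validated `TruthConfig`.
#' @examples
#' cfg <- truthConfig(seed = 1, nChrom = 2, chromLength = 60000L, nGenes = 40)
#' @export
truthConfig <- function(seed = 1L,
                        nChrom = 4L, chromLength = 250000L,
                        nGenes = 280L,
                        geneLenMeanlog = log(1200), geneLenSdlog = 0.45,
                        fracTrna = 0.05, fracSnorna = 0.04,
                        telomereLength = 5000L,
                        nEarlyArs = 40L,
                        muBg = 5, alphaBg = 0.1,
                        hybridScale = 10, exprSdlog = 0.5,
                        fGain = 3,
                        nGainHpr1 = 40L, nGainSen1 = 24L, nGainCommon = 20L,
                        piHO = 0.8,
                        sigmaDam = 1000, aDam = 0.8, damageMass = 2000,
                        h2apBaselineMean = 1, h2apBaselineDisp = 0.2,
                        nReplicates = 2L,
                        callBin = 50L, countBin = 200L, covBin = 10L) {
  new("TruthConfig",
      seed = as.integer(seed), nChrom = as.integer(nChrom),
      chromLength = as.integer(chromLength), nGenes = as.integer(nGenes),
      geneLenMeanlog = geneLenMeanlog, geneLenSdlog = geneLenSdlog,
      fracTrna = fracTrna, fracSnorna = fracSnorna,
      telomereLength = as.integer(telomereLength),
      nEarlyArs = as.integer(nEarlyArs),
      muBg = muBg, alphaBg = alphaBg,
      hybridScale = hybridScale, exprSdlog = exprSdlog, fGain = fGain,
      nGainHpr1 = as.integer(nGainHpr1), nGainSen1 = as.integer(nGainSen1),
      nGainCommon = as.integer(nGainCommon), piHO = piHO,
      sigmaDam = sigmaDam, aDam = aDam, damageMass = damageMass,
      h2apBaselineMean = h2apBaselineMean, h2apBaselineDisp = h2apBaselineDisp,
      nReplicates = as.integer(nReplicates),
      callBin = as.integer(callBin), countBin = as.integer(countBin),
      covBin = as.integer(covBin))
}

#' Synthetic truth: genome, annotation and planted ground truth
#'
#' @slot seqinfo the synthetic genome.
#' @slot genes protein-coding genes (mcols: `geneId`, `biotype`,
#'   `expression`, `arsProximal`, `orientation`).
#' @slot features all annotated features including tRNA/snoRNA genes and
#'   telomeres (mcols: `featureId`, `biotype`).
#' @slot ars early-origin midpoints (width-1 ranges).
#' @slot gainRegions planted gain regions (mcols: `label` in
#'   hpr1-specific / sen1-specific / common, `geneId`, `forkDirection`).
#' @slot config the generating [TruthConfig-class].
#' @exportClass RLoopTruth
setClass("RLoopTruth",
  representation(seqinfo = "Seqinfo", genes = "GRanges",
                 features = "GRanges", ars = "GRanges",
                 gainRegions = "GRanges", config = "TruthConfig")
)
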