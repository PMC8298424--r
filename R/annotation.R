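# Peak-to-feature annotation and gain-gene property comparisons.

.featureClass <- function(biotype) {
  cls <- rep("other", length(biotype))
  cls[biotype %in% c("gene", "protein_coding")] <- "protein-coding"
  cls[biotype == "tRNA_gene"] <- "tRNA"
  cls[biotype == "snoRNA_gene"] <- "snoRNA"
  cls[biotype == "telomere"] <- "telomere"
  cls
}

#' Annotate peaks to genomic features
#'
#' A peak is annotated to a feature when it overlaps the feature or lies
#' within `upstreamMax` bp upstream of the feature's 5' end (the window is
#' strand-relative; a peak whose nearest edge sits exactly `upstreamMax`
#' bp away is outside).  A peak may be annotated to more than one feature;
#' peaks with no assignment get a single `unannotated` row.
#'
#' @param peaks peak `GRanges`.
#' @param features feature `GRanges` with mcols `featureId` and `biotype`.
#' @param upstreamMax upstream window in bp (default 200).
#' @param ignoreStrand ignore peak strand when matching (feature strand
#'   still defines "upstream"); default `TRUE`.
#' @return a `data.frame` with columns `peakId`, `featureId`,
#'   `featureClass`, `relation` (`overlap`, `upstream`, `unannotated`).
#' @export
annotatePeaks <- function(peaks, features, upstreamMax = 200,
                          ignoreStrand = TRUE) {
  peakId <- if (!is.null(peaks$name)) peaks$name
            else sprintf("peak%05d", seq_along(peaks))
  rows <- list()
  ovl <- GenomicRanges::findOverlaps(peaks, features,
                                     ignore.strand = ignoreStrand)
  if (length(ovl))
    rows[[1]] <- data.frame(
      peakIdx = S4Vectors::queryHits(ovl),
      featureId = features$featureId[S4Vectors::subjectHits(ovl)],
      featureClass = .featureClass(features$biotype[S4Vectors::subjectHits(ovl)]),
      relation = "overlap")
  stranded <- as.character(BiocGenerics::strand(features)) %in% c("+", "-")
  if (any(stranded) && upstreamMax > 0) {
    # flank windows of features at chromosome edges run out of bounds
    # before trimming; that is expected, not an input error
    up <- suppressWarnings(
      GenomicRanges::trim(GenomicRanges::flank(features[stranded],
                                               as.integer(upstreamMax),
                                               start = TRUE)))
    upHits <- GenomicRanges::findOverlaps(peaks, up, ignore.strand = TRUE)
    if (length(upHits)) {
      fidx <- which(stranded)[S4Vectors::subjectHits(upHits)]
      rows[[length(rows) + 1L]] <- data.frame(
        peakIdx = S4Vectors::queryHits(upHits),
        featureId = features$featureId[fidx],
        featureClass = .featureClass(features$biotype[fidx]),
        relation = "upstream")
    }
  }
  ann <- if (length(rows)) do.call(rbind, rows)
         else data.frame(peakIdx = integer(0), featureId = character(0),
                         featureClass = character(0), relation = character(0))
  # an overlap supersedes the upstream relation for the same pair
  ann <- ann[order(ann$peakIdx, ann$featureId, ann$relation != "overlap"), ]
  ann <- ann[!duplicated(ann[, c("peakIdx", "featureId")]), ]
  orphan <- setdiff(seq_along(peaks), ann$peakIdx)
  if (length(orphan))
    ann <- rbind(ann, data.frame(peakIdx = orphan, featureId = NA_character_,
                                 featureClass = NA_character_,
                                 relation = "unannotated"))
  ann <- ann[order(ann$peakIdx), ]
  data.frame(peakId = peakId[ann$peakIdx],
             featureId = ann$featureId,
             featureClass = ann$featureClass,
             relation = ann$relation,
             row.names = NULL)
}

#' Fraction of peaks per feature class
#'
#' For each feature class, the fraction of peaks carrying at least one
#' annotation of that class.  Classes are not mutually exclusive, so the
#' fractions may sum to more than 1.
#'
#' @param annotations output of [annotatePeaks()].
#' @return named numeric vector of fractions (including `unannotated`).
#' @export
featureClassFractions <- function(annotations) {
  nPeaks <- length(unique(annotations$peakId))
  stopIfNot(nPeaks > 0L, "empty peak set")
  cls <- unique(stats::na.omit(c(annotations$featureClass, "unannotated")))
  out <- vapply(cls, function(cl) {
    if (cl == "unannotated")
      length(unique(annotations$peakId[annotations$relation == "unannotated"])) / nPeaks
    else
      length(unique(annotations$peakId[
        !is.na(annotations$featureClass) & annotations$featureClass == cl])) / nPeaks
  }, numeric(1))
  out
}

#' Reads per kilobase per million mapped reads
#'
#' `count / (length/1000 * librarySize/1e6)`.
#'
#' @param count read count(s).
#' @param lengthBp feature length(s) in bp (> 0).
#' @param librarySize total mapped reads (> 0).
#' @return numeric RPKM value(s).
#' @examples
#' rpkm(10, 500, 1e6)   # 20
#' @export
rpkm <- function(count, lengthBp, librarySize) {
  stopIfNot(all(lengthBp > 0), "feature length must be positive")
  stopIfNot(all(librarySize > 0), "library size must be positive")
  count / (lengthBp / 1000 * librarySize / 1e6)
}

#' Compare properties of gain genes against the genome background
#'
#' Median gene length and median expression of the R-loop-gain gene set
#' versus all genes, with two-sided Wilcoxon rank-sum p-values.
#'
#' @param gainGenes `GRanges` of gain genes (mcol `geneId`).
#' @param allGenes `GRanges` of all genes (mcol `geneId`).
#' @param expression named numeric vector of per-gene expression covering
#'   `allGenes` (names = geneId); any unit, e.g. RPKM.
#' @return list with `medianLength`, `medianExpression` (each a
#'   gain/genome pair plus their ratio) and `pLength`, `pExpression`.
#' @export
compareGeneProperties <- function(gainGenes, allGenes, expression) {
  stopIfNot(length(gainGenes) > 0L, "empty gain gene set")
  stopIfNot(all(allGenes$geneId %in% names(expression)),
            "expression table must cover all genes")
  lenGain <- BiocGenerics::width(gainGenes)
  lenAll <- BiocGenerics::width(allGenes)
  exGain <- expression[gainGenes$geneId]
  exAll <- expression[allGenes$geneId]
  list(
    medianLength = c(gain = stats::median(lenGain),
                     genome = stats::median(lenAll),
                     ratio = stats::median(lenGain) / stats::median(lenAll)),
    medianExpression = c(gain = stats::median(exGain),
                         genome = stats::median(exAll),
                         ratio = stats::median(exGain) / stats::median(exAll)),
    pLength = stats::wilcox.test(lenGain, lenAll, exact = FALSE)$p.value,
    pExpression = stats::wilcox.test(exGain, exAll, exact = FALSE)$p.value)
}
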