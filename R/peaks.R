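#' Call peaks from enriched-state posteriors
#'
#' Candidate peaks are maximal runs of bins whose enriched-state posterior
#' exceeds 0.5; a candidate is retained only if the maximum posterior
#' within the run reaches `cutoff` (default 0.99999) and the run spans at
#' least `minLength` bp (default 100; shorter peaks are discarded).
#' Coordinates are snapped to bin boundaries.
#'
#' @param x an [NBHMMFit-class], or a numeric posterior vector (then
#'   `bins` is required).
#' @param bins `GRanges` of the bins behind the posteriors (ignored for an
#'   `NBHMMFit`).
#' @param cutoff maximum-posterior cutoff in the peak.
#' @param minLength minimum peak length in bp.
#' @return `GRanges` of peaks with mcols `maxPosterior` and `nBins`.
#' @export
callPeaks <- function(x, bins = NULL, cutoff = 0.99999, minLength = 100) {
  if (is(x, "NBHMMFit")) {
    post <- enrichedPosterior(x)
    bins <- x@bins
  } else {
    post <- as.numeric(x)
  }
  stopIfNot(!is.null(bins) && length(bins) == length(post),
            "one bin per posterior value is required")
  stopIfNot(all(post >= 0 & post <= 1), "posteriors must lie in [0, 1]")
  if (length(post) == 0L) return(GRanges())
  chr <- as.character(seqnames(bins))
  strandChar <- as.character(BiocGenerics::strand(bins))
  key <- paste(chr, strandChar)
  peakList <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    p <- post[idx]
    r <- rle(p > 0.5)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      i0 <- idx[starts[j]]; i1 <- idx[ends[j]]
      st <- GenomicRanges::start(bins)[i0]
      en <- GenomicRanges::end(bins)[i1]
      mp <- max(post[idx[starts[j]:ends[j]]])
      if (mp >= cutoff && (en - st + 1L) >= minLength) {
        pk <- GRanges(chr[i0], IRanges(st, en), strand = strandChar[i0],
                      seqinfo = seqinfo(bins))
        pk$maxPosterior <- mp
        pk$nBins <- ends[j] - starts[j] + 1L
        peakList[[length(peakList) + 1L]] <- pk
      }
    }
  }
  if (length(peakList) == 0L) return(GRanges(seqinfo = seqinfo(bins)))
  BiocGenerics::sort(suppressWarnings(do.call(c, peakList)),
                     ignore.strand = TRUE)
}

#' Replicate-consensus peaks
#'
#' Keeps only signal present in both replicates: the output is the
#' base-pair intersection of every overlapping pair of replicate-1 and
#' replicate-2 peaks (same strand, >= 1 bp overlap); the pair's
#' `maxPosterior` is the smaller of the two.  Peaks private to one
#' replicate are dropped.  Symmetric in its arguments, and
#' `consensusPeaks(x, x)` returns `x`.
#'
#' @param peaks1,peaks2 peak `GRanges` from two replicates of the same
#'   strand and condition.
#' @return consensus peak `GRanges`.
#' @export
consensusPeaks <- function(peaks1, peaks2) {
  if (length(peaks1) == 0L || length(peaks2) == 0L)
    return(GRanges(seqinfo = seqinfo(peaks1)))
  hits <- GenomicRanges::findOverlaps(peaks1, peaks2, ignore.strand = FALSE)
  if (length(hits) == 0L) return(GRanges(seqinfo = seqinfo(peaks1)))
  a <- peaks1[S4Vectors::queryHits(hits)]
  b <- peaks2[S4Vectors::subjectHits(hits)]
  out <- GenomicRanges::pintersect(granges(a), granges(b))
  out$hit <- NULL
  mpa <- if (!is.null(a$maxPosterior)) a$maxPosterior else rep(1, length(a))
  mpb <- if (!is.null(b$maxPosterior)) b$maxPosterior else rep(1, length(b))
  out$maxPosterior <- pmin(mpa, mpb)
  BiocGenerics::sort(unique(out), ignore.strand = TRUE)
}

#' Consensus peak calling for one condition
#'
#' Fits the NB HMM per replicate and strand, calls peaks, and intersects
#' replicates ([consensusPeaks()]).  With a single replicate the consensus
#' step is skipped.
#'
#' @param bcList list of single-sample stranded [BinnedCounts-class]
#'   replicates.
#' @param cutoff,minLength see [callPeaks()].
#' @param strands strands to call (default `+` and `-`).
#' @return `GRanges` of (consensus) peaks across both strands.
#' @export
callConditionPeaks <- function(bcList, cutoff = 0.99999, minLength = 100,
                               strands = c("+", "-")) {
  perStrand <- lapply(strands, function(s) {
    reps <- lapply(bcList, function(bc) {
      fit <- fitNbHmm(bc, strand = s)
      callPeaks(fit, cutoff = cutoff, minLength = minLength)
    })
    cons <- reps[[1]]
    if (length(reps) > 1L)
      for (j in 2:length(reps)) cons <- consensusPeaks(cons, reps[[j]])
    cons
  })
  BiocGenerics::sort(suppressWarnings(do.call(c, perStrand)),
                     ignore.strand = TRUE)
}
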