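# RPKM coverage, RNase-H scaling, wild-type subtraction, oriented
# metaprofiles (reference-point and scaled-region), sense/antisense
# splitting and the damage asymmetry index.

#' RPKM coverage from binned counts
#'
#' `value = count / (binWidth/1000 * totalReads/1e6)` per bin.
#'
#' @param bc a genome-tiling single-sample [BinnedCounts-class].
#' @param sample column index or name.
#' @param strand strand to extract for stranded counts (`"*"` for
#'   unstranded input).
#' @param totalReads total mapped reads (> 0); defaults to the sample's
#'   library size.
#' @return an RPKM-normalised [CoverageTrack-class].
#' @export
coverageRpkm <- function(bc, sample = 1L, strand = "*", totalReads = NULL) {
  if (is.null(totalReads)) totalReads <- librarySizes(bc)[[sample]]
  stopIfNot(totalReads > 0, "totalReads must be positive")
  rr <- rowRanges(bc)
  keep <- if (strand == "*") as.character(BiocGenerics::strand(rr)) %in% c("*", "+")
          else as.character(BiocGenerics::strand(rr)) == strand
  if (strand == "*" && any(as.character(BiocGenerics::strand(rr)) == "-"))
    stop("stranded counts: pick strand '+' or '-'", call. = FALSE)
  bins <- rr[keep]
  bw <- binWidth(bc)
  v <- counts(bc)[keep, sample] / (bw / 1000 * totalReads / 1e6)
  chr <- as.character(seqnames(bins))
  vals <- split(v, factor(chr, levels = seqlevels(seqinfo(rr))))
  CoverageTrack(lapply(vals, as.numeric), seqinfo(rr), bw, strand = strand,
                normalization = "RPKM", totalReads = totalReads)
}

#' Scale an RNase-H-treated track by its unique/total read ratio
#'
#' Multiplies every bin by `uniqueReads / totalReads`, the scale factor
#' that makes hybrid-depleted control samples comparable to untreated
#' ones.
#'
#' @param track a [CoverageTrack-class].
#' @param uniqueReads,totalReads read counts with
#'   `0 < uniqueReads <= totalReads`.
#' @return the scaled track, tagged `RNH-scaled`.
#' @export
scaleRnh <- function(track, uniqueReads, totalReads) {
  stopIfNot(uniqueReads > 0 && totalReads > 0, "read counts must be positive")
  stopIfNot(uniqueReads <= totalReads, "uniqueReads must not exceed totalReads")
  sf <- uniqueReads / totalReads
  new("CoverageTrack",
      values = lapply(trackValues(track), function(v) v * sf),
      seqinfo = seqinfo(track), binWidth = binWidth(track),
      strand = strand(track), normalization = "RNH-scaled",
      totalReads = as.numeric(totalReads), uniqueReads = as.numeric(uniqueReads))
}

#' Subtract a wild-type track from a mutant track
#'
#' Elementwise `mutant - WT`; negative values are preserved (no
#' clamping), so regions where the wild type is higher stay visible.
#'
#' @param mutantTrack,wtTrack [CoverageTrack-class] objects on the same
#'   genome and bin width.
#' @return the difference track, tagged `WT-subtracted`.
#' @export
subtractWt <- function(mutantTrack, wtTrack) {
  stopIfNot(binWidth(mutantTrack) == binWidth(wtTrack),
            "mismatched bin widths")
  stopIfNot(identical(seqlengths(seqinfo(mutantTrack)),
                      seqlengths(seqinfo(wtTrack))),
            "tracks must share a genome")
  vals <- Map(`-`, trackValues(mutantTrack), trackValues(wtTrack))
  new("CoverageTrack", values = vals, seqinfo = seqinfo(mutantTrack),
      binWidth = binWidth(mutantTrack), strand = strand(mutantTrack),
      normalization = "WT-subtracted",
      totalReads = mutantTrack@totalReads, uniqueReads = mutantTrack@uniqueReads)
}

#' Average replicate tracks
#'
#' @param tracks list of [CoverageTrack-class] replicates (same genome,
#'   bin width).
#' @return the elementwise mean track.
#' @export
averageTracks <- function(tracks) {
  if (is(tracks, "CoverageTrack")) return(tracks)
  stopIfNot(length(tracks) >= 1L, "need at least one track")
  t1 <- tracks[[1]]
  if (length(tracks) == 1L) return(t1)
  vals <- trackValues(t1)
  for (j in 2:length(tracks)) {
    stopIfNot(binWidth(tracks[[j]]) == binWidth(t1), "mismatched bin widths")
    vals <- Map(`+`, vals, trackValues(tracks[[j]]))
  }
  vals <- lapply(vals, function(v) v / length(tracks))
  new("CoverageTrack", values = vals, seqinfo = seqinfo(t1),
      binWidth = binWidth(t1), strand = strand(t1),
      normalization = normalization(t1),
      totalReads = NA_real_, uniqueReads = NA_real_)
}

# Piecewise-constant integral of a track on one chromosome: F(x) for
# 0-based continuous x in [0, L]; area-preserving cell means follow as
# (F(b) - F(a)) / (b - a).  x outside [0, L] yields NA.
.trackIntegral <- function(v, bw, L, x) {
  cs <- c(0, cumsum(v) * bw)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & x >= 0 & x <= L
  xi <- x[ok]
  j <- pmin(floor(xi / bw), length(v) - 1L)
  out[ok] <- cs[j + 1L] + v[j + 1L] * (xi - j * bw)
  out
}

# Resample a window [a, b) (0-based bp) of one chromosome into nCells
# overlap-weighted means; cells extending beyond the chromosome are NA.
.resampleWindow <- function(v, bw, L, a, b, nCells) {
  edges <- seq(a, b, length.out = nCells + 1L)
  Fv <- .trackIntegral(v, bw, L, edges)
  (Fv[-1L] - Fv[-length(Fv)]) / diff(edges)
}

.forkDirections <- function(anchors, ars) {
  stopIfNot(!is.null(ars) && length(ars) > 0L, "an origin set is required")
  mids <- rangeMid(anchors)
  vapply(seq_along(anchors), function(i) {
    onChr <- which(as.character(seqnames(ars)) ==
                     as.character(seqnames(anchors))[i])
    stopIfNot(length(onChr) > 0L, "no origin on an anchor's chromosome")
    am <- GenomicRanges::start(ars)[onChr]
    if (mids[i] >= am[which.min(abs(am - mids[i]))]) "+" else "-"
  }, character(1))
}

#' Reference-point metaplot around anchors
#'
#' Extracts the window anchor-midpoint +/- `flankBp`, resampled to
#' `nBins` positions, for every anchor; rows are flipped so the position
#' axis runs 5'->3' of the anchor (`orientBy = "strand"`) or fork-upstream
#' to fork-downstream (`orientBy = "fork"`, direction away from the
#' nearest origin midpoint in `ars`).  Replicate tracks are averaged
#' first.  Windows entirely off-chromosome are dropped (with a notice);
#' partially off-chromosome positions are `NaN`.
#'
#' @param tracks a [CoverageTrack-class] or list of replicate tracks.
#' @param anchors anchor `GRanges`.
#' @param flankBp half-window in bp.
#' @param nBins number of positions across the window.
#' @param orientBy `"strand"` or `"fork"`.
#' @param ars origin midpoints (`GRanges`), required for
#'   `orientBy = "fork"`.
#' @return a [MetaplotMatrix-class]; positions are bp offsets from the
#'   anchor midpoint (negative = upstream after orientation).
#' @export
metaplotReferencePoint <- function(tracks, anchors, flankBp = 5000,
                                   nBins = 100L, orientBy = c("strand", "fork"),
                                   ars = NULL) {
  orientBy <- match.arg(orientBy)
  track <- averageTracks(tracks)
  bw <- binWidth(track)
  sl <- seqlengths(seqinfo(track))
  flip <- if (orientBy == "fork") .forkDirections(anchors, ars) == "-"
          else as.character(BiocGenerics::strand(anchors)) == "-"
  mids0 <- rangeMid(anchors) - 0.5          # 0-based continuous midpoints
  mat <- matrix(NA_real_, length(anchors), nBins)
  keep <- rep(TRUE, length(anchors))
  for (i in seq_along(anchors)) {
    chr <- as.character(seqnames(anchors))[i]
    L <- sl[[chr]]
    a <- mids0[i] - flankBp; b <- mids0[i] + flankBp
    if (b <= 0 || a >= L) { keep[i] <- FALSE; next }
    row <- .resampleWindow(trackValues(track)[[chr]], bw, L, a, b, nBins)
    if (flip[i]) row <- rev(row)
    mat[i, ] <- row
  }
  if (any(!keep))
    message(sum(!keep), " anchor window(s) fully off-chromosome dropped")
  mat <- mat[keep, , drop = FALSE]
  ids <- if (!is.null(anchors$name)) anchors$name[keep]
         else sprintf("anchor%05d", which(keep))
  rownames(mat) <- ids
  cw <- 2 * flankBp / nBins
  new("MetaplotMatrix", values = mat,
      positions = seq(-flankBp + cw / 2, flankBp - cw / 2, length.out = nBins),
      mode = "refpoint", oriented = TRUE)
}

#' Scaled-region metaplot (gene-body style)
#'
#' The region body is linearly rescaled to `bodyBins` positions
#' (area-preserving resampling; regions shorter than `bodyBins` bp are
#' interpolated, not rejected); fixed-resolution flanks of `flankBp` bp at
#' `flankBinWidth` bp per position are attached on both sides.  Rows of
#' minus-strand regions are reversed so the axis runs 5'->3'.
#'
#' @param tracks a [CoverageTrack-class] or list of replicates.
#' @param regions region `GRanges`.
#' @param bodyBins positions across the region body.
#' @param flankBp flank extent in bp.
#' @param flankBinWidth bp per flank position.
#' @return a [MetaplotMatrix-class]; positions are column indices
#'   (upstream flank, body, downstream flank).
#' @export
metaplotScaledRegions <- function(tracks, regions, bodyBins = 100L,
                                  flankBp = 2000, flankBinWidth = 10) {
  stopIfNot(all(BiocGenerics::width(regions) >= 1L), "degenerate region")
  track <- averageTracks(tracks)
  bw <- binWidth(track)
  sl <- seqlengths(seqinfo(track))
  nFlank <- as.integer(round(flankBp / flankBinWidth))
  nCol <- 2L * nFlank + bodyBins
  mat <- matrix(NA_real_, length(regions), nCol)
  for (i in seq_along(regions)) {
    chr <- as.character(seqnames(regions))[i]
    L <- sl[[chr]]
    v <- trackValues(track)[[chr]]
    s0 <- GenomicRanges::start(regions)[i] - 1L
    e0 <- GenomicRanges::end(regions)[i]
    left <- .resampleWindow(v, bw, L, s0 - flankBp, s0, nFlank)
    body <- .resampleWindow(v, bw, L, s0, e0, bodyBins)
    right <- .resampleWindow(v, bw, L, e0, e0 + flankBp, nFlank)
    row <- c(left, body, right)
    if (as.character(BiocGenerics::strand(regions))[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  rownames(mat) <- if (!is.null(regions$name)) regions$name
                   else sprintf("region%05d", seq_along(regions))
  new("MetaplotMatrix", values = mat, positions = seq_len(nCol),
      mode = "scaled", oriented = TRUE)
}

#' Sense and antisense metaplots over genes
#'
#' Splits stranded signal by gene orientation: the sense matrix takes the
#' track matching each gene's strand, the antisense matrix the opposite
#' track; both are oriented 5'->3' of the gene.  The sum of the two
#' matrices equals the scaled metaplot of the pooled (plus + minus)
#' track.
#'
#' @param plusTrack,minusTrack stranded [CoverageTrack-class] objects.
#' @param genes gene `GRanges` (stranded).
#' @param ... passed to [metaplotScaledRegions()].
#' @return list with `MetaplotMatrix` elements `sense` and `antisense`.
#' @export
senseAntisenseSplit <- function(plusTrack, minusTrack, genes, ...) {
  stopIfNot(is(plusTrack, "CoverageTrack") && is(minusTrack, "CoverageTrack"),
            "both strand tracks are required")
  mmPlus <- metaplotScaledRegions(plusTrack, genes, ...)
  mmMinus <- metaplotScaledRegions(minusTrack, genes, ...)
  onPlus <- as.character(BiocGenerics::strand(genes)) == "+"
  sense <- mmPlus@values
  sense[!onPlus, ] <- mmMinus@values[!onPlus, ]
  anti <- mmMinus@values
  anti[!onPlus, ] <- mmPlus@values[!onPlus, ]
  list(sense = new("MetaplotMatrix", values = sense,
                   positions = mmPlus@positions, mode = "scaled",
                   oriented = TRUE),
       antisense = new("MetaplotMatrix", values = anti,
                       positions = mmPlus@positions, mode = "scaled",
                       oriented = TRUE))
}

#' Damage asymmetry index around anchors
#'
#' Per anchor, `U` is the mean signal of the upstream flank and `D` of the
#' downstream flank of an oriented reference-point matrix, excluding
#' positions within `coreExclusionBp` of the anchor point; the asymmetry
#' index is `AI = (D - U) / (D + U)` in `[-1, 1]` (0 = symmetric
#' spreading).  Anchors with `D + U <= 0` or undefined flanks are
#' excluded and counted.  The summary is the mean AI with a bootstrap
#' 95% confidence interval.
#'
#' @param mm an oriented reference-point [MetaplotMatrix-class].
#' @param coreExclusionBp half-width of the excluded core around the
#'   anchor point (must be smaller than the flank).
#' @param nBoot bootstrap resamples for the CI.
#' @param seed RNG seed for the bootstrap.
#' @return an [AsymmetryIndex-class].
#' @export
asymmetryIndex <- function(mm, coreExclusionBp = 500, nBoot = 1000L,
                           seed = 1L) {
  stopIfNot(mm@mode == "refpoint", "a reference-point matrix is required")
  pos <- mm@positions
  stopIfNot(max(pos) > coreExclusionBp,
            "flank must extend beyond the core exclusion")
  upCols <- pos < -coreExclusionBp
  dnCols <- pos > coreExclusionBp
  U <- rowMeans(mm@values[, upCols, drop = FALSE], na.rm = TRUE)
  D <- rowMeans(mm@values[, dnCols, drop = FALSE], na.rm = TRUE)
  ai <- (D - U) / (D + U)
  ok <- is.finite(ai) & (D + U) > 0
  nExcluded <- sum(!ok)
  ai <- ai[ok]
  stopIfNot(length(ai) > 0L, "no anchor with nonzero flank signal")
  bootMeans <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
    mean(ai[sample.int(length(ai), replace = TRUE)])
  }, numeric(1)))
  ci <- stats::quantile(bootMeans, c(0.025, 0.975), names = FALSE)
  new("AsymmetryIndex", ai = ai, mean = mean(ai),
      ciLower = ci[1], ciUpper = ci[2], nExcluded = as.integer(nExcluded))
}
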