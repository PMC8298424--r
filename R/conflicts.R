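# Head-on / codirectional transcription-replication conflict analysis
# around early replication origins: origin-proximal gene selection,
# orientation calls against the fork direction, per-orientation gain
# percentages and the one-sided 2x2 chi-square test.

#' Select genes close to early origin midpoints
#'
#' A gene is kept when the distance from its nearest edge to some origin
#' midpoint is strictly below `maxDist` bp (0 when the midpoint falls
#' inside the gene; a distance of exactly `maxDist` is excluded).  The
#' nearest origin is recorded; ties are broken toward the origin with the
#' lower coordinate.  Orientation versus the fork (see [orientHoCd()]) is
#' attached.
#'
#' @param genes protein-coding gene `GRanges` (stranded; optional mcol
#'   `geneId`).
#' @param ars origin midpoints as width-1 `GRanges` (optional mcol
#'   `arsId`); supply early origins only.
#' @param maxDist distance threshold in bp (strict).
#' @return the kept genes with mcols `geneId`, `arsId`, `arsMid`,
#'   `distance`, `orientation` (`HO`, `CD`, or `NA` for the ambiguous
#'   midpoint-on-midpoint case).
#' @export
arsProximalGenes <- function(genes, ars, maxDist = 1000) {
  stopIfNot(length(ars) > 0L, "empty origin set")
  geneId <- if (!is.null(genes$geneId)) genes$geneId
            else sprintf("gene%05d", seq_along(genes))
  arsId <- if (!is.null(ars$arsId)) ars$arsId
           else sprintf("ARS%03d", seq_along(ars))
  arsChr <- as.character(seqnames(ars))
  arsMidAll <- GenomicRanges::start(ars)
  geneChr <- as.character(seqnames(genes))
  gs <- GenomicRanges::start(genes); ge <- GenomicRanges::end(genes)
  keep <- logical(length(genes))
  nearIdx <- integer(length(genes))
  nearDist <- numeric(length(genes))
  for (chr in unique(geneChr)) {
    gIdx <- which(geneChr == chr)
    aIdx <- which(arsChr == chr)
    if (length(aIdx) == 0L) next
    am <- arsMidAll[aIdx]
    # gap distance gene x origin-midpoint (0 when the midpoint is inside)
    d <- pmax(outer(gs[gIdx], am, function(s, m) s - m - 1L),
              outer(ge[gIdx], am, function(e, m) m - e - 1L), 0)
    ord <- order(am)   # ties broken toward the lower-coordinate origin
    d <- d[, ord, drop = FALSE]
    best <- max.col(-d, ties.method = "first")
    dmin <- d[cbind(seq_along(gIdx), best)]
    ok <- dmin < maxDist
    keep[gIdx] <- ok
    nearIdx[gIdx] <- aIdx[ord][best]
    nearDist[gIdx] <- dmin
  }
  out <- genes[keep]
  idx <- nearIdx[keep]
  out$geneId <- geneId[keep]
  out$arsId <- arsId[idx]
  out$arsMid <- arsMidAll[idx]
  out$distance <- nearDist[keep]
  out$orientation <- orientHoCd(out, out$arsMid)
  out
}

#' Head-on or codirectional orientation versus the replication fork
#'
#' The fork is modelled as strictly bidirectional from the origin
#' midpoint: a gene whose midpoint lies right of the origin faces a
#' rightward (`+`) fork, left of it a leftward (`-`) fork.  The gene is
#' codirectional (`CD`) when its strand equals the fork direction and
#' head-on (`HO`) otherwise.  A gene midpoint exactly on the origin
#' midpoint is ambiguous: it is labelled `NA` and reported via a message.
#'
#' @param genes stranded gene `GRanges`.
#' @param arsMid origin midpoint position(s) in bp (recycled).
#' @return character vector `"HO"` / `"CD"` with `NA` for ambiguous genes.
#' @examples
#' g <- GenomicRanges::GRanges("chrI", IRanges::IRanges(11001, 12000), strand = "-")
#' orientHoCd(g, 10000)   # "HO": rightward fork meets leftward transcription
#' @export
orientHoCd <- function(genes, arsMid) {
  arsMid <- rep_len(arsMid, length(genes))
  gm <- rangeMid(genes)
  side <- sign(gm - arsMid)
  fork <- ifelse(side > 0, "+", "-")
  strandChar <- as.character(BiocGenerics::strand(genes))
  out <- ifelse(strandChar == fork, "CD", "HO")
  out[side == 0 | !strandChar %in% c("+", "-")] <- NA_character_
  if (anyNA(out))
    message(sum(is.na(out)), " gene(s) ambiguous (midpoint on origin midpoint ",
            "or unstranded); excluded")
  out
}

#' Orientation-by-gain contingency table
#'
#' Counts origin-proximal genes as R-loop-gain when they overlap at least
#' one gain region of the requested class, split by head-on versus
#' codirectional orientation, and reports per-orientation gain
#' percentages.
#'
#' @param calls output of [arsProximalGenes()] (ambiguous genes are
#'   dropped).
#' @param gainRegions gain-region `GRanges`, optionally with an mcol
#'   `label`/`class`.
#' @param gainClass restrict to regions of this label (default: all).
#' @param ignoreStrand ignore strand in the gene/region overlap (default
#'   `TRUE`; a gain region marks its locus regardless of strand).
#' @return list with `table` (2x2 integer matrix, rows HO/CD, columns
#'   gain/noGain) and `percentages` (named HO/CD, `NA` and a warning when
#'   an orientation has no genes).
#' @export
orientationGainTable <- function(calls, gainRegions, gainClass = NULL,
                                 ignoreStrand = TRUE) {
  calls <- calls[!is.na(calls$orientation)]
  regions <- gainRegions
  if (!is.null(gainClass)) {
    lab <- if (!is.null(regions$label)) regions$label else regions$class
    stopIfNot(!is.null(lab), "gain regions carry no class label")
    regions <- regions[lab == gainClass]
  }
  gain <- IRanges::overlapsAny(calls, regions,
                                     ignore.strand = ignoreStrand)
  tab <- matrix(0L, 2, 2, dimnames = list(c("HO", "CD"), c("gain", "noGain")))
  for (o in c("HO", "CD")) {
    sel <- calls$orientation == o
    tab[o, "gain"] <- sum(gain & sel)
    tab[o, "noGain"] <- sum(!gain & sel)
  }
  tot <- rowSums(tab)
  pct <- ifelse(tot > 0, 100 * tab[, "gain"] / tot, NA_real_)
  if (any(tot == 0))
    warning("orientation with zero genes: percentage undefined")
  list(table = tab, percentages = pct)
}

#' One-sided chi-square test for a 2x2 table
#'
#' Uses the closed form `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`
#' without continuity correction (1 degree of freedom).  The one-sided
#' p-value is half the two-sided tail when the observed direction matches
#' `alternative`, and `1 - two-sided/2` otherwise.
#'
#' @param table 2x2 non-negative integer matrix, rows = orientations,
#'   columns = (gain, no gain).
#' @param alternative `"greater"` (row-1 gain proportion exceeds row 2),
#'   `"less"`, or `"two.sided"`.
#' @return list with `statistic`, `pvalue`, `alternative`.
#' @examples
#' chiSquare2x2(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))$statistic  # 20
#' @export
chiSquare2x2 <- function(table, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopIfNot(all(dim(table) == c(2L, 2L)), "a 2x2 table is required")
  stopIfNot(all(table >= 0), "counts must be non-negative")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  marg <- c(a + b, c + d, a + c, b + d)
  stopIfNot(all(marg > 0), "degenerate table: a margin is zero")
  N <- a + b + c + d
  stat <- N * (a * d - b * c)^2 / prod(marg)
  pTwo <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (alternative == "two.sided") {
    p <- pTwo
  } else {
    diff <- a / (a + b) - c / (c + d)
    matches <- (alternative == "greater" && diff > 0) ||
      (alternative == "less" && diff < 0)
    p <- if (diff == 0) 0.5 else if (matches) pTwo / 2 else 1 - pTwo / 2
  }
  list(statistic = stat, pvalue = p, alternative = alternative)
}

#' Simulate an orientation-bias dataset and test it
#'
#' Calibration helper: builds a toy single-chromosome genome whose origins
#' each carry one random-strand gene per side within 1 kb, assigns
#' `nGain` gain genes so that an expected fraction `piHO` of them are
#' head-on (binomial draw, pools capped), and runs the full
#' origin-proximal / orientation / contingency / one-sided chi-square
#' path.  Used for type-I error and power checks of the orientation test.
#'
#' @param nArs number of origins (two flanking genes each).
#' @param nGain gain genes to plant.
#' @param piHO probability a gain gene is drawn from the head-on pool
#'   (0.5 = no bias, the null).
#' @param seed RNG seed.
#' @return list with `table`, `percentages`, `statistic`, `pvalue`.
#' @export
simulateOrientationTable <- function(nArs = 40L, nGain = 40L, piHO = 0.8,
                                     seed = 1L) {
  withSeed(seed, {
    pitch <- 20000L
    L <- (nArs + 1L) * pitch
    si <- Seqinfo("chrSim", L)
    mids <- pitch * seq_len(nArs)
    ars <- GRanges("chrSim", IRanges(mids, width = 1L), seqinfo = si)
    ars$arsId <- paste0("ARS", seq_len(nArs))
    gap <- 200L; len <- 600L
    starts <- c(mids - gap - len + 1L, mids + gap)
    genes <- GRanges("chrSim", IRanges(starts, width = len),
                     strand = sample(c("+", "-"), 2L * nArs, replace = TRUE),
                     seqinfo = si)
    genes$geneId <- sprintf("g%04d", seq_along(genes))
    calls <- arsProximalGenes(genes, ars, maxDist = 1000)
    # weighted sampling without replacement: head-on genes carry odds
    # piHO : (1 - piHO); at piHO = 0.5 this is exactly uniform gain
    # assignment, i.e. the null of no orientation association
    w <- ifelse(calls$orientation == "HO", piHO, 1 - piHO)
    gainIdx <- sample(seq_along(calls), min(nGain, length(calls)), prob = w)
    gains <- granges(calls)[gainIdx]
    tab <- orientationGainTable(calls, gains)
    chi <- chiSquare2x2(tab$table, alternative = "greater")
    list(table = tab$table, percentages = tab$percentages,
         statistic = chi$statistic, pvalue = chi$pvalue)
  })
}
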