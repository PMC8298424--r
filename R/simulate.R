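# Synthetic genome / annotation / signal generator with planted, labelled
# ground truth: wild-type-like hybrid landscapes, an orientation-blind
# G1+S gain condition (hpr1-type), an S-only head-on-biased gain condition
# (sen1-type), an RNase-H control, and damage tracks with symmetric vs
# fork-downstream-asymmetric spreading.

#' Tile a genome into fixed-width bins
#'
#' @param seqinfo a [GenomeInfoDb::Seqinfo].
#' @param binWidth bin width in bp.
#' @param stranded duplicate the tiling on `+` and `-` strands?
#' @return `GRanges` of bins in genomic order (all `+` bins then all `-`
#'   when `stranded`).
#' @export
genomeBins <- function(seqinfo, binWidth, stranded = FALSE) {
  sl <- seqlengths(seqinfo)
  grl <- lapply(names(sl), function(chr) {
    s <- seq(1L, sl[[chr]], by = binWidth)
    GRanges(chr, IRanges(s, pmin(s + binWidth - 1L, sl[[chr]])),
            seqinfo = seqinfo)
  })
  bins <- suppressWarnings(do.call(c, grl))
  if (stranded) {
    plus <- bins; BiocGenerics::strand(plus) <- "+"
    minus <- bins; BiocGenerics::strand(minus) <- "-"
    bins <- c(plus, minus)
  }
  bins
}

.geneLengths <- function(n, cfg) {
  pmin(pmax(round(stats::rlnorm(n, cfg@geneLenMeanlog, cfg@geneLenSdlog)), 300L),
       5000L)
}

#' Generate a synthetic genome, annotation and planted truth
#'
#' Builds a multi-chromosome genome with telomeres, early replication
#' origins (midpoints >= 20 kb apart, each deliberately flanked by one gene
#' per side within 1 kb so head-on and codirectional origin-proximal gene
#' pools exist), non-overlapping protein-coding genes with random strands
#' and log-normal lengths, tRNA/snoRNA features, per-gene expression
#' levels, and planted gain regions labelled hpr1-specific (active G1+S),
#' sen1-specific (active S only, placed on head-on origin-proximal genes
#' with probability `piHO` and on codirectional ones otherwise) and common.
#' Fully deterministic given the configuration seed.
#'
#' @param config a [TruthConfig-class].
#' @return an [RLoopTruth-class].
#' @examples
#' truth <- generateAnnotation(truthConfig(seed = 7, nChrom = 2,
#'   chromLength = 80000L, nGenes = 40, nEarlyArs = 6L,
#'   nGainHpr1 = 5L, nGainSen1 = 4L, nGainCommon = 2L))
#' truth
#' @export
generateAnnotation <- function(config) {
  stopifnot(is(config, "TruthConfig"))
  validObject(config)
  withSeed(deriveSeed(config@seed, "annotation"), {
    chromNames <- paste0("chr", as.character(utils::as.roman(seq_len(config@nChrom))))
    sl <- stats::setNames(rep(config@chromLength, config@nChrom), chromNames)
    si <- Seqinfo(chromNames, sl, genome = "synthetic")
    telo <- config@telomereLength
    L <- config@chromLength

    telomeres <- GRanges(rep(chromNames, each = 2),
                         IRanges(rep(c(1L, L - telo + 1L), config@nChrom),
                                 rep(c(telo, L), config@nChrom)),
                         seqinfo = si)
    telomeres$biotype <- "telomere"
    telomeres$featureId <- paste0("TEL", seq_along(telomeres))

    # --- early origins, evenly spread with jitter, >= 20 kb apart -------
    nPer <- rep(config@nEarlyArs %/% config@nChrom, config@nChrom)
    extra <- config@nEarlyArs %% config@nChrom
    if (extra > 0) nPer[seq_len(extra)] <- nPer[seq_len(extra)] + 1L
    span <- L - 2L * telo
    arsList <- vector("list", config@nChrom)
    for (i in seq_len(config@nChrom)) {
      if (nPer[i] == 0L) { arsList[[i]] <- GRanges(seqinfo = si); next }
      if (span / nPer[i] < 21000)
        stop(sprintf(
          "genome too small: cannot place %d origin midpoints >= 20 kb apart on %s",
          nPer[i], chromNames[i]), call. = FALSE)
      base <- telo + round((seq_len(nPer[i]) - 0.5) * span / nPer[i])
      mids <- base + sample(-500:500, nPer[i], replace = TRUE)
      arsList[[i]] <- GRanges(chromNames[i], IRanges(mids, width = 1L),
                              seqinfo = si)
    }
    ars <- suppressWarnings(do.call(c, arsList))
    ars$arsId <- paste0("ARS", seq_along(ars))

    # --- genes: one flanking gene per origin side (within 1 kb), then
    #     fill the remaining space ---------------------------------------
    geneList <- list()
    for (i in seq_along(ars)) {
      mid <- GenomicRanges::start(ars)[i]
      chr <- as.character(seqnames(ars))[i]
      lenL <- .geneLengths(1L, config); gapL <- sample(100:800, 1L)
      lenR <- .geneLengths(1L, config); gapR <- sample(100:800, 1L)
      geneList[[length(geneList) + 1L]] <-
        GRanges(chr, IRanges(mid - gapL - lenL + 1L, mid - gapL),
                strand = sample(c("+", "-"), 1L), seqinfo = si)
      geneList[[length(geneList) + 1L]] <-
        GRanges(chr, IRanges(mid + gapR, mid + gapR + lenR - 1L),
                strand = sample(c("+", "-"), 1L), seqinfo = si)
    }
    flanking <- suppressWarnings(do.call(c, geneList))
    if (any(GenomicRanges::start(flanking) <= telo) ||
        any(GenomicRanges::end(flanking) > L - telo) ||
        !identical(GenomicRanges::countOverlaps(flanking, flanking),
                   rep(1L, length(flanking))))
      stop("genome too small: origin-flanking genes collide", call. = FALSE)

    usable <- GRanges(chromNames, IRanges(telo + 1L, L - telo), seqinfo = si)
    occupied <- c(granges(flanking), granges(ars))
    gaps <- GenomicRanges::setdiff(usable,
                                   GenomicRanges::resize(occupied,
                                     BiocGenerics::width(occupied) + 400L,
                                     fix = "center"),
                                   ignore.strand = TRUE)
    # fill every gap with candidate slots, then sample the required number
    candList <- list()
    for (i in seq_along(gaps)) {
      pos <- GenomicRanges::start(gaps)[i]
      gapEnd <- GenomicRanges::end(gaps)[i]
      chr <- as.character(seqnames(gaps))[i]
      repeat {
        pad <- sample(200:1500, 1L)
        len <- .geneLengths(1L, config)
        if (pos + pad + len - 1L > gapEnd) break
        candList[[length(candList) + 1L]] <-
          GRanges(chr, IRanges(pos + pad, pos + pad + len - 1L),
                  strand = sample(c("+", "-"), 1L), seqinfo = si)
        pos <- pos + pad + len
      }
    }
    cands <- if (length(candList))
      suppressWarnings(do.call(c, candList)) else GRanges(seqinfo = si)
    nOther <- config@nGenes - length(flanking)
    nTrna <- round(config@fracTrna * config@nGenes)
    nSno <- round(config@fracSnorna * config@nGenes)
    if (nOther < 0L)
      stop("nGenes smaller than the number of origin-flanking genes", call. = FALSE)
    if (length(cands) < nOther + nTrna + nSno)
      stop(sprintf(
        "genome too small: %d candidate slots for %d genes + %d tRNA + %d snoRNA",
        length(cands), nOther, nTrna, nSno), call. = FALSE)
    idx <- sample(length(cands))
    otherGenes <- cands[idx[seq_len(nOther)]]
    trnaSlots <- cands[idx[nOther + seq_len(nTrna)]]
    snoSlots <- cands[idx[nOther + nTrna + seq_len(nSno)]]

    genes <- BiocGenerics::sort(c(flanking, otherGenes), ignore.strand = TRUE)
    genes$geneId <- sprintf("gene%04d", seq_along(genes))
    genes$biotype <- "gene"
    genes$expression <- stats::rlnorm(length(genes), 0, config@exprSdlog)

    shrinkTo <- function(slots, lens, prefix, biotype) {
      if (length(slots) == 0L) {
        out <- GRanges(seqinfo = si)
        out$featureId <- character(0); out$biotype <- character(0)
        return(out)
      }
      out <- GenomicRanges::resize(granges(slots), lens, fix = "start")
      BiocGenerics::strand(out) <- BiocGenerics::strand(slots)
      out$featureId <- paste0(prefix, seq_along(out))
      out$biotype <- biotype
      out
    }
    trna <- shrinkTo(trnaSlots, sample(70:100, nTrna, replace = TRUE),
                     "tRNA", "tRNA_gene")
    sno <- shrinkTo(snoSlots, sample(120:250, nSno, replace = TRUE),
                    "snoRNA", "snoRNA_gene")

    # --- origin proximity and head-on / codirectional orientation -------
    prox <- arsProximalGenes(genes, ars, maxDist = 1000)
    genes$arsProximal <- genes$geneId %in% prox$geneId
    genes$orientation <- NA_character_
    if (length(prox))
      genes$orientation[match(prox$geneId, genes$geneId)] <- prox$orientation
    # fork direction at each gene: away from the nearest origin midpoint
    gm <- rangeMid(genes)
    nearestMid <- vapply(seq_along(genes), function(i) {
      onChr <- which(as.character(seqnames(ars)) == as.character(seqnames(genes))[i])
      mids <- GenomicRanges::start(ars)[onChr]
      mids[which.min(abs(mids - gm[i]))]
    }, numeric(1))
    genes$forkDirection <- ifelse(gm >= nearestMid, "+", "-")

    # --- planted gain regions -------------------------------------------
    # sen1-type gains: at most one per origin, so the asymmetric damage
    # clouds of origin-flanking anchors never overlap each other's flanks
    nHO <- round(config@piHO * config@nGainSen1)
    nCD <- config@nGainSen1 - nHO
    proxIdx <- which(genes$arsProximal)
    arsOf <- prox$arsId[match(genes$geneId[proxIdx], prox$geneId)]
    pickPerArs <- function(wanted, n, usedArs) {
      sel <- integer(0)
      for (aid in sample(unique(arsOf))) {
        if (length(sel) >= n) break
        if (aid %in% usedArs) next
        cand <- proxIdx[arsOf == aid &
                          genes$orientation[proxIdx] %in% wanted]
        if (length(cand) == 0L) next
        sel <- c(sel, if (length(cand) == 1L) cand else sample(cand, 1L))
        usedArs <- c(usedArs, aid)
      }
      list(sel = sel, usedArs = usedArs)
    }
    ho <- pickPerArs("HO", nHO, character(0))
    cd <- pickPerArs("CD", nCD, ho$usedArs)
    if (length(ho$sel) < nHO || length(cd$sel) < nCD)
      stop(sprintf(paste0(
        "genome too small: need %d head-on and %d codirectional ",
        "origin-proximal gain genes on distinct origins, found %d and %d"),
        nHO, nCD, length(ho$sel), length(cd$sel)), call. = FALSE)
    sen1Idx <- c(ho$sel, cd$sel)
    # common gains (damage-active in the sen1-type track too) stay off
    # origin-proximal genes and >= 12 kb from every sen1-active anchor
    activeMids <- rangeMid(genes)[sen1Idx]
    activeChr <- as.character(seqnames(genes))[sen1Idx]
    farFromActive <- function(i) {
      same <- activeChr == as.character(seqnames(genes))[i]
      !any(abs(activeMids[same] - rangeMid(genes)[i]) < 12000)
    }
    commonIdx <- integer(0)
    for (i in sample(setdiff(which(!genes$arsProximal), sen1Idx))) {
      if (length(commonIdx) >= config@nGainCommon) break
      if (farFromActive(i)) {
        commonIdx <- c(commonIdx, i)
        activeMids <- c(activeMids, rangeMid(genes)[i])
        activeChr <- c(activeChr, as.character(seqnames(genes))[i])
      }
    }
    if (length(commonIdx) < config@nGainCommon)
      stop("genome too small: cannot space common gain regions away from sen1 anchors",
           call. = FALSE)
    rest <- setdiff(seq_along(genes), c(sen1Idx, commonIdx))
    if (length(rest) < config@nGainHpr1)
      stop("genome too small: not enough genes left for hpr1 gains",
           call. = FALSE)
    hpr1Idx <- sample(rest, config@nGainHpr1)
    gainIdx <- c(hpr1Idx, sen1Idx, commonIdx)
    gains <- granges(genes)[gainIdx]
    gains$label <- rep(c("hpr1-specific", "sen1-specific", "common"),
                       c(length(hpr1Idx), length(sen1Idx), length(commonIdx)))
    gains$geneId <- genes$geneId[gainIdx]
    gains$forkDirection <- genes$forkDirection[gainIdx]
    gains <- BiocGenerics::sort(gains, ignore.strand = TRUE)

    featMeta <- rbind(
      data.frame(featureId = genes$geneId, biotype = genes$biotype),
      data.frame(featureId = trna$featureId, biotype = trna$biotype),
      data.frame(featureId = sno$featureId, biotype = sno$biotype),
      data.frame(featureId = telomeres$featureId, biotype = telomeres$biotype))
    allFeat <- c(granges(genes), granges(trna), granges(sno), granges(telomeres))
    ord <- order(as.integer(seqnames(allFeat)), GenomicRanges::start(allFeat))
    features <- allFeat[ord]
    features$featureId <- featMeta$featureId[ord]
    features$biotype <- featMeta$biotype[ord]

    new("RLoopTruth", seqinfo = si, genes = genes, features = features,
        ars = ars, gainRegions = gains, config = config)
  })
}

.gainActive <- function(label, condition, phase) {
  switch(condition,
    WT = rep(FALSE, length(label)),
    RNH = rep(FALSE, length(label)),
    hpr1 = label %in% c("hpr1-specific", "common"),
    sen1 = (label %in% c("sen1-specific", "common")) & phase == "S",
    stop(sprintf("unknown condition '%s'", condition), call. = FALSE))
}

#' Expected per-bin hybrid means of the DRIPc simulator
#'
#' The noiseless mean surface used by [simulateDripCounts()]: background
#' `muBg` everywhere; on a gene's sense strand an added hybrid term
#' `hybridScale * expression * ramp`, where the ramp rises linearly from
#' 0.5x to 1.5x along the gene 5'->3'; bins inside planted gain regions
#' active in the requested (condition, phase) are multiplied by `fGain`.
#'
#' @param truth an [RLoopTruth-class].
#' @param condition one of `"WT"`, `"hpr1"`, `"sen1"`, `"RNH"`.
#' @param phase `"G1"` or `"S"`.
#' @param binWidth bin width in bp (default: configured calling bin).
#' @return list with per-strand (`"+"`, `"-"`) named lists of per-chromosome
#'   mean vectors.
#' @export
dripExpectedMeans <- function(truth, condition, phase,
                              binWidth = truthConfigOf(truth)@callBin) {
  cfg <- truth@config
  stopIfNot(condition %in% c("WT", "hpr1", "sen1", "RNH"),
            sprintf("unknown condition '%s'", condition))
  stopIfNot(phase %in% c("G1", "S"), sprintf("unknown phase '%s'", phase))
  sl <- seqlengths(truth@seqinfo)
  mu <- list(`+` = lapply(sl, function(L) rep(cfg@muBg, ceiling(L / binWidth))),
             `-` = lapply(sl, function(L) rep(cfg@muBg, ceiling(L / binWidth))))
  if (condition != "RNH") {
    genes <- truth@genes
    for (i in seq_along(genes)) {
      chr <- as.character(seqnames(genes))[i]
      st <- GenomicRanges::start(genes)[i]; en <- GenomicRanges::end(genes)[i]
      sstr <- as.character(BiocGenerics::strand(genes))[i]
      b0 <- (st - 1L) %/% binWidth + 1L; b1 <- (en - 1L) %/% binWidth + 1L
      centers <- ((b0:b1) - 0.5) * binWidth
      inside <- centers >= st & centers <= en
      if (!any(inside)) next
      bidx <- (b0:b1)[inside]
      tpos <- (centers[inside] - st) / max(en - st, 1L)
      if (sstr == "-") tpos <- 1 - tpos
      ramp <- 0.5 + tpos
      mu[[sstr]][[chr]][bidx] <- mu[[sstr]][[chr]][bidx] +
        cfg@hybridScale * genes$expression[i] * ramp
    }
    gains <- truth@gainRegions
    active <- .gainActive(gains$label, condition, phase)
    for (i in which(active)) {
      chr <- as.character(seqnames(gains))[i]
      st <- GenomicRanges::start(gains)[i]; en <- GenomicRanges::end(gains)[i]
      sstr <- as.character(BiocGenerics::strand(gains))[i]
      b0 <- (st - 1L) %/% binWidth + 1L; b1 <- (en - 1L) %/% binWidth + 1L
      centers <- ((b0:b1) - 0.5) * binWidth
      bidx <- (b0:b1)[centers >= st & centers <= en]
      mu[[sstr]][[chr]][bidx] <- mu[[sstr]][[chr]][bidx] * cfg@fGain
    }
  }
  mu
}

#' Simulate stranded DRIPc-seq binned counts for one sample
#'
#' Draws negative-binomial counts (dispersion `alphaBg`) around the mean
#' surface of [dripExpectedMeans()]: background everywhere, 3'-ramped
#' gene-body hybrid signal on the sense strand, condition/phase-dependent
#' planted gains (hpr1-type in G1 and S; sen1-type in S only), and a
#' hybrid-free RNase-H control.  Deterministic given
#' `(truth, condition, phase, replicate, seed)`; different replicates share
#' the planted truth and differ only in noise.
#'
#' @inheritParams dripExpectedMeans
#' @param replicate replicate index (enters the derived RNG stream).
#' @param binWidth counting bin width in bp.
#' @param seed optional explicit seed; default derives one from the
#'   configuration seed, condition, phase and replicate.
#' @return a single-sample stranded [BinnedCounts-class] (`+` bins then
#'   `-` bins).
#' @export
simulateDripCounts <- function(truth, condition, phase, replicate = 1L,
                               binWidth = truthConfigOf(truth)@callBin,
                               seed = NULL) {
  cfg <- truth@config
  mu <- dripExpectedMeans(truth, condition, phase, binWidth)
  if (is.null(seed))
    seed <- deriveSeed(cfg@seed, "drip", condition, phase, replicate, binWidth)
  muVec <- c(unlist(mu[["+"]], use.names = FALSE),
             unlist(mu[["-"]], use.names = FALSE))
  cts <- withSeed(seed, stats::rnbinom(length(muVec), mu = muVec,
                                       size = 1 / cfg@alphaBg))
  bins <- genomeBins(truth@seqinfo, binWidth, stranded = TRUE)
  m <- matrix(as.integer(cts), ncol = 1,
              dimnames = list(NULL, sprintf("%s_%s_rep%d", condition, phase,
                                            replicate)))
  BinnedCounts(bins, m, librarySizes = sum(cts), binWidth = binWidth)
}

#' Sum binned counts into coarser bins
#'
#' Aggregates a genome-tiling [BinnedCounts-class] into bins `factor`
#' times wider (e.g. 50 bp calling bins into the 200 bp counting bins used
#' for normalization), per strand and chromosome.
#'
#' @param bc a genome-tiling `BinnedCounts`.
#' @param factor integer widening factor.
#' @return a `BinnedCounts` at `binWidth(bc) * factor`.
#' @export
rebinCounts <- function(bc, factor) {
  factor <- as.integer(factor)
  stopIfNot(factor >= 1L, "factor must be a positive integer")
  if (factor == 1L) return(bc)
  bw <- binWidth(bc)
  rr <- rowRanges(bc)
  grp <- paste(as.character(seqnames(rr)), as.character(BiocGenerics::strand(rr)),
               (GenomicRanges::start(rr) - 1L) %/% (bw * factor), sep = ":")
  grp <- factor(grp, levels = unique(grp))
  newCounts <- apply(counts(bc), 2, function(v) rowsum(v, grp)[, 1])
  first <- !duplicated(grp)
  newRanges <- GRanges(seqnames(rr)[first],
                       IRanges(GenomicRanges::start(rr)[first],
                               width = pmin(bw * factor,
                                 seqlengths(seqinfo(rr))[as.character(seqnames(rr)[first])] -
                                   GenomicRanges::start(rr)[first] + 1L)),
                       strand = BiocGenerics::strand(rr)[first],
                       seqinfo = seqinfo(rr))
  BinnedCounts(newRanges, newCounts, librarySizes = librarySizes(bc),
               binWidth = bw * factor)
}

#' Simulate an unstranded damage (H2A-P-like) coverage track
#'
#' Baseline negative-binomial noise everywhere; around each planted gain
#' region active in `condition`, Poisson damage counts totalling
#' `damageMass` spread with a Gaussian kernel of width `sigmaDam` around
#' the region midpoint, with a fraction of the mass placed downstream of
#' the local fork direction (away from the nearest origin): 0.5 for the
#' hpr1-type condition (symmetric), `aDam` for the sen1-type condition
#' (asymmetric).  `condition = "WT"` yields baseline only.
#'
#' @inheritParams dripExpectedMeans
#' @param seed optional explicit seed (default derived).
#' @param aDam override the downstream mass fraction (default: 0.5 for
#'   hpr1, configured `aDam` for sen1).
#' @return an unstranded raw [CoverageTrack-class] at the configured
#'   coverage bin width.
#' @export
simulateH2apTrack <- function(truth, condition, seed = NULL, aDam = NULL) {
  cfg <- truth@config
  stopIfNot(condition %in% c("WT", "hpr1", "sen1"),
            sprintf("unknown condition '%s'", condition))
  if (is.null(seed)) seed <- deriveSeed(cfg@seed, "h2ap", condition)
  bw <- cfg@covBin
  sl <- seqlengths(truth@seqinfo)
  withSeed(seed, {
    vals <- lapply(sl, function(L) {
      n <- ceiling(L / bw)
      as.numeric(stats::rnbinom(n, mu = cfg@h2apBaselineMean,
                                size = 1 / max(cfg@h2apBaselineDisp, 1e-8)))
    })
    if (condition != "WT") {
      a <- if (!is.null(aDam)) aDam else if (condition == "hpr1") 0.5 else cfg@aDam
      gains <- truth@gainRegions
      anchors <- gains[.gainActive(gains$label, condition, "S")]
      for (i in seq_along(anchors)) {
        chr <- as.character(seqnames(anchors))[i]
        mid <- rangeMid(anchors)[i]
        dirSign <- if (anchors$forkDirection[i] == "+") 1 else -1
        halfSpan <- ceiling(5 * cfg@sigmaDam / bw)
        centerBin <- (mid - 1L) %/% bw + 1L
        bidx <- max(1L, centerBin - halfSpan):min(length(vals[[chr]]),
                                                  centerBin + halfSpan)
        x <- (bidx - 0.5) * bw - mid
        side <- sign(x) * dirSign
        frac <- ifelse(side > 0, 2 * a, ifelse(side < 0, 2 * (1 - a), 1))
        w <- cfg@damageMass * stats::dnorm(x, 0, cfg@sigmaDam) * bw * frac
        vals[[chr]][bidx] <- vals[[chr]][bidx] + stats::rpois(length(w), w)
      }
    }
    tot <- sum(vapply(vals, sum, numeric(1)))
    CoverageTrack(vals, truth@seqinfo, bw, strand = "*",
                  normalization = "raw", totalReads = tot, uniqueReads = tot)
  })
}
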