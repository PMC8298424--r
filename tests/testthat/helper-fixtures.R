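suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(GenomeInfoDb)
})

# A compact configuration for unit tests: everything present, fast to run.
smallTruthConfig <- function(seed = 1L, ...) {
  truthConfig(seed = seed, nChrom = 2L, chromLength = 80000L, nGenes = 40L,
              telomereLength = 2000L, nEarlyArs = 6L,
              nGainHpr1 = 6L, nGainSen1 = 4L, nGainCommon = 3L, ...)
}

smallSeqinfo <- function(len = 10000L, chroms = "chrI") {
  Seqinfo(chroms, rep(len, length(chroms)))
}

randomIntervals <- function(n, len = 10000L, maxWidth = 500L,
                            stranded = FALSE) {
  s <- sample.int(len - maxWidth, n, replace = TRUE)
  w <- sample.int(maxWidth, n, replace = TRUE)
  GRanges("chrI", IRanges(s, width = w),
          strand = if (stranded) sample(c("+", "-"), n, TRUE) else "*",
          seqinfo = smallSeqinfo(len))
}

# --- independent brute-force oracles ----------------------------------

# per-bp union + gap closure: mark covered bp, close gaps < fuseDist
bfMergeFuse <- function(gr, fuseDist, len = 10000L) {
  cov <- logical(len)
  for (i in seq_along(gr))
    cov[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- TRUE
  r <- rle(cov)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  gap <- which(!r$values & r$lengths < fuseDist)
  gap <- gap[gap > 1 & gap < length(r$values)]
  for (j in gap) cov[starts[j]:ends[j]] <- TRUE
  r <- rle(cov)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  on <- which(r$values)
  GRanges("chrI", IRanges(starts[on], ends[on]))
}

bfOverlapPairs <- function(a, b) {
  out <- NULL
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (as.character(GenomicRanges::seqnames(a))[i] == as.character(GenomicRanges::seqnames(b))[j] &&
        GenomicRanges::start(a)[i] <= GenomicRanges::end(b)[j] && GenomicRanges::start(b)[j] <= GenomicRanges::end(a)[i])
      out <- rbind(out, c(i, j))
  }
  out
}

# all-pairs peak/feature annotation scan (overlap or < upstreamMax bp
# 5' of the feature on its strand)
bfAnnotate <- function(peaks, features, upstreamMax = 200) {
  out <- NULL
  for (i in seq_along(peaks)) for (j in seq_along(features)) {
    if (as.character(GenomicRanges::seqnames(peaks))[i] != as.character(GenomicRanges::seqnames(features))[j])
      next
    ov <- GenomicRanges::start(peaks)[i] <= GenomicRanges::end(features)[j] &&
      GenomicRanges::start(features)[j] <= GenomicRanges::end(peaks)[i]
    str <- as.character(BiocGenerics::strand(features))[j]
    up <- FALSE
    if (str == "+") {
      winS <- GenomicRanges::start(features)[j] - upstreamMax; winE <- GenomicRanges::start(features)[j] - 1
      up <- winE >= winS && GenomicRanges::start(peaks)[i] <= winE && winS <= GenomicRanges::end(peaks)[i]
    } else if (str == "-") {
      winS <- GenomicRanges::end(features)[j] + 1; winE <- GenomicRanges::end(features)[j] + upstreamMax
      up <- GenomicRanges::start(peaks)[i] <= winE && winS <= GenomicRanges::end(peaks)[i]
    }
    if (ov || up)
      out <- rbind(out, data.frame(peak = i, feature = j,
                                   relation = if (ov) "overlap" else "upstream"))
  }
  out
}

# all-pairs minimum gap distance gene x origin midpoint
bfArsProximal <- function(genes, ars, maxDist = 1000) {
  keep <- integer(0); nearest <- integer(0)
  for (i in seq_along(genes)) {
    best <- Inf; bestJ <- NA_integer_
    for (j in seq_along(ars)) {
      if (as.character(GenomicRanges::seqnames(genes))[i] != as.character(GenomicRanges::seqnames(ars))[j])
        next
      m <- GenomicRanges::start(ars)[j]
      d <- if (m >= GenomicRanges::start(genes)[i] && m <= GenomicRanges::end(genes)[i]) 0
           else if (m > GenomicRanges::end(genes)[i]) m - GenomicRanges::end(genes)[i] - 1
           else GenomicRanges::start(genes)[i] - m - 1
      if (d < best || (d == best && !is.na(bestJ) && m < GenomicRanges::start(ars)[bestJ])) {
        best <- d; bestJ <- j
      }
    }
    if (is.finite(best) && best < maxDist) {
      keep <- c(keep, i); nearest <- c(nearest, bestJ)
    }
  }
  list(keep = keep, nearest = nearest)
}

constantTrack <- function(value, len = 10000L, bw = 10L, chroms = "chrI") {
  si <- smallSeqinfo(len, chroms)
  CoverageTrack(setNames(lapply(chroms, function(x) rep(value, len / bw)),
                         chroms), si, bw)
}
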