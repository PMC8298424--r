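#' Read a BED file of intervals
#'
#' Reads 3- to 6-column BED (0-based, half-open on disk) into a 1-based
#' closed [GenomicRanges::GRanges].  A missing strand column yields `"*"`.
#' Coordinate violations are rejected, never repaired: a malformed line or
#' a line with `start >= end` raises an error naming the line number.
#'
#' @param path path to a tab-separated BED file.
#' @param seqinfo optional [GenomeInfoDb::Seqinfo] to attach and validate
#'   against.
#' @return `GRanges` with optional mcols `name` and `score`.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chrI\t100\t200\tp1\t0\t+", f)
#' readBed(f)
#' @export
readBed <- function(path, seqinfo = NULL) {
  stopIfNot(file.exists(path), sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(GRanges(seqinfo = seqinfo))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("malformed BED line %d: fewer than 3 tab-separated columns",
                 which(nf < 3L)[1]), call. = FALSE)
  chrom <- vapply(fields, `[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  bad <- which(is.na(start0) | is.na(end0) | start0 != round(start0) |
                 end0 != round(end0) | start0 < 0)
  if (length(bad))
    stop(sprintf("malformed BED line %d: non-integer or negative coordinates",
                 bad[1]), call. = FALSE)
  rev <- which(start0 >= end0)
  if (length(rev))
    stop(sprintf("malformed BED line %d: start >= end", rev[1]), call. = FALSE)
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))],
                                  character(1)), NA_character_)
  score <- ifelse(nf >= 5L,
                  suppressWarnings(as.numeric(
                    vapply(fields, function(f) f[min(5L, length(f))],
                           character(1)))), NA_real_)
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))],
                                    character(1)), ".")
  okStrand <- strand %in% c("+", "-", ".")
  if (!all(okStrand))
    stop(sprintf("malformed BED line %d: unknown strand symbol '%s'",
                 which(!okStrand)[1], strand[!okStrand][1]), call. = FALSE)
  strand[strand == "."] <- "*"
  gr <- GRanges(chrom, IRanges(start0 + 1, end0), strand = strand)
  if (any(nf >= 4L)) gr$name <- name
  if (any(nf >= 5L)) gr$score <- score
  if (!is.null(seqinfo)) {
    unknown <- setdiff(unique(chrom), seqlevels(seqinfo))
    stopIfNot(length(unknown) == 0L,
              sprintf("unknown chromosome in BED: %s", unknown[1]))
    GenomeInfoDb::seqlevels(gr) <- seqlevels(seqinfo)
    GenomeInfoDb::seqinfo(gr) <- seqinfo
  }
  gr
}

#' Write intervals as 6-column BED
#'
#' Inverse of [readBed()]: emits 0-based half-open coordinates with `name`
#' (or `.`), `score` (or `0`) and strand (`*` becomes `.`).
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  name <- if (!is.null(gr$name)) gr$name else rep(".", length(gr))
  score <- if (!is.null(gr$score)) gr$score else rep(0, length(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   as.character(seqnames(gr)),
                   GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                   name, vapply(score, format, character(1), scientific = FALSE),
                   strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene features from GFF3
#'
#' Imports a GFF3 file via [rtracklayer::import()] (1-based inclusive
#' coordinates, the native GRanges convention) and returns feature ranges
#' whose biotype is taken from the GFF3 type column (`gene`, `tRNA_gene`,
#' `snoRNA_gene`, ...).  Coordinates below 1 are rejected.
#'
#' @param path path to a GFF3 file.
#' @param types GFF3 type values to keep; `NULL` keeps all.
#' @return `GRanges` with mcols `biotype` and, when present, `featureId`
#'   (from the `ID` attribute).
#' @export
readGff3Genes <- function(path, types = NULL) {
  stopIfNot(file.exists(path), sprintf("GFF3 file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) {
    out <- GRanges()
    out$biotype <- character(0)
    return(out)
  }
  stopIfNot(all(GenomicRanges::start(gr) >= 1L),
            "GFF3 coordinates must be >= 1 (1-based inclusive)")
  if (!is.null(types)) gr <- gr[as.character(gr$type) %in% types]
  out <- granges(gr)
  out$biotype <- as.character(gr$type)
  if (!is.null(gr$ID)) out$featureId <- as.character(gr$ID)
  out
}

#' Read a bedGraph file into a CoverageTrack
#'
#' Intervals must align exactly to the bin grid implied by `binWidth`
#' (no silent resampling); uncovered bins are zero.  Unknown chromosomes
#' and off-grid intervals are errors.
#'
#' @param path bedGraph path (0-based half-open on disk).
#' @param seqinfo genome description; defines chromosomes and lengths.
#' @param binWidth bin width in bp.
#' @param strand strand tag for the resulting track.
#' @return a [CoverageTrack-class].
#' @export
readBedGraph <- function(path, seqinfo, binWidth, strand = "*") {
  stopIfNot(file.exists(path), sprintf("bedGraph file not found: %s", path))
  binWidth <- as.integer(binWidth)
  sl <- seqlengths(seqinfo)
  vals <- lapply(sl, function(L) numeric(ceiling(L / binWidth)))
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) > 0L) {
    chrom <- as.character(seqnames(gr))
    unknown <- setdiff(unique(chrom), names(sl))
    stopIfNot(length(unknown) == 0L,
              sprintf("unknown chromosome in bedGraph: %s", unknown[1]))
    s0 <- GenomicRanges::start(gr) - 1L   # back to 0-based
    e0 <- GenomicRanges::end(gr)
    onGrid <- (s0 %% binWidth == 0L) &
      (e0 %% binWidth == 0L | e0 == sl[chrom])
    stopIfNot(all(onGrid),
              sprintf("bedGraph interval off the %d bp bin grid at %s:%d-%d",
                      binWidth, chrom[!onGrid][1], s0[!onGrid][1], e0[!onGrid][1]))
    for (i in seq_along(gr)) {
      b0 <- s0[i] %/% binWidth + 1L
      b1 <- ceiling(e0[i] / binWidth)
      vals[[chrom[i]]][b0:b1] <- gr$score[i]
    }
  }
  CoverageTrack(vals, seqinfo, binWidth, strand = strand)
}

#' Write a CoverageTrack as bedGraph
#'
#' Emits one line per nonzero bin (0-based half-open); zero bins are
#' implicit.
#'
#' @param track a [CoverageTrack-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, path) {
  bw <- binWidth(track)
  sl <- seqlengths(seqinfo(track))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chr in names(trackValues(track))) {
    v <- trackValues(track)[[chr]]
    nz <- which(v != 0)
    if (length(nz) == 0L) next
    s0 <- (nz - 1L) * bw
    e0 <- pmin(nz * bw, sl[[chr]])
    writeLines(sprintf("%s\t%d\t%d\t%s", chr, s0, e0,
                       vapply(v[nz], format, character(1), scientific = FALSE)),
               con)
  }
  invisible(path)
}
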