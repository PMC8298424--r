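# End-to-end orchestration: simulate -> call peaks -> differential ->
# specific/common classification -> phase categories -> annotation ->
# damage metaprofiles + asymmetry -> orientation conflicts -> report.

#' Pipeline run configuration
#'
#' Aggregates the synthetic-truth configuration with every analysis
#' threshold: peak fusion distance (200 bp, strict), minimum peak length
#' (100 bp), maximum-posterior cutoff (0.99999), S-phase enrichment
#' thresholds (FC > 1.2, -log10 p > 0.6), G1 thresholds (FC > 2,
#' -log10 p > 1), upstream annotation window (200 bp), origin proximity
#' (1 kb), and the metaprofile flank / asymmetry core settings.
#'
#' @slot truth a [TruthConfig-class].
#' @slot fuseDist,minPeakLength,posteriorCutoff,upstreamMax,arsMaxDist,metaplotFlank,aiCoreExclusion
#'   numeric thresholds, see above.
#' @slot verbose emit per-stage messages?
#' @exportClass RunConfig
setClass("RunConfig",
  representation(truth = "TruthConfig",
                 fuseDist = "numeric", minPeakLength = "numeric",
                 posteriorCutoff = "numeric",
                 upstreamMax = "numeric", arsMaxDist = "numeric",
                 metaplotFlank = "numeric", aiCoreExclusion = "numeric",
                 verbose = "logical")
)

setValidity("RunConfig", function(object) {
  thr <- c(object@fuseDist, object@minPeakLength, object@posteriorCutoff,
           object@upstreamMax, object@arsMaxDist, object@metaplotFlank,
           object@aiCoreExclusion)
  if (any(thr <= 0)) "every threshold must be positive" else TRUE
})

#' @rdname RunConfig-class
#' @param truth a [TruthConfig-class] (carries the seed).
#' @param fuseDist,minPeakLength,posteriorCutoff,upstreamMax,arsMaxDist,metaplotFlank,aiCoreExclusion
#'   thresholds, see [RunConfig-class].
#' @param verbose emit per-stage messages?
#' @export
runConfig <- function(truth = truthConfig(),
                      fuseDist = 200, minPeakLength = 100,
                      posteriorCutoff = 0.99999,
                      upstreamMax = 200, arsMaxDist = 1000,
                      metaplotFlank = 5000, aiCoreExclusion = 500,
                      verbose = FALSE) {
  new("RunConfig", truth = truth, fuseDist = fuseDist,
      minPeakLength = minPeakLength, posteriorCutoff = posteriorCutoff,
      upstreamMax = upstreamMax, arsMaxDist = arsMaxDist,
      metaplotFlank = metaplotFlank, aiCoreExclusion = aiCoreExclusion,
      verbose = verbose)
}

#' Serialise a RunConfig to a plain list (and back)
#'
#' `configAsList()` flattens every field to base types; `runConfigFromList()`
#' reconstructs an identical configuration, so configurations round-trip
#' through JSON/YAML unchanged.  `configHash()` is an md5 digest of the
#' canonical serialisation: it changes iff some field changes.
#'
#' @param config a [RunConfig-class].
#' @return `configAsList`: named list; `configHash`: md5 string.
#' @export
configAsList <- function(config) {
  tc <- config@truth
  truthFields <- slotNames(tc)
  truth <- stats::setNames(lapply(truthFields, function(s) slot(tc, s)),
                           truthFields)
  runFields <- setdiff(slotNames(config), "truth")
  run <- stats::setNames(lapply(runFields, function(s) slot(config, s)),
                         runFields)
  c(list(truth = truth), run)
}

#' @rdname configAsList
#' @param x a list produced by `configAsList()`.
#' @export
runConfigFromList <- function(x) {
  truth <- do.call(truthConfig, x$truth)
  do.call(runConfig, c(list(truth = truth), x[setdiff(names(x), "truth")]))
}

#' @rdname configAsList
#' @export
configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(configAsList(config), auto_unbox = TRUE,
                              digits = NA), tf)
  unname(tools::md5sum(tf))
}

.stageMsg <- function(verbose, ...) if (verbose) message("[RLoopCycle] ", ...)

#' Run the full synthetic analysis pipeline
#'
#' Generates the synthetic truth, simulates stranded hybrid counts for
#' wild type and both depletion conditions in G1 and S phase, calls
#' consensus HMM peaks per condition, tests mutant-versus-wild-type
#' differential enrichment per phase (TMM factors on genome-wide 200 bp
#' bins), classifies S-phase gains as mutant-specific or common, derives
#' G1/S overlap categories, annotates gains to features, measures damage
#' asymmetry around mutant-specific regions on wild-type-subtracted
#' damage tracks (fork-oriented), and tabulates head-on versus
#' codirectional gain percentages with the one-sided chi-square test.
#' Fully deterministic given the configuration (all randomness derives
#' from the truth seed).
#'
#' @param config a [RunConfig-class].
#' @param outDir optional directory for TSV/BED outputs and the report.
#' @return a list report bundle; see the components in the source and the
#'   methods vignette.
#' @export
runPipeline <- function(config = runConfig(), outDir = NULL) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  cfg <- config@truth
  vb <- config@verbose
  conditions <- c("WT", "hpr1", "sen1")
  phases <- c("G1", "S")

  .stageMsg(vb, "annotation: generating synthetic genome and truth")
  truth <- generateAnnotation(cfg)

  .stageMsg(vb, "simulate: stranded hybrid counts (",
            length(conditions) * length(phases) * cfg@nReplicates, " samples)")
  simCounts <- lapply(stats::setNames(phases, phases), function(ph)
    lapply(stats::setNames(conditions, conditions), function(cd)
      lapply(seq_len(cfg@nReplicates), function(r)
        simulateDripCounts(truth, cd, ph, replicate = r))))

  .stageMsg(vb, "peaks: NB-HMM consensus calling per condition/phase")
  peaks <- lapply(simCounts, function(byCond)
    lapply(byCond, function(reps)
      callConditionPeaks(reps, cutoff = config@posteriorCutoff,
                         minLength = config@minPeakLength)))

  .stageMsg(vb, "differential: mutant vs WT per phase")
  gains <- list(); diffs <- list()
  for (ph in phases) {
    gains[[ph]] <- list(); diffs[[ph]] <- list()
    for (mut in c("hpr1", "sen1")) {
      bc <- do.call(SummarizedExperiment::cbind,
                    c(simCounts[[ph]][["WT"]], simCounts[[ph]][[mut]]))
      grp <- rep(c("WT", mut), each = cfg@nReplicates)
      fac <- tmmFactors(rebinCounts(bc, cfg@countBin %/% cfg@callBin))
      regions <- mergeAndFuse(
        suppressWarnings(c(granges(peaks[[ph]][["WT"]]),
                           granges(peaks[[ph]][[mut]]))),
        config@fuseDist)
      res <- if (length(regions)) testRegions(regions, bc, grp, fac)
             else GRanges()
      diffs[[ph]][[mut]] <- res
      gains[[ph]][[mut]] <- if (length(res)) enrichedRegions(res, ph)
                            else GRanges()
    }
  }

  .stageMsg(vb, "classification: hpr1-specific / sen1-specific / common (S)")
  bcS <- do.call(SummarizedExperiment::cbind,
                 c(simCounts[["S"]][["sen1"]], simCounts[["S"]][["hpr1"]]))
  grpS <- rep(c("sen1", "hpr1"), each = cfg@nReplicates)
  facS <- tmmFactors(rebinCounts(bcS, cfg@countBin %/% cfg@callBin))
  classes <- classifySpecificCommon(gains[["S"]][["hpr1"]],
                                    gains[["S"]][["sen1"]],
                                    bcS, grpS, facS, phase = "S",
                                    fuseDist = config@fuseDist)

  .stageMsg(vb, "phase categories: G1 vs S overlap per mutant")
  phaseCats <- lapply(stats::setNames(c("hpr1", "sen1"), c("hpr1", "sen1")),
                      function(mut)
    phaseOverlapCategories(gains[["G1"]][[mut]], gains[["S"]][[mut]]))

  .stageMsg(vb, "annotation of gains and gene properties")
  features <- truthFeatures(truth)
  genes <- truthGenes(truth)
  expr <- stats::setNames(genes$expression, genes$geneId)
  annotation <- list(); geneProps <- list()
  for (mut in c("hpr1", "sen1")) {
    g <- gains[["S"]][[mut]]
    if (length(g)) {
      ann <- annotatePeaks(g, features, upstreamMax = config@upstreamMax)
      annotation[[mut]] <- featureClassFractions(ann)
      gGenes <- genes[IRanges::overlapsAny(genes, g, ignore.strand = TRUE)]
      if (length(gGenes))
        geneProps[[mut]] <- compareGeneProperties(gGenes, genes, expr)
    }
  }

  .stageMsg(vb, "metaprofiles: damage asymmetry around specific regions")
  wtDamage <- simulateH2apTrack(truth, "WT")
  asymmetry <- list()
  for (mut in c("hpr1", "sen1")) {
    anchors <- classes[!is.null(classes$class) &
                         classes$class == paste0(mut, "-specific")]
    if (length(classes) == 0L || length(anchors) < 3L) {
      asymmetry[[mut]] <- NULL
      next
    }
    damage <- subtractWt(simulateH2apTrack(truth, mut), wtDamage)
    mm <- metaplotReferencePoint(damage, anchors,
                                 flankBp = config@metaplotFlank,
                                 nBins = 100L, orientBy = "fork",
                                 ars = truthArs(truth))
    asymmetry[[mut]] <- asymmetryIndex(mm, config@aiCoreExclusion,
                                       seed = deriveSeed(cfg@seed, "boot", mut))
  }

  .stageMsg(vb, "conflicts: head-on vs codirectional gain percentages")
  prox <- arsProximalGenes(genes, truthArs(truth), maxDist = config@arsMaxDist)
  orientation <- list()
  for (cl in c("hpr1-specific", "sen1-specific", "common")) {
    if (length(classes) == 0L) break
    regions <- classes[classes$class == cl]
    if (length(regions) == 0L) next
    tab <- orientationGainTable(prox, regions)
    chi <- tryCatch(chiSquare2x2(tab$table, alternative = "greater"),
                    error = function(e) list(statistic = NA_real_,
                                             pvalue = NA_real_))
    orientation[[cl]] <- list(table = tab$table,
                              percentages = tab$percentages,
                              statistic = chi$statistic,
                              pvalue = chi$pvalue)
  }

  peakCounts <- vapply(phases, function(ph)
    vapply(conditions, function(cd) length(peaks[[ph]][[cd]]), integer(1)),
    integer(length(conditions)))
  gainCounts <- vapply(phases, function(ph)
    c(hpr1 = length(gains[[ph]][["hpr1"]]), sen1 = length(gains[[ph]][["sen1"]])),
    numeric(2))
  enrichmentFold <- vapply(phases, function(ph)
    c(hpr1 = length(gains[[ph]][["hpr1"]]) / max(1L, length(peaks[[ph]][["WT"]])),
      sen1 = length(gains[[ph]][["sen1"]]) / max(1L, length(peaks[[ph]][["WT"]]))),
    numeric(2))

  result <- list(
    config = config, configHash = configHash(config), seed = cfg@seed,
    truth = truth, counts = simCounts, peaks = peaks, differential = diffs,
    gains = gains, classes = classes, phaseCategories = phaseCats,
    annotation = annotation, geneProperties = geneProps,
    asymmetry = asymmetry, orientation = orientation,
    peakCounts = peakCounts, gainCounts = gainCounts,
    enrichmentFold = enrichmentFold)
  if (!is.null(outDir)) writePipelineOutputs(result, outDir)
  result
}

#' Write pipeline stage outputs as plain-text files
#'
#' Emits per-condition peak BEDs, per-phase differential TSVs, the class
#' and phase-category TSVs and the markdown report into `outDir`.
#' Re-running with the same configuration reproduces every file
#' byte-identically.
#'
#' @param result a [runPipeline()] bundle.
#' @param outDir output directory (created if missing).
#' @return `outDir`, invisibly.
#' @export
writePipelineOutputs <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  grToDf <- function(gr) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start0 = GenomicRanges::start(gr) - 1L,
                     end0 = GenomicRanges::end(gr),
                     strand = as.character(BiocGenerics::strand(gr)))
    cbind(df, as.data.frame(S4Vectors::mcols(gr)))
  }
  for (ph in names(result$peaks))
    for (cd in names(result$peaks[[ph]]))
      writeBed(result$peaks[[ph]][[cd]],
               file.path(outDir, sprintf("peaks_%s_%s.bed", cd, ph)))
  for (ph in names(result$differential))
    for (mut in names(result$differential[[ph]])) {
      res <- result$differential[[ph]][[mut]]
      if (length(res))
        utils::write.table(grToDf(res),
                           file.path(outDir, sprintf("diff_%s_%s.tsv", mut, ph)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  if (length(result$classes))
    utils::write.table(grToDf(result$classes),
                       file.path(outDir, "classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (mut in names(result$phaseCategories)) {
    pc <- result$phaseCategories[[mut]]
    if (length(pc))
      utils::write.table(grToDf(pc),
                         file.path(outDir, sprintf("phase_categories_%s.tsv", mut)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(pipelineReport(result), file.path(outDir, "report.md"))
  invisible(outDir)
}

#' Render a pipeline report
#'
#' Human-readable markdown summary of every stage: peak counts,
#' enrichment folds over wild type, class and phase-category counts,
#' annotation fractions, asymmetry summaries and orientation tables, with
#' provenance (configuration hash and seed).  Renders zeros, never
#' crashes, on empty stages.
#'
#' @param result a [runPipeline()] bundle.
#' @return character vector of markdown lines.
#' @export
pipelineReport <- function(result) {
  ln <- c("# R-loop / damage landscape pipeline report", "",
          sprintf("- config hash: `%s`", result$configHash),
          sprintf("- seed: %d", result$seed), "",
          "## Consensus peak counts (condition x phase)", "")
  pc <- result$peakCounts
  ln <- c(ln, paste0("| condition | ", paste(colnames(pc), collapse = " | "), " |"),
          paste0("|---|", paste(rep("---|", ncol(pc)), collapse = "")))
  for (cd in rownames(pc))
    ln <- c(ln, paste0("| ", cd, " | ", paste(pc[cd, ], collapse = " | "), " |"))
  ln <- c(ln, "", "## R-loop-gain regions (enriched over WT)", "")
  gc <- result$gainCounts
  for (ph in colnames(gc))
    for (mut in rownames(gc))
      ln <- c(ln, sprintf("- %s, %s phase: %d gain regions (%.2f per WT peak)",
                          mut, ph, as.integer(gc[mut, ph]),
                          result$enrichmentFold[mut, ph]))
  ln <- c(ln, "", "## Specific / common classification (S phase)", "")
  if (length(result$classes)) {
    tab <- table(result$classes$class)
    for (cl in names(tab)) ln <- c(ln, sprintf("- %s: %d", cl, tab[[cl]]))
  } else ln <- c(ln, "- no classified regions")
  ln <- c(ln, "", "## G1/S overlap categories", "")
  for (mut in names(result$phaseCategories)) {
    pcats <- result$phaseCategories[[mut]]
    if (length(pcats)) {
      tab <- table(pcats$category)
      ln <- c(ln, sprintf("- %s: %s", mut,
                          paste(sprintf("%s = %d", names(tab), as.integer(tab)),
                                collapse = ", ")))
    } else ln <- c(ln, sprintf("- %s: none", mut))
  }
  ln <- c(ln, "", "## Damage asymmetry (fork-oriented AI)", "")
  for (mut in names(result$asymmetry)) {
    ai <- result$asymmetry[[mut]]
    if (!is.null(ai))
      ln <- c(ln, sprintf("- %s: mean AI %.3f [95%% CI %.3f, %.3f], n = %d",
                          mut, ai@mean, ai@ciLower, ai@ciUpper, length(ai@ai)))
  }
  ln <- c(ln, "", "## Head-on vs codirectional gain percentages", "")
  for (cl in names(result$orientation)) {
    o <- result$orientation[[cl]]
    ln <- c(ln, sprintf(
      "- %s: HO %.1f%%, CD %.1f%% (chi-square %.2f, one-sided p %.3g)",
      cl, o$percentages[["HO"]], o$percentages[["CD"]],
      o$statistic, o$pvalue))
  }
  ln
}
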