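# End-to-end orchestration: the dynamics and NDR pipelines and routine
# group-comparison statistics.  Sex chromosomes are dropped at this
# level by default (the conventional autosome-only analysis choice);
# the data model underneath retains them.

#' Run the peak-dynamics pipeline
#'
#' Chains [splitDeNovo()] (against the premeiotic stages by default) ->
#' [hotspotAssociated()] -> [buildPresenceMatrix()] over L/mZ/lZ/e1P ->
#' [classifyDynamics()] and summarizes.  Also reports the
#' hotspot-associated leptotene count and how many of those leptotene
#' peaks persist to early 1-pachytene, which are related to but not
#' defined by the early-forming class, so all three are reported
#' side by side.
#'
#' @param stageSeries Named list of [PeakSet-class], keyed by stage;
#'   must contain the target and the classification stages L, mZ, lZ,
#'   e1P.
#' @param hotspots `GRanges` of DSB hotspots.
#' @param layout [GenomeLayout-class].
#' @param targetStage Reference stage (default `"mZ"`).
#' @param priorStages Stages defining "de novo" (default: the
#'   premeiotic stages present in the series).
#' @param autosomesOnly Drop sex-chromosome peaks first (default TRUE).
#' @param minBp Overlap threshold in bp.
#' @return List: `deNovoCount`, `commonCount`, `hotspotAssociatedCount`,
#'   `classCounts`, `labels`, `reference` (the labeled [PeakSet-class]),
#'   `report` (full [dynamicsReport()]), `leptoteneHotspotCount`,
#'   `leptotenePersistingCount`.
#' @export
runDynamics <- function(stageSeries, hotspots, layout,
                        targetStage = "mZ", priorStages = NULL,
                        autosomesOnly = TRUE, minBp = 1L) {
  if (is.null(priorStages))
    priorStages <- intersect(c("Undiff", "A1", "B", "mpL"),
                             names(stageSeries))
  if (autosomesOnly) {
    stageSeries <- lapply(stageSeries, autosomalOnly, layout = layout)
    hotspots <- autosomalOnly(.gr(hotspots), layout)
  }
  sp <- splitDeNovo(stageSeries, targetStage, priorStages, minBp)
  hsAssoc <- hotspotAssociated(sp$deNovo, hotspots, minBp)
  clStages <- c("L", "mZ", "lZ", "e1P")
  if (!all(clStages %in% names(stageSeries))) {
    message("classification stages not all present; dynamics step skipped")
    return(list(deNovoCount = length(sp$deNovo),
                commonCount = length(sp$common),
                hotspotAssociatedCount = length(hsAssoc),
                classCounts = NULL, labels = NULL, reference = hsAssoc))
  }
  pm <- buildPresenceMatrix(hsAssoc, stageSeries, clStages, minBp)
  labels <- classifyDynamics(pm)
  rep <- dynamicsReport(hsAssoc, labels)
  # leptotene-side quantities, reported separately from the class counts
  lDeNovo <- splitDeNovo(stageSeries, "L",
                         intersect(priorStages, names(stageSeries)), minBp)
  lAssoc <- hotspotAssociated(lDeNovo$deNovo, hotspots, minBp)
  lPersist <- if (length(lAssoc))
    sum(overlapsAny(peakRanges(lAssoc),
                    peakRanges(stageSeries[["lZ"]]), minoverlap = minBp) &
        overlapsAny(peakRanges(lAssoc),
                    peakRanges(stageSeries[["e1P"]]), minoverlap = minBp))
  else 0L
  list(deNovoCount = length(sp$deNovo), commonCount = length(sp$common),
       hotspotAssociatedCount = length(hsAssoc),
       classCounts = rep$counts, labels = labels, reference = hsAssoc,
       report = rep,
       leptoteneHotspotCount = length(lAssoc),
       leptotenePersistingCount = lPersist)
}

#' Run the NDR pipeline
#'
#' Chains [filterDepth()] -> [callNdrs()] -> [classifyNdr()] ->
#' [hotspotNdrPartition()] -> [accessibilityRatio()] of the hotspots.
#'
#' @param nome A [CytosineTable-class] (filtered here if not already).
#' @param layout [GenomeLayout-class].
#' @param tss `GRanges` of TSS (missing/empty: NDRs left distal with a
#'   warning).
#' @param hotspots `GRanges` of DSB hotspots.
#' @param depthCutoff Per-site depth cutoff (default 3).
#' @param ... Passed to [callNdrs()] (pMax, minSites, minLen, win,
#'   step).
#' @return List: `ndrs` (classified `GRanges`), `nNdr`, `nProximal`,
#'   `nDistal`, `partition` (hotspot split), `fracHotspotsInNdr`,
#'   `accessibilityRatios` (per hotspot), `medianAccessibilityRatio`.
#' @export
runNdr <- function(nome, layout, tss, hotspots, depthCutoff = 3L, ...) {
  if (!isTRUE(nome@depthFiltered)) nome <- filterDepth(nome, depthCutoff)
  ndrs <- callNdrs(nome, layout, ...)
  ndrs <- classifyNdr(ndrs, tss)
  part <- hotspotNdrPartition(hotspots, ndrs)
  ratios <- accessibilityRatio(.gr(hotspots), nome)
  list(ndrs = ndrs, nNdr = length(ndrs),
       nProximal = sum(mcols(ndrs)$class == "proximal"),
       nDistal = sum(mcols(ndrs)$class == "distal"),
       partition = part, fracHotspotsInNdr = part$fracWithin,
       accessibilityRatios = ratios,
       medianAccessibilityRatio = median(ratios, na.rm = TRUE))
}

#' Routine two-group or 2x2 comparison
#'
#' `t_test` performs Welch's unpaired two-sample t-test on the first
#' two groups (two-tailed by default), the convention for comparing
#' peak widths between turnover classes; `fisher` expects a 2x2 count
#' table.
#'
#' @param values For `t_test`: list of >= 2 numeric vectors (first two
#'   compared).  For `fisher`: a 2x2 matrix.
#' @param test `"t_test"` or `"fisher"`.
#' @param alternative Passed to the underlying test.
#' @return List with `statistic` (t or odds ratio), `pValue`.
#' @export
compareGroups <- function(values, test = c("t_test", "fisher"),
                          alternative = "two.sided") {
  test <- match.arg(test)
  if (test == "t_test") {
    if (!is.list(values) || length(values) < 2)
      stop("t_test needs a list of at least two groups")
    if (any(lengths(values[1:2]) < 2))
      stop("each compared group needs at least two values")
    if (sd(values[[1]]) == 0 && sd(values[[2]]) == 0)
      return(list(statistic = NA_real_, pValue = NA_real_,
                  note = "degenerate: both groups have zero variance"))
    tt <- t.test(values[[1]], values[[2]], alternative = alternative)
    list(statistic = unname(tt$statistic), pValue = tt$p.value)
  } else {
    if (!is.matrix(values) || !all(dim(values) == c(2, 2)))
      stop("fisher needs a 2x2 matrix")
    ft <- fisher.test(values, alternative = alternative)
    list(statistic = unname(ft$estimate), pValue = ft$p.value)
  }
}
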