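# Stage-comparative peak classification: de novo vs common peaks,
# hotspot association, the four-class turnover taxonomy, H3K9me2 dips
# and spatial overlap testing.

.gr <- function(x) if (is(x, "PeakSet")) x@ranges else x

#' Split a stage's peaks into de novo and common
#'
#' A peak is de novo at the target stage when it overlaps (by at least
#' `minBp` bases) no peak of the same mark at any of the prior stages;
#' all remaining peaks are common.  The prior list defaults to every
#' stage in the series strictly earlier than the target.  For
#' PRDM9-mediated H3K4me3 the conventional prior list is the premeiotic
#' stages only (see [runDynamics()]), so that peaks first appearing in
#' leptotene remain de novo at mid-zygotene.
#'
#' @param stageSeries Named list of [PeakSet-class], keyed by stage.
#' @param targetStage Stage whose peaks are partitioned.
#' @param priorStages Stages to compare against; must all be strictly
#'   earlier than `targetStage`.
#' @param minBp Minimum overlap in bp (default 1).
#' @return List with elements `deNovo` and `common`, both [PeakSet-class].
#' @export
splitDeNovo <- function(stageSeries, targetStage, priorStages = NULL,
                        minBp = 1L) {
  if (!targetStage %in% names(stageSeries))
    stop("target stage '", targetStage, "' missing from series")
  if (is.null(priorStages))
    priorStages <- names(stageSeries)[
      stageRank(names(stageSeries)) < stageRank(targetStage)]
  if (any(stageRank(priorStages) >= stageRank(targetStage)))
    stop("prior stages must be strictly earlier than the target stage")
  missing <- setdiff(priorStages, names(stageSeries))
  if (length(missing))
    stop("prior stage(s) missing from series: ", paste(missing, collapse = ", "))
  target <- stageSeries[[targetStage]]
  prior <- lapply(stageSeries[priorStages], .gr)
  gr <- .gr(target)
  seen <- rep(FALSE, length(gr))
  for (p in prior)
    if (length(p)) seen <- seen | overlapsAny(gr, p, minoverlap = minBp)
  list(deNovo = peakSet(gr[!seen], target@mark, target@stage),
       common = peakSet(gr[seen], target@mark, target@stage))
}

#' Subset peaks to those overlapping DSB hotspots
#'
#' @param peaks [PeakSet-class] or `GRanges`.
#' @param hotspots `GRanges` (or [PeakSet-class]) of DSB hotspots
#'   (SPO11-oligo clusters or DMC1-ssDNA peaks).
#' @param minBp Minimum overlap in bp.
#' @return Object of the same class as `peaks`, restricted to
#'   hotspot-overlapping peaks, with a metadata column `hotspotIds`
#'   (comma-separated indices of the overlapped hotspots).
#' @export
hotspotAssociated <- function(peaks, hotspots, minBp = 1L) {
  gr <- .gr(peaks)
  hs <- .gr(hotspots)
  if (!length(hs)) {
    warning("empty hotspot set: no peak is hotspot-associated")
    keep <- logical(length(gr))
  } else keep <- overlapsAny(gr, hs, minoverlap = minBp)
  out <- gr[keep]
  if (length(hs)) {
    ov <- findOverlaps(out, hs, minoverlap = minBp)
    ids <- vapply(split(subjectHits(ov), factor(queryHits(ov),
                                                levels = seq_along(out))),
                  function(i) paste(i, collapse = ","), "")
    mcols(out)$hotspotIds <- unname(ids)
  }
  if (is(peaks, "PeakSet")) peakSet(out, peaks@mark, peaks@stage) else out
}

#' Build a presence matrix of reference peaks across ordered stages
#'
#' Row i, column s is TRUE when reference peak i overlaps (>= `minBp`
#' bp) any peak called at stage s.
#'
#' @param reference [PeakSet-class] or `GRanges` of reference peaks.
#' @param stageSeries Named list of [PeakSet-class], keyed by stage.
#' @param stages Stage columns, in [stageLevels()] order.
#' @param minBp Minimum overlap in bp.
#' @return Logical matrix, one row per reference peak.
#' @export
buildPresenceMatrix <- function(reference, stageSeries, stages, minBp = 1L) {
  missing <- setdiff(stages, names(stageSeries))
  if (length(missing))
    stop("stage(s) missing from series: ", paste(missing, collapse = ", "))
  if (is.unsorted(stageRank(stages)))
    stop("stages must follow the canonical stage order")
  ref <- .gr(reference)
  m <- matrix(FALSE, nrow = length(ref), ncol = length(stages),
              dimnames = list(NULL, stages))
  for (s in stages)
    m[, s] <- overlapsAny(ref, .gr(stageSeries[[s]]), minoverlap = minBp)
  m
}

#' Classify hotspot-associated mid-zygotene peaks by turnover
#'
#' Given presence across leptotene (L), mid-zygotene (mZ), late-zygotene
#' (lZ) and early 1-pachytene (e1P):
#' * present in L: **early_forming** (appeared with the first DSBs);
#' * absent in L and lZ: **fast_turnover** (erased by late zygotene);
#' * absent in L, present in lZ, absent in e1P: **slow_turnover**;
#' * absent in L, present in lZ and e1P: **persistent**;
#' * any other pattern (e.g. absent then reappearing): **unclassified**.
#'
#' Every peak must be present in mZ (they are mid-zygotene reference
#' peaks by construction).
#'
#' @param presence Logical matrix with columns `L`, `mZ`, `lZ`, `e1P`.
#' @return Factor of labels with levels [dynamicsLevels()].
#' @export
classifyDynamics <- function(presence) {
  need <- c("L", "mZ", "lZ", "e1P")
  if (!all(need %in% colnames(presence)))
    stop("presence matrix must have columns L, mZ, lZ, e1P")
  if (!all(presence[, "mZ"]))
    stop("all rows must be present in mZ (hotspot-associated mid-zygotene ",
         "reference peaks)")
  L <- presence[, "L"]; lZ <- presence[, "lZ"]; e1P <- presence[, "e1P"]
  lab <- rep("unclassified", nrow(presence))
  lab[L] <- "early_forming"
  lab[!L & !lZ & !e1P] <- "fast_turnover"
  lab[!L & lZ & !e1P] <- "slow_turnover"
  lab[!L & lZ & e1P] <- "persistent"
  factor(lab, levels = dynamicsLevels())
}

#' Turnover class labels
#' @return Character vector of the four turnover classes plus
#'   `unclassified`.
#' @export
dynamicsLevels <- function()
  c("early_forming", "fast_turnover", "slow_turnover", "persistent",
    "unclassified")

#' Summarize a dynamics classification
#'
#' @param reference [PeakSet-class] or `GRanges` the labels refer to.
#' @param labels Factor from [classifyDynamics()].
#' @return List with `labels`, per-class `counts`, and per-class width
#'   summaries (`widthMean`, `widthMedian`); per-class score means when a
#'   `score` metadata column exists.
#' @export
dynamicsReport <- function(reference, labels) {
  gr <- .gr(reference)
  stopifnot(length(gr) == length(labels))
  counts <- table(labels)
  w <- split(width(gr), labels)
  rep <- list(labels = labels, counts = counts,
              widthMean = vapply(w, function(x) mean(as.numeric(x)), 1),
              widthMedian = vapply(w, function(x)
                if (length(x)) median(as.numeric(x)) else NA_real_, 1))
  if ("score" %in% names(mcols(gr)))
    rep$scoreMean <- vapply(split(mcols(gr)$score, labels),
                            function(x) mean(as.numeric(x)), 1)
  stopifnot(sum(counts) == length(labels))
  rep
}

#' Detect H3K9me2 dips at DSB hotspots
#'
#' For a hotspot of width w, the mean signal density inside is compared
#' with the mean of the two flanking regions of width 2w each
#' (`[start - 2w, start)` and `[end, end + 2w)`); the hotspot is a dip
#' when inside / mean(flanks) < `ratioThreshold`.  Flanks are clipped at
#' chromosome ends and the truncated span is used; if one flank vanishes
#' the other is used alone; hotspots with both flanks gone, or with zero
#' signal in both flanks (undefined ratio), are skipped with a warning.
#'
#' @param hotspots `GRanges` or [PeakSet-class] of hotspots.
#' @param track [SignalTrack-class] covering the hotspot chromosomes.
#' @param ratioThreshold Dip calls require inside/flank ratio below this
#'   value (default 0.5, i.e. flanks at least twice the hotspot).
#' @return `GRanges` of dip hotspots with metadata columns
#'   `insideMean`, `flankMean` and `ratio`.
#' @export
h3k9me2Dip <- function(hotspots, track, ratioThreshold = 0.5) {
  gr <- .gr(hotspots)
  if (!length(gr)) return(gr)
  w <- width(gr)
  lens <- track@chromLengths
  chrom <- as.character(seqnames(gr))
  inside <- regionMeanDensity(track, gr)
  lS <- start(gr) - 2L * w; lE <- start(gr) - 1L
  rS <- end(gr) + 1L; rE <- end(gr) + 2L * w
  leftOk <- lE >= 1L
  rightOk <- rS <= lens[chrom]
  flankMean <- rep(NA_real_, length(gr))
  mkFlank <- function(s, e) {
    GRanges(chrom, IRanges(pmax(s, 1L), pmin(e, lens[chrom])))
  }
  lMean <- rep(NA_real_, length(gr)); rMean <- rep(NA_real_, length(gr))
  if (any(leftOk))
    lMean[leftOk] <- regionMeanDensity(track, mkFlank(lS[leftOk], lE[leftOk]))
  if (any(rightOk))
    rMean[rightOk] <- regionMeanDensity(track, mkFlank(rS[rightOk], rE[rightOk]))
  flankMean <- rowMeans(cbind(lMean, rMean), na.rm = TRUE)
  skip <- (!leftOk & !rightOk) | is.nan(flankMean) | flankMean == 0
  if (any(skip))
    warning(sum(skip), " hotspot(s) skipped (no usable flank or zero ",
            "flank signal)")
  ratio <- inside / flankMean
  keep <- !skip & !is.na(ratio) & ratio < ratioThreshold
  out <- gr[keep]
  mcols(out)$insideMean <- inside[keep]
  mcols(out)$flankMean <- flankMean[keep]
  mcols(out)$ratio <- ratio[keep]
  out
}

#' Fisher's exact test for spatial association of two peak sets
#'
#' The genome is tiled into non-overlapping bins; each bin is classified
#' by whether it overlaps set A and set B, and the resulting 2x2 counts
#' are tested with Fisher's exact test (two-sided).
#'
#' @param setA,setB [PeakSet-class] or `GRanges`; both non-empty.
#' @param layout [GenomeLayout-class].
#' @param binSize Tile width in bp (default 1000).
#' @return List with `oddsRatio`, `pValue` and the 2x2 `table`.
#' @export
fisherOverlapTest <- function(setA, setB, layout, binSize = 1000L) {
  if (binSize <= 0) stop("binSize must be positive")
  a <- .gr(setA); b <- .gr(setB)
  if (!length(a) || !length(b)) stop("both peak sets must be non-empty")
  bins <- tileGenome(setNames(as.integer(chromLengths(layout)),
                              names(chromLengths(layout))),
                     tilewidth = binSize, cut.last.tile.in.chrom = TRUE)
  inA <- overlapsAny(bins, a)
  inB <- overlapsAny(bins, b)
  tab <- matrix(c(sum(inA & inB), sum(inA & !inB),
                  sum(!inA & inB), sum(!inA & !inB)), nrow = 2,
                dimnames = list(A = c("inA", "outA"), B = c("inB", "outB")))
  ft <- fisher.test(tab)
  list(oddsRatio = unname(ft$estimate), pValue = ft$p.value, table = tab)
}

#' Venn-style overlap summary of two or three peak sets
#'
#' Peaks of the first (reference) set are classified by which of the
#' other sets they overlap; counts are keyed by membership pattern
#' (e.g. `"110"` = in sets 1 and 2 only).  Peaks of the non-reference
#' sets that do not touch the reference are tallied separately, since a
#' reference-anchored Venn cannot subdivide them.
#'
#' @param sets List of 2-3 [PeakSet-class] or `GRanges`.
#' @param minBp Minimum overlap in bp.
#' @return List with `reference` (named pattern counts over reference
#'   peaks) and `outsideReference` (per non-reference set, peaks not
#'   overlapping the reference).
#' @export
overlapSummary <- function(sets, minBp = 1L) {
  k <- length(sets)
  if (k < 2 || k > 3) stop("overlapSummary supports 2 or 3 sets")
  grs <- lapply(sets, .gr)
  ref <- grs[[1]]
  memb <- cbind(rep(TRUE, length(ref)),
                vapply(grs[-1], function(g)
                  overlapsAny(ref, g, minoverlap = minBp),
                  logical(length(ref))))
  pats <- apply(matrix(as.integer(memb), ncol = k), 1, paste, collapse = "")
  allPats <- apply(expand.grid(rep(list(0:1), k - 1))[, rev(seq_len(k - 1)),
                                                      drop = FALSE],
                   1, function(b) paste(c(1, b), collapse = ""))
  counts <- setNames(integer(length(allPats)), sort(allPats))
  tab <- table(pats)
  counts[names(tab)] <- as.integer(tab)
  outside <- vapply(grs[-1], function(g)
    sum(!overlapsAny(g, ref, minoverlap = minBp)), 1L)
  names(outside) <- paste0("set", seq(2, k))
  list(reference = counts, outsideReference = outside)
}
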