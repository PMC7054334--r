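# NOMe-seq analytics: cytosine context classification, site and region
# methylation levels, the sliding-window chi-squared NDR caller,
# proximal/distal annotation and accessibility ratios.
#
# GCH methylation (deposited in vitro by the GpC methyltransferase on
# accessible chromatin) reports accessibility; WCG methylation reports
# endogenous CpG methylation.  GCG/CCG sites are ambiguous between the
# two signals and are excluded from both contexts.

#' Construct a CytosineTable
#'
#' @param calls data.frame with columns chrom, pos (1-based), strand,
#'   context (`WCG`/`GCH`/`other`), meth, total.
#' @param depthFiltered Has a depth cutoff already been applied?
#' @param depthCutoff The cutoff applied (NA if none).
#' @return A [CytosineTable-class].
#' @export
cytosineTable <- function(calls, depthFiltered = FALSE, depthCutoff = NA_real_) {
  calls <- as.data.frame(calls)
  rownames(calls) <- NULL
  new("CytosineTable", calls = calls, depthFiltered = depthFiltered,
      depthCutoff = depthCutoff)
}

#' @describeIn cytosineTable The underlying call data.frame.
#' @param x A `CytosineTable`.
#' @export
cytosineCalls <- function(x) x@calls

#' @export
setMethod("length", "CytosineTable", function(x) nrow(x@calls))

setMethod("show", "CytosineTable", function(object) {
  d <- object@calls
  cat(sprintf("CytosineTable: %d site(s) (%d GCH, %d WCG)%s\n",
              nrow(d), sum(d$context == "GCH"), sum(d$context == "WCG"),
              if (isTRUE(object@depthFiltered))
                sprintf(", depth >= %g", object@depthCutoff) else ""))
})

#' Classify a cytosine's trinucleotide context
#'
#' WCG (ACG/TCG) sites report endogenous CpG methylation; GCH
#' (GCA/GCC/GCT) sites report enzyme-deposited accessibility signal.
#' GCG (and anything else) is `other` and excluded from both analyses.
#' Bases must be given strand-resolved, i.e. on the strand of the
#' cytosine.
#'
#' @param upstream,downstream Bases flanking the cytosine (A/C/G/T/N).
#' @param cBase The central base; must be `"C"`.
#' @return Character vector: `"WCG"`, `"GCH"` or `"other"`.
#' @examples
#' classifyContext("A", "G")  # WCG
#' classifyContext("G", "T")  # GCH
#' classifyContext("G", "G")  # other (GCG is ambiguous)
#' @export
classifyContext <- function(upstream, downstream, cBase = "C") {
  if (any(cBase != "C")) stop("central base must be a cytosine")
  ok <- c("A", "C", "G", "T", "N")
  if (!all(upstream %in% ok) || !all(downstream %in% ok))
    stop("bases must be one of A, C, G, T, N")
  out <- rep("other", length(upstream))
  out[upstream %in% c("A", "T") & downstream == "G"] <- "WCG"
  out[upstream == "G" & downstream %in% c("A", "C", "T")] <- "GCH"
  out
}

#' Read a cytosine-report-style TSV
#'
#' Expects tab-separated columns: chrom, 1-based position, strand,
#' methylated count, unmethylated count, and either a context label
#' (WCG/GCH/other) or a trinucleotide (e.g. `ACG`), in which case the
#' context is derived with [classifyContext()].
#'
#' @param path File path.
#' @return An unfiltered [CytosineTable-class].
#' @export
readCytosineReport <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "pos", "strand", "meth",
                                "unmeth", "context"),
                  colClasses = c("character", "numeric", "character",
                                 "numeric", "numeric", "character"))
  ctx <- d$context
  tri <- grepl("^[ACGTN]{3}$", ctx) & !ctx %in% c("WCG", "GCH")
  if (any(tri))
    ctx[tri] <- classifyContext(substr(ctx[tri], 1, 1),
                                substr(ctx[tri], 3, 3))
  ctx[!ctx %in% c("WCG", "GCH")] <- "other"
  cytosineTable(data.frame(chrom = d$chrom, pos = d$pos, strand = d$strand,
                           context = ctx, meth = d$meth,
                           total = d$meth + d$unmeth))
}

#' Write a CytosineTable as a cytosine-report-style TSV
#' @param x A [CytosineTable-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeCytosineReport <- function(x, path) {
  d <- x@calls
  write.table(data.frame(d$chrom, d$pos, d$strand, d$meth,
                         d$total - d$meth, d$context),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Apply the per-site read-depth cutoff
#'
#' Sites with fewer than `cutoff` total reads are removed before any
#' window or region statistic is computed (default 3x).
#'
#' @param x A [CytosineTable-class].
#' @param cutoff Minimum total reads per site.
#' @return Depth-filtered [CytosineTable-class].
#' @export
filterDepth <- function(x, cutoff = 3L) {
  cytosineTable(x@calls[x@calls$total >= cutoff, , drop = FALSE],
                depthFiltered = TRUE, depthCutoff = cutoff)
}

#' Merge replicate call tables by summing counts per site
#'
#' @param x,y Unfiltered [CytosineTable-class] objects from the two
#'   replicates.
#' @return Merged, unfiltered [CytosineTable-class].
#' @export
mergeReplicates <- function(x, y) {
  d <- rbind(x@calls, y@calls)
  key <- paste(d$chrom, d$pos, d$strand, d$context, sep = "\r")
  agg <- rowsum(cbind(meth = d$meth, total = d$total), key, reorder = FALSE)
  first <- !duplicated(key)
  cytosineTable(data.frame(chrom = d$chrom[first], pos = d$pos[first],
                           strand = d$strand[first],
                           context = d$context[first],
                           meth = agg[, "meth"], total = agg[, "total"]))
}

#' Per-site methylation level
#'
#' Methylated reads divided by all detected reads at the site.
#'
#' @param x [CytosineTable-class] (optionally restricted by `context`),
#'   or a numeric vector of methylated counts.
#' @param total Total counts when `x` is numeric.
#' @param context Optional context restriction when `x` is a table.
#' @return Numeric fractions in \[0, 1\].
#' @export
siteLevel <- function(x, total = NULL, context = NULL) {
  if (is.numeric(x)) return(x / total)
  d <- x@calls
  if (!is.null(context)) d <- d[d$context == context, , drop = FALSE]
  d$meth / d$total
}

#' Whole-genome background for one context
#'
#' Pooled methylated/total read counts over every site of the context,
#' plus the unweighted mean of per-site levels.  The pooled counts feed
#' the window chi-squared test; the mean level is the one-sidedness
#' reference.
#'
#' @param x Depth-filtered [CytosineTable-class].
#' @param context `"GCH"` or `"WCG"`.
#' @return List with `meth`, `total`, `mean`, `nSites`.
#' @export
genomeBackground <- function(x, context = "GCH") {
  d <- x@calls[x@calls$context == context, , drop = FALSE]
  if (!nrow(d)) stop("no ", context, " sites in table")
  list(meth = sum(d$meth), total = sum(d$total),
       mean = mean(d$meth / d$total), nSites = nrow(d))
}

# 2x2 Pearson chi-squared (no continuity correction), vectorised over
# windows: columns are (meth, unmeth) for window vs genome.
.chisqP <- function(a, b, c, d) {
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  p[!is.finite(stat)] <- 1
  p
}

.siteRanges <- function(d) GRanges(d$chrom, IRanges(d$pos, d$pos))

#' Sliding-window scan of GCH accessibility with chi-squared testing
#'
#' The mean GCH methylation level is evaluated in 100-bp windows sliding
#' by 20 bp across each chromosome.  Each window's pooled
#' methylated/unmethylated counts are tested against the whole-genome
#' pooled counts in a 2x2 chi-squared test (no continuity correction).
#' The test is one-sided by construction: windows whose mean site level
#' does not exceed the genome background mean are assigned p = 1, as are
#' windows with no covered GCH site.
#'
#' @param x Depth-filtered [CytosineTable-class].
#' @param layout [GenomeLayout-class].
#' @param win,step Window width and slide step in bp.
#' @param context Context scanned (default `"GCH"`).
#' @param background Optional precomputed [genomeBackground()] of the
#'   same table.
#' @return data.frame with columns chrom, start, end (1-based closed),
#'   nSites, meth, total, meanLevel, p.
#' @export
scanWindows <- function(x, layout, win = 100L, step = 20L,
                        context = "GCH", background = NULL) {
  if (is.null(background)) background <- genomeBackground(x, context)
  d <- x@calls[x@calls$context == context, , drop = FALSE]
  lens <- chromLengths(layout)
  res <- lapply(names(lens), function(chrom) {
    len <- lens[[chrom]]
    starts <- seq(1L, max(1L, len - win + 1L), by = step)
    ends <- pmin(starts + win - 1L, len)
    dc <- d[d$chrom == chrom, , drop = FALSE]
    nS <- meth <- total <- numeric(length(starts))
    meanLvl <- numeric(length(starts))
    if (nrow(dc)) {
      ov <- findOverlaps(IRanges(starts, ends), IRanges(dc$pos, dc$pos))
      q <- queryHits(ov); s <- subjectHits(ov)
      add <- function(v) {
        out <- numeric(length(starts))
        if (length(q)) {
          agg <- rowsum(v[s], q)
          out[as.integer(rownames(agg))] <- agg
        }
        out
      }
      nS <- add(rep(1, nrow(dc)))
      meth <- add(dc$meth)
      total <- add(dc$total)
      sumLvl <- add(dc$meth / dc$total)
      meanLvl <- ifelse(nS > 0, sumLvl / nS, 0)
    }
    data.frame(chrom = chrom, start = starts, end = ends, nSites = nS,
               meth = meth, total = total, meanLevel = meanLvl)
  })
  w <- do.call(rbind, res)
  p <- .chisqP(w$meth, w$total - w$meth,
               background$meth, background$total - background$meth)
  p[w$nSites == 0 | w$total == 0] <- 1
  p[w$meanLevel <= background$mean] <- 1   # one-sided "higher" requirement
  w$p <- p
  w
}

#' Call nucleosome-depleted regions from GCH accessibility
#'
#' Significant scan windows (p <= `pMax`) are merged when overlapping or
#' bookended; a merged region is reported as an NDR when it contains
#' more than 5 covered GCH sites (`minSites` = 6) and is longer than
#' 140 bp (`minLen` = 141).  Each NDR carries the minimum window p of
#' its constituent windows.
#'
#' @inheritParams scanWindows
#' @param pMax Window significance ceiling (default 1e-10).
#' @param minSites Minimum GCH sites per merged region (default 6,
#'   i.e. strictly more than 5).
#' @param minLen Minimum merged-region width in bp (default 141,
#'   i.e. strictly more than 140).
#' @param windows Optional precomputed [scanWindows()] output.
#' @return `GRanges` of NDRs with metadata columns `nSites`,
#'   `meanLevel` and `minP`.
#' @export
callNdrs <- function(x, layout, pMax = 1e-10, minSites = 6L, minLen = 141L,
                     win = 100L, step = 20L, context = "GCH",
                     background = NULL, windows = NULL) {
  if (is.null(windows))
    windows <- scanWindows(x, layout, win = win, step = step,
                           context = context, background = background)
  sig <- windows[windows$p <= pMax, , drop = FALSE]
  si <- asSeqinfo(layout)
  if (!nrow(sig)) return(GRanges(seqinfo = si))
  wgr <- GRanges(sig$chrom, IRanges(sig$start, sig$end), seqinfo = si)
  merged <- reduce(wgr, min.gapwidth = 1L)  # overlapping or bookended
  d <- x@calls[x@calls$context == context, , drop = FALSE]
  ovS <- findOverlaps(merged, .siteRanges(d))
  nSites <- countOverlaps(merged, .siteRanges(d))
  lvl <- rep(NA_real_, length(merged))
  if (length(ovS)) {
    sAgg <- rowsum((d$meth / d$total)[subjectHits(ovS)], queryHits(ovS))
    lvl[as.integer(rownames(sAgg))] <-
      sAgg / nSites[as.integer(rownames(sAgg))]
  }
  ovW <- findOverlaps(merged, wgr)
  minP <- vapply(split(sig$p[subjectHits(ovW)],
                       factor(queryHits(ovW), levels = seq_along(merged))),
                 min, 1)
  mcols(merged)$nSites <- nSites
  mcols(merged)$meanLevel <- lvl
  mcols(merged)$minP <- unname(minP)
  merged[nSites >= minSites & width(merged) >= minLen]
}

#' Annotate NDRs as TSS-proximal or distal
#'
#' An NDR is proximal when it overlaps the window from 1.5 kb upstream
#' to 1.5 kb downstream of any TSS (boundary inclusive, strand-agnostic
#' since the window is symmetric); otherwise distal.
#'
#' @param ndrs `GRanges` of NDRs.
#' @param tss `GRanges` of TSS positions (width-1 anchors are
#'   conventional; wider ranges are reduced to their start).
#' @param flank Half-width of the proximal window in bp (default 1500).
#' @return `ndrs` with a metadata column `class`
#'   (`"proximal"`/`"distal"`).
#' @export
classifyNdr <- function(ndrs, tss, flank = 1500L) {
  if (!length(tss)) {
    warning("empty TSS set: all NDRs classified distal")
    mcols(ndrs)$class <- rep("distal", length(ndrs))
    return(ndrs)
  }
  p <- start(tss)
  win <- GRanges(seqnames(tss), IRanges(pmax(p - flank, 1L), p + flank))
  prox <- overlapsAny(ndrs, win)
  mcols(ndrs)$class <- ifelse(prox, "proximal", "distal")
  ndrs
}

#' Mean methylation level of regions
#'
#' Unweighted mean of per-site levels for context sites inside each
#' region; regions with fewer than `minSites` sites get `NA` (undefined,
#' never zero).
#'
#' @param regions `GRanges` or [PeakSet-class].
#' @param x Depth-filtered [CytosineTable-class].
#' @param context `"GCH"` or `"WCG"`.
#' @param minSites Minimum sites per region (default 3).
#' @return Numeric vector along `regions`.
#' @export
regionLevel <- function(regions, x, context = "GCH", minSites = 3L) {
  gr <- .gr(regions)
  d <- x@calls[x@calls$context == context, , drop = FALSE]
  out <- rep(NA_real_, length(gr))
  if (!nrow(d) || !length(gr)) return(out)
  ov <- findOverlaps(gr, .siteRanges(d))
  lv <- d$meth / d$total
  # mean() per region over sites in table order, matching the genome
  # background accumulation exactly
  sp <- split(lv[subjectHits(ov)],
              factor(queryHits(ov), levels = seq_along(gr)))
  out <- vapply(sp, function(v)
    if (length(v) >= minSites) mean(v) else NA_real_, 1)
  unname(out)
}

#' Accessibility ratio of regions over the genome background
#'
#' Region GCH level divided by the whole-genome GCH level (unweighted
#' mean of site levels in both cases).
#'
#' @inheritParams regionLevel
#' @return Numeric ratios along `regions` (NA where the region level is
#'   undefined).
#' @export
accessibilityRatio <- function(regions, x, context = "GCH", minSites = 3L) {
  bg <- genomeBackground(x, context)
  if (bg$mean == 0) stop("genome background level is zero")
  regionLevel(regions, x, context, minSites) / bg$mean
}

#' Partition DSB hotspots by NDR membership
#'
#' A hotspot lies within an NDR when its center base falls inside the
#' NDR interval.  When the NDRs carry a `class` column the within-NDR
#' hotspots are further split into proximal/distal.
#'
#' @param hotspots `GRanges` or [PeakSet-class] of hotspots.
#' @param ndrs `GRanges` of NDRs (optionally classified by
#'   [classifyNdr()]).
#' @return List with counts `nWithin`, `nOutside`, fraction
#'   `fracWithin`, and (when available) `withinProximal`/`withinDistal`.
#' @export
hotspotNdrPartition <- function(hotspots, ndrs) {
  gr <- .gr(hotspots)
  center <- floor((start(gr) - 1 + end(gr)) / 2) + 1  # center base
  cgr <- GRanges(seqnames(gr), IRanges(center, center))
  hit <- findOverlaps(cgr, ndrs, select = "first")
  within <- !is.na(hit)
  out <- list(nWithin = sum(within), nOutside = sum(!within),
              fracWithin = if (length(gr)) mean(within) else NA_real_)
  if ("class" %in% names(mcols(ndrs))) {
    cls <- mcols(ndrs)$class[hit[within]]
    out$withinProximal <- sum(cls == "proximal")
    out$withinDistal <- sum(cls == "distal")
  }
  out
}
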