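# Genome layout, interval primitives and BED-family I/O.

.MARKS <- c("H3K4me3", "H3K4me1", "H3K27ac", "H3K36me3", "H3K9me2",
            "H3K9me3", "H3K27me3")
# Ordered spermatogenic stages: mitotic spermatogonia (Undiff, A1, B),
# meiotic S phase (mpL), then prophase I substages.
.STAGES <- c("Undiff", "A1", "B", "mpL", "L", "eZ", "mZ", "lZ",
             "e1P", "e2P", "mP", "D")

#' Supported histone mark labels
#' @return Character vector of mark names.
#' @export
markLevels <- function() .MARKS

#' Ordered spermatogenic stage labels, earliest first
#'
#' Undifferentiated (Undiff), type A1 and type B spermatogonia,
#' mid-preleptotene (mpL), leptotene (L), early/mid/late zygotene
#' (eZ/mZ/lZ), early 1- and 2-pachytene (e1P/e2P), mid-pachytene (mP)
#' and diplotene (D).
#' @return Character vector defining the total stage order.
#' @export
stageLevels <- function() .STAGES

#' Position of stages in the canonical order
#' @param stage Character vector of stage labels.
#' @return Integer rank(s); errors on unknown labels.
#' @export
stageRank <- function(stage) {
  r <- match(stage, .STAGES)
  if (anyNA(r)) stop("unknown stage label(s): ",
                     paste(stage[is.na(r)], collapse = ", "))
  r
}

#' Construct a GenomeLayout
#'
#' @param lengths Named vector of chromosome lengths (bp).
#' @param autosome Optional named logical; by default chromosomes named
#'   `chrX`, `chrY`, `X` or `Y` are flagged as sex chromosomes.
#' @return A [GenomeLayout-class] object.
#' @examples
#' genomeLayout(c(chr1 = 2e6, chrX = 1e6))
#' @export
genomeLayout <- function(lengths, autosome = NULL) {
  lengths <- setNames(round(as.numeric(lengths)), names(lengths))
  if (is.null(autosome))
    autosome <- !(names(lengths) %in% c("chrX", "chrY", "X", "Y"))
  autosome <- setNames(as.logical(autosome), names(lengths))
  new("GenomeLayout", lengths = lengths, autosome = autosome)
}

#' @describeIn genomeLayout Chromosome lengths of a layout.
#' @param x A `GenomeLayout`.
#' @export
chromLengths <- function(x) x@lengths

#' @describeIn genomeLayout Autosome flags of a layout.
#' @export
isAutosome <- function(x) x@autosome

#' @describeIn genomeLayout Convert to a [GenomeInfoDb::Seqinfo].
#' @export
asSeqinfo <- function(x)
  Seqinfo(seqnames = names(x@lengths), seqlengths = as.integer(x@lengths))

#' Read a two-column chromosome-sizes file
#' @param path Tab-separated file: chromosome name, length.
#' @inheritParams genomeLayout
#' @return A [GenomeLayout-class].
#' @export
readChromSizes <- function(path, autosome = NULL) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "length"),
                  colClasses = c("character", "numeric"))
  genomeLayout(setNames(d$length, d$chrom), autosome)
}

setMethod("show", "GenomeLayout", function(object) {
  cat(sprintf("GenomeLayout with %d chromosome(s), %.3g Mb total (%d autosome)\n",
              length(object@lengths), sum(object@lengths) / 1e6,
              sum(object@autosome)))
})

# canonical sort + dedup used by the PeakSet validity method
sortRanges <- function(gr) {
  gr <- gr[order(as.integer(seqnames(gr)), start(gr), end(gr))]
  unique(gr)
}

#' Construct a PeakSet
#'
#' @param ranges A `GRanges` (any order; sorted and deduplicated here).
#'   Its seqinfo is replaced from `layout` when given.
#' @param mark,stage Mark and stage labels (see [markLevels()],
#'   [stageLevels()]).
#' @param layout Optional [GenomeLayout-class] supplying seqlengths.
#' @return A [PeakSet-class].
#' @export
peakSet <- function(ranges, mark, stage, layout = NULL) {
  if (!is.null(layout)) {
    si <- asSeqinfo(layout)
    bad <- setdiff(as.character(unique(seqnames(ranges))), seqlevels(si))
    if (length(bad))
      stop("chromosome(s) absent from layout: ", paste(bad, collapse = ", "))
    gr <- GRanges(seqnames(ranges), IRanges(start(ranges), end(ranges)),
                  seqinfo = si)
    mcols(gr) <- mcols(ranges)
    ranges <- gr
  }
  new("PeakSet", mark = mark, stage = stage, ranges = sortRanges(ranges))
}

#' @describeIn peakSet Underlying `GRanges` of a peak set.
#' @param x A `PeakSet`.
#' @export
peakRanges <- function(x) x@ranges

#' @describeIn peakSet Mark label.
#' @export
peakMark <- function(x) x@mark

#' @describeIn peakSet Stage label.
#' @export
peakStage <- function(x) x@stage

#' @export
setMethod("length", "PeakSet", function(x) length(x@ranges))

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet: %s @ %s, %d interval(s)\n",
              object@mark, object@stage, length(object@ranges)))
  if (length(object@ranges)) {
    w <- width(object@ranges)
    cat(sprintf("  width: median %d bp [%d-%d]\n",
                as.integer(median(w)), min(w), max(w)))
  }
})

#' Interval width in bp
#'
#' The width of a peak is its end coordinate minus its start coordinate
#' (BED half-open convention), i.e. the number of bases it covers.
#'
#' @param x A `GRanges` or [PeakSet-class].
#' @return Integer widths.
#' @export
intervalWidth <- function(x) {
  if (is(x, "PeakSet")) x <- x@ranges
  width(x)
}

#' Pairwise overlap predicate
#'
#' TRUE where intervals of `a` share at least `minBp` bases with any
#' interval of `b` (half-open/closed semantics agree: abutting intervals
#' do not overlap).
#'
#' @param a,b `GRanges` or [PeakSet-class] objects on the same layout.
#' @param minBp Minimum shared bases (default 1).
#' @return Logical vector along `a`.
#' @export
overlapsIntervals <- function(a, b, minBp = 1L) {
  if (minBp < 1) stop("minBp must be >= 1")
  if (is(a, "PeakSet")) a <- a@ranges
  if (is(b, "PeakSet")) b <- b@ranges
  overlapsAny(a, b, minoverlap = minBp)
}

#' Extend an interval on both sides, clipping at chromosome ends
#'
#' @param x `GRanges` with seqlengths, or a [PeakSet-class].
#' @param leftBp,rightBp Non-negative extensions in bp.
#' @return `GRanges` with a logical metadata column `clipped` set where
#'   truncation at a chromosome boundary occurred.
#' @export
extendInterval <- function(x, leftBp, rightBp) {
  if (any(leftBp < 0) || any(rightBp < 0))
    stop("extensions must be non-negative")
  if (is(x, "PeakSet")) x <- x@ranges
  sl <- seqlengths(x)
  if (any(is.na(sl))) stop("seqlengths required for clipped extension")
  s <- start(x) - leftBp
  e <- end(x) + rightBp
  lim <- sl[as.character(seqnames(x))]
  clipped <- s < 1L | e > lim
  out <- GRanges(seqnames(x), IRanges(pmax(s, 1L), pmin(e, lim)),
                 seqinfo = seqinfo(x))
  mcols(out) <- mcols(x)
  mcols(out)$clipped <- clipped
  out
}

#' Read a BED3+/narrowPeak file into a PeakSet
#'
#' Accepts 3+ tab-separated columns; columns 4/5 populate `name`/`score`
#' and, for 10-column narrowPeak rows, column 8 (-log10 p) populates
#' `pvalue`.  Input coordinates are BED half-open 0-based by default;
#' `oneBased = TRUE` accepts 1-based closed coordinates instead.
#'
#' @param path File path.
#' @param layout [GenomeLayout-class] used for validation.
#' @param mark,stage Labels for the resulting [PeakSet-class].
#' @param oneBased Coordinate dialect flag (default FALSE = BED).
#' @return A [PeakSet-class].
#' @export
readBed <- function(path, layout, mark = "H3K4me3", stage = "mZ",
                    oneBased = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(#|track|browser)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(peakSet(GRanges(seqinfo = asSeqinfo(layout)), mark, stage))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("parse error at line %d: fewer than 3 fields",
                 lineno[which(nf < 3)[1]]))
  chrom <- vapply(fields, `[`, "", 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- is.na(s) | is.na(e) | s != round(s) | e != round(e)
  if (any(bad))
    stop(sprintf("parse error at line %d: non-integer coordinates",
                 lineno[which(bad)[1]]))
  if (!oneBased) s <- s + 1  # BED half-open -> 1-based closed
  bad <- s > e
  if (any(bad))
    stop(sprintf("invalid interval at line %d: start >= end",
                 lineno[which(bad)[1]]))
  lens <- chromLengths(layout)
  bad <- !(chrom %in% names(lens))
  if (any(bad))
    stop(sprintf("validation error at line %d: chromosome '%s' not in layout",
                 lineno[which(bad)[1]], chrom[which(bad)[1]]))
  bad <- s < 1 | e > lens[chrom]
  if (any(bad))
    stop(sprintf("validation error at line %d: interval outside chromosome",
                 lineno[which(bad)[1]]))
  gr <- GRanges(chrom, IRanges(s, e), seqinfo = asSeqinfo(layout))
  if (all(nf >= 4)) mcols(gr)$name <- vapply(fields, `[`, "", 4L)
  if (all(nf >= 5))
    mcols(gr)$score <- suppressWarnings(
      as.numeric(vapply(fields, `[`, "", 5L)))
  if (all(nf >= 10))  # narrowPeak: col 8 is -log10(p)
    mcols(gr)$pvalue <- suppressWarnings(
      10^(-as.numeric(vapply(fields, `[`, "", 8L))))
  peakSet(gr, mark, stage)
}

#' Write a PeakSet as BED or narrowPeak
#'
#' Emits BED3 plus `name`/`score` columns when present; with
#' `narrowPeak = TRUE` writes the 10-column dialect (p-value re-encoded
#' as -log10).
#'
#' @param x A [PeakSet-class] or `GRanges`.
#' @param path Output path.
#' @param narrowPeak Write 10-column narrowPeak instead of BED.
#' @return Invisibly, the path.
#' @export
writeBed <- function(x, path, narrowPeak = FALSE) {
  gr <- if (is(x, "PeakSet")) x@ranges else x
  m <- mcols(gr)
  nm <- if ("name" %in% names(m)) as.character(m$name)
        else sprintf("peak_%d", seq_along(gr))
  sc <- if ("score" %in% names(m)) m$score else rep(0, length(gr))
  d <- data.frame(chrom = as.character(seqnames(gr)),
                  start = start(gr) - 1L, end = end(gr),   # back to half-open
                  name = nm, score = sc)
  if (narrowPeak) {
    pv <- if ("pvalue" %in% names(m)) -log10(m$pvalue) else rep(-1, length(gr))
    d <- cbind(d, strand = ".", signalValue = sc, pValue = pv,
               qValue = -1, peak = -1)
  }
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Drop intervals on sex chromosomes
#'
#' Hotspot analyses are conventionally restricted to autosomes; this
#' filter applies that choice explicitly rather than baking it into the
#' data model.
#'
#' @param x [PeakSet-class] or `GRanges`.
#' @param layout [GenomeLayout-class] carrying autosome flags.
#' @return Object of the same class, autosomal intervals only.
#' @export
autosomalOnly <- function(x, layout) {
  auto <- names(chromLengths(layout))[isAutosome(layout)]
  if (is(x, "PeakSet"))
    return(peakSet(x@ranges[as.character(seqnames(x@ranges)) %in% auto],
                   x@mark, x@stage))
  x[as.character(seqnames(x)) %in% auto]
}
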