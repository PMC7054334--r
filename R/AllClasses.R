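#' @import methods
#' @importFrom GenomicRanges GRanges granges findOverlaps countOverlaps
#'   tileGenome seqnames start end width strand resize trim shift mcols
#'   mcols<- coverage reduce
#' @importFrom IRanges IRanges Views viewSums overlapsAny subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits Rle runValue runLength
#' @importFrom GenomeInfoDb Seqinfo seqinfo seqlengths seqlevels
#' @importFrom stats rbinom rpois rgamma rbeta runif rnorm median
#'   pchisq fisher.test t.test ks.test setNames quantile sd
#' @importFrom utils read.table write.table head tail
NULL

#' Chromosome set with lengths and autosome flags
#'
#' A minimal genome description: named chromosome lengths (bp) plus a flag
#' marking autosomes.  Sex chromosomes are kept in the model and excluded
#' only by explicit filters at analysis time, mirroring the common practice
#' of restricting meiotic hotspot analyses to autosomes.
#'
#' @slot lengths Named integer vector of chromosome lengths in bp.
#' @slot autosome Named logical vector, parallel to `lengths`.
#' @export
setClass("GenomeLayout",
  representation(lengths = "numeric", autosome = "logical"))

setValidity("GenomeLayout", function(object) {
  msg <- character()
  if (is.null(names(object@lengths)) || anyDuplicated(names(object@lengths)))
    msg <- c(msg, "chromosome names must be present and unique")
  if (any(object@lengths <= 0) || any(object@lengths != round(object@lengths)))
    msg <- c(msg, "chromosome lengths must be positive integers")
  if (!identical(names(object@lengths), names(object@autosome)))
    msg <- c(msg, "autosome flags must be named parallel to lengths")
  if (length(msg)) msg else TRUE
})

#' Coordinate-sorted peak set for one histone mark at one stage
#'
#' Intervals live in a [GenomicRanges::GRanges] (1-based, closed; BED
#' half-open coordinates are converted at the I/O boundary).  Optional
#' metadata columns `name`, `score` and `pvalue` carry narrowPeak fields.
#'
#' @slot mark Histone mark label, one of [markLevels()].
#' @slot stage Spermatogenic stage label, one of [stageLevels()].
#' @slot ranges Sorted `GRanges` with seqlengths from the layout.
#' @export
setClass("PeakSet",
  representation(mark = "character", stage = "character", ranges = "GRanges"))

setValidity("PeakSet", function(object) {
  msg <- character()
  if (length(object@mark) != 1L || !object@mark %in% markLevels())
    msg <- c(msg, sprintf("mark must be one of: %s",
                          paste(markLevels(), collapse = ", ")))
  if (length(object@stage) != 1L || !object@stage %in% stageLevels())
    msg <- c(msg, sprintf("stage must be one of: %s",
                          paste(stageLevels(), collapse = ", ")))
  gr <- object@ranges
  if (!identical(granges(gr), granges(sortRanges(gr))))
    msg <- c(msg, "ranges must be coordinate-sorted with no duplicates")
  sl <- seqlengths(gr)
  if (any(is.na(sl)))
    msg <- c(msg, "ranges must carry seqlengths for every chromosome")
  else if (length(gr) && (any(start(gr) < 1L) ||
           any(end(gr) > sl[as.character(seqnames(gr))])))
    msg <- c(msg, "intervals must lie within chromosome bounds")
  if (length(msg)) msg else TRUE
})

#' Cytosine-level NOMe-seq call table
#'
#' Per-site methylated/total read counts with trinucleotide context class
#' (WCG for endogenous CpG methylation, GCH for enzyme-deposited
#' accessibility signal).  Positions are stored 1-based to match the
#' GRanges convention; cytosine-report input (1-based) passes through
#' unchanged and BED-style output converts on write.
#'
#' @slot calls data.frame with columns chrom, pos, strand, context,
#'   meth, total.
#' @slot depthFiltered logical; TRUE once the read-depth cutoff has been
#'   applied (all total >= the cutoff used).
#' @slot depthCutoff integer; the cutoff applied (NA before filtering).
#' @export
setClass("CytosineTable",
  representation(calls = "data.frame", depthFiltered = "logical",
                 depthCutoff = "numeric"))

setValidity("CytosineTable", function(object) {
  d <- object@calls
  need <- c("chrom", "pos", "strand", "context", "meth", "total")
  if (!all(need %in% names(d)))
    return(sprintf("calls must have columns: %s", paste(need, collapse = ", ")))
  if (any(d$meth < 0) || any(d$meth > d$total))
    return("need 0 <= meth <= total for every site")
  if (!all(d$context %in% c("WCG", "GCH", "other")))
    return("context must be WCG, GCH or other")
  if (isTRUE(object@depthFiltered) && !is.na(object@depthCutoff) &&
      any(d$total < object@depthCutoff))
    return("depth-filtered table contains sites below the cutoff")
  TRUE
})

#' Fixed-bin signal track
#'
#' Dense per-chromosome vectors of mean per-base fragment depth in
#' consecutive bins (default 50 bp; the final bin of a chromosome may be
#' shorter).  A spike-in normalization factor, once applied, is recorded.
#'
#' @slot bins Named list of numeric vectors, one per chromosome.
#' @slot binSize Bin width in bp.
#' @slot chromLengths Named chromosome lengths (to recover the true width
#'   of the final partial bin).
#' @slot factor Normalization factor already applied to the values.
#' @slot sample Sample label.
#' @export
setClass("SignalTrack",
  representation(bins = "list", binSize = "numeric", chromLengths = "numeric",
                 factor = "numeric", sample = "character"))

setValidity("SignalTrack", function(object) {
  if (!identical(names(object@bins), names(object@chromLengths)))
    return("bins and chromLengths must cover the same chromosomes")
  nb <- vapply(object@bins, length, 1L)
  if (any(nb != ceiling(object@chromLengths / object@binSize)))
    return("bin count must equal ceiling(chrom length / bin size)")
  if (any(vapply(object@bins, function(v) any(v < 0), TRUE)))
    return("bin values must be non-negative")
  TRUE
})
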