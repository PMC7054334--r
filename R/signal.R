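# Spike-in-normalized binned coverage tracks and region-anchored
# matrices and profiles.
#
# Track values are mean per-base fragment depth within each bin, so a
# fragment contributes to a partial bin in proportion to the bases it
# covers there, and total mass (value x bin width, summed) equals the
# summed clipped fragment lengths.

#' Construct a SignalTrack from bin vectors
#' @param bins Named list of numeric vectors, one per chromosome.
#' @param binSize Bin width in bp.
#' @param layout [GenomeLayout-class] (supplies chromosome lengths).
#' @param factor Normalization factor already applied (default 1).
#' @param sample Sample label.
#' @return A [SignalTrack-class].
#' @export
signalTrack <- function(bins, binSize, layout, factor = 1,
                        sample = "sample") {
  new("SignalTrack", bins = bins, binSize = binSize,
      chromLengths = chromLengths(layout)[names(bins)],
      factor = factor, sample = sample)
}

setMethod("show", "SignalTrack", function(object) {
  cat(sprintf("SignalTrack '%s': %d chromosome(s), %d-bp bins, factor %.4g\n",
              object@sample, length(object@bins), as.integer(object@binSize),
              object@factor))
})

#' @describeIn signalTrack Bin vectors of a track.
#' @param x A `SignalTrack`.
#' @export
trackBins <- function(x) x@bins

#' @describeIn signalTrack Bin width in bp.
#' @export
trackBinSize <- function(x) x@binSize

# actual width of each bin on a chromosome (final bin may be partial)
.binWidths <- function(track, chrom) {
  n <- length(track@bins[[chrom]])
  w <- rep(track@binSize, n)
  w[n] <- track@chromLengths[[chrom]] - (n - 1) * track@binSize
  w
}

#' Read a fragment table (chrom, 0-based 5' position, strand)
#' @param path Tab-separated file.
#' @return data.frame with chrom, pos (1-based), strand.
#' @export
readFragments <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "pos", "strand"),
                  colClasses = c("character", "numeric", "character"))
  d$pos <- d$pos + 1
  d
}

#' Write a fragment table (chrom, 0-based 5' position, strand)
#' @param frags data.frame with chrom, pos (1-based), strand.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeFragments <- function(frags, path) {
  write.table(data.frame(frags$chrom, frags$pos - 1, frags$strand),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Binned coverage from extended reads
#'
#' Each mapped read, represented by its 5' position and strand, is
#' extended 3'-ward to the average sonicated fragment length (150 bp by
#' default) and piled up; per-bin values are mean per-base depth, with
#' fragments clipped at chromosome ends.  Reads whose 5' position lies
#' off-chromosome are rejected (count reported in the `rejected`
#' attribute).
#'
#' @param frags data.frame with chrom, pos (1-based 5' base), strand
#'   (`"+"`/`"-"`).
#' @param layout [GenomeLayout-class].
#' @param extension Fragment length in bp (default 150).
#' @param binSize Bin width in bp (default 50).
#' @param sample Sample label.
#' @return A [SignalTrack-class]; attribute `rejected` counts dropped
#'   fragments.
#' @export
coverageFromFragments <- function(frags, layout, extension = 150L,
                                  binSize = 50L, sample = "sample") {
  lens <- chromLengths(layout)
  ok <- frags$chrom %in% names(lens)
  ok[ok] <- frags$pos[ok] >= 1 & frags$pos[ok] <= lens[frags$chrom[ok]]
  rejected <- sum(!ok)
  f <- frags[ok, , drop = FALSE]
  s <- ifelse(f$strand == "+", f$pos, f$pos - extension + 1)
  e <- ifelse(f$strand == "+", f$pos + extension - 1, f$pos)
  gr <- trim(GRanges(f$chrom, IRanges(pmax(s, 1),
                                      pmin(e, lens[f$chrom])),
                     seqinfo = asSeqinfo(layout)))
  cov <- coverage(gr)
  bins <- lapply(names(lens), function(chrom) {
    len <- lens[[chrom]]
    starts <- seq(1, len, by = binSize)
    ends <- pmin(starts + binSize - 1, len)
    v <- if (chrom %in% names(cov)) cov[[chrom]] else Rle(0L, len)
    as.numeric(viewSums(Views(v, starts, ends))) / (ends - starts + 1)
  })
  names(bins) <- names(lens)
  out <- signalTrack(bins, binSize, layout, sample = sample)
  attr(out, "rejected") <- rejected
  out
}

#' Spike-in normalization factors
#'
#' With the default `"min"` reference, each sample's factor is the
#' smallest spike-in read count divided by that sample's count, so the
#' sample with fewest spike reads keeps factor 1 and all signal is
#' scaled down, never inflated.  `"perMillion"` gives 1e6 / count
#' instead.  Applying the factors equalizes spike-derived signal totals
#' across samples.
#'
#' @param counts Named vector of spike-in mapped read counts, all > 0.
#' @param mode `"min"` (default) or `"perMillion"`.
#' @return Named numeric factors.
#' @export
spikeFactors <- function(counts, mode = c("min", "perMillion")) {
  mode <- match.arg(mode)
  if (any(counts <= 0)) stop("spike-in counts must be positive")
  if (mode == "min") min(counts) / counts else 1e6 / counts
}

#' Scale a track by a normalization factor
#' @param track A [SignalTrack-class].
#' @param factor Multiplicative factor.
#' @return Scaled [SignalTrack-class] with the cumulative factor
#'   recorded.
#' @export
scaleTrack <- function(track, factor) {
  track@bins <- lapply(track@bins, `*`, factor)
  track@factor <- track@factor * factor
  track
}

#' Total signal mass of a track
#'
#' Sum over bins of value times true bin width; for an unnormalized
#' track this equals the summed clipped fragment lengths.
#'
#' @param track A [SignalTrack-class].
#' @return Numeric scalar.
#' @export
trackTotalMass <- function(track) {
  sum(vapply(names(track@bins), function(chrom)
    sum(track@bins[[chrom]] * .binWidths(track, chrom)), 1))
}

#' Length-weighted mean track density over intervals
#'
#' @param track A [SignalTrack-class].
#' @param intervals `GRanges` (clipped to the chromosome; zero-length
#'   after clipping gives NA).
#' @return Numeric vector along `intervals`.
#' @export
regionMeanDensity <- function(track, intervals) {
  gr <- .gr(intervals)
  vapply(seq_along(gr), function(i) {
    chrom <- as.character(seqnames(gr))[i]
    if (!chrom %in% names(track@bins)) return(NA_real_)
    len <- track@chromLengths[[chrom]]
    s <- max(start(gr)[i], 1); e <- min(end(gr)[i], len)
    if (s > e) return(NA_real_)
    b <- track@binSize
    i1 <- (s - 1) %/% b + 1; i2 <- (e - 1) %/% b + 1
    v <- track@bins[[chrom]][i1:i2]
    bs <- (seq(i1, i2) - 1) * b + 1
    be <- pmin(bs + b - 1, len)
    w <- pmin(be, e) - pmax(bs, s) + 1
    sum(v * w) / sum(w)
  }, 1)
}

#' Signal matrix around region centers
#'
#' Row r holds the track density in consecutive `bin`-bp cells across
#' center(region r) +/- `flank`.  Cells extending beyond the chromosome
#' are missing (NA), not zero, so edge regions do not dilute profiles.
#' With `rankScores` given, rows are ordered by descending score (the
#' conventional heatmap ranking, e.g. by SPO11-oligo density).
#'
#' @param regions `GRanges` or [PeakSet-class].
#' @param track A [SignalTrack-class].
#' @param flank Half-window in bp (default 5000); must be a multiple of
#'   `bin`.
#' @param bin Cell width in bp (default 50).
#' @param rankScores Optional numeric scores along `regions`.
#' @return Numeric matrix (rows = regions, columns = 2*flank/bin);
#'   attribute `order` gives the row permutation applied.
#' @export
matrixAround <- function(regions, track, flank = 5000L, bin = 50L,
                         rankScores = NULL) {
  if (flank %% bin != 0) stop("flank must be a multiple of bin")
  gr <- .gr(regions)
  ncol <- 2L * flank %/% bin
  center <- floor((start(gr) - 1 + end(gr)) / 2) + 1
  m <- matrix(NA_real_, nrow = length(gr), ncol = ncol)
  for (i in seq_along(gr)) {
    chrom <- as.character(seqnames(gr))[i]
    if (!chrom %in% names(track@bins)) next
    len <- track@chromLengths[[chrom]]
    cs <- center[i] - flank + (seq_len(ncol) - 1L) * bin
    ce <- cs + bin - 1L
    ok <- cs >= 1 & ce <= len
    if (any(ok))
      m[i, ok] <- regionMeanDensity(
        track, GRanges(chrom, IRanges(cs[ok], ce[ok])))
  }
  ord <- seq_along(gr)
  if (!is.null(rankScores)) {
    if (length(rankScores) != length(gr))
      stop("rankScores must match the region count")
    ord <- order(rankScores, decreasing = TRUE)
    m <- m[ord, , drop = FALSE]
  }
  attr(m, "order") <- ord
  m
}

#' Column means of a signal matrix, ignoring missing cells
#'
#' @param m Matrix from [matrixAround()]; must have at least one row.
#' @return Numeric vector of per-column means; columns that are all
#'   missing give NA.
#' @export
meanProfile <- function(m) {
  if (!nrow(m)) stop("matrix must have at least one row")
  out <- colMeans(m, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Write a track as bedGraph (equal-valued adjacent bins merged)
#' @param track A [SignalTrack-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeBedGraph <- function(track, path) {
  si <- Seqinfo(names(track@chromLengths),
                as.integer(track@chromLengths))
  recs <- lapply(names(track@bins), function(chrom) {
    v <- track@bins[[chrom]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    GRanges(chrom,
            IRanges((starts - 1L) * track@binSize + 1L,
                    pmin(ends * track@binSize,
                         track@chromLengths[[chrom]])),
            score = r$values, seqinfo = si)
  })
  gr <- do.call(c, recs)
  gr <- gr[mcols(gr)$score != 0]  # standard sparse compaction
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph into a SignalTrack
#'
#' Records are averaged per-base into the requested bin grid, so any
#' bedGraph (fixed-step or compacted) reconstructs the same dense track.
#'
#' @param path bedGraph path (0-based half-open records).
#' @param layout [GenomeLayout-class].
#' @param binSize Bin width in bp.
#' @param sample Sample label.
#' @return A [SignalTrack-class].
#' @export
readBedGraph <- function(path, layout, binSize = 50L, sample = "sample") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  lens <- chromLengths(layout)
  bins <- lapply(names(lens), function(chrom) {
    len <- lens[[chrom]]
    dc <- gr[as.character(seqnames(gr)) == chrom]
    v <- Rle(0, len)
    if (length(dc)) {
      # bedGraph records are disjoint; build the per-base vector by runs
      ord <- order(start(dc))
      dc <- dc[ord]
      gaps <- c(start(dc), len + 1L) - c(1L, end(dc) + 1L)
      vals <- as.numeric(rbind(0, c(mcols(dc)$score, 0)))
      runs <- as.integer(rbind(gaps, c(width(dc), 0L)))
      keep <- runs > 0
      v <- Rle(vals[keep], runs[keep])
    }
    starts <- seq(1, len, by = binSize)
    ends <- pmin(starts + binSize - 1, len)
    as.numeric(viewSums(Views(v, starts, ends))) / (ends - starts + 1)
  })
  names(bins) <- names(lens)
  signalTrack(bins, binSize, layout, sample = sample)
}
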