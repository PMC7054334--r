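# Shared fixtures and independent brute-force oracles.  Oracles here
# never call the code paths they check: overlaps are base-set
# intersections, coverage is a per-base pileup, the NDR oracle
# enumerates every window with stats::chisq.test and merges by sweep.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

tinyLayout <- function(sizes = c(chrA = 10000, chrB = 8000))
  genomeLayout(sizes)

randomIntervals <- function(n, layout, maxWidth = 500, minWidth = 10) {
  lens <- chromLengths(layout)
  chrom <- sample(names(lens), n, replace = TRUE)
  w <- sample(minWidth:maxWidth, n, replace = TRUE)
  s <- vapply(seq_len(n), function(i)
    sample.int(lens[[chrom[i]]] - w[i], 1), 1L)
  GRanges(chrom, IRanges(s, s + w - 1), seqinfo = asSeqinfo(layout))
}

# enumerate the bases an interval covers, as "chrom:pos" keys
baseKeys <- function(gr, i)
  paste0(as.character(seqnames(gr))[i], ":",
         seq(start(gr)[i], end(gr)[i]))

# shared bases between interval i of a and interval j of b
oracleSharedBases <- function(a, i, b, j)
  length(intersect(baseKeys(a, i), baseKeys(b, j)))

# per-base pileup of extended fragments, then mean per bin
oraclePileup <- function(frags, layout, extension = 150, binSize = 50) {
  lens <- chromLengths(layout)
  depth <- lapply(lens, function(l) numeric(l))
  for (k in seq_len(nrow(frags))) {
    ch <- frags$chrom[k]
    if (!ch %in% names(lens)) next
    p <- frags$pos[k]
    if (p < 1 || p > lens[[ch]]) next
    if (frags$strand[k] == "+") { s <- p; e <- p + extension - 1 }
    else { s <- p - extension + 1; e <- p }
    s <- max(s, 1); e <- min(e, lens[[ch]])
    depth[[ch]][s:e] <- depth[[ch]][s:e] + 1
  }
  lapply(names(lens), function(ch) {
    starts <- seq(1, lens[[ch]], by = binSize)
    ends <- pmin(starts + binSize - 1, lens[[ch]])
    vapply(seq_along(starts), function(i)
      mean(depth[[ch]][starts[i]:ends[i]]), 1)
  }) |> setNames(names(lens))
}

# brute-force NDR caller: every window at the sliding phase, 2x2
# chi-squared via stats::chisq.test, one-sidedness, sweep merge,
# post-merge filters
oracleNdrs <- function(tab, layout, pMax = 1e-10, minSites = 6,
                       minLen = 141, win = 100, step = 20) {
  d <- cytosineCalls(tab)
  d <- d[d$context == "GCH", , drop = FALSE]
  bgMeth <- sum(d$meth); bgTot <- sum(d$total)
  bgMean <- mean(d$meth / d$total)
  lens <- chromLengths(layout)
  sig <- NULL
  for (ch in names(lens)) {
    dc <- d[d$chrom == ch, , drop = FALSE]
    for (s in seq(1, max(1, lens[[ch]] - win + 1), by = step)) {
      e <- min(s + win - 1, lens[[ch]])
      inw <- dc$pos >= s & dc$pos <= e
      if (!any(inw)) next
      m <- sum(dc$meth[inw]); t <- sum(dc$total[inw])
      if (t == 0) next
      if (mean(dc$meth[inw] / dc$total[inw]) <= bgMean) next
      tb <- matrix(c(m, t - m, bgMeth, bgTot - bgMeth), nrow = 2)
      p <- suppressWarnings(chisq.test(tb, correct = FALSE)$p.value)
      if (!is.na(p) && p <= pMax)
        sig <- rbind(sig, data.frame(chrom = ch, start = s, end = e,
                                     p = p))
    }
  }
  if (is.null(sig)) return(NULL)
  sig <- sig[order(sig$chrom, sig$start), ]
  out <- NULL
  cur <- sig[1, ]
  flush <- function(cur, out) rbind(out, cur)
  for (k in seq_len(nrow(sig))[-1]) {
    r <- sig[k, ]
    if (r$chrom == cur$chrom && r$start <= cur$end + 1) {
      cur$end <- max(cur$end, r$end)
      cur$p <- min(cur$p, r$p)
    } else { out <- flush(cur, out); cur <- r }
  }
  out <- flush(cur, out)
  keep <- logical(nrow(out))
  nS <- lvl <- numeric(nrow(out))
  for (k in seq_len(nrow(out))) {
    inr <- d$chrom == out$chrom[k] & d$pos >= out$start[k] &
      d$pos <= out$end[k]
    nS[k] <- sum(inr)
    lvl[k] <- mean((d$meth / d$total)[inr])
    keep[k] <- nS[k] >= minSites && (out$end[k] - out$start[k] + 1) >= minLen
  }
  out$nSites <- nS; out$meanLevel <- lvl
  out[keep, , drop = FALSE]
}

# a small random cytosine table with optional planted high regions
randomCytosineTable <- function(layout, spacing = 10, depthMin = 3,
                                depthMean = 10, bgLevel = 0.05,
                                high = NULL, highLevel = 0.5) {
  lens <- chromLengths(layout)
  tabs <- lapply(names(lens), function(ch) {
    pos <- seq(spacing, lens[[ch]], by = spacing)
    p <- rep(bgLevel, length(pos))
    if (!is.null(high)) {
      hi <- high[as.character(seqnames(high)) == ch]
      for (i in seq_along(hi))
        p[pos >= start(hi)[i] & pos <= end(hi)[i]] <- highLevel
    }
    depth <- depthMin + rpois(length(pos), depthMean - depthMin)
    data.frame(chrom = ch, pos = pos, strand = "+", context = "GCH",
               meth = rbinom(length(pos), depth, p), total = depth)
  })
  cytosineTable(do.call(rbind, tabs))
}

# exact two-sided Fisher p by direct hypergeometric enumeration
oracleFisherP <- function(tab) {
  m <- tab[1, 1] + tab[1, 2]   # row-1 margin
  n <- tab[2, 1] + tab[2, 2]
  k <- tab[1, 1] + tab[2, 1]   # col-1 margin
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  pObs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# one full simulator bundle shared across test files
.bundleCache <- new.env(parent = emptyenv())
sharedBundle <- function(seed = 2024) {
  key <- as.character(seed)
  if (is.null(.bundleCache[[key]]))
    .bundleCache[[key]] <- simulateBundle(simConfig(seed = seed))
  .bundleCache[[key]]
}
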