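test_that("trinucleotide context classification follows WCG/GCH rules", {
  expect_equal(classifyContext("A", "G"), "WCG")
  expect_equal(classifyContext("T", "G"), "WCG")
  expect_equal(classifyContext("G", "A"), "GCH")
  expect_equal(classifyContext("G", "C"), "GCH")
  expect_equal(classifyContext("G", "T"), "GCH")
  expect_equal(classifyContext("G", "G"), "other")  # GCG ambiguous
  expect_equal(classifyContext("C", "G"), "other")  # CCG ambiguous
  expect_equal(classifyContext(c("A", "G", "N"), c("G", "T", "A")),
               c("WCG", "GCH", "other"))
  expect_error(classifyContext("A", "G", cBase = "T"), "cytosine")
  expect_error(classifyContext("X", "G"), "bases")
})

test_that("site levels, depth filter and replicate merging", {
  tab <- cytosineTable(data.frame(
    chrom = "chrA", pos = c(10, 20, 30), strand = "+",
    context = c("GCH", "GCH", "WCG"),
    meth = c(3, 0, 2), total = c(4, 5, 2)))
  expect_equal(siteLevel(tab), c(0.75, 0, 1))
  expect_equal(siteLevel(tab, context = "GCH"), c(0.75, 0))
  f <- filterDepth(tab, 3)
  expect_equal(length(f), 2L)                # the depth-2 site is excluded
  expect_true(f@depthFiltered)

  rep2 <- cytosineTable(data.frame(
    chrom = "chrA", pos = c(10, 40), strand = "+",
    context = c("GCH", "GCH"), meth = c(1, 2), total = c(2, 4)))
  m <- mergeReplicates(tab, rep2)
  d <- cytosineCalls(m)
  expect_equal(d$meth[d$pos == 10], 4)
  expect_equal(d$total[d$pos == 10], 6)
  expect_equal(nrow(d), 4L)
  expect_error(cytosineTable(data.frame(chrom = "c", pos = 1, strand = "+",
                                        context = "GCH", meth = 5,
                                        total = 4)), "meth")
})

test_that("cytosine report reader derives context from trinucleotides", {
  f <- tempfile()
  writeLines(c("chrA\t10\t+\t3\t1\tACG",
               "chrA\t20\t+\t2\t2\tGCT",
               "chrA\t30\t+\t1\t0\tGCG",
               "chrA\t40\t-\t4\t0\tGCH"), f)
  tab <- readCytosineReport(f)
  d <- cytosineCalls(tab)
  expect_equal(d$context, c("WCG", "GCH", "other", "GCH"))
  expect_equal(d$total, c(4, 4, 1, 4))
  # write/read round-trip preserves values
  f2 <- tempfile()
  writeCytosineReport(tab, f2)
  d2 <- cytosineCalls(readCytosineReport(f2))
  expect_equal(d2$meth, d$meth)
  expect_equal(d2$pos, d$pos)
})

test_that("genome background pools counts and averages site levels", {
  tab <- cytosineTable(data.frame(
    chrom = "chrA", pos = c(10, 20), strand = "+", context = "GCH",
    meth = c(2, 4), total = c(10, 10)))
  bg <- genomeBackground(tab, "GCH")
  expect_equal(bg$mean, 0.3)          # unweighted mean of 0.2, 0.4
  expect_equal(bg$meth, 6)
  expect_equal(bg$total, 20)
  expect_error(genomeBackground(tab, "WCG"), "no WCG sites")
  set.seed(42)
  gl <- genomeLayout(c(chrA = 5e4))
  rt <- randomCytosineTable(gl)
  bg <- genomeBackground(rt, "GCH")
  d <- cytosineCalls(rt)
  expect_equal(bg$meth, sum(d$meth))
  expect_equal(bg$total, sum(d$total))
})

test_that("window scan matches chisq.test and enforces one-sidedness", {
  gl <- genomeLayout(c(chrA = 2000))
  set.seed(8)
  high <- GRanges("chrA", IRanges(501, 900))
  tab <- randomCytosineTable(gl, high = high, highLevel = 0.6)
  w <- scanWindows(tab, gl)
  expect_true(all(w$p >= 0 & w$p <= 1))
  bg <- genomeBackground(tab, "GCH")
  # any window with above-background level: p equals the chisq oracle
  hot <- which(w$meanLevel > bg$mean & w$total > 0)
  for (i in hot[seq(1, length(hot), length.out = min(8, length(hot)))]) {
    tb <- matrix(c(w$meth[i], w$total[i] - w$meth[i],
                   bg$meth, bg$total - bg$meth), nrow = 2)
    expect_equal(w$p[i],
                 suppressWarnings(chisq.test(tb, correct = FALSE)$p.value),
                 tolerance = 1e-9)
  }
  # at/below background -> p forced to 1
  expect_true(all(w$p[w$meanLevel <= bg$mean] == 1))
  # windows with no sites -> p = 1 and no site count
  empty <- w$nSites == 0
  if (any(empty)) expect_true(all(w$p[empty] == 1))
  # a strong window over a weak background is overwhelmingly significant
  strongest <- which.min(w$p)
  expect_lt(w$p[strongest], 1e-10)
})

test_that("NDR caller output is record-identical to the window-enumeration oracle", {
  for (seed in c(13, 77, 140)) {
    set.seed(seed)
    gl <- genomeLayout(c(chrA = 6e4, chrB = 4e4))
    nHigh <- sample(2:4, 1)
    high <- randomIntervals(nHigh, gl, maxWidth = 600, minWidth = 150)
    tab <- randomCytosineTable(gl, high = high, highLevel = 0.5)
    got <- callNdrs(tab, gl)
    want <- oracleNdrs(tab, gl)
    expect_equal(length(got), if (is.null(want)) 0L else nrow(want))
    if (!is.null(want) && length(got)) {
      expect_equal(as.character(seqnames(got)), want$chrom)
      expect_equal(start(got), want$start)
      expect_equal(end(got), want$end)
      expect_equal(mcols(got)$nSites, want$nSites)
      expect_equal(mcols(got)$meanLevel, want$meanLevel)
      expect_equal(mcols(got)$minP, want$p, tolerance = 1e-9)
    }
  }
})

test_that("merged-region filters reject short or sparse candidates", {
  gl <- genomeLayout(c(chrA = 2000))
  mkTab <- function(pos) cytosineTable(data.frame(
    chrom = "chrA", pos = pos, strand = "+", context = "GCH",
    meth = 10, total = 10))
  mkWin <- function(starts, sitesIn) data.frame(
    chrom = "chrA", start = starts, end = starts + 99,
    nSites = sitesIn, meth = 0, total = 0, meanLevel = 1, p = 1e-20)
  # merged width 120 (< 141): rejected despite significance
  tab <- mkTab(seq(5, 115, by = 18))   # 7 sites in [1,120]
  out <- callNdrs(tab, gl, windows = mkWin(c(1, 21), 7))
  expect_equal(length(out), 0L)
  # merged width 160 but exactly 5 sites: rejected
  tab5 <- mkTab(seq(10, 150, by = 35))  # 5 sites
  out5 <- callNdrs(tab5, gl, windows = mkWin(c(1, 21, 41, 61), 5))
  expect_equal(length(out5), 0L)
  # same span with 6 sites: accepted, and all criteria hold per record
  tab6 <- mkTab(seq(10, 160, by = 30))  # 6 sites
  out6 <- callNdrs(tab6, gl, windows = mkWin(c(1, 21, 41, 61), 6))
  expect_equal(length(out6), 1L)
  expect_gt(width(out6), 140)
  expect_gt(mcols(out6)$nSites, 5)
  expect_lte(mcols(out6)$minP, 1e-10)
})

test_that("tightening the p ceiling yields nested NDR sets", {
  set.seed(19)
  gl <- genomeLayout(c(chrA = 5e4))
  high <- randomIntervals(3, gl, maxWidth = 500, minWidth = 200)
  tab <- randomCytosineTable(gl, high = high, highLevel = 0.35)
  loose <- callNdrs(tab, gl, pMax = 1e-6)
  tight <- callNdrs(tab, gl, pMax = 1e-14)
  expect_true(all(overlapsAny(tight, loose)))
  expect_lte(length(tight), length(loose))
})

test_that("NDRs classify as proximal within 1.5 kb of a TSS, else distal", {
  gl <- genomeLayout(c(chrA = 1e5))
  si <- asSeqinfo(gl)
  tss <- GRanges("chrA", IRanges(50000, 50000), seqinfo = si)
  ndr <- function(s, e) GRanges("chrA", IRanges(s, e), seqinfo = si)
  near <- classifyNdr(ndr(48800, 49000), tss)   # 1.0 kb away
  expect_equal(mcols(near)$class, "proximal")
  far <- classifyNdr(ndr(52001, 52400), tss)    # 2.0 kb away
  expect_equal(mcols(far)$class, "distal")
  edge <- classifyNdr(ndr(48200, 48500), tss)   # ends exactly at -1.5 kb
  expect_equal(mcols(edge)$class, "proximal")
  expect_warning(none <- classifyNdr(ndr(1, 200), GRanges(seqinfo = si)),
                 "empty TSS")
  expect_equal(mcols(none)$class, "distal")
})

test_that("region levels are site-order invariant and need three sites", {
  gl <- genomeLayout(c(chrA = 1000))
  si <- asSeqinfo(gl)
  d <- data.frame(chrom = "chrA", pos = c(100, 200, 300), strand = "+",
                  context = "GCH", meth = c(2, 4, 6), total = 10)
  tab <- cytosineTable(d)
  region <- GRanges("chrA", IRanges(1, 1000), seqinfo = si)
  expect_equal(regionLevel(region, tab), 0.4)   # mean of .2 .4 .6
  shuf <- cytosineTable(d[c(3, 1, 2), ])
  expect_equal(regionLevel(region, tab), regionLevel(region, shuf))
  # two sites only: undefined, propagated as NA
  two <- GRanges("chrA", IRanges(1, 250), seqinfo = si)
  expect_true(is.na(regionLevel(two, tab)))
  # whole genome equals the background mean
  expect_equal(regionLevel(region, tab),
               genomeBackground(tab, "GCH")$mean)
})

test_that("accessibility ratio is region level over genome level", {
  set.seed(55)
  gl <- genomeLayout(c(chrA = 2e4))
  tab <- randomCytosineTable(gl)
  genome <- GRanges("chrA", IRanges(1, 2e4), seqinfo = asSeqinfo(gl))
  expect_equal(accessibilityRatio(genome, tab), 1.0)
  tab2 <- cytosineTable(data.frame(
    chrom = "chrA", pos = seq(10, 100, by = 10), strand = "+",
    context = "GCH", meth = c(rep(1, 5), rep(2, 5)), total = 20))
  # region holds the level-0.10 sites; genome mean is 0.075
  reg <- GRanges("chrA", IRanges(51, 100), seqinfo = asSeqinfo(gl))
  expect_equal(accessibilityRatio(reg, tab2), 0.10 / 0.075)
})

test_that("hotspot partition uses the center-base rule", {
  gl <- genomeLayout(c(chrA = 1e5))
  si <- asSeqinfo(gl)
  hs <- GRanges("chrA", IRanges(c(1000, 30000), c(1999, 30999)),
                seqinfo = si)
  none <- hotspotNdrPartition(hs, GRanges(seqinfo = si))
  expect_equal(none$nWithin, 0L)
  expect_equal(none$fracWithin, 0)
  # NDR covering the center of hotspot 1 only; distal class
  ndr <- GRanges("chrA", IRanges(1400, 1600), seqinfo = si)
  mcols(ndr)$class <- "distal"
  part <- hotspotNdrPartition(hs, ndr)
  expect_equal(part$nWithin, 1L)
  expect_equal(part$withinDistal, 1L)
  expect_equal(part$withinProximal, 0L)
  # NDR touching hotspot 2 but not its center base (center = 30500)
  edgeNdr <- GRanges("chrA", IRanges(30000, 30100), seqinfo = si)
  expect_equal(hotspotNdrPartition(hs[2], edgeNdr)$nWithin, 0L)
})
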