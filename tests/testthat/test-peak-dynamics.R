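mkSeries <- function(gl, ...) {
  args <- list(...)
  lapply(setNames(names(args), names(args)), function(st)
    peakSet(args[[st]], "H3K4me3", st))
}

test_that("de novo / common split partitions the target set", {
  gl <- tinyLayout()
  si <- asSeqinfo(gl)
  p1 <- GRanges("chrA", IRanges(100, 200), seqinfo = si)  # overlaps B-stage
  p2 <- GRanges("chrA", IRanges(5000, 5100), seqinfo = si)
  series <- mkSeries(gl, B = GRanges("chrA", IRanges(150, 250),
                                     seqinfo = si),
                     mZ = c(p1, p2))
  sp <- splitDeNovo(series, "mZ")
  expect_equal(start(peakRanges(sp$deNovo)), 5000L)
  expect_equal(start(peakRanges(sp$common)), 100L)

  # empty priors: everything de novo
  series$B <- peakSet(GRanges(seqinfo = si), "H3K4me3", "B")
  sp <- splitDeNovo(series, "mZ")
  expect_equal(length(sp$deNovo), 2L)
  expect_equal(length(sp$common), 0L)

  expect_error(splitDeNovo(series, "mZ", priorStages = "lZ"),
               "strictly earlier")
  expect_error(splitDeNovo(series, "e1P"), "missing")

  # partition property on random sets
  set.seed(21)
  for (rep in 1:5) {
    series <- mkSeries(gl, B = randomIntervals(25, gl),
                       L = randomIntervals(25, gl),
                       mZ = randomIntervals(40, gl))
    sp <- splitDeNovo(series, "mZ")
    both <- sort(unique(c(peakRanges(sp$deNovo), peakRanges(sp$common))))
    expect_identical(granges(both), granges(peakRanges(series$mZ)))
    expect_false(any(overlapsIntervals(sp$deNovo, series$B)) ||
                 any(overlapsIntervals(sp$deNovo, series$L)))
    if (length(sp$common))
      expect_true(all(overlapsIntervals(sp$common, series$B) |
                      overlapsIntervals(sp$common, series$L)))
    expect_equal(length(sp$deNovo) + length(sp$common), 40L)
  }
})

test_that("hotspot association matches an all-pairs overlap scan", {
  gl <- tinyLayout()
  si <- asSeqinfo(gl)
  pk <- GRanges("chrA", IRanges(101, 200), seqinfo = si)   # BED [100,200)
  hs <- GRanges("chrA", IRanges(201, 300), seqinfo = si)   # BED [200,300)
  expect_equal(length(hotspotAssociated(pk, hs)), 0L)  # abutting excluded
  expect_warning(out <- hotspotAssociated(pk, GRanges(seqinfo = si)),
                 "empty hotspot")
  expect_equal(length(out), 0L)

  set.seed(5)
  peaks <- randomIntervals(50, gl)
  hsr <- randomIntervals(30, gl)
  got <- hotspotAssociated(peaks, hsr)
  want <- vapply(seq_along(peaks), function(i)
    any(vapply(seq_along(hsr), function(j)
      oracleSharedBases(peaks, i, hsr, j) >= 1, TRUE)), TRUE)
  expect_identical(granges(got), granges(peaks[want]))  # input order kept
  # association map points at truly overlapped hotspots
  ids <- as.integer(unlist(strsplit(mcols(got)$hotspotIds[1], ",")))
  expect_true(all(overlapsIntervals(hsr[ids], got[1])))
})

test_that("presence matrix equals cell-wise overlap calls", {
  gl <- tinyLayout()
  si <- asSeqinfo(gl)
  ref <- GRanges("chrA", IRanges(1000, 1500), seqinfo = si)
  series <- mkSeries(gl,
    L = GRanges("chrB", IRanges(1, 100), seqinfo = si),
    mZ = GRanges("chrA", IRanges(1100, 1200), seqinfo = si),
    lZ = GRanges("chrA", IRanges(1499, 1600), seqinfo = si),
    e1P = GRanges("chrA", IRanges(1501, 1600), seqinfo = si))  # abuts only
  m <- buildPresenceMatrix(ref, series, c("L", "mZ", "lZ", "e1P"))
  expect_equal(m[1, ], c(L = FALSE, mZ = TRUE, lZ = TRUE, e1P = FALSE))

  m0 <- buildPresenceMatrix(GRanges(seqinfo = si), series,
                            c("L", "mZ"))
  expect_equal(nrow(m0), 0L)
  expect_error(buildPresenceMatrix(ref, series, c("mZ", "L")),
               "order")
  expect_error(buildPresenceMatrix(ref, series, c("L", "eZ")), "missing")

  set.seed(31)
  ref <- randomIntervals(30, gl)
  series <- mkSeries(gl, L = randomIntervals(20, gl),
                     mZ = randomIntervals(20, gl))
  m <- buildPresenceMatrix(ref, series, c("L", "mZ"))
  for (st in c("L", "mZ"))
    expect_equal(unname(m[, st]),
                 unname(overlapsIntervals(ref, series[[st]])))
})

test_that("turnover classification implements the four presence patterns", {
  pats <- rbind(early  = c(1, 1, 1, 1),
                early2 = c(1, 1, 0, 0),   # L presence dominates
                fast   = c(0, 1, 0, 0),
                slow   = c(0, 1, 1, 0),
                pers   = c(0, 1, 1, 1),
                reapp  = c(0, 1, 0, 1))   # absent then back: unclassified
  m <- matrix(pats == 1, ncol = 4,
              dimnames = list(NULL, c("L", "mZ", "lZ", "e1P")))
  lab <- classifyDynamics(m)
  expect_equal(as.character(lab),
               c("early_forming", "early_forming", "fast_turnover",
                 "slow_turnover", "persistent", "unclassified"))
  # invariant to row order; counts always sum to n
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(as.character(classifyDynamics(m[perm, ])),
               as.character(lab)[perm])
  expect_equal(sum(table(lab)), nrow(m))
  # mZ precondition
  bad <- m; bad[2, "mZ"] <- FALSE
  expect_error(classifyDynamics(bad), "mZ")
  expect_error(classifyDynamics(m[, c("L", "mZ", "lZ")]), "columns")
})

test_that("dynamics report counts and width summaries are self-consistent", {
  gl <- tinyLayout()
  set.seed(12)
  ref <- randomIntervals(20, gl)
  lab <- factor(sample(dynamicsLevels()[1:4], 20, replace = TRUE),
                levels = dynamicsLevels())
  rep <- dynamicsReport(ref, lab)
  expect_equal(sum(rep$counts), 20)
  for (cl in levels(lab)[table(lab) > 0])
    expect_equal(rep$widthMean[[cl]],
                 mean(width(ref)[lab == cl]))
})

test_that("H3K9me2 dip rule compares hotspot density with 2w flanks", {
  gl <- genomeLayout(c(chr = 10000))
  # track: density 3 everywhere except 1 inside [4001,4500]
  bins <- rep(3, 200)
  bins[81:90] <- 1   # bins covering 4001-4500
  tr <- signalTrack(list(chr = bins), 50, gl)
  hs <- GRanges("chr", IRanges(4001, 4500),
                seqinfo = asSeqinfo(gl))
  dip <- h3k9me2Dip(hs, tr)
  expect_equal(length(dip), 1L)
  expect_equal(mcols(dip)$ratio, 1 / 3)
  # equal means: not a dip
  flat <- signalTrack(list(chr = rep(2, 200)), 50, gl)
  expect_equal(length(h3k9me2Dip(hs, flat)), 0L)
  # flat zero: undefined ratio, skipped with warning
  zero <- signalTrack(list(chr = rep(0, 200)), 50, gl)
  expect_warning(out <- h3k9me2Dip(hs, zero), "skipped")
  expect_equal(length(out), 0L)
})

test_that("spatial Fisher test reproduces hypergeometric enumeration", {
  # layout of 100 1-kb bins; craft sets giving the table (10,5;5,80)
  gl <- genomeLayout(c(chr = 1e5))
  si <- asSeqinfo(gl)
  binAt <- function(i) GRanges("chr", IRanges((i - 1) * 1000 + 1, i * 1000),
                               seqinfo = si)
  A <- do.call(c, lapply(1:15, binAt))          # bins 1-15
  B <- do.call(c, lapply(c(1:10, 16:20), binAt))
  ft <- fisherOverlapTest(A, B, gl, binSize = 1000)
  expect_equal(as.vector(ft$table), c(10, 5, 5, 80))
  expect_equal(ft$pValue, oracleFisherP(ft$table), tolerance = 1e-12)
  # identity: infinite odds ratio, minimal p
  ftAA <- fisherOverlapTest(A, A, gl, binSize = 1000)
  expect_true(is.infinite(ftAA$oddsRatio))
  expect_lt(ftAA$pValue, 1e-10)
  expect_error(fisherOverlapTest(A, GRanges(seqinfo = si), gl), "non-empty")
})

test_that("overlap summary tabulates membership patterns of the reference", {
  gl <- tinyLayout()
  si <- asSeqinfo(gl)
  a <- GRanges("chrA", IRanges(c(100, 1000), c(200, 1100)), seqinfo = si)
  b <- GRanges("chrA", IRanges(150, 250), seqinfo = si)
  c3 <- GRanges("chrB", IRanges(100, 200), seqinfo = si)
  # disjoint: no intersection class populated
  disj <- overlapSummary(list(a, c3))
  expect_equal(unname(disj$reference["11"]), 0L)
  expect_equal(unname(disj$reference["10"]), 2L)
  # identical: only the full-intersection class
  same <- overlapSummary(list(a, a, a))
  expect_equal(unname(same$reference["111"]), 2L)
  expect_equal(sum(same$reference), 2L)
  expect_equal(unname(same$outsideReference), c(0L, 0L))
  # random sets vs per-peak membership oracle
  set.seed(9)
  x <- randomIntervals(25, gl); y <- randomIntervals(25, gl)
  z <- randomIntervals(25, gl)
  got <- overlapSummary(list(x, y, z))
  pat <- paste0("1", as.integer(overlapsIntervals(x, y)),
                as.integer(overlapsIntervals(x, z)))
  for (p in names(got$reference))
    expect_equal(unname(got$reference[p]), sum(pat == p))
  expect_error(overlapSummary(list(x)), "2 or 3")
  expect_error(overlapSummary(list(x, y, z, x)), "2 or 3")
})
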