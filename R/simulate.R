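# Seeded synthetic-data generator: a miniature genome with planted
# DSB hotspots, a stage series of H3K4me3 peaks realizing the four
# turnover classes, NOMe cytosine tables with planted NDRs, fragment
# sets with spike-in counts, and the ground truth all of it is tested
# against.
#
# Defaults echo the relative structure of stage-synchronized mouse
# spermatocyte data at desk scale: the four turnover classes at the
# ratio 27:24:10:40 (the full-depth study counts 2700/2369/1036/4032
# scaled down 100-fold), class width means ordered early-forming >
# persistent > slow-turnover > fast-turnover, heavy-tailed hotspot
# strengths, and NDR effect sizes of GCH 0.5 inside vs 0.05 background
# at ~10x depth and 10-bp site spacing.

#' Simulation configuration with study-scale defaults
#'
#' @param seed Master seed (mandatory).  Each generator component
#'   (genome, peaks, NOMe, signal) derives its own fixed offset stream
#'   from it, so adding one component never perturbs another.
#' @param chromSizes Named chromosome lengths (default three 2-Mb
#'   autosomes).
#' @param classCounts Planted peaks per turnover class.
#' @param classWidthMeans Mean mid-zygotene peak width per class, bp.
#' @param nCommon,nTss Common promoter peaks and TSS count.
#' @param nHotspots DSB hotspot count (must be >= sum(classCounts)).
#' @param nDistractors Non-hotspot de novo peaks added at mid-zygotene.
#' @param hotspotWidthShape,hotspotWidthScale Gamma parameters of
#'   hotspot widths (default mean 600 bp).
#' @param strengthShape,strengthScale Gamma parameters of the
#'   heavy-tailed hotspot strength distribution.
#' @param commonWidth Width of promoter peaks, bp.
#' @param minSpacing Minimum spacing between planted features, bp.
#' @param nNdr,ndrWidth Planted NDR count and width (bp).
#' @param ndrHotspotFraction Fraction of hotspots carrying an NDR at
#'   their center (the study-scale minority).
#' @param gchSpacing,wcgSpacing Site spacing in bp.
#' @param gchInside,gchOutside,wcgLevel Beta (shape1, shape2) pairs for
#'   per-site methylation probabilities: accessibility inside planted
#'   NDRs (mean 0.5), genome background (mean 0.05) and endogenous CpG
#'   methylation (mean 0.7).
#' @param hotspotAccessFold Fold elevation of GCH accessibility inside
#'   hotspots over background (applied only when hotspots are passed to
#'   [simulateNome()]).
#' @param depthMin,depthMean Per-site read depth: `depthMin` plus a
#'   Poisson draw with mean `depthMean - depthMin`.
#' @param fragmentsPerStage ChIP fragments simulated per stage track.
#' @param noise Fraction of fragments placed uniformly rather than in
#'   peaks.
#' @param dipDepletion Fractional H3K9me2 depletion inside hotspots.
#' @param extension,binSize Fragment extension and track bin size, bp.
#' @param spikeRange Range of spike-in read counts per sample.
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(seed,
                      chromSizes = c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6),
                      classCounts = c(early_forming = 27, fast_turnover = 24,
                                      slow_turnover = 10, persistent = 40),
                      classWidthMeans = c(early_forming = 2000,
                                          fast_turnover = 800,
                                          slow_turnover = 1100,
                                          persistent = 1400),
                      nCommon = 30, nTss = 30, nHotspots = 120,
                      nDistractors = 20,
                      hotspotWidthShape = 4, hotspotWidthScale = 150,
                      strengthShape = 0.8, strengthScale = 10,
                      commonWidth = 1500, minSpacing = 6000,
                      nNdr = 40, ndrWidth = 400,
                      ndrHotspotFraction = 0.142,
                      gchSpacing = 10, wcgSpacing = 100,
                      gchInside = c(50, 50), gchOutside = c(5, 95),
                      wcgLevel = c(21, 9), hotspotAccessFold = 3,
                      depthMin = 3, depthMean = 10,
                      fragmentsPerStage = 20000, noise = 0.1,
                      dipDepletion = 0.8,
                      extension = 150, binSize = 50,
                      spikeRange = c(5000, 20000)) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg[c("classCounts", "nCommon", "nTss", "nHotspots",
                             "nDistractors", "nNdr")]) >= 0),
            nHotspots >= sum(classCounts),
            ndrHotspotFraction >= 0, ndrHotspotFraction <= 1,
            noise >= 0, noise <= 1, depthMin >= 1)
  class(cfg) <- "SimConfig"
  cfg
}

# fixed offset streams per component; all < 2^31
.componentSeed <- function(cfg, k)
  (as.integer(cfg$seed) %% 100000000L) * 10L + k

# draw n positions with minimum pairwise spacing, also away from `avoid`
.placePositions <- function(n, lens, minSpacing, avoid = NULL) {
  si <- Seqinfo(names(lens), as.integer(lens))
  if (n == 0) return(GRanges(seqinfo = si))
  taken <- if (is.null(avoid)) GRanges(seqinfo = si)
           else GRanges(seqnames(avoid),
                        IRanges(start(avoid), end(avoid)), seqinfo = si)
  out <- GRanges(seqinfo = si)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 200L * n)
      stop("genome too small to host the requested features at the ",
           "configured spacing")
    chrom <- sample(names(lens), 1, prob = lens / sum(lens))
    pos <- sample.int(lens[[chrom]] - 2L * minSpacing, 1) + minSpacing
    cand <- GRanges(chrom, IRanges(pos, pos), seqinfo = si)
    pad <- GRanges(chrom, IRanges(pos - minSpacing, pos + minSpacing),
                   seqinfo = si)
    if (!overlapsAny(pad, taken) && !overlapsAny(pad, out))
      out <- c(out, cand)
  }
  sortRanges(out)
}

#' Simulate the miniature genome: layout and TSS positions
#'
#' TSS are placed uniformly with minimum spacing; deterministic for a
#' given seed.
#'
#' @param config A [simConfig()] object.
#' @return List with `layout` ([GenomeLayout-class]) and `tss`
#'   (width-1 `GRanges`).
#' @export
simulateGenome <- function(config) {
  set.seed(.componentSeed(config, 0L))
  layout <- genomeLayout(config$chromSizes)
  tss <- .placePositions(config$nTss, chromLengths(layout),
                         config$minSpacing)
  list(layout = layout, tss = tss)
}

#' Simulate DSB hotspots with heavy-tailed strengths
#'
#' @param config A [simConfig()] object.
#' @param layout [GenomeLayout-class].
#' @param tss TSS positions to keep clear of.
#' @return `GRanges` with metadata column `strength`.
#' @export
simulateHotspots <- function(config, layout, tss) {
  set.seed(.componentSeed(config, 1L))
  lens <- chromLengths(layout)
  centers <- .placePositions(config$nHotspots, lens, config$minSpacing,
                             avoid = tss)
  w <- pmax(100, round(rgamma(length(centers), config$hotspotWidthShape,
                              scale = config$hotspotWidthScale)))
  hs <- GRanges(seqnames(centers),
                IRanges(pmax(start(centers) - floor(w / 2), 1),
                        pmin(start(centers) + ceiling(w / 2) - 1,
                             lens[as.character(seqnames(centers))])),
                seqinfo = asSeqinfo(layout))
  mcols(hs)$strength <- rgamma(length(hs), config$strengthShape,
                               scale = config$strengthScale)
  hs
}

# stage presence pattern per turnover class, over the classified stages
.classPattern <- function() {
  list(early_forming = c("L", "mZ", "lZ", "e1P"),
       fast_turnover = c("mZ"),
       slow_turnover = c("mZ", "lZ"),
       persistent = c("mZ", "lZ", "e1P"))
}

#' Simulate the stage series of H3K4me3 peaks with planted classes
#'
#' Hotspot-associated peaks realize the four turnover classes at their
#' assigned hotspots (early-forming present L through e1P; fast-turnover
#' mZ only; slow-turnover mZ and lZ; persistent mZ through e1P); common
#' promoter peaks sit at TSS in every stage, including the premeiotic
#' ones; non-hotspot de novo distractor peaks are added at mid-zygotene.
#' Peak widths are drawn per class with the configured ordering and
#' centers jitter slightly between stages.
#'
#' @param config A [simConfig()] object.
#' @param layout [GenomeLayout-class].
#' @param hotspots `GRanges` from [simulateHotspots()].
#' @param tss TSS `GRanges`.
#' @return List with `peakSets` (named list of [PeakSet-class] over
#'   stages Undiff..e1P) and `truth` (data.frame: hotspot index, class,
#'   mid-zygotene peak start/end).
#' @export
simulateStagePeaks <- function(config, layout, hotspots, tss) {
  set.seed(.componentSeed(config, 2L))
  lens <- chromLengths(layout)
  nClass <- config$classCounts
  if (sum(nClass) > length(hotspots))
    stop("class counts exceed the hotspot count")
  classes <- rep(names(nClass), nClass)
  hsIdx <- sample(seq_along(hotspots), sum(nClass))
  widths <- pmax(200, round(rnorm(length(classes),
                                  config$classWidthMeans[classes],
                                  0.15 * config$classWidthMeans[classes])))
  centers <- floor((start(hotspots)[hsIdx] - 1 + end(hotspots)[hsIdx]) / 2) + 1
  chrom <- as.character(seqnames(hotspots))[hsIdx]
  stages <- c("Undiff", "A1", "B", "mpL", "L", "mZ", "lZ", "e1P")
  pattern <- .classPattern()
  # distractors: de novo mZ peaks away from hotspots and TSS
  distr <- .placePositions(config$nDistractors, lens, config$minSpacing,
                           avoid = c(granges(hotspots), granges(tss)))
  distrW <- pmax(200, round(rnorm(length(distr), 700, 100)))
  mk <- function(ch, ctr, w) {
    GRanges(ch, IRanges(pmax(ctr - floor(w / 2), 1),
                        pmin(ctr + ceiling(w / 2) - 1, lens[ch])),
            seqinfo = asSeqinfo(layout))
  }
  peakSets <- list()
  truthMz <- NULL
  for (st in stages) {
    grs <- GRanges(seqinfo = asSeqinfo(layout))
    if (config$nCommon > 0 && length(tss)) {
      at <- head(seq_along(tss), config$nCommon)
      jit <- sample(-50:50, length(at), replace = TRUE)
      grs <- c(grs, mk(as.character(seqnames(tss))[at],
                       start(tss)[at] + jit,
                       rep(config$commonWidth, length(at))))
    }
    present <- vapply(classes, function(cl) st %in% pattern[[cl]], TRUE)
    if (any(present)) {
      jit <- sample(-50:50, sum(present), replace = TRUE)
      g <- mk(chrom[present], centers[present] + jit, widths[present])
      if (st == "mZ")
        truthMz <- data.frame(hotspot = hsIdx[present],
                              class = classes[present],
                              start = start(g), end = end(g),
                              chrom = chrom[present])
      grs <- c(grs, g)
    }
    if (st == "mZ" && length(distr))
      grs <- c(grs, mk(as.character(seqnames(distr)), start(distr), distrW))
    peakSets[[st]] <- peakSet(grs, "H3K4me3", st)
  }
  list(peakSets = peakSets, truth = truthMz)
}

#' Simulate planted NDR intervals
#'
#' A configured fraction of hotspots receive an NDR centered on them;
#' the remainder are placed away from all features, half of them near a
#' TSS (so both proximal and distal classes are represented).
#'
#' @param config A [simConfig()] object.
#' @param layout [GenomeLayout-class].
#' @param hotspots `GRanges` (or NULL for a hotspot-free table).
#' @param tss TSS `GRanges`.
#' @return `GRanges` of planted NDRs (overlapping plants merged), with
#'   a logical metadata column `atHotspot`.
#' @export
simulateNdrTruth <- function(config, layout, hotspots = NULL, tss = NULL) {
  set.seed(.componentSeed(config, 3L))
  lens <- chromLengths(layout)
  w <- config$ndrWidth
  out <- GRanges(seqinfo = asSeqinfo(layout))
  nAtHs <- 0L
  if (!is.null(hotspots) && length(hotspots)) {
    nAtHs <- min(round(config$ndrHotspotFraction * length(hotspots)),
                 config$nNdr)
    at <- sample(seq_along(hotspots), nAtHs)
    ctr <- floor((start(hotspots)[at] - 1 + end(hotspots)[at]) / 2) + 1
    out <- c(out, GRanges(as.character(seqnames(hotspots))[at],
                          IRanges(ctr - floor(w / 2),
                                  ctr + ceiling(w / 2) - 1),
                          seqinfo = asSeqinfo(layout)))
  }
  nFree <- config$nNdr - nAtHs
  if (nFree > 0) {
    nNearTss <- if (!is.null(tss) && length(tss)) min(nFree %/% 2,
                                                      length(tss)) else 0L
    if (nNearTss > 0) {
      at <- sample(seq_along(tss), nNearTss)
      off <- sample(200:1000, nNearTss, replace = TRUE) *
        sample(c(-1L, 1L), nNearTss, replace = TRUE)
      ctr <- start(tss)[at] + off
      out <- c(out, GRanges(as.character(seqnames(tss))[at],
                            IRanges(ctr - floor(w / 2),
                                    ctr + ceiling(w / 2) - 1),
                            seqinfo = asSeqinfo(layout)))
    }
    avoid <- c(if (!is.null(hotspots)) granges(hotspots) else GRanges(),
               if (!is.null(tss)) granges(tss) else GRanges())
    free <- .placePositions(nFree - nNearTss, lens, config$minSpacing,
                            avoid = c(avoid, granges(out)))
    if (length(free))
      out <- c(out, GRanges(seqnames(free),
                            IRanges(start(free) - floor(w / 2),
                                    start(free) + ceiling(w / 2) - 1),
                            seqinfo = asSeqinfo(layout)))
  }
  out <- trim(out)
  merged <- reduce(sortRanges(out))  # overlapping plants merge in truth
  if (!is.null(hotspots) && length(hotspots))
    mcols(merged)$atHotspot <- overlapsAny(merged, hotspots)
  else mcols(merged)$atHotspot <- rep(FALSE, length(merged))
  merged
}

#' Simulate a NOMe-seq cytosine table with planted NDRs
#'
#' GCH sites are laid down at the configured spacing with per-site
#' methylation probability drawn from the inside beta within planted
#' NDRs and the background beta elsewhere; when hotspots are supplied,
#' sites inside hotspots (and outside NDRs) are elevated to
#' `hotspotAccessFold` times the background mean.  WCG sites carry the
#' endogenous methylation background.  Per-site depth is `depthMin`
#' plus a Poisson draw.
#'
#' @param config A [simConfig()] object.
#' @param layout [GenomeLayout-class].
#' @param ndrTruth `GRanges` of planted NDRs (see [simulateNdrTruth()]).
#' @param hotspots Optional `GRanges`; enables hotspot accessibility
#'   elevation.
#' @return A depth-consistent, unfiltered [CytosineTable-class] (all
#'   sites already satisfy the 3x cutoff by construction of the depth
#'   model, but [filterDepth()] is still the documented gate).
#' @export
simulateNome <- function(config, layout, ndrTruth, hotspots = NULL) {
  set.seed(.componentSeed(config, 4L))
  lens <- chromLengths(layout)
  bgMean <- config$gchOutside[1] / sum(config$gchOutside)
  hsMean <- min(0.95, config$hotspotAccessFold * bgMean)
  conc <- 300  # tight beta around the hotspot elevation level
  tabs <- lapply(names(lens), function(chrom) {
    gpos <- seq(config$gchSpacing, lens[[chrom]], by = config$gchSpacing)
    pgr <- GRanges(chrom, IRanges(gpos, gpos))
    inNdr <- overlapsAny(pgr, ndrTruth)
    p <- rbeta(length(gpos), config$gchOutside[1], config$gchOutside[2])
    if (!is.null(hotspots)) {
      inHs <- overlapsAny(pgr, hotspots) & !inNdr
      p[inHs] <- rbeta(sum(inHs), hsMean * conc, (1 - hsMean) * conc)
    }
    p[inNdr] <- rbeta(sum(inNdr), config$gchInside[1], config$gchInside[2])
    depth <- config$depthMin +
      rpois(length(gpos), config$depthMean - config$depthMin)
    meth <- rbinom(length(gpos), depth, p)
    gch <- data.frame(chrom = chrom, pos = gpos, strand = "+",
                      context = "GCH", meth = meth, total = depth)
    wpos <- seq(config$wcgSpacing %/% 2, lens[[chrom]],
                by = config$wcgSpacing)
    wdepth <- config$depthMin +
      rpois(length(wpos), config$depthMean - config$depthMin)
    wp <- rbeta(length(wpos), config$wcgLevel[1], config$wcgLevel[2])
    wcg <- data.frame(chrom = chrom, pos = wpos, strand = "+",
                      context = "WCG",
                      meth = rbinom(length(wpos), wdepth, wp),
                      total = wdepth)
    rbind(gch, wcg)
  })
  cytosineTable(do.call(rbind, tabs))
}

#' Simulate ChIP fragment sets and spike-in counts
#'
#' H3K4me3 fragments concentrate in each stage's peaks proportionally
#' to peak strength over a uniform background; an H3K9me2 fragment set
#' (leptotene) is depleted inside hotspots to plant dip regions.  Spike
#' counts are drawn per sample from the configured range.
#'
#' @param config A [simConfig()] object.
#' @param layout [GenomeLayout-class].
#' @param peakSets Named list of [PeakSet-class] from
#'   [simulateStagePeaks()].
#' @param hotspots `GRanges` of hotspots (for the H3K9me2 depletion).
#' @return List with `fragments` (named list of data.frames: chrom,
#'   pos, strand), `spikeCounts` (named vector over the same samples),
#'   and `peakStrengths` (per-stage numeric, the planted rates).
#' @export
simulateSignal <- function(config, layout, peakSets, hotspots) {
  set.seed(.componentSeed(config, 5L))
  lens <- chromLengths(layout)
  nFrag <- config$fragmentsPerStage
  sampleUniform <- function(n) {
    chrom <- sample(names(lens), n, replace = TRUE,
                    prob = lens / sum(lens))
    data.frame(chrom = chrom,
               pos = vapply(chrom, function(ch) sample.int(lens[[ch]], 1),
                            1L),
               strand = sample(c("+", "-"), n, replace = TRUE))
  }
  fragments <- list()
  strengths <- list()
  for (st in names(peakSets)) {
    gr <- peakRanges(peakSets[[st]])
    str <- rgamma(length(gr), config$strengthShape,
                  scale = config$strengthScale) + 0.5
    strengths[[st]] <- str
    nBg <- round(config$noise * nFrag)
    nPk <- nFrag - nBg
    if (length(gr) && nPk > 0) {
      pk <- sample(seq_along(gr), nPk, replace = TRUE,
                   prob = str * width(gr) / sum(str * width(gr)))
      pos <- start(gr)[pk] +
        floor(runif(nPk) * width(gr)[pk])
      inPeak <- data.frame(chrom = as.character(seqnames(gr))[pk],
                           pos = pos,
                           strand = sample(c("+", "-"), nPk,
                                           replace = TRUE))
    } else inPeak <- NULL
    fragments[[paste0("H3K4me3_", st)]] <-
      rbind(inPeak, if (nBg > 0) sampleUniform(nBg))
  }
  # H3K9me2 (leptotene): uniform background, depleted inside hotspots
  bg <- sampleUniform(nFrag)
  inHs <- overlapsAny(GRanges(bg$chrom, IRanges(bg$pos, bg$pos)), hotspots)
  drop <- inHs & runif(nFrag) < config$dipDepletion
  fragments[["H3K9me2_L"]] <- bg[!drop, , drop = FALSE]
  spike <- sample(seq(config$spikeRange[1], config$spikeRange[2]),
                  length(fragments), replace = TRUE)
  names(spike) <- names(fragments)
  list(fragments = fragments, spikeCounts = spike,
       peakStrengths = strengths)
}

#' Run the full generator under one configuration
#'
#' @param config A [simConfig()] object.
#' @return List of class `SimBundle`: `config`, `layout`, `tss`,
#'   `hotspots`, `peakSets`, `peakTruth`, `ndrTruth`, `nome`,
#'   `fragments`, `spikeCounts`, `peakStrengths`.
#' @export
simulateBundle <- function(config) {
  g <- simulateGenome(config)
  hotspots <- simulateHotspots(config, g$layout, g$tss)
  pk <- simulateStagePeaks(config, g$layout, hotspots, g$tss)
  ndrTruth <- simulateNdrTruth(config, g$layout, hotspots, g$tss)
  nome <- simulateNome(config, g$layout, ndrTruth, hotspots)
  sig <- simulateSignal(config, g$layout, pk$peakSets, hotspots)
  out <- list(config = config, layout = g$layout, tss = g$tss,
              hotspots = hotspots, peakSets = pk$peakSets,
              peakTruth = pk$truth, ndrTruth = ndrTruth, nome = nome,
              fragments = sig$fragments, spikeCounts = sig$spikeCounts,
              peakStrengths = sig$peakStrengths)
  class(out) <- "SimBundle"
  out
}

#' @export
print.SimBundle <- function(x, ...) {
  cat(sprintf(
    "SimBundle (seed %s): %d hotspots, %d stage peak sets, %d planted NDRs, %d cytosine sites\n",
    format(x$config$seed), length(x$hotspots), length(x$peakSets),
    length(x$ndrTruth), length(x$nome)))
  invisible(x)
}

#' Write a bundle to a fixture directory
#'
#' Emits chrom.sizes, TSS/hotspot/stage-peak BEDs, the cytosine TSV,
#' fragment TSVs, spike counts (JSON), truth tables, the config echo
#' (YAML) and an md5 manifest.
#'
#' @param bundle A `SimBundle` from [simulateBundle()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
writeBundle <- function(bundle, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir)
  lens <- chromLengths(bundle$layout)
  write.table(data.frame(names(lens), as.integer(lens)),
              file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeBed(bundle$tss, file.path(dir, "tss.bed"))
  hs <- bundle$hotspots
  mcols(hs)$name <- sprintf("hotspot_%d", seq_along(hs))
  mcols(hs)$score <- mcols(hs)$strength
  writeBed(hs, file.path(dir, "hotspots.bed"))
  for (st in names(bundle$peakSets))
    writeBed(bundle$peakSets[[st]],
             file.path(dir, sprintf("peaks_%s.bed", st)))
  writeCytosineReport(bundle$nome, file.path(dir, "cytosine_calls.tsv"))
  for (sm in names(bundle$fragments))
    writeFragments(bundle$fragments[[sm]],
                   file.path(dir, sprintf("fragments_%s.tsv", sm)))
  jsonlite::write_json(as.list(bundle$spikeCounts),
                       file.path(dir, "spike_counts.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(bundle$peakTruth, file.path(dir, "truth_peaks.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeBed(bundle$ndrTruth, file.path(dir, "truth_ndrs.bed"))
  cfg <- bundle$config
  class(cfg) <- NULL
  cfg$chromSizes <- as.list(cfg$chromSizes)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  files <- setdiff(list.files(dir), "manifest.json")
  sums <- tools::md5sum(file.path(dir, files))
  names(sums) <- files
  jsonlite::write_json(as.list(sums), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(file.path(dir, "manifest.json"))
}

#' Verify a bundle directory against its manifest
#' @param dir Bundle directory.
#' @return TRUE invisibly, or an error naming the mismatched file.
#' @export
verifyBundle <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  sums <- tools::md5sum(file.path(dir, names(man)))
  bad <- names(man)[is.na(sums) | sums != unlist(man)]
  if (length(bad))
    stop("manifest checksum mismatch: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Read a bundle directory back into memory
#' @param dir Bundle directory written by [writeBundle()].
#' @return A `SimBundle` list (config restored from the YAML echo).
#' @export
readBundle <- function(dir) {
  cfgList <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfgList <- lapply(cfgList, function(x) if (is.list(x)) unlist(x) else x)
  cfg <- do.call(simConfig, cfgList)
  layout <- readChromSizes(file.path(dir, "chrom.sizes"))
  tss <- peakRanges(readBed(file.path(dir, "tss.bed"), layout))
  hs <- peakRanges(readBed(file.path(dir, "hotspots.bed"), layout))
  mcols(hs)$strength <- mcols(hs)$score
  stageFiles <- list.files(dir, pattern = "^peaks_.*\\.bed$")
  stages <- sub("^peaks_(.*)\\.bed$", "\\1", stageFiles)
  peakSets <- setNames(lapply(seq_along(stages), function(i)
    readBed(file.path(dir, stageFiles[i]), layout, "H3K4me3",
            stages[i])), stages)
  peakSets <- peakSets[order(stageRank(names(peakSets)))]
  fragFiles <- list.files(dir, pattern = "^fragments_.*\\.tsv$")
  samples <- sub("^fragments_(.*)\\.tsv$", "\\1", fragFiles)
  fragments <- setNames(lapply(fragFiles, function(f)
    readFragments(file.path(dir, f))), samples)
  spike <- unlist(jsonlite::read_json(file.path(dir, "spike_counts.json"),
                                      simplifyVector = TRUE))
  out <- list(config = cfg, layout = layout, tss = tss, hotspots = hs,
              peakSets = peakSets,
              peakTruth = read.table(file.path(dir, "truth_peaks.tsv"),
                                     header = TRUE, sep = "\t"),
              ndrTruth = peakRanges(readBed(file.path(dir, "truth_ndrs.bed"),
                                            layout)),
              nome = readCytosineReport(file.path(dir,
                                                  "cytosine_calls.tsv")),
              fragments = fragments[order(names(fragments))],
              spikeCounts = spike[order(names(spike))])
  class(out) <- "SimBundle"
  out
}
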