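# Shared builders for the test suite: tiny genomes, probe series and runs
# kept small enough that every unit test is fast.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# a one/two-chromosome toy genome
toyGenome <- function() c(`1` = 50e6, `2` = 50e6)

# evenly spaced probes carrying a ratio vector on one chromosome
probeSeries <- function(ratio, chrom = "1", spacing = 1e5, start = 1e6,
                        genome = hg19Lengths()) {
  n <- length(ratio)
  pos <- seq(start, by = spacing, length.out = n)
  gr <- gi(rep(chrom, n), pos, pos + 59, genome = genome)
  mcols(gr)$ratio <- ratio
  gr
}

# a compact paired run on the toy genome: nArrays arrays, optional truth
# CNVs placed as list(arrayIndex, channel, cnvsGRanges)
toyRun <- function(nProbes = 1200, nArrays = 6, placements = list(),
                   noiseSd = 0.2, affinitySd = 0.2, seed = 1) {
  design <- makeDesign(nProbes, genome = toyGenome(), seed = seed)
  specs <- lapply(seq_len(2 * nArrays), function(i)
    sampleSpec(sprintf("S%02d", i)))
  for (pl in placements) {
    idx <- 2L * (pl$array - 1L) + if (pl$channel == "cy3") 1L else 2L
    specs[[idx]] <- sampleSpec(sprintf("S%02d", idx), cnvs = pl$cnvs)
  }
  pairs <- lapply(seq_len(nArrays), function(k)
    list(cy3 = specs[[2 * k - 1]], cy5 = specs[[2 * k]]))
  simulateRun(design, pairs, noiseSd = noiseSd, affinitySd = affinitySd,
              seed = seed + 1000L)
}

# truth CNV helper on the toy genome
toyCnv <- function(chrom, start, end, copies, fraction = 1,
                   genome = toyGenome()) {
  cnv <- gi(chrom, start, end, genome = genome)
  mcols(cnv)$copies <- as.integer(copies)
  mcols(cnv)$fraction <- fraction
  cnv
}

# reciprocal overlap of two length-1 GRanges
reciprocalOverlap <- function(a, b) {
  if (as.character(seqnames(a)) != as.character(seqnames(b))) return(0)
  ov <- min(end(a), end(b)) - max(start(a), start(b)) + 1
  if (ov <= 0) return(0)
  min(ov / width(a), ov / width(b))
}

sharedBands <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- readCytoband(systemBandFile())
    cache
  }
})
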