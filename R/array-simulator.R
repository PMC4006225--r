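# Synthetic paired-hybridization array runs with known truth CNVs.
# Emulates the production design: two differentially labelled diagnostic
# samples per 60K oligo array, several arrays batched per run so that every
# array has run-mates for channel disambiguation.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' ArrayDesign: probe layout of an array
#'
#' @slot probes Sorted \code{GRanges} of ~60 bp probes, names = probe ids.
#' @slot genome Named numeric vector of chromosome lengths.
#' @export
setClass("ArrayDesign", representation(probes = "GRanges",
                                       genome = "numeric"))

setValidity("ArrayDesign", function(object) {
  p <- object@probes
  if (anyDuplicated(names(p))) return("probe ids must be unique")
  if (!identical(order(match(as.character(seqnames(p)), .CHROMS),
                       start(p)), seq_along(p)))
    return("probes must be sorted by (chrom, start)")
  TRUE
})

setMethod("show", "ArrayDesign", function(object) {
  cat(sprintf("ArrayDesign: %d probes on %d chromosomes\n",
              length(object@probes),
              length(unique(seqnames(object@probes)))))
})

#' @rdname ArrayDesign-class
#' @param design An \code{ArrayDesign}.
#' @export
designProbes <- function(design) design@probes

#' PairedArray: one array, two co-hybridized samples
#'
#' @slot arrayId,runId Identifiers.
#' @slot cy3Sample,cy5Sample Sample ids per dye channel.
#' @slot cy3,cy5 Per-probe channel intensities (positive reals, design order).
#' @export
setClass("PairedArray", representation(
  arrayId = "character", runId = "character",
  cy3Sample = "character", cy5Sample = "character",
  cy3 = "numeric", cy5 = "numeric"))

setValidity("PairedArray", function(object) {
  if (length(object@cy3) != length(object@cy5))
    return("channel intensity vectors must have equal length")
  if (any(object@cy3 <= 0) || any(object@cy5 <= 0))
    return("intensities must be > 0")
  TRUE
})

setMethod("show", "PairedArray", function(object) {
  cat(sprintf("PairedArray %s (run %s): cy3=%s cy5=%s, %d probes\n",
              object@arrayId, object@runId, object@cy3Sample,
              object@cy5Sample, length(object@cy3)))
})

#' Per-probe log2(cy3/cy5) ratios of an array
#'
#' @param array A \code{PairedArray}.
#' @return Numeric vector in design probe order.
#' @export
log2Ratios <- function(array) log2(array@cy3 / array@cy5)

#' Run: arrays sharing one design and one hybridization batch
#'
#' @slot runId Identifier.
#' @slot design The shared \code{ArrayDesign}.
#' @slot arrays List of \code{PairedArray}.
#' @export
setClass("Run", representation(runId = "character", design = "ArrayDesign",
                               arrays = "list"))

setValidity("Run", function(object) {
  if (length(object@arrays) < 1L) return("a run needs at least one array")
  np <- length(object@design@probes)
  for (a in object@arrays) {
    if (!is(a, "PairedArray")) return("arrays must be PairedArray objects")
    if (length(a@cy3) != np)
      return("array intensity length does not match design")
  }
  TRUE
})

setMethod("show", "Run", function(object) {
  cat(sprintf("Run %s: %d arrays x %d probes\n", object@runId,
              length(object@arrays), length(object@design@probes)))
})

#' @rdname Run-class
#' @param run A \code{Run}.
#' @export
runArrays <- function(run) run@arrays

#' @rdname Run-class
#' @export
runDesign <- function(run) run@design

#' @rdname Run-class
#' @export
arrayIds <- function(run) vapply(run@arrays, function(a) a@arrayId, "")

#' Sample specification for simulation
#'
#' @param id Sample id.
#' @param sex "XX" or "XY".
#' @param cnvs \code{GRanges} of truth CNVs with mcols \code{copies}
#'   (integer target copies) and optional \code{fraction} (mosaic fraction
#'   in (0,1], default 1). Must be non-overlapping.
#' @return A list of class \code{SampleSpec}.
#' @export
sampleSpec <- function(id, sex = "XX", cnvs = NULL) {
  sex <- match.arg(sex, c("XX", "XY"))
  if (is.null(cnvs)) {
    cnvs <- GRanges()
    seqlevels(cnvs) <- .CHROMS
    mcols(cnvs)$copies <- integer(0)
    mcols(cnvs)$fraction <- numeric(0)
  } else {
    if (is.null(cnvs$copies)) stop("truth CNVs need a 'copies' mcol")
    if (is.null(cnvs$fraction)) mcols(cnvs)$fraction <- 1
    if (any(cnvs$fraction <= 0 | cnvs$fraction > 1))
      stop("mosaic fraction must be in (0, 1]")
    if (length(cnvs) > 1L &&
        any(countOverlaps(cnvs, cnvs) > 1L))
      stop("truth CNVs within one sample must not overlap")
  }
  structure(list(id = id, sex = sex, cnvs = cnvs), class = "SampleSpec")
}

#' Generate an array design
#'
#' Places \code{nProbes} ~60 bp probes uniformly at random across the
#' genome, with probe density multiplied by \code{boostFactor} inside
#' targeted regions (emulating a backbone + boosted-target layout).
#' Deterministic given \code{seed}.
#'
#' @param nProbes Number of probes (>= 2).
#' @param genome Named chromosome-length vector (default hg19).
#' @param targetedRegions Optional \code{GRanges} of boosted regions.
#' @param boostFactor Density multiplier inside targeted regions (>= 1).
#' @param seed Integer seed (optional).
#' @return An \code{ArrayDesign}.
#' @examples
#' d <- makeDesign(1000, seed = 1)
#' @export
makeDesign <- function(nProbes, genome = hg19Lengths(),
                       targetedRegions = NULL, boostFactor = 1L,
                       seed = NULL) {
  stopifnot(nProbes >= 2L, boostFactor >= 1L)
  .withSeed(seed, {
    segs <- gi(names(genome), 1, unname(genome), genome = genome)
    w <- as.numeric(width(segs))
    if (!is.null(targetedRegions) && boostFactor > 1L) {
      tr <- gi(as.character(seqnames(targetedRegions)),
               start(targetedRegions), end(targetedRegions),
               genome = genome)
      if (any(end(tr) > genome[as.character(seqnames(tr))]))
        stop("targeted region outside genome table")
      segs <- c(segs, tr)
      w <- c(w, as.numeric(width(tr)) * (boostFactor - 1))
    }
    pick <- sample.int(length(segs), nProbes, replace = TRUE, prob = w)
    pos <- floor(start(segs)[pick] +
                 runif(nProbes) * (width(segs)[pick] - 60)) + 1
    pos <- pmax(pos, 1)
    gr <- gi(as.character(seqnames(segs))[pick], pos, pos + 59,
             genome = genome)
    gr <- sort(gr)
    names(gr) <- sprintf("P%06d", seq_len(nProbes))
    new("ArrayDesign", probes = gr, genome = genome)
  })
}

# expected copies per probe for one sample (mosaic-blended, possibly 0)
.probeCopies <- function(design, spec) {
  ref <- referenceCopies(spec$sex)
  chrom <- as.character(seqnames(design@probes))
  eff <- refv <- unname(ref[chrom])
  cnvs <- spec$cnvs
  if (length(cnvs)) {
    ov <- findOverlaps(design@probes, cnvs)
    i <- queryHits(ov); j <- subjectHits(ov)
    f <- cnvs$fraction[j]
    eff[i] <- f * cnvs$copies[j] + (1 - f) * refv[i]
  }
  list(eff = eff, ref = refv)
}

#' Simulate a paired-hybridization run
#'
#' Intensity model, per probe i / array / channel:
#' \deqn{I = 2^{B + a_i} \cdot (c_i / r_i) \cdot 2^{\epsilon}}
#' where \eqn{a_i} is a per-probe affinity shared by every array in the run
#' (Gaussian, sd \code{affinitySd} log2 units), \eqn{c_i/r_i} the
#' mosaic-blended copy ratio of the channel's sample, and \eqn{\epsilon}
#' independent Gaussian noise (sd \code{noiseSd} log2 units). Zero-copy
#' probes (chrY in XX samples) fall to a small background factor.
#'
#' @param design An \code{ArrayDesign}.
#' @param pairs List of pairs; each element a list with \code{cy3} and
#'   \code{cy5} \code{SampleSpec}s.
#' @param noiseSd Per-channel log2 noise sd (>= 0; default 0.2).
#' @param affinitySd Shared per-probe affinity sd (default 0.2).
#' @param seed Integer seed (optional).
#' @param runId Run identifier.
#' @return list(run = \code{Run}, truth = \code{GRanges} with mcols
#'   \code{sample}, \code{arrayId}, \code{channel}, \code{copies},
#'   \code{fraction}).
#' @examples
#' d <- makeDesign(500, seed = 1)
#' del <- gi("2", 1e7, 3e7); del$copies <- 1L
#' p <- list(list(cy3 = sampleSpec("case", cnvs = del),
#'                cy5 = sampleSpec("ref")))
#' sim <- simulateRun(d, p, seed = 2)
#' @export
simulateRun <- function(design, pairs, noiseSd = 0.2, affinitySd = 0.2,
                        seed = NULL, runId = "R1") {
  stopifnot(length(pairs) >= 1L, noiseSd >= 0)
  .withSeed(seed, {
    np <- length(design@probes)
    affinity <- rnorm(np, 0, affinitySd)
    base <- 10  # log2 baseline intensity (~1000 units)
    bg <- 2^-5  # background copy factor for zero-copy probes
    arrays <- list()
    truthRows <- list()
    for (k in seq_along(pairs)) {
      pr <- pairs[[k]]
      stopifnot(is(pr$cy3, "SampleSpec"), is(pr$cy5, "SampleSpec"))
      arrayId <- sprintf("%s_A%d", runId, k)
      chans <- list(cy3 = pr$cy3, cy5 = pr$cy5)
      inten <- lapply(chans, function(spec) {
        cp <- .probeCopies(design, spec)
        fac <- ifelse(cp$ref > 0, cp$eff / cp$ref, bg)
        fac <- pmax(fac, bg)
        2^(base + affinity + log2(fac) + rnorm(np, 0, noiseSd))
      })
      arrays[[k]] <- new("PairedArray", arrayId = arrayId, runId = runId,
                         cy3Sample = pr$cy3$id, cy5Sample = pr$cy5$id,
                         cy3 = inten$cy3, cy5 = inten$cy5)
      for (ch in names(chans)) {
        cnvs <- chans[[ch]]$cnvs
        if (length(cnvs)) {
          t <- granges(cnvs)
          mcols(t) <- DataFrame(sample = chans[[ch]]$id, arrayId = arrayId,
                                channel = ch, copies = cnvs$copies,
                                fraction = cnvs$fraction)
          truthRows[[length(truthRows) + 1L]] <- t
        }
      }
    }
    truth <- if (length(truthRows))
      unlist(GRangesList(truthRows), use.names = FALSE)
    else {
      t <- GRanges(); seqlevels(t) <- .CHROMS
      mcols(t) <- DataFrame(sample = character(0), arrayId = character(0),
                            channel = character(0), copies = integer(0),
                            fraction = numeric(0))
      t
    }
    list(run = new("Run", runId = runId, design = design, arrays = arrays),
         truth = truth)
  })
}

#' Draw random truth CNVs snapped to probe spans
#'
#' Picks non-overlapping autosomal probe windows whose genomic span is
#' approximately uniform over \code{sizeRange}; each truth interval is the
#' exact span of its probes (boundary accuracy is probe-limited by design).
#'
#' @param design An \code{ArrayDesign}.
#' @param n Number of CNVs.
#' @param sizeRange bp range of CNV sizes (default 1-5 Mb, spanning the
#'   syndromic critical-region scale up to backbone-sized imbalances).
#' @param copies Integer vector of copy numbers to sample from (default
#'   heterozygous deletion 1 and duplication 3, equally likely).
#' @param seed Integer seed (optional).
#' @return \code{GRanges} with mcols \code{copies}, \code{fraction} (1) and
#'   \code{nProbes}.
#' @export
randomTruthCnvs <- function(design, n, sizeRange = c(1e6, 5e6),
                            copies = c(1L, 3L), seed = NULL) {
  .withSeed(seed, {
    p <- design@probes
    auto <- which(as.character(seqnames(p)) %in% as.character(1:22))
    chrom <- as.character(seqnames(p))
    out <- NULL
    guard <- 0L
    while ((is.null(out) || length(out) < n) && guard < 1000L) {
      guard <- guard + 1L
      size <- runif(1, sizeRange[1], sizeRange[2])
      i <- sample(auto, 1)
      ch <- chrom[i]
      j <- i
      while (j < length(p) && chrom[j + 1L] == ch &&
             end(p)[j] - start(p)[i] + 1 < size)
        j <- j + 1L
      if (chrom[j] != ch || end(p)[j] - start(p)[i] + 1 < size) next
      cand <- gi(ch, start(p)[i], end(p)[j], genome = design@genome)
      if (!is.null(out) && any(overlapsAny(cand, out))) next
      mcols(cand)$copies <- sample(copies, 1)
      mcols(cand)$fraction <- 1
      mcols(cand)$nProbes <- j - i + 1L
      out <- if (is.null(out)) cand else c(out, cand)
    }
    if (is.null(out) || length(out) < n)
      stop("could not place ", n, " non-overlapping CNVs")
    sort(out)
  })
}

#' Match a call against a truth table by reciprocal overlap
#'
#' Returns the truth CNV with the best reciprocal overlap >=
#' \code{minReciprocal} (ties: larger overlap, then smaller truth
#' interval), or NULL.
#'
#' @param call Length-1 \code{GRanges}.
#' @param truth \code{GRanges} truth table.
#' @param minReciprocal Fraction in (0, 1], default 0.5.
#' @return Length-1 \code{GRanges} (a truth row) or NULL.
#' @export
truthOverlap <- function(call, truth, minReciprocal = 0.5) {
  stopifnot(length(call) == 1L, minReciprocal > 0, minReciprocal <= 1)
  if (length(truth) == 0L) return(NULL)
  same <- as.character(seqnames(truth)) == as.character(seqnames(call))
  ovStart <- pmax(start(truth), start(call))
  ovEnd <- pmin(end(truth), end(call))
  ov <- ifelse(same, pmax(ovEnd - ovStart + 1, 0), 0)
  recip <- pmin(ov / intervalSize(call), ov / intervalSize(truth))
  ok <- which(recip >= minReciprocal)
  if (!length(ok)) return(NULL)
  best <- ok[order(-ov[ok], intervalSize(truth)[ok])][1]
  truth[best]
}

# -- IO ---------------------------------------------------------------------

#' Write / read probe matrices and run manifests
#'
#' The interchange format is one tab-delimited matrix per array (columns:
#' probe, chrom, start, end, cy3, cy5) plus a run manifest TSV (array_id,
#' cy3_sample, cy5_sample, file). \code{writeRun} emits both;
#' \code{readRun} reconstructs a \code{Run} (the design is taken from the
#' first matrix).
#'
#' @param run A \code{Run}.
#' @param dir Output directory (created if needed).
#' @return \code{writeRun}: the manifest path, invisibly. \code{readRun}: a
#'   \code{Run}.
#' @export
writeRun <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- run@design@probes
  files <- character(0)
  for (a in run@arrays) {
    d <- data.frame(probe = names(p), chrom = as.character(seqnames(p)),
                    start = start(p), end = end(p),
                    cy3 = a@cy3, cy5 = a@cy5)
    f <- file.path(dir, paste0(a@arrayId, ".tsv"))
    write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, basename(f))
  }
  man <- data.frame(
    array_id = arrayIds(run),
    cy3_sample = vapply(run@arrays, function(a) a@cy3Sample, ""),
    cy5_sample = vapply(run@arrays, function(a) a@cy5Sample, ""),
    file = files)
  mf <- file.path(dir, paste0(run@runId, ".manifest.tsv"))
  write.table(man, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mf)
}

#' @rdname writeRun
#' @param manifest Path to a run manifest TSV.
#' @param genome Chromosome-length table for the reconstructed design.
#' @export
readRun <- function(manifest, genome = hg19Lengths()) {
  man <- read.delim(manifest, colClasses = "character")
  dir <- dirname(manifest)
  runId <- sub("\\.manifest\\.tsv$", "", basename(manifest))
  design <- NULL
  arrays <- list()
  for (k in seq_len(nrow(man))) {
    d <- read.delim(file.path(dir, man$file[k]))
    if (is.null(design)) {
      gr <- gi(d$chrom, d$start, d$end, genome = genome)
      names(gr) <- d$probe
      design <- new("ArrayDesign", probes = gr, genome = genome)
    }
    arrays[[k]] <- new("PairedArray", arrayId = man$array_id[k],
                       runId = runId, cy3Sample = man$cy3_sample[k],
                       cy5Sample = man$cy5_sample[k],
                       cy3 = d$cy3, cy5 = d$cy5)
  }
  new("Run", runId = runId, design = design, arrays = arrays)
}
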