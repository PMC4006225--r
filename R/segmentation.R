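# Aberration calling from per-probe log2 ratios with a quality-weighted
# interval z-score. The commercial algorithm used on the original platform
# (ADM-2) is proprietary; the statistic implemented here is a documented
# stand-in honouring its published interface: a score threshold (6) and a
# minimum-probe rule (3 in full-resolution mode).

#' Interval score
#'
#' The segmentation statistic: for probes i..j with log2 ratios x and error
#' estimates sigma, \deqn{S(i,j) = |\sum_{k=i}^{j} x_k/\sigma_k| /
#' \sqrt{j-i+1}} i.e. the absolute quality-weighted mean z times the square
#' root of the probe count.
#'
#' @param x Numeric log2 ratios.
#' @param sigma Per-probe error estimates (> 0), recycled.
#' @param i,j 1-based probe indices, i <= j.
#' @return The score (non-negative scalar).
#' @examples
#' scoreInterval(rep(-1, 4), 0.5, 1, 4)  # |−8|/2 = 4
#' @export
scoreInterval <- function(x, sigma, i, j) {
  stopifnot(i >= 1, j >= i, j <= length(x))
  sigma <- rep_len(sigma, length(x))
  z <- x[i:j] / sigma[i:j]
  abs(sum(z)) / sqrt(j - i + 1)
}

#' Robust per-array noise estimate
#'
#' The derivative-spread estimator: median absolute deviation of
#' probe-to-probe differences divided by sqrt(2). Insensitive to the CNVs
#' themselves, which affect only a handful of the differences.
#'
#' @param x Numeric log2 ratios (one array; chromosome order).
#' @return Scalar sigma estimate.
#' @export
estimateSigma <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop("too few finite probes to estimate sigma")
  mad(diff(x)) / sqrt(2)
}

#' Exhaustive best-interval search (oracle)
#'
#' Direct enumeration of all O(n^2) intervals, kept deliberately independent
#' of the compiled greedy caller so it can act as its oracle in tests. Ties
#' broken by longer interval, then leftmost.
#'
#' @param x Log2 ratios on one chromosome.
#' @param sigma Per-probe error estimates (recycled).
#' @param minProbes Minimum interval length.
#' @return list(i, j, score), or NULL if fewer than minProbes probes.
#' @export
exhaustiveBestInterval <- function(x, sigma, minProbes = 1L) {
  n <- length(x)
  if (n < minProbes) return(NULL)
  sigma <- rep_len(sigma, n)
  z <- x / sigma
  cz <- c(0, cumsum(z))
  best <- list(i = NA_integer_, j = NA_integer_, score = -1)
  bestLen <- -1L
  for (i in seq_len(n - minProbes + 1L)) {
    js <- (i + minProbes - 1L):n
    s <- abs(cz[js + 1L] - cz[i]) / sqrt(js - i + 1)
    # leftmost-longest tie-break within this i: prefer larger j on equal s
    kmax <- max(s)
    j <- max(js[s == kmax])
    len <- j - i + 1L
    if (kmax > best$score ||
        (kmax == best$score && len > bestLen)) {
      best <- list(i = i, j = j, score = kmax)
      bestLen <- len
    }
  }
  best
}

#' Call copy-number aberrations on one array
#'
#' Greedy maximal-score extraction: repeatedly select the interval with the
#' highest score S >= threshold and at least \code{minProbes} probes among
#' probes not yet assigned to a call, emit it, mask its probes, and repeat.
#' Runs per chromosome; calls never overlap. Segment boundaries are the
#' outermost probe coordinates.
#'
#' @param probes \code{GRanges} of probe positions (sorted) with mcol
#'   \code{ratio} (log2). Non-finite ratios are dropped with a message.
#' @param sigma Per-probe error estimate(s); default a single per-array
#'   \code{estimateSigma} value.
#' @param threshold Score threshold (default 6).
#' @param minProbes Minimum probes per call (default 3).
#' @param sexReference Reference copies per chromosome for copy-state
#'   estimation, as from \code{referenceCopies}; default autosome 2.
#' @param mosaicWindow |mean log2| window reported as mosaic.
#' @return \code{GRanges} of calls with mcols \code{probeCount},
#'   \code{meanLog2}, \code{score}, \code{direction}, \code{copies},
#'   \code{copiesHigh}, \code{refCopies}, \code{kind},
#'   \code{carrierChannel} (initially "unassigned") and probe index bounds
#'   \code{firstProbe}, \code{lastProbe}.
#' @examples
#' d <- gi(rep("1", 20), seq(1e6, by = 1e5, length.out = 20),
#'         seq(1e6, by = 1e5, length.out = 20) + 59)
#' d$ratio <- c(rep(0, 7), rep(-1, 6), rep(0, 7))
#' callAberrations(d, sigma = 0.2)
#' @export
callAberrations <- function(probes, sigma = NULL, threshold = 6,
                            minProbes = 3L, sexReference = NULL,
                            mosaicWindow = c(0.25, 0.8)) {
  stopifnot(threshold > 0, minProbes >= 1L)
  empty <- function() {
    out <- GRanges()
    seqlevels(out) <- seqlevels(probes)
    mcols(out) <- DataFrame(probeCount = integer(0), meanLog2 = numeric(0),
                            score = numeric(0), direction = character(0),
                            copies = integer(0), copiesHigh = integer(0),
                            refCopies = integer(0), kind = character(0),
                            carrierChannel = character(0),
                            firstProbe = integer(0), lastProbe = integer(0))
    out
  }
  if (length(probes) == 0L) return(empty())
  x <- mcols(probes)$ratio
  if (is.null(x)) stop("probes must carry a 'ratio' mcol")
  keep <- is.finite(x)
  if (!all(keep)) {
    message(sum(!keep), " probe(s) with non-finite ratio dropped")
    probes <- probes[keep]
    x <- x[keep]
  }
  if (length(probes) == 0L) return(empty())
  if (is.null(sigma)) sigma <- estimateSigma(x)
  sigma <- rep_len(sigma, length(probes))
  if (any(sigma <= 0)) stop("sigma must be > 0")
  z <- x / sigma
  ord <- order(match(as.character(seqnames(probes)), .CHROMS), start(probes))
  probes <- probes[ord]; x <- x[ord]; z <- z[ord]
  chrom <- as.character(seqnames(probes))
  res <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    m <- .greedy_calls_cpp(z[idx], threshold, as.integer(minProbes))
    if (nrow(m) == 0L) next
    gi1 <- idx[m[, "i"]]; gj <- idx[m[, "j"]]
    gr <- gi(rep(ch, nrow(m)), start(probes)[gi1], end(probes)[gj],
             genome = NULL)
    means <- vapply(seq_len(nrow(m)),
                    function(r) mean(x[gi1[r]:gj[r]]), 0)
    ref <- if (is.null(sexReference)) rep(2L, nrow(m))
           else rep_len(as.integer(sexReference[ch]), nrow(m))
    cs <- estimateCopyState(means, ref, mosaicWindow)
    mcols(gr) <- DataFrame(
      probeCount = as.integer(unname(m[, "j"] - m[, "i"] + 1)),
      meanLog2 = unname(means), score = unname(m[, "score"]),
      direction = ifelse(means < 0, "loss", "gain"),
      copies = cs$copies, copiesHigh = cs$copiesHigh,
      refCopies = ref, kind = cs$kind,
      carrierChannel = "unassigned",
      firstProbe = gi1, lastProbe = gj)
    res[[ch]] <- gr
  }
  if (!length(res)) return(empty())
  out <- unlist(GRangesList(unname(res)), use.names = FALSE)
  seqlevels(out) <- seqlevels(probes)
  sort(out)
}

#' Reference copies per chromosome for a sample sex
#'
#' @param sex "XX" or "XY".
#' @return Named integer vector over chromosomes 1-22, X, Y.
#' @export
referenceCopies <- function(sex = c("XX", "XY")) {
  sex <- match.arg(sex)
  ref <- setNames(rep(2L, length(.CHROMS)), .CHROMS)
  if (sex == "XY") { ref["X"] <- 1L; ref["Y"] <- 1L } else ref["Y"] <- 0L
  ref
}

#' Copy-state estimate from a mean log2 ratio
#'
#' Copies = reference * 2^meanLog2 rounded to the nearest integer; estimates
#' of 5 copies or more are amplifications; |meanLog2| inside the mosaic
#' window yields a mosaic pair bracketing the (non-integer) estimate.
#'
#' @param meanLog2 Numeric vector of segment means.
#' @param reference Expected copies (recycled; 2 for autosomes).
#' @param mosaicWindow Increasing pair of |log2| bounds (default 0.25-0.8).
#' @return data.frame with \code{copies}, \code{copiesHigh}, \code{kind}.
#' @examples
#' estimateCopyState(c(-1, 1, -0.4))
#' @export
estimateCopyState <- function(meanLog2, reference = 2L,
                              mosaicWindow = c(0.25, 0.8)) {
  reference <- rep_len(as.integer(reference), length(meanLog2))
  est <- reference * 2^meanLog2
  mosaic <- abs(meanLog2) > mosaicWindow[1] & abs(meanLog2) < mosaicWindow[2]
  copies <- as.integer(round(est))
  copiesHigh <- rep(NA_integer_, length(est))
  lo <- as.integer(floor(est)); hi <- as.integer(ceiling(est))
  usePair <- mosaic & lo < hi
  copies[usePair] <- lo[usePair]
  copiesHigh[usePair] <- hi[usePair]
  # a mosaic bracketing >= 5 copies is still an amplification call
  kind <- .copyKind(copies, copiesHigh, reference)
  data.frame(copies = copies, copiesHigh = copiesHigh, kind = kind,
             stringsAsFactors = FALSE)
}
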