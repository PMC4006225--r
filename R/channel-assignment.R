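# Channel disambiguation: a paired array cannot tell which of its two
# co-hybridized samples carries a called CNV from the ratio alone. Each
# channel's raw intensities over the call region are therefore compared
# against the same channel on run-mate arrays that have no call there.

#' Run-mates eligible as references for a region
#'
#' Run-mates of \code{arrayId} whose own call set (both channels) has no
#' call overlapping \code{region}. Eligibility is call-based only; sample
#' sex is not consulted (a documented caveat for sex-chromosome regions).
#'
#' @param run A \code{Run}.
#' @param arrayId The array being assessed.
#' @param region \code{GRanges}, length 1.
#' @param callSets Named list (by array id) of call \code{GRanges}, one per
#'   array in the run; pass the run's full call set so "no CNV in the
#'   called region" can be established.
#' @return Character vector of eligible array ids.
#' @export
eligibleReferences <- function(run, arrayId, region, callSets) {
  ids <- setdiff(arrayIds(run), arrayId)
  keep <- vapply(ids, function(id) {
    cs <- callSets[[id]]
    is.null(cs) || length(cs) == 0L || !any(overlapsAny(region, cs))
  }, TRUE)
  ids[keep]
}

#' Assign the carrier channel of a call
#'
#' For each channel, the deviation is the median over call-region probes of
#' log2(this array's channel intensity / run-median channel intensity),
#' the run-median taken per probe across the eligible reference arrays.
#' The carrier is the channel whose absolute deviation reaches
#' \code{deviationThreshold} with the sign implied by the call direction
#' (for cy3 the deviation carries the sign of the log2(cy3/cy5) shift; for
#' cy5 the opposite sign), provided the other channel stays below
#' threshold. Otherwise the call is retained with carrier "unassigned" and
#' a status explaining why.
#'
#' @param run A \code{Run}.
#' @param arrayId Array carrying the call.
#' @param call Length-1 \code{GRanges} with mcol \code{meanLog2}.
#' @param cfg An \code{AnalysisConfig} (uses \code{minReferenceArrays},
#'   \code{deviationThreshold}).
#' @param callSets Named list of per-array call sets (see
#'   \code{eligibleReferences}).
#' @return list(carrier = "cy3"/"cy5"/"unassigned", status = "assigned"/
#'   "ambiguous"/"insufficient_references", deviations = data.frame
#'   (channel, deviation, nReferenceArrays), carrierSample).
#' @export
assignCarrier <- function(run, arrayId, call, cfg, callSets) {
  stopifnot(length(call) == 1L)
  ids <- arrayIds(run)
  a <- run@arrays[[match(arrayId, ids)]]
  if (is.na(match(arrayId, ids))) stop("array not in run: ", arrayId)
  refIds <- eligibleReferences(run, arrayId, call, callSets)
  probes <- run@design@probes
  idx <- which(overlapsAny(probes, call))
  if (!length(idx)) stop("call region contains no probes")
  if (length(refIds) < cfg@minReferenceArrays)
    return(list(carrier = "unassigned", status = "insufficient_references",
                deviations = data.frame(
                  channel = c("cy3", "cy5"), deviation = NA_real_,
                  nReferenceArrays = length(refIds)),
                carrierSample = NA_character_))
  refArrays <- run@arrays[match(refIds, ids)]
  dev <- vapply(c(cy3 = "cy3", cy5 = "cy5"), function(ch) {
    mine <- slot(a, ch)[idx]
    refMat <- vapply(refArrays, function(r) slot(r, ch)[idx],
                     numeric(length(idx)))
    refMed <- apply(matrix(refMat, nrow = length(idx)), 1, median)
    median(log2(mine / refMed))
  }, 0)
  expSign <- sign(call$meanLog2) * c(cy3 = 1, cy5 = -1)
  qual <- abs(dev) >= cfg@deviationThreshold & sign(dev) == expSign
  other <- abs(rev(dev)) < cfg@deviationThreshold
  hit <- qual & other
  devTab <- data.frame(channel = c("cy3", "cy5"), deviation = unname(dev),
                       nReferenceArrays = length(refIds))
  if (sum(hit) != 1L)
    return(list(carrier = "unassigned", status = "ambiguous",
                deviations = devTab, carrierSample = NA_character_))
  carrier <- names(dev)[hit]
  list(carrier = carrier, status = "assigned", deviations = devTab,
       carrierSample = if (carrier == "cy3") a@cy3Sample else a@cy5Sample)
}

#' Segment and disambiguate every array of a run
#'
#' Calls aberrations on each array's log2 ratios, then assigns a carrier
#' channel/sample to every call using the run's full call set for reference
#' eligibility. The per-sample copy state is re-estimated from the
#' carrier-adjusted mean log2 (the ratio is inverted when the carrier is
#' the cy5 sample).
#'
#' @param run A \code{Run}.
#' @param cfg An \code{AnalysisConfig}.
#' @param minProbes Override of the minimum-probe rule (defaults to
#'   \code{cfg@minProbes}).
#' @return Named list (by array id) of call \code{GRanges} augmented with
#'   mcols \code{carrierChannel}, \code{carrierSample}, \code{cy3Dev},
#'   \code{cy5Dev}, \code{nRefs}, \code{assignStatus}; copy-state mcols
#'   refer to the carrier sample when assigned.
#' @export
segmentRun <- function(run, cfg, minProbes = NULL) {
  if (is.null(minProbes)) minProbes <- cfg@minProbes
  probes <- run@design@probes
  callSets <- lapply(run@arrays, function(a) {
    p <- probes
    mcols(p)$ratio <- log2Ratios(a)
    callAberrations(p, threshold = cfg@segThreshold, minProbes = minProbes,
                    mosaicWindow = cfg@mosaicWindow)
  })
  names(callSets) <- arrayIds(run)
  for (id in names(callSets)) {
    calls <- callSets[[id]]
    if (!length(calls)) {
      mcols(calls)$carrierSample <- character(0)
      mcols(calls)$cy3Dev <- numeric(0)
      mcols(calls)$cy5Dev <- numeric(0)
      mcols(calls)$nRefs <- integer(0)
      mcols(calls)$assignStatus <- character(0)
      callSets[[id]] <- calls
      next
    }
    asg <- lapply(seq_along(calls), function(k)
      assignCarrier(run, id, calls[k], cfg, callSets))
    mcols(calls)$carrierChannel <- vapply(asg, `[[`, "", "carrier")
    mcols(calls)$carrierSample <- vapply(asg, `[[`, "", "carrierSample")
    mcols(calls)$cy3Dev <- vapply(asg, function(x) x$deviations$deviation[1], 0)
    mcols(calls)$cy5Dev <- vapply(asg, function(x) x$deviations$deviation[2], 0)
    mcols(calls)$nRefs <- vapply(asg, function(x)
      x$deviations$nReferenceArrays[1], 0L)
    mcols(calls)$assignStatus <- vapply(asg, `[[`, "", "status")
    # re-orient copy state to the carrier sample
    flip <- mcols(calls)$carrierChannel == "cy5"
    adj <- ifelse(flip, -mcols(calls)$meanLog2, mcols(calls)$meanLog2)
    assigned <- mcols(calls)$carrierChannel != "unassigned"
    if (any(assigned)) {
      cs <- estimateCopyState(adj[assigned],
                              mcols(calls)$refCopies[assigned],
                              cfg@mosaicWindow)
      mcols(calls)$copies[assigned] <- cs$copies
      mcols(calls)$copiesHigh[assigned] <- cs$copiesHigh
      mcols(calls)$kind[assigned] <- cs$kind
      mcols(calls)$direction[assigned] <- ifelse(adj[assigned] < 0,
                                                 "loss", "gain")
    }
    callSets[[id]] <- calls
  }
  callSets
}
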