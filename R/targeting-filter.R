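# The heart of software targeting: every CNV call is either reportable
# (strictly larger than the backbone threshold, overlapping a targeted
# syndrome region with a compatible direction, or adjacent to a reportable
# call) or masked. Masking happens here, downstream of segmentation, so the
# same stored data supports both a prenatal report and a later
# full-resolution "unmasking" reanalysis.

.statusLevels <- c("reportable_backbone", "reportable_target",
                   "reportable_adjacent", "masked")

#' Classify one or more CNV calls against a configuration
#'
#' Status logic per call: \code{reportable_backbone} if the interval size
#' (end - start + 1) is strictly greater than the backbone threshold;
#' otherwise \code{reportable_target} if the call overlaps (by at least
#' \code{minTargetOverlap} bp) an enabled target whose direction is
#' \code{both} or equals the call direction; otherwise \code{masked}.
#' Backbone precedes target in the reason ordering when both apply. A match
#' against a default-origin target is vetoed when the overlapped part lies
#' entirely inside an exclusion region (case-specific targets override
#' exclusions).
#'
#' @param calls \code{GRanges} with mcol \code{direction} (\code{loss} /
#'   \code{gain} / NA).
#' @param cfg An \code{AnalysisConfig}.
#' @return The calls with added mcols \code{status} and \code{reasons}
#'   (semicolon-separated rule list); the config fingerprint is recorded in
#'   \code{metadata(x)$configFingerprint}.
#' @examples
#' cfg <- defaultConfig()
#' x <- parseResultString("22q11.21(18,896,971-21,440,514)x1")
#' classifyCalls(x, cfg)$status
#' @export
classifyCalls <- function(calls, cfg) {
  n <- length(calls)
  status <- rep("masked", n)
  reasons <- rep("", n)
  if (n) {
    dir <- mcols(calls)$direction
    if (is.null(dir)) dir <- rep(NA_character_, n)
    sz <- intervalSize(calls)
    backbone <- sz > cfg@backboneMinSize
    targets <- cfg@targets[cfg@targets$enabled]
    tHits <- vector("list", n)
    if (length(targets)) {
      ov <- findOverlaps(calls, targets, minoverlap = cfg@minTargetOverlap)
      for (k in seq_len(length(ov))) {
        i <- queryHits(ov)[k]; j <- subjectHits(ov)[k]
        tdir <- targets$direction[j]
        if (!(tdir == "both" || (!is.na(dir[i]) && tdir == dir[i]))) next
        if (targets$origin[j] == "default" && length(cfg@exclusions)) {
          ovPart <- pintersect(calls[i], targets[j])
          inExcl <- any(start(cfg@exclusions) <= start(ovPart) &
                          end(cfg@exclusions) >= end(ovPart) &
                          as.character(seqnames(cfg@exclusions)) ==
                            as.character(seqnames(ovPart)))
          if (inExcl) next
        }
        tHits[[i]] <- c(tHits[[i]], targets$name[j])
      }
    }
    for (i in seq_len(n)) {
      r <- character(0)
      if (backbone[i])
        r <- c(r, sprintf("backbone:size=%d>%d", as.integer(sz[i]),
                          as.integer(cfg@backboneMinSize)))
      if (length(tHits[[i]]))
        r <- c(r, paste0("target:", tHits[[i]]))
      if (backbone[i]) status[i] <- "reportable_backbone"
      else if (length(tHits[[i]])) status[i] <- "reportable_target"
      reasons[i] <- paste(r, collapse = ";")
    }
  }
  mcols(calls)$status <- status
  mcols(calls)$reasons <- reasons
  metadata(calls)$configFingerprint <- configFingerprint(cfg)
  calls
}

#' Promote masked calls adjacent to reportable ones
#'
#' Any masked call on the same chromosome within \code{adjacencyGap} bp of
#' a reportable call is promoted to \code{reportable_adjacent}; iterated to
#' a fixed point so chains of contiguous calls are co-reported. Calls must
#' come from a single sample.
#'
#' @param classified \code{GRanges} as returned by \code{classifyCalls}.
#' @param cfg An \code{AnalysisConfig}.
#' @return The calls with updated \code{status}/\code{reasons}.
#' @export
applyAdjacencyRule <- function(classified, cfg) {
  n <- length(classified)
  if (n < 2L) return(classified)
  st <- mcols(classified)$status
  repeat {
    changed <- FALSE
    rep_idx <- which(st != "masked")
    for (i in which(st == "masked")) {
      for (j in rep_idx) {
        if (as.character(seqnames(classified))[i] !=
            as.character(seqnames(classified))[j]) next
        gap <- max(start(classified)[i], start(classified)[j]) -
          min(end(classified)[i], end(classified)[j]) - 1
        if (gap <= cfg@adjacencyGap) {
          st[i] <- "reportable_adjacent"
          mcols(classified)$reasons[i] <- paste(
            c(mcols(classified)$reasons[i][nzchar(mcols(classified)$reasons[i])],
              sprintf("adjacent:gap=%d<=%d", as.integer(max(gap, 0)),
                      as.integer(cfg@adjacencyGap))),
            collapse = ";")
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  mcols(classified)$status <- st
  classified
}

#' Classify a sample's call set
#'
#' Classifies every call, applies the adjacency rule, and summarises the
#' sample as \code{abnormal} (at least one reportable call) or
#' \code{no_abnormality_detected}.
#'
#' @param calls \code{GRanges} of one sample's calls.
#' @param cfg An \code{AnalysisConfig}.
#' @return list(status, classified).
#' @export
classifySample <- function(calls, cfg) {
  cls <- applyAdjacencyRule(classifyCalls(calls, cfg), cfg)
  abnormal <- length(cls) > 0L && any(mcols(cls)$status != "masked")
  list(status = if (abnormal) "abnormal" else "no_abnormality_detected",
       classified = cls)
}
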