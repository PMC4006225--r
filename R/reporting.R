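# Prenatal reports, full-resolution "unmasking" reanalyses, resolution
# sweeps and size-threshold summaries.

#' ReportRecord: one sample's issued result
#'
#' @slot sampleId Sample identifier.
#' @slot status "abnormal" or "no_abnormality_detected".
#' @slot resultStrings ISCN-style strings for reportable calls only.
#' @slot referral Free-text referral indication.
#' @slot disclaimer Text naming the backbone cut-off and the excluded
#'   susceptibility loci.
#' @slot mode "prenatal" or "full_resolution".
#' @slot configFingerprint Hash of the config the classification used.
#' @export
setClass("ReportRecord", representation(
  sampleId = "character", status = "character",
  resultStrings = "character", referral = "character",
  disclaimer = "character", mode = "character",
  configFingerprint = "character"))

setValidity("ReportRecord", function(object) {
  if (object@status == "abnormal" && length(object@resultStrings) == 0L)
    return("an abnormal report needs at least one result string")
  if (object@status == "no_abnormality_detected" &&
      length(object@resultStrings) > 0L)
    return("an NAD report must carry no result strings")
  TRUE
})

setMethod("show", "ReportRecord", function(object) {
  cat(sprintf("%s report for %s: %s\n", object@mode, object@sampleId,
              object@status))
  for (s in object@resultStrings) cat("  ", s, "\n")
})

.disclaimerText <- function(cfg) {
  excl <- if (length(cfg@exclusions))
    paste(cfg@exclusions$name, collapse = ", ")
  else "none"
  sprintf(paste0(
    "Copy number analysis restricted to imbalances > %g Mb and to targeted ",
    "deletion/duplication syndrome regions (%d regions). ",
    "Susceptibility loci deliberately excluded from targeting: %s."),
    cfg@backboneMinSize / 1e6, sum(cfg@targets$enabled), excl)
}

#' Issue a prenatal report for one sample
#'
#' Formats result strings (via the band map) for reportable calls only;
#' masked calls never appear. An auto-generated disclaimer names the size
#' cut-off and the excluded susceptibility loci.
#'
#' @param sampleId Sample identifier.
#' @param classified \code{GRanges} from \code{classifySample} /
#'   \code{applyAdjacencyRule}.
#' @param cfg The \code{AnalysisConfig} used.
#' @param bands A \code{CytobandMap}.
#' @param referral Optional referral indication text.
#' @param mode Report mode label.
#' @return A \code{ReportRecord}.
#' @export
prenatalReport <- function(sampleId, classified, cfg, bands,
                           referral = "", mode = "prenatal") {
  st <- mcols(classified)$status
  if (is.null(st)) stop("calls must be classified first")
  keep <- classified[st != "masked"]
  # one string per chromosome, comma-joining co-reported calls
  chs <- unique(as.character(seqnames(keep)))
  chs <- chs[order(match(chs, .CHROMS))]
  strings <- vapply(chs, function(ch)
    formatResultString(keep[as.character(seqnames(keep)) == ch], bands), "",
    USE.NAMES = FALSE)
  new("ReportRecord", sampleId = sampleId,
      status = if (length(keep)) "abnormal" else "no_abnormality_detected",
      resultStrings = strings, referral = referral,
      disclaimer = .disclaimerText(cfg), mode = mode,
      configFingerprint = configFingerprint(cfg))
}

#' Full-resolution reanalysis ("unmasking")
#'
#' Re-segments stored probe data with the postnatal minimum-probe rule and
#' no backbone/target masking, returning the complete call set. Operates on
#' stored data only: no re-hybridization is modelled.
#'
#' @param run A \code{Run} (stored or reloaded via \code{readRun}).
#' @param cfg An \code{AnalysisConfig} (\code{minProbesFullRes} applies).
#' @return Named list (by array id) of call \code{GRanges}.
#' @export
fullResolutionReanalysis <- function(run, cfg) {
  segmentRun(run, cfg, minProbes = cfg@minProbesFullRes)
}

#' Resolution sweep
#'
#' For each candidate backbone threshold, counts the calls that would
#' become reportable at that threshold but are masked under the reference
#' configuration (targets held fixed). By construction the count is
#' monotone non-increasing in the threshold.
#'
#' @param fullResCalls \code{GRanges} of full-resolution calls (pooled).
#' @param thresholds Increasing numeric vector of backbone sizes in bp.
#' @param cfg Reference \code{AnalysisConfig}.
#' @return data.frame with \code{threshold_bp} and \code{additional_cnvs}.
#' @examples
#' fx <- loadFixtures()
#' calls <- fx$retrospective
#' resolutionSweep(calls, c(1e6, 2e6, 3e6), defaultConfig())
#' @export
resolutionSweep <- function(fullResCalls, thresholds, cfg) {
  stopifnot(all(thresholds > 0), !is.unsorted(thresholds))
  ref <- classifyCalls(fullResCalls, cfg)
  maskedRef <- mcols(ref)$status == "masked"
  counts <- vapply(thresholds, function(t) {
    cfgT <- cfg
    cfgT@backboneMinSize <- as.numeric(t)
    clsT <- classifyCalls(fullResCalls, cfgT)
    sum(maskedRef & mcols(clsT)$status != "masked")
  }, 0L)
  data.frame(threshold_bp = thresholds, additional_cnvs = counts)
}

#' Fraction of CNVs excluded by a size threshold
#'
#' Proportion of sizes strictly below the threshold — the summary used to
#' justify a backbone cut-off from a postnatal CNV size distribution.
#'
#' @param sizes Numeric CNV sizes in bp (non-empty).
#' @param threshold Size threshold in bp.
#' @return Fraction in [0, 1].
#' @examples
#' sizeThresholdExclusionFraction(c(1e6, 2e6, 3e6, 4e6), 3e6)  # 0.5
#' @export
sizeThresholdExclusionFraction <- function(sizes, threshold) {
  if (!length(sizes)) stop("sizes must be non-empty")
  mean(sizes < threshold)
}

#' Serialize a report
#'
#' Writes a human-readable text block and (optionally) a JSON record
#' carrying the config fingerprint for auditability.
#'
#' @param record A \code{ReportRecord}.
#' @param path Output path without extension; writes \code{<path>.txt} and
#'   \code{<path>.json}.
#' @return Invisible character vector of files written.
#' @export
writeReport <- function(record, path) {
  txt <- c(sprintf("Sample: %s", record@sampleId),
           sprintf("Mode: %s", record@mode),
           sprintf("Result: %s", record@status),
           if (length(record@resultStrings))
             paste0("  ", record@resultStrings),
           if (nzchar(record@referral))
             sprintf("Referral: %s", record@referral),
           sprintf("Disclaimer: %s", record@disclaimer),
           sprintf("Config: %s", record@configFingerprint))
  writeLines(txt, paste0(path, ".txt"))
  jsonlite::write_json(list(
    sample_id = record@sampleId, mode = record@mode,
    status = record@status, result_strings = record@resultStrings,
    referral = record@referral, disclaimer = record@disclaimer,
    config_fingerprint = record@configFingerprint),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(paste0(path, c(".txt", ".json")))
}

#' Plot helpers for sweep and size-distribution summaries
#'
#' Simple base-graphics renderings written to PNG: the number of
#' additional CNVs a lower backbone threshold would surface, and the size
#' distribution of a CNV set against the backbone cut-off.
#'
#' @param sweep data.frame from \code{resolutionSweep}.
#' @param path Output PNG path.
#' @return \code{path}, invisibly.
#' @export
plotResolutionSweep <- function(sweep, path) {
  grDevices::png(path, width = 720, height = 480)
  on.exit(grDevices::dev.off())
  graphics::barplot(sweep$additional_cnvs,
                    names.arg = sprintf("%.3g", sweep$threshold_bp / 1e6),
                    xlab = "Backbone threshold (Mb)",
                    ylab = "Additional CNVs vs reference config",
                    col = "steelblue", border = NA,
                    main = "Additional CNVs at increased backbone resolution")
  invisible(path)
}

#' @rdname plotResolutionSweep
#' @param sizes Numeric CNV sizes in bp.
#' @param threshold Backbone threshold drawn as a reference line (bp).
#' @export
plotSizeDistribution <- function(sizes, path, threshold = 3e6) {
  grDevices::png(path, width = 720, height = 480)
  on.exit(grDevices::dev.off())
  graphics::hist(log10(sizes), breaks = 20, col = "grey70", border = "white",
                 xlab = "log10 CNV size (bp)", main = "CNV size distribution")
  graphics::abline(v = log10(threshold), col = "firebrick", lwd = 2, lty = 2)
  invisible(path)
}
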