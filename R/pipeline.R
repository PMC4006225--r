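# End-to-end wiring: simulate/load -> segment -> assign -> classify ->
# report, plus a written manifest so any stage can be re-run from stored
# data. The command-line wrapper in inst/scripts/targetcma dispatches to
# these functions.

#' Run the full analysis pipeline on a run
#'
#' Segments every array, assigns carrier channels, classifies each
#' sample's calls under the configuration and writes per-sample reports
#' (text + JSON), a call table (TSV) and a pipeline manifest (JSON). In
#' \code{full_resolution} mode no masking is applied and the complete call
#' set is reported.
#'
#' Calls whose carrier could not be assigned are conservatively attributed
#' to both samples of their array, flagged by \code{assignStatus}.
#'
#' @param run A \code{Run}.
#' @param cfg An \code{AnalysisConfig}.
#' @param mode "prenatal" or "full_resolution".
#' @param outDir Output directory.
#' @param bands A \code{CytobandMap} (default the shipped synthetic map).
#' @param referrals Optional named character vector of referral texts by
#'   sample id.
#' @return list(manifest = path, reports = list of \code{ReportRecord},
#'   calls = named list of classified call \code{GRanges} by sample).
#' @export
runPipeline <- function(run, cfg, mode = c("prenatal", "full_resolution"),
                        outDir, bands = readCytoband(systemBandFile()),
                        referrals = character(0)) {
  mode <- match.arg(mode)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  minProbes <- if (mode == "full_resolution") cfg@minProbesFullRes
               else cfg@minProbes
  callSets <- segmentRun(run, cfg, minProbes = minProbes)
  # group calls by carrier sample
  samples <- unique(unlist(lapply(run@arrays, function(a)
    c(a@cy3Sample, a@cy5Sample))))
  bySample <- setNames(vector("list", length(samples)), samples)
  for (id in names(callSets)) {
    calls <- callSets[[id]]
    if (!length(calls)) next
    a <- run@arrays[[match(id, arrayIds(run))]]
    for (k in seq_along(calls)) {
      carriers <- switch(mcols(calls)$carrierChannel[k],
                         cy3 = a@cy3Sample, cy5 = a@cy5Sample,
                         c(a@cy3Sample, a@cy5Sample))
      for (s in carriers)
        bySample[[s]] <- if (is.null(bySample[[s]])) calls[k]
                         else c(bySample[[s]], calls[k])
    }
  }
  reports <- list()
  classifiedBySample <- list()
  callRows <- list()
  for (s in samples) {
    calls <- bySample[[s]]
    if (is.null(calls)) {
      calls <- callSets[[1]][0]
    }
    if (mode == "prenatal") {
      res <- classifySample(calls, cfg)
      cls <- res$classified
    } else {
      cls <- classifyCalls(calls, cfg)
      # unmasking: everything is reported
      mcols(cls)$status[mcols(cls)$status == "masked"] <-
        "reportable_full_resolution"
      if (length(cls) == 0L) res <- list(status = "no_abnormality_detected")
      else res <- list(status = "abnormal")
    }
    classifiedBySample[[s]] <- cls
    rec <- prenatalReport(s, cls, cfg, bands,
                          referral = if (s %in% names(referrals))
                            referrals[[s]] else "",
                          mode = mode)
    reports[[s]] <- rec
    writeReport(rec, file.path(outDir, paste0(s, ".", mode)))
    if (length(cls))
      callRows[[s]] <- data.frame(
        sample = s, chrom = as.character(seqnames(cls)),
        start = start(cls), end = end(cls),
        size_bp = intervalSize(cls),
        probe_count = mcols(cls)$probeCount,
        mean_log2 = round(mcols(cls)$meanLog2, 4),
        score = round(mcols(cls)$score, 3),
        suffix = copySuffix(mcols(cls)$copies, mcols(cls)$copiesHigh),
        carrier_channel = mcols(cls)$carrierChannel,
        assign_status = mcols(cls)$assignStatus,
        status = mcols(cls)$status,
        reasons = mcols(cls)$reasons)
  }
  callTab <- if (length(callRows)) do.call(rbind, callRows)
             else data.frame()
  callsPath <- file.path(outDir, paste0(run@runId, ".", mode, ".calls.tsv"))
  write.table(callTab, callsPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifestPath <- file.path(outDir,
                            paste0(run@runId, ".", mode, ".manifest.json"))
  jsonlite::write_json(list(
    run_id = run@runId, mode = mode,
    tool_version = as.character(packageVersion("targetCMA")),
    config_fingerprint = configFingerprint(cfg),
    n_arrays = length(run@arrays),
    samples = samples,
    # paths relative to the manifest so outputs are location-independent
    files = c(basename(callsPath),
              paste0(samples, ".", mode, ".txt"),
              paste0(samples, ".", mode, ".json"))),
    manifestPath, auto_unbox = TRUE)
  list(manifest = manifestPath, reports = reports,
       calls = classifiedBySample)
}
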