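# Analysis configuration: backbone threshold, targeted syndrome regions,
# susceptibility-locus exclusions, per-case additions.

#' AnalysisConfig: the software-targeting configuration
#'
#' Holds every tunable of the prenatal analysis: the backbone size threshold
#' (CNVs strictly larger are always reportable), the targeted
#' deletion/duplication syndrome regions (reportable at full probe
#' resolution, optionally direction-filtered), the susceptibility-locus
#' exclusions that document why certain recurrent CNV loci are deliberately
#' not targets, segmentation settings and channel-disambiguation settings.
#'
#' @slot backboneMinSize Backbone threshold in bp (default 3,000,000); a CNV
#'   is backbone-reportable iff its size is strictly greater.
#' @slot targets \code{GRanges} with mcols \code{name}, \code{omim},
#'   \code{direction} (\code{loss}/\code{gain}/\code{both}), \code{enabled},
#'   \code{origin} (\code{default}/\code{case_specific}).
#' @slot exclusions \code{GRanges} with mcol \code{name}.
#' @slot minProbes Minimum probes per segmentation call (prenatal mode).
#' @slot minProbesFullRes Minimum probes in full-resolution reanalysis.
#' @slot segThreshold Interval-score threshold (default 6).
#' @slot adjacencyGap Max gap (bp) for co-reporting a masked call next to a
#'   reportable one (default 1,000,000).
#' @slot minReferenceArrays Run-mates required for channel disambiguation
#'   (default 5).
#' @slot deviationThreshold Channel-deviation threshold in log2 units
#'   (default 0.3, about half a heterozygous-deletion shift).
#' @slot mosaicWindow |mean log2| window calling a mosaic copy state.
#' @slot minTargetOverlap Minimum call/target overlap in bp (default 1).
#' @export
setClass("AnalysisConfig", representation(
  backboneMinSize = "numeric",
  targets = "GRanges",
  exclusions = "GRanges",
  minProbes = "integer",
  minProbesFullRes = "integer",
  segThreshold = "numeric",
  adjacencyGap = "numeric",
  minReferenceArrays = "integer",
  deviationThreshold = "numeric",
  mosaicWindow = "numeric",
  minTargetOverlap = "numeric"))

setValidity("AnalysisConfig", function(object) {
  msg <- character(0)
  if (object@backboneMinSize <= 0) msg <- c(msg, "backboneMinSize must be > 0")
  if (object@minProbesFullRes < 1L) msg <- c(msg, "minProbesFullRes must be >= 1")
  if (object@minProbes < 1L) msg <- c(msg, "minProbes must be >= 1")
  if (object@minReferenceArrays < 1L)
    msg <- c(msg, "minReferenceArrays must be >= 1")
  t <- object@targets
  need <- c("name", "omim", "direction", "enabled", "origin")
  if (!all(need %in% names(mcols(t))))
    msg <- c(msg, paste("targets must carry mcols:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(t$name)) msg <- c(msg, "target names must be unique")
    if (!all(t$direction %in% c("loss", "gain", "both")))
      msg <- c(msg, "target direction must be loss/gain/both")
  }
  if (length(object@mosaicWindow) != 2L ||
      object@mosaicWindow[1] >= object@mosaicWindow[2])
    msg <- c(msg, "mosaicWindow must be an increasing pair")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n")
  cat(sprintf("  backbone        : > %.1f Mb\n", object@backboneMinSize / 1e6))
  cat(sprintf("  targets         : %d (%d case-specific, %d disabled)\n",
              length(object@targets),
              sum(object@targets$origin == "case_specific"),
              sum(!object@targets$enabled)))
  cat(sprintf("  exclusions      : %d\n", length(object@exclusions)))
  cat(sprintf("  segmentation    : threshold %.4g, min %d probes (full-res %d)\n",
              object@segThreshold, object@minProbes, object@minProbesFullRes))
  cat(sprintf("  disambiguation  : %d reference arrays, deviation %.4g\n",
              object@minReferenceArrays, object@deviationThreshold))
  cat(sprintf("  fingerprint     : %s\n", configFingerprint(object)))
})

# accessors -----------------------------------------------------------------

#' @rdname AnalysisConfig-class
#' @param cfg An \code{AnalysisConfig}.
#' @export
backboneMinSize <- function(cfg) cfg@backboneMinSize

#' @rdname AnalysisConfig-class
#' @export
configTargets <- function(cfg) cfg@targets

#' @rdname AnalysisConfig-class
#' @export
configExclusions <- function(cfg) cfg@exclusions

#' Fingerprint of a configuration
#'
#' Stable hash of all classification-relevant settings, recorded in every
#' classified call set and report for auditability.
#'
#' @param cfg An \code{AnalysisConfig}.
#' @return Character scalar hash.
#' @export
configFingerprint <- function(cfg) {
  t <- cfg@targets
  e <- cfg@exclusions
  rlang::hash(list(
    cfg@backboneMinSize,
    data.frame(chrom = as.character(seqnames(t)), start = start(t),
               end = end(t), name = t$name, direction = t$direction,
               enabled = t$enabled, origin = t$origin),
    data.frame(chrom = as.character(seqnames(e)), start = start(e),
               end = end(e), name = e$name),
    cfg@minProbes, cfg@minProbesFullRes, cfg@segThreshold, cfg@adjacencyGap,
    cfg@minReferenceArrays, cfg@deviationThreshold, cfg@mosaicWindow,
    cfg@minTargetOverlap))
}

.emptyTargets <- function() {
  gr <- GRanges()
  seqlevels(gr) <- .CHROMS
  mcols(gr)$name <- character(0)
  mcols(gr)$omim <- character(0)
  mcols(gr)$direction <- character(0)
  mcols(gr)$enabled <- logical(0)
  mcols(gr)$origin <- character(0)
  gr
}

.emptyExclusions <- function() {
  gr <- GRanges()
  seqlevels(gr) <- .CHROMS
  mcols(gr)$name <- character(0)
  gr
}

#' Construct an AnalysisConfig directly
#'
#' @param backboneMinSize,minProbes,minProbesFullRes,segThreshold See
#'   \linkS4class{AnalysisConfig}.
#' @param targets,exclusions \code{GRanges} (targets need mcols \code{name};
#'   missing \code{omim}/\code{direction}/\code{enabled}/\code{origin} are
#'   defaulted).
#' @param adjacencyGap,minReferenceArrays,deviationThreshold,mosaicWindow,minTargetOverlap
#'   See \linkS4class{AnalysisConfig}.
#' @return An \code{AnalysisConfig}.
#' @export
analysisConfig <- function(backboneMinSize = 3e6,
                           targets = .emptyTargets(),
                           exclusions = .emptyExclusions(),
                           minProbes = 3L, minProbesFullRes = 3L,
                           segThreshold = 6, adjacencyGap = 1e6,
                           minReferenceArrays = 5L,
                           deviationThreshold = 0.3,
                           mosaicWindow = c(0.25, 0.8),
                           minTargetOverlap = 1) {
  m <- mcols(targets)
  if (is.null(m$name) && length(targets))
    stop("targets must have a 'name' mcol")
  if (is.null(m$omim)) mcols(targets)$omim <- rep(".", length(targets))
  if (is.null(m$direction))
    mcols(targets)$direction <- rep("both", length(targets))
  if (is.null(m$enabled)) mcols(targets)$enabled <- rep(TRUE, length(targets))
  if (is.null(m$origin)) mcols(targets)$origin <- rep("default", length(targets))
  if (length(targets)) mcols(targets)$name <- as.character(mcols(targets)$name)
  if (is.null(mcols(exclusions)$name) && length(exclusions))
    mcols(exclusions)$name <- paste0("exclusion_", seq_along(exclusions))
  new("AnalysisConfig",
      backboneMinSize = as.numeric(backboneMinSize),
      targets = targets, exclusions = exclusions,
      minProbes = as.integer(minProbes),
      minProbesFullRes = as.integer(minProbesFullRes),
      segThreshold = as.numeric(segThreshold),
      adjacencyGap = as.numeric(adjacencyGap),
      minReferenceArrays = as.integer(minReferenceArrays),
      deviationThreshold = as.numeric(deviationThreshold),
      mosaicWindow = as.numeric(mosaicWindow),
      minTargetOverlap = as.numeric(minTargetOverlap))
}

#' Load a configuration file
#'
#' Reads the documented YAML key-value format. BED paths
#' (\code{targets_bed}, \code{exclusions_bed}) are resolved relative to the
#' config file; the targets BED is BED6+2 with columns 7-8 carrying OMIM ids
#' and a per-target direction (\code{loss}/\code{gain}/\code{both}).
#'
#' @param path Path to a YAML config file.
#' @return An \code{AnalysisConfig} with defaults filled.
#' @examples
#' cfg <- defaultConfig()
#' length(configTargets(cfg))
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- c("backbone_min_size", "min_probes", "min_probes_full_res",
             "segmentation_threshold", "adjacency_gap",
             "min_reference_arrays", "deviation_threshold", "mosaic_window",
             "min_target_overlap", "targets_bed", "exclusions_bed")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  rel <- function(p) if (file.exists(p)) p else file.path(dirname(path), p)
  targets <- .emptyTargets()
  if (!is.null(y$targets_bed)) {
    bp <- rel(y$targets_bed)
    if (!file.exists(bp)) stop("targets_bed not found: ", y$targets_bed)
    b <- readBed(bp, extraCols = c(omim = "character",
                                   direction = "character"))
    targets <- granges(b)
    mcols(targets)$name <- b$name
    mcols(targets)$omim <- b$omim
    mcols(targets)$direction <- b$direction
    mcols(targets)$enabled <- TRUE
    mcols(targets)$origin <- "default"
  }
  exclusions <- .emptyExclusions()
  if (!is.null(y$exclusions_bed)) {
    bp <- rel(y$exclusions_bed)
    if (!file.exists(bp)) stop("exclusions_bed not found: ", y$exclusions_bed)
    b <- readBed(bp)
    exclusions <- granges(b)
    mcols(exclusions)$name <- b$name
  }
  grab <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
  analysisConfig(
    backboneMinSize = grab("backbone_min_size", 3e6),
    targets = targets, exclusions = exclusions,
    minProbes = grab("min_probes", 3L),
    minProbesFullRes = grab("min_probes_full_res", 3L),
    segThreshold = grab("segmentation_threshold", 6),
    adjacencyGap = grab("adjacency_gap", 1e6),
    minReferenceArrays = grab("min_reference_arrays", 5L),
    deviationThreshold = grab("deviation_threshold", 0.3),
    mosaicWindow = unlist(grab("mosaic_window", c(0.25, 0.8))),
    minTargetOverlap = grab("min_target_overlap", 1))
}

#' The shipped default configuration
#'
#' 3 Mb backbone, the packaged syndrome-region target set (hg19
#' reconstruction of the published target list) and the three named
#' susceptibility-locus exclusions (15q11.2 BP1-BP2, 1q21.1, proximal
#' 16p11.2).
#'
#' @return An \code{AnalysisConfig}.
#' @export
defaultConfig <- function() {
  loadConfig(system.file("extdata", "default_config.yaml",
                         package = "targetCMA", mustWork = TRUE))
}

#' Add a case-specific target region
#'
#' Appends a target added "live" for one referral (e.g. an RBM8A region for
#' a suspected TAR-syndrome fetus). The input config is not modified.
#' Case-specific targets deliberately override exclusion regions; adding a
#' target that overlaps an exclusion is accepted with a warning.
#'
#' @param cfg An \code{AnalysisConfig}.
#' @param region Length-1 \code{GRanges}.
#' @param name Unique target name.
#' @param direction \code{loss}, \code{gain} or \code{both}.
#' @param omim Optional identifier string.
#' @return A new \code{AnalysisConfig}.
#' @examples
#' cfg <- addCaseTarget(defaultConfig(), gi("1", 145507556, 145513535),
#'                      name = "RBM8A")
#' @export
addCaseTarget <- function(cfg, region, name, direction = "both",
                          omim = ".") {
  stopifnot(is(region, "GRanges"), length(region) == 1L)
  if (name %in% cfg@targets$name)
    stop("duplicate target name: ", name)
  if (!direction %in% c("loss", "gain", "both"))
    stop("direction must be loss/gain/both")
  if (length(cfg@exclusions) && any(intervalsOverlap(
        rep(region, length(cfg@exclusions)), cfg@exclusions)))
    warning("case target '", name, "' overlaps exclusion region(s) ",
            paste(cfg@exclusions$name[intervalsOverlap(
              rep(region, length(cfg@exclusions)), cfg@exclusions)],
              collapse = ", "),
            "; case-specific targets override exclusions")
  add <- gi(as.character(seqnames(region)), start(region), end(region))
  mcols(add) <- DataFrame(name = name, omim = omim, direction = direction,
                          enabled = TRUE, origin = "case_specific")
  out <- cfg
  seqlevels(add) <- seqlevels(out@targets)
  out@targets <- c(out@targets, add)
  validObject(out)
  out
}

#' Remove a target by name
#'
#' Inverse of \code{addCaseTarget}; removing a name that was just added
#' returns a config equal to the original.
#'
#' @param cfg An \code{AnalysisConfig}.
#' @param name Target name to drop.
#' @return A new \code{AnalysisConfig}.
#' @export
removeTarget <- function(cfg, name) {
  if (!name %in% cfg@targets$name) stop("no such target: ", name)
  out <- cfg
  out@targets <- out@targets[out@targets$name != name]
  out
}

#' Validate a configuration
#'
#' Returns informational findings rather than raising: default-target /
#' exclusion overlaps, targets larger than the backbone threshold,
#' single-base ("zero-size") regions and duplicate names.
#'
#' @param cfg An \code{AnalysisConfig}.
#' @return data.frame with columns \code{level}, \code{field},
#'   \code{message} (zero rows when clean).
#' @export
validateConfig <- function(cfg) {
  f <- list()
  note <- function(level, field, message)
    f[[length(f) + 1L]] <<- data.frame(level = level, field = field,
                                       message = message)
  t <- cfg@targets
  if (anyDuplicated(t$name))
    note("error", "targets",
         paste("duplicate target name(s):",
               paste(unique(t$name[duplicated(t$name)]), collapse = ", ")))
  if (length(t) && length(cfg@exclusions)) {
    ov <- findOverlaps(t, cfg@exclusions)
    for (k in seq_len(length(ov))) {
      i <- queryHits(ov)[k]; j <- subjectHits(ov)[k]
      if (t$origin[i] == "default")
        note("warning", paste0("targets/", t$name[i]),
             paste("default target overlaps exclusion", cfg@exclusions$name[j]))
    }
  }
  big <- which(intervalSize(t) > cfg@backboneMinSize)
  for (i in big)
    note("info", paste0("targets/", t$name[i]),
         "target larger than backbone threshold (always backbone-reportable)")
  tiny <- which(intervalSize(t) <= 1)
  for (i in tiny)
    note("info", paste0("targets/", t$name[i]), "single-base target region")
  if (length(f)) do.call(rbind, f)
  else data.frame(level = character(0), field = character(0),
                  message = character(0))
}
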