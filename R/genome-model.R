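#' @import methods
#' @importFrom stats median mad rnorm runif setNames
#' @importFrom utils read.delim write.table packageVersion head tail
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges GRangesList granges seqnames start end
#'   width mcols mcols<- findOverlaps countOverlaps pintersect
#'   sort.GenomicRanges
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits DataFrame metadata metadata<-
#' @importFrom GenomeInfoDb seqlevels seqlevels<- seqlengths seqlengths<-
#'   seqinfo Seqinfo keepSeqlevels
#' @importFrom Rcpp evalCpp
#' @useDynLib targetCMA, .registration = TRUE
NULL

# -- chromosome naming ------------------------------------------------------

.CHROMS <- c(as.character(1:22), "X", "Y")

#' hg19 chromosome lengths
#'
#' Named integer vector of GRCh37/hg19 chromosome lengths (chromosomes 1-22,
#' X and Y; no "chr" prefix). Used as the default genome table for array
#' designs and interval validation.
#'
#' @return Named numeric vector of chromosome lengths in bp.
#' @examples
#' hg19Lengths()[["22"]]
#' @export
hg19Lengths <- function() {
  c(`1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566, X = 155270560, Y = 59373566)
}

#' Normalize chromosome names
#'
#' Strips a leading "chr" prefix and validates against the supported
#' chromosome set (1-22, X, Y).
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @examples
#' normChrom(c("chr1", "X", "chr22"))
#' @export
normChrom <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom))
  bad <- setdiff(unique(chrom), .CHROMS)
  if (length(bad))
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  chrom
}

#' Construct genomic intervals
#'
#' Builds a \code{GRanges} of 1-based inclusive intervals on the supported
#' chromosome set. This is the universal coordinate unit of the package;
#' sizes are \code{end - start + 1}.
#'
#' @param chrom Chromosome names (with or without "chr" prefix).
#' @param start,end 1-based inclusive positions.
#' @param genome Named vector of chromosome lengths (default hg19) used as
#'   seqlengths; pass \code{NULL} to skip bounds information.
#' @return A \code{GRanges}.
#' @examples
#' gi("22", 18896971, 21440514)
#' @export
gi <- function(chrom, start, end, genome = hg19Lengths()) {
  chrom <- normChrom(chrom)
  if (any(start < 1)) stop("interval start must be >= 1")
  if (any(end < start)) stop("interval end must be >= start")
  if (!is.null(genome)) {
    over <- end > genome[chrom]
    if (any(is.na(over) | over))
      stop("interval extends beyond chromosome end: ",
           paste(paste0(chrom, ":", start, "-", end)[is.na(over) | over],
                 collapse = ", "))
  }
  gr <- GRanges(chrom, IRanges(start = start, end = end))
  if (!is.null(genome)) {
    seqlevels(gr) <- names(genome)
    seqlengths(gr) <- unname(genome)
  } else {
    seqlevels(gr) <- union(seqlevels(gr), .CHROMS)
  }
  gr
}

#' Interval size in bp
#'
#' Size of a 1-based inclusive interval: \code{end - start + 1}.
#'
#' @param iv A \code{GRanges}.
#' @return Numeric vector of sizes in bp.
#' @examples
#' intervalSize(gi("2", 222834667, 224926273))  # 2,091,607 bp (~2.09 Mb)
#' @export
intervalSize <- function(iv) {
  as.numeric(width(iv))
}

#' Closed-interval overlap test
#'
#' TRUE iff the intervals share a chromosome and at least one base
#' (closed-interval arithmetic).
#'
#' @param a,b \code{GRanges} of equal length (or length 1, recycled).
#' @return Logical vector.
#' @examples
#' intervalsOverlap(gi("22", 18896971, 21440514), gi("22", 18900000, 21900000))
#' @export
intervalsOverlap <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  as.character(seqnames(a)) == as.character(seqnames(b)) &
    start(a) <= end(b) & start(b) <= end(a)
}

# -- cytoband map -----------------------------------------------------------

#' CytobandMap: chromosome banding for result-string formatting
#'
#' Wraps a \code{GRanges} of cytogenetic bands (1-based inclusive after
#' conversion from UCSC's 0-based half-open convention). Validity requires
#' that bands tile each chromosome without gaps or overlaps and that band
#' labels are unique per chromosome.
#'
#' @slot bands \code{GRanges} with mcols \code{band} and \code{stain}.
#' @export
setClass("CytobandMap", representation(bands = "GRanges"))

setValidity("CytobandMap", function(object) {
  b <- object@bands
  if (is.null(b$band)) return("bands must carry a 'band' mcol")
  for (ch in unique(as.character(seqnames(b)))) {
    x <- b[seqnames(b) == ch]
    x <- x[order(start(x))]
    if (anyDuplicated(x$band))
      return(sprintf("duplicate band labels on chromosome %s", ch))
    if (length(x) > 1L &&
        any(start(x)[-1L] != end(x)[-length(x)] + 1L))
      return(sprintf("bands do not tile chromosome %s", ch))
  }
  TRUE
})

setMethod("show", "CytobandMap", function(object) {
  b <- object@bands
  cat("CytobandMap with", length(b), "bands on",
      length(unique(seqnames(b))), "chromosomes\n")
})

#' Read a UCSC cytoBand file
#'
#' Reads a tab-delimited UCSC \code{cytoBand.txt} (chrom, chromStart,
#' chromEnd, name, gieStain; 0-based half-open) and converts it to the
#' package's 1-based inclusive convention. A synthetic hg19-like band map
#' consistent with the packaged cohort fixtures ships with the package
#' (see \code{systemBandFile()}).
#'
#' @param path Path to a cytoBand file.
#' @return A \code{CytobandMap}.
#' @examples
#' bands <- readCytoband(systemBandFile())
#' @export
readCytoband <- function(path) {
  if (!file.exists(path)) stop("cytoband file not found: ", path)
  d <- read.delim(path, header = FALSE,
                  col.names = c("chrom", "start", "end", "band", "stain"),
                  colClasses = c("character", "numeric", "numeric",
                                 "character", "character"))
  keep <- sub("^chr", "", d$chrom) %in% .CHROMS
  d <- d[keep, , drop = FALSE]
  gr <- gi(d$chrom, d$start + 1L, d$end, genome = NULL)
  mcols(gr)$band <- d$band
  mcols(gr)$stain <- d$stain
  gr <- sort(gr)
  new("CytobandMap", bands = gr)
}

#' Path of the shipped synthetic band file
#'
#' The packaged band map is synthetic: band boundaries are derived from the
#' coordinate-to-band relations printed in the validation cohort's result
#' strings, then padded to hg19 chromosome arms. It is intended for
#' formatting and round-trip work; substitute a real UCSC cytoBand.txt for
#' production use.
#'
#' @return File path.
#' @export
systemBandFile <- function() {
  system.file("extdata", "cytoBand_synthetic_hg19.txt",
              package = "targetCMA", mustWork = TRUE)
}

#' Band label at a position
#'
#' @param bands A \code{CytobandMap}.
#' @param chrom Chromosome name(s).
#' @param pos Position(s), 1-based.
#' @return Character vector of band labels (without the chromosome prefix).
#' @export
bandAt <- function(bands, chrom, pos) {
  q <- gi(chrom, pos, pos, genome = NULL)
  hit <- findOverlaps(q, bands@bands, select = "first")
  if (anyNA(hit))
    stop("position outside band map: ",
         paste(paste0(chrom, ":", pos)[is.na(hit)], collapse = ", "))
  bands@bands$band[hit]
}

# -- copy states ------------------------------------------------------------

.AMP_COPIES <- 5L  # copies at or above this are reported as "amp"

.copyKind <- function(copies, copiesHigh, refCopies) {
  ifelse(!is.na(copiesHigh), "mosaic",
  ifelse(is.na(copies), "amplification",
  ifelse(copies >= .AMP_COPIES, "amplification",
  ifelse(copies < refCopies, "loss",
  ifelse(copies > refCopies, "gain", "neutral")))))
}

.copyDirection <- function(copies, copiesHigh, refCopies) {
  eff <- ifelse(is.na(copiesHigh), copies, (copies + copiesHigh) / 2)
  eff[is.na(eff)] <- Inf  # "amp" with unstated copies is a gain
  ifelse(eff < refCopies, "loss", ifelse(eff > refCopies, "gain", NA))
}

#' Format a copy-state suffix
#'
#' Maps copy-state fields to the result-string suffix dialect:
#' \code{xN} for integer states, \code{xN~M} for mosaic pairs, \code{amp}
#' for amplifications (>= 5 copies or unstated high copy number).
#'
#' @param copies Integer copies (NA for an amplification of unstated level).
#' @param copiesHigh Upper copies of a mosaic pair, NA otherwise.
#' @return Character suffixes.
#' @export
copySuffix <- function(copies, copiesHigh = NA_integer_) {
  n <- max(length(copies), length(copiesHigh))
  copies <- rep_len(copies, n); copiesHigh <- rep_len(copiesHigh, n)
  ifelse(!is.na(copiesHigh), paste0("x", copies, "~", copiesHigh),
  ifelse(is.na(copies) | copies >= .AMP_COPIES, "amp",
         paste0("x", copies)))
}

# -- result-string parsing / formatting ------------------------------------

# split on commas that sit outside parentheses
.splitTopLevel <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L; cut <- integer(0)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    else if (chars[k] == ")") depth <- depth - 1L
    else if (chars[k] == "," && depth == 0L) cut <- c(cut, k)
  }
  pieces <- character(0); prev <- 1L
  for (k in c(cut, length(chars) + 1L)) {
    pieces <- c(pieces, paste(chars[prev:(k - 1L)], collapse = ""))
    prev <- k + 1L
  }
  trimws(pieces)
}

.TOKEN_RE <- paste0(
  "^(\\d{1,2}|X|Y)",                 # chromosome
  "([pq][\\d.]*)",                   # start band
  "(?:-?(?:\\d{1,2}|X|Y)?([pq][\\d.]*))?",  # optional end band
  "\\(([\\d,]+)-([\\d,]+)\\)",       # coordinates
  "(amp|x\\d+(?:[~∼]\\d+)?)$")  # suffix

.stripSep <- function(x) as.numeric(gsub(",", "", x, fixed = TRUE))

#' Parse ISCN-style CNV result strings
#'
#' Parses the compact result-string dialect used on prenatal CMA reports,
#' e.g. \code{"22q11.21(18,896,971-21,440,514)x1"}. Several CNVs may be
#' comma-separated; thousands separators are optional; the mosaic separator
#' is accepted as ASCII \code{~} or U+223C; band pairs may be concatenated
#' (\code{9p24.2p13.1}) or hyphenated (\code{19p13.2-p13.13}).
#'
#' @param s A single result string (possibly multiple comma-separated CNVs).
#' @param reference Expected copies used to orient the state (2 for
#'   autosomes; pass 1 for male sex chromosomes). Recycled per CNV.
#' @param genome Chromosome-length table for validation.
#' @return A \code{GRanges} with mcols: \code{copies}, \code{copiesHigh},
#'   \code{refCopies}, \code{kind}, \code{direction}, \code{bandStart},
#'   \code{bandEnd}.
#' @examples
#' parseResultString("22q11.21(18,896,971-21,440,514)x1")
#' @export
parseResultString <- function(s, reference = 2L, genome = hg19Lengths()) {
  stopifnot(length(s) == 1L)
  toks <- .splitTopLevel(s)
  m <- regmatches(toks, regexec(.TOKEN_RE, toks, perl = TRUE))
  bad <- lengths(m) == 0L
  if (any(bad))
    stop("malformed result string token: '", toks[bad][1], "'")
  ref <- rep_len(as.integer(reference), length(toks))
  rows <- lapply(seq_along(m), function(k) {
    g <- m[[k]]
    suffix <- g[7]
    copies <- copiesHigh <- NA_integer_
    if (suffix != "amp") {
      nums <- as.integer(strsplit(sub("^x", "", suffix), "[~∼]")[[1]])
      copies <- nums[1]
      if (length(nums) > 1L) {
        if (nums[2] <= nums[1])
          stop("mosaic pair must be ordered low~high in '", toks[k], "'")
        copiesHigh <- nums[2]
      }
    }
    list(chrom = g[2],
         start = .stripSep(g[5]), end = .stripSep(g[6]),
         bandStart = g[3],
         bandEnd = if (nzchar(g[4])) g[4] else g[3],
         copies = copies, copiesHigh = copiesHigh)
  })
  gr <- gi(vapply(rows, `[[`, "", "chrom"),
           vapply(rows, `[[`, 0, "start"),
           vapply(rows, `[[`, 0, "end"), genome = genome)
  copies <- vapply(rows, `[[`, NA_integer_, "copies")
  copiesHigh <- vapply(rows, `[[`, NA_integer_, "copiesHigh")
  mcols(gr)$copies <- copies
  mcols(gr)$copiesHigh <- copiesHigh
  mcols(gr)$refCopies <- ref
  mcols(gr)$kind <- .copyKind(copies, copiesHigh, ref)
  mcols(gr)$direction <- .copyDirection(copies, copiesHigh, ref)
  mcols(gr)$bandStart <- vapply(rows, `[[`, "", "bandStart")
  mcols(gr)$bandEnd <- vapply(rows, `[[`, "", "bandEnd")
  gr
}

#' Format CNVs as an ISCN-style result string
#'
#' Inverse of \code{parseResultString} up to thousands separators and the
#' hyphen-vs-concatenated band-pair dialect: the band of the start and end
#' position are looked up in the band map (one band token if equal), the
#' coordinates are printed with separators, and the copy-state suffix
#' appended (mosaic separator emitted as ASCII \code{~}).
#'
#' @param calls \code{GRanges} with mcols \code{copies} and (optionally)
#'   \code{copiesHigh} as produced by \code{parseResultString} or the
#'   segmentation layer.
#' @param bands A \code{CytobandMap}.
#' @param collapse Separator between CNVs (default ",").
#' @return A single character string.
#' @examples
#' bands <- readCytoband(systemBandFile())
#' x <- parseResultString("17p11.2(16,532,735-20,221,695)x3")
#' formatResultString(x, bands)
#' @export
formatResultString <- function(calls, bands, collapse = ",") {
  if (length(calls) == 0L) return("")
  ch <- as.character(seqnames(calls))
  b1 <- bandAt(bands, ch, start(calls))
  b2 <- bandAt(bands, ch, end(calls))
  bandTok <- ifelse(b1 == b2, b1, paste0(b1, b2))
  fmt <- function(x) formatC(x, format = "d", big.mark = ",")
  ch2 <- copySuffix(calls$copies,
                    if (is.null(calls$copiesHigh)) NA_integer_
                    else calls$copiesHigh)
  paste0(ch, bandTok, "(", fmt(start(calls)), "-", fmt(end(calls)), ")",
         ch2, collapse = collapse)
}

# -- BED IO -----------------------------------------------------------------

#' Write intervals as BED
#'
#' Writes a BED3/BED6(+) file (0-based half-open, "chr"-prefixed) from a
#' \code{GRanges}. Extra mcols given in \code{extra} are appended as
#' additional columns.
#'
#' @param gr A \code{GRanges}.
#' @param path Output path.
#' @param name,score Optional vectors for BED columns 4-5.
#' @param extra Character vector of mcol names to append after column 6.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(gr, path, name = names(gr), score = 0L,
                     extra = character(0)) {
  d <- data.frame(chrom = paste0("chr", as.character(seqnames(gr))),
                  start = start(gr) - 1L, end = end(gr),
                  stringsAsFactors = FALSE)
  if (!is.null(name) || length(extra)) {
    d$name <- if (is.null(name)) "." else name
    d$score <- rep_len(score, length(gr))
    d$strand <- "."
    for (col in extra) d[[col]] <- mcols(gr)[[col]]
  }
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as 1-based intervals
#'
#' Thin wrapper over \code{rtracklayer::import} returning normalized
#' chromosome names and optional extra columns.
#'
#' @param path BED file path.
#' @param extraCols Named character vector passed to
#'   \code{rtracklayer::import} for columns beyond BED6.
#' @return A \code{GRanges}.
#' @export
readBed <- function(path, extraCols = character(0)) {
  gr <- rtracklayer::import(path, format = "BED", extraCols = extraCols)
  gr2 <- gi(as.character(seqnames(gr)), start(gr), end(gr))
  mcols(gr2) <- mcols(gr)
  gr2
}
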