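# Readers/writers and shared genomic containers.
#
# All on-disk interval formats (BED, bedGraph, fragments TSV) are 0-based
# half-open; in memory everything is a GRanges/IRanges (1-based closed).
# Conversion happens only here, at the boundary.

#' Read a chrom.sizes file
#'
#' Two-column tab-separated file of chromosome name and length in bp.
#'
#' @param path Path to the chrom.sizes file.
#' @return A \code{Seqinfo}.
#' @export
readChromSizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "integer"))
  if (anyDuplicated(df$chrom))
    stop("duplicate chromosome names in ", path)
  if (any(df$length <= 0L))
    stop("non-positive chromosome length in ", path)
  Seqinfo(df$chrom, df$length)
}

#' Read a BED file of genomic intervals
#'
#' Parses a 3+ column tab-separated BED file (0-based half-open on disk)
#' into a sorted \code{GRanges} (1-based closed in memory). Column 4 becomes
#' \code{name}, column 5 \code{score}, column 6 the strand.
#'
#' @param path Path to the BED file.
#' @param seqinfo Optional \code{Seqinfo}; when supplied, intervals are
#'   validated against (and carry) these chromosome bounds.
#' @return A \code{GRanges} sorted by (chrom, start).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t10\t20", bed)
#' gr <- readBed(bed)          # chr1:11-20 (1-based closed)
#' @export
readBed <- function(path, seqinfo = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) {
    gr <- GRanges()
    if (!is.null(seqinfo)) seqinfo(gr) <- seqinfo
    return(gr)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", idx[which(nf < 3L)[1L]], " in ", path,
         ": fewer than 3 tab-separated fields")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop("malformed BED line ", idx[bad[1L]], " in ", path,
         ": non-integer coordinates")
  bad <- which(start0 >= end0 | start0 < 0L)
  if (length(bad))
    stop("invalid interval on BED line ", idx[bad[1L]], " in ", path,
         ": requires 0 <= start < end")
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
  if (any(nf >= 4L))
    gr$name <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_,
                      character(1))
  if (any(nf >= 5L))
    gr$score <- suppressWarnings(as.numeric(
      vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else NA_character_,
             character(1))))
  if (any(nf >= 6L)) {
    s <- vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else ".",
                character(1))
    s[!s %in% c("+", "-")] <- "*"
    strand(gr) <- s
  }
  if (!is.null(seqinfo)) {
    missing <- setdiff(unique(chrom), seqnames(seqinfo))
    if (length(missing))
      stop("BED file ", path, " references chromosomes absent from the ",
           "chromosome-size table: ", paste(missing, collapse = ", "))
    seqlevels(gr) <- seqnames(seqinfo)
    seqinfo(gr) <- seqinfo
    if (any(end(gr) > seqlengths(seqinfo)[as.character(seqnames(gr))]))
      stop("BED interval exceeds chromosome length in ", path)
  }
  sort(gr, ignore.strand = TRUE)
}

#' Write a GRanges to BED
#'
#' Writes 0-based half-open coordinates; \code{name}, \code{score} and
#' strand columns are emitted when present.
#'
#' @param gr A \code{GRanges}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeBed <- function(gr, path) {
  n <- length(gr)
  cols <- list(as.character(seqnames(gr)), start(gr) - 1L, end(gr))
  has_name <- !is.null(gr$name)
  has_score <- !is.null(gr$score)
  has_strand <- any(as.character(strand(gr)) != "*")
  if (has_name || has_score || has_strand)
    cols <- c(cols, list(if (has_name) gr$name else rep(".", n)))
  if (has_score || has_strand)
    cols <- c(cols, list(if (has_score) gr$score else rep(0, n)))
  if (has_strand) {
    s <- as.character(strand(gr)); s[s == "*"] <- "."
    cols <- c(cols, list(s))
  }
  write.table(as.data.frame(cols, optional = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a fragments TSV (10x dialect)
#'
#' Five tab-separated columns: chrom, start, end, barcode, count; 0-based
#' half-open coordinates; lines starting with \code{#} are ignored.
#' Fragment ends in this dialect are already Tn5-corrected.
#'
#' @param path Path to the fragments TSV.
#' @param seqinfo Optional \code{Seqinfo}; fragments on chromosomes absent
#'   from it are dropped with a message.
#' @return A \code{GRanges} with metadata columns \code{barcode} and
#'   \code{count}.
#' @export
readFragments <- function(path, seqinfo = NULL) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) {
    gr <- GRanges(barcode = character(0), count = integer(0))
    if (!is.null(seqinfo)) seqinfo(gr) <- seqinfo
    return(gr)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L))
    stop("malformed fragments line ", idx[which(nf < 5L)[1L]], " in ", path)
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start0) || anyNA(end0))
    stop("non-integer coordinates on fragments line ",
         idx[which(is.na(start0) | is.na(end0))[1L]], " in ", path)
  if (any(start0 >= end0))
    stop("fragment with start >= end on line ", idx[which(start0 >= end0)[1L]],
         " in ", path)
  barcode <- vapply(fields, `[[`, character(1), 4L)
  count <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 5L)))
  if (anyNA(count) || any(count < 1L))
    stop("fragment count must be a positive integer in ", path)
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), barcode = barcode,
                count = count)
  if (!is.null(seqinfo)) {
    known <- as.character(seqnames(gr)) %in% seqnames(seqinfo)
    if (any(!known))
      message(sum(!known), " fragment(s) on chromosomes absent from the ",
              "chromosome-size table were dropped")
    gr <- gr[known]
    seqlevels(gr) <- seqnames(seqinfo)
    seqinfo(gr) <- seqinfo
  }
  gr
}

#' Write a fragments TSV
#'
#' @param fragments A \code{GRanges} with \code{barcode} and \code{count}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeFragments <- function(fragments, path) {
  df <- data.frame(as.character(seqnames(fragments)),
                   start(fragments) - 1L, end(fragments),
                   if (is.null(fragments$barcode)) "." else fragments$barcode,
                   if (is.null(fragments$count)) 1L else fragments$count)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a SignalTrack to disk
#'
#' bedGraph is the canonical text dialect: one line per maximal run of a
#' nonzero constant value, 0-based half-open coordinates, zero runs omitted.
#' bigWig encoding delegates to \pkg{rtracklayer} over the same runs.
#'
#' @param track A \code{SignalTrack}.
#' @param path Output path.
#' @param format \code{"bedGraph"} (default) or \code{"bigWig"}.
#' @return Invisibly, \code{path}.
#' @export
writeTrack <- function(track, path, format = c("bedGraph", "bigWig")) {
  format <- match.arg(format)
  sig <- trackSignal(track)
  if (format == "bigWig") {
    gr <- GRanges(seqinfo = seqinfo(track))
    pieces <- lapply(names(sig), function(chr) {
      r <- sig[[chr]]
      ends <- cumsum(runLength(r))
      starts <- ends - runLength(r) + 1L
      keep <- runValue(r) != 0
      GRanges(chr, IRanges(starts[keep], ends[keep]),
              score = runValue(r)[keep], seqinfo = seqinfo(track))
    })
    gr <- do.call(c, pieces)
    rtracklayer::export.bw(gr, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(sig)) {
    r <- sig[[chr]]
    ends <- cumsum(runLength(r))
    starts <- ends - runLength(r) + 1L
    keep <- runValue(r) != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%.10g", chr, starts[keep] - 1L,
                       ends[keep], runValue(r)[keep]), con)
  }
  invisible(path)
}

#' Read a SignalTrack from disk
#'
#' Reads a bedGraph (or bigWig) file into a dense per-base
#' \code{SignalTrack}; bases not covered by any interval are 0.
#'
#' @param path Path to a bedGraph or bigWig file.
#' @param seqinfo A \code{Seqinfo} giving the chromosome lengths.
#' @param format \code{"bedGraph"} (default, or inferred from a .bw/.bigwig
#'   extension) or \code{"bigWig"}.
#' @param normalization Normalization state to record on the result.
#' @return A \code{SignalTrack}.
#' @export
readTrack <- function(path, seqinfo, format = NULL,
                      normalization = c("raw", "RP20M", "minmax", "other")) {
  normalization <- match.arg(normalization)
  if (is.null(format))
    format <- if (grepl("\\.(bw|bigwig)$", tolower(path))) "bigWig" else "bedGraph"
  if (format == "bigWig") {
    gr <- rtracklayer::import.bw(path)
  } else {
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("chrom", "start", "end", "value"),
                     colClasses = c("character", "integer", "integer", "numeric"))
    if (any(df$start >= df$end))
      stop("bedGraph interval with start >= end in ", path)
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end), score = df$value)
  }
  missing <- setdiff(unique(as.character(seqnames(gr))), seqnames(seqinfo))
  if (length(missing))
    stop("track in ", path, " references unknown chromosomes: ",
         paste(missing, collapse = ", "))
  if (any(end(gr) > seqlengths(seqinfo)[as.character(seqnames(gr))]))
    stop("track interval exceeds chromosome length in ", path)
  seqlevels(gr) <- seqnames(seqinfo)
  seqinfo(gr) <- seqinfo
  cov <- coverage(gr, weight = "score")
  hits <- coverage(gr)
  if (any(vapply(hits, function(r) any(runValue(r) > 1L), logical(1))))
    stop("overlapping intervals in track ", path)
  SignalTrack(cov, seqinfo, normalization = normalization)
}

#' Read ATAC-seq alignments from a BAM file
#'
#' Loads aligned reads as a stranded \code{GRanges} suitable for
#' [inferCutSites()] (read mode). Coordinates are reference-space
#' (CIGAR-aware). Requires the \pkg{Rsamtools} and
#' \pkg{GenomicAlignments} packages.
#'
#' @param path Path to a coordinate-sorted, indexed BAM file (an index is
#'   created if missing).
#' @param seqinfo Optional \code{Seqinfo}; alignments on chromosomes
#'   absent from it are dropped.
#' @param mapqFilter Minimum mapping quality (default 0).
#' @return A stranded \code{GRanges} of aligned reads.
#' @export
readAlignments <- function(path, seqinfo = NULL, mapqFilter = 0L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicAlignments", quietly = TRUE))
    stop("readAlignments() requires the Rsamtools and GenomicAlignments packages")
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
    mapqFilter = mapqFilter)
  ga <- GenomicAlignments::readGAlignments(path, param = param)
  gr <- GRanges(seqnames(ga), IRanges(start(ga), end(ga)), strand = strand(ga))
  if (!is.null(seqinfo)) {
    gr <- gr[as.character(seqnames(gr)) %in% seqnames(seqinfo)]
    seqlevels(gr) <- seqnames(seqinfo)
    seqinfo(gr) <- seqinfo
  }
  gr
}
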