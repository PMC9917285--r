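# Tn5 cut-site inference, smoothing, depth normalization and robust
# min-max scaling: the transform from alignments/fragments to the
# accessibility signal the model consumes.

#' ATAC-seq signal-processing configuration
#'
#' The Tn5 transposase inserts adapters with a strand-specific 9 bp offset;
#' read starts are shifted +4 bp on the plus strand and read ends -5 bp on
#' the minus strand so both ends land on the cut site. Cut sites are then
#' extended by \code{smooth_flank} bp each side (the default 40 bp window
#' matches the ~38 bp Tn5 dimer footprint), depth-scaled to
#' reads-per-20-million (RP20M) and robustly min-max normalized against the
#' \code{minmax_percentile}-th percentile of the nonzero signal.
#'
#' @param shift_plus Plus-strand read-start shift in bp (default 4).
#' @param shift_minus Minus-strand read-end shift in bp (default 5).
#' @param smooth_flank Cut-site extension in bp each side (default 20).
#' @param target_depth Depth the coverage is scaled to (default 20 million).
#' @param minmax_percentile Percentile in (0,100] used as the robust
#'   maximum (default 99; the published models also evaluated 95 and 100).
#' @param clip_max Clip normalized signal above 1 to 1 (default TRUE).
#' @return A list of class \code{"SignalConfig"}.
#' @export
signalConfig <- function(shift_plus = 4L, shift_minus = 5L,
                         smooth_flank = 20L, target_depth = 2e7,
                         minmax_percentile = 99, clip_max = TRUE) {
  stopifnot(smooth_flank >= 0, target_depth > 0,
            minmax_percentile > 0, minmax_percentile <= 100)
  structure(list(shift_plus = as.integer(shift_plus),
                 shift_minus = as.integer(shift_minus),
                 smooth_flank = as.integer(smooth_flank),
                 target_depth = target_depth,
                 minmax_percentile = minmax_percentile,
                 clip_max = isTRUE(clip_max)),
            class = "SignalConfig")
}

#' Infer Tn5 cut sites from reads or fragments
#'
#' In read mode, a plus-strand read starting at 0-based position p yields
#' the insertion point p + \code{shift_plus}; a minus-strand read with
#' 0-based exclusive end e yields e - \code{shift_minus}. In fragment mode
#' (10x fragments dialect, ends already Tn5-corrected) both fragment ends
#' become cut sites with no additional shift.
#'
#' @param x A \code{GRanges} of stranded reads, or of fragments (metadata
#'   column \code{barcode} present, or \code{mode = "fragments"}).
#' @param config A [signalConfig()].
#' @param mode \code{"auto"} (fragments iff a \code{barcode} column is
#'   present), \code{"reads"} or \code{"fragments"}.
#' @return A width-1 \code{GRanges} of cut sites (one base per site; the
#'   base at 1-based position b covers the 0-based insertion point b - 1).
#' @examples
#' si <- GenomeInfoDb::Seqinfo("chr1", 1000L)
#' rd <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 150),
#'                              strand = "+", seqinfo = si)
#' inferCutSites(rd)  # base 105 = 0-based point 104
#' @export
inferCutSites <- function(x, config = signalConfig(),
                          mode = c("auto", "reads", "fragments")) {
  mode <- match.arg(mode)
  if (mode == "auto")
    mode <- if (!is.null(x$barcode)) "fragments" else "reads"
  if (mode == "fragments") {
    pts <- c(GRanges(seqnames(x), IRanges(start(x), width = 1L),
                     seqinfo = seqinfo(x)),
             GRanges(seqnames(x), IRanges(end(x), width = 1L),
                     seqinfo = seqinfo(x)))
    return(sort(pts, ignore.strand = TRUE))
  }
  s <- as.character(strand(x))
  if (any(s == "*"))
    stop("read without strand information; cut-site inference requires ",
         "stranded alignments")
  pos <- ifelse(s == "+", start(x) + config$shift_plus,
                end(x) - config$shift_minus + 1L)
  sort(GRanges(seqnames(x), IRanges(pos, width = 1L), seqinfo = seqinfo(x)),
       ignore.strand = TRUE)
}

#' Extend cut sites into smoothing windows
#'
#' Each insertion point c (0-based, between-base) becomes the window
#' [c - flank, c + flank), clamped to the chromosome; the default flank of
#' 20 bp yields exactly 40 bp windows. A flank of 0 degenerates to the 1 bp
#' cut-site base itself.
#'
#' @param points Width-1 \code{GRanges} from [inferCutSites()].
#' @param config A [signalConfig()].
#' @param seqinfo Optional \code{Seqinfo} for clamping (defaults to the
#'   points' own seqinfo).
#' @return A \code{GRanges} of smoothing windows.
#' @export
smoothCutSites <- function(points, config = signalConfig(), seqinfo = NULL) {
  if (is.null(seqinfo)) seqinfo <- seqinfo(points)
  f <- config$smooth_flank
  if (f == 0L) return(points)
  sl <- seqlengths(seqinfo)[as.character(seqnames(points))]
  st <- pmax(start(points) - f, 1L)
  en <- pmin(start(points) + f - 1L, sl)
  GRanges(seqnames(points), IRanges(st, en), seqinfo = seqinfo)
}

#' RP20M scale factor
#'
#' Reads-per-20-million scaling: the per-base count is multiplied by
#' \code{target_depth / depth} so tracks from libraries of different
#' sequencing depth are comparable.
#'
#' @param depth Sequencing depth (mapped reads / cut sites) of the library.
#' @param target_depth Target depth (default 20 million).
#' @return The scale factor \code{target_depth / depth}.
#' @examples
#' rp20mScaleFactor(4e7)  # 0.5
#' @export
rp20mScaleFactor <- function(depth, target_depth = 2e7) {
  if (depth <= 0) stop("sequencing depth must be > 0")
  target_depth / depth
}

#' Per-base coverage track from intervals
#'
#' The value at base b is \code{scale} times the number of intervals
#' covering b.
#'
#' @param intervals A \code{GRanges} (e.g. smoothed cut-site windows).
#' @param scale Multiplier applied to the coverage (e.g. the RP20M scale
#'   factor).
#' @param seqinfo \code{Seqinfo} defining the chromosomes (defaults to the
#'   intervals' own).
#' @param normalization Normalization state of the result (\code{"raw"} for
#'   \code{scale = 1}, \code{"RP20M"} for a depth scale factor).
#' @return A \code{SignalTrack}.
#' @export
coverageTrack <- function(intervals, scale = 1, seqinfo = NULL,
                          normalization = if (scale == 1) "raw" else "RP20M") {
  if (is.null(seqinfo)) seqinfo <- seqinfo(intervals)
  sl <- seqlengths(seqinfo)
  cov <- coverage(intervals, width = as.list(sl))
  if (scale != 1) cov <- cov * scale
  SignalTrack(cov, seqinfo, normalization = normalization)
}

#' Average replicate tracks
#'
#' Per-base arithmetic mean of RP20M tracks across biological replicates.
#'
#' @param tracks A list of \code{SignalTrack}s over identical chromosomes.
#' @return A \code{SignalTrack} of per-base means.
#' @export
averageReplicates <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  si <- seqinfo(tracks[[1L]])
  for (t in tracks[-1L])
    if (!identical(seqlengths(seqinfo(t)), seqlengths(si)))
      stop("replicate tracks have mismatched chromosome sets")
  if (length(tracks) == 1L) return(tracks[[1L]])
  total <- Reduce(`+`, lapply(tracks, trackSignal))
  SignalTrack(total / length(tracks), si,
              normalization = normalizationState(tracks[[1L]]))
}

#' Fit robust min-max parameters
#'
#' The robust maximum is the nearest-rank \code{percentile}-th percentile
#' of the nonzero per-base signal values (the genome is mostly zeros, so
#' percentiles are taken over covered bases); the minimum is fixed at 0.
#'
#' @param track A \code{SignalTrack} (typically the replicate-averaged
#'   RP20M track).
#' @param percentile Percent in (0, 100]; 100 gives the global maximum
#'   (standard min-max).
#' @return A \linkS4class{MinMaxParams}.
#' @export
fitMinMax <- function(track, percentile = 99) {
  stopifnot(percentile > 0, percentile <= 100)
  sig <- trackSignal(track)
  vals <- unlist(lapply(sig, runValue), use.names = FALSE)
  lens <- unlist(lapply(sig, function(r) as.numeric(runLength(r))),
                 use.names = FALSE)
  nz <- vals > 0
  if (!any(nz)) stop("all-zero track: cannot fit min-max parameters")
  vals <- vals[nz]; lens <- lens[nz]
  ord <- order(vals)
  vals <- vals[ord]; lens <- lens[ord]
  n <- sum(lens)
  k <- ceiling(percentile / 100 * n)
  max_p <- vals[which(cumsum(lens) >= k)[1L]]
  MinMaxParams(min = 0, max_p = max_p, percentile = percentile)
}

#' Robust min-max normalization
#'
#' Maps signal v to (v - min) / (max_p - min); with \code{clip}, values
#' above 1 (signal beyond the robust maximum) are set to 1 so the track
#' lies in [0,1].
#'
#' @param track A \code{SignalTrack}.
#' @param params A \linkS4class{MinMaxParams} from [fitMinMax()].
#' @param clip Clip to [0,1] (default TRUE).
#' @return A \code{SignalTrack} with \code{normalization == "minmax"}.
#' @export
minmaxNormalize <- function(track, params, clip = TRUE) {
  stopifnot(is(params, "MinMaxParams"), params@max_p > 0)
  sig <- (trackSignal(track) - params@min) / (params@max_p - params@min)
  if (clip) {
    sig <- RleList(lapply(sig, function(r) {
      v <- runValue(r)
      runValue(r) <- pmin(pmax(v, 0), 1)
      r
    }), compress = FALSE)
  }
  SignalTrack(sig, seqinfo(track), normalization = "minmax",
              minmaxParams = list(min = params@min, max_p = params@max_p,
                                  percentile = params@percentile,
                                  clipped = clip))
}

#' Remove blacklisted regions
#'
#' Cut sites or intervals overlapping any blacklist interval are dropped;
#' track bases inside the blacklist are set to 0. Idempotent.
#'
#' @param x A \code{GRanges} (cut sites or intervals) or a
#'   \code{SignalTrack}.
#' @param blacklist A \code{GRanges} of blacklisted regions (NULL or empty
#'   for no-op).
#' @return An object of the same kind as \code{x}.
#' @export
setGeneric("applyBlacklist", function(x, blacklist) standardGeneric("applyBlacklist"))

#' @rdname applyBlacklist
#' @export
setMethod("applyBlacklist", "GRanges", function(x, blacklist) {
  if (is.null(blacklist) || length(blacklist) == 0L) return(x)
  hits <- overlapsAny(x, blacklist, ignore.strand = TRUE)
  x[!hits]
})

#' @rdname applyBlacklist
#' @export
setMethod("applyBlacklist", "SignalTrack", function(x, blacklist) {
  if (is.null(blacklist) || length(blacklist) == 0L) return(x)
  si <- seqinfo(x)
  bl <- blacklist[as.character(seqnames(blacklist)) %in% seqnames(si)]
  mask <- coverage(GRanges(seqnames(bl), IRanges(start(bl), end(bl))),
                   width = as.list(seqlengths(si)))
  sig <- trackSignal(x) * (1 - (mask > 0L))
  initialize(x, signal = sig)
})

#' Downsample fragments
#'
#' Uniform sample of \code{n} fragments without replacement, deterministic
#' for a fixed seed. Used to emulate smaller pseudobulk library sizes.
#'
#' @param fragments A fragments \code{GRanges}.
#' @param n Number of fragments to retain.
#' @param seed Integer seed.
#' @return A \code{GRanges} of \code{n} fragments (original order).
#' @export
downsampleFragments <- function(fragments, n, seed) {
  total <- length(fragments)
  if (n > total)
    stop("cannot downsample to ", n, " fragments: only ", total, " available")
  idx <- withSeed(seed, sample.int(total, n))
  fragments[sort(idx)]
}

#' Full ATAC-seq signal preparation
#'
#' Runs the complete signal pipeline on one library: cut-site inference,
#' blacklist filtering, smoothing, coverage, RP20M depth scaling and robust
#' min-max normalization.
#'
#' @param x Reads or fragments \code{GRanges} (see [inferCutSites()]).
#' @param seqinfo A \code{Seqinfo}.
#' @param blacklist Optional blacklist \code{GRanges}.
#' @param config A [signalConfig()].
#' @param mode Passed to [inferCutSites()].
#' @return A list with elements \code{raw}, \code{rp20m}, \code{minmax}
#'   (three \code{SignalTrack}s), \code{params} (\code{MinMaxParams}) and
#'   \code{depth} (cut sites inferred before blacklist filtering).
#' @export
prepareSignal <- function(x, seqinfo, blacklist = NULL,
                          config = signalConfig(),
                          mode = c("auto", "reads", "fragments")) {
  cuts <- inferCutSites(x, config, mode = match.arg(mode))
  seqinfo(cuts) <- seqinfo
  depth <- length(cuts)
  cuts <- applyBlacklist(cuts, blacklist)
  windows <- smoothCutSites(cuts, config, seqinfo)
  raw <- coverageTrack(windows, 1, seqinfo)
  rp20m <- coverageTrack(windows,
                         rp20mScaleFactor(depth, config$target_depth),
                         seqinfo, normalization = "RP20M")
  params <- fitMinMax(rp20m, config$minmax_percentile)
  minmax <- minmaxNormalize(rp20m, params, clip = config$clip_max)
  list(raw = raw, rp20m = rp20m, minmax = minmax, params = params,
       depth = depth)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}
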