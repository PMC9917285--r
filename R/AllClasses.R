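#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import GenomeInfoDb
#' @import Biostrings
#' @importFrom rtracklayer export.bw import.bw
#' @importFrom jsonlite write_json
#' @importFrom stats runif setNames
#' @importFrom utils read.table write.table
#' @useDynLib bindcast, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' SignalTrack: dense per-base genomic signal
#'
#' A per-base numeric coverage track over named chromosomes, stored
#' run-length encoded (\code{RleList}, one \code{Rle} per chromosome, one
#' value per bp). The \code{normalization} slot records the processing state
#' of the values: \code{"raw"} (cut-site counts), \code{"RP20M"}
#' (reads-per-20-million depth scaling), \code{"minmax"} (robust min-max
#' normalized to [0,1]) or \code{"other"} (e.g. ChIP -log10 p-values).
#'
#' @slot signal An \code{RleList} of numeric values, one element per
#'   chromosome, each of length equal to the chromosome length.
#' @slot seqinfo A \code{Seqinfo} giving the governing chromosome sizes.
#' @slot normalization Character scalar, one of \code{"raw"}, \code{"RP20M"},
#'   \code{"minmax"}, \code{"other"}.
#' @slot minmaxParams A list, empty unless \code{normalization == "minmax"},
#'   with elements \code{min}, \code{max_p}, \code{percentile}.
#' @export
setClass("SignalTrack",
  representation(
    signal = "RleList",
    seqinfo = "Seqinfo",
    normalization = "character",
    minmaxParams = "list"
  ),
  prototype(normalization = "raw", minmaxParams = list())
)

setValidity("SignalTrack", function(object) {
  msgs <- character()
  sl <- seqlengths(object@seqinfo)
  sig <- object@signal
  if (!identical(sort(names(sig)), sort(names(sl))))
    msgs <- c(msgs, "signal chromosomes must match seqinfo")
  else {
    for (chr in names(sig)) {
      if (length(sig[[chr]]) != sl[[chr]])
        msgs <- c(msgs, sprintf("length of signal on %s (%d) != chromosome length (%d)",
                                chr, length(sig[[chr]]), sl[[chr]]))
      if (any(runValue(sig[[chr]]) < 0))
        msgs <- c(msgs, sprintf("negative signal values on %s", chr))
    }
  }
  if (length(object@normalization) != 1L ||
      !object@normalization %in% c("raw", "RP20M", "minmax", "other"))
    msgs <- c(msgs, "normalization must be one of raw/RP20M/minmax/other")
  if (object@normalization == "minmax" &&
      !isFALSE(object@minmaxParams$clipped)) {
    mx <- suppressWarnings(max(vapply(sig, function(r)
      if (length(r)) max(runValue(r)) else 0, numeric(1))))
    if (is.finite(mx) && mx > 1 + 1e-9)
      msgs <- c(msgs, "minmax-normalized track has values > 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SignalTrack
#'
#' @param signal A named \code{RleList} or a named list of numeric vectors,
#'   one per chromosome.
#' @param seqinfo A \code{Seqinfo} object (see [readChromSizes()]).
#' @param normalization Processing state of the values.
#' @param minmaxParams Optional list with \code{min}, \code{max_p},
#'   \code{percentile} (required when \code{normalization == "minmax"}).
#' @return A \code{SignalTrack}.
#' @examples
#' si <- GenomeInfoDb::Seqinfo("chrT", 10L)
#' SignalTrack(list(chrT = c(0, 0, 1, 2, 2, 1, 0, 0, 0, 0)), si)
#' @export
SignalTrack <- function(signal, seqinfo,
                        normalization = c("raw", "RP20M", "minmax", "other"),
                        minmaxParams = list()) {
  normalization <- match.arg(normalization)
  if (!is(signal, "RleList"))
    signal <- RleList(lapply(signal, Rle), compress = FALSE)
  signal <- signal[names(seqlengths(seqinfo))]
  new("SignalTrack", signal = signal, seqinfo = seqinfo,
      normalization = normalization, minmaxParams = minmaxParams)
}

#' @describeIn SignalTrack-class Per-chromosome signal as an \code{RleList}.
#' @param x,object A \code{SignalTrack}.
#' @export
setGeneric("trackSignal", function(x) standardGeneric("trackSignal"))
#' @export
setMethod("trackSignal", "SignalTrack", function(x) x@signal)

#' @describeIn SignalTrack-class Normalization state.
#' @export
setGeneric("normalizationState", function(x) standardGeneric("normalizationState"))
#' @export
setMethod("normalizationState", "SignalTrack", function(x) x@normalization)

#' @export
setMethod("seqinfo", "SignalTrack", function(x) x@seqinfo)

setMethod("show", "SignalTrack", function(object) {
  sl <- seqlengths(object@seqinfo)
  cat("SignalTrack across", length(sl), "chromosome(s) [",
      object@normalization, "]\n")
  tot <- sum(vapply(object@signal, function(r) sum(as.numeric(runLength(r)) * runValue(r)),
                    numeric(1)))
  cat("  total signal:", format(tot), " genome:", sum(as.numeric(sl)), "bp\n")
  if (length(object@minmaxParams))
    cat(sprintf("  minmax params: min=%g max_p=%g (p=%g)\n",
                object@minmaxParams$min, object@minmaxParams$max_p,
                object@minmaxParams$percentile))
})

#' PredictionTrack: model scores at fixed bin resolution
#'
#' A \code{SignalTrack} whose values are model TFBS scores in [0,1], constant
#' within non-overlapping bins of \code{binWidth} bp (32 bp for the default
#' architecture). Blacklisted bins hold 0.
#'
#' @slot binWidth Width in bp of the scored bins.
#' @export
setClass("PredictionTrack", contains = "SignalTrack",
         representation(binWidth = "integer"),
         prototype(binWidth = 32L, normalization = "other"))

setValidity("PredictionTrack", function(object) {
  mx <- suppressWarnings(max(vapply(object@signal, function(r)
    if (length(r)) max(runValue(r)) else 0, numeric(1))))
  if (is.finite(mx) && mx > 1 + 1e-9) "prediction scores must lie in [0,1]" else TRUE
})

#' @describeIn PredictionTrack-class Bin width accessor.
#' @param x A \code{PredictionTrack}.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))
#' @export
setMethod("binWidth", "PredictionTrack", function(x) x@binWidth)

setMethod("show", "PredictionTrack", function(object) {
  cat("PredictionTrack (", object@binWidth, "bp bins) across ",
      length(seqlengths(object@seqinfo)), " chromosome(s)\n", sep = "")
})

#' MinMaxParams: robust min-max normalization parameters
#'
#' Parameters of the robust min-max transform: signal is mapped to
#' \code{(signal - min) / (max_p - min)}, where \code{max_p} is the
#' \code{percentile}-th nearest-rank percentile of the nonzero per-base
#' signal and \code{min} is fixed at the signal floor (0 for coverage).
#'
#' @slot min Numeric, minimum (floor) of the transform.
#' @slot max_p Numeric, percentile signal value used as the robust maximum.
#' @slot percentile Percent in (0, 100] defining \code{max_p}.
#' @export
setClass("MinMaxParams",
  representation(min = "numeric", max_p = "numeric", percentile = "numeric"))

setValidity("MinMaxParams", function(object) {
  if (object@max_p <= object@min) "max_p must exceed min"
  else if (object@percentile <= 0 || object@percentile > 100)
    "percentile must lie in (0, 100]"
  else TRUE
})

#' @rdname MinMaxParams-class
#' @param min,max_p,percentile See slots.
#' @export
MinMaxParams <- function(min, max_p, percentile) {
  new("MinMaxParams", min = min, max_p = max_p, percentile = percentile)
}

setMethod("show", "MinMaxParams", function(object) {
  cat(sprintf("MinMaxParams: min=%g, max_p=%g (percentile %g%%)\n",
              object@min, object@max_p, object@percentile))
})

#' ArchitectureSpec: hyperparameters of the dilated convolutional network
#'
#' Captures every printed hyperparameter of the TFBS model: 1,024 bp input
#' with 5 channels (4 one-hot DNA + 1 accessibility signal), 5 convolutional
#' blocks of two same-padded, ReLU-activated width-7 convolutions each, batch
#' normalization per block, width-2 max pooling between blocks, filter counts
#' growing from 15 by a factor of 1.5 per block (truncated: 15, 22, 33, 50,
#' 75), dilation schedule 1, 1, 2, 4, 8 over the blocks plus 16 on a final
#' two-layer convolutional stage, and a sigmoid-activated output convolution
#' emitting one score per 32 bp bin (32 bins over 1,024 bp).
#'
#' @slot inputLength Input window length in bp.
#' @slot inputChannels Input channels (4 one-hot + 1 signal).
#' @slot nBlocks Number of convolutional blocks.
#' @slot layersPerBlock Convolution layers per block.
#' @slot kernelWidth Convolution kernel width in taps.
#' @slot baseFilters Filters in the first block.
#' @slot filterGrowth Per-block filter growth factor.
#' @slot dilationSchedule Dilation rates; one per block plus one for the
#'   final pre-output stage.
#' @slot poolWidth Max-pooling width (= stride).
#' @slot outputBins Number of output bins (sigmoid scores).
#' @export
setClass("ArchitectureSpec",
  representation(
    inputLength = "integer", inputChannels = "integer",
    nBlocks = "integer", layersPerBlock = "integer",
    kernelWidth = "integer", baseFilters = "integer",
    filterGrowth = "numeric", dilationSchedule = "integer",
    poolWidth = "integer", outputBins = "integer"
  )
)

setValidity("ArchitectureSpec", function(object) {
  msgs <- character()
  cnt <- c(object@inputLength, object@inputChannels, object@nBlocks,
           object@layersPerBlock, object@kernelWidth, object@baseFilters,
           object@poolWidth, object@outputBins)
  if (any(cnt < 1L)) msgs <- c(msgs, "all counts must be >= 1")
  if (object@filterGrowth <= 0) msgs <- c(msgs, "filterGrowth must be > 0")
  if (length(object@dilationSchedule) < object@nBlocks)
    msgs <- c(msgs, "need at least one dilation rate per block")
  if (object@inputLength %% object@outputBins != 0L)
    msgs <- c(msgs, "inputLength must be divisible by outputBins")
  ratio <- object@inputLength %/% object@outputBins
  np <- log(ratio) / log(object@poolWidth)
  if (abs(np - round(np)) > 1e-9)
    msgs <- c(msgs, sprintf(
      "inputLength/outputBins = %d is not a power of poolWidth %d; cannot derive pooling stages",
      ratio, object@poolWidth))
  if (length(msgs)) msgs else TRUE
})

#' Construct an ArchitectureSpec
#'
#' Defaults reproduce the published network exactly; see
#' \linkS4class{ArchitectureSpec}.
#'
#' @param inputLength,inputChannels,nBlocks,layersPerBlock,kernelWidth
#'   Architecture counts; see slots.
#' @param baseFilters,filterGrowth Filter schedule; block k holds
#'   \code{trunc(baseFilters * filterGrowth^(k-1))} filters.
#' @param dilationSchedule Integer dilation rates: one per block, plus a
#'   final entry applied to a two-layer convolutional stage preceding the
#'   sigmoid output.
#' @param poolWidth,outputBins Pooling width and number of output bins; the
#'   number of pooling stages is derived so that
#'   \code{inputLength / poolWidth^stages == outputBins}.
#' @return An \code{ArchitectureSpec}.
#' @examples
#' spec <- architectureSpec()
#' blockFilters(spec, 5)  # 75
#' @export
architectureSpec <- function(inputLength = 1024L, inputChannels = 5L,
                             nBlocks = 5L, layersPerBlock = 2L,
                             kernelWidth = 7L, baseFilters = 15L,
                             filterGrowth = 1.5,
                             dilationSchedule = c(1L, 1L, 2L, 4L, 8L, 16L),
                             poolWidth = 2L, outputBins = 32L) {
  new("ArchitectureSpec",
      inputLength = as.integer(inputLength),
      inputChannels = as.integer(inputChannels),
      nBlocks = as.integer(nBlocks),
      layersPerBlock = as.integer(layersPerBlock),
      kernelWidth = as.integer(kernelWidth),
      baseFilters = as.integer(baseFilters),
      filterGrowth = filterGrowth,
      dilationSchedule = as.integer(dilationSchedule),
      poolWidth = as.integer(poolWidth),
      outputBins = as.integer(outputBins))
}

setMethod("show", "ArchitectureSpec", function(object) {
  filt <- vapply(seq_len(object@nBlocks), function(k) blockFilters(object, k),
                 integer(1))
  cat("ArchitectureSpec:", object@inputLength, "bp x",
      object@inputChannels, "channels ->", object@outputBins, "bins\n")
  cat("  blocks:", object@nBlocks, "x", object@layersPerBlock,
      "conv layers, kernel", object@kernelWidth, "\n")
  cat("  filters:", paste(filt, collapse = ", "), "\n")
  cat("  dilations:", paste(object@dilationSchedule, collapse = ", "), "\n")
})

#' ModelHandle: a (possibly trained) network with its specification
#'
#' Opaque container pairing an \linkS4class{ArchitectureSpec} with the layer
#' parameters, the initialization seed and (after training) the per-epoch
#' history. The forward pass maps an \code{inputLength x inputChannels}
#' window to \code{outputBins} sigmoid scores in [0,1].
#'
#' @slot spec The \code{ArchitectureSpec}.
#' @slot params List of layer parameter sets (internal layout).
#' @slot seed Integer seed used for Glorot initialization.
#' @slot trained Logical; TRUE after [trainModel()].
#' @slot history data.frame of per-epoch loss and validation dice
#'   (empty before training).
#' @export
setClass("ModelHandle",
  representation(spec = "ArchitectureSpec", params = "list",
                 seed = "integer", trained = "logical",
                 history = "data.frame"),
  prototype(trained = FALSE, history = data.frame()))

#' @describeIn ModelHandle-class Architecture accessor.
#' @param x A \code{ModelHandle}.
#' @export
setGeneric("modelSpec", function(x) standardGeneric("modelSpec"))
#' @export
setMethod("modelSpec", "ModelHandle", function(x) x@spec)

#' @describeIn ModelHandle-class Training history accessor.
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
#' @export
setMethod("trainingHistory", "ModelHandle", function(x) x@history)

setMethod("show", "ModelHandle", function(object) {
  np <- sum(vapply(object@params, function(l)
    sum(vapply(l[names(l) %in% c("W", "b", "gamma", "beta")], length,
               integer(1))), integer(1)))
  cat("ModelHandle:", if (object@trained) "trained" else "untrained",
      "network,", np, "parameters (seed", object@seed, ")\n")
  show(object@spec)
  if (nrow(object@history)) {
    best <- which.max(object@history$val_dice)
    cat(sprintf("  best epoch %d: val dice %.4f\n", best,
                object@history$val_dice[best]))
  }
})

#' Pwm: position weight matrix
#'
#' Per-position nucleotide probabilities for a TF motif, with a background
#' model and pseudocount regularization (each column sums to 1 after adding
#' the pseudocount).
#'
#' @slot id Motif identifier.
#' @slot matrix 4 x width numeric matrix, rows A, C, G, T, columns summing
#'   to 1.
#' @slot background Length-4 background nucleotide probabilities.
#' @slot pseudocount Pseudocount applied when regularizing probabilities.
#' @export
setClass("Pwm",
  representation(id = "character", matrix = "matrix",
                 background = "numeric", pseudocount = "numeric"))

setValidity("Pwm", function(object) {
  msgs <- character()
  if (nrow(object@matrix) != 4L) msgs <- c(msgs, "matrix must have 4 rows (A,C,G,T)")
  if (any(abs(colSums(object@matrix) - 1) > 1e-6))
    msgs <- c(msgs, "each PWM position must sum to 1")
  if (length(object@background) != 4L || abs(sum(object@background) - 1) > 1e-6)
    msgs <- c(msgs, "background must be 4 probabilities summing to 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Pwm
#'
#' @param matrix 4 x width matrix of nucleotide probabilities (rows A,C,G,T).
#' @param id Motif identifier.
#' @param background Background probabilities (default uniform).
#' @param pseudocount Added to every entry before renormalizing columns, so
#'   that log-odds scores stay finite.
#' @return A \code{Pwm}.
#' @export
Pwm <- function(matrix, id = "motif", background = rep(0.25, 4),
                pseudocount = 1e-4) {
  matrix <- sweep(matrix + pseudocount, 2, colSums(matrix + pseudocount), "/")
  rownames(matrix) <- c("A", "C", "G", "T")
  new("Pwm", id = id, matrix = matrix, background = background,
      pseudocount = pseudocount)
}

setMethod("show", "Pwm", function(object) {
  cat("Pwm", object@id, "of width", ncol(object@matrix), "\n")
  print(round(object@matrix, 3))
})
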