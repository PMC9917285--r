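# Deterministic toy genomes with planted TF motifs, cell-type-specific
# accessibility and matched ChIP gold standards, so the whole pipeline is
# testable end-to-end without downloads.

#' Synthetic-fixture configuration
#'
#' Describes a toy study: a uniform-background genome whose chromosomes
#' map onto the default chromosome split (chr1 test, chr2 validation,
#' chr3/chr4 training), candidate accessible regions, a planted consensus
#' motif, and per-cell-type accessibility/binding structure. A region is
#' bound (a true TFBS, hence a ChIP peak) in a cell type only if it
#' carries the motif and is accessible in that cell type, emulating
#' context-specific TF binding.
#'
#' @param seed Integer master seed; generation is fully deterministic.
#' @param chrom_lengths Named chromosome lengths in bp.
#' @param motif Consensus motif string planted verbatim.
#' @param n_cell_types Number of cell types.
#' @param accessible_region_count Candidate regions per 100 kb of
#'   chromosome.
#' @param region_width Accessible-region width in bp.
#' @param motif_fraction Fraction of candidate regions carrying a planted
#'   motif.
#' @param shared_fraction Fraction of candidate regions accessible in
#'   every cell type; the rest are each accessible in a single cell type
#'   (cell-type specificity).
#' @param bound_fraction Probability that an accessible, motif-carrying
#'   region is bound in a given cell type.
#' @param n_fragments Fragments per cell-type library.
#' @param enrichment Coverage enrichment of accessible over background
#'   regions (the lambda_high / lambda_low ratio).
#' @param fragment_length Min/max uniform fragment length in bp.
#' @param noise_rate Fraction of bases receiving background ChIP-signal
#'   noise.
#' @return A list of class \code{"FixtureConfig"}.
#' @export
fixtureConfig <- function(seed = 1L,
                          chrom_lengths = c(chr1 = 50000L, chr2 = 50000L,
                                            chr3 = 100000L, chr4 = 100000L),
                          motif = "TGACGTCA", n_cell_types = 2L,
                          accessible_region_count = 40L, region_width = 500L,
                          motif_fraction = 0.6, shared_fraction = 0.5,
                          bound_fraction = 0.85, n_fragments = 30000L,
                          enrichment = 10, fragment_length = c(80L, 250L),
                          noise_rate = 0.01) {
  stopifnot(all(chrom_lengths > 0), n_cell_types >= 1L, enrichment >= 1)
  margin <- 2000L
  if (any(chrom_lengths < 2L * margin + region_width))
    stop("chromosomes too short for the requested regions")
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 motif = motif, n_cell_types = as.integer(n_cell_types),
                 accessible_region_count = as.integer(accessible_region_count),
                 region_width = as.integer(region_width),
                 motif_fraction = motif_fraction,
                 shared_fraction = shared_fraction,
                 bound_fraction = bound_fraction,
                 n_fragments = as.integer(n_fragments),
                 enrichment = enrichment,
                 fragment_length = as.integer(fragment_length),
                 noise_rate = noise_rate, margin = margin),
            class = "FixtureConfig")
}

#' Generate a synthetic fixture
#'
#' Draws the genome (i.i.d. uniform background), places non-overlapping
#' candidate regions, plants the motif in a fraction of them, assigns
#' per-cell-type accessibility and binding, samples fragment libraries
#' enriched in accessible chromatin, and builds a ChIP signal track per
#' cell type (stepped peak pyramid over true TFBS plus sparse noise).
#' Deterministic for a fixed seed; optionally writes all files to
#' \code{dir} (FASTA, chrom.sizes, per-cell fragments TSV and BEDs,
#' bedGraph ChIP signal, blacklist BED, truth JSON).
#'
#' @param config A [fixtureConfig()].
#' @param dir Optional output directory.
#' @return A list of class \code{"FixtureTruth"}: \code{genome}
#'   (\code{DNAStringSet}), \code{seqinfo}, \code{blacklist},
#'   \code{motifSites} (\code{GRanges}), \code{cellTypes} (per cell type:
#'   \code{accessible}, \code{chipPeaks}, \code{fragments},
#'   \code{chipSignal}) and \code{config}.
#' @export
generateFixture <- function(config = fixtureConfig(), dir = NULL) {
  withSeed(config$seed, {
    sl <- config$chrom_lengths
    si <- Seqinfo(names(sl), unname(as.integer(sl)))
    bases <- c("A", "C", "G", "T")
    genome <- DNAStringSet(vapply(names(sl), function(chr)
      paste(sample(bases, sl[[chr]], replace = TRUE), collapse = ""),
      character(1)))
    names(genome) <- names(sl)

    # candidate regions on a gapped grid (never overlapping, clear of the
    # chromosome margins and of the blacklist placed in the tail margin)
    w <- config$region_width
    regions <- do.call(c, lapply(names(sl), function(chr) {
      nR <- max(1L, as.integer(round(config$accessible_region_count *
                                       sl[[chr]] / 1e5)))
      slots <- seq(config$margin, sl[[chr]] - config$margin - w,
                   by = w + 100L)
      starts <- sort(sample(slots, min(nR, length(slots))))
      GRanges(chr, IRanges(starts, width = w), seqinfo = si)
    }))
    nR <- length(regions)
    blacklist <- GRanges(names(sl),
                         IRanges(unname(sl) - 1500L, width = 1000L),
                         seqinfo = si)

    # plant the motif at region centers
    hasMotif <- runif(nR) < config$motif_fraction
    mw <- nchar(config$motif)
    motifStart <- (start(regions) + end(regions)) %/% 2L - mw %/% 2L
    for (i in which(hasMotif)) {
      chr <- as.character(seqnames(regions)[i])
      genome[[chr]] <- replaceMotif(genome[[chr]], motifStart[i],
                                    config$motif)
    }
    motifSites <- GRanges(seqnames(regions)[hasMotif],
                          IRanges(motifStart[hasMotif], width = mw),
                          seqinfo = si)

    # accessibility: shared regions open everywhere, the rest in one cell
    ctNames <- paste0("cell", seq_len(config$n_cell_types))
    shared <- runif(nR) < config$shared_fraction
    owner <- sample(config$n_cell_types, nR, replace = TRUE)
    cellTypes <- setNames(vector("list", length(ctNames)), ctNames)
    G <- sum(as.numeric(sl))
    for (c in seq_along(ctNames)) {
      acc <- regions[shared | owner == c]
      bound <- acc[overlapsAny(acc, motifSites) &
                     runif(length(acc)) < config$bound_fraction]
      chip <- GRanges(seqnames(bound),
                      IRanges((start(bound) + end(bound)) %/% 2L - 99L,
                              width = 200L), seqinfo = si)
      fragments <- sampleFragments(acc, si, config, G)
      chipSignal <- chipSignalTrack(chip, si, config)
      cellTypes[[c]] <- list(name = ctNames[c], accessible = acc,
                             chipPeaks = chip, fragments = fragments,
                             chipSignal = chipSignal)
    }
    truth <- structure(list(genome = genome, seqinfo = si,
                            blacklist = blacklist, motifSites = motifSites,
                            cellTypes = cellTypes, config = config),
                       class = "FixtureTruth")
    if (!is.null(dir)) writeFixture(truth, dir)
    truth
  })
}

# Substitute `motif` into `seq` at 1-based position `at`.
replaceMotif <- function(seq, at, motif) {
  replaceLetterAt(seq, at:(at + nchar(motif) - 1L), motif)
}

# Fragment library: mixture of uniform-over-accessible and
# uniform-over-genome fragment midpoints, mixed so that mean coverage in
# accessible regions is `enrichment` times the background.
sampleFragments <- function(accessible, si, config, G) {
  A <- sum(width(accessible))
  q <- (config$enrichment - 1) * A / (G + (config$enrichment - 1) * A)
  n <- config$n_fragments
  inAcc <- runif(n) < q
  sl <- seqlengths(si)
  cumG <- cumsum(as.numeric(sl))
  lens <- sample(seq(config$fragment_length[1L], config$fragment_length[2L]),
                 n, replace = TRUE)
  mids <- integer(n)
  chrom <- character(n)
  # accessible draws: uniform over the accessible bp
  if (any(inAcc)) {
    cw <- cumsum(width(accessible))
    pos <- sample.int(A, sum(inAcc), replace = TRUE)
    ri <- findInterval(pos - 1L, c(0L, cw), left.open = FALSE)
    off <- pos - c(0L, cw)[ri] - 1L
    chrom[inAcc] <- as.character(seqnames(accessible)[ri])
    mids[inAcc] <- start(accessible)[ri] + off
  }
  if (any(!inAcc)) {
    pos <- ceiling(runif(sum(!inAcc)) * G)
    ci <- findInterval(pos - 1, c(0, cumG), left.open = FALSE)
    chrom[!inAcc] <- names(sl)[ci]
    mids[!inAcc] <- as.integer(pos - c(0, cumG)[ci])
  }
  st <- pmax(1L, mids - lens %/% 2L)
  en <- pmin(st + lens - 1L, sl[chrom])
  st <- pmax(1L, pmin(st, en - 1L))
  gr <- GRanges(chrom, IRanges(st, en),
                barcode = sprintf("BC%06d", sample.int(4000L, n, replace = TRUE)),
                count = rep(1L, n), seqinfo = si)
  sort(gr, ignore.strand = TRUE)
}

# ChIP -log10 p-value-like track: stepped pyramid over each true TFBS plus
# sparse exponential background noise.
chipSignalTrack <- function(chip, si, config) {
  sl <- seqlengths(si)
  core <- coverage(chip, width = as.list(sl)) * 6
  mid <- coverage(resize(chip, width(chip) + 100L, fix = "center"),
                  width = as.list(sl)) * 3
  outer <- coverage(resize(chip, width(chip) + 300L, fix = "center"),
                    width = as.list(sl)) * 1
  noiseN <- round(config$noise_rate * sum(as.numeric(sl)))
  noiseChrom <- sample(names(sl), noiseN, replace = TRUE,
                       prob = as.numeric(sl))
  noise <- do.call(c, lapply(names(sl), function(chr) {
    cnt <- sum(noiseChrom == chr)
    GRanges(chr, IRanges(sample.int(sl[[chr]], cnt, replace = TRUE),
                         width = 1L), seqinfo = si)
  }))
  nz <- coverage(noise, width = as.list(sl)) * 0.5
  SignalTrack(core + mid + outer + nz, si, normalization = "other")
}

#' Write a fixture to disk
#'
#' Emits \code{ref.fa}, \code{chrom.sizes}, \code{blacklist.bed},
#' \code{truth.json} and, per cell type, \code{<cell>.fragments.tsv},
#' \code{<cell>.atac_peaks.bed}, \code{<cell>.chip_peaks.bed} and
#' \code{<cell>.chip_pval.bedgraph}.
#'
#' @param truth A \code{"FixtureTruth"} from [generateFixture()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
writeFixture <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeXStringSet(truth$genome, file.path(dir, "ref.fa"))
  sl <- seqlengths(truth$seqinfo)
  write.table(data.frame(names(sl), unname(sl)),
              file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeBed(truth$blacklist, file.path(dir, "blacklist.bed"))
  for (ct in truth$cellTypes) {
    writeFragments(ct$fragments,
                   file.path(dir, paste0(ct$name, ".fragments.tsv")))
    writeBed(ct$accessible,
             file.path(dir, paste0(ct$name, ".atac_peaks.bed")))
    writeBed(ct$chipPeaks,
             file.path(dir, paste0(ct$name, ".chip_peaks.bed")))
    writeTrack(ct$chipSignal,
               file.path(dir, paste0(ct$name, ".chip_pval.bedgraph")))
  }
  meta <- list(seed = truth$config$seed, motif = truth$config$motif,
               cell_types = names(truth$cellTypes),
               n_tfbs = lapply(truth$cellTypes, function(ct)
                 length(ct$chipPeaks)))
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Prepare fixture cell types for training
#'
#' Runs the full signal pipeline ([prepareSignal()]) on each cell type's
#' fragment library and assembles \linkS4class{CellTypeData} objects.
#'
#' @param truth A \code{"FixtureTruth"}.
#' @param config A [signalConfig()].
#' @return A named list of \code{CellTypeData}.
#' @export
prepareFixtureCellTypes <- function(truth, config = signalConfig()) {
  out <- lapply(truth$cellTypes, function(ct) {
    prep <- prepareSignal(ct$fragments, truth$seqinfo, truth$blacklist,
                          config, mode = "fragments")
    cellTypeData(ct$name, prep$minmax, ct$accessible, ct$chipPeaks,
                 ct$chipSignal)
  })
  setNames(out, names(truth$cellTypes))
}

#' Oracle prediction track
#'
#' The "cheating" score track: 1 on every bin overlapping a true TFBS of
#' the given cell type, 0 elsewhere. Calibrates the benchmark ceiling
#' (perfect ranking yields AUPR 1).
#'
#' @param truth A \code{"FixtureTruth"}.
#' @param cellType Cell-type name.
#' @param bin_width Score bin width in bp (default 32).
#' @return A \linkS4class{PredictionTrack}.
#' @export
oracleScores <- function(truth, cellType, bin_width = 32L) {
  chip <- truth$cellTypes[[cellType]]$chipPeaks
  sl <- seqlengths(truth$seqinfo)
  out <- setNames(vector("list", length(sl)), names(sl))
  for (chr in names(sl)) {
    len <- sl[[chr]]
    nBins <- ceiling(len / bin_width)
    binGr <- GRanges(chr, IRanges((seq_len(nBins) - 1L) * bin_width + 1L,
                                  width = bin_width))
    scores <- as.numeric(overlapsAny(binGr, chip, ignore.strand = TRUE))
    out[[chr]] <- S4Vectors::window(Rle(rep(scores, each = bin_width)),
                                    1L, len)
  }
  new("PredictionTrack", signal = RleList(out, compress = FALSE),
      seqinfo = truth$seqinfo, normalization = "other",
      minmaxParams = list(), binWidth = as.integer(bin_width))
}
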