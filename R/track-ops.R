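## The `scale` engine: scaling factors, smoothing, two-file operations and
## the assay presets (rfd, reptime, endseq/endseqr).

#' Genome-size scaling factor
#'
#' `genomeLength / alignedBases`: the reciprocal of mean sequencing depth.
#' Multiplying a coverage track by it reduces per-bin coverage when more
#' bases were sequenced than the genome holds and raises it otherwise, so
#' separately scaled samples become directly comparable without being
#' co-processed.
#'
#' @param stats a \linkS4class{LibraryStats}.
#' @return a positive scalar.
#' @examples
#' genomeSizeFactor(LibraryStats(10, 10, 2000, 1000))  # 0.5
#' @export
genomeSizeFactor <- function(stats) {
    if (stats@alignedBases <= 0)
        stop("cannot compute genome-size factor: no aligned bases")
    stats@genomeLength / stats@alignedBases
}

#' Smallest-library scaling factors
#'
#' For a set of co-processed samples, `min(nReads) / nReads[s]` per sample:
#' the smallest library keeps factor 1, deeper ones are scaled down.
#'
#' @param statsList a list of \linkS4class{LibraryStats}.
#' @param useFragments scale by fragment counts instead of read counts.
#' @return numeric vector of factors in input order.
#' @export
libsizeFactors <- function(statsList, useFragments = FALSE) {
    if (length(statsList) == 0L) stop("empty sample set")
    n <- vapply(statsList, function(s)
        if (useFragments) s@nFragments else s@nReads, numeric(1))
    if (any(n <= 0)) stop("every library must have at least one read")
    min(n) / n
}

.sameGeometry <- function(t1, t2) {
    if (t1@binSize != t2@binSize)
        stop("tracks have different bin sizes (", t1@binSize, " vs ",
             t2@binSize, ")")
    if (!identical(seqlengths(t1@seqinfo), seqlengths(t2@seqinfo)))
        stop("tracks are defined on different reference geometries")
    invisible(TRUE)
}

#' Scale track values by a constant factor
#'
#' @param track a \linkS4class{BinnedTrack} or \linkS4class{IntervalTrack}.
#' @param factor positive multiplier (e.g. from [genomeSizeFactor()],
#'   [libsizeFactors()] or a user-supplied custom factor such as a
#'   reciprocal DESeq2 size factor).
#' @return a track of the same class with every value multiplied and the
#'   semantics tag set to `"scaled"`.
#' @export
setGeneric("scaleTrack", function(track, factor) standardGeneric("scaleTrack"))

#' @rdname scaleTrack
#' @export
setMethod("scaleTrack", "BinnedTrack", function(track, factor) {
    if (factor <= 0) stop("scaling factor must be positive")
    track@values <- lapply(track@values, `*`, factor)
    track@semantics <- "scaled"
    track
})

#' @rdname scaleTrack
#' @export
setMethod("scaleTrack", "IntervalTrack", function(track, factor) {
    if (factor <= 0) stop("scaling factor must be positive")
    track@runs$score <- track@runs$score * factor
    track@semantics <- "scaled"
    track
})

## truncated running mean over window [i - n, i + n]
.smoothVec <- function(v, n) {
    L <- length(v)
    if (n == 0L || L == 0L) return(v)
    cs <- cumsum(c(0, v))
    i <- seq_len(L)
    lo <- pmax(i - n, 1L)
    hi <- pmin(i + n, L)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth a binned track over adjacent bins
#'
#' Replaces each bin by the mean over the `nAdjacent` bins on either side
#' (a window of `2 * nAdjacent + 1` bins), truncated at chromosome ends so
#' no implicit zeros bias the edges.  Smoothing never crosses chromosome
#' boundaries.  `nAdjacent = 0` is the identity.
#'
#' @param track a \linkS4class{BinnedTrack}.
#' @param nAdjacent number of bins on each side of the window.
#' @return a smoothed \linkS4class{BinnedTrack}.
#' @export
smoothTrack <- function(track, nAdjacent) {
    nAdjacent <- as.integer(nAdjacent)
    if (nAdjacent < 0L) stop("nAdjacent must be >= 0")
    track@values <- lapply(track@values, .smoothVec, n = nAdjacent)
    track
}

#' Bin-wise log2 ratio of two tracks
#'
#' `log2((v1 + p) / (v2 + p))` with the first track as numerator.  With the
#' default pseudocount `p = 0`, bins where either input is zero (or missing)
#' are set to `NA` and omitted by the writers, so no ratio is fabricated
#' from an empty bin; a positive pseudocount emits every bin.
#'
#' @param track1,track2 \linkS4class{BinnedTrack}s with identical bin size
#'   and reference geometry.
#' @param pseudocount non-negative value added to both terms.
#' @return a \linkS4class{BinnedTrack} tagged `"log2"`.
#' @export
log2Ratio <- function(track1, track2, pseudocount = 0) {
    .sameGeometry(track1, track2)
    if (pseudocount < 0) stop("pseudocount must be >= 0")
    vals <- mapply(function(v1, v2) {
        out <- log2((v1 + pseudocount) / (v2 + pseudocount))
        out[!is.finite(out)] <- NA_real_
        out
    }, track1@values, track2@values, SIMPLIFY = FALSE)
    BinnedTrack(track1@binSize, vals, track1@seqinfo, semantics = "log2")
}

#' Bin-wise difference of two tracks
#'
#' `v1 - v2`; values may be negative.
#'
#' @inheritParams log2Ratio
#' @return a \linkS4class{BinnedTrack} tagged `"difference"`.
#' @export
subtractTracks <- function(track1, track2) {
    .sameGeometry(track1, track2)
    vals <- mapply(`-`, track1@values, track2@values, SIMPLIFY = FALSE)
    BinnedTrack(track1@binSize, vals, track1@seqinfo,
                semantics = "difference")
}

#' Replication fork directionality (RFD) track from OK-seq data
#'
#' Computes forward-strand (Watson) and reverse-strand (Crick) binned
#' coverage under the same filter, then per bin
#' `RFD = (Crick - Watson) / (Crick + Watson)`, in `[-1, 1]`.  Bins with no
#' reads on either strand are `NA` (omitted on output), keeping a genuine 0
#' (balanced fork directions) distinguishable from no data.  A -/+ sign
#' change along a chromosome marks a replication initiation zone.
#'
#' @inheritParams binnedCoverage
#' @param binSize bin width in bp (OK-seq default 1000).
#' @return a \linkS4class{BinnedTrack} tagged `"rfd"`.
#' @export
rfdTrack <- function(bamPath, filter = AlignmentFilter(), binSize = 1000L,
                     orientation = c("forward", "reverse"), threads = 1L) {
    orientation <- match.arg(orientation)
    fwd <- binnedCoverage(bamPath, filter, binSize, spliceAware = FALSE,
                          strand = "forward", orientation = orientation,
                          threads = threads)
    rev <- binnedCoverage(bamPath, filter, binSize, spliceAware = FALSE,
                          strand = "reverse", orientation = orientation,
                          threads = threads)
    vals <- mapply(function(watson, crick) {
        tot <- crick + watson
        out <- (crick - watson) / tot
        out[tot == 0] <- NA_real_
        out
    }, fwd@values, rev@values, SIMPLIFY = FALSE)
    BinnedTrack(as.integer(binSize), vals, fwd@seqinfo, semantics = "rfd")
}

#' Replication timing log2-ratio track
#'
#' The replication-timing preset: binned coverage of the two BAM files at
#' `binSize`, each smoothed over `smoothen` adjacent bins, then the log2
#' ratio with the first file as numerator.  The defaults (100 bp bins,
#' 500-bin smoothing) suit bulk replication-timing data; single-cell
#' Repli-seq and BrdU-IP analyses typically use 50 kb bins with smoothing 4
#' (a 400 kb window).  Users choose the argument order to match the desired
#' sign convention.
#'
#' @param bamPath1,bamPath2 indexed BAM files on the same reference
#'   (numerator first).
#' @inheritParams binnedCoverage
#' @param smoothen bins on each side of the smoothing window.
#' @param pseudocount passed to [log2Ratio()].
#' @return a \linkS4class{BinnedTrack} tagged `"log2"`.
#' @export
reptimeTrack <- function(bamPath1, bamPath2, filter = AlignmentFilter(),
                         binSize = 100L, smoothen = 500L, pseudocount = 0,
                         threads = 1L) {
    si1 <- bamSeqinfo(bamPath1)
    si2 <- bamSeqinfo(bamPath2)
    if (!identical(seqlengths(si1), seqlengths(si2)))
        stop("the two BAM files are aligned to different references")
    t1 <- binnedCoverage(bamPath1, filter, binSize, threads = threads)
    t2 <- binnedCoverage(bamPath2, filter, binSize, threads = threads)
    log2Ratio(smoothTrack(t1, smoothen), smoothTrack(t2, smoothen),
              pseudocount = pseudocount)
}

#' Strand-resolved END-seq coverage tracks
#'
#' Computes separate forward- and reverse-strand coverage tracks for
#' DNA-break mapping data.  With `negateReverse` (the "endseqr" preset)
#' every reverse-strand value is multiplied by -1 so the two tracks can be
#' overlaid in one panel; otherwise both tracks are positive ("endseq").
#'
#' @inheritParams binnedCoverage
#' @param binSize bin width in bp (END-seq default 1).
#' @param negateReverse negate the reverse-strand track.
#' @return a named list with `forward` and `reverse`
#'   \linkS4class{BinnedTrack}s.
#' @export
endseqTracks <- function(bamPath, filter = AlignmentFilter(), binSize = 1L,
                         negateReverse = FALSE,
                         orientation = c("forward", "reverse"),
                         threads = 1L) {
    orientation <- match.arg(orientation)
    fwd <- binnedCoverage(bamPath, filter, binSize, strand = "forward",
                          orientation = orientation, threads = threads)
    rev <- binnedCoverage(bamPath, filter, binSize, strand = "reverse",
                          orientation = orientation, threads = threads)
    if (negateReverse) {
        rev@values <- lapply(rev@values, function(v) -v)
        rev@semantics <- "scaled"
    }
    list(forward = fwd, reverse = rev)
}
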