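## Writers: bigWig (via rtracklayer) and bedGraph (text fallback) from
## BinnedTrack / IntervalTrack, with exact coordinate bookkeeping.

#' @importFrom rtracklayer export.bw import
NULL

#' Convert a track to a GRanges of merged intervals
#'
#' For a \linkS4class{BinnedTrack}: drops `NA` bins, converts bin indices to
#' reference coordinates (the last bin of a chromosome keeps its true
#' width), and merges consecutive equal-valued bins into single intervals.
#' For an \linkS4class{IntervalTrack} the runs are returned as-is.
#' Chromosomes appear in BAM-header order, never re-sorted.
#'
#' @param track a \linkS4class{BinnedTrack} or \linkS4class{IntervalTrack}.
#' @return a [GenomicRanges::GRanges] with a `score` column.
#' @export
trackToGRanges <- function(track) {
    if (is(track, "IntervalTrack"))
        return(track@runs)
    if (!is(track, "BinnedTrack"))
        stop("expected a BinnedTrack or IntervalTrack")
    si <- track@seqinfo
    bin <- track@binSize
    sl <- seqlengths(si)
    parts <- lapply(names(track@values), function(chrom) {
        v <- track@values[[chrom]]
        n <- length(v)
        if (n == 0L) return(NULL)
        starts <- (seq_len(n) - 1L) * bin + 1L
        ends <- pmin(seq_len(n) * bin, sl[[chrom]])
        idx <- which(!is.na(v))
        if (length(idx) == 0L) return(NULL)
        ## merge consecutive equal-valued (and coordinate-adjacent) bins
        newGroup <- c(TRUE, diff(idx) != 1L |
                      v[idx[-1L]] != v[idx[-length(idx)]])
        grp <- cumsum(newGroup)
        first <- idx[!duplicated(grp)]
        last <- idx[!duplicated(grp, fromLast = TRUE)]
        GRanges(chrom, IRanges(starts[first], ends[last]),
                score = v[first], seqinfo = si)
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts) == 0L)
        return(GRanges(score = numeric(), seqinfo = si))
    do.call(c, parts)
}

#' Write a track as bigWig
#'
#' Emits 0-based half-open intervals with 32-bit float values, merged per
#' [trackToGRanges()]; `NA` bins are omitted.  The chromosome set and order
#' come from the track's BAM-header `Seqinfo`.  The file is readable by
#' standard genome browsers.
#'
#' @param track a \linkS4class{BinnedTrack} or \linkS4class{IntervalTrack}.
#' @param path output path (conventionally `.bw`; stranded callers use
#'   `<prefix>.fwd.bw` / `<prefix>.rev.bw`).
#' @return `path`, invisibly.
#' @export
writeBigWig <- function(track, path) {
    gr <- trackToGRanges(track)
    if (any(is.na(seqlengths(gr))))
        stop("track seqinfo lacks chromosome lengths; cannot write bigWig")
    export.bw(gr, path)
    invisible(path)
}

#' Write a track as bedGraph
#'
#' Text fallback with identical interval semantics to [writeBigWig()]:
#' 4 columns (chrom, 0-based start, end, value), values with 6 significant
#' digits, chromosomes in header order.  An empty track yields an empty
#' file.
#'
#' @inheritParams writeBigWig
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, path) {
    gr <- trackToGRanges(track)
    con <- file(path, "w")
    on.exit(close(con))
    if (length(gr))
        writeLines(sprintf("%s\t%d\t%d\t%.6g",
                           as.character(seqnames(gr)), start(gr) - 1L,
                           end(gr), gr$score), con)
    invisible(path)
}
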