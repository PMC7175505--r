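#' @import methods
#' @importFrom S4Vectors metadata mcols mcols<- DataFrame isSingleString
#' @importFrom GenomeInfoDb Seqinfo seqnames seqlengths seqinfo seqlevels
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

#' Alignment filter settings
#'
#' Read-level inclusion rules that define which alignments contribute to
#' library statistics, coverage and peak counts.  The defaults reproduce the
#' flag-based filtering a typical ChIP-seq/ATAC-seq workflow expects:
#' duplicates, secondary, supplementary, QC-fail and unmapped records are
#' dropped, paired reads whose mate maps to a different chromosome are
#' dropped, and no MAPQ cutoff is applied.
#'
#' @slot minMapq minimum MAPQ; reads below are excluded (default 0, i.e. no
#'   MAPQ filtering).
#' @slot dropDuplicates,dropSecondary,dropSupplementary,dropQcfail,dropUnmapped
#'   logical flag filters, all `TRUE` by default.
#' @slot requireSameChromMate drop paired reads whose mapped mate is on a
#'   different reference sequence (default `TRUE`).
#' @slot fragmentMode count properly paired reads as one fragment instead of
#'   two reads (default `FALSE`).  Affects peak counting and the effective
#'   library size.
#' @slot strandSelect one of `"both"`, `"forward"`, `"reverse"`,
#'   `"match_feature"`; restricts counting/coverage to reads assigned to one
#'   strand (see [assignedStrand()] for the paired-end strand convention).
#'
#' @seealso [readPassesFilter()], [computeLibraryStats()]
#' @export
setClass("AlignmentFilter",
    representation(
        minMapq = "integer",
        dropDuplicates = "logical",
        dropSecondary = "logical",
        dropSupplementary = "logical",
        dropQcfail = "logical",
        dropUnmapped = "logical",
        requireSameChromMate = "logical",
        fragmentMode = "logical",
        strandSelect = "character"
    )
)

setValidity("AlignmentFilter", function(object) {
    msg <- character()
    if (length(object@minMapq) != 1L || is.na(object@minMapq) ||
        object@minMapq < 0L)
        msg <- c(msg, "'minMapq' must be a single non-negative integer")
    for (s in c("dropDuplicates", "dropSecondary", "dropSupplementary",
                "dropQcfail", "dropUnmapped", "requireSameChromMate",
                "fragmentMode")) {
        v <- slot(object, s)
        if (length(v) != 1L || is.na(v))
            msg <- c(msg, sprintf("'%s' must be TRUE or FALSE", s))
    }
    if (length(object@strandSelect) != 1L ||
        !object@strandSelect %in% c("both", "forward", "reverse",
                                    "match_feature"))
        msg <- c(msg, "'strandSelect' must be one of both/forward/reverse/match_feature")
    if (length(msg)) msg else TRUE
})

#' @param minMapq,dropDuplicates,dropSecondary,dropSupplementary,dropQcfail,dropUnmapped,requireSameChromMate,fragmentMode,strandSelect
#'   see slot documentation.
#' @return `AlignmentFilter()` returns an \linkS4class{AlignmentFilter}
#'   object.
#' @examples
#' AlignmentFilter()
#' AlignmentFilter(minMapq = 30L, dropDuplicates = FALSE)
#' @rdname AlignmentFilter-class
#' @export
AlignmentFilter <- function(minMapq = 0L, dropDuplicates = TRUE,
                            dropSecondary = TRUE, dropSupplementary = TRUE,
                            dropQcfail = TRUE, dropUnmapped = TRUE,
                            requireSameChromMate = TRUE,
                            fragmentMode = FALSE,
                            strandSelect = c("both", "forward", "reverse",
                                             "match_feature")) {
    new("AlignmentFilter",
        minMapq = as.integer(minMapq),
        dropDuplicates = dropDuplicates,
        dropSecondary = dropSecondary,
        dropSupplementary = dropSupplementary,
        dropQcfail = dropQcfail,
        dropUnmapped = dropUnmapped,
        requireSameChromMate = requireSameChromMate,
        fragmentMode = fragmentMode,
        strandSelect = match.arg(strandSelect))
}

setMethod("show", "AlignmentFilter", function(object) {
    cat("AlignmentFilter\n")
    cat("  minMapq:", object@minMapq, "\n")
    cat("  drop: ",
        paste(c("duplicates", "secondary", "supplementary", "qcfail",
                "unmapped")[c(object@dropDuplicates, object@dropSecondary,
                              object@dropSupplementary, object@dropQcfail,
                              object@dropUnmapped)], collapse = ", "),
        "\n", sep = "")
    cat("  requireSameChromMate:", object@requireSameChromMate, "\n")
    cat("  fragmentMode:", object@fragmentMode,
        " strandSelect:", object@strandSelect, "\n")
})

#' Per-library alignment statistics
#'
#' Counts obtained from a full filtered pass over a BAM file: the number of
#' filter-passing reads, the number of distinct filter-passing fragments
#' (read names), the total number of aligned bases (sum of CIGAR M/=/X
#' lengths over passing reads) and the genome length declared in the BAM
#' header.  These are the "effective" quantities used for normalization and
#' scaling; they deliberately differ from BAM index totals, which include
#' duplicate and low-quality reads.
#'
#' @slot nReads number of filter-passing read records.
#' @slot nFragments number of distinct read names among passing records.
#' @slot alignedBases total reference-aligned bases (CIGAR M/=/X) of passing
#'   records.
#' @slot genomeLength sum of contig lengths declared in the BAM header.
#' @slot bamPath source file.
#'
#' @seealso [computeLibraryStats()], [genomeSizeFactor()], [libsizeFactors()]
#' @export
setClass("LibraryStats",
    representation(
        nReads = "numeric",
        nFragments = "numeric",
        alignedBases = "numeric",
        genomeLength = "numeric",
        bamPath = "character"
    )
)

setValidity("LibraryStats", function(object) {
    msg <- character()
    if (object@nReads < object@nFragments || object@nFragments < 0)
        msg <- c(msg, "need nReads >= nFragments >= 0")
    if (object@alignedBases < 0)
        msg <- c(msg, "alignedBases must be non-negative")
    if (object@genomeLength <= 0)
        msg <- c(msg, "genomeLength must be positive")
    if (length(msg)) msg else TRUE
})

#' @param nReads,nFragments,alignedBases,genomeLength,bamPath see slots.
#' @return `LibraryStats()` returns a \linkS4class{LibraryStats} object.
#' @rdname LibraryStats-class
#' @export
LibraryStats <- function(nReads, nFragments, alignedBases, genomeLength,
                         bamPath = NA_character_) {
    new("LibraryStats", nReads = as.numeric(nReads),
        nFragments = as.numeric(nFragments),
        alignedBases = as.numeric(alignedBases),
        genomeLength = as.numeric(genomeLength),
        bamPath = bamPath)
}

setMethod("show", "LibraryStats", function(object) {
    cat("LibraryStats for", object@bamPath, "\n")
    cat(sprintf("  reads: %d  fragments: %d\n",
                as.integer(object@nReads), as.integer(object@nFragments)))
    cat(sprintf("  aligned bases: %.0f  genome length: %.0f (mean depth %.3f)\n",
                object@alignedBases, object@genomeLength,
                object@alignedBases / object@genomeLength))
})

#' Fixed-bin genome-wide signal track
#'
#' One dense numeric vector of bin values per chromosome, in BAM-header
#' order.  Bin `i` (1-based) covers reference bases
#' `[(i-1)*binSize + 1, min(i*binSize, chromLength)]`; the last bin of a
#' chromosome may be narrower.  `NA` values mark bins with no defined value
#' (e.g. log2 ratios over empty bins or RFD bins with no reads); writers omit
#' them.
#'
#' @slot binSize bin width in bp.
#' @slot values named list of numeric vectors, one per chromosome, each of
#'   length `ceiling(chromLength / binSize)`.
#' @slot seqinfo a [GenomeInfoDb::Seqinfo] taken from the source BAM header;
#'   chromosome order is preserved everywhere.
#' @slot semantics free-text tag recording what the values are
#'   (`"raw-coverage"`, `"scaled"`, `"log2"`, `"rfd"`, `"difference"`).
#'
#' @seealso [binnedCoverage()], [scaleTrack()], [smoothTrack()],
#'   [writeBigWig()]
#' @export
setClass("BinnedTrack",
    representation(
        binSize = "integer",
        values = "list",
        seqinfo = "Seqinfo",
        semantics = "character"
    )
)

setValidity("BinnedTrack", function(object) {
    msg <- character()
    sl <- seqlengths(object@seqinfo)
    if (!identical(names(object@values), names(sl)))
        msg <- c(msg, "names(values) must equal seqinfo chromosomes, in order")
    if (length(object@binSize) != 1L || is.na(object@binSize) ||
        object@binSize < 1L)
        msg <- c(msg, "binSize must be a positive integer")
    else {
        expected <- ceiling(sl / object@binSize)
        got <- lengths(object@values)
        if (!all(got == expected[names(object@values)]))
            msg <- c(msg, "each chromosome needs ceiling(length/binSize) bins")
    }
    if (length(msg)) msg else TRUE
})

#' @param binSize,values,seqinfo,semantics see slots.
#' @return `BinnedTrack()` returns a \linkS4class{BinnedTrack} object.
#' @rdname BinnedTrack-class
#' @export
BinnedTrack <- function(binSize, values, seqinfo,
                        semantics = "raw-coverage") {
    new("BinnedTrack", binSize = as.integer(binSize),
        values = values, seqinfo = seqinfo, semantics = semantics)
}

setMethod("show", "BinnedTrack", function(object) {
    v <- unlist(object@values, use.names = FALSE)
    cat(sprintf("BinnedTrack (%s): %d chromosome(s), bin size %d bp, %d bins\n",
                object@semantics, length(object@values), object@binSize,
                length(v)))
    ok <- !is.na(v)
    if (any(ok))
        cat(sprintf("  value range: [%.4g, %.4g], %d NA bin(s)\n",
                    min(v[ok]), max(v[ok]), sum(!ok)))
})

#' Variable-width signal track
#'
#' Sorted, non-overlapping (start, end, value) runs per chromosome, used for
#' adaptive-resolution RNA-seq coverage where bin-sized runs and single-base
#' runs coexist.  Runs tile each chromosome completely (explicit zero runs
#' are kept) so expanding the track back to per-base values is total.
#'
#' @slot runs a [GenomicRanges::GRanges] with a numeric `score` column and a
#'   complete `seqinfo`.
#' @slot semantics value tag, as for \linkS4class{BinnedTrack}.
#'
#' @seealso [adaptiveBins()], [rnaTracks()]
#' @export
setClass("IntervalTrack",
    representation(runs = "GRanges", semantics = "character"))

setValidity("IntervalTrack", function(object) {
    msg <- character()
    gr <- object@runs
    if (is.null(gr$score))
        msg <- c(msg, "runs must carry a 'score' column")
    if (any(is.na(seqlengths(gr))))
        msg <- c(msg, "runs must have complete seqlengths")
    else if (any(GenomicRanges::end(gr) >
                 seqlengths(gr)[as.character(GenomicRanges::seqnames(gr))]))
        msg <- c(msg, "runs extend beyond chromosome bounds")
    if (length(gr) > 1L) {
        byChrom <- split(IRanges::ranges(gr), GenomicRanges::seqnames(gr))
        bad <- vapply(byChrom, function(r) {
            length(r) > 1L && (is.unsorted(IRanges::start(r)) ||
                               !IRanges::isDisjoint(r))
        }, logical(1))
        if (any(bad))
            msg <- c(msg, "runs must be sorted and non-overlapping")
    }
    if (length(msg)) msg else TRUE
})

#' @param runs,semantics see slots.
#' @return `IntervalTrack()` returns an \linkS4class{IntervalTrack} object.
#' @rdname IntervalTrack-class
#' @export
IntervalTrack <- function(runs, semantics = "raw-coverage") {
    new("IntervalTrack", runs = runs, semantics = semantics)
}

setMethod("show", "IntervalTrack", function(object) {
    cat(sprintf("IntervalTrack (%s): %d run(s) on %d chromosome(s)\n",
                object@semantics, length(object@runs),
                length(unique(as.character(
                    GenomicRanges::seqnames(object@runs))))))
})

#' Peak quantification results
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] with one row per
#' peak and one column per BAM file, carrying four assays: `counts` (raw
#' read or fragment counts), `fpkm`, `tpm` and `libnorm` (scaled to the
#' smallest effective library in the set).  `colData` holds the per-sample
#' library statistics; `metadata` records the filter used.
#'
#' @seealso [quantifyPeaks()], [writeQuantTable()]
#' @export
setClass("PeakQuant", contains = "RangedSummarizedExperiment")

setMethod("show", "PeakQuant", function(object) {
    cat(sprintf("PeakQuant: %d peak(s) x %d sample(s)\n",
                nrow(object), ncol(object)))
    cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                           collapse = ", "), "\n")
    cat("  samples:", paste(colnames(object), collapse = ", "), "\n")
})
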