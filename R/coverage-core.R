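## BAM record access, the filter predicate, library statistics and
## strand-/splice-aware coverage extraction.

#' @importFrom Rsamtools BamFile ScanBamParam scanBam scanBamWhat
#'   scanBamHeader yieldSize isOpen
#' @importFrom GenomicAlignments cigarWidthAlongReferenceSpace
#'   cigarRangesAlongReferenceSpace cigarOpTable explodeCigarOps
#' @importFrom IRanges IRanges Views coverage
#' @importFrom S4Vectors Rle runValue
NULL

## SAM flag bits
.FLAG <- c(paired = 1L, proper = 2L, unmapped = 4L, munmapped = 8L,
           reverse = 16L, mreverse = 32L, first = 64L, second = 128L,
           secondary = 256L, qcfail = 512L, duplicate = 1024L,
           supplementary = 2048L)

.hasFlag <- function(flag, bit) bitwAnd(flag, .FLAG[[bit]]) > 0L

#' Seqinfo from a BAM header
#'
#' Returns the ordered (chromosome, length) pairs declared in the BAM header
#' as a [GenomeInfoDb::Seqinfo].  All tracks produced by this package carry
#' this object; chromosome order is never re-sorted.
#'
#' @param bamPath path to an indexed BAM file.
#' @return a `Seqinfo`.
#' @examples
#' bam <- makeBam(c(chrA = 1000L), exampleReadSpecs(), tempfile())
#' bamSeqinfo(bam)
#' @export
bamSeqinfo <- function(bamPath) {
    if (!file.exists(bamPath))
        stop("BAM file not found: ", bamPath)
    targets <- scanBamHeader(bamPath)[[1L]]$targets
    if (length(targets) == 0L)
        stop("BAM header of ", bamPath, " declares no reference sequences")
    Seqinfo(seqnames = names(targets), seqlengths = unname(targets))
}

## Scan raw records (one chromosome, or the whole file when chrom is NULL).
## Returns a plain data.frame; flag-level filtering is done in R so that the
## predicate below is the single source of truth.
.scanRecords <- function(bamPath, chrom = NULL, si = NULL) {
    what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
              "mpos", "isize")
    if (is.null(chrom)) {
        param <- ScanBamParam(what = what)
        res <- scanBam(bamPath, param = param)[[1L]]
    } else {
        if (is.null(si)) si <- bamSeqinfo(bamPath)
        which <- GRanges(chrom, IRanges(1L, seqlengths(si)[[chrom]]))
        param <- ScanBamParam(what = what, which = which)
        res <- scanBam(bamPath, param = param)[[1L]]
    }
    data.frame(qname = res$qname, flag = res$flag,
               rname = as.character(res$rname), pos = res$pos,
               mapq = res$mapq, cigar = res$cigar,
               mrnm = as.character(res$mrnm), mpos = res$mpos,
               isize = res$isize, stringsAsFactors = FALSE)
}

#' Test reads against an alignment filter
#'
#' Pure predicate deciding which alignment records survive the filter rules:
#' flag-based exclusions (unmapped, duplicate, secondary, supplementary,
#' QC-fail), the MAPQ cutoff, and the mate-chromosome rule that drops paired
#' reads whose mapped mate sits on a different reference sequence --- the
#' rule that prevents spurious counts at loci covered mostly by
#' inter-chromosomal pairs.  Strand selection is not part of the predicate;
#' it is applied by the coverage and counting functions, which know the
#' feature strand where relevant.
#'
#' @param records a data.frame with at least `flag`, `mapq`, `rname` and
#'   `mrnm` columns (as returned internally from a BAM scan).
#' @param filter an \linkS4class{AlignmentFilter}.
#' @return a logical vector, one entry per record.
#' @examples
#' rec <- data.frame(flag = c(4L, 1024L, 0L), mapq = 60L,
#'                   rname = "chr1", mrnm = NA_character_)
#' readPassesFilter(rec, AlignmentFilter())
#' @export
readPassesFilter <- function(records, filter = AlignmentFilter()) {
    f <- records$flag
    keep <- rep(TRUE, length(f))
    if (filter@dropUnmapped)
        keep <- keep & !.hasFlag(f, "unmapped")
    if (filter@dropDuplicates)
        keep <- keep & !.hasFlag(f, "duplicate")
    if (filter@dropSecondary)
        keep <- keep & !.hasFlag(f, "secondary")
    if (filter@dropSupplementary)
        keep <- keep & !.hasFlag(f, "supplementary")
    if (filter@dropQcfail)
        keep <- keep & !.hasFlag(f, "qcfail")
    if (filter@minMapq > 0L) {
        mq <- records$mapq
        keep <- keep & !is.na(mq) & mq >= filter@minMapq
    }
    if (filter@requireSameChromMate) {
        discordant <- .hasFlag(f, "paired") & !.hasFlag(f, "munmapped") &
            !is.na(records$mrnm) & records$mrnm != records$rname
        keep <- keep & !discordant
    }
    keep
}

#' Strand assigned to a read
#'
#' For single-end reads the assigned strand is the alignment strand (SAM
#' flag 0x10).  For paired reads the fragment strand is that of mate 1: the
#' second mate is flipped to its mate's strand.  `orientation = "reverse"`
#' flips the result for every read, accommodating dUTP-style protocols where
#' mate 1 carries the antisense strand.
#'
#' @param flag integer vector of SAM flags.
#' @param orientation `"forward"` (default) or `"reverse"`.
#' @return character vector of `"+"` / `"-"`.
#' @export
assignedStrand <- function(flag, orientation = c("forward", "reverse")) {
    orientation <- match.arg(orientation)
    own <- ifelse(.hasFlag(flag, "reverse"), "-", "+")
    flip2 <- .hasFlag(flag, "paired") & .hasFlag(flag, "second")
    s <- ifelse(flip2, ifelse(own == "+", "-", "+"), own)
    if (orientation == "reverse")
        s <- ifelse(s == "+", "-", "+")
    s
}

## aligned bases = sum of reference-consuming match ops (M, =, X); N and D
## consume reference but carry no aligned signal
.alignedBasesPerRead <- function(cigar) {
    tab <- cigarOpTable(cigar)
    as.numeric(tab[, "M"] + tab[, "="] + tab[, "X"])
}

#' Effective library statistics from a full BAM pass
#'
#' Reads every record of the BAM file, applies the alignment filter, and
#' returns the effective library size quantities: passing read count,
#' distinct passing fragment (read-name) count, total aligned bases (CIGAR
#' M/=/X), and the genome length from the header.  A full pass is used
#' deliberately --- BAM index totals include duplicates and low-quality
#' reads and would distort normalization.
#'
#' @param bamPath path to an indexed BAM file.
#' @param filter an \linkS4class{AlignmentFilter}.
#' @param yieldSize records per chunk for the streaming pass.
#' @return a \linkS4class{LibraryStats}.
#' @examples
#' bam <- makeBam(c(chrA = 1000L), exampleReadSpecs(), tempfile())
#' computeLibraryStats(bam)
#' @export
computeLibraryStats <- function(bamPath, filter = AlignmentFilter(),
                                yieldSize = 1e6L) {
    si <- bamSeqinfo(bamPath)
    bf <- BamFile(bamPath, yieldSize = yieldSize)
    param <- ScanBamParam(what = c("qname", "flag", "rname", "mapq",
                                   "cigar", "mrnm"))
    nReads <- 0; alignedBases <- 0
    qnames <- character()
    open(bf)
    on.exit(close(bf))
    repeat {
        res <- scanBam(bf, param = param)[[1L]]
        if (length(res$flag) == 0L) break
        rec <- data.frame(qname = res$qname, flag = res$flag,
                          rname = as.character(res$rname), mapq = res$mapq,
                          cigar = res$cigar, mrnm = as.character(res$mrnm),
                          stringsAsFactors = FALSE)
        keep <- readPassesFilter(rec, filter)
        nReads <- nReads + sum(keep)
        if (any(keep))
            alignedBases <- alignedBases +
                sum(.alignedBasesPerRead(rec$cigar[keep]))
        qnames <- unique(c(qnames, rec$qname[keep]))
    }
    LibraryStats(nReads = nReads, nFragments = length(qnames),
                 alignedBases = alignedBases,
                 genomeLength = sum(as.numeric(seqlengths(si))),
                 bamPath = bamPath)
}

## Reference ranges covered by each read: M/=/X segments when spliceAware
## (introns N and deletions D are holes), otherwise the outermost aligned
## span.  Returns a flat IRanges.
.coveredRanges <- function(rec, spliceAware) {
    if (nrow(rec) == 0L) return(IRanges())
    if (spliceAware) {
        rl <- cigarRangesAlongReferenceSpace(rec$cigar, pos = rec$pos,
                                             ops = c("M", "=", "X"))
        unlist(rl, use.names = FALSE)
    } else {
        w <- cigarWidthAlongReferenceSpace(rec$cigar)
        IRanges(rec$pos, width = w)
    }
}

## Coverage Rle for one chromosome under a filter/strand selection.
.chromCoverage <- function(bamPath, chrom, filter, spliceAware, strand,
                           orientation, si) {
    len <- seqlengths(si)[[chrom]]
    rec <- .scanRecords(bamPath, chrom, si)
    keep <- readPassesFilter(rec, filter)
    rec <- rec[keep, , drop = FALSE]
    if (strand != "both" && nrow(rec) > 0L) {
        want <- if (strand == "forward") "+" else "-"
        rec <- rec[assignedStrand(rec$flag, orientation) == want, ,
                   drop = FALSE]
    }
    ir <- .coveredRanges(rec, spliceAware)
    ## clip to chromosome bounds (defensive; fixtures stay inside)
    if (length(ir)) ir <- IRanges::restrict(ir, start = 1L, end = len)
    coverage(ir, width = len)
}

.checkStrandArg <- function(strand) {
    if (!strand %in% c("both", "forward", "reverse"))
        stop("'strand' must be one of both/forward/reverse")
    strand
}

#' Per-base read coverage of a region
#'
#' Depth at each base of `region`: the number of filter-passing reads whose
#' aligned segments cover that base.  With `spliceAware = TRUE` the CIGAR
#' M/=/X segments are used so that intron skips (N) and deletions (D) leave
#' no signal; otherwise each read covers its full outermost reference span.
#'
#' @param bamPath indexed BAM file.
#' @param chrom chromosome name (must be declared in the BAM header).
#' @param start,end 1-based closed region bounds; defaults to the whole
#'   chromosome.
#' @param filter an \linkS4class{AlignmentFilter}.
#' @param spliceAware skip N (and D) CIGAR operations.
#' @param strand `"both"`, `"forward"` or `"reverse"` (assigned strand, see
#'   [assignedStrand()]).
#' @param orientation strand convention for paired data.
#' @return a numeric vector of length `end - start + 1`.
#' @examples
#' bam <- makeBam(c(chrA = 1000L), exampleReadSpecs(), tempfile())
#' perBaseCoverage(bam, "chrA", 1, 120)
#' @export
perBaseCoverage <- function(bamPath, chrom, start = 1L, end = NULL,
                            filter = AlignmentFilter(), spliceAware = FALSE,
                            strand = "both",
                            orientation = c("forward", "reverse")) {
    orientation <- match.arg(orientation)
    .checkStrandArg(strand)
    si <- bamSeqinfo(bamPath)
    if (!chrom %in% seqnames(si))
        stop("chromosome ", chrom, " not declared in BAM header of ",
             bamPath)
    len <- seqlengths(si)[[chrom]]
    if (is.null(end)) end <- len
    if (start < 1L || end > len || end < start)
        stop(sprintf("region %s:%d-%d outside chromosome bounds (1-%d)",
                     chrom, start, end, len))
    cov <- .chromCoverage(bamPath, chrom, filter, spliceAware, strand,
                          orientation, si)
    as.numeric(S4Vectors::window(cov, start = start, end = end))
}

#' Genome-wide binned coverage
#'
#' Tiles every chromosome with fixed bins and reports, per bin, the mean
#' per-base depth (sum of covered bases in the bin divided by the true bin
#' width; the last bin of a chromosome uses its actual width).  Mean rather
#' than summed depth keeps values comparable across bin sizes and is the
#' quantity the ratio operations (log2, RFD) expect.
#'
#' @inheritParams perBaseCoverage
#' @param binSize bin width in bp (>= 1).
#' @param threads number of worker processes for per-chromosome
#'   parallelism; results are merged in header order and are identical for
#'   any thread count.
#' @return a \linkS4class{BinnedTrack}.
#' @examples
#' bam <- makeBam(c(chrA = 1000L), exampleReadSpecs(), tempfile())
#' binnedCoverage(bam, binSize = 100L)
#' @export
binnedCoverage <- function(bamPath, filter = AlignmentFilter(),
                           binSize = 5L, spliceAware = FALSE,
                           strand = "both",
                           orientation = c("forward", "reverse"),
                           threads = 1L) {
    orientation <- match.arg(orientation)
    .checkStrandArg(strand)
    if (binSize < 1L) stop("binSize must be >= 1")
    si <- bamSeqinfo(bamPath)
    chroms <- seqnames(si)
    oneChrom <- function(chrom) {
        cov <- .chromCoverage(bamPath, chrom, filter, spliceAware, strand,
                              orientation, si)
        .binRle(cov, binSize)
    }
    vals <- .overChromosomes(chroms, oneChrom, threads)
    names(vals) <- chroms
    BinnedTrack(binSize = binSize, values = vals, seqinfo = si,
                semantics = "raw-coverage")
}

## mean depth per fixed bin of an Rle; last bin keeps its true width
.binRle <- function(cov, binSize) {
    len <- length(cov)
    starts <- seq.int(1L, len, by = binSize)
    ends <- pmin(starts + binSize - 1L, len)
    as.numeric(IRanges::viewMeans(Views(cov, start = starts, end = ends)))
}

## deterministic per-chromosome parallel map: results always assembled in
## the order of `chroms` (the BAM header order)
.overChromosomes <- function(chroms, fun, threads) {
    threads <- max(1L, as.integer(threads))
    if (threads == 1L || length(chroms) <= 1L ||
        .Platform$OS.type == "windows") {
        lapply(chroms, fun)
    } else {
        parallel::mclapply(chroms, fun, mc.cores = threads,
                           mc.preschedule = TRUE)
    }
}
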