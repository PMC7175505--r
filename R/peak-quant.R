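## Peak quantification: BED input, overlap counting, FPKM/TPM/library-size
## normalization, the orchestrating quantifyPeaks() and the TSV writer.

#' @importFrom GenomicRanges GRanges seqnames start end strand width
#'   countOverlaps
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowRanges colData
NULL

#' Read a BED file of peak intervals
#'
#' Parses BED3/BED6 with strict validation: every line needs at least three
#' tab-separated columns, numeric 0-based half-open coordinates and
#' `end > start`; violations abort with the offending line number.  Missing
#' names are auto-generated as `chrom:start-end` (0-based, as in the file);
#' missing strands become `"*"`.
#'
#' @param path BED file path.
#' @param seqinfo optional [GenomeInfoDb::Seqinfo] to attach.
#' @return a [GenomicRanges::GRanges] in file order with a `name` column.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t0\t100", "chr1\t150\t300\tpk2\t0\t-"), bed)
#' readPeaks(bed)
#' @export
readPeaks <- function(path, seqinfo = NULL) {
    if (!file.exists(path)) stop("BED file not found: ", path)
    lines <- readLines(path)
    lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
    if (length(lines) == 0L)
        return(GRanges(name = character()))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("malformed BED line ", which(nf < 3L)[1L],
             ": fewer than 3 columns")
    chrom <- vapply(fields, `[[`, character(1), 1L)
    start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`,
                                                 character(1), 2L)))
    end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`,
                                               character(1), 3L)))
    bad <- is.na(start0) | is.na(end0)
    if (any(bad))
        stop("malformed BED line ", which(bad)[1L],
             ": non-numeric coordinates")
    bad <- end0 <= start0 | start0 < 0
    if (any(bad))
        stop("malformed BED line ", which(bad)[1L],
             ": zero-length or negative interval")
    name <- ifelse(nf >= 4L, vapply(fields, function(x)
        if (length(x) >= 4L) x[[4L]] else "", character(1)), "")
    auto <- sprintf("%s:%d-%d", chrom, as.integer(start0), as.integer(end0))
    name[!nzchar(name) | name == "."] <- auto[!nzchar(name) | name == "."]
    str <- vapply(fields, function(x)
        if (length(x) >= 6L && x[[6L]] %in% c("+", "-")) x[[6L]] else "*",
        character(1))
    gr <- GRanges(chrom, IRanges(as.integer(start0) + 1L,
                                 as.integer(end0)), strand = str)
    gr$name <- name
    if (!is.null(seqinfo)) {
        GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(seqinfo)
        GenomeInfoDb::seqinfo(gr) <- seqinfo
    }
    gr
}

#' Count reads or fragments overlapping peaks
#'
#' A read counts toward every peak its aligned reference span (outermost
#' span, including intron skips) overlaps by at least one base.  In fragment
#' mode a properly paired fragment is evaluated once, on its leftmost mate,
#' using the fragment interval from the leftmost start over |TLEN| bases;
#' pairs without a usable TLEN fall back to single-read counting.  With
#' `strandSelect = "match_feature"` only reads whose assigned strand equals
#' the peak's strand are counted (peaks with strand `"*"` accept both).
#'
#' @param bamPath indexed BAM file.
#' @param peaks a [GenomicRanges::GRanges] (e.g. from [readPeaks()]).
#' @param filter an \linkS4class{AlignmentFilter}; `strandSelect` and
#'   `fragmentMode` control the counting mode.
#' @param orientation paired-end strand convention, see [assignedStrand()].
#' @param threads per-chromosome worker count; deterministic for any value.
#' @return integer vector of counts, one per peak, in input order.  Peaks on
#'   chromosomes absent from the BAM header get 0 with a warning.
#' @export
countReadsInPeaks <- function(bamPath, peaks, filter = AlignmentFilter(),
                              orientation = c("forward", "reverse"),
                              threads = 1L) {
    orientation <- match.arg(orientation)
    si <- bamSeqinfo(bamPath)
    pChrom <- as.character(seqnames(peaks))
    known <- pChrom %in% seqnames(si)
    if (!all(known))
        warning("peak chromosome(s) absent from BAM header: ",
                paste(unique(pChrom[!known]), collapse = ", "),
                "; their counts are 0")
    counts <- integer(length(peaks))
    chroms <- intersect(seqnames(si), unique(pChrom))
    perChrom <- .overChromosomes(chroms, function(chrom) {
        idx <- which(pChrom == chrom)
        .countOnChrom(bamPath, chrom, peaks[idx], filter, orientation, si)
    }, threads)
    for (k in seq_along(chroms))
        counts[pChrom == chroms[k]] <- perChrom[[k]]
    counts
}

.countOnChrom <- function(bamPath, chrom, peaks, filter, orientation, si) {
    rec <- .scanRecords(bamPath, chrom, si)
    rec <- rec[readPassesFilter(rec, filter), , drop = FALSE]
    sel <- filter@strandSelect
    rstrand <- assignedStrand(rec$flag, orientation)
    if (sel %in% c("forward", "reverse")) {
        rec <- rec[rstrand == if (sel == "forward") "+" else "-", ,
                   drop = FALSE]
        rstrand <- rstrand[rstrand == if (sel == "forward") "+" else "-"]
    }
    if (nrow(rec) == 0L) return(integer(length(peaks)))
    w <- cigarWidthAlongReferenceSpace(rec$cigar)
    if (filter@fragmentMode) {
        proper <- .hasFlag(rec$flag, "paired") & .hasFlag(rec$flag, "proper") &
            !is.na(rec$isize) & rec$isize != 0L &
            !is.na(rec$mrnm) & rec$mrnm == rec$rname
        leftmost <- proper & rec$isize > 0L
        rightmost <- proper & rec$isize < 0L
        ## fragment interval evaluated on the leftmost mate only; the
        ## rightmost mate of a proper pair is skipped entirely; anything
        ## else keeps its own aligned span
        keepRow <- !rightmost
        st <- ifelse(leftmost, rec$pos, rec$pos)
        wd <- ifelse(leftmost, abs(rec$isize), w)
        ir <- IRanges(st[keepRow], width = wd[keepRow])
        rstrand <- rstrand[keepRow]
    } else {
        ir <- IRanges(rec$pos, width = w)
    }
    pk <- IRanges::ranges(peaks)
    n <- countOverlaps(pk, ir, minoverlap = 1L)
    if (sel == "match_feature") {
        pStrand <- as.character(strand(peaks))
        stranded <- pStrand %in% c("+", "-")
        if (any(stranded)) {
            nPlus <- countOverlaps(pk, ir[rstrand == "+"], minoverlap = 1L)
            nMinus <- countOverlaps(pk, ir[rstrand == "-"], minoverlap = 1L)
            n[stranded & pStrand == "+"] <- nPlus[stranded & pStrand == "+"]
            n[stranded & pStrand == "-"] <- nMinus[stranded & pStrand == "-"]
        }
    }
    as.integer(n)
}

#' FPKM normalization
#'
#' Fragments (reads) per kilobase of interval per million library reads:
#' `count * 1e9 / (lengthBp * librarySize)`.
#'
#' @param counts numeric vector of raw counts.
#' @param lengthsBp interval lengths in bp (>= 1).
#' @param librarySize effective library size (> 0), from
#'   [computeLibraryStats()].
#' @return numeric vector of FPKM values.
#' @examples
#' fpkm(10, 1000, 1e6)  # 10
#' @export
fpkm <- function(counts, lengthsBp, librarySize) {
    if (any(lengthsBp < 1)) stop("interval lengths must be >= 1 bp")
    if (length(librarySize) != 1L || is.na(librarySize) || librarySize <= 0)
        stop("librarySize must be a single positive number")
    counts * 1e9 / (lengthsBp * librarySize)
}

#' TPM normalization
#'
#' Transcripts per million: length-normalized count rates rescaled so the
#' per-sample column sums to one million.  All-zero counts yield all zeros.
#'
#' @param counts numeric vector of raw counts.
#' @param lengthsBp interval lengths in bp (>= 1).
#' @return numeric vector of TPM values.
#' @examples
#' tpm(c(10, 30), c(1000, 3000))  # both 5e5: equal per-kb rates
#' @export
tpm <- function(counts, lengthsBp) {
    if (any(lengthsBp < 1)) stop("interval lengths must be >= 1 bp")
    rate <- counts / (lengthsBp / 1e3)
    tot <- sum(rate)
    if (tot == 0) return(rep(0, length(counts)))
    1e6 * rate / tot
}

#' Library-size normalization (scale to the smallest library)
#'
#' Multiplies each sample's counts by `min(librarySizes) / librarySize[s]`,
#' so the smallest library keeps its raw counts and deeper libraries are
#' shrunk proportionally.
#'
#' @param counts matrix of raw counts, peaks x samples (a vector is treated
#'   as one sample).
#' @param librarySizes per-sample effective library sizes (> 0).
#' @return numeric matrix of normalized counts.
#' @examples
#' libsizeNormalize(cbind(a = c(100, 10), b = c(100, 10)), c(1e6, 2e6))
#' @export
libsizeNormalize <- function(counts, librarySizes) {
    counts <- as.matrix(counts)
    if (ncol(counts) != length(librarySizes))
        stop("need one library size per sample column")
    if (any(is.na(librarySizes)) || any(librarySizes <= 0))
        stop("library sizes must all be positive")
    factors <- min(librarySizes) / librarySizes
    sweep(counts, 2L, factors, `*`)
}

#' Quantify peaks over one or more BAM files
#'
#' The full quantification pipeline: a complete filtered pass over each BAM
#' for effective library sizes, overlap counting per peak, then FPKM, TPM
#' and smallest-library normalization.  The effective library size is the
#' passing read count, or the passing fragment count when
#' `filter@fragmentMode` is set.
#'
#' @param bamPaths character vector of indexed BAM files.
#' @param peaks a `GRanges` of peaks or the path to a BED file.
#' @param filter an \linkS4class{AlignmentFilter}.
#' @param orientation paired-end strand convention.
#' @param sampleNames column names; defaults to BAM basenames.
#' @param threads per-chromosome worker count.
#' @return a \linkS4class{PeakQuant} with assays `counts`, `fpkm`, `tpm`,
#'   `libnorm` and per-sample library statistics in `colData`.
#' @examples
#' bam <- makeBam(c(chrA = 1000L), exampleReadSpecs(), tempfile())
#' peaks <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 200))
#' peaks$name <- "pk1"
#' quantifyPeaks(bam, peaks)
#' @export
quantifyPeaks <- function(bamPaths, peaks, filter = AlignmentFilter(),
                          orientation = c("forward", "reverse"),
                          sampleNames = NULL, threads = 1L) {
    orientation <- match.arg(orientation)
    if (length(bamPaths) < 1L) stop("need at least one BAM file")
    if (is.character(peaks)) peaks <- readPeaks(peaks)
    if (is.null(sampleNames))
        sampleNames <- make.unique(sub("\\.bam$", "", basename(bamPaths)))
    stats <- lapply(bamPaths, computeLibraryStats, filter = filter)
    effSize <- vapply(stats, function(s)
        if (filter@fragmentMode) s@nFragments else s@nReads, numeric(1))
    if (any(effSize <= 0))
        stop("effective library size is zero for: ",
             paste(sampleNames[effSize <= 0], collapse = ", "))
    raw <- vapply(bamPaths, countReadsInPeaks, integer(length(peaks)),
                  peaks = peaks, filter = filter, orientation = orientation,
                  threads = threads)
    raw <- matrix(raw, nrow = length(peaks), ncol = length(bamPaths),
                  dimnames = list(NULL, sampleNames))
    lens <- width(peaks)
    fpkmM <- vapply(seq_along(bamPaths), function(j)
        fpkm(raw[, j], lens, effSize[j]), numeric(length(peaks)))
    tpmM <- vapply(seq_along(bamPaths), function(j)
        tpm(raw[, j], lens), numeric(length(peaks)))
    fpkmM <- matrix(fpkmM, nrow = length(peaks), ncol = length(bamPaths),
                    dimnames = list(NULL, sampleNames))
    tpmM <- matrix(tpmM, nrow = length(peaks), ncol = length(bamPaths),
                   dimnames = list(NULL, sampleNames))
    libnormM <- libsizeNormalize(raw, effSize)
    cd <- DataFrame(
        bam = bamPaths,
        nReads = vapply(stats, slot, numeric(1), "nReads"),
        nFragments = vapply(stats, slot, numeric(1), "nFragments"),
        alignedBases = vapply(stats, slot, numeric(1), "alignedBases"),
        genomeLength = vapply(stats, slot, numeric(1), "genomeLength"),
        effectiveLibrarySize = effSize,
        libsizeFactor = min(effSize) / effSize,
        row.names = sampleNames)
    se <- SummarizedExperiment(
        assays = list(counts = raw, fpkm = fpkmM, tpm = tpmM,
                      libnorm = libnormM),
        rowRanges = peaks, colData = cd,
        metadata = list(filter = filter, orientation = orientation))
    new("PeakQuant", se)
}

#' Write a peak quantification table as TSV
#'
#' One row per peak in input order; coordinate columns use the BED 0-based
#' half-open convention; value columns are grouped by normalization
#' (all raw counts, then FPKM, TPM and library-size blocks), named
#' `<sample>.<assay>`.  Floats are written with 6 significant digits.
#'
#' @param pq a \linkS4class{PeakQuant}.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeQuantTable <- function(pq, path) {
    gr <- rowRanges(pq)
    samples <- colnames(pq)
    blocks <- c("counts", "fpkm", "tpm", "libnorm")
    labels <- c(counts = "raw", fpkm = "FPKM", tpm = "TPM",
                libnorm = "libnorm")
    header <- c("chr", "start", "end", "name", "strand",
                unlist(lapply(blocks, function(b)
                    paste(samples, labels[[b]], sep = "."))))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(header, collapse = "\t"), con)
    if (nrow(pq) == 0L) return(invisible(path))
    fmt <- function(m, int) {
        if (int) apply(m, 1L, function(r) paste(as.integer(r),
                                                collapse = "\t"))
        else apply(m, 1L, function(r) paste(sprintf("%.6g", r),
                                            collapse = "\t"))
    }
    valcols <- lapply(blocks, function(b)
        fmt(as.matrix(assay(pq, b)), int = (b == "counts")))
    lines <- paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   if (!is.null(gr$name)) gr$name else
                       sprintf("%s:%d-%d", seqnames(gr), start(gr) - 1L,
                               end(gr)),
                   as.character(strand(gr)),
                   do.call(paste, c(valcols, sep = "\t")), sep = "\t")
    writeLines(lines, con)
    invisible(path)
}
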