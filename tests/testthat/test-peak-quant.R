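## BED input, overlap counting modes, normalizations, the orchestrator and
## the TSV writer.

test_that("BED parsing validates and fills defaults", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t0\t100",
                 "chr1\t150\t300\tpk2\t0\t-",
                 "chr2\t10\t20\tpk3"), bed)
    gr <- readPeaks(bed)
    expect_equal(length(gr), 3L)
    expect_equal(GenomicRanges::start(gr), c(1L, 151L, 11L))
    expect_equal(GenomicRanges::end(gr), c(100L, 300L, 20L))
    expect_equal(gr$name, c("chr1:0-100", "pk2", "pk3"))
    expect_equal(as.character(GenomicRanges::strand(gr)),
                 c("*", "-", "*"))

    writeLines("chr1\t100\t100", bed)
    expect_error(readPeaks(bed), "line 1.*zero-length")
    writeLines(c("chr1\t0\t100", "chr1\tfoo\t200"), bed)
    expect_error(readPeaks(bed), "line 2.*non-numeric")
    writeLines("chr1\t5", bed)
    expect_error(readPeaks(bed), "fewer than 3")
})

test_that("FPKM follows the count / (length x library) formula", {
    expect_equal(fpkm(10, 1000, 1e6), 10)
    expect_equal(fpkm(0, 1000, 1e6), 0)
    expect_equal(fpkm(7, 350, 2.5e6), 8)  # 7e9 / (350 * 2.5e6)
    expect_error(fpkm(1, 100, 0), "positive")
    expect_error(fpkm(1, 0, 1e6), ">= 1")
})

test_that("TPM renormalizes per-kb rates to one million", {
    expect_equal(tpm(5, 777), 1e6)
    expect_equal(tpm(c(3, 3), c(200, 200)), c(5e5, 5e5))
    expect_equal(tpm(c(10, 30), c(1000, 3000)), c(5e5, 5e5))
    expect_equal(tpm(c(0, 0), c(100, 100)), c(0, 0))
    set.seed(1)
    counts <- rpois(40, 20); lens <- sample(200:2000, 40)
    expect_equal(sum(tpm(counts, lens)), 1e6, tolerance = 1e-9)
})

test_that("library-size normalization scales to the smallest library", {
    expect_equal(libsizeNormalize(matrix(c(7, 9), ncol = 1), 5e5),
                 matrix(c(7, 9), ncol = 1))
    got <- libsizeNormalize(cbind(a = c(100, 10), b = c(100, 10)),
                            c(1e6, 2e6))
    expect_equal(unname(got[, "a"]), c(100, 10))
    expect_equal(unname(got[, "b"]), c(50, 5))
    m <- matrix(rep(c(30, 60), each = 2), ncol = 2, byrow = TRUE)
    got3 <- libsizeNormalize(cbind(m, m[, 1]), c(4e6, 2e6, 8e6))
    expect_equal(got3[, 2], m[, 2] * 1)        # smallest: unchanged
    expect_equal(got3[, 1], m[, 1] * 0.5)
    expect_equal(got3[, 3], m[, 1] * 0.25)
    expect_error(libsizeNormalize(m, c(1e6, 0)), "positive")
})

test_that("single reads count on >= 1 bp overlap with a peak", {
    genome <- c(chrA = 1000L)
    ## read covering bases 101-150 vs peak 141-200: 10 bp overlap
    specs <- data.frame(qname = c("r1", "r2"), chrom = "chrA",
                        pos = c(101L, 501L), cigar = "50M", strand = "+")
    bam <- makeBam(genome, specs, tempfile())
    peaks <- GenomicRanges::GRanges("chrA",
                                    IRanges::IRanges(c(141, 151), c(200, 300)))
    expect_equal(countReadsInPeaks(bam, peaks), c(1L, 0L))
})

test_that("fragment mode counts a proper pair once via its TLEN span", {
    genome <- c(chrA = 1000L)
    pr <- rbind(
        data.frame(qname = "f1", chrom = "chrA", pos = 101L, cigar = "50M",
                   strand = "+", paired = TRUE, proper = TRUE, first = TRUE,
                   mateChrom = "chrA", matePos = 301L, mateStrand = "-",
                   tlen = 250L),
        data.frame(qname = "f1", chrom = "chrA", pos = 301L, cigar = "50M",
                   strand = "-", paired = TRUE, proper = TRUE,
                   first = FALSE, mateChrom = "chrA", matePos = 101L,
                   mateStrand = "+", tlen = -250L))
    bam <- makeBam(genome, pr, tempfile())
    ## peak sits between the two mates: covered by the fragment interval
    peak <- GenomicRanges::GRanges("chrA", IRanges::IRanges(201, 220))
    expect_equal(countReadsInPeaks(bam, peak,
        AlignmentFilter(fragmentMode = TRUE)), 1L)
    ## in single-read mode neither mate overlaps it
    expect_equal(countReadsInPeaks(bam, peak), 0L)
    ## a peak over one mate counts the fragment exactly once
    peak2 <- GenomicRanges::GRanges("chrA", IRanges::IRanges(310, 340))
    expect_equal(countReadsInPeaks(bam, peak2,
        AlignmentFilter(fragmentMode = TRUE)), 1L)
    expect_equal(countReadsInPeaks(bam, peak2), 1L)
})

test_that("every counting mode matches the brute-force oracle", {
    set.seed(77)
    sim <- simulateAssay("atac",
        params = list(nPairs = 1500L, nPeaks = 20L,
                      nDiscordantPairs = 30L), seed = 77)
    peaks <- readPeaks(sim$bed)
    filters <- list(
        AlignmentFilter(),
        AlignmentFilter(strandSelect = "forward"),
        AlignmentFilter(strandSelect = "reverse"),
        AlignmentFilter(strandSelect = "match_feature"),
        AlignmentFilter(fragmentMode = TRUE),
        AlignmentFilter(dropDuplicates = FALSE,
                        requireSameChromMate = FALSE))
    for (f in filters) {
        expect_equal(countReadsInPeaks(sim$bam, peaks, f),
                     oracleCounts(sim$specs, peaks, f))
    }
})

test_that("peaks on chromosomes missing from the header count 0 with a warning", {
    bam <- makeBam(c(chrA = 1000L), exampleReadSpecs(), tempfile())
    peaks <- GenomicRanges::GRanges(c("chrA", "chrZ"),
                                    IRanges::IRanges(c(1, 1), width = 200))
    expect_warning(n <- countReadsInPeaks(bam, peaks), "chrZ")
    expect_equal(n[2], 0L)
    expect_true(n[1] > 0L)
})

test_that("quantifyPeaks assembles counts and all three normalizations", {
    sim <- simulateAssay("atac",
        params = list(nPairs = 800L, nPeaks = 15L), seed = 5)
    peaks <- readPeaks(sim$bed)
    pq <- quantifyPeaks(c(sim$bam, sim$bam), peaks,
                        sampleNames = c("s1", "s2"))
    expect_s4_class(pq, "PeakQuant")
    expect_equal(dim(pq), c(15L, 2L))
    expect_equal(SummarizedExperiment::assayNames(pq),
                 c("counts", "fpkm", "tpm", "libnorm"))
    a <- SummarizedExperiment::assays(pq)
    ## identical BAM twice: identical columns, libnorm factor 1
    for (nm in names(a))
        expect_equal(a[[nm]][, 1], a[[nm]][, 2])
    expect_equal(SummarizedExperiment::colData(pq)$libsizeFactor, c(1, 1))
    ## each cell reproduces the component pipeline
    st <- computeLibraryStats(sim$bam)
    raw <- countReadsInPeaks(sim$bam, peaks)
    lens <- GenomicRanges::width(peaks)
    expect_equal(unname(a$counts[, 1]), raw)
    expect_equal(unname(a$fpkm[, 1]), fpkm(raw, lens, st@nReads))
    expect_equal(unname(a$tpm[, 1]), tpm(raw, lens))
    expect_equal(unname(a$libnorm[, 1]), raw * 1)
    expect_equal(sum(a$tpm[, 1]), 1e6, tolerance = 1e-9)
})

test_that("FPKM and TPM are invariant to duplicating every read", {
    genome <- c(chrA = 2000L)
    specs <- data.frame(qname = sprintf("r%02d", 1:10), chrom = "chrA",
                        pos = seq(1L, 901L, by = 100L), cigar = "50M",
                        strand = "+")
    doubled <- rbind(specs,
                     transform(specs, qname = paste0(qname, "b")))
    bam1 <- makeBam(genome, specs, tempfile())
    bam2 <- makeBam(genome, doubled, tempfile())
    peaks <- GenomicRanges::GRanges("chrA",
                                    IRanges::IRanges(c(1, 401), c(400, 1000)))
    peaks$name <- c("p1", "p2")
    q1 <- quantifyPeaks(bam1, peaks)
    q2 <- quantifyPeaks(bam2, peaks)
    expect_equal(SummarizedExperiment::assay(q2, "counts")[, 1],
                 2L * SummarizedExperiment::assay(q1, "counts")[, 1])
    expect_equal(SummarizedExperiment::assay(q2, "fpkm")[, 1],
                 SummarizedExperiment::assay(q1, "fpkm")[, 1])
    expect_equal(SummarizedExperiment::assay(q2, "tpm")[, 1],
                 SummarizedExperiment::assay(q1, "tpm")[, 1])
})

test_that("the TSV table round-trips and keeps peak order", {
    sim <- simulateAssay("atac",
        params = list(nPairs = 500L, nPeaks = 20L), seed = 9)
    peaks <- readPeaks(sim$bed)
    pq <- quantifyPeaks(sim$bam, peaks, sampleNames = "s1")
    out <- tempfile(fileext = ".tsv")
    writeQuantTable(pq, out)
    lines <- readLines(out)
    expect_length(lines, 21L)  # header + 20 peaks
    tab <- utils::read.delim(out, check.names = FALSE)
    expect_equal(tab$name, peaks$name)
    expect_equal(tab$start, GenomicRanges::start(peaks) - 1L)
    expect_equal(tab[["s1.raw"]],
                 unname(SummarizedExperiment::assay(pq, "counts")[, 1]))
    expect_equal(tab[["s1.TPM"]],
                 unname(SummarizedExperiment::assay(pq, "tpm")[, 1]),
                 tolerance = 1e-5)

    ## empty peak set -> header only
    empty <- quantifyPeaks(sim$bam, peaks[0], sampleNames = "s1")
    writeQuantTable(empty, out)
    expect_length(readLines(out), 1L)
})
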