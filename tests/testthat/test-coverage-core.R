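## Filtering, library statistics and coverage extraction.

test_that("filter predicate applies each rule and its toggle", {
    rec <- function(flag, mapq = 60L, rname = "chrA", mrnm = NA_character_)
        data.frame(flag = flag, mapq = mapq, rname = rname, mrnm = mrnm)
    f <- AlignmentFilter()
    expect_false(readPassesFilter(rec(4L), f))          # unmapped
    expect_false(readPassesFilter(rec(1024L), f))       # duplicate
    expect_true(readPassesFilter(rec(1024L),
        AlignmentFilter(dropDuplicates = FALSE)))
    expect_false(readPassesFilter(rec(256L), f))        # secondary
    expect_false(readPassesFilter(rec(2048L), f))       # supplementary
    expect_false(readPassesFilter(rec(512L), f))        # QC fail
    expect_true(readPassesFilter(rec(0L), f))
    ## paired read with mapped mate on another chromosome
    disc <- rec(1L, mrnm = "chrB")
    expect_false(readPassesFilter(disc, f))
    expect_true(readPassesFilter(disc,
        AlignmentFilter(requireSameChromMate = FALSE)))
    ## same-chromosome mate passes
    expect_true(readPassesFilter(rec(1L, mrnm = "chrA"), f))
    ## MAPQ cutoff
    expect_false(readPassesFilter(rec(0L, mapq = 10L),
        AlignmentFilter(minMapq = 30L)))
    expect_true(readPassesFilter(rec(0L, mapq = 30L),
        AlignmentFilter(minMapq = 30L)))
})

test_that("library statistics count filtered reads, fragments and bases", {
    genome <- c(chrA = 2000L)
    plain <- data.frame(qname = sprintf("r%02d", 1:10), chrom = "chrA",
                        pos = seq(1L, 901L, by = 100L), cigar = "50M",
                        strand = "+")
    bam <- makeBam(genome, plain, tempfile())
    st <- computeLibraryStats(bam)
    expect_equal(st@nReads, 10)
    expect_equal(st@nFragments, 10)
    expect_equal(st@alignedBases, 500)
    expect_equal(st@genomeLength, 2000)

    ## two duplicate-flagged among ten
    dup <- plain
    dup$duplicate <- c(rep(FALSE, 8), TRUE, TRUE)
    bam2 <- makeBam(genome, dup, tempfile())
    expect_equal(computeLibraryStats(bam2)@nReads, 8)

    ## spliced reads: N consumes reference but contributes no aligned bases
    spl <- data.frame(qname = c("s1", "s2"), chrom = "chrA",
                      pos = c(1L, 500L), cigar = "20M100N20M",
                      strand = "+")
    bam3 <- makeBam(genome, spl, tempfile())
    st3 <- computeLibraryStats(bam3)
    expect_equal(st3@alignedBases, 80)  # 40 per read

    ## paired fragments: 2 pairs -> 4 reads, 2 fragments
    pr <- rbind(
        data.frame(qname = "f1", chrom = "chrA", pos = 1L, cigar = "50M",
                   strand = "+", paired = TRUE, proper = TRUE,
                   first = TRUE, mateChrom = "chrA", matePos = 201L,
                   mateStrand = "-", tlen = 250L),
        data.frame(qname = "f1", chrom = "chrA", pos = 201L, cigar = "50M",
                   strand = "-", paired = TRUE, proper = TRUE,
                   first = FALSE, mateChrom = "chrA", matePos = 1L,
                   mateStrand = "+", tlen = -250L),
        data.frame(qname = "f2", chrom = "chrA", pos = 501L, cigar = "50M",
                   strand = "+", paired = TRUE, proper = TRUE,
                   first = TRUE, mateChrom = "chrA", matePos = 701L,
                   mateStrand = "-", tlen = 250L),
        data.frame(qname = "f2", chrom = "chrA", pos = 701L, cigar = "50M",
                   strand = "-", paired = TRUE, proper = TRUE,
                   first = FALSE, mateChrom = "chrA", matePos = 501L,
                   mateStrand = "+", tlen = -250L))
    bam4 <- makeBam(genome, pr, tempfile())
    st4 <- computeLibraryStats(bam4)
    expect_equal(st4@nReads, 4)
    expect_equal(st4@nFragments, 2)
})

test_that("library stats fail informatively on broken input", {
    expect_error(computeLibraryStats(tempfile()), "not found")
})

test_that("per-base coverage handles single reads and splices", {
    genome <- c(chrA = 500L)
    one <- data.frame(qname = "r1", chrom = "chrA", pos = 101L,
                      cigar = "10M", strand = "+")
    bam <- makeBam(genome, one, tempfile())
    cov <- perBaseCoverage(bam, "chrA")
    expect_equal(which(cov > 0), 101:110)
    expect_true(all(cov[101:110] == 1))

    ## spliced read: zeros over the N gap when splice-aware, covered when not
    spl <- data.frame(qname = "s1", chrom = "chrA", pos = 101L,
                      cigar = "5M10N5M", strand = "+")
    bam2 <- makeBam(genome, spl, tempfile())
    covS <- perBaseCoverage(bam2, "chrA", spliceAware = TRUE)
    expect_equal(which(covS > 0), c(101:105, 116:120))
    covU <- perBaseCoverage(bam2, "chrA", spliceAware = FALSE)
    expect_equal(which(covU > 0), 101:120)

    expect_error(perBaseCoverage(bam, "chrA", 400, 600), "outside")
    expect_error(perBaseCoverage(bam, "chrZ"), "not declared")
})

test_that("coverage matches the interval-stabbing oracle on random fixtures", {
    set.seed(101)
    genome <- c(chrA = 5000L, chrB = 3000L)
    for (rep in 1:3) {
        specs <- helperRandomSpecs(200L, genome, spliced = TRUE)
        bam <- makeBam(genome, specs, tempfile())
        for (sa in c(TRUE, FALSE)) for (strand in c("both", "forward",
                                                    "reverse")) {
            got <- perBaseCoverage(bam, "chrA", spliceAware = sa,
                                   strand = strand)
            want <- helperCoverage(specs, "chrA", 5000L,
                                   spliceAware = sa, strand = strand)
            expect_equal(got, want)
        }
    }
})

test_that("binned coverage is the mean per-base depth with a true-width last bin", {
    genome <- c(chrA = 250L)  # 100-bp bins; last bin is 50 bp wide
    specs <- data.frame(qname = c("r1", "r2"), chrom = "chrA",
                        pos = c(21L, 226L), cigar = c("10M", "25M"),
                        strand = "+")
    bam <- makeBam(genome, specs, tempfile())
    bt <- binnedCoverage(bam, binSize = 100L)
    ## one 10M read fully inside a 100-bp bin -> 10/100
    expect_equal(bt@values$chrA[1], 0.1)
    ## last bin: 25 covered bases over its true width of 50
    expect_equal(bt@values$chrA[3], 0.5)
    expect_equal(length(bt@values$chrA), 3L)

    ## unit bins reproduce per-base coverage
    bt1 <- binnedCoverage(bam, binSize = 1L)
    expect_equal(bt1@values$chrA, perBaseCoverage(bam, "chrA"))
})

test_that("binned coverage equals the aggregated oracle and conserves mass", {
    set.seed(202)
    genome <- c(chrA = 5000L, chrB = 3000L)
    specs <- helperRandomSpecs(300L, genome)
    bam <- makeBam(genome, specs, tempfile())
    bt <- binnedCoverage(bam, binSize = 128L)
    for (ch in names(genome)) {
        want <- helperBin(helperCoverage(specs, ch, genome[[ch]]), 128L)
        expect_equal(bt@values[[ch]], want)
    }
    ## conservation: sum over bins of value x true bin width = aligned bases
    st <- computeLibraryStats(bam)
    covered <- sum(vapply(names(genome), function(ch) {
        L <- genome[[ch]]
        widths <- diff(c(seq(0, L - 1, by = 128L), L))
        sum(bt@values[[ch]] * widths)
    }, numeric(1)))
    expect_equal(covered, st@alignedBases)
})

test_that("forward and reverse tracks partition the unstranded track", {
    set.seed(303)
    genome <- c(chrA = 4000L)
    specs <- helperRandomSpecs(250L, genome)
    bam <- makeBam(genome, specs, tempfile())
    both <- binnedCoverage(bam, binSize = 50L)
    fwd <- binnedCoverage(bam, binSize = 50L, strand = "forward")
    rev <- binnedCoverage(bam, binSize = 50L, strand = "reverse")
    expect_equal(fwd@values$chrA + rev@values$chrA, both@values$chrA)
})

test_that("coverage and counting are invariant to the thread count", {
    set.seed(404)
    genome <- c(chrA = 4000L, chrB = 3000L, chrC = 2000L)
    specs <- helperRandomSpecs(300L, genome)
    bam <- makeBam(genome, specs, tempfile())
    t1 <- binnedCoverage(bam, binSize = 100L, threads = 1L)
    t4 <- binnedCoverage(bam, binSize = 100L, threads = 4L)
    expect_identical(t1@values, t4@values)
    peaks <- GenomicRanges::GRanges(
        rep(names(genome), each = 3),
        IRanges::IRanges(rep(c(1, 1001, 1501), 3), width = 400))
    expect_identical(countReadsInPeaks(bam, peaks, threads = 1L),
                     countReadsInPeaks(bam, peaks, threads = 4L))
})
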