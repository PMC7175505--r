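## Naive, loop-based oracles used to verify the production paths.  They
## re-derive everything from the read-spec data.frames (never from SAM
## flags or Bioconductor machinery) so they share no code with the package
## internals they check.

## does a spec row survive the filter? (re-derivation of the filter rules)
helperPass <- function(specs, filter = AlignmentFilter()) {
    pass <- rep(TRUE, nrow(specs))
    if (filter@dropUnmapped) pass <- pass & !specs$unmapped
    if (filter@dropDuplicates) pass <- pass & !specs$duplicate
    if (filter@dropSecondary) pass <- pass & !specs$secondary
    if (filter@dropSupplementary) pass <- pass & !specs$supplementary
    if (filter@dropQcfail) pass <- pass & !specs$qcfail
    if (filter@minMapq > 0) pass <- pass & specs$mapq >= filter@minMapq
    if (filter@requireSameChromMate)
        pass <- pass & !(specs$paired & !is.na(specs$mateChrom) &
                         specs$mateChrom != specs$chrom)
    pass
}

## assigned strand of each spec row (mate-1 convention)
helperStrand <- function(specs, orientation = "forward") {
    s <- ifelse(specs$paired & !specs$first,
                ifelse(specs$strand == "+", "-", "+"), specs$strand)
    if (orientation == "reverse") s <- ifelse(s == "+", "-", "+")
    s
}

## covered reference positions of one read, by walking the CIGAR text
helperBlocks <- function(cigar, pos, spliceAware) {
    m <- regmatches(cigar, gregexpr("\\d+[A-Z=]", cigar))[[1]]
    op <- substr(m, nchar(m), nchar(m))
    n <- as.integer(substr(m, 1, nchar(m) - 1))
    covered <- integer(0)
    at <- pos
    for (k in seq_along(op)) {
        if (op[k] %in% c("M", "=", "X")) {
            covered <- c(covered, at:(at + n[k] - 1))
            at <- at + n[k]
        } else if (op[k] %in% c("D", "N")) {
            if (!spliceAware)
                covered <- c(covered, at:(at + n[k] - 1))
            at <- at + n[k]
        }
        ## I, S, H, P consume no reference
    }
    covered
}

## per-base depth over a chromosome by interval stabbing, one read at a time
helperCoverage <- function(specs, chrom, chromLen,
                           filter = AlignmentFilter(),
                           spliceAware = FALSE, strand = "both",
                           orientation = "forward") {
    pass <- helperPass(specs, filter)
    if (strand != "both") {
        want <- if (strand == "forward") "+" else "-"
        pass <- pass & helperStrand(specs, orientation) == want
    }
    depth <- numeric(chromLen)
    for (i in which(pass & specs$chrom == chrom)) {
        b <- helperBlocks(specs$cigar[i], specs$pos[i], spliceAware)
        b <- b[b >= 1 & b <= chromLen]
        depth[b] <- depth[b] + 1
    }
    depth
}

## mean-per-bin aggregation of a per-base vector (true last-bin width)
helperBin <- function(depth, binSize) {
    L <- length(depth)
    starts <- seq(1, L, by = binSize)
    vapply(starts, function(s) mean(depth[s:min(s + binSize - 1, L)]),
           numeric(1))
}

## windowed mean with truncation at the ends
helperSmooth <- function(v, n) {
    vapply(seq_along(v), function(i)
        mean(v[max(1, i - n):min(length(v), i + n)]), numeric(1))
}

## a small mixed-feature read set on two chromosomes used by several tests:
## plain, duplicate, low-MAPQ, discordant-mate, spliced and paired reads
helperMixedSpecs <- function() {
    plain <- data.frame(qname = sprintf("p%02d", 1:10), chrom = "chrA",
                        pos = seq(11L, 911L, by = 100L), cigar = "50M",
                        strand = rep(c("+", "-"), 5))
    dup <- data.frame(qname = c("d1", "d2"), chrom = "chrA",
                      pos = c(11L, 111L), cigar = "50M", strand = "+",
                      duplicate = TRUE)
    lowq <- data.frame(qname = "q1", chrom = "chrA", pos = 201L,
                       cigar = "50M", strand = "+", mapq = 5L)
    disc <- data.frame(qname = "x1", chrom = "chrA", pos = 301L,
                       cigar = "50M", strand = "+", paired = TRUE,
                       first = TRUE, mateChrom = "chrB", matePos = 11L,
                       mateStrand = "-", tlen = 0L)
    spliced <- data.frame(qname = "s1", chrom = "chrB", pos = 101L,
                          cigar = "20M100N20M", strand = "+")
    pair <- rbind(
        data.frame(qname = "f1", chrom = "chrB", pos = 501L,
                   cigar = "40M", strand = "+", paired = TRUE,
                   proper = TRUE, first = TRUE, mateChrom = "chrB",
                   matePos = 701L, mateStrand = "-", tlen = 240L),
        data.frame(qname = "f1", chrom = "chrB", pos = 701L,
                   cigar = "40M", strand = "-", paired = TRUE,
                   proper = TRUE, first = FALSE, mateChrom = "chrB",
                   matePos = 501L, mateStrand = "+", tlen = -240L))
    out <- list(plain, dup, lowq, disc, spliced, pair)
    cols <- c("qname", "chrom", "pos", "cigar", "strand")
    full <- lapply(out, function(df) {
        df2 <- binscale:::.fillSpecs(df)
        df2[, names(binscale:::.SPEC_COLS)]
    })
    do.call(rbind, full)
}

helperMixedGenome <- function() c(chrA = 1000L, chrB = 1000L)

## random single/paired read specs for property tests
helperRandomSpecs <- function(n, genome, spliced = FALSE) {
    chrom <- sample(names(genome), n, replace = TRUE)
    len <- 40L
    pos <- vapply(chrom, function(ch)
        sample.int(genome[[ch]] - 200L, 1L), integer(1))
    cigar <- if (spliced)
        ifelse(runif(n) < 0.4,
               sprintf("%dM%dN%dM", 15L, sample(20:80, n, TRUE), 25L),
               sprintf("%dM", len))
    else sprintf("%dM", len)
    binscale:::.fillSpecs(
        data.frame(qname = sprintf("r%05d", seq_len(n)), chrom = chrom,
                   pos = as.integer(pos), cigar = cigar,
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   mapq = sample(c(0L, 10L, 60L), n, TRUE,
                                 prob = c(.1, .1, .8)),
                   duplicate = runif(n) < 0.05))
}

## a BinnedTrack built directly from numbers (for operator tests)
helperTrack <- function(values, binSize = 10L, chromLen = NULL) {
    if (is.null(chromLen)) chromLen <- length(values) * binSize
    si <- GenomeInfoDb::Seqinfo("chrT", chromLen)
    binscale:::BinnedTrack(binSize, list(chrT = as.numeric(values)), si)
}
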