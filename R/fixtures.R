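## Synthetic-data generator and naive counting oracle.  Every generator is
## seed-deterministic; the oracle shares no code with the production
## counting path (CIGARs are re-parsed with regular expressions and filter
## rules re-derived from the spec columns, not from SAM flags).

#' @importFrom Rsamtools asBam
#' @importFrom GenomicAlignments cigarWidthAlongQuerySpace
#' @importFrom stats runif rbinom
NULL

.SPEC_COLS <- list(qname = NA_character_, chrom = NA_character_,
                pos = NA_integer_, cigar = NA_character_,
                strand = "+", mapq = 60L, paired = FALSE, proper = FALSE,
                first = TRUE, mateChrom = NA_character_,
                matePos = NA_integer_, mateStrand = NA_character_,
                tlen = NA_integer_, duplicate = FALSE, secondary = FALSE,
                supplementary = FALSE, qcfail = FALSE, unmapped = FALSE)

## fill optional read-spec columns with their defaults
.fillSpecs <- function(specs) {
    for (col in names(.SPEC_COLS)) {
        if (!col %in% names(specs))
            specs[[col]] <- .SPEC_COLS[[col]]
    }
    stopifnot(!anyNA(specs$qname), !anyNA(specs$chrom), !anyNA(specs$pos),
              !anyNA(specs$cigar))
    specs
}

.specFlag <- function(s) {
    flag <- integer(nrow(s))
    add <- function(cond, bit) flag + ifelse(cond, bit, 0L)
    flag <- add(s$paired, 1L)
    flag <- add(s$paired & s$proper, 2L)
    flag <- add(s$unmapped, 4L)
    flag <- add(s$paired & is.na(s$mateChrom), 8L)
    flag <- add(s$strand == "-", 16L)
    flag <- add(s$paired & !is.na(s$mateStrand) & s$mateStrand == "-", 32L)
    flag <- add(s$paired & s$first, 64L)
    flag <- add(s$paired & !s$first, 128L)
    flag <- add(s$secondary, 256L)
    flag <- add(s$qcfail, 512L)
    flag <- add(s$duplicate, 1024L)
    flag <- add(s$supplementary, 2048L)
    flag
}

#' A handful of read specifications for examples
#'
#' Six single-end 50M reads on `chrA`, used in the function examples.
#'
#' @return a read-spec data.frame accepted by [makeBam()].
#' @export
exampleReadSpecs <- function() {
    data.frame(qname = paste0("r", 1:6), chrom = "chrA",
               pos = c(1L, 51L, 101L, 101L, 301L, 601L),
               cigar = "50M", strand = c("+", "+", "-", "+", "+", "-"))
}

#' Build a sorted, indexed BAM from read specifications
#'
#' Deterministically writes a SAM file from a data.frame of read
#' specifications (one row per record; see [exampleReadSpecs()] for the
#' minimal columns and the package vignette for the full set, covering
#' pairing, mate location, TLEN and the flag toggles), then sorts and
#' indexes it.  Identical specs always give identical records.
#'
#' @param genome named integer vector of chromosome lengths (header order),
#'   or a [GenomeInfoDb::Seqinfo].
#' @param specs read-spec data.frame.
#' @param path output prefix; the function writes `<path>.bam` and its
#'   index and returns the BAM path.
#' @return path to the sorted, indexed BAM.
#' @examples
#' bam <- makeBam(c(chrA = 1000L), exampleReadSpecs(), tempfile())
#' @export
makeBam <- function(genome, specs, path) {
    if (is(genome, "Seqinfo"))
        genome <- stats::setNames(seqlengths(genome), seqnames(genome))
    specs <- .fillSpecs(specs)
    if (!all(specs$chrom %in% names(genome)))
        stop("spec chromosome not in genome: ",
             paste(setdiff(specs$chrom, names(genome)), collapse = ", "))
    qlen <- rep(10L, nrow(specs))
    mapped <- specs$cigar != "*"
    if (any(mapped))
        qlen[mapped] <- cigarWidthAlongQuerySpace(specs$cigar[mapped])
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                        as.integer(genome)))
    rnext <- ifelse(!specs$paired | is.na(specs$mateChrom), "*",
                    ifelse(specs$mateChrom == specs$chrom, "=",
                           specs$mateChrom))
    pnext <- ifelse(is.na(specs$matePos), 0L, specs$matePos)
    tlen <- ifelse(is.na(specs$tlen), 0L, specs$tlen)
    recs <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
                    specs$qname, .specFlag(specs), specs$chrom, specs$pos,
                    specs$mapq, specs$cigar, rnext, pnext, tlen,
                    strrep("A", qlen))
    path <- sub("\\.bam$", "", path)
    sam <- paste0(path, ".sam")
    writeLines(c(header, recs), sam)
    bam <- suppressWarnings(asBam(sam, path, overwrite = TRUE,
                                  indexDestination = TRUE))
    unlink(sam)
    bam
}

.simGenome <- function(params,
                       default = c(chr1 = 50000L, chr2 = 50000L,
                                   chr3 = 50000L)) {
    g <- params$genome
    if (is.null(g)) g <- default
    g
}

## FR pairs, vectorized: left mates on "+", right mates on "-"; which mate
## is first-of-pair alternates so the mate-1 strand convention is exercised
.pairRows <- function(qname, chrom, left, fragLen, readLen, firstIsLeft,
                      duplicate = FALSE) {
    right <- left + fragLen - readLen
    cigar <- sprintf("%dM", readLen)
    rbind(
        data.frame(qname = qname, chrom = chrom, pos = left,
                   cigar = cigar, strand = "+", mapq = 60L, paired = TRUE,
                   proper = TRUE, first = firstIsLeft, mateChrom = chrom,
                   matePos = right, mateStrand = "-", tlen = fragLen,
                   duplicate = duplicate),
        data.frame(qname = qname, chrom = chrom, pos = right,
                   cigar = cigar, strand = "-", mapq = 60L, paired = TRUE,
                   proper = TRUE, first = !firstIsLeft, mateChrom = chrom,
                   matePos = left, mateStrand = "+", tlen = -fragLen,
                   duplicate = duplicate))
}

.simAtac <- function(params) {
    genome <- .simGenome(params)
    nPairs <- params$nPairs %||% 25000L
    nPeaks <- params$nPeaks %||% 200L
    widthRange <- params$peakWidth %||% c(200L, 2000L)
    dupRate <- params$dupRate %||% 0.05
    background <- params$background %||% 0.3
    readLen <- params$readLen %||% 50L
    fragRange <- params$fragLen %||% c(150L, 400L)
    nDiscordant <- params$nDiscordantPairs %||% 0L
    margin <- max(fragRange) + 1L
    ## peaks spread over chromosomes proportionally to length
    pChrom <- sample(names(genome), nPeaks, replace = TRUE,
                     prob = genome / sum(genome))
    pWidth <- round(runif(nPeaks, widthRange[1], widthRange[2]))
    pStart <- vapply(seq_len(nPeaks), function(i)
        round(runif(1, margin, genome[[pChrom[i]]] - pWidth[i] - margin)),
        numeric(1))
    peaks <- data.frame(chrom = pChrom, start = as.integer(pStart),
                        end = as.integer(pStart + pWidth - 1L),
                        name = sprintf("peak_%03d", seq_len(nPeaks)),
                        strand = sample(c("+", "-"), nPeaks,
                                        replace = TRUE))
    inPeak <- rbinom(nPairs, 1L, 1 - background) == 1L
    whichPeak <- sample(nPeaks, nPairs, replace = TRUE)
    fragLen <- round(runif(nPairs, fragRange[1], fragRange[2]))
    chrom <- ifelse(inPeak, peaks$chrom[whichPeak],
                    sample(names(genome), nPairs, replace = TRUE,
                           prob = genome / sum(genome)))
    center <- ifelse(inPeak,
                     round(runif(nPairs, peaks$start[whichPeak],
                                 peaks$end[whichPeak])),
                     round(runif(nPairs, margin,
                                 genome[chrom] - margin)))
    left <- pmax(1L, as.integer(center - fragLen %/% 2L))
    left <- pmin(left, genome[chrom] - fragLen)
    specs <- .pairRows(sprintf("frag%06d", seq_len(nPairs)), chrom, left,
                       fragLen, readLen,
                       firstIsLeft = seq_len(nPairs) %% 2L == 0L)
    ## duplicate-flagged copies of a sample of pairs
    nDup <- round(dupRate * nPairs)
    if (nDup > 0L) {
        di <- sample(nPairs, nDup)
        dup <- .pairRows(sprintf("dup%06d", seq_len(nDup)), chrom[di],
                         left[di], fragLen[di], readLen,
                         firstIsLeft = TRUE, duplicate = TRUE)
        specs <- rbind(specs, dup)
    }
    ## inter-chromosomal pairs piled on the first peak (the discordant-peak
    ## mechanism: dropped by default, counted when the mate rule is off)
    if (nDiscordant > 0L) {
        tgt <- peaks[1L, ]
        otherChrom <- setdiff(names(genome), tgt$chrom)[1L]
        pos <- round(runif(nDiscordant, tgt$start,
                           pmax(tgt$start, tgt$end - readLen)))
        disc <- data.frame(
            qname = sprintf("disc%05d", seq_len(nDiscordant)),
            chrom = tgt$chrom, pos = as.integer(pos),
            cigar = sprintf("%dM", readLen),
            strand = "+", mapq = 60L, paired = TRUE, proper = FALSE,
            first = TRUE, mateChrom = otherChrom, matePos = 1000L,
            mateStrand = "-", tlen = 0L, duplicate = FALSE)
        specs <- .fillSpecs(specs)
        specs <- rbind(specs, .fillSpecs(disc))
    }
    list(genome = genome, specs = .fillSpecs(specs),
         truth = list(peaks = peaks))
}

.simOkseq <- function(params) {
    genome <- .simGenome(params)
    nReads <- params$nReads %||% 30000L
    readLen <- params$readLen %||% 50L
    bias <- params$bias %||% 0.9
    origins <- params$origins %||%
        data.frame(chrom = names(genome),
                   pos = as.integer(genome %/% 2L))
    chrom <- sample(names(genome), nReads, replace = TRUE,
                    prob = genome / sum(genome))
    pos <- as.integer(round(runif(nReads, 1, genome[chrom] - readLen)))
    strand <- character(nReads)
    for (ch in unique(chrom)) {
        i <- chrom == ch
        ori <- origins$pos[origins$chrom == ch]
        nearest <- ori[max.col(-abs(outer(pos[i], ori, "-")),
                               ties.method = "first")]
        ## Okazaki fragments: Watson (+) leftward of the origin, Crick (-)
        ## rightward, each with probability `bias`
        pPlus <- ifelse(pos[i] < nearest, bias, 1 - bias)
        strand[i] <- ifelse(runif(sum(i)) < pPlus, "+", "-")
    }
    specs <- data.frame(qname = sprintf("ok%06d", seq_len(nReads)),
                        chrom = chrom, pos = pos,
                        cigar = sprintf("%dM", readLen), strand = strand)
    list(genome = genome, specs = .fillSpecs(specs),
         truth = list(origins = origins))
}

.simEndseq <- function(params) {
    genome <- .simGenome(params, default = c(chrE = 50000L))
    breaks <- params$breaks %||%
        data.frame(chrom = names(genome)[1L],
                   pos = c(10000L, 25000L, 40000L),
                   strand = c("+", "-", "+"))
    nPerBreak <- params$nReadsPerBreak %||% 100L
    readLen <- params$readLen %||% 36L
    strandMode <- params$strandMode %||% "both"
    if (strandMode == "forward") breaks$strand <- "+"
    rows <- lapply(seq_len(nrow(breaks)), function(i) {
        b <- breaks[i, ]
        ## break-proximal read ends stack at the break position
        pos <- if (b$strand == "+") b$pos - readLen + 1L else b$pos
        data.frame(qname = sprintf("end%d_%04d", i, seq_len(nPerBreak)),
                   chrom = b$chrom, pos = as.integer(pos),
                   cigar = sprintf("%dM", readLen), strand = b$strand)
    })
    list(genome = genome, specs = .fillSpecs(do.call(rbind, rows)),
         truth = list(breaks = breaks))
}

.simReptime <- function(params) {
    genome <- .simGenome(params, default = c(chrR = 1500000L))
    nReads <- params$nReads %||% 30000L
    readLen <- params$readLen %||% 50L
    ratio <- params$ratio %||% 2
    blocks <- params$earlyBlocks %||%
        data.frame(chrom = names(genome)[1L], start = 500001L,
                   end = 1000000L)
    uniformSpecs <- function(prefix, n) {
        chrom <- sample(names(genome), n, replace = TRUE,
                        prob = genome / sum(genome))
        pos <- as.integer(round(runif(n, 1, genome[chrom] - readLen)))
        data.frame(qname = sprintf("%s%06d", prefix, seq_len(n)),
                   chrom = chrom, pos = pos,
                   cigar = sprintf("%dM", readLen),
                   strand = sample(c("+", "-"), n, replace = TRUE))
    }
    g1 <- uniformSpecs("g1_", nReads)
    s <- uniformSpecs("s_", nReads)
    blockFrac <- sum(blocks$end - blocks$start + 1) /
        sum(as.numeric(genome))
    nExtra <- round(nReads * blockFrac * (ratio - 1))
    bi <- sample(nrow(blocks), nExtra, replace = TRUE,
                 prob = blocks$end - blocks$start + 1)
    extraPos <- as.integer(round(runif(nExtra, blocks$start[bi],
                                       blocks$end[bi] - readLen)))
    extra <- data.frame(qname = sprintf("se_%06d", seq_len(nExtra)),
                        chrom = blocks$chrom[bi], pos = extraPos,
                        cigar = sprintf("%dM", readLen),
                        strand = sample(c("+", "-"), nExtra,
                                        replace = TRUE))
    list(genome = genome,
         specs = list(s = .fillSpecs(rbind(s, extra)),
                      g1 = .fillSpecs(g1)),
         truth = list(earlyBlocks = blocks, ratio = ratio))
}

.simRna <- function(params) {
    genome <- .simGenome(params, default = c(chrG = 10000L))
    genes <- params$genes %||% list(
        geneA = list(chrom = names(genome)[1L], strand = "+",
                     exons = cbind(start = c(1001L, 2001L, 3501L),
                                   end = c(1500L, 2600L, 4000L))),
        geneB = list(chrom = names(genome)[1L], strand = "-",
                     exons = cbind(start = c(6001L, 7501L),
                                   end = c(6800L, 8200L))))
    nReadsPerGene <- params$nReads %||% 2000L
    readLen <- params$readLen %||% 60L
    rows <- lapply(names(genes), function(g) {
        gene <- genes[[g]]
        txLen <- sum(gene$exons[, "end"] - gene$exons[, "start"] + 1L)
        txStart <- as.integer(round(runif(nReadsPerGene, 1,
                                          txLen - readLen)))
        blk <- lapply(txStart, .txToGenomic, len = readLen,
                      exons = gene$exons)
        data.frame(qname = sprintf("%s_%05d", g, seq_len(nReadsPerGene)),
                   chrom = gene$chrom,
                   pos = vapply(blk, `[[`, integer(1), "pos"),
                   cigar = vapply(blk, `[[`, character(1), "cigar"),
                   strand = gene$strand)
    })
    exonTab <- do.call(rbind, lapply(names(genes), function(g)
        data.frame(gene = g, chrom = genes[[g]]$chrom,
                   start = genes[[g]]$exons[, "start"],
                   end = genes[[g]]$exons[, "end"],
                   strand = genes[[g]]$strand)))
    list(genome = genome, specs = .fillSpecs(do.call(rbind, rows)),
         truth = list(genes = exonTab))
}

## map a transcript-coordinate interval onto genomic blocks -> pos + CIGAR
## with N gaps across introns
.txToGenomic <- function(txStart, len, exons) {
    exw <- exons[, "end"] - exons[, "start"] + 1L
    cumEnd <- cumsum(exw)
    cumStart <- cumEnd - exw + 1L
    txEnd <- txStart + len - 1L
    ops <- character()
    pos <- NA_integer_
    for (e in seq_len(nrow(exons))) {
        lo <- max(txStart, cumStart[e])
        hi <- min(txEnd, cumEnd[e])
        if (lo > hi) next
        gLo <- exons[e, "start"] + (lo - cumStart[e])
        gHi <- exons[e, "start"] + (hi - cumStart[e])
        if (is.na(pos)) {
            pos <- gLo
        } else {
            ops <- c(ops, sprintf("%dN", gLo - prevHi - 1L))
        }
        ops <- c(ops, sprintf("%dM", gHi - gLo + 1L))
        prevHi <- gHi
    }
    list(pos = as.integer(pos), cigar = paste(ops, collapse = ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a sequencing assay as BAM file(s) plus ground truth
#'
#' Deterministic (seeded) generators for the assay classes the package
#' serves: `atac`/`chip` (paired-end reads enriched in planted peaks, with
#' duplicate-flagged pairs and optional inter-chromosomal pairs piled on
#' one peak), `okseq` (single-end reads Watson-biased left and Crick-biased
#' right of planted origins, so true RFD switches from - to + at each
#' origin), `endseq` (stranded read stacks at planted break sites),
#' `reptime` (an S-phase/G1 pair with doubled S coverage inside planted
#' early-replicating blocks) and `rna` (spliced reads over 2-3-exon toy
#' genes).  Truth tables record every planted feature so planted quantities
#' can be computed without re-reading the BAM.
#'
#' @param kind one of `"atac"`, `"chip"`, `"okseq"`, `"endseq"`,
#'   `"reptime"`, `"rna"`.
#' @param params named list of overrides (read counts, layouts, rates); see
#'   the vignette for each generator's parameters and defaults.
#' @param seed integer seed; equal seeds give byte-identical BAM records.
#' @param dir output directory.
#' @return a list with `genome` (named lengths), `specs` (read-spec
#'   data.frame, or a list of two for `reptime`), `bam` (path or named list
#'   of paths), `truth` (list of truth tables) and, for peak assays, `bed`
#'   (path to the planted peak BED file).
#' @examples
#' sim <- simulateAssay("okseq", params = list(nReads = 500L), seed = 7)
#' sim$truth$origins
#' @export
simulateAssay <- function(kind = c("atac", "chip", "okseq", "endseq",
                                   "reptime", "rna"),
                          params = list(), seed = 1L,
                          dir = tempfile("sim")) {
    kind <- match.arg(kind)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(seed)
    sim <- switch(kind,
        atac = .simAtac(params),
        chip = .simAtac(c(params, list(
            nPeaks = params$nPeaks %||% 50L,
            peakWidth = params$peakWidth %||% c(1000L, 5000L)))),
        okseq = .simOkseq(params),
        endseq = .simEndseq(params),
        reptime = .simReptime(params),
        rna = .simRna(params))
    if (is.data.frame(sim$specs)) {
        sim$bam <- makeBam(sim$genome, sim$specs,
                           file.path(dir, kind))
    } else {
        sim$bam <- lapply(names(sim$specs), function(nm)
            makeBam(sim$genome, sim$specs[[nm]],
                    file.path(dir, paste0(kind, "_", nm))))
        names(sim$bam) <- names(sim$specs)
    }
    if (!is.null(sim$truth$peaks)) {
        bed <- file.path(dir, paste0(kind, "_peaks.bed"))
        p <- sim$truth$peaks
        writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", p$chrom,
                           p$start - 1L, p$end, p$name, p$strand), bed)
        sim$bed <- bed
    }
    sim$kind <- kind
    sim
}

## reference-consuming width straight from the CIGAR string, by regex;
## parses each distinct CIGAR once (fixtures repeat a few shapes heavily)
.oracleRefWidth <- function(cigar) {
    u <- unique(cigar)
    w <- vapply(u, function(cg) {
        if (is.na(cg) || cg == "*") return(0)
        m <- regmatches(cg, gregexpr("\\d+[A-Z=]", cg))[[1L]]
        op <- substr(m, nchar(m), nchar(m))
        n <- as.numeric(substr(m, 1L, nchar(m) - 1L))
        sum(n[op %in% c("M", "=", "X", "D", "N")])
    }, numeric(1), USE.NAMES = FALSE)
    w[match(cigar, u)]
}

#' Brute-force oracle for peak read counting
#'
#' Exhaustively evaluates read-vs-peak overlap straight from the read
#' specifications: the filter rules are re-derived from the spec columns
#' (never from encoded SAM flags), CIGAR reference widths are re-parsed
#' with regular expressions, and overlap is tested peak by peak.  Shares no
#' code with [countReadsInPeaks()]; intended as the independent verifier.
#'
#' @param specs read-spec data.frame (as passed to [makeBam()]).
#' @param peaks data.frame with `chrom`, `start`, `end` (1-based closed)
#'   and optionally `strand`, or a `GRanges`.
#' @param filter an \linkS4class{AlignmentFilter}.
#' @param orientation paired-end strand convention.
#' @return integer vector of counts per peak.
#' @export
oracleCounts <- function(specs, peaks, filter = AlignmentFilter(),
                         orientation = "forward") {
    specs <- .fillSpecs(specs)
    if (is(peaks, "GRanges")) {
        peaks <- data.frame(chrom = as.character(seqnames(peaks)),
                            start = start(peaks), end = end(peaks),
                            strand = as.character(strand(peaks)))
    }
    pass <- rep(TRUE, nrow(specs))
    if (filter@dropUnmapped) pass <- pass & !specs$unmapped
    if (filter@dropDuplicates) pass <- pass & !specs$duplicate
    if (filter@dropSecondary) pass <- pass & !specs$secondary
    if (filter@dropSupplementary) pass <- pass & !specs$supplementary
    if (filter@dropQcfail) pass <- pass & !specs$qcfail
    if (filter@minMapq > 0L) pass <- pass & specs$mapq >= filter@minMapq
    if (filter@requireSameChromMate)
        pass <- pass & !(specs$paired & !is.na(specs$mateChrom) &
                         specs$mateChrom != specs$chrom)
    rstrand <- ifelse(specs$paired & !specs$first,
                      ifelse(specs$strand == "+", "-", "+"), specs$strand)
    if (orientation == "reverse")
        rstrand <- ifelse(rstrand == "+", "-", "+")
    sel <- filter@strandSelect
    if (sel == "forward") pass <- pass & rstrand == "+"
    if (sel == "reverse") pass <- pass & rstrand == "-"
    refw <- .oracleRefWidth(specs$cigar)
    s <- specs$pos
    e <- specs$pos + refw - 1
    if (filter@fragmentMode) {
        properPair <- specs$paired & specs$proper & !is.na(specs$tlen) &
            specs$tlen != 0L & !is.na(specs$mateChrom) &
            specs$mateChrom == specs$chrom
        pass <- pass & !(properPair & specs$tlen < 0L)
        isLeft <- properPair & specs$tlen > 0L
        e <- ifelse(isLeft, specs$pos + abs(specs$tlen) - 1, e)
    }
    n <- integer(nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
        hit <- pass & specs$chrom == peaks$chrom[i] &
            s <= peaks$end[i] & e >= peaks$start[i]
        if (sel == "match_feature" && !is.null(peaks$strand) &&
            peaks$strand[i] %in% c("+", "-"))
            hit <- hit & rstrand == peaks$strand[i]
        n[i] <- sum(hit)
    }
    n
}
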