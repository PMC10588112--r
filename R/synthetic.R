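# Synthetic-data generators: all empirical-side inputs (TE annotations,
# cluster intervals, insertion-frequency tables, strand-resolved small-RNA
# reads, consensus-mapped ping-pong reads) with known ground truth, so the
# interval and small-RNA operators are testable without any downloads.
# Coordinates and labels only — no sequence is simulated.

#' Synthetic genome layout
#'
#' Mirrors the simulator's genome: equally sized chromosomes with
#' piRNA-cluster-like intervals at the chromosome starts.
#'
#' @param nChromosomes,chromLength,clusterFraction layout parameters;
#'   defaults match the simulated genome (5 x 10 Mb, clusters covering
#'   3.5\% of the genome at the chromosome starts).
#' @return list with \code{clusters} (a \code{GRanges}) and
#'   \code{seqlengths} (named integer vector).
#' @export
synthGenomeLayout <- function(nChromosomes = 5, chromLength = 1e7,
                              clusterFraction = 0.035) {
    arch <- buildArchitecture(nChromosomes, chromLength,
                              trapFraction = clusterFraction,
                              referenceFraction = 0)
    list(clusters = trapIntervals(arch), seqlengths = chromLengths(arch))
}

#' Synthetic TE annotations with planted cluster membership
#'
#' Places, for each family, a known number of TE copies with their
#' midpoints inside cluster intervals and a known number outside.
#' Divergences are drawn uniformly on [0, 15]\% and lengths uniformly on
#' [50, consensus length] bp, so the standard annotation filters (length
#' >= 100 bp, divergence <= 10\%) have records to discard. Deterministic
#' for a fixed seed.
#'
#' @param nFamilies number of TE families (named \code{fam01}, ...).
#' @param copiesInside,copiesOutside copies per family inside/outside
#'   clusters (recycled across families).
#' @param layout a layout from [synthGenomeLayout()].
#' @param consensusLength consensus length per family (recycled).
#' @param seed integer RNG seed.
#' @return list with \code{tes} (annotated \code{GRanges}),
#'   \code{clusters}, and \code{truth} (data.frame with one row per
#'   planted record: family, in_cluster, length, divergence).
#' @export
synthAnnotations <- function(nFamilies = 5, copiesInside = 3,
                             copiesOutside = 7,
                             layout = synthGenomeLayout(),
                             consensusLength = 5000, seed = 1) {
    set.seed(seed)
    families <- sprintf("fam%02d", seq_len(nFamilies))
    nIn <- rep_len(copiesInside, nFamilies)
    nOut <- rep_len(copiesOutside, nFamilies)
    consLen <- rep_len(consensusLength, nFamilies)
    clusters <- layout$clusters
    sl <- layout$seqlengths
    chroms <- names(sl)

    rows <- list()
    for (k in seq_len(nFamilies)) {
        n <- nIn[k] + nOut[k]
        if (n == 0L) next
        len <- as.integer(round(runif(n, 50, consLen[k])))
        inside <- rep(c(TRUE, FALSE), c(nIn[k], nOut[k]))
        start <- integer(n)
        chrom <- character(n)
        for (j in seq_len(n)) {
            if (inside[j]) {
                # fully inside a random cluster, so the midpoint is inside
                ci <- sample(length(clusters), 1L)
                cs <- GenomicRanges::start(clusters)[ci]
                ce <- GenomicRanges::end(clusters)[ci]
                if (ce - cs + 1L <= len[j])
                    stop("cluster too small to place a TE copy")
                chrom[j] <- as.character(
                    GenomicRanges::seqnames(clusters)[ci])
                start[j] <- as.integer(floor(runif(1, cs, ce - len[j] + 1)))
            } else {
                # start beyond every cluster end on the chromosome
                chrom[j] <- sample(chroms, 1L)
                onChr <- clusters[as.character(
                    GenomicRanges::seqnames(clusters)) == chrom[j]]
                lo <- if (length(onChr)) max(GenomicRanges::end(onChr)) + 1L
                      else 1L
                hi <- sl[[chrom[j]]] - len[j]
                start[j] <- as.integer(floor(runif(1, lo, hi + 1)))
            }
        }
        rows[[k]] <- data.frame(
            family = families[k], chrom = chrom, start = start,
            end = start + len - 1L, strand = sample(c("+", "-"), n, TRUE),
            divergence = round(runif(n, 0, 15), 2),
            consensus_length = consLen[k], in_cluster = inside)
    }
    truth <- do.call(rbind, rows)
    tes <- GenomicRanges::GRanges(
        truth$chrom, IRanges::IRanges(truth$start, truth$end),
        strand = truth$strand, family = truth$family,
        divergence = truth$divergence,
        consensus_length = truth$consensus_length,
        seqlengths = sl)
    list(tes = tes, clusters = clusters,
         truth = truth[c("family", "in_cluster", "chrom", "start", "end",
                         "strand", "divergence", "consensus_length")])
}

#' Synthetic insertion-frequency table with planted frequencies
#'
#' Emulates the tabular output of a paired-end TE caller: one record per
#' insertion with its (exactly planted) population frequency, positioned
#' inside or outside clusters as requested, so the haploid conversion of
#' the output is computable in closed form from the truth.
#'
#' @param plan data.frame with columns \code{family}, \code{frequency},
#'   \code{in_cluster} (logical).
#' @param layout a layout from [synthGenomeLayout()].
#' @param seed integer RNG seed (positions only; frequencies are exact).
#' @return list with \code{records} (data.frame: family, chrom, pos,
#'   frequency), \code{clusters}, and \code{truth} (the plan with
#'   positions).
#' @export
synthFreqTable <- function(plan, layout = synthGenomeLayout(), seed = 1) {
    set.seed(seed)
    if (nrow(plan) == 0L)
        return(list(records = data.frame(family = character(0),
                                         chrom = character(0),
                                         pos = integer(0),
                                         frequency = numeric(0)),
                    clusters = layout$clusters, truth = plan))
    stopifnot(all(plan$frequency >= 0 & plan$frequency <= 1))
    clusters <- layout$clusters
    sl <- layout$seqlengths
    n <- nrow(plan)
    chrom <- character(n)
    pos <- integer(n)
    for (j in seq_len(n)) {
        if (plan$in_cluster[j]) {
            ci <- sample(length(clusters), 1L)
            chrom[j] <- as.character(GenomicRanges::seqnames(clusters)[ci])
            pos[j] <- as.integer(floor(runif(
                1, GenomicRanges::start(clusters)[ci],
                GenomicRanges::end(clusters)[ci] + 1)))
        } else {
            chrom[j] <- sample(names(sl), 1L)
            onChr <- clusters[as.character(
                GenomicRanges::seqnames(clusters)) == chrom[j]]
            lo <- if (length(onChr)) max(GenomicRanges::end(onChr)) + 1L
                  else 1L
            pos[j] <- as.integer(floor(runif(1, lo, sl[[chrom[j]]] + 1)))
        }
    }
    records <- data.frame(family = plan$family, chrom = chrom, pos = pos,
                          frequency = plan$frequency)
    truth <- cbind(plan, chrom = chrom, pos = pos)
    list(records = records, clusters = clusters, truth = truth)
}

# Build a read GRanges from 5' end positions.
.readsFrom5prime <- function(chrom, p5, strand, len, mapq = 37L,
                             ncRNA = FALSE, seqlengths = NULL) {
    strand <- rep_len(strand, length(p5))
    len <- rep_len(len, length(p5))
    start <- ifelse(strand == "-", p5 - len + 1L, p5)
    end <- ifelse(strand == "-", p5, p5 + len - 1L)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                           strand = strand, mapq = mapq, ncRNA = ncRNA,
                           seqlengths = seqlengths)
}

#' Synthetic strand-resolved small-RNA reads with planted DSL signatures
#'
#' For every TE marked as a true DSL, antisense reads are planted with
#' their 5' ends in the upstream flank and sense reads in the downstream
#' flank (in the TE's orientation) at \code{signalFold} times the detection
#' threshold. All other TE flanks, and the flanks of any control genes, get
#' a strand-symmetric Poisson background hard-capped at half the threshold,
#' so that planted DSL are recovered exactly and the control rate is 0.
#' Remaining reads are scattered uniformly away from all feature flanks to
#' reach exactly \code{librarySize} filter-surviving reads (making rpm
#' values exact), plus a set of decoy reads (out-of-range lengths, low
#' mapping quality, ncRNA-flagged) that the piRNA filter must remove.
#'
#' @param tes stranded TE annotations (\code{GRanges} with seqlengths).
#' @param clusters cluster intervals (unused for read placement but
#'   returned for convenience in downstream calls).
#' @param dslTruth logical vector, one per TE: is it a true DSL?
#' @param genes optional stranded control-gene \code{GRanges}.
#' @param librarySize number of filter-surviving reads to generate.
#' @param flank,minRpm must match the detector settings.
#' @param signalFold planted signal as a multiple of \code{minRpm}.
#' @param noiseMeanReads Poisson mean of the per-window per-strand
#'   background in reads (capped at half the threshold).
#' @param decoyFraction extra decoy reads as a fraction of
#'   \code{librarySize}.
#' @param seed integer RNG seed.
#' @return list with \code{reads} (unfiltered \code{GRanges}),
#'   \code{librarySize}, and \code{truth} (logical DSL labels).
#' @export
synthSmallRNA <- function(tes, clusters, dslTruth, genes = NULL,
                          librarySize = 4e5, flank = 500, minRpm = 5,
                          signalFold = 2, noiseMeanReads = NULL,
                          decoyFraction = 0.01, seed = 1) {
    set.seed(seed)
    stopifnot(length(dslTruth) == length(tes), librarySize > 0)
    kSig <- as.integer(ceiling(signalFold * minRpm * librarySize / 1e6))
    cap <- as.integer(floor(0.5 * minRpm * librarySize / 1e6))
    if (is.null(noiseMeanReads)) noiseMeanReads <- cap / 2
    sl <- GenomeInfoDb::seqlengths(tes)

    lens <- function(n) sample(23:29, n, replace = TRUE)
    parts <- list()

    plantWindows <- function(features) {
        fstr <- as.character(GenomicRanges::strand(features))
        s <- GenomicRanges::start(features)
        e <- GenomicRanges::end(features)
        plus <- fstr == "+"
        data.frame(
            chrom = as.character(GenomicRanges::seqnames(features)),
            upS = ifelse(plus, s - flank, e + 1L),
            upE = ifelse(plus, s - 1L, e + flank),
            dnS = ifelse(plus, e + 1L, s - flank),
            dnE = ifelse(plus, e + flank, s - 1L),
            anti = ifelse(plus, "-", "+"), sense = fstr)
    }

    plant <- function(chrom, lo, hi, strand, n) {
        if (n <= 0L) return(NULL)
        # keep whole reads on the contig
        lo <- max(lo, 40L)
        hi <- min(hi, sl[[chrom]] - 40L)
        if (hi < lo) return(NULL)
        p5 <- as.integer(floor(runif(n, lo, hi + 1)))
        .readsFrom5prime(chrom, p5, strand, lens(n), seqlengths = sl)
    }

    wTE <- plantWindows(tes)
    for (i in seq_along(tes)) {
        if (dslTruth[i]) {
            parts[[length(parts) + 1L]] <-
                plant(wTE$chrom[i], wTE$upS[i], wTE$upE[i], wTE$anti[i], kSig)
            parts[[length(parts) + 1L]] <-
                plant(wTE$chrom[i], wTE$dnS[i], wTE$dnE[i], wTE$sense[i], kSig)
        }
        for (w in list(c(wTE$upS[i], wTE$upE[i]), c(wTE$dnS[i], wTE$dnE[i])))
            for (str in c("+", "-")) {
                nb <- min(rpois(1, noiseMeanReads), cap)
                if (dslTruth[i]) nb <- 0L  # keep the planted signal exact
                parts[[length(parts) + 1L]] <-
                    plant(wTE$chrom[i], w[1], w[2], str, nb)
            }
    }
    if (!is.null(genes)) {
        wG <- plantWindows(genes)
        for (i in seq_along(genes))
            for (w in list(c(wG$upS[i], wG$upE[i]), c(wG$dnS[i], wG$dnE[i])))
                for (str in c("+", "-")) {
                    nb <- min(rpois(1, noiseMeanReads), cap)
                    parts[[length(parts) + 1L]] <-
                        plant(wG$chrom[i], w[1], w[2], str, nb)
                }
    }
    placed <- if (length(parts)) do.call(c, parts) else NULL
    nPlaced <- if (is.null(placed)) 0L else length(placed)
    nFiller <- librarySize - nPlaced
    if (nFiller < 0)
        stop("librarySize too small for the planted reads")

    # filler avoids every feature's flanks so it cannot create signatures
    forbidden <- GenomicRanges::reduce(c(
        GenomicRanges::resize(GenomicRanges::granges(tes),
            GenomicRanges::width(tes) + 2L * (flank + 40L), fix = "center"),
        if (!is.null(genes))
            GenomicRanges::resize(GenomicRanges::granges(genes),
                GenomicRanges::width(genes) + 2L * (flank + 40L),
                fix = "center")
        else GenomicRanges::GRanges()))
    filler <- NULL
    while (nFiller > 0L) {
        chrom <- sample(names(sl), nFiller, replace = TRUE)
        p5 <- as.integer(floor(runif(nFiller, 40, sl[chrom] - 40)))
        cand <- .readsFrom5prime(chrom, p5,
                                 sample(c("+", "-"), nFiller, TRUE),
                                 lens(nFiller), seqlengths = sl)
        ok <- !IRanges::overlapsAny(fivePrimeEnds(cand), forbidden,
                                    ignore.strand = TRUE)
        filler <- if (is.null(filler)) cand[ok] else c(filler, cand[ok])
        nFiller <- nFiller - sum(ok)
    }

    good <- if (is.null(placed)) filler else c(placed, filler)
    nDecoy <- as.integer(ceiling(decoyFraction * librarySize))
    decoys <- NULL
    if (nDecoy > 0L) {
        chrom <- sample(names(sl), nDecoy, replace = TRUE)
        p5 <- as.integer(floor(runif(nDecoy, 40, sl[chrom] - 40)))
        kind <- sample(3, nDecoy, replace = TRUE)
        decoys <- .readsFrom5prime(
            chrom, p5, sample(c("+", "-"), nDecoy, TRUE),
            ifelse(kind == 1L, sample(c(18:22, 30:35), nDecoy, TRUE),
                   lens(nDecoy)),
            mapq = ifelse(kind == 2L, 0L, 37L),
            ncRNA = kind == 3L, seqlengths = sl)
    }
    reads <- if (is.null(decoys)) good else c(good, decoys)
    reads <- reads[sample(length(reads))]
    list(reads = reads, librarySize = librarySize, truth = dslTruth)
}

#' Synthetic consensus-mapped reads with a planted ping-pong signal
#'
#' Generates \code{nPairs} (sense, antisense) read pairs on one consensus
#' coordinate system: a fraction \code{signalFraction} at the exact 10-nt
#' 5'-5' overlap, the remainder at offsets uniform on 1..20 excluding 10.
#' The ping-pong Z-score increases monotonically with
#' \code{signalFraction}.
#'
#' @param nPairs number of read pairs.
#' @param signalFraction fraction of pairs at the 10-nt overlap, in
#'   \eqn{[0, 1]}.
#' @param consensusLength consensus length in nt.
#' @param seed integer RNG seed.
#' @return a \code{GRanges} of reads on seqname \code{"consensus"}.
#' @export
synthPingPongReads <- function(nPairs = 1000, signalFraction = 0.5,
                               consensusLength = 5000, seed = 1) {
    set.seed(seed)
    stopifnot(signalFraction >= 0, signalFraction <= 1, nPairs >= 1)
    nSig <- round(signalFraction * nPairs)
    # background pairs cover all offsets (including 10) so that zero signal
    # is a true null with z10 ~ 0; signal pairs add on top of it
    off <- c(rep(10L, nSig), sample(1:20, nPairs - nSig, replace = TRUE))
    # when there is room, pairs are spaced further apart than the offset
    # range so reads from different pairs can never form 1..20 nt overlaps
    # and the planted histogram is exact; at high density placement falls
    # back to uniform (cross-pair overlaps then add symmetric background)
    lo <- 40L
    hi <- as.integer(consensusLength) - 60L
    minGap <- 60L
    nSlots <- (hi - lo) %/% minGap
    s5 <- if (nPairs <= nSlots) {
        lo + minGap * (sample(nSlots, nPairs) - 1L) +
            sample(0:19, nPairs, replace = TRUE)
    } else {
        sample(lo:hi, nPairs, replace = TRUE)
    }
    a5 <- s5 + off - 1L
    lenS <- sample(23:29, nPairs, replace = TRUE)
    lenA <- sample(23:29, nPairs, replace = TRUE)
    sl <- c(consensus = as.integer(consensusLength))
    c(.readsFrom5prime("consensus", s5, "+", lenS, seqlengths = sl),
      .readsFrom5prime("consensus", a5, "-", lenA, seqlengths = sl))
}
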