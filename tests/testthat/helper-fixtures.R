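# Shared fixtures and independent oracles used across the test files.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
})

# A small, fast genome for simulator unit tests: 2 chromosomes of 1 Mb.
tinyArch <- function(trapFraction = 0.035, referenceFraction = 0.035) {
    buildArchitecture(nChromosomes = 2, chromLength = 1e6,
                      trapFraction = trapFraction,
                      referenceFraction = referenceFraction, recombRate = 4)
}

tinyConfig <- function(arch = tinyArch(), N = 100, u = 0.1, nSeed = 100,
                       sampleGeneration = 200, ...) {
    simulationConfig(architecture = arch, N = N, u = u,
                     nSeedInsertions = nSeed,
                     sampleGeneration = sampleGeneration, ...)
}

# Selection model with one deleterious class at coefficient x hitting
# `fraction` of sites.
twoClassSelection <- function(x, fraction, trapsNeutral = TRUE) {
    selectionModel(
        classEffects = c(neutral = 0, del = x),
        classFractions = c(neutral = 1 - fraction, del = fraction),
        trapsNeutral = trapsNeutral)
}

# O(n^2) pair-enumeration oracle for tie-corrected Kendall tau (tau-b).
kendallOracle <- function(x, y) {
    n <- length(x)
    conc <- disc <- tx <- ty <- 0
    for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
            dx <- sign(x[j] - x[i])
            dy <- sign(y[j] - y[i])
            if (dx == 0 && dy == 0) next
            if (dx == 0) tx <- tx + 1
            else if (dy == 0) ty <- ty + 1
            else if (dx == dy) conc <- conc + 1
            else disc <- disc + 1
        }
    }
    (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Per-bp membership oracle for interval union size.
coverageOracle <- function(starts, ends, upTo) {
    hit <- logical(upTo)
    for (k in seq_along(starts)) hit[starts[k]:ends[k]] <- TRUE
    sum(hit)
}

# All-pairs oracle for the ping-pong 5'-5' overlap histogram.
pingPongOracle <- function(reads, maxOffset = 20) {
    str <- as.character(strand(reads))
    s5 <- start(reads)[str == "+"]
    a5 <- end(reads)[str == "-"]
    counts <- setNames(integer(maxOffset), seq_len(maxOffset))
    for (s in s5) {
        for (a in a5) {
            o <- a - s + 1
            if (o >= 1 && o <= maxOffset) counts[o] <- counts[o] + 1L
        }
    }
    counts
}

# Reads builder: 5' ends + strands -> GRanges with mapq/ncRNA mcols.
readsAt <- function(chrom, p5, strand, len = 25, mapq = 37, ncRNA = FALSE,
                    seqlengths = NULL) {
    len <- rep_len(len, length(p5))
    strand <- rep_len(strand, length(p5))
    start <- ifelse(strand == "-", p5 - len + 1, p5)
    end <- ifelse(strand == "-", p5, p5 + len - 1)
    GRanges(chrom, IRanges(start, end), strand = strand,
            mapq = rep_len(mapq, length(p5)),
            ncRNA = rep_len(ncRNA, length(p5)), seqlengths = seqlengths)
}
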