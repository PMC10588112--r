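#' Build a genome architecture with traps and reference regions at opposite
#' chromosome ends
#'
#' Places, on every chromosome, a transposon-trap interval at the start
#' (\code{[1, round(trapFraction * L)]}) and a reference interval at the end
#' (\code{[L - round(referenceFraction * L) + 1, L]}), mimicking equally
#' sized piRNA-cluster-like regions and null comparator regions on opposite
#' chromosome ends. Defaults are a fly-like genome: 5 chromosomes of 10 Mb,
#' 4 cM/Mb, traps and reference regions each 3.5% of the genome.
#'
#' @param nChromosomes number of chromosomes.
#' @param chromLength chromosome length in bp.
#' @param trapFraction,referenceFraction fraction of the genome covered by
#'   traps / reference regions; must each be \code{>= 0} and sum to
#'   \code{<= 1}.
#' @param recombRate uniform recombination rate in cM/Mb.
#' @return a [GenomeArchitecture-class].
#' @examples
#' arch <- buildArchitecture()
#' trapIntervals(arch)
#' @export
buildArchitecture <- function(nChromosomes = 5L, chromLength = 1e7,
                              trapFraction = 0.035, referenceFraction = 0.035,
                              recombRate = 4) {
    stopifnot(trapFraction >= 0, referenceFraction >= 0, recombRate >= 0)
    if (trapFraction + referenceFraction > 1)
        stop("trapFraction + referenceFraction must be <= 1 (intervals would overlap)")
    nChromosomes <- as.integer(nChromosomes)
    chromLength <- as.integer(chromLength)
    chroms <- paste0("chr", seq_len(nChromosomes))
    sl <- setNames(rep(chromLength, nChromosomes), chroms)

    trapLen <- as.integer(round(trapFraction * chromLength))
    refLen <- as.integer(round(referenceFraction * chromLength))
    emptyGR <- GenomicRanges::GRanges(seqlengths = sl)
    trap <- if (trapLen > 0L) {
        GenomicRanges::GRanges(chroms, IRanges::IRanges(1L, trapLen),
                               seqlengths = sl)
    } else emptyGR
    ref <- if (refLen > 0L) {
        GenomicRanges::GRanges(chroms,
                               IRanges::IRanges(chromLength - refLen + 1L,
                                                chromLength),
                               seqlengths = sl)
    } else emptyGR

    new("GenomeArchitecture",
        nChromosomes = nChromosomes, chromLength = chromLength,
        recombRate = as.numeric(recombRate),
        trapIntervals = trap, referenceIntervals = ref,
        trapFraction = as.numeric(trapFraction),
        referenceFraction = as.numeric(referenceFraction))
}

# GRanges (1-based closed) -> global 0-based half-open coordinates used by
# the C++ core.
.globalIntervals <- function(gr, arch) {
    if (length(gr) == 0L)
        return(list(start = integer(0), end = integer(0)))
    idx <- match(as.character(GenomicRanges::seqnames(gr)),
                 paste0("chr", seq_len(arch@nChromosomes)))
    if (anyNA(idx)) stop("interval on unknown chromosome")
    off <- (idx - 1L) * arch@chromLength
    o <- order(off + GenomicRanges::start(gr))
    list(start = (off + GenomicRanges::start(gr) - 1L)[o],
         end = (off + GenomicRanges::end(gr))[o])
}

.archParams <- function(arch) {
    trap <- .globalIntervals(arch@trapIntervals, arch)
    ref <- .globalIntervals(arch@referenceIntervals, arch)
    list(nChrom = arch@nChromosomes, chromLength = arch@chromLength,
         recombRate = arch@recombRate,
         trapStart = trap$start, trapEnd = trap$end,
         refStart = ref$start, refEnd = ref$end)
}

.selParams <- function(sel) {
    list(x = unname(sel@classEffects), frac = unname(sel@classFractions),
         trapsNeutral = sel@trapsNeutral)
}
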