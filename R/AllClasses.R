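#' @import methods
#' @importFrom GenomicRanges GRanges start end width strand seqnames
#'   findOverlaps countOverlaps reduce sort
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
#' @importFrom stats cor.test rbinom rpois runif sd aggregate setNames
#' @importFrom utils read.delim write.table head
#' @useDynLib trapTE, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Chromosome layout with transposon traps and reference regions
#'
#' A \code{GenomeArchitecture} describes the simulated genome: a number of
#' equally sized chromosomes, a uniform recombination rate, and two sets of
#' disjoint intervals — transposon traps (piRNA-cluster-like regions in which
#' a single insertion silences all TE copies of the carrier) and reference
#' regions (equally sized regions with no effect on TE activity).
#'
#' Intervals are stored as \link[GenomicRanges]{GRanges} in the usual
#' Bioconductor 1-based closed convention, on chromosomes named
#' \code{"chr1"}, \code{"chr2"}, ...
#'
#' @slot nChromosomes number of chromosomes.
#' @slot chromLength chromosome length in bp (identical for all chromosomes).
#' @slot recombRate uniform recombination rate in cM/Mb.
#' @slot trapIntervals,referenceIntervals \code{GRanges} of trap and
#'   reference intervals.
#' @slot trapFraction,referenceFraction fraction of the total genome covered
#'   by traps and reference regions.
#'
#' @seealso [buildArchitecture()]
#' @export
setClass("GenomeArchitecture",
    representation(
        nChromosomes = "integer",
        chromLength = "integer",
        recombRate = "numeric",
        trapIntervals = "GRanges",
        referenceIntervals = "GRanges",
        trapFraction = "numeric",
        referenceFraction = "numeric"
    )
)

setValidity("GenomeArchitecture", function(object) {
    msg <- character()
    if (object@nChromosomes < 1L)
        msg <- c(msg, "need at least one chromosome")
    if (as.double(object@nChromosomes) * object@chromLength >= 2^31)
        msg <- c(msg, "total genome size must be below 2^31 bp")
    both <- c(object@trapIntervals, object@referenceIntervals)
    if (length(both) > 1L) {
        ov <- GenomicRanges::findOverlaps(both, drop.self = TRUE)
        if (length(ov) > 0L)
            msg <- c(msg, "trap and reference intervals must be pairwise disjoint")
    }
    for (gr in list(object@trapIntervals, object@referenceIntervals)) {
        if (length(gr) > 0L &&
            (any(GenomicRanges::start(gr) < 1L) ||
             any(GenomicRanges::end(gr) > object@chromLength)))
            msg <- c(msg, "intervals must lie within the chromosomes")
    }
    G <- as.double(object@nChromosomes) * object@chromLength
    tol <- object@nChromosomes / G  # one bp rounding per chromosome
    if (abs(sum(as.double(GenomicRanges::width(object@trapIntervals))) / G -
            object@trapFraction) > tol)
        msg <- c(msg, "trap intervals do not cover trapFraction of the genome")
    if (abs(sum(as.double(GenomicRanges::width(object@referenceIntervals))) / G -
            object@referenceFraction) > tol)
        msg <- c(msg, "reference intervals do not cover referenceFraction of the genome")
    if (length(msg)) msg else TRUE
})

#' Selection model for TE insertions
#'
#' Site-class selection: each insertion is assigned an effect class at
#' insertion time (drawn from \code{classFractions}) and contributes its
#' class coefficient \eqn{x} to the linear fitness cost
#' \eqn{w = 1 - \sum_i x_i}. When \code{trapsNeutral} is \code{TRUE},
#' insertions inside transposon traps contribute nothing regardless of class.
#'
#' @slot classEffects named numeric, selection coefficient \eqn{x \ge 0} per
#'   effect class.
#' @slot classFractions named numeric, fraction of genomic sites per class;
#'   must sum to 1 and share names with \code{classEffects}.
#' @slot trapsNeutral logical flag.
#'
#' @seealso [selectionModel()], [neutralSelection()]
#' @export
setClass("SelectionModel",
    representation(
        classEffects = "numeric",
        classFractions = "numeric",
        trapsNeutral = "logical"
    )
)

setValidity("SelectionModel", function(object) {
    msg <- character()
    if (length(object@classEffects) == 0L)
        msg <- c(msg, "need at least one effect class")
    if (!identical(names(object@classEffects), names(object@classFractions)))
        msg <- c(msg, "classEffects and classFractions must share names")
    if (any(object@classEffects < 0))
        msg <- c(msg, "selection coefficients must be >= 0")
    if (abs(sum(object@classFractions) - 1) > 1e-8)
        msg <- c(msg, "classFractions must sum to 1")
    if (length(msg)) msg else TRUE
})

#' Scenario configuration for a TE invasion simulation
#'
#' Bundles everything [runReplicate()] needs: the genome architecture, the
#' diploid population size, the per-copy transposition rate (a single value
#' or a \code{c(min, max)} range sampled uniformly per replicate), the
#' selection model, the number of seed insertions, and the sampling
#' generation (fixed, or an integer range sampled uniformly per replicate).
#'
#' @slot architecture a [GenomeArchitecture-class].
#' @slot N diploid population size.
#' @slot u transposition rate per copy per generation; length 1, or length 2
#'   for a per-replicate uniform sampler.
#' @slot selection a [SelectionModel-class].
#' @slot nSeedInsertions number of insertions used to trigger the invasion;
#'   each starts on one haplotype of one individual, i.e. at population
#'   frequency \eqn{1/(2N)}.
#' @slot maxGenerations hard cap on the number of generations.
#' @slot sampleGeneration generation at which the population is sampled;
#'   length 1, or length 2 for a per-replicate integer-uniform sampler.
#' @slot extinctionFitness mean-fitness floor below which the population is
#'   recorded as extinct.
#' @slot transpositionConditioning \code{"parent"} (the default: only
#'   copies inherited from a non-silenced parent transpose — transposition
#'   happens in the parental germline) or \code{"zygote"} (a newly formed
#'   individual transposes all its copies at rate \eqn{u} unless it carries
#'   a trap insertion itself).
#'
#' @seealso [simulationConfig()]
#' @export
setClass("SimulationConfig",
    representation(
        architecture = "GenomeArchitecture",
        N = "integer",
        u = "numeric",
        selection = "SelectionModel",
        nSeedInsertions = "integer",
        maxGenerations = "integer",
        sampleGeneration = "numeric",
        extinctionFitness = "numeric",
        transpositionConditioning = "character"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@N < 1L) msg <- c(msg, "N must be >= 1")
    if (!length(object@u) %in% 1:2 || any(object@u < 0) || any(object@u > 1))
        msg <- c(msg, "u must be one value or a range within [0, 1]")
    if (length(object@u) == 2L && object@u[1] > object@u[2])
        msg <- c(msg, "u range must be increasing")
    if (!length(object@sampleGeneration) %in% 1:2 ||
        any(object@sampleGeneration < 0) ||
        any(object@sampleGeneration > object@maxGenerations))
        msg <- c(msg, "sampleGeneration must lie within [0, maxGenerations]")
    if (object@extinctionFitness <= 0 || object@extinctionFitness >= 1)
        msg <- c(msg, "extinctionFitness must be in (0, 1)")
    if (object@nSeedInsertions < 0L)
        msg <- c(msg, "nSeedInsertions must be >= 0")
    if (!object@transpositionConditioning %in% c("zygote", "parent"))
        msg <- c(msg, "transpositionConditioning must be 'zygote' or 'parent'")
    if (length(msg)) msg else TRUE
})

#' A diploid population
#'
#' The simulator's state: a list of diploid individuals plus a generation
#' counter. Each individual is a plain list with haplotypes \code{h1} and
#' \code{h2}; each haplotype is a list with sorted integer vector \code{pos}
#' (global 0-based insertion positions) and parallel integer vector
#' \code{cls} (1-based effect-class index). Use [makeHaplotype()] /
#' [makeIndividual()] to build individuals in chromosome coordinates.
#'
#' @slot individuals list of individuals.
#' @slot generation generation index (0 after seeding).
#' @export
setClass("Population",
    representation(individuals = "list", generation = "integer")
)

#' Summary of one simulated TE invasion
#'
#' Produced by [runReplicate()]. Holds the per-individual diploid insertion
#' counts in traps, reference regions, and the whole genome at the sampling
#' generation, the invasion phase at sampling, and the copy-number
#' trajectory. Counts are diploid; divide by 2 for haploid estimates.
#'
#' @slot replicateId replicate index within an ensemble.
#' @slot seed RNG seed used for this replicate.
#' @slot u realized transposition rate (after any per-replicate sampling).
#' @slot sampleGeneration realized sampling generation.
#' @slot phase one of \code{"rapid"}, \code{"shotgun"}, \code{"inactive"},
#'   \code{"extinct"}.
#' @slot extinct logical; mean fitness fell below the extinction floor
#'   before sampling.
#' @slot firstAllSilenced first generation at which every individual carried
#'   at least one trap insertion (\code{NA} if never reached).
#' @slot meanTrapAtSilencing mean diploid trap-insertion count at that
#'   generation (\code{NA} if never reached).
#' @slot counts data.frame with one row per individual: \code{trap},
#'   \code{reference}, \code{genome} (diploid counts).
#' @slot trajectory data.frame per generation: \code{generation},
#'   \code{mean_diploid_copies}, \code{fraction_silenced},
#'   \code{mean_trap_diploid}.
#' @export
setClass("ReplicateSummary",
    representation(
        replicateId = "integer",
        seed = "integer",
        u = "numeric",
        sampleGeneration = "integer",
        phase = "character",
        extinct = "logical",
        firstAllSilenced = "integer",
        meanTrapAtSilencing = "numeric",
        counts = "data.frame",
        trajectory = "data.frame"
    )
)

#' An ensemble of simulated TE invasions
#'
#' A list of [ReplicateSummary-class] objects produced by [runEnsemble()]
#' under one [SimulationConfig-class]. Replicates are interpreted as
#' invasions of distinct TE families in the same population, which links the
#' simulations to the observed abundance of TE families in piRNA clusters.
#'
#' @slot replicates list of \code{ReplicateSummary}.
#' @slot config the shared configuration.
#' @slot baseSeed base seed from which per-replicate seeds were derived.
#' @export
setClass("InvasionEnsemble",
    representation(
        replicates = "list",
        config = "SimulationConfig",
        baseSeed = "integer"
    )
)
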