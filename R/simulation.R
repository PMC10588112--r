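#' Construct a selection model
#'
#' @param classEffects named numeric vector of selection coefficients
#'   \eqn{x \ge 0} per effect class.
#' @param classFractions named numeric vector of site fractions per class
#'   (must sum to 1). New insertions draw their class from these fractions.
#' @param trapsNeutral if \code{TRUE} (the default), insertions inside
#'   transposon traps are neutral regardless of their class.
#' @return a [SelectionModel-class].
#' @examples
#' # 10% of sites each at x = 0.1, 0.01, 0.001, 0.0001; 60% neutral
#' selectionModel(
#'     classEffects  = c(neutral = 0, s1 = 0.1, s2 = 0.01, s3 = 0.001, s4 = 1e-4),
#'     classFractions = c(neutral = 0.6, s1 = 0.1, s2 = 0.1, s3 = 0.1, s4 = 0.1))
#' @export
selectionModel <- function(classEffects = c(neutral = 0),
                           classFractions = c(neutral = 1),
                           trapsNeutral = TRUE) {
    new("SelectionModel", classEffects = classEffects,
        classFractions = classFractions, trapsNeutral = trapsNeutral)
}

#' @rdname selectionModel
#' @export
neutralSelection <- function() selectionModel()

#' Construct a simulation configuration
#'
#' Defaults reproduce the baseline invasion scenario: 1000 diploid
#' individuals, constant transposition rate \eqn{u = 0.1}, neutral
#' insertions, 1000 seed insertions each at population frequency
#' \eqn{1/(2N)}, sampling at generation 2000, and extinction when the mean
#' fitness falls below 0.1.
#'
#' @param architecture a [GenomeArchitecture-class].
#' @param N diploid population size.
#' @param u transposition rate per copy per generation; give \code{c(min,
#'   max)} for a per-replicate uniform sampler.
#' @param selection a [SelectionModel-class].
#' @param nSeedInsertions number of seed insertions.
#' @param maxGenerations generation cap.
#' @param sampleGeneration sampling generation; give \code{c(min, max)} for
#'   a per-replicate integer-uniform sampler.
#' @param extinctionFitness mean-fitness extinction floor.
#' @param transpositionConditioning whose genotype gates transposition:
#'   the contributing parent's (\code{"parent"}, default: transposition in
#'   the parental germline, so copies from silenced parents never
#'   transpose) or the newly formed individual's own (\code{"zygote"}).
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(architecture = buildArchitecture(), N = 1000,
                             u = 0.1, selection = neutralSelection(),
                             nSeedInsertions = 1000, maxGenerations = 10000,
                             sampleGeneration = 2000, extinctionFitness = 0.1,
                             transpositionConditioning = c("parent", "zygote")) {
    new("SimulationConfig", architecture = architecture, N = as.integer(N),
        u = as.numeric(u), selection = selection,
        nSeedInsertions = as.integer(nSeedInsertions),
        maxGenerations = as.integer(maxGenerations),
        sampleGeneration = as.numeric(sampleGeneration),
        extinctionFitness = as.numeric(extinctionFitness),
        transpositionConditioning = match.arg(transpositionConditioning))
}

#' Build haplotypes and individuals in chromosome coordinates
#'
#' Helpers for constructing simulator inputs by hand (mostly for tests and
#' small worked examples). Positions are 1-based within chromosomes; they
#' are converted to the sorted internal representation.
#'
#' @param arch a [GenomeArchitecture-class].
#' @param chrom integer chromosome index (1-based), recycled.
#' @param pos integer positions within the chromosome, 1-based.
#' @param class integer effect-class index (1-based into the selection
#'   model's classes), recycled.
#' @return \code{makeHaplotype}: a haplotype (list with \code{pos},
#'   \code{cls}); \code{makeIndividual}: an individual (list with \code{h1},
#'   \code{h2}).
#' @examples
#' arch <- buildArchitecture()
#' ind <- makeIndividual(makeHaplotype(arch, 1, c(100, 5e6)))
#' isSilenced(ind, arch)
#' @export
makeHaplotype <- function(arch, chrom = integer(0), pos = integer(0),
                          class = 1L) {
    stopifnot(length(pos) == 0L || all(pos >= 1 & pos <= arch@chromLength))
    n <- length(pos)
    chrom <- rep_len(as.integer(chrom), n)
    class <- rep_len(as.integer(class), n)
    g <- (chrom - 1L) * arch@chromLength + as.integer(pos) - 1L
    o <- order(g)
    if (anyDuplicated(g)) stop("duplicate positions on one haplotype")
    list(pos = g[o], cls = class[o])
}

#' @rdname makeHaplotype
#' @param h1,h2 haplotypes.
#' @export
makeIndividual <- function(h1 = makeHaplotype(buildArchitecture()), h2 = NULL) {
    if (is.null(h2)) h2 <- list(pos = integer(0), cls = integer(0))
    list(h1 = h1, h2 = h2)
}

#' Convert a haplotype back to chromosome coordinates
#'
#' @param hap a haplotype as stored in a [Population-class].
#' @param arch the matching [GenomeArchitecture-class].
#' @return data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{class}.
#' @export
haplotypeInsertions <- function(hap, arch) {
    data.frame(chrom = hap$pos %/% arch@chromLength + 1L,
               pos = hap$pos %% arch@chromLength + 1L,
               class = hap$cls)
}

#' Seed a population with low-frequency TE insertions
#'
#' Triggers an invasion by placing \code{nSeedInsertions} insertions at
#' uniformly random genomic positions, each on one uniformly chosen
#' haplotype of one uniformly chosen individual, so that every seed
#' segregates at population frequency \eqn{1/(2N)}. Effect classes are drawn
#' from the selection model's class fractions.
#'
#' @param config a [SimulationConfig-class].
#' @param seed optional integer seed (calls \code{set.seed}).
#' @return a [Population-class] at generation 0.
#' @export
seedPopulation <- function(config, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    inds <- seed_population_cpp(.archParams(config@architecture),
                                .selParams(config@selection),
                                config@N, config@nSeedInsertions)
    new("Population", individuals = inds, generation = 0L)
}

#' Fitness of a diploid individual
#'
#' \eqn{w = 1 - \sum_i x_i} over all insertions on both haplotypes, where
#' \eqn{x_i} is the effect of insertion \eqn{i}'s class; insertions in
#' transposon traps contribute 0 when the selection model's
#' \code{trapsNeutral} is set. Clamped at 0.
#'
#' @param individual an individual (see [makeIndividual()]).
#' @param selection a [SelectionModel-class].
#' @param arch a [GenomeArchitecture-class].
#' @return fitness in \eqn{[0, 1]}.
#' @examples
#' arch <- buildArchitecture()
#' sel <- selectionModel(c(neutral = 0, del = 0.1), c(neutral = 0.9, del = 0.1))
#' ind <- makeIndividual(makeHaplotype(arch, 1, c(5e6, 6e6), class = 2L))
#' individualFitness(ind, sel, arch)  # 0.8: two x = 0.1 insertions
#' @export
individualFitness <- function(individual, selection, arch) {
    fitness_cpp(individual, .archParams(arch), .selParams(selection))
}

#' Is an individual silenced?
#'
#' \code{TRUE} iff any insertion on either haplotype lies within a
#' transposon-trap interval: under the trap model a single trap insertion
#' silences all TE copies of the carrier.
#'
#' @inheritParams individualFitness
#' @return logical.
#' @export
isSilenced <- function(individual, arch) {
    silenced_cpp(individual, .archParams(arch))
}

#' Produce one gamete from a diploid parent
#'
#' Per chromosome, the crossover count is Poisson with mean
#' \code{recombRate * chromLength(Mb) / 100} (Morgans); crossover positions
#' are uniform; the gamete alternates between the parental haplotypes at
#' breakpoints, starting from a fair-coin choice, and chromosomes assort
#' independently. Uses R's RNG (seed with \code{set.seed}).
#'
#' @inheritParams individualFitness
#' @return a haplotype.
#' @export
makeGamete <- function(individual, arch) {
    gamete_cpp(individual, .archParams(arch))
}

#' Advance a population by one Wright-Fisher generation
#'
#' Each of the \eqn{N} offspring draws two parents independently with
#' probability proportional to fitness (selfing allowed), receives one
#' gamete from each, and then undergoes transposition: every TE copy
#' inherited on a gamete from a non-silenced parent generates, with
#' probability \eqn{u}, a new insertion at a uniformly random genome
#' position on a uniformly chosen haplotype of the offspring. Copies from
#' silenced parents never transpose.
#'
#' @param population a [Population-class].
#' @param config a [SimulationConfig-class]; when \code{u} is a range its
#'   lower bound is used (use [runReplicate()] for per-replicate sampling).
#' @return the next [Population-class].
#' @export
reproduce <- function(population, config) {
    inds <- next_generation_cpp(population@individuals,
                                .archParams(config@architecture),
                                .selParams(config@selection),
                                config@u[1],
                                config@transpositionConditioning == "zygote")
    new("Population", individuals = inds,
        generation = population@generation + 1L)
}

#' Classify the phase of an invasion
#'
#' \code{"rapid"} while at least one individual is unsilenced (the TE still
#' spreads), \code{"shotgun"} once every individual is silenced by
#' segregating trap insertions, and \code{"inactive"} once some trap
#' insertion is fixed (present on all \eqn{2N} haplotypes at one site).
#'
#' @param population a [Population-class].
#' @param arch a [GenomeArchitecture-class].
#' @return character phase label.
#' @export
classifyPhase <- function(population, arch) {
    classify_phase_cpp(population@individuals, .archParams(arch))
}

#' Per-individual insertion counts in traps, reference regions and the genome
#'
#' Insertions are classified by interval membership. Counts are diploid
#' (both haplotypes).
#'
#' @param population a [Population-class].
#' @param arch a [GenomeArchitecture-class].
#' @return data.frame with columns \code{trap}, \code{reference},
#'   \code{genome}, one row per individual.
#' @export
countRegions <- function(population, arch) {
    as.data.frame(region_counts_cpp(population@individuals, .archParams(arch)))
}

# Deterministic per-replicate seed derivation; kept below 2^31.
.replicateSeed <- function(baseSeed, i) {
    as.integer((as.numeric(baseSeed) %% 2147483647 * 48271 + i * 16807) %%
               2147483647)
}

#' Simulate one complete TE invasion
#'
#' Seeds a population and iterates Wright-Fisher generations until the
#' sampling generation, recording the copy-number trajectory, the first
#' generation at which every individual is silenced, and — at sampling —
#' the per-individual regional counts and the invasion phase. The
#' simulation is marked extinct when the mean fitness drops below the
#' configured floor before sampling (checked before reproduction each
#' generation). Identical \code{config} and \code{seed} give identical
#' output.
#'
#' @param config a [SimulationConfig-class].
#' @param seed integer RNG seed for this replicate.
#' @param replicateId replicate index stored in the summary.
#' @param recordTrajectory record the per-generation trajectory
#'   (default \code{TRUE}).
#' @return a [ReplicateSummary-class].
#' @export
runReplicate <- function(config, seed = 1L, replicateId = 1L,
                         recordTrajectory = TRUE) {
    set.seed(seed)
    u <- if (length(config@u) == 2L) {
        runif(1, config@u[1], config@u[2])
    } else config@u
    sg <- if (length(config@sampleGeneration) == 2L) {
        lo <- config@sampleGeneration[1]
        hi <- config@sampleGeneration[2]
        as.integer(floor(runif(1, lo, hi + 1)))
    } else as.integer(config@sampleGeneration)
    sg <- min(sg, config@maxGenerations)

    res <- run_replicate_cpp(.archParams(config@architecture),
                             .selParams(config@selection),
                             config@N, u, config@nSeedInsertions, sg,
                             config@extinctionFitness, recordTrajectory,
                             FALSE,
                             config@transpositionConditioning == "zygote")
    new("ReplicateSummary",
        replicateId = as.integer(replicateId), seed = as.integer(seed),
        u = u, sampleGeneration = as.integer(res$generation),
        phase = res$phase, extinct = res$extinct,
        firstAllSilenced = as.integer(res$firstAllSilenced),
        meanTrapAtSilencing = as.numeric(res$meanTrapAtSilencing),
        counts = data.frame(trap = res$trap, reference = res$reference,
                            genome = res$genome),
        trajectory = res$trajectory)
}

#' Simulate an ensemble of TE invasions
#'
#' Runs \code{nReplicates} invasions under one configuration. Replicate
#' \code{i} uses a seed derived deterministically from \code{(baseSeed, i)};
#' per-replicate transposition rates and sampling generations are drawn from
#' the configured samplers. Replicates are interpreted as invasions of
#' distinct TE families in the same population.
#'
#' @param config a [SimulationConfig-class].
#' @param nReplicates number of replicate invasions.
#' @param baseSeed integer base seed.
#' @param recordTrajectory record per-generation trajectories.
#' @return an [InvasionEnsemble-class].
#' @export
runEnsemble <- function(config, nReplicates = 300, baseSeed = 1L,
                        recordTrajectory = TRUE) {
    stopifnot(nReplicates >= 1)
    reps <- lapply(seq_len(nReplicates), function(i) {
        runReplicate(config, seed = .replicateSeed(baseSeed, i),
                     replicateId = i, recordTrajectory = recordTrajectory)
    })
    new("InvasionEnsemble", replicates = reps, config = config,
        baseSeed = as.integer(baseSeed))
}

#' Tabular summary of an ensemble
#'
#' @param ensemble an [InvasionEnsemble-class].
#' @return data.frame with one row per replicate: realized sampling
#'   generation, phase, mean diploid copy number and per-haploid mean counts
#'   in traps, reference regions and the genome.
#' @export
ensembleSummary <- function(ensemble) {
    do.call(rbind, lapply(replicates(ensemble), function(r) {
        cc <- individualCounts(r)
        data.frame(replicate = r@replicateId,
                   sample_generation = r@sampleGeneration,
                   u = r@u, phase = r@phase, extinct = r@extinct,
                   first_all_silenced = r@firstAllSilenced,
                   mean_diploid_copies = mean(cc$genome),
                   trap_per_haploid = mean(cc$trap) / 2,
                   reference_per_haploid = mean(cc$reference) / 2,
                   genome_per_haploid = mean(cc$genome) / 2)
    }))
}
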