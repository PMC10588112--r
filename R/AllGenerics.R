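# Generics and accessors. Slots are never touched directly by user code.

#' @rdname GenomeArchitecture-class
#' @param x a \code{GenomeArchitecture}.
#' @export
setGeneric("trapIntervals", function(x) standardGeneric("trapIntervals"))

#' @rdname GenomeArchitecture-class
#' @export
setGeneric("referenceIntervals", function(x) standardGeneric("referenceIntervals"))

#' @rdname GenomeArchitecture-class
#' @export
setGeneric("recombRate", function(x) standardGeneric("recombRate"))

#' @rdname GenomeArchitecture-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname ReplicateSummary-class
#' @param x a \code{ReplicateSummary} or \code{InvasionEnsemble}.
#' @export
setGeneric("phase", function(x) standardGeneric("phase"))

#' @rdname ReplicateSummary-class
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' @rdname ReplicateSummary-class
#' @export
setGeneric("individualCounts", function(x) standardGeneric("individualCounts"))

#' @rdname InvasionEnsemble-class
#' @export
setGeneric("replicates", function(x) standardGeneric("replicates"))

#' Kendall correlation between a region's TE abundance and the rest of the genome
#'
#' For an [InvasionEnsemble-class], correlates per-replicate mean haploid
#' insertion counts in the chosen region with the mean haploid count in the
#' rest of the genome (one point per replicate, i.e. per TE family). For an
#' empirical family count table (see [familyCopyTable()]), correlates
#' per-family cluster counts with non-cluster counts.
#'
#' Under the trap model no positive correlation is expected for transposon
#' traps, while reference regions correlate positively with the rest of the
#' genome.
#'
#' @param x an \code{InvasionEnsemble} or a family count table (data.frame).
#' @param region \code{"trap"} or \code{"reference"} (ensemble input only).
#' @param ... passed to methods.
#' @return a list with elements \code{tau}, \code{p}, \code{n},
#'   \code{region}, \code{undefined} (see [kendallTau()]).
#' @export
setGeneric("correlationReport", function(x, ...) standardGeneric("correlationReport"))

setMethod("trapIntervals", "GenomeArchitecture", function(x) x@trapIntervals)
setMethod("referenceIntervals", "GenomeArchitecture", function(x) x@referenceIntervals)
setMethod("recombRate", "GenomeArchitecture", function(x) x@recombRate)
setMethod("chromLengths", "GenomeArchitecture", function(x)
    setNames(rep(x@chromLength, x@nChromosomes),
             paste0("chr", seq_len(x@nChromosomes))))

setMethod("phase", "ReplicateSummary", function(x) x@phase)
setMethod("trajectory", "ReplicateSummary", function(x) x@trajectory)
setMethod("individualCounts", "ReplicateSummary", function(x) x@counts)
setMethod("phase", "InvasionEnsemble",
    function(x) vapply(x@replicates, phase, character(1)))
setMethod("replicates", "InvasionEnsemble", function(x) x@replicates)

#' @export
#' @rdname InvasionEnsemble-class
#' @param x an \code{InvasionEnsemble}.
setMethod("length", "InvasionEnsemble", function(x) length(x@replicates))

#' @export
#' @rdname InvasionEnsemble-class
#' @param i replicate index.
setMethod("[[", "InvasionEnsemble", function(x, i) x@replicates[[i]])

setMethod("show", "GenomeArchitecture", function(object) {
    cat("GenomeArchitecture:", object@nChromosomes, "chromosome(s) of",
        object@chromLength, "bp,", object@recombRate, "cM/Mb\n")
    cat("  traps:    ", length(object@trapIntervals), "interval(s),",
        sprintf("%.2f%%", 100 * object@trapFraction), "of the genome\n")
    cat("  reference:", length(object@referenceIntervals), "interval(s),",
        sprintf("%.2f%%", 100 * object@referenceFraction), "of the genome\n")
})

setMethod("show", "SelectionModel", function(object) {
    cat("SelectionModel (traps",
        if (object@trapsNeutral) "neutral" else "selected", ")\n")
    print(data.frame(class = names(object@classEffects),
                     x = unname(object@classEffects),
                     fraction = unname(object@classFractions)))
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig: N =", object@N,
        "| u =", paste(object@u, collapse = "-"),
        "| seeds =", object@nSeedInsertions,
        "| sample at", paste(object@sampleGeneration, collapse = "-"), "\n")
    show(object@architecture)
})

setMethod("show", "Population", function(object) {
    n <- sum(vapply(object@individuals,
                    function(i) length(i$h1$pos) + length(i$h2$pos), integer(1)))
    cat("Population of", length(object@individuals), "diploid individuals,",
        "generation", object@generation, ",", n, "insertions\n")
})

setMethod("show", "ReplicateSummary", function(object) {
    cat("ReplicateSummary", object@replicateId, "| phase:", object@phase,
        "| sampled at generation", object@sampleGeneration,
        "| u =", signif(object@u, 3), "\n")
    cat("  mean diploid counts: trap", round(mean(object@counts$trap), 2),
        "| reference", round(mean(object@counts$reference), 2),
        "| genome", round(mean(object@counts$genome), 2), "\n")
})

setMethod("show", "InvasionEnsemble", function(object) {
    cat("InvasionEnsemble of", length(object@replicates), "replicate(s)\n")
    print(table(phase(object)))
})
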