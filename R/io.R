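# Readers and writers for the plain-text formats the empirical operators
# consume: BED intervals, RepeatMasker-shaped TE annotation tables,
# insertion-frequency tables, small-RNA read tables (TSV or SAM/BAM), and a
# YAML scenario configuration for the simulator. The package's own TSV
# dialects use 0-based half-open coordinates on disk (like BED) and are
# converted to 1-based GRanges on ingest.

#' Read cluster (or any) intervals from a BED file
#'
#' @param path BED file path.
#' @return a \code{GRanges} (rtracklayer converts BED's 0-based half-open
#'   coordinates to 1-based closed).
#' @export
readClusterBED <- function(path) {
    rtracklayer::import(path, format = "BED")
}

#' @rdname readClusterBED
#' @param intervals a \code{GRanges} to write.
#' @export
writeClusterBED <- function(intervals, path) {
    rtracklayer::export(intervals, path, format = "BED")
}

#' Read a TE annotation table
#'
#' Tab-separated with header columns \code{chrom}, \code{start},
#' \code{end} (0-based half-open), \code{strand}, \code{family},
#' \code{divergence} (percent), \code{consensus_length} (bp).
#'
#' @param path file path.
#' @return an annotated \code{GRanges}.
#' @export
readTETable <- function(path) {
    d <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "strand", "family", "divergence",
              "consensus_length")
    if (!all(need %in% names(d)))
        stop("TE table must have columns: ", paste(need, collapse = ", "))
    GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end),
                           strand = d$strand, family = d$family,
                           divergence = d$divergence,
                           consensus_length = d$consensus_length)
}

#' @rdname readTETable
#' @param tes annotated \code{GRanges} to write.
#' @export
writeTETable <- function(tes, path) {
    d <- data.frame(chrom = as.character(GenomicRanges::seqnames(tes)),
                    start = GenomicRanges::start(tes) - 1L,
                    end = GenomicRanges::end(tes),
                    strand = as.character(GenomicRanges::strand(tes)),
                    family = S4Vectors::mcols(tes)$family,
                    divergence = S4Vectors::mcols(tes)$divergence,
                    consensus_length = S4Vectors::mcols(tes)$consensus_length)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an insertion-frequency table
#'
#' Tab-separated with header columns \code{family}, \code{chrom},
#' \code{pos} (0-based), \code{frequency}.
#'
#' @param path file path.
#' @return data.frame with \code{pos} converted to 1-based.
#' @export
readFrequencyTable <- function(path) {
    d <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("family", "chrom", "pos", "frequency")
    if (!all(need %in% names(d)))
        stop("frequency table must have columns: ",
             paste(need, collapse = ", "))
    d$pos <- d$pos + 1L
    d
}

#' Read small-RNA alignment records
#'
#' Either a tab-separated read table with header columns \code{chrom},
#' \code{start}, \code{end} (0-based half-open), \code{strand},
#' \code{mapq}, \code{ncRNA} (logical), or a SAM/BAM file (mapped reads
#' only; the \code{ncRNA} flag is set to \code{FALSE} — structural-RNA
#' matching happens upstream).
#'
#' @param path file path.
#' @param format \code{"tsv"}, \code{"sam"} or \code{"bam"} (guessed from
#'   the extension by default).
#' @return a \code{GRanges} with \code{mapq} and \code{ncRNA} metadata
#'   columns.
#' @export
readSmallRNAReads <- function(path, format = c("auto", "tsv", "sam", "bam")) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- if (ext %in% c("sam", "bam")) ext else "tsv"
    }
    if (format == "tsv") {
        d <- read.delim(path, stringsAsFactors = FALSE)
        need <- c("chrom", "start", "end", "strand", "mapq", "ncRNA")
        if (!all(need %in% names(d)))
            stop("read table must have columns: ",
                 paste(need, collapse = ", "))
        return(GenomicRanges::GRanges(
            d$chrom, IRanges::IRanges(d$start + 1L, d$end),
            strand = d$strand, mapq = d$mapq, ncRNA = as.logical(d$ncRNA)))
    }
    if (format == "sam") {
        bam <- Rsamtools::asBam(path,
                                destination = tempfile(fileext = ""),
                                overwrite = TRUE, indexDestination = FALSE)
        on.exit(unlink(bam))
        path <- bam
    }
    p <- Rsamtools::ScanBamParam(
        what = c("rname", "pos", "strand", "mapq", "qwidth"),
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    GenomicRanges::GRanges(as.character(b$rname),
                           IRanges::IRanges(b$pos, b$pos + b$qwidth - 1L),
                           strand = b$strand, mapq = b$mapq, ncRNA = FALSE)
}

#' @rdname readSmallRNAReads
#' @param reads \code{GRanges} of reads to write as the TSV dialect.
#' @export
writeSmallRNAReads <- function(reads, path) {
    d <- data.frame(chrom = as.character(GenomicRanges::seqnames(reads)),
                    start = GenomicRanges::start(reads) - 1L,
                    end = GenomicRanges::end(reads),
                    strand = as.character(GenomicRanges::strand(reads)),
                    length = GenomicRanges::width(reads),
                    mapq = S4Vectors::mcols(reads)$mapq,
                    ncRNA = S4Vectors::mcols(reads)$ncRNA)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write analysis tables
#'
#' Thin tab-separated writers for the family count table, DSL call table,
#' ensemble summary and abundance histograms (optionally truncating the
#' exported bins for display, which does not touch the underlying masses).
#'
#' @param x the object to write.
#' @param path output file path.
#' @export
writeFamilyCountTable <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeFamilyCountTable
#' @export
writeDSLCalls <- function(x, path) {
    x$start <- x$start - 1L  # back to 0-based half-open on disk
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeFamilyCountTable
#' @param ensemble an [InvasionEnsemble-class].
#' @export
writeEnsembleSummary <- function(ensemble, path) {
    write.table(ensembleSummary(ensemble), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
}

#' @rdname writeFamilyCountTable
#' @param truncateAt drop exported bins above this value (display only).
#' @export
writeHistogram <- function(x, path, truncateAt = NULL) {
    if (!is.null(truncateAt)) x <- x[x$bin <= truncateAt, ]
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a simulation scenario from a YAML file
#'
#' Keys mirror [simulationConfig()] and [buildArchitecture()]:
#' \code{n_chromosomes}, \code{chrom_length}, \code{trap_fraction},
#' \code{reference_fraction}, \code{recomb_rate}, \code{population_size},
#' \code{u} (scalar or \code{[min, max]}), \code{n_seed_insertions},
#' \code{max_generations}, \code{sample_generation} (scalar or range),
#' \code{extinction_fitness}, and optionally \code{selection} with
#' \code{effects}, \code{fractions} (named maps) and \code{traps_neutral}.
#' Missing keys fall back to the defaults.
#'
#' @param path YAML file path.
#' @return a [SimulationConfig-class].
#' @export
readScenarioConfig <- function(path) {
    y <- yaml::read_yaml(path)
    g <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
    arch <- buildArchitecture(
        nChromosomes = g("n_chromosomes", 5L),
        chromLength = g("chrom_length", 1e7),
        trapFraction = g("trap_fraction", 0.035),
        referenceFraction = g("reference_fraction", 0.035),
        recombRate = g("recomb_rate", 4))
    sel <- if (is.null(y$selection)) {
        neutralSelection()
    } else {
        selectionModel(
            classEffects = unlist(y$selection$effects),
            classFractions = unlist(y$selection$fractions),
            trapsNeutral = isTRUE(y$selection$traps_neutral) ||
                is.null(y$selection$traps_neutral))
    }
    simulationConfig(
        architecture = arch, N = g("population_size", 1000),
        u = unlist(g("u", 0.1)), selection = sel,
        nSeedInsertions = g("n_seed_insertions", 1000),
        maxGenerations = g("max_generations", 10000),
        sampleGeneration = unlist(g("sample_generation", 2000)),
        extinctionFitness = g("extinction_fitness", 0.1),
        transpositionConditioning = g("transposition_conditioning", "parent"))
}
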