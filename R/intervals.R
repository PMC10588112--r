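# Empirical-side interval operators: piRNA-cluster construction rules, TE
# annotation filters, and copy-number tabulation inside vs outside clusters.
# All intervals are GRanges (1-based closed); BED files are converted on
# import by rtracklayer.

#' Merge overlapping intervals
#'
#' Returns the minimal sorted set of disjoint intervals covering the same
#' base pairs (adjacent book-ended intervals are also joined, as bedtools
#' merge does).
#'
#' @param intervals a \code{GRanges}.
#' @return a sorted, disjoint \code{GRanges}.
#' @export
mergeOverlapping <- function(intervals) {
    GenomicRanges::reduce(GenomicRanges::sort(intervals))
}

#' Join neighbouring piRNA clusters
#'
#' Iteratively joins adjacent clusters on the same chromosome whenever the
#' gap between them is smaller than their combined lengths, replacing the
#' pair with its span, until a fixed point is reached. This is the
#' neighbour-joining rule applied to de novo cluster annotations.
#'
#' @param clusters a \code{GRanges} of cluster intervals.
#' @return a \code{GRanges} of joined clusters, sorted.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(1, 1501), c(1000, 2500)))
#' joinProtracNeighbors(gr)  # gap 500 < 1000 + 1000 -> one span
#' @export
joinProtracNeighbors <- function(clusters) {
    clusters <- GenomicRanges::sort(clusters)
    if (length(clusters) < 2L) return(clusters)
    chrOut <- character(0)
    sOut <- eOut <- integer(0)
    for (chr in unique(as.character(GenomicRanges::seqnames(clusters)))) {
        g <- clusters[as.character(GenomicRanges::seqnames(clusters)) == chr]
        s <- GenomicRanges::start(g)
        e <- GenomicRanges::end(g)
        repeat {
            joined <- FALSE
            i <- 1L
            while (i < length(s)) {
                gap <- s[i + 1L] - e[i] - 1L
                if (gap < (e[i] - s[i] + 1L) + (e[i + 1L] - s[i + 1L] + 1L)) {
                    e[i] <- max(e[i], e[i + 1L])
                    s <- s[-(i + 1L)]
                    e <- e[-(i + 1L)]
                    joined <- TRUE
                } else {
                    i <- i + 1L
                }
            }
            if (!joined) break
        }
        chrOut <- c(chrOut, rep(chr, length(s)))
        sOut <- c(sOut, s)
        eOut <- c(eOut, e)
    }
    res <- GenomicRanges::GRanges(chrOut, IRanges::IRanges(sOut, eOut),
                                  seqinfo = GenomeInfoDb::seqinfo(clusters))
    GenomicRanges::sort(res)
}

#' Annotate the regions between aligned cluster flanks
#'
#' Given the alignment coordinates of the unique sequences flanking each
#' reference piRNA cluster, the region between the end of the left flank and
#' the start of the right flank is annotated as the lifted-over cluster.
#' Pairs whose flanks map to different chromosomes or in inverted
#' orientation (right flank not strictly after the left flank) are flagged
#' as unresolvable and returned separately.
#'
#' @param leftFlanks,rightFlanks parallel \code{GRanges} of aligned flank
#'   coordinates.
#' @return list with \code{clusters} (a \code{GRanges}) and
#'   \code{unresolved} (integer indices of pairs that could not be lifted).
#' @export
regionBetweenFlanks <- function(leftFlanks, rightFlanks) {
    stopifnot(length(leftFlanks) == length(rightFlanks))
    sameChr <- as.character(GenomicRanges::seqnames(leftFlanks)) ==
        as.character(GenomicRanges::seqnames(rightFlanks))
    cs <- GenomicRanges::end(leftFlanks) + 1L
    ce <- GenomicRanges::start(rightFlanks) - 1L
    ok <- sameChr & (ce >= cs)
    clusters <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(leftFlanks)[ok],
        IRanges::IRanges(cs[ok], ce[ok]))
    list(clusters = clusters, unresolved = which(!ok))
}

#' Annotate telomeric (TAS) clusters
#'
#' Telomere-associated piRNA clusters are not flanked by a unique pair of
#' sequences; instead, the region between the most distal gene of a
#' chromosome arm and the end of the contig is annotated as the TAS cluster.
#'
#' @param genes \code{GRanges} of the most distal gene per contig.
#' @param contigLengths named integer vector of contig lengths (taken from
#'   \code{seqlengths(genes)} when missing).
#' @return a \code{GRanges} of TAS clusters.
#' @export
tasClusters <- function(genes, contigLengths = NULL) {
    if (is.null(contigLengths))
        contigLengths <- GenomeInfoDb::seqlengths(genes)
    len <- contigLengths[as.character(GenomicRanges::seqnames(genes))]
    if (anyNA(len)) stop("missing contig length for some genes")
    s <- GenomicRanges::end(genes) + 1L
    keep <- s <= len
    GenomicRanges::GRanges(GenomicRanges::seqnames(genes)[keep],
                           IRanges::IRanges(s[keep], as.integer(len[keep])))
}

#' Filter TE annotations
#'
#' Keeps annotations with a minimum length of 100 bp and a maximum
#' divergence of 10\% from the family consensus (both bounds inclusive),
#' optionally restricted to a whitelist of germline-active families and/or
#' to (near) full-length insertions, defined as
#' \code{length >= fullLengthFraction * consensus_length}.
#'
#' @param tes \code{GRanges} with metadata columns \code{family},
#'   \code{divergence} (percent) and, for the full-length filter,
#'   \code{consensus_length} (bp).
#' @param minLength minimum annotation length in bp (inclusive).
#' @param maxDivergence maximum percent divergence (inclusive).
#' @param familyWhitelist optional character vector of families to keep.
#' @param fullLengthOnly keep only near full-length insertions.
#' @param fullLengthFraction fraction of the consensus length an insertion
#'   must reach to count as full length.
#' @return the filtered \code{GRanges}.
#' @export
filterTEAnnotations <- function(tes, minLength = 100, maxDivergence = 10,
                                familyWhitelist = NULL,
                                fullLengthOnly = FALSE,
                                fullLengthFraction = 0.95) {
    keep <- GenomicRanges::width(tes) >= minLength &
        S4Vectors::mcols(tes)$divergence <= maxDivergence
    if (!is.null(familyWhitelist))
        keep <- keep & S4Vectors::mcols(tes)$family %in% familyWhitelist
    if (fullLengthOnly)
        keep <- keep & GenomicRanges::width(tes) >=
            fullLengthFraction * S4Vectors::mcols(tes)$consensus_length
    tes[keep]
}

# Midpoint of an annotation as a width-1 GRanges; membership of a TE in a
# cluster is decided by its midpoint (annotations may straddle cluster
# edges).
.midpoints <- function(gr) {
    mid <- GenomicRanges::start(gr) + (GenomicRanges::width(gr) - 1L) %/% 2L
    GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                           IRanges::IRanges(mid, mid))
}

#' Per-family haploid copy numbers inside and outside piRNA clusters
#'
#' Counts, for each TE family, annotations whose midpoint falls inside any
#' cluster interval versus outside. Assembly-derived annotations are already
#' per haploid genome. Families with zero cluster copies are retained.
#'
#' @param tes filtered TE annotations (\code{GRanges} with a \code{family}
#'   column).
#' @param clusters cluster intervals (\code{GRanges}).
#' @param strain optional strain label stored in the table.
#' @return data.frame with columns \code{family}, \code{cluster_count},
#'   \code{noncluster_count}, \code{strain}.
#' @export
familyCopyTable <- function(tes, clusters, strain = NA_character_) {
    fam <- as.character(S4Vectors::mcols(tes)$family)
    inCluster <- IRanges::overlapsAny(.midpoints(tes), clusters,
                                      ignore.strand = TRUE)
    families <- sort(unique(fam))
    data.frame(
        family = families,
        cluster_count = vapply(families,
            function(f) sum(inCluster[fam == f]), numeric(1)),
        noncluster_count = vapply(families,
            function(f) sum(!inCluster[fam == f]), numeric(1)),
        strain = strain, row.names = NULL)
}

#' Haploid copy numbers from an insertion-frequency table
#'
#' Converts population-frequency estimates of TE insertions (as produced by
#' paired-end-read TE callers) into per-family haploid copy numbers:
#' records below the minimum frequency are discarded as unreliable or
#' somatic; records with \code{minFrequency <= f < hetCutoff} are assumed
#' heterozygous and contribute 0.5 haploid copies; records with
#' \code{f >= hetCutoff} contribute 1.0.
#'
#' @param records data.frame with columns \code{family}, \code{chrom},
#'   \code{pos} (1-based), \code{frequency} in \eqn{[0, 1]}.
#' @param clusters cluster intervals (\code{GRanges}).
#' @param minFrequency minimum population frequency (default 0.3).
#' @param hetCutoff frequency below which insertions count as heterozygous
#'   (default 0.6).
#' @param strain optional strain label.
#' @return data.frame as in [familyCopyTable()] (counts may be
#'   half-integers).
#' @examples
#' recs <- data.frame(family = "A", chrom = "chr1",
#'                    pos = c(5e5, 6e5, 7e5), frequency = c(0.2, 0.4, 0.8))
#' cl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
#' freqToHaploidCounts(recs, cl)  # 0 + 0.5 + 1.0 = 1.5 outside clusters
#' @export
freqToHaploidCounts <- function(records, clusters, minFrequency = 0.3,
                                hetCutoff = 0.6, strain = NA_character_) {
    f <- records$frequency
    if (any(f < 0 | f > 1)) stop("frequencies must lie in [0, 1]")
    w <- ifelse(f < minFrequency, 0, ifelse(f < hetCutoff, 0.5, 1))
    posGR <- GenomicRanges::GRanges(records$chrom,
                                    IRanges::IRanges(records$pos, records$pos))
    inCluster <- IRanges::overlapsAny(posGR, clusters, ignore.strand = TRUE)
    fam <- as.character(records$family)
    families <- sort(unique(fam))
    data.frame(
        family = families,
        cluster_count = vapply(families,
            function(x) sum(w[fam == x & inCluster]), numeric(1)),
        noncluster_count = vapply(families,
            function(x) sum(w[fam == x & !inCluster]), numeric(1)),
        strain = strain, row.names = NULL)
}

#' Average family count tables across strains
#'
#' Per family, the arithmetic mean of cluster and non-cluster counts over
#' the strains in which the family is present. Families absent from a
#' strain are treated as missing in that strain (excluded from the mean),
#' not as zero — only families actually present in a strain are considered
#' for it; set \code{absentAsZero = TRUE} for the alternative convention.
#'
#' @param tables list of per-strain family count tables
#'   (see [familyCopyTable()]).
#' @param absentAsZero treat absence as a zero count instead of missing.
#' @return an averaged family count table with \code{strain = "mean"}.
#' @export
averageTables <- function(tables, absentAsZero = FALSE) {
    stopifnot(length(tables) >= 1L)
    all <- do.call(rbind, tables)
    families <- sort(unique(all$family))
    nStrains <- length(tables)
    avg <- function(f, col) {
        v <- all[[col]][all$family == f]
        if (absentAsZero) sum(v) / nStrains else mean(v)
    }
    data.frame(
        family = families,
        cluster_count = vapply(families, avg, numeric(1),
                               col = "cluster_count"),
        noncluster_count = vapply(families, avg, numeric(1),
                                  col = "noncluster_count"),
        strain = "mean", row.names = NULL)
}
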