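# Small-RNA operators: piRNA-sized read filtering, flank signatures around
# TE insertions, dispersed piRNA source locus (DSL) detection with the
# conserved-gene negative control, and ping-pong signature Z-scores.
#
# Reads are GRanges (1-based closed) with metadata columns `mapq` and
# `ncRNA` (TRUE when the read matched a miRNA/rRNA/snRNA/snoRNA/tRNA/mRNA
# reference upstream). The 5' end of a read is its start on the + strand
# and its end on the - strand.

#' Filter reads down to putative piRNAs
#'
#' Keeps reads with a length between 23 and 29 nt (inclusive), a minimum
#' mapping quality of 5 (uniquely mapping), and no match to structural
#' ncRNA references.
#'
#' @param reads \code{GRanges} with \code{mapq} and \code{ncRNA} metadata
#'   columns.
#' @param minLen,maxLen inclusive read-length bounds in nt.
#' @param minMapq minimum mapping quality.
#' @return the filtered \code{GRanges}.
#' @export
filterPiRNAReads <- function(reads, minLen = 23, maxLen = 29, minMapq = 5) {
    w <- GenomicRanges::width(reads)
    keep <- w >= minLen & w <= maxLen &
        S4Vectors::mcols(reads)$mapq >= minMapq &
        !S4Vectors::mcols(reads)$ncRNA
    reads[keep]
}

#' 5' ends of reads as width-1 stranded ranges
#' @param reads a \code{GRanges} of reads.
#' @return a width-1 \code{GRanges} keeping the read strands.
#' @export
fivePrimeEnds <- function(reads) {
    p <- ifelse(as.character(GenomicRanges::strand(reads)) == "-",
                GenomicRanges::end(reads), GenomicRanges::start(reads))
    GenomicRanges::GRanges(GenomicRanges::seqnames(reads),
                           IRanges::IRanges(p, p),
                           strand = GenomicRanges::strand(reads))
}

# Count reads whose 5' end lies in [ws, we] on the required strand,
# vectorized over windows. Windows are truncated at contig edges; invalid
# (fully off-contig) windows count 0.
.count5prime <- function(chrom, ws, we, wstrand, p5, seqlen) {
    ws2 <- pmax(ws, 1L)
    sl <- seqlen[as.character(chrom)]
    we2 <- ifelse(!is.na(sl), pmin(we, sl), we)
    we2 <- pmax(we2, ws2 - 1L)  # zero-width when the window is empty
    win <- GenomicRanges::GRanges(chrom, IRanges::IRanges(ws2, we2),
                                  strand = wstrand)
    GenomeInfoDb::seqlevels(win) <-
        union(GenomeInfoDb::seqlevels(win), GenomeInfoDb::seqlevels(p5))
    GenomeInfoDb::seqlevels(p5) <- GenomeInfoDb::seqlevels(win)
    GenomicRanges::countOverlaps(win, p5, ignore.strand = FALSE)
}

#' Flanking piRNA signature of oriented features
#'
#' For each stranded feature (a TE insertion or a control gene), counts
#' piRNA-sized reads whose 5' end falls in the 500 bp window upstream of
#' the feature on the antisense strand, and in the 500 bp window downstream
#' on the sense strand — the asymmetric signature of a dispersed piRNA
#' source locus, where piRNA production extends from the TE into its
#' genomic flanks. Upstream/downstream and sense/antisense are defined in
#' the feature's orientation: for a \code{-} strand feature both the
#' genomic windows and the strand comparisons flip. Windows abut the
#' feature and are truncated at contig edges; counts are normalized to
#' reads per million (rpm).
#'
#' @param features stranded \code{GRanges}.
#' @param reads filtered reads (see [filterPiRNAReads()]).
#' @param flank flank width in bp (default 500).
#' @param librarySize normalization denominator in reads; defaults to
#'   \code{length(reads)}, i.e. all filtered piRNA-sized reads.
#' @return data.frame with columns \code{upstream_antisense_rpm} and
#'   \code{downstream_sense_rpm}, one row per feature.
#' @export
flankSignature <- function(features, reads, flank = 500,
                           librarySize = length(reads)) {
    if (flank <= 0) stop("flank must be > 0")
    stopifnot(librarySize > 0)
    fstr <- as.character(GenomicRanges::strand(features))
    if (any(fstr == "*")) stop("features must be stranded")
    p5 <- fivePrimeEnds(reads)
    s <- GenomicRanges::start(features)
    e <- GenomicRanges::end(features)
    plus <- fstr == "+"
    chrom <- GenomicRanges::seqnames(features)
    seqlen <- GenomeInfoDb::seqlengths(features)

    upS <- ifelse(plus, s - flank, e + 1L)
    upE <- ifelse(plus, s - 1L, e + flank)
    dnS <- ifelse(plus, e + 1L, s - flank)
    dnE <- ifelse(plus, e + flank, s - 1L)
    antisense <- ifelse(plus, "-", "+")
    sense <- fstr

    up <- .count5prime(chrom, upS, upE, antisense, p5, seqlen)
    dn <- .count5prime(chrom, dnS, dnE, sense, p5, seqlen)
    data.frame(upstream_antisense_rpm = up * 1e6 / librarySize,
               downstream_sense_rpm = dn * 1e6 / librarySize)
}

#' Detect dispersed piRNA source loci (DSL)
#'
#' A TE insertion is called a DSL when its upstream-antisense and
#' downstream-sense flank signals both reach the minimum of 5 reads per
#' million and the insertion lies outside all piRNA clusters (cluster
#' insertions are never counted as DSL; membership by insertion midpoint).
#'
#' @param tes stranded TE annotations (\code{GRanges}, \code{family}
#'   metadata column recommended).
#' @param clusters piRNA-cluster intervals (\code{GRanges}).
#' @param reads filtered reads (see [filterPiRNAReads()]).
#' @param flank flank width in bp.
#' @param minRpm rpm threshold applied to both windows.
#' @param librarySize normalization denominator.
#' @return data.frame with one row per TE: coordinates, family (when
#'   present), both rpm values, \code{in_cluster} and \code{is_dsl}.
#' @export
detectDSL <- function(tes, clusters, reads, flank = 500, minRpm = 5,
                      librarySize = length(reads)) {
    sig <- flankSignature(tes, reads, flank = flank,
                          librarySize = librarySize)
    inCluster <- IRanges::overlapsAny(.midpoints(tes), clusters,
                                      ignore.strand = TRUE)
    out <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(tes)),
        start = GenomicRanges::start(tes),
        end = GenomicRanges::end(tes),
        strand = as.character(GenomicRanges::strand(tes)))
    if (!is.null(S4Vectors::mcols(tes)$family))
        out$family <- as.character(S4Vectors::mcols(tes)$family)
    out$upstream_antisense_rpm <- sig$upstream_antisense_rpm
    out$downstream_sense_rpm <- sig$downstream_sense_rpm
    out$in_cluster <- inCluster
    out$is_dsl <- sig$upstream_antisense_rpm >= minRpm &
        sig$downstream_sense_rpm >= minRpm & !inCluster
    out
}

#' False-positive DSL rate on conserved genes
#'
#' Conserved single-copy (BUSCO-like) genes are not expected to act as
#' piRNA source loci; the fraction of genes whose flanks nevertheless meet
#' the DSL criteria estimates the method's false-positive rate. Genes
#' shorter than \code{minGeneLength} are excluded from the denominator.
#'
#' @param genes stranded gene intervals (\code{GRanges}).
#' @param reads filtered reads.
#' @param flank,minRpm,librarySize as in [detectDSL()].
#' @param minGeneLength minimum gene length in bp (default 100).
#' @return fraction of genes with a DSL-like signature.
#' @export
controlDSLRate <- function(genes, reads, flank = 500, minRpm = 5,
                           librarySize = length(reads),
                           minGeneLength = 100) {
    genes <- genes[GenomicRanges::width(genes) >= minGeneLength]
    if (length(genes) == 0L) stop("no genes pass the length filter")
    sig <- flankSignature(genes, reads, flank = flank,
                          librarySize = librarySize)
    mean(sig$upstream_antisense_rpm >= minRpm &
         sig$downstream_sense_rpm >= minRpm)
}

#' Ping-pong 5'-5' overlap histogram
#'
#' For reads mapped to one TE consensus sequence, counts, for every offset
#' \eqn{o} in 1..\code{maxOffset}, the (sense, antisense) read pairs whose
#' 5' ends overlap by exactly \eqn{o} nt: the antisense 5' end sits at
#' sense 5' end \eqn{+ o - 1} on the opposite strand. Sense means the read
#' strand matches the consensus orientation (\code{+}). Secondary piRNA
#' amplification (the ping-pong cycle) enriches the 10-nt overlap.
#'
#' @param reads \code{GRanges} of consensus-mapped reads (strands
#'   \code{+}/\code{-}).
#' @param maxOffset largest overlap offset tabulated (default 20).
#' @return integer vector of pair counts, named by offset 1..maxOffset.
#' @examples
#' r <- GenomicRanges::GRanges("cons",
#'     IRanges::IRanges(c(100, 85), c(125, 109)), strand = c("+", "-"))
#' pingPongOverlapHistogram(r)  # one pair at offset 10
#' @export
pingPongOverlapHistogram <- function(reads, maxOffset = 20) {
    str <- as.character(GenomicRanges::strand(reads))
    s5 <- GenomicRanges::start(reads)[str == "+"]
    a5 <- GenomicRanges::end(reads)[str == "-"]
    counts <- setNames(integer(maxOffset), seq_len(maxOffset))
    if (length(s5) == 0L || length(a5) == 0L) return(counts)
    cs <- table(s5)
    ca <- table(a5)
    ps <- as.integer(names(cs))
    pa <- as.integer(names(ca))
    for (o in seq_len(maxOffset)) {
        m <- match(ps + o - 1L, pa)
        hit <- !is.na(m)
        counts[o] <- sum(as.integer(cs[hit]) * as.integer(ca[m[hit]]))
    }
    counts
}

#' Ping-pong Z-score of the 10-nt overlap
#'
#' \eqn{z_{10} = (c_{10} - \bar c_{bg}) / sd(c_{bg})} where the background
#' is all other offsets of the overlap histogram. A zero background
#' standard deviation leaves the score undefined (flagged, not an error).
#'
#' @param histogram overlap counts from [pingPongOverlapHistogram()].
#' @param signalOffset the signal offset (default 10).
#' @return list with \code{z10} and \code{undefined}.
#' @export
pingPongZ <- function(histogram, signalOffset = 10) {
    stopifnot(length(histogram) >= 2L, signalOffset <= length(histogram))
    bg <- histogram[-signalOffset]
    s <- sd(bg)
    if (s == 0) {
        # a perfectly flat histogram has no enrichment: 0/0 resolves to 0
        if (histogram[signalOffset] == mean(bg))
            return(list(z10 = 0, undefined = FALSE))
        return(list(z10 = NA_real_, undefined = TRUE))
    }
    list(z10 = unname((histogram[signalOffset] - mean(bg)) / s),
         undefined = FALSE)
}
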