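# Cluster-interval rules, TE annotation filters, copy-number tabulation and
# the frequency -> haploid conversion.

test_that("overlap merging is minimal, sorted, and matches a per-bp oracle", {
    gr <- GRanges("chr1", IRanges(c(1, 51), c(100, 150)))
    m <- mergeOverlapping(gr)
    expect_equal(start(m), 1)
    expect_equal(end(m), 150)
    disjoint <- GRanges("chr1", IRanges(c(1, 21), c(10, 30)))
    expect_equal(width(mergeOverlapping(disjoint)), c(10, 10))
    set.seed(91)
    s <- sample(900, 20)
    e <- pmin(s + sample(5:120, 20, TRUE), 1000)
    rand <- GRanges("chr1", IRanges(s, e))
    merged <- mergeOverlapping(rand)
    expect_equal(sum(width(merged)), coverageOracle(s, e, 1000))
    # idempotent, never increasing covered bp
    expect_identical(mergeOverlapping(merged), merged)
    expect_lte(sum(width(merged)), sum(width(rand)))
})

test_that("neighbouring clusters join when the gap is under their combined lengths", {
    # gap 500 < 1000 + 1000 -> joined
    close <- GRanges("chr1", IRanges(c(1, 1501), c(1000, 2500)))
    j <- joinProtracNeighbors(close)
    expect_equal(start(j), 1)
    expect_equal(end(j), 2500)
    # gap 4900 >= 100 + 100 -> untouched
    far <- GRanges("chr1", IRanges(c(1, 5001), c(100, 5100)))
    expect_equal(width(joinProtracNeighbors(far)), c(100, 100))
})

test_that("chains of close clusters collapse to one span at a fixed point", {
    chain <- GRanges("chr1", IRanges(c(1, 1501, 3001), c(1000, 2500, 4000)))
    j <- joinProtracNeighbors(chain)
    expect_length(j, 1)
    expect_equal(c(start(j), end(j)), c(1, 4000))
    # scan-order independence on this input: reversed input gives the same
    jr <- joinProtracNeighbors(rev(chain))
    expect_identical(j, jr)
    # fixed point: joining again changes nothing
    expect_identical(joinProtracNeighbors(j), j)
    # chromosomes never mix
    multi <- GRanges(c("chr1", "chr2"), IRanges(c(1, 200), c(100, 300)))
    expect_length(joinProtracNeighbors(multi), 2)
})

test_that("regions between aligned flanks become clusters; bad pairs are flagged", {
    left <- GRanges(c("chr1", "chr1", "chr2"),
                    IRanges(c(500, 7000, 100), c(1000, 8000, 200)))
    right <- GRanges(c("chr1", "chr1", "chr3"),
                     IRanges(c(5001, 6000, 5000), c(5600, 6500, 5100)))
    out <- regionBetweenFlanks(left, right)
    # pair 1 resolves to 0-based [1000, 5000) == 1-based [1001, 5000]
    expect_length(out$clusters, 1)
    expect_equal(start(out$clusters), 1001)
    expect_equal(end(out$clusters), 5000)
    # pair 2 inverted, pair 3 on different chromosomes
    expect_equal(out$unresolved, c(2L, 3L))
})

test_that("telomeric clusters span from the distal gene to the contig end", {
    genes <- GRanges("ctg1", IRanges(95001, 99000), strand = "+",
                     seqlengths = c(ctg1 = 100000L))
    tas <- tasClusters(genes)
    expect_equal(start(tas), 99001)
    expect_equal(end(tas), 100000)
    expect_equal(width(tas), 1000)
})

test_that("annotation filters apply inclusive length and divergence bounds", {
    tes <- GRanges("chr1", IRanges(c(1, 101, 201, 301, 401) * 1000,
                                   width = c(99, 100, 150, 150, 4900)),
                   strand = "+",
                   family = c("A", "A", "B", "B", "C"),
                   divergence = c(1, 1, 10.0, 10.1, 2),
                   consensus_length = 5000)
    f <- filterTEAnnotations(tes)
    # 99 bp dropped; 100 bp kept; 10.0% kept; 10.1% dropped
    expect_equal(width(f), c(100, 150, 4900))
    expect_equal(S4Vectors::mcols(f)$divergence, c(1, 10.0, 2))
    # whitelist
    fw <- filterTEAnnotations(tes, familyWhitelist = c("A"))
    expect_true(all(S4Vectors::mcols(fw)$family == "A"))
    # full length: 4900 / 5000 = 0.98 >= 0.95 retained, the rest dropped
    ff <- filterTEAnnotations(tes, fullLengthOnly = TRUE)
    expect_equal(width(ff), 4900)
})

test_that("family copy tables count midpoints in clusters and conserve totals", {
    clusters <- GRanges("chr1", IRanges(1, 10000))
    tes <- c(
        GRanges("chr1", IRanges(c(100, 2000, 9000), width = 500),
                strand = "+", family = "A", divergence = 1,
                consensus_length = 1000),
        GRanges("chr1", IRanges(seq(20000, 90000, by = 10000), width = 500),
                strand = "+", family = "A", divergence = 1,
                consensus_length = 1000),
        GRanges("chr1", IRanges(50000, width = 300), strand = "-",
                family = "B", divergence = 1, consensus_length = 1000))
    tab <- familyCopyTable(tes, clusters)
    expect_equal(tab$cluster_count[tab$family == "A"], 3)
    expect_equal(tab$noncluster_count[tab$family == "A"], 8)
    # zero-cluster families stay in the table
    expect_equal(tab$cluster_count[tab$family == "B"], 0)
    expect_equal(tab$noncluster_count[tab$family == "B"], 1)
    # conservation: cluster + non-cluster == total per family
    expect_equal(tab$cluster_count + tab$noncluster_count,
                 as.numeric(table(S4Vectors::mcols(tes)$family)[tab$family]))
})

test_that("midpoint membership equals a per-TE brute-force test", {
    set.seed(101)
    clusters <- GRanges("chr1", IRanges(c(1000, 50000), c(5000, 60000)))
    s <- sample(80000, 100)
    tes <- GRanges("chr1", IRanges(s, width = sample(100:900, 100, TRUE)),
                   strand = "+", family = "F", divergence = 0,
                   consensus_length = 1000)
    tab <- familyCopyTable(tes, clusters)
    mid <- start(tes) + (width(tes) - 1) %/% 2
    manual <- vapply(mid, function(m)
        any(m >= start(clusters) & m <= end(clusters)), logical(1))
    expect_equal(tab$cluster_count, sum(manual))
    expect_equal(tab$noncluster_count, sum(!manual))
})

test_that("frequency records convert to haploid counts by the 0.3/0.6 rules", {
    clusters <- GRanges("chr1", IRanges(1, 1000))
    recs <- data.frame(family = "A", chrom = "chr1",
                       pos = c(5000, 6000, 7000, 8000),
                       frequency = c(0.29, 0.3, 0.5, 0.6))
    tab <- freqToHaploidCounts(recs, clusters)
    # 0 + 0.5 + 0.5 + 1.0
    expect_equal(tab$noncluster_count, 2.0)
    expect_equal(tab$cluster_count, 0)
    # in-cluster records land in the cluster column
    recs2 <- data.frame(family = "A", chrom = "chr1", pos = c(10, 5000),
                        frequency = c(0.9, 0.9))
    tab2 <- freqToHaploidCounts(recs2, clusters)
    expect_equal(tab2$cluster_count, 1.0)
    expect_equal(tab2$noncluster_count, 1.0)
    # invalid frequencies are rejected
    bad <- data.frame(family = "A", chrom = "chr1", pos = 1,
                      frequency = 1.2)
    expect_error(freqToHaploidCounts(bad, clusters), "frequencies")
})

test_that("raising a frequency never lowers a family's haploid count", {
    clusters <- GRanges("chr1", IRanges(1, 1000))
    set.seed(111)
    f <- runif(30)
    recs <- data.frame(family = "A", chrom = "chr1",
                       pos = sample(2000:90000, 30), frequency = f)
    base <- freqToHaploidCounts(recs, clusters)$noncluster_count
    for (i in c(1, 7, 19)) {
        up <- recs
        up$frequency[i] <- min(1, up$frequency[i] + 0.35)
        expect_gte(freqToHaploidCounts(up, clusters)$noncluster_count, base)
    }
})

test_that("averaging tables respects per-family strain presence", {
    t1 <- data.frame(family = c("A", "B"), cluster_count = c(2, 1),
                     noncluster_count = c(10, 4), strain = "s1")
    t2 <- data.frame(family = "A", cluster_count = 4,
                     noncluster_count = 20, strain = "s2")
    avg <- averageTables(list(t1, t2))
    expect_equal(avg$cluster_count[avg$family == "A"], 3)
    expect_equal(avg$noncluster_count[avg$family == "A"], 15)
    # family B present only in strain 1: averaged over strains where present
    expect_equal(avg$cluster_count[avg$family == "B"], 1)
    # absent-as-zero alternative halves it
    avg0 <- averageTables(list(t1, t2), absentAsZero = TRUE)
    expect_equal(avg0$cluster_count[avg0$family == "B"], 0.5)
    # single table is the identity
    one <- averageTables(list(t1))
    expect_equal(one$cluster_count, t1$cluster_count)
})
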