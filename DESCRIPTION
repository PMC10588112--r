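Package: trapTE
Title: Transposon Trap Dynamics and the Composition of piRNA Clusters
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Forward-in-time Wright-Fisher simulation of transposable element
    (TE) invasions in diploid populations under the trap model, in which a
    single insertion into a piRNA-cluster-like "transposon trap" silences all
    copies of the TE in that individual, together with the composition
    statistics that discriminate transposon traps from neutral reference
    regions (abundance tail fractions and Kendall rank correlations between
    regional and genome-wide copy numbers). Also provides the empirical-side
    operators used to measure piRNA-cluster composition from annotation data:
    cluster-interval construction rules (overlap merging, neighbour joining,
    regions between aligned flanks), TE annotation filters, haploid
    copy-number conversion from insertion-frequency tables, detection of
    dispersed piRNA source loci (DSL) from strand-resolved small-RNA
    alignments, and ping-pong signature Z-scores. A synthetic-data module
    generates all empirical inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    Rsamtools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Genetics, PopulationGenetics, SmallRNA, Sequencing, Transposon
Config/testthat/edition: 3
RoxygenNote: 7.3.3
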