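# trapTE

Population-genetic tests of the **transposon trap model** of piRNA-cluster
function. Under the trap model, the invasion of a transposable element (TE)
family is stopped when one copy jumps into a piRNA cluster: the cluster
insertion converts the host defence against all copies of that TE in the
carrier. `trapTE` is for population geneticists and TE biologists who want
to (a) simulate TE invasions under this model and (b) ask whether observed
piRNA-cluster composition looks like the composition of a real transposon
trap.

## What the package computes

**Simulator.** A forward-in-time Wright–Fisher simulation of diploid
populations (C++ core): genomes of `n` chromosomes with a trap interval at
one end and a same-sized neutral *reference region* at the other, uniform
recombination, per-copy transposition at rate *u*, seed insertions at
frequency 1/(2N), optional site-class selection with fitness

> w = 1 − Σᵢ xᵢ   (clamped at 0),

and silencing of all copies in any individual that carries at least one
trap insertion. The baseline scenario (the defaults) is a fly-like genome:
5 × 10 Mb chromosomes, 4 cM/Mb, traps and reference regions each 3.5% of
the genome, N = 1000, u = 0.1, 1000 seed insertions, sampling at
generation 2000.

**Composition statistics.** The two signatures that separate traps from
reference regions across replicate invasions (= TE families):

* *tail fractions* — the share of individuals with fewer than `low` (1) or
  more than `high` (14) insertions in a region; narrow for traps, broad
  for reference regions;
* *Kendall rank correlation* (tau-b) between a region's per-family haploid
  copy number and the rest of the genome; positive for reference regions,
  absent (or negative under selection) for traps.

**Empirical operators.** Cluster-interval rules (overlap merging,
neighbour joining when the gap is smaller than the combined lengths,
regions between aligned flanking sequences, telomeric clusters), TE
annotation filters (length ≥ 100 bp, divergence ≤ 10%, family whitelist,
full-length), per-family copy tables inside/outside clusters,
frequency-to-haploid conversion (f < 0.3 dropped; 0.3 ≤ f < 0.6 counts
0.5; f ≥ 0.6 counts 1.0), detection of dispersed piRNA source loci (DSL:
≥ 5 rpm antisense piRNAs upstream *and* ≥ 5 rpm sense piRNAs downstream,
outside clusters) with a conserved-gene false-positive control, and
ping-pong 10-nt overlap Z-scores.

**Synthetic data.** Generators for every empirical input (annotations,
cluster intervals, frequency tables, strand-resolved small-RNA reads,
consensus-mapped ping-pong reads) with planted ground truth, so the whole
empirical side is testable without external data.

## Worked example

A scaled-down ensemble (2 × 1 Mb genome, N = 150, 25 replicate invasions)
shows the two key differences in about three seconds:

```r
library(trapTE)
cfg <- simulationConfig(
    architecture = buildArchitecture(2, 1e6, 0.035, 0.035, 4),
    N = 150, u = 0.1, nSeedInsertions = 150, sampleGeneration = 400)
ens <- runEnsemble(cfg, nReplicates = 25, baseSeed = 42)
head(ensembleSummary(ens)[c("replicate", "phase", "mean_diploid_copies",
                            "trap_per_haploid", "reference_per_haploid")], 4)
#>   replicate    phase mean_diploid_copies trap_per_haploid reference_per_haploid
#> 1         1 inactive            61.36667             1.00             1.4200000
#> 2         2  shotgun            72.65333             1.74             1.9466667
#> 3         3 inactive           114.60000             1.41             1.0066667
#> 4         4  shotgun            76.34000             1.23             0.8733333

cc <- regionCounts(ens)
tailFractions(cc, "trap")[c("frac_below", "frac_above")]
# trap tails: <1 0.32%, >14 0.00%  — narrow
tailFractions(cc, "reference")[c("frac_below", "frac_above")]
# reference tails: <1 3.95%, >14 1.63% — broad on both sides

correlationReport(ens, "reference")  # tau 0.48, p = 0.00077: positive
correlationReport(ens, "trap")       # tau 0.15, p = 0.28: not significant
```

Each replicate is one TE family: every family ends up with roughly 1–2
trap insertions per haploid genome regardless of how many copies it
accumulated genome-wide (replicate 1: 61 diploid copies, replicate 3:
115), which is why trap counts cannot correlate with the rest of the
genome while reference counts do.

On the empirical side:

```r
a <- synthAnnotations(nFamilies = 5, copiesInside = 3, copiesOutside = 7, seed = 1)
familyCopyTable(filterTEAnnotations(a$tes), a$clusters)
# per-family copies inside/outside clusters after the standard filters

r <- synthPingPongReads(nPairs = 500, signalFraction = 0.4, seed = 2)
pingPongZ(pingPongOverlapHistogram(r))$z10
# 22.6: a strong ping-pong signature
```

See `vignettes/trapTE-methods.Rmd` for the model, its assumptions, all
tunable parameters, and known limitations.

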