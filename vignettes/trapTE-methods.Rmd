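---
title: "Testing the transposon trap model: simulation, statistics, and empirical operators"
author: "trapTE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the transposon trap model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapTE)
set.seed(1)
```

# The scientific question

piRNA clusters are genomic regions that produce 23–29 nt small RNAs which
silence transposable elements (TEs). Under the *trap model*, a TE invasion
of a population is stopped when one copy of the TE jumps into such a
cluster: the insertion converts the host's defence against all copies of
that TE in the carrier individual. `trapTE` implements the population
genetics of this model: a forward-in-time Wright–Fisher simulator of TE
invasions with "transposon traps" (piRNA-cluster-like silencing regions)
and neutral "reference regions"; the composition statistics that
discriminate the two region types; and the empirical operators needed to
measure piRNA-cluster composition from annotation, frequency, and
small-RNA data — including the detection of dispersed piRNA source loci
(DSL) and ping-pong signatures.

The simulations yield two testable predictions about any region that acts
as a trap, as opposed to a same-sized region with no effect on TE
activity:

1. the distribution of TE insertion counts in traps is **narrow** (under
   the baseline scenario, very few individuals carry fewer than 1 or more
   than 14 trap insertions, while several percent fall outside this range
   for reference regions), and
2. TE abundance in traps is **not positively correlated** with abundance
   in the rest of the genome, whereas reference regions correlate
   strongly.

# The simulation model

A diploid Wright–Fisher population of constant size $N$ evolves in
non-overlapping generations. The genome is `nChromosomes` chromosomes of
equal length with a uniform recombination rate (cM/Mb). On each
chromosome a trap interval sits at the start and a reference interval at
the end, each covering a configurable fraction of the genome
(`buildArchitecture()`). The defaults are the baseline fly-like scenario:
5 chromosomes of 10 Mb, 4 cM/Mb, traps and reference regions each 3.5% of
the genome, $N = 1000$, transposition rate $u = 0.1$ per copy per
generation, 1000 seed insertions each starting at population frequency
$1/(2N)$, sampling at generation 2000, and extinction when mean fitness
drops below 0.1.

Each generation:

* **Fitness.** $w = 1 - \sum_i x_i$ over all insertions of an individual,
  clamped at 0, where $x_i$ is the selection coefficient of the
  insertion's effect class; insertions inside traps contribute nothing
  when `trapsNeutral` is set. The default model is fully neutral.
* **Mating.** Each of the $N$ offspring draws two parents independently
  with probability proportional to fitness (selfing allowed) — the
  simplest Wright–Fisher scheme consistent with non-overlapping
  generations.
* **Recombination.** One gamete per parent; per chromosome the crossover
  count is Poisson with mean `recombRate * length(Mb) / 100` Morgans,
  crossover positions are continuous-uniform floored to integer bp
  (a crossover at $p$ splits $[0,p)\,|\,[p,L)$), the starting haplotype is
  a fair coin, and chromosomes assort independently.
* **Transposition and silencing.** A single trap insertion silences all
  TE copies of its carrier. Each transmitted copy generates, with
  probability $u$, a new insertion at a uniformly random genome position
  on a random haplotype of the offspring — by default only for copies
  contributed by a non-silenced parent (see "Design choices" for the
  conditioning alternatives).

Insertion positions are discrete base pairs; a transposition landing on an
occupied position of the same haplotype is redrawn, which keeps haplotypes
duplicate-free (at 50 Mb the collision probability is negligible, so this
does not distort the placement distribution).

A replicate records, per generation, the mean diploid copy number, the
fraction of silenced individuals and the mean trap count, and — at the
sampling generation — the per-individual counts in traps, reference
regions and the whole genome, plus the invasion phase: `rapid` while any
individual is unsilenced, `shotgun` when all individuals are silenced by
segregating trap insertions, `inactive` once a trap insertion is fixed on
all $2N$ haplotypes. These phase labels operationalize published verbal
definitions; the exact thresholds of the original study chain are not
published, so the simplest literal reading is used.

Replicates of an ensemble (`runEnsemble()`) are interpreted as invasions
of *different TE families* in one population, which is what links the
simulations to the observed abundance of TE families in piRNA clusters.
Per-replicate samplers (when a range is configured) are uniform: $u$ on
$[u_{min}, u_{max}]$, the sampling generation integer-uniform on its
range. The sources describe these draws only as "random"; uniform is the
natural uninformative choice.

```{r quick-look}
arch <- buildArchitecture()
arch
sel <- selectionModel(c(neutral = 0, del = 0.1), c(neutral = 0.9, del = 0.1))
ind <- makeIndividual(makeHaplotype(arch, 1, c(5e6, 6e6), class = 2L))
individualFitness(ind, sel, arch)   # two x = 0.1 insertions: w = 0.8
```

A scaled-down invasion (a small population on a short genome) shows the
characteristic behaviour in a few seconds:

```{r small-invasion}
cfg <- simulationConfig(
    architecture = buildArchitecture(2, 1e6, 0.035, 0.035, 4),
    N = 150, u = 0.1, nSeedInsertions = 150, sampleGeneration = 400)
rep1 <- runReplicate(cfg, seed = 11)
rep1
tail(trajectory(rep1), 3)
```

# Design choices

**Who is conditioned on for transposition.** The trap model states that an
individual carrying a cluster insertion has transposition rate 0, and that
the TE stays active *in individuals without cluster insertions*. Two
implementations are consistent with a Wright–Fisher cycle: condition each
inherited copy on the silencing status of the contributing *parent*
(transposition in the parental germline), or condition all copies of the
newly formed individual on its *own* genotype (transposition in the
zygote's germline, visible in its offspring). The package implements both
(`transpositionConditioning` in `simulationConfig()`) and defaults to
parent conditioning — transposition as a germline event of the individual
producing the gametes, under which copies inherited from a silenced
parent can never transpose. An active trap-free individual still
amplifies its copies, just at its own reproduction rather than at its
birth, so "the TE is active in individuals without cluster insertions"
holds under both schemes, offset by one generation. In 60-replicate
baseline ensembles the two schemes give statistically indistinguishable
trap accumulation (about 3 insertions per haploid genome, silencing at
4.3–4.9 diploid trap insertions) and the same correlation structure; the
pooled tail fractions differ between seeds by more than between schemes.

**Fitness clamping.** The linear fitness function can go negative for
heavily loaded genomes; clamping at 0 preserves "sampling probability
proportional to fitness".

**Effect classes.** An insertion draws its selection class at insertion
time from the configured class fractions (equivalent to site-specific
classes under uniform insertion) and retains it through inheritance;
`trapsNeutral` overrides the class inside traps at fitness evaluation.

**Extinction** is evaluated before reproduction each generation; an
extinct replicate keeps its counts at the extinction generation and is
excluded from pooled statistics by default.

**Determinism.** Each replicate derives one RNG seed from
`(baseSeed, replicateIndex)`; all stochastic draws (including per-replicate
samplers) flow from R's RNG, so identical configuration and seed give
bitwise-identical output.

# Composition statistics

`regionCounts()` pools per-individual diploid counts across an ensemble;
`tailFractions()` computes the fractions below/above the count thresholds
(defaults 1 and 14, strict inequalities, on the diploid per-individual
scale of the histograms they summarize). `replicateMeans()` divides by 2.0
to obtain per-haploid estimates, one observation per replicate (family).
`correlationReport()` computes the tie-corrected Kendall $\tau_b$ (via
`stats::cor.test`; exact p-values for very small $n$, normal approximation
otherwise) between a region's per-replicate mean haploid count and the
rest of the genome, where "rest" is the genome count minus the focal
region's count. Averaging counts first and rank-correlating afterwards
mirrors how per-strain averages are analysed on the empirical side.
Constant inputs leave $\tau$ undefined and are flagged rather than raising
an error. `abundanceHistogram()` bins per-haploid counts with masses
summing to 1; axis truncation is a display concern applied only on export.

# Empirical operators

All intervals are `GRanges` in the Bioconductor 1-based closed convention;
BED input/output is 0-based half-open on disk and converted by
`rtracklayer`, as are the package's own TSV dialects.

* `mergeOverlapping()` — minimal disjoint union of cluster intervals.
* `joinProtracNeighbors()` — de novo clusters are joined iteratively when
  the gap between neighbours is smaller than their combined lengths, to a
  fixed point.
* `regionBetweenFlanks()` / `tasClusters()` — lift-over of reference
  cluster annotations: the region between the aligned unique flanking
  sequences becomes the cluster; telomere-associated clusters run from the
  most distal gene to the contig end. Pairs on different chromosomes or in
  inverted orientation are flagged unresolvable.
* `filterTEAnnotations()` — minimum length 100 bp and maximum divergence
  10% (both inclusive), an optional germline-active family whitelist
  (supplied as data, not recomputed), and an optional full-length filter.
  "Full length" is operationalized as length $\ge$ 0.95 $\times$ the
  consensus length (configurable; the sources say only "contiguous
  full-length insertions").
* `familyCopyTable()` — per-family copies inside/outside clusters;
  membership by the insertion *midpoint*, since annotations may straddle
  cluster edges and the sources do not specify a rule.
* `freqToHaploidCounts()` — population-frequency records below 0.3 are
  discarded (unreliable or somatic); $0.3 \le f < 0.6$ counts 0.5 haploid
  copies (heterozygous), $f \ge 0.6$ counts 1.0.
* `averageTables()` — per-family mean across strains, counting only
  strains in which the family is present (absence is missing data, not a
  zero; configurable).

## Small-RNA operators

`filterPiRNAReads()` keeps 23–29 nt reads (inclusive) with mapping quality
$\ge 5$ and no structural-ncRNA match. A read is assigned to a flank
window by its 5' end — the position that defines a piRNA. Windows abut the
feature: upstream $[start - flank, start)$ and downstream
$[end, end + flank)$ in the feature's orientation (everything flips for a
minus-strand feature), truncated at contig edges, with rpm computed from
raw counts (no length renormalization). The "per million" denominator is
the number of filter-surviving reads, the most reproducible choice given
that the original normalization base is unstated.

A TE insertion is a **DSL** when upstream-antisense and downstream-sense
signals both reach 5 rpm and the insertion (by midpoint) lies outside all
clusters (`detectDSL()`). `controlDSLRate()` applies identical logic to
conserved single-copy genes of $\ge$ 100 bp — which should never behave
like piRNA source loci — to estimate the false-positive rate.

`pingPongOverlapHistogram()` counts, for offsets 1..20, sense/antisense
read pairs whose 5' ends overlap by exactly that many nt; secondary piRNA
amplification enriches offset 10. `pingPongZ()` standardizes the 10-nt
count against the other offsets: $z_{10} = (c_{10} - \bar c)/sd(c)$. A
flat histogram gives $z_{10} = 0$; a zero background standard deviation
with a non-zero numerator is flagged undefined.

```{r pingpong}
r <- synthPingPongReads(nPairs = 500, signalFraction = 0.4, seed = 2)
h <- pingPongOverlapHistogram(r)
pingPongZ(h)$z10
```

# The synthetic-data generators

The study's strain data (assemblies, insertion-frequency tables, ovarian
small-RNA libraries) are not redistributable at package scale, so
`synthAnnotations()`, `synthFreqTable()`, `synthSmallRNA()` and
`synthPingPongReads()` generate the *processed forms* of those inputs with
planted ground truth, deterministic per seed:

* annotations place a known number of copies per family inside/outside
  clusters, with divergences uniform on [0, 15]% and lengths uniform on
  [50, consensus] bp so the standard filters have work to do;
* frequency tables carry exactly planted frequencies, making the haploid
  conversion computable in closed form;
* small-RNA libraries plant DSL flank signals at twice the detection
  threshold and strand-symmetric Poisson background hard-capped at half
  the threshold (so planted calls are exactly recoverable and the control
  rate is 0 by construction), plus filler reads away from all feature
  flanks to make the library size — and hence every rpm value — exact,
  plus decoy reads the piRNA filter must remove;
* ping-pong libraries place read pairs with a configurable fraction at
  the exact 10-nt overlap, the rest at offsets uniform over all of 1..20
  so that zero signal is a true null with $z_{10} \approx 0$ (excluding
  offset 10 from the background would force a negative score on null
  data); when the consensus has room, pairs are spaced so cross-pair
  overlaps cannot contaminate the histogram.

What these generators deliberately do **not** emulate: sequence content
(no bases, only coordinates and labels), mapping ambiguity, fragmented or
nested annotations, assembly gaps, and biological background piRNA
production outside planted loci. Tests passing on synthetic data
demonstrate the operators' rule arithmetic and detection logic, not
robustness to those real-data complications.

# Problem sizes and numerical notes

The packaged test suite and the acceptance script run the baseline
scenario at 30 replicates (the original study used 300), pooling 30 000
individuals; smaller unit tests use populations of 50–200 on 1–2 Mb
chromosomes, which preserve the qualitative dynamics (silencing within a
few hundred generations, trap counts around 4 per diploid at silencing).
The simulator core is C++ (via Rcpp), as is usual for forward-in-time
population simulators; a full-scale baseline replicate (1000 diploids,
2000 generations, 50 Mb) takes on the order of 15–20 s.

Total genome size must stay below $2^{31}$ bp (positions are stored as
32-bit integers in a global coordinate). Kendall correlations on fewer
than 3 observations, frequencies outside [0, 1], and unstranded features
in flank scans are rejected with errors; extinct replicates and constant
correlation inputs are flagged, not errors.

# Known limitations

* No paramutation or maternal piRNA inheritance, no separate soma/germline
  piRNA pathways, no TE excision, no insertion-site preference, no
  explicit sequence evolution — matching the scope of the trap-model
  predictions being tested.
* The phase operationalization and the zygote-conditioning choice are
  documented judgement calls where the original tool chain's exact rules
  are not published; both are switchable or inspectable.
* Empirical headline quantities that depend on the real strain data
  (genome-wide DSL percentages, counts of families without full-length
  cluster insertions) are out of reach without those data; the package
  provides the operators and validates them on planted truth instead.
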