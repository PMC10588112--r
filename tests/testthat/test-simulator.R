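# Unit and property tests for the forward simulator.

test_that("fitness is 1 - sum(x_i), clamped, with neutral traps", {
    arch <- buildArchitecture()
    sel <- twoClassSelection(0.1, 0.1)
    # two x = 0.1 insertions outside traps -> 20% fitness reduction
    ind <- makeIndividual(makeHaplotype(arch, 1, c(5e6, 6e6), class = 2L))
    expect_equal(individualFitness(ind, sel, arch), 0.8)
    # no insertions
    expect_equal(individualFitness(makeIndividual(), sel, arch), 1.0)
    # 15 insertions of x = 0.1 -> clamped at 0
    many <- makeIndividual(makeHaplotype(arch, 1, seq(4e6, 4e6 + 14e4, 1e4),
                                         class = 2L))
    expect_equal(individualFitness(many, sel, arch), 0.0)
    # deleterious insertion inside a trap contributes 0 when traps are neutral
    trapIns <- makeIndividual(makeHaplotype(arch, 1, 100, class = 2L))
    expect_equal(individualFitness(trapIns, sel, arch), 1.0)
    selAll <- twoClassSelection(0.1, 0.1, trapsNeutral = FALSE)
    expect_equal(individualFitness(trapIns, selAll, arch), 0.9)
})

test_that("a single trap insertion silences, reference insertions do not", {
    arch <- buildArchitecture()
    expect_true(isSilenced(
        makeIndividual(makeHaplotype(arch, 1, 100)), arch))
    expect_false(isSilenced(
        makeIndividual(makeHaplotype(arch, 1, 9700000)), arch))
    expect_false(isSilenced(makeIndividual(), arch))
    # second haplotype counts too
    expect_true(isSilenced(
        makeIndividual(h2 = makeHaplotype(arch, 2, 349999)), arch))
})

test_that("seeding places every insertion at frequency 1/(2N)", {
    cfg <- tinyConfig(N = 50, nSeed = 40)
    pop <- seedPopulation(cfg, seed = 7)
    allPos <- unlist(lapply(pop@individuals,
                            function(i) c(i$h1$pos, i$h2$pos)))
    expect_length(allPos, 40)
    # no seed position recurs, so each segregates at 1/(2N)
    expect_equal(max(table(allPos)), 1)
    # zero seeds -> empty population
    empty <- seedPopulation(tinyConfig(nSeed = 0), seed = 1)
    expect_equal(sum(lengths(lapply(empty@individuals,
                                    function(i) i$h1$pos))), 0)
})

test_that("seed placement is uniform: trap share matches the trap fraction", {
    cfg <- tinyConfig(N = 20, nSeed = 100)
    set.seed(11)
    fracs <- vapply(seq_len(200), function(i) {
        pop <- seedPopulation(cfg)
        cc <- countRegions(pop, cfg@architecture)
        sum(cc$trap) / sum(cc$genome)
    }, numeric(1))
    # binomial expectation 0.035, 3 SEs over 200 x 100 draws
    se <- sqrt(0.035 * 0.965 / (200 * 100))
    expect_lt(abs(mean(fracs) - 0.035), 3 * se)
})

test_that("gametes from homozygous parents reproduce the haplotype exactly", {
    arch <- tinyArch()
    h <- makeHaplotype(arch, c(1, 1, 2), c(1000, 5e5, 123), class = 1L)
    par <- makeIndividual(h, h)
    set.seed(5)
    for (i in 1:5) expect_identical(makeGamete(par, arch), h)
})

test_that("with no recombination a gamete equals one parental chromosome", {
    arch <- buildArchitecture(1, 1e6, 0, 0, recombRate = 0)
    h1 <- makeHaplotype(arch, 1, c(10, 20, 30))
    h2 <- makeHaplotype(arch, 1, c(100, 200))
    par <- makeIndividual(h1, h2)
    set.seed(3)
    picks <- replicate(200, length(makeGamete(par, arch)$pos))
    expect_true(all(picks %in% c(2L, 3L)))
    # fair coin per chromosome
    expect_gt(mean(picks == 3L), 0.35)
    expect_lt(mean(picks == 3L), 0.65)
})

test_that("crossover rate matches the Poisson expectation (0.4 per 10 Mb at 4 cM/Mb)", {
    arch <- buildArchitecture(1, 1e7, 0, 0, recombRate = 4)
    # distinguishable dense markers: switches between marker origins count
    # crossovers (marker spacing 10 kb makes double-crossover losses negligible)
    p1 <- seq(1, 1e7, by = 2e4)
    p2 <- p1 + 1e4
    par <- makeIndividual(makeHaplotype(arch, 1, p1, class = 1L),
                          makeHaplotype(arch, 1, p2, class = 2L))
    set.seed(17)
    nSwitch <- vapply(seq_len(10000), function(i) {
        g <- makeGamete(par, arch)
        sum(diff(g$cls) != 0L)
    }, numeric(1))
    se <- sqrt(0.4 / 10000)  # Poisson variance = mean
    expect_lt(abs(mean(nSwitch) - 0.4), 3 * se)
})

test_that("with u = 0 offspring insertions are drawn only from parental haplotypes", {
    cfg <- tinyConfig(N = 60, u = 0, nSeed = 120)
    pop <- seedPopulation(cfg, seed = 21)
    parental <- sort(unique(unlist(lapply(pop@individuals,
                                          function(i) c(i$h1$pos, i$h2$pos)))))
    nxt <- reproduce(pop, cfg)
    offspring <- unlist(lapply(nxt@individuals,
                               function(i) c(i$h1$pos, i$h2$pos)))
    expect_true(all(offspring %in% parental))
    expect_equal(nxt@generation, 1L)
})

test_that("copies from silenced parents never transpose", {
    # all-trap genome: every carrier is silenced, so no new positions can appear
    arch <- buildArchitecture(1, 1e5, trapFraction = 1, referenceFraction = 0)
    cfg <- simulationConfig(architecture = arch, N = 40, u = 0.5,
                            nSeedInsertions = 80, sampleGeneration = 5)
    pop <- seedPopulation(cfg, seed = 2)
    parental <- unique(unlist(lapply(pop@individuals,
                                     function(i) c(i$h1$pos, i$h2$pos))))
    for (g in 1:5) {
        pop <- reproduce(pop, cfg)
        now <- unlist(lapply(pop@individuals,
                             function(i) c(i$h1$pos, i$h2$pos)))
        expect_true(all(now %in% parental))
    }
})

test_that("early neutral invasions grow by about (1 + u) per generation", {
    # no traps, no reference: unconstrained exponential growth phase
    arch <- buildArchitecture(1, 1e6, 0, 0, recombRate = 4)
    cfg <- simulationConfig(architecture = arch, N = 200, u = 0.1,
                            nSeedInsertions = 400, sampleGeneration = 15)
    set.seed(31)
    rates <- vapply(1:5, function(i) {
        r <- runReplicate(cfg, seed = 100 + i)
        tr <- trajectory(r)
        n0 <- tr$mean_diploid_copies[1]
        n15 <- tr$mean_diploid_copies[16]
        (n15 / n0)^(1 / 15)
    }, numeric(1))
    expect_lt(abs(mean(rates) - 1.1), 0.03)
})

test_that("total copy number is conserved in expectation under u = 0, no selection", {
    cfg <- tinyConfig(N = 100, u = 0, nSeed = 200, sampleGeneration = 50)
    set.seed(41)
    ratios <- vapply(1:10, function(i) {
        r <- runReplicate(cfg, seed = 500 + i)
        tr <- trajectory(r)
        tr$mean_diploid_copies[51] / tr$mean_diploid_copies[1]
    }, numeric(1))
    # drift only: mean ratio ~ 1 within 3 SEs of the observed spread
    expect_lt(abs(mean(ratios) - 1), 3 * sd(ratios) / sqrt(10))
})

test_that("phases are classified from silencing and fixation", {
    arch <- tinyArch()
    trapPos <- 100
    silenced <- makeIndividual(makeHaplotype(arch, 1, trapPos),
                               makeHaplotype(arch, 1, trapPos))
    free <- makeIndividual(makeHaplotype(arch, 1, 5e5))
    segregating <- makeIndividual(makeHaplotype(arch, 1, 200))

    popRapid <- new("Population", individuals = list(silenced, free),
                    generation = 0L)
    expect_equal(classifyPhase(popRapid, arch), "rapid")

    popShotgun <- new("Population", individuals = list(silenced, segregating),
                      generation = 0L)
    expect_equal(classifyPhase(popShotgun, arch), "shotgun")

    popInactive <- new("Population", individuals = list(silenced, silenced),
                       generation = 0L)
    expect_equal(classifyPhase(popInactive, arch), "inactive")
})

test_that("replicates are bitwise reproducible for a fixed seed", {
    cfg <- tinyConfig(N = 60, nSeed = 60, sampleGeneration = 100)
    a <- runReplicate(cfg, seed = 99)
    b <- runReplicate(cfg, seed = 99)
    expect_identical(individualCounts(a), individualCounts(b))
    expect_identical(trajectory(a), trajectory(b))
    expect_identical(phase(a), phase(b))
    c <- runReplicate(cfg, seed = 100)
    expect_false(identical(individualCounts(a), individualCounts(c)))
})

test_that("selection on trap insertions can hold invasions short of full silencing", {
    # transposition-selection-cluster balance: with deleterious trap
    # insertions the invasion plateaus without an all-silenced state
    cfg <- tinyConfig(N = 150, nSeed = 150, sampleGeneration = 300,
                      selection = twoClassSelection(0.03, 1,
                                                    trapsNeutral = FALSE))
    r <- runReplicate(cfg, seed = 13)
    expect_false(r@extinct)
    expect_identical(phase(r), "rapid")
    tr <- trajectory(r)
    # copies persist, most individuals stay unsilenced, growth has stalled
    expect_gt(tail(tr$mean_diploid_copies, 1), 0)
    expect_lt(tail(tr$fraction_silenced, 1), 1)
    late <- tr$mean_diploid_copies[tr$generation >= 200]
    expect_lt(max(late) / max(1, min(late)), 2.5)
})

test_that("strong unconditional selection drives populations extinct", {
    arch <- tinyArch()
    cfg <- simulationConfig(architecture = arch, N = 50, u = 0.5,
                            selection = twoClassSelection(0.2, 1,
                                                          trapsNeutral = FALSE),
                            nSeedInsertions = 500, sampleGeneration = 300)
    r <- runReplicate(cfg, seed = 8)
    expect_true(r@extinct)
    expect_equal(phase(r), "extinct")
})

test_that("small trap-model invasions leave the rapid phase and accumulate trap insertions", {
    cfg <- tinyConfig(N = 100, nSeed = 100, sampleGeneration = 400)
    set.seed(55)
    reps <- lapply(1:5, function(i) runReplicate(cfg, seed = 700 + i))
    ph <- vapply(reps, phase, character(1))
    expect_true(all(ph %in% c("shotgun", "inactive")))
    expect_true(all(vapply(reps, function(r) mean(individualCounts(r)$trap),
                           numeric(1)) > 0))
})

test_that("per-replicate samplers draw u and the sampling generation uniformly", {
    cfg <- tinyConfig(N = 10, nSeed = 0, u = c(0.005, 0.5),
                      sampleGeneration = c(50, 150))
    ens <- runEnsemble(cfg, nReplicates = 300, baseSeed = 3,
                       recordTrajectory = FALSE)
    us <- vapply(replicates(ens), function(r) r@u, numeric(1))
    sg <- vapply(replicates(ens), function(r) r@sampleGeneration, integer(1))
    se <- (0.5 - 0.005) / sqrt(12) / sqrt(300)
    expect_lt(abs(mean(us) - 0.2525), 3 * se)
    expect_true(all(sg >= 50 & sg <= 150))
    expect_gt(length(unique(sg)), 30)
})

test_that("ensembles derive replicate seeds deterministically", {
    cfg <- tinyConfig(N = 30, nSeed = 30, sampleGeneration = 50)
    ens <- runEnsemble(cfg, nReplicates = 2, baseSeed = 12)
    single <- runReplicate(cfg, seed = trapTE:::.replicateSeed(12, 1))
    expect_identical(individualCounts(ens[[1]]), individualCounts(single))
    expect_equal(length(ens), 2L)
})

test_that("tail narrowness is insensitive to trap size (1% vs 10%)", {
    set.seed(61)
    for (tf in c(0.01, 0.10)) {
        cfg <- simulationConfig(
            architecture = buildArchitecture(2, 1e6, tf, 0.035, 4),
            N = 150, u = 0.1, nSeedInsertions = 150, sampleGeneration = 400)
        ens <- runEnsemble(cfg, nReplicates = 8, baseSeed = round(tf * 1000))
        cc <- regionCounts(ens)
        outside <- mean(cc$trap < 1 | cc$trap > 14)
        expect_lt(outside, 0.15)
    }
})
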