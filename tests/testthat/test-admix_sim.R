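test_that("single founder pool yields single-ancestry samples", {
    g <- genomeModel(rep(0.2, 5))
    cfg <- admixtureConfig(proportions = c(EUR = 1, NAM = 0, AFR = 0),
                           T = 4, Ne = 40, nSample = 10)
    sim <- simulatePopulation(cfg, g, seed = 3)
    expect_true(all(sim@anc == 0L))
    expect_equal(unname(realizedProportions(sim)), c(1, 0, 0))
})

test_that("T = 0 samples founders: one tract per chromosome", {
    g <- genomeModel(rep(0.3, 4))
    cfg <- admixtureConfig(T = 0, Ne = 50, nSample = 20)
    sim <- simulatePopulation(cfg, g, seed = 5)
    expect_true(all(junctionCounts(sim) == 0L))
    tr <- tracts(sim, which = 1)
    expect_equal(nrow(tr), 4)
    expect_equal(tr$end_M, rep(0.3, 4))
})

test_that("tracts tile every chromosome with no gaps after simulation", {
    g <- genomeModel(c(0.5, 0.2, 1.0))
    cfg <- admixtureConfig(T = 6, Ne = 60, nSample = 15)
    sim <- simulatePopulation(cfg, g, seed = 8)
    tr <- tracts(sim)
    for (h in unique(tr$haplotype)) {
        for (c in seq_len(3)) {
            t <- tr[tr$haplotype == h & tr$chrom == g@chroms$name[c], ]
            expect_equal(t$start_M[1], 0)
            expect_equal(t$end_M[nrow(t)], g@chroms$length_M[c])
            if (nrow(t) > 1) {
                expect_equal(t$start_M[-1], t$end_M[-nrow(t)])
                # canonical form: adjacent tracts change ancestry
                expect_true(all(diff(t$ancestry) != 0))
            }
        }
    }
})

test_that("meiosis of identical or unlinked parents behaves as forced", {
    g <- genomeModel(rep(0.2, 3))
    set.seed(1)
    gam <- meiosis(constantHap(g, 0L), constantHap(g, 0L), g)
    expect_equal(nrow(gam), 3)
    expect_true(all(gam$ancestry == 0L))

    # effectively zero genetic length: no crossovers can be drawn
    g0 <- genomeModel(rep(1e-12, 2), lengthBp = c(100, 100))
    set.seed(2)
    gam0 <- meiosis(constantHap(g0, 0L), constantHap(g0, 1L), g0)
    expect_true(all(gam0$ancestry %in% c(0L, 1L)))
    expect_equal(nrow(gam0), 2)  # whole-chromosome inheritance
})

test_that("crossover count per meiosis is Poisson with mean = Morgans", {
    g <- genomeModel(2, lengthBp = 2e8)
    a <- constantHap(g, 0L)
    b <- constantHap(g, 1L)
    set.seed(42)
    n <- 3000
    junc <- vapply(seq_len(n), function(i) nrow(meiosis(a, b, g)) - 1L,
                   integer(1))
    # ancestry switches in the gamete = crossovers between opposite-ancestry
    # parents (coincident breakpoints have probability zero)
    expect_lt(abs(mean(junc) - 2), 0.1)
    expect_lt(abs(var(junc) - 2), 0.35)
})

test_that("junction density matches L * T * (1 - sum(a^2)) for T << Ne", {
    g <- genomeModel(1, lengthBp = 1e8)
    cfg <- admixtureConfig(proportions = c(EUR = 0.5, NAM = 0.5, AFR = 0),
                           T = 2, Ne = 10000, nSample = 1000)
    sim <- simulatePopulation(cfg, g, seed = 7)
    expect_lt(abs(mean(junctionCounts(sim)) - 1.0), 0.1)
})

test_that("junction count is non-decreasing in T in expectation", {
    g <- genomeModel(rep(0.5, 8))
    means <- vapply(c(1, 4, 10), function(T) {
        cfg <- admixtureConfig(T = T, Ne = 400, nSample = 150)
        mean(junctionCounts(simulatePopulation(cfg, g, seed = 11)))
    }, numeric(1))
    expect_true(all(diff(means) > 0))
})

test_that("physical to genetic projection is linear and order-preserving", {
    g <- genomeModel(0.2, lengthBp = 1e6, names = "1")
    map <- data.frame(snp_id = c("a", "b", "c"), chrom = "1",
                      pos_bp = c(250000L, 500000L, 1000000L),
                      gpos_M = NA_real_)
    out <- physicalToGenetic(map, g)
    expect_equal(out$gpos_M, c(0.05, 0.1, 0.2))
    bad <- map; bad$pos_bp[3] <- 2000000L
    expect_error(physicalToGenetic(bad, g), "exceeds")
    expect_error(physicalToGenetic(transform(map, chrom = "chrX"), g),
                 "not in genome")
})

test_that("tract projection uses the half-open interval convention", {
    g <- genomeModel(0.5, names = "1")
    cfg <- admixtureConfig(T = 0, Ne = 10, nSample = 1,
                           proportions = c(EUR = 1, NAM = 0, AFR = 0))
    sim <- simulatePopulation(cfg, g, seed = 1)
    # overwrite tracts by hand: EUR on [0, 0.2), NAM on [0.2, 0.5)
    sim@ends <- rep(c(0.2, 0.5), 2)
    sim@anc <- rep(c(0L, 1L), 2)
    sim@off <- c(0L, 2L, 4L)
    map <- data.frame(snp_id = c("a", "b", "c"), chrom = "1",
                      pos_bp = c(1L, 2L, 3L),
                      gpos_M = c(0.1, 0.2, 0.5))
    ac <- projectTractsToSnps(sim, map)
    expect_equal(unname(calls(ac)[1, ]), c(0L, 1L, 1L))
    mapNA <- transform(map, gpos_M = NA_real_)
    expect_error(projectTractsToSnps(sim, mapNA), "gpos_M")
})

test_that("single-tract haplotypes project to constant rows", {
    g <- genomeModel(0.4, names = "1")
    cfg <- admixtureConfig(T = 0, Ne = 30, nSample = 10)
    sim <- simulatePopulation(cfg, g, seed = 13)
    map <- data.frame(snp_id = sprintf("s%d", 1:6), chrom = "1",
                      pos_bp = 1:6 * 100L,
                      gpos_M = seq(0.05, 0.35, length.out = 6))
    m <- calls(projectTractsToSnps(sim, map))
    expect_true(all(apply(m, 1, function(r) length(unique(r)) == 1L)))
})

test_that("default genome has the documented dimensions and determinism", {
    d <- defaultGenome(189, seed = 4)
    expect_equal(nrow(d$genome@chroms), 189)
    expect_equal(sum(d$genome@chroms$length_M), 37.8)
    expect_equal(nrow(d$snpMap), 189)
    expect_true(all(!is.na(d$snpMap$gpos_M)))
    d2 <- defaultGenome(189, seed = 4)
    expect_identical(d, d2)
    d20 <- defaultGenome(10, seed = 1, nChrom = 5, chromMorgans = 20)
    expect_equal(sum(d20$genome@chroms$length_M), 100)
})

test_that("simulation is bit-identical for a fixed seed", {
    g <- defaultGenome(500, seed = 2, nChrom = 20)
    cfg <- admixtureConfig(T = 5, Ne = 100, nSample = 40)
    s1 <- simulatePopulation(cfg, g$genome, seed = 99)
    s2 <- simulatePopulation(cfg, g$genome, seed = 99)
    expect_identical(s1@ends, s2@ends)
    expect_identical(s1@anc, s2@anc)
    expect_identical(calls(projectTractsToSnps(s1, g$snpMap)),
                     calls(projectTractsToSnps(s2, g$snpMap)))
})

test_that("config validation rejects impossible scenarios", {
    expect_error(admixtureConfig(Ne = 100, nSample = 200), "nSample")
    expect_error(admixtureConfig(T = -1), "T must be")
    # proportions are normalized
    cfg <- admixtureConfig(proportions = c(EUR = 2, NAM = 1, AFR = 1))
    expect_equal(sum(cfg@proportions), 1)
    expect_equal(unname(cfg@proportions), c(0.5, 0.25, 0.25))
})

test_that("sampled ancestry proportions converge on configured values", {
    g <- genomeModel(rep(0.2, 10))
    cfg <- admixtureConfig(T = 8, Ne = 500, nSample = 250)
    props <- t(vapply(replicateSeeds(31, 12), function(s)
        ancestryProportions(simulatePopulation(cfg, g, s)), numeric(3)))
    est <- colMeans(props)
    mcse <- apply(props, 2, function(x) stats::sd(x) / sqrt(nrow(props)))
    expect_true(all(abs(est - c(0.521, 0.442, 0.037)) < 3 * mcse + 1e-12))
})

test_that("forward-simulated per-SNP variance matches the drift model", {
    # near-zero-length chromosomes = unlinked loci; one SNP on each
    nChrom <- 40
    g <- genomeModel(rep(1e-9, nChrom), lengthBp = rep(1000, nChrom))
    map <- data.frame(snp_id = sprintf("u%02d", seq_len(nChrom)),
                      chrom = g@chroms$name, pos_bp = 500L,
                      gpos_M = 5e-10)
    cfg <- admixtureConfig(T = 8, Ne = 200, nSample = 30)
    fracs <- t(vapply(replicateSeeds(17, 200), function(s) {
        sim <- simulatePopulation(cfg, g, s)
        unname(snpMeanAncestry(projectTractsToSnps(sim, map), "EUR"))
    }, numeric(nChrom)))
    vEmp <- mean(apply(fracs, 2, function(x) mean((x - mean(x))^2)))
    vModel <- modelObservedVariance(0.521, 8, 200, 60)
    expect_lt(abs(vEmp / vModel - 1), 0.12)
})
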