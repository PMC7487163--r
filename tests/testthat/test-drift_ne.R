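test_that("drift variance has the documented limits and values", {
    pq <- 0.521 * 0.479
    expect_equal(driftVariance(0.521, 10, 1e12), 0, tolerance = 1e-10)
    expect_equal(driftVariance(0.521, 1e9, 4500), pq, tolerance = 1e-8)
    expect_equal(driftVariance(0.521, 10, 4500), 2.771338e-4,
                 tolerance = 1e-6)
    # discrete Wright-Fisher factor agrees to ~1/(2Ne) relative here
    disc <- pq * (1 - (1 - 1 / 9000)^10)
    expect_equal(driftVariance(0.521, 10, 4500), disc, tolerance = 1e-4)
})

test_that("beta moment matching is exact and guards its domain", {
    bm <- betaMoments(0.5, 0.05)
    expect_equal(bm$alpha, 2)
    expect_equal(bm$beta, 2)
    expect_error(betaMoments(0.521, 0.521 * 0.479), "Beta")
    expect_error(betaMoments(0.521, 0), "Beta")
    # round trip through Beta moments
    for (p0 in c(0.1, 0.521, 0.9)) {
        v <- 0.3 * p0 * (1 - p0)
        bm <- betaMoments(p0, v)
        a <- bm$alpha; b <- bm$beta
        expect_equal(a / (a + b), p0, tolerance = 1e-12)
        expect_equal(a * b / ((a + b)^2 * (a + b + 1)), v, tolerance = 1e-12)
    }
})

test_that("observed-fraction variance matches its closed forms and limits", {
    pq <- 0.521 * 0.479
    expect_equal(modelObservedVariance(0.521, 0, 4500, 370), pq / 370)
    expect_equal(modelObservedVariance(0.521, 10, 4500, 370), 9.508686e-4,
                 tolerance = 1e-6)
    expect_equal(modelObservedVariance(0.521, 10, 4500, 1e9),
                 driftVariance(0.521, 10, 4500), tolerance = 1e-6)
    # equivalent correlation form (p0 q0 / K) (1 + (K-1) rho)
    rho <- 1 - exp(-10 / 9000)
    expect_equal(modelObservedVariance(0.521, 10, 4500, 370),
                 pq / 370 * (1 + 369 * rho), tolerance = 1e-12)
})

test_that("closed form agrees with numeric integration of the compound", {
    for (Ne in c(1000, 4500)) {
        v <- driftVariance(0.521, 10, Ne)
        bm <- betaMoments(0.521, v)
        K <- 370
        # Var(k/K) = E[p(1-p)]/K + Var(p) under p ~ Beta(alpha, beta)
        f1 <- integrate(function(p) p * (1 - p) * dbeta(p, bm$alpha, bm$beta),
                        0, 1, rel.tol = 1e-12)$value
        f2 <- integrate(function(p) (p - 0.521)^2 *
                            dbeta(p, bm$alpha, bm$beta),
                        0, 1, rel.tol = 1e-12)$value
        quad <- f1 / K + f2
        expect_equal(modelObservedVariance(0.521, 10, Ne, K), quad,
                     tolerance = 1e-8)
    }
})

test_that("closed-form variance matches Monte-Carlo beta-binomial draws", {
    set.seed(5)
    n <- 1e5; K <- 370
    v <- driftVariance(0.521, 10, 4500)
    bm <- betaMoments(0.521, v)
    f <- rbinom(n, K, rbeta(n, bm$alpha, bm$beta)) / K
    vHat <- var(f)
    se <- sqrt((mean((f - mean(f))^4) - vHat^2) / n)
    expect_lt(abs(vHat - modelObservedVariance(0.521, 10, 4500, K)), 3 * se)
})

test_that("empirical variance uses the population denominator", {
    # fractions per SNP: 0.6 and 0.4 EUR of 10 haplotypes
    ac <- ancestryCalls(
        cbind(c(rep(0L, 4), rep(1L, 6)), c(rep(0L, 6), rep(1L, 4))),
        makeSnpMap(2), ancestryLabels(c("EUR", "NAM")))
    ev <- empiricalAncestryVariance(ac, "EUR")
    expect_equal(ev$V_emp, 0.01)   # ((0.4-0.5)^2 + (0.6-0.5)^2)/2
    expect_equal(ev$p_bar, 0.5)
    one <- ancestryCalls(matrix(0L, 4, 1), makeSnpMap(1))
    expect_error(empiricalAncestryVariance(one), "at least 2")
    # permutation invariance and zero for constant fractions
    ac2 <- randomCalls(10, 12, seed = 2)
    perm <- ancestryCalls(calls(ac2)[, 12:1], makeSnpMap(12),
                          labelSet(ac2))
    expect_equal(empiricalAncestryVariance(ac2)$V_emp,
                 empiricalAncestryVariance(perm)$V_emp)
    const <- ancestryCalls(matrix(rep(c(0L, 1L), 6), 2, 6),
                           makeSnpMap(6), ancestryLabels(c("EUR", "NAM")))
    expect_equal(empiricalAncestryVariance(const)$V_emp, 0)
})

test_that("Ne estimation inverts the variance model exactly", {
    for (Ne in c(500, 2000, 4500, 8000, 20000)) {
        for (T in c(5, 10, 12, 15, 20)) {
            V <- modelObservedVariance(0.521, T, Ne, 370)
            expect_lt(abs(estimateNe(V, 0.521, T, 370) / Ne - 1), 1e-6)
        }
    }
})

test_that("closed-form inversion agrees with root finding to 1e-9", {
    for (Ne in c(700, 4500, 15000)) {
        V <- modelObservedVariance(0.521, 10, Ne, 370)
        root <- uniroot(function(lnNe)
            modelObservedVariance(0.521, 10, exp(lnNe), 370) - V,
            c(log(2), log(1e8)), tol = 1e-13)$root
        expect_lt(abs(estimateNe(V, 0.521, 10, 370) / exp(root) - 1), 1e-9)
    }
})

test_that("Ne estimation errors at its boundaries and is monotone", {
    pq <- 0.521 * 0.479
    expect_error(estimateNe(pq / 370, 0.521, 10, 370), "no detectable drift")
    expect_error(estimateNe(pq, 0.521, 10, 370), "undefined")
    v1 <- modelObservedVariance(0.521, 10, 3000, 370)
    v2 <- modelObservedVariance(0.521, 10, 6000, 370)
    expect_gt(v1, v2)  # decreasing in Ne
    expect_lt(estimateNe(v1 * 1.05, 0.521, 10, 370),
              estimateNe(v1, 0.521, 10, 370))  # larger V -> smaller Ne
    expect_gt(modelObservedVariance(0.521, 15, 4500, 370),
              modelObservedVariance(0.521, 10, 4500, 370))  # increasing in T
})

test_that("estimator recovers Ne from exact Wright-Fisher drift draws", {
    set.seed(33)
    for (par in list(c(10, 4500), c(12, 6000), c(15, 7000))) {
        f <- simulateDriftLoci(5000, 0.521, par[1], par[2], 370)
        V <- mean((f - mean(f))^2)
        neHat <- estimateNe(V, mean(f), par[1], 370)
        expect_lt(abs(neHat / par[2] - 1), 0.15)
    }
})
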