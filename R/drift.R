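#' Drift variance of an ancestry proportion
#'
#' Variance accumulated by an ancestry proportion over T generations of
#' genetic drift in a Wright-Fisher population of Ne diploids, in the
#' diffusion approximation: p0 (1 - p0) (1 - exp(-T / (2 Ne))). The
#' expectation of the drifted proportion stays p0. The discrete-generation
#' factor 1 - (1 - 1/(2 Ne))^T agrees to several significant digits at the
#' parameter scales of interest (T << Ne); the continuous form is used
#' throughout.
#'
#' @param p0 Initial ancestry proportion in (0, 1).
#' @param T Generations (>= 0).
#' @param Ne Diploid effective population size (> 1).
#' @return The drift variance, in [0, p0 (1 - p0)).
#' @examples
#' driftVariance(0.521, 10, 4500)   # 2.771e-4
#' @export
driftVariance <- function(p0, T, Ne) {
    stopifnot(p0 > 0, p0 < 1, T >= 0, Ne > 1)
    p0 * (1 - p0) * (1 - exp(-T / (2 * Ne)))
}

#' Beta moment matching
#'
#' Parameters of the Beta distribution with given mean and variance, used
#' to approximate the distribution of a drifted ancestry proportion.
#'
#' @param p0 Mean in (0, 1).
#' @param variance Variance; must satisfy 0 < variance < p0 (1 - p0).
#' @return list with elements \code{alpha} and \code{beta}.
#' @examples
#' betaMoments(0.5, 0.05)  # alpha = beta = 2
#' @export
betaMoments <- function(p0, variance) {
    stopifnot(p0 > 0, p0 < 1)
    pq <- p0 * (1 - p0)
    if (variance <= 0 || variance >= pq)
        stop("variance must lie in (0, p0*(1-p0)) for a Beta to exist")
    nu <- pq / variance - 1
    list(alpha = p0 * nu, beta = (1 - p0) * nu)
}

#' Variance of an observed ancestry fraction under drift plus sampling
#'
#' The ancestry fraction observed at a SNP in K sampled haplotypes is a
#' binomial draw whose success probability is itself the drifted proportion
#' (approximated by a Beta). The resulting Beta-binomial fraction k/K has
#' variance (p0 (1 - p0) / K) (1 + (K - 1) rho) with rho = 1 - exp(-T / (2
#' Ne)); equivalently drift variance plus the sampling remainder
#' (p0 (1 - p0) - drift) / K.
#'
#' @inheritParams driftVariance
#' @param K Number of sampled haplotypes (>= 2).
#' @return The model variance of k/K.
#' @examples
#' modelObservedVariance(0.521, 10, 4500, 370)  # 9.509e-4
#' @export
modelObservedVariance <- function(p0, T, Ne, K) {
    stopifnot(K >= 2)
    v <- driftVariance(p0, T, Ne)
    v + (p0 * (1 - p0) - v) / K
}

#' Empirical across-SNP ancestry variance
#'
#' Across-SNP variance (population denominator 1/M, fixed for
#' reproducibility) and mean of the per-SNP observed ancestry fractions.
#' All SNPs enter, including linked ones: linkage affects the precision of
#' the downstream Ne estimate, not the variance-matching identity.
#'
#' @param x An \code{\link{AncestryCalls}} object with >= 2 SNPs.
#' @param targetLabel Ancestry name.
#' @return list with elements \code{V_emp} and \code{p_bar}.
#' @export
empiricalAncestryVariance <- function(x, targetLabel = "EUR") {
    p <- snpMeanAncestry(x, targetLabel)
    if (length(p) < 2) stop("need at least 2 SNPs")
    list(V_emp = mean((p - mean(p))^2), p_bar = mean(p))
}

#' Effective population size by variance matching
#'
#' Inverts the drift-plus-sampling variance model: given the empirical
#' across-SNP variance of observed ancestry fractions, the admixture
#' proportion, the time since admixture and the haplotype sample size,
#' returns the Ne whose model variance equals the empirical variance. The
#' inversion is closed-form: rho = (K V / (p0 (1 - p0)) - 1) / (K - 1),
#' Ne = -T / (2 log(1 - rho)).
#'
#' @param V_emp Empirical variance of k/K across SNPs.
#' @param p0 Ancestry proportion in (0, 1).
#' @param T Generations since admixture (> 0).
#' @param K Haplotype sample size (>= 2).
#' @return The estimated diploid Ne.
#' @examples
#' V <- modelObservedVariance(0.521, 10, 4500, 370)
#' estimateNe(V, 0.521, 10, 370)    # 4500 (round trip)
#' @export
estimateNe <- function(V_emp, p0, T, K) {
    stopifnot(p0 > 0, p0 < 1, T > 0, K >= 2)
    pq <- p0 * (1 - p0)
    if (V_emp >= pq)
        stop("empirical variance at or above p0*(1-p0): model undefined")
    if (V_emp <= pq / K)
        stop("no detectable drift: empirical variance does not exceed ",
             "pure sampling variance p0*(1-p0)/K (Ne -> Inf)")
    rho <- (K * V_emp / pq - 1) / (K - 1)
    -T / (2 * log(1 - rho))
}

#' Simulate unlinked loci under Wright-Fisher ancestry drift
#'
#' For each locus, the ancestry proportion starts at p0 and drifts for T
#' generations by binomial resampling of 2 Ne alleles; the observed
#' fraction is then a Binomial(K, p_T) draw divided by K. This is the exact
#' single-locus process the Beta-binomial variance model approximates, and
#' the workhorse for estimator-recovery experiments.
#'
#' @param nLoci Number of independent loci.
#' @param p0 Initial ancestry proportion.
#' @param T Generations of drift.
#' @param Ne Diploid effective size.
#' @param K Haplotypes sampled per locus.
#' @return Numeric vector of nLoci observed fractions k/K.
#' @examples
#' set.seed(1)
#' f <- simulateDriftLoci(1000, 0.521, 10, 4500, 370)
#' var(f)  # close to modelObservedVariance(0.521, 10, 4500, 370)
#' @export
simulateDriftLoci <- function(nLoci, p0, T, Ne, K) {
    stopifnot(nLoci >= 1, p0 > 0, p0 < 1, T >= 0, Ne > 1, K >= 1)
    p <- rep(p0, nLoci)
    for (t in seq_len(T)) p <- rbinom(nLoci, 2 * Ne, p) / (2 * Ne)
    rbinom(nLoci, K, p) / K
}
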