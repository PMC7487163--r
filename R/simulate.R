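#' Forward Wright-Fisher simulation of ancestry tracts
#'
#' Simulates a single pulse of admixture followed by T generations of
#' neutral random mating in a population of Ne diploids, tracking ancestry
#' tracts (not per-SNP states) so large Ne and many chromosomes stay cheap.
#' Generation 0 consists of 2 Ne founder haplotypes, each a single-ancestry
#' genome with ancestry drawn i.i.d. from the configured proportions. Each
#' later generation is formed by Wright-Fisher resampling: every offspring
#' picks two parents uniformly with replacement (one from each sex pool in
#' two-sex mode) and receives one recombinant gamete from each. Crossovers
#' per chromosome are Poisson(length in Morgans) with uniform breakpoints
#' and no interference. After T generations, nSample diploids are drawn
#' without replacement. Output is bit-identical for a fixed seed.
#'
#' @param config An \code{\link{admixtureConfig}}.
#' @param genome A \code{\link{genomeModel}}.
#' @param seed Integer seed.
#' @return A \code{\link{SimulatedSample}}.
#' @examples
#' cfg <- admixtureConfig(T = 2, Ne = 50, nSample = 10)
#' sim <- simulatePopulation(cfg, genomeModel(rep(0.2, 4)), seed = 1)
#' realizedProportions(sim)
#' @export
simulatePopulation <- function(config, genome, seed) {
    stopifnot(is(config, "AdmixtureConfig"), is(genome, "GenomeModel"))
    validObject(config)
    validObject(genome)
    set.seed(seed)
    ch <- genome@chroms
    res <- .wf_simulate(ch$length_M, unname(config@proportions),
                        config@Ne, config@T, config@nSample,
                        config@mating == "two_sex", config@nFemale)
    realized <- res$founder_count / (2 * config@Ne)
    names(realized) <- names(config@proportions)
    sex <- if (config@mating == "two_sex")
        ifelse(res$chosen < config@nFemale, "F", "M") else character()
    new("SimulatedSample", ends = res$ends, anc = res$anc, off = res$off,
        nHap = res$n_hap, config = config, genome = genome,
        realizedProportions = realized,
        sampleIds = paste0("sim", seq_len(config@nSample)), sex = sex)
}

#' @describeIn SimulatedSample-class Tract table of sampled haplotypes:
#'   columns \code{haplotype}, \code{chrom}, \code{start_M}, \code{end_M},
#'   \code{ancestry} (code). Tracts tile each chromosome exactly and
#'   adjacent tracts differ in ancestry.
#' @param which Optional haplotype indices to extract.
#' @param ... Unused.
#' @export
setMethod("tracts", "SimulatedSample", function(x, which = NULL, ...) {
    nChrom <- nrow(x@genome@chroms)
    if (is.null(which)) which <- seq_len(x@nHap)
    out <- vector("list", length(which))
    for (k in seq_along(which)) {
        h <- which[k]
        rows <- list()
        for (c in seq_len(nChrom)) {
            lo <- x@off[(h - 1L) * nChrom + c] + 1L
            hi <- x@off[(h - 1L) * nChrom + c + 1L]
            e <- x@ends[lo:hi]
            rows[[c]] <- data.frame(
                haplotype = h, chrom = x@genome@chroms$name[c],
                start_M = c(0, e[-length(e)]), end_M = e,
                ancestry = x@anc[lo:hi])
        }
        out[[k]] <- do.call(rbind, rows)
    }
    do.call(rbind, out)
})

#' Single meiosis on tract genomes
#'
#' Produces one recombinant gamete from two parental tract genomes given as
#' tables in the format returned by \code{\link{tracts}} (columns
#' \code{chrom}, \code{start_M}, \code{end_M}, \code{ancestry}). Uses the
#' current R random number stream. Crossover count per chromosome is
#' Poisson(length_M), breakpoints uniform, starting haplotype a fair coin;
#' adjacent same-ancestry tracts in the gamete are merged.
#'
#' @param hapA,hapB Parental tract tables covering every chromosome of
#'   \code{genome}.
#' @param genome A \code{GenomeModel}.
#' @return A tract table for the gamete.
#' @export
meiosis <- function(hapA, hapB, genome) {
    stopifnot(is(genome, "GenomeModel"))
    ch <- genome@chroms
    flat <- function(h) {
        ends <- numeric(0); anc <- integer(0); off <- integer(nrow(ch) + 1L)
        for (c in seq_len(nrow(ch))) {
            t <- h[h$chrom == ch$name[c], , drop = FALSE]
            if (!nrow(t))
                stop("haplotype has no tracts on chromosome ", ch$name[c])
            t <- t[order(t$start_M), ]
            if (abs(t$end_M[nrow(t)] - ch$length_M[c]) > 1e-12 ||
                t$start_M[1] != 0 ||
                any(abs(t$start_M[-1] - t$end_M[-nrow(t)]) > 1e-12))
                stop("tracts must tile [0, length_M) on chromosome ",
                     ch$name[c])
            ends <- c(ends, t$end_M); anc <- c(anc, as.integer(t$ancestry))
            off[c + 1L] <- length(ends)
        }
        list(ends = ends, anc = anc, off = off)
    }
    a <- flat(hapA); b <- flat(hapB)
    res <- .meiosis_one(a$ends, a$anc, a$off, b$ends, b$anc, b$off,
                        ch$length_M)
    nChrom <- nrow(ch)
    rows <- vector("list", nChrom)
    for (c in seq_len(nChrom)) {
        lo <- res$off[c] + 1L; hi <- res$off[c + 1L]
        e <- res$ends[lo:hi]
        rows[[c]] <- data.frame(chrom = ch$name[c],
                                start_M = c(0, e[-length(e)]), end_M = e,
                                ancestry = res$anc[lo:hi])
    }
    do.call(rbind, rows)
}

#' Project simulated tracts onto SNP positions
#'
#' Assigns each haplotype x SNP cell the ancestry of the tract whose
#' half-open interval [start, end) contains the SNP's genetic position (a
#' SNP exactly at a junction takes the right-hand tract; a SNP at the
#' chromosome's full genetic length takes the last tract). This reproduces
#' the spatial autocorrelation of real local-ancestry data at the mapped SNP
#' density.
#'
#' @param sample A \code{\link{SimulatedSample}}.
#' @param snpMap SNP map with \code{gpos_M} filled (see
#'   \code{\link{physicalToGenetic}}).
#' @return An \code{\link{AncestryCalls}} object with the simulator's label
#'   set.
#' @export
projectTractsToSnps <- function(sample, snpMap) {
    stopifnot(is(sample, "SimulatedSample"))
    validateSnpMap(snpMap)
    if (anyNA(snpMap$gpos_M))
        stop("snpMap must have gpos_M filled (see physicalToGenetic)")
    ch <- sample@genome@chroms
    ci <- match(snpMap$chrom, ch$name)
    if (anyNA(ci)) stop("SNP chromosome not present in simulated genome")
    if (any(snpMap$gpos_M > ch$length_M[ci] + 1e-12))
        stop("gpos_M exceeds chromosome genetic length")
    ord <- order(ci, snpMap$gpos_M)
    snpOff <- c(0L, cumsum(tabulate(ci, nbins = nrow(ch))))
    m <- .project_tracts(sample@ends, sample@anc, sample@off, sample@nHap,
                         nrow(ch), snpMap$gpos_M[ord], snpOff)
    m <- m[, order(ord), drop = FALSE]  # back to map column order
    labels <- structure(seq_along(sample@config@proportions) - 1L,
                        names = names(sample@config@proportions))
    ancestryCalls(m, snpMap, labels, sampleIds = sample@sampleIds,
                  sex = sample@sex)
}

#' Junction counts per haplotype
#'
#' Number of ancestry switches (junctions) along each sampled haplotype,
#' summed over chromosomes. Useful for checking recombination behaviour:
#' for T generations since admixture with founding proportions a, the
#' expected junction count per haplotype is close to
#' L_total * T * (1 - sum(a^2)) when T is much smaller than Ne.
#'
#' @param sample A \code{\link{SimulatedSample}}.
#' @return Integer vector, one count per haplotype.
#' @export
junctionCounts <- function(sample) {
    stopifnot(is(sample, "SimulatedSample"))
    nChrom <- nrow(sample@genome@chroms)
    nTracts <- diff(sample@off)
    perHap <- matrix(nTracts, nrow = nChrom)
    as.integer(colSums(perHap - 1L))
}

#' Length-weighted ancestry proportions of a simulated sample
#'
#' @param sample A \code{\link{SimulatedSample}}.
#' @return Named numeric vector over the configured ancestry labels.
#' @export
ancestryProportions <- function(sample) {
    stopifnot(is(sample, "SimulatedSample"))
    first <- sample@off[-length(sample@off)] + 1L
    len <- sample@ends
    prev <- c(0, sample@ends[-length(sample@ends)])
    prev[first] <- 0
    w <- len - prev
    tot <- tapply(w, factor(sample@anc,
                            levels = seq_along(sample@config@proportions) - 1L),
                  sum, default = 0)
    out <- as.numeric(tot) / sum(w)
    names(out) <- names(sample@config@proportions)
    out
}

#' Independent replicate seeds
#'
#' Derives n child seeds from one master seed by seeding R's RNG with the
#' master and drawing n integers without replacement from 1..(2^31 - 2).
#' This is the splitting rule used by every replicated computation in the
#' package, so a batch is reproducible from its master seed alone.
#'
#' @param seed Master integer seed.
#' @param n Number of replicate seeds.
#' @return Integer vector of length n.
#' @export
replicateSeeds <- function(seed, n) {
    set.seed(seed)
    sample.int(2147483646L, n)
}
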