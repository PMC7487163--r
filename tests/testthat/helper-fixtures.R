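# Small programmatic fixtures shared across test files.

makeSnpMap <- function(nSnps, chrom = "1", gpos = NULL) {
    data.frame(snp_id = sprintf("s%03d", seq_len(nSnps)),
               chrom = rep(chrom, length.out = nSnps),
               pos_bp = as.integer(seq_len(nSnps) * 1000L),
               gpos_M = if (is.null(gpos)) rep(NA_real_, nSnps) else gpos,
               stringsAsFactors = FALSE)
}

randomCalls <- function(nHap, nSnps, nAnc = 3, seed = 1) {
    set.seed(seed)
    m <- matrix(sample.int(nAnc, nHap * nSnps, replace = TRUE) - 1L,
                nHap, nSnps)
    labs <- ancestryLabels(c("EUR", "NAM", "AFR")[seq_len(nAnc)])
    ancestryCalls(m, makeSnpMap(nSnps), labs)
}

# i.i.d. Bernoulli(p0) EUR calls: the null model of the scan's calibration
nullCalls <- function(nHap, nSnps, p0, seed = 1) {
    set.seed(seed)
    m <- matrix(as.integer(runif(nHap * nSnps) > p0), nHap, nSnps)
    ancestryCalls(m, makeSnpMap(nSnps), ancestryLabels(c("EUR", "NAM")))
}

# one-tract haplotype table covering a genome, single ancestry
constantHap <- function(genome, ancestry = 0L) {
    ch <- genome@chroms
    data.frame(chrom = ch$name, start_M = 0, end_M = ch$length_M,
               ancestry = ancestry)
}
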