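#' Genome-wide mean local ancestry
#'
#' Mean over all haplotype x SNP cells of the indicator of the target
#' ancestry; the null proportion of the deviation scan when \code{p0 =
#' "auto"}. Equals the unweighted mean of the per-SNP ancestry fractions.
#'
#' @param x An \code{\link{AncestryCalls}} object.
#' @param targetLabel Ancestry name.
#' @return A scalar in [0, 1].
#' @export
genomeWideMean <- function(x, targetLabel = "EUR") {
    stopifnot(is(x, "AncestryCalls"))
    if (!targetLabel %in% names(x@labels))
        stop("unknown ancestry label: ", targetLabel)
    if (!length(x@calls)) stop("empty call matrix")
    mean(x@calls == x@labels[[targetLabel]])
}

#' Per-SNP mean local ancestry
#'
#' The maximum-likelihood estimate of the target-ancestry proportion at each
#' SNP: the fraction of the K sampled haplotypes carrying that ancestry.
#'
#' @inheritParams genomeWideMean
#' @return Numeric vector of length nSnps, named by snp id.
#' @export
snpMeanAncestry <- function(x, targetLabel = "EUR") {
    stopifnot(is(x, "AncestryCalls"))
    if (!targetLabel %in% names(x@labels))
        stop("unknown ancestry label: ", targetLabel)
    p <- colMeans(x@calls == x@labels[[targetLabel]])
    names(p) <- x@snpMap$snp_id
    p
}

#' Ancestry deviation test
#'
#' Tests H0: p = p0 against an excess (default), deficit, or two-sided
#' alternative for binomially sampled ancestry fractions, using binomial MLE
#' asymptotics. The default \code{"score"} statistic standardizes by the
#' null standard error sqrt(p0 (1 - p0) / K) and uses a normal reference;
#' \code{"wald"} standardizes by the estimated standard error (falling back
#' to the null SE, with a warning, at p_hat of exactly 0 or 1 where the
#' Wald SE is degenerate); \code{"t"} uses the score statistic with a
#' Student reference on K - 1 degrees of freedom. At K = 370 haplotypes the
#' three variants agree to displayed precision. P-values are clamped to the
#' smallest positive representable double so downstream logs stay finite.
#'
#' @param pHat Numeric vector of observed ancestry fractions.
#' @param K Number of haplotypes (even, >= 2).
#' @param p0 Null proportion in (0, 1).
#' @param tail \code{"upper"}, \code{"lower"} or \code{"two_sided"}.
#' @param statistic \code{"score"}, \code{"wald"} or \code{"t"}.
#' @return data.frame with columns \code{z} and \code{p_value}.
#' @examples
#' deviationTest(0.6516, K = 370, p0 = 0.521)   # z ~ 5.03, p ~ 2.5e-7
#' @export
deviationTest <- function(pHat, K, p0,
                          tail = c("upper", "lower", "two_sided"),
                          statistic = c("score", "wald", "t")) {
    tail <- match.arg(tail)
    statistic <- match.arg(statistic)
    stopifnot(K >= 2, K %% 2 == 0, p0 > 0, p0 < 1,
              all(pHat >= 0), all(pHat <= 1))
    se0 <- sqrt(p0 * (1 - p0) / K)
    if (statistic == "wald") {
        se <- sqrt(pHat * (1 - pHat) / K)
        degen <- se == 0
        if (any(degen)) {
            warning("Wald SE degenerate at p_hat of 0 or 1 for ",
                    sum(degen), " SNP(s); using the null SE there")
            se[degen] <- se0
        }
    } else se <- se0
    z <- (pHat - p0) / se
    p <- switch(tail,
                upper = if (statistic == "t") pt(z, K - 1, lower.tail = FALSE)
                        else pnorm(z, lower.tail = FALSE),
                lower = if (statistic == "t") pt(z, K - 1)
                        else pnorm(z),
                two_sided = 2 * (if (statistic == "t")
                    pt(abs(z), K - 1, lower.tail = FALSE)
                    else pnorm(abs(z), lower.tail = FALSE)))
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
    data.frame(z = z, p_value = p)
}

#' Run the local-ancestry deviation scan
#'
#' Tests every SNP for an excess of the target ancestry over the
#' genome-wide mean and flags SNPs below the significance threshold. With
#' \code{p0 = "auto"} (default) the null proportion is the realized
#' genome-wide mean of the input, mirroring how a scan treats real data; a
#' numeric \code{p0} fixes it instead. The default threshold 1e-5 is the
#' genome-wide cutoff recommended for recently admixed populations; no
#' additional multiple-testing correction is applied — extremeness is
#' instead calibrated against neutral simulation
#' (\code{\link{runNullReplicates}}).
#'
#' @param x An \code{\link{AncestryCalls}} object.
#' @param targetLabel Ancestry tested for excess (default \code{"EUR"}).
#' @param p0 \code{"auto"} or a numeric null proportion in (0, 1).
#' @param tail,statistic Passed to \code{\link{deviationTest}}.
#' @param alpha Significance threshold (default 1e-5).
#' @return A \code{\link{ScanResult}}.
#' @examples
#' map <- data.frame(snp_id = c("a", "b"), chrom = "1",
#'                   pos_bp = c(1L, 2L), gpos_M = NA_real_)
#' m <- matrix(c(0L, 0L, 0L, 1L), 2, 2)
#' runScan(ancestryCalls(m, map), p0 = 0.5, alpha = 0.05)
#' @export
runScan <- function(x, targetLabel = "EUR", p0 = "auto",
                    tail = "upper", statistic = "score", alpha = 1e-5) {
    stopifnot(is(x, "AncestryCalls"), alpha > 0, alpha < 1)
    p0Used <- if (identical(p0, "auto"))
        genomeWideMean(x, targetLabel) else as.numeric(p0)
    stopifnot(p0Used > 0, p0Used < 1)
    pHat <- snpMeanAncestry(x, targetLabel)
    K <- nrow(x@calls)
    t <- deviationTest(pHat, K, p0Used, tail, statistic)
    tab <- data.frame(snp_id = x@snpMap$snp_id, chrom = x@snpMap$chrom,
                      pos_bp = x@snpMap$pos_bp, p_hat = unname(pHat),
                      z = t$z, p_value = t$p_value,
                      significant = t$p_value < alpha,
                      stringsAsFactors = FALSE)
    new("ScanResult", table = tab, targetLabel = targetLabel,
        p0Used = p0Used, K = as.integer(K), alpha = alpha,
        statistic = statistic, tail = tail)
}

#' Group significant SNPs into regions
#'
#' Clusters significant SNPs on the same chromosome whose consecutive
#' positions are at most \code{maxGapBp} apart into maximal runs.
#'
#' @param scan A \code{\link{ScanResult}}.
#' @param maxGapBp Maximum gap (bp) between consecutive significant SNPs in
#'   one region (default 500 kb).
#' @return data.frame with columns \code{chrom}, \code{start_bp},
#'   \code{end_bp}, \code{n_snps}, \code{min_p}; zero rows if nothing is
#'   significant.
#' @export
significantRegions <- function(scan, maxGapBp = 5e5) {
    stopifnot(is(scan, "ScanResult"))
    sig <- scan@table[scan@table$significant, , drop = FALSE]
    empty <- data.frame(chrom = character(), start_bp = integer(),
                        end_bp = integer(), n_snps = integer(),
                        min_p = numeric(), stringsAsFactors = FALSE)
    if (!nrow(sig)) return(empty)
    sig <- sig[order(sig$chrom, sig$pos_bp), ]
    newRegion <- c(TRUE, sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                       diff(sig$pos_bp) > maxGapBp)
    id <- cumsum(newRegion)
    do.call(rbind, lapply(split(sig, id), function(g) data.frame(
        chrom = g$chrom[1], start_bp = min(g$pos_bp),
        end_bp = max(g$pos_bp), n_snps = nrow(g), min_p = min(g$p_value),
        stringsAsFactors = FALSE)))
}

#' Manhattan-style scan plot
#'
#' Two stacked tracks over concatenated chromosomes: per-SNP target-ancestry
#' mean with the genome-wide mean as a horizontal line, and -log10 p-values
#' with the significance threshold as a dashed line.
#'
#' @param scan A \code{\link{ScanResult}}.
#' @return Invisibly, the plotting coordinates.
#' @export
plotScan <- function(scan) {
    stopifnot(is(scan, "ScanResult"))
    tab <- scan@table
    chrom <- factor(tab$chrom, levels = unique(tab$chrom))
    off <- c(0, cumsum(tapply(tab$pos_bp, chrom, max)))
    xpos <- tab$pos_bp + off[as.integer(chrom)]
    col <- c("grey30", "grey60")[1 + as.integer(chrom) %% 2]
    op <- par(mfrow = c(2, 1), mar = c(2.5, 4, 1, 1))
    on.exit(par(op))
    plot(xpos, tab$p_hat, pch = 16, cex = 0.3, col = col, xaxt = "n",
         xlab = "", ylab = paste0("mean ", scan@targetLabel, " ancestry"))
    abline(h = scan@p0Used)
    plot(xpos, -log10(tab$p_value), pch = 16, cex = 0.3, col = col,
         xaxt = "n", xlab = "concatenated chromosomes",
         ylab = expression(-log[10] * italic(P)))
    abline(h = -log10(scan@alpha), lty = 2)
    invisible(data.frame(x = xpos, p_hat = tab$p_hat,
                         mlogp = -log10(tab$p_value)))
}
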