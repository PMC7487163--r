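#' Neutral-null replicates of the deviation scan
#'
#' Repeats the full pipeline under neutrality: forward-simulate the admixed
#' population, project tracts onto the SNP map, scan for target-ancestry
#' excess, and record the SNP with the largest deviation and its p-value.
#' The collection of per-replicate extreme p-values is the null
#' distribution of the scan's most extreme signal under genetic drift
#' alone; an observed peak below every neutral extreme cannot be explained
#' by drift. Replicate seeds derive from the master seed via
#' \code{\link{replicateSeeds}}, so results are reproducible and invariant
#' to the order replicates run in.
#'
#' @param config An \code{\link{admixtureConfig}}.
#' @param genome A \code{\link{genomeModel}}.
#' @param snpMap SNP map with \code{gpos_M} filled.
#' @param nReplicates Number of neutral replicates (>= 1).
#' @param seed Master seed.
#' @param targetLabel Ancestry scanned for excess.
#' @param p0 \code{"auto"} (each replicate uses its own realized genome-wide
#'   mean, mirroring how real data are scanned) or a fixed numeric value.
#' @param alpha Scan threshold.
#' @param statistic Test variant, see \code{\link{deviationTest}}.
#' @param deviation \code{"signed"} (maximal excess p_hat - p0, matching
#'   the upper-tailed test) or \code{"absolute"}.
#' @return A \code{\link{NullSummary}}.
#' @export
runNullReplicates <- function(config, genome, snpMap, nReplicates = 20,
                              seed = 1L, targetLabel = "EUR", p0 = "auto",
                              alpha = 1e-5, statistic = "score",
                              deviation = c("signed", "absolute")) {
    deviation <- match.arg(deviation)
    if (nReplicates < 1) stop("need at least 1 replicate")
    seeds <- replicateSeeds(seed, nReplicates)
    rows <- vector("list", nReplicates)
    for (r in seq_len(nReplicates)) {
        rec <- tryCatch({
            sim <- simulatePopulation(config, genome, seeds[r])
            ac <- projectTractsToSnps(sim, snpMap)
            sc <- runScan(ac, targetLabel, p0 = p0, tail = "upper",
                          statistic = statistic, alpha = alpha)
            tab <- scanTable(sc)
            dev <- tab$p_hat - p0Used(sc)
            i <- if (deviation == "absolute") which.max(abs(dev))
                 else which.max(dev)
            data.frame(replicate = r, seed = seeds[r],
                       snp_id = tab$snp_id[i], p_hat = tab$p_hat[i],
                       p0 = p0Used(sc), z = tab$z[i],
                       p_value = tab$p_value[i], stringsAsFactors = FALSE)
        }, error = function(e)
            stop("replicate ", r, " (seed ", seeds[r], ") failed: ",
                 conditionMessage(e)))
        rows[[r]] <- rec
    }
    reps <- do.call(rbind, rows)
    new("NullSummary", replicates = reps, alpha = alpha,
        minP = min(reps$p_value), anyBelowAlpha = any(reps$p_value < alpha))
}

#' Chance that the minimum of n uniform p-values falls below x
#'
#' Closed form 1 - (1 - x)^n for n independent tests; an analytic yardstick
#' for the replicate engine when drift is negligible and per-SNP p-values
#' are approximately independent uniforms.
#'
#' @param nTests Number of independent tests (>= 1).
#' @param x Threshold in (0, 1].
#' @return The probability.
#' @examples
#' expectedMinP(100, 0.01)   # 0.634
#' @export
expectedMinP <- function(nTests, x) {
    stopifnot(nTests >= 1, x > 0, x <= 1)
    1 - (1 - x)^nTests
}

#' Compare an observed scan extreme with the neutral null
#'
#' States (i) whether any neutral replicate's max-deviation p-value
#' breached the significance threshold, and (ii) whether the observed
#' minimum p-value lies below every neutral extreme. An observed peak that
#' beats every neutral replicate while no replicate breaches the threshold
#' is evidence that the peak exceeds what drift can produce.
#'
#' @param nullSummary A \code{\link{NullSummary}}.
#' @param observedMinP Minimum p-value of an observed (real or synthetic)
#'   scan.
#' @return list with fields \code{any_null_below_alpha},
#'   \code{observed_below_all_null}, \code{alpha}, \code{null_min_p},
#'   \code{observed_min_p}, \code{n_replicates} and a one-line
#'   \code{verdict} string; suitable for JSON serialization.
#' @export
compareToThreshold <- function(nullSummary, observedMinP) {
    stopifnot(is(nullSummary, "NullSummary"))
    if (!nrow(nullSummary@replicates)) stop("empty null summary")
    stopifnot(is.numeric(observedMinP), length(observedMinP) == 1,
              observedMinP > 0, observedMinP <= 1)
    below <- observedMinP < min(nullSummary@replicates$p_value)
    list(any_null_below_alpha = nullSummary@anyBelowAlpha,
         observed_below_all_null = below,
         alpha = nullSummary@alpha,
         null_min_p = nullSummary@minP,
         observed_min_p = observedMinP,
         n_replicates = nrow(nullSummary@replicates),
         verdict = if (below && !nullSummary@anyBelowAlpha)
             "exceeds neutral null" else "consistent with drift")
}
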