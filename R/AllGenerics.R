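#' @rdname AncestryCalls-class
#' @param object,x An object.
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname AncestryCalls-class
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))

#' @rdname AncestryCalls-class
#' @export
setGeneric("labelSet", function(x) standardGeneric("labelSet"))

#' @rdname AncestryCalls-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname AncestryCalls-class
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' @rdname AncestryCalls-class
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname SimulatedSample-class
#' @param x An object.
#' @export
setGeneric("tracts", function(x, ...) standardGeneric("tracts"))

#' @rdname SimulatedSample-class
#' @export
setGeneric("realizedProportions",
           function(x) standardGeneric("realizedProportions"))

#' @rdname ScanResult-class
#' @param x An object.
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))

#' @rdname ScanResult-class
#' @export
setGeneric("p0Used", function(x) standardGeneric("p0Used"))

#' @rdname ScanResult-class
#' @export
setGeneric("nSignificant", function(x) standardGeneric("nSignificant"))

#' @rdname NullSummary-class
#' @param x An object.
#' @export
setGeneric("replicateTable", function(x) standardGeneric("replicateTable"))

#' @rdname NullSummary-class
#' @export
setGeneric("minPValue", function(x) standardGeneric("minPValue"))

#' Accessors
#'
#' @name accessors
#' @keywords internal
NULL

#' @rdname AncestryCalls-class
#' @export
setMethod("calls", "AncestryCalls", function(x) x@calls)

#' @rdname AncestryCalls-class
#' @export
setMethod("snpMap", "AncestryCalls", function(x) x@snpMap)

#' @rdname AncestryCalls-class
#' @export
setMethod("labelSet", "AncestryCalls", function(x) x@labels)

#' @rdname AncestryCalls-class
#' @export
setMethod("sampleIds", "AncestryCalls", function(x) x@sampleIds)

#' @rdname AncestryCalls-class
#' @export
setMethod("nHaplotypes", "AncestryCalls", function(x) nrow(x@calls))

#' @rdname AncestryCalls-class
#' @export
setMethod("nSnps", "AncestryCalls", function(x) ncol(x@calls))

#' @rdname AncestryCalls-class
#' @export
setMethod("show", "AncestryCalls", function(object) {
    cat("AncestryCalls:", nrow(object@calls), "haplotypes (",
        length(object@sampleIds), "diploids ) x", ncol(object@calls),
        "SNPs\n  labels:",
        paste(names(object@labels), unname(object@labels), sep = "=",
              collapse = " "),
        "\n  chromosomes:", length(unique(object@snpMap$chrom)), "\n")
})

#' @rdname SimulatedSample-class
#' @export
setMethod("realizedProportions", "SimulatedSample",
          function(x) x@realizedProportions)

#' @rdname SimulatedSample-class
#' @export
setMethod("nHaplotypes", "SimulatedSample", function(x) x@nHap)

#' @rdname SimulatedSample-class
#' @export
setMethod("show", "SimulatedSample", function(object) {
    cfg <- object@config
    cat("SimulatedSample:", object@nHap, "haplotypes on",
        nrow(object@genome@chroms), "chromosomes\n  pulse",
        cfg@T, "generations ago, Ne =", cfg@Ne, ", mating:", cfg@mating,
        "\n  founder proportions (realized):",
        paste(names(object@realizedProportions),
              sprintf("%.3f", object@realizedProportions), sep = "=",
              collapse = " "), "\n")
})

#' @rdname ScanResult-class
#' @export
setMethod("scanTable", "ScanResult", function(x) x@table)

#' @rdname ScanResult-class
#' @export
setMethod("p0Used", "ScanResult", function(x) x@p0Used)

#' @rdname ScanResult-class
#' @export
setMethod("nSignificant", "ScanResult", function(x) sum(x@table$significant))

#' @rdname ScanResult-class
#' @export
setMethod("show", "ScanResult", function(object) {
    tab <- object@table
    cat("ScanResult:", nrow(tab), "SNPs,", object@K, "haplotypes\n",
        " target", object@targetLabel, "excess vs p0 =",
        format(object@p0Used, digits = 4), "(", object@statistic, ",",
        object@tail, "tail )\n  significant at alpha =", object@alpha, ":",
        sum(tab$significant), "SNPs\n")
    if (any(tab$significant)) {
        top <- tab[which.min(tab$p_value), ]
        cat("  top hit:", top$snp_id, "chrom", top$chrom, "p_hat =",
            format(top$p_hat, digits = 4), "p =",
            format(top$p_value, digits = 3), "\n")
    }
})

#' @rdname NullSummary-class
#' @export
setMethod("replicateTable", "NullSummary", function(x) x@replicates)

#' @rdname NullSummary-class
#' @export
setMethod("minPValue", "NullSummary", function(x) x@minP)

#' @rdname NullSummary-class
#' @export
setMethod("show", "NullSummary", function(object) {
    cat("NullSummary:", nrow(object@replicates),
        "neutral replicates\n  min max-deviation p-value:",
        format(object@minP, digits = 4), "\n  any below alpha =",
        object@alpha, ":", object@anyBelowAlpha, "\n")
})
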