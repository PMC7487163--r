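#' Ancestry label set
#'
#' Constructs the ordered set of ancestry labels and their integer codes.
#' Codes run 0..(A-1) in label order, matching the LAMP-LD convention where
#' European, Native American and African ancestry are coded 0, 1 and 2.
#'
#' @param labels Character vector of ancestry names, in code order.
#' @return A named integer vector mapping label to code.
#' @examples
#' ancestryLabels()               # EUR=0, NAM=1, AFR=2
#' ancestryLabels(c("A", "B"))
#' @export
ancestryLabels <- function(labels = c("EUR", "NAM", "AFR")) {
    if (!is.character(labels) || length(labels) < 1L || anyDuplicated(labels))
        stop("'labels' must be a non-empty character vector without duplicates")
    structure(seq_along(labels) - 1L, names = labels)
}

.checkLabels <- function(labels) {
    if (!is.integer(labels) || is.null(names(labels)) ||
        anyDuplicated(names(labels)) ||
        !identical(sort(unname(labels)), seq_along(labels) - 1L))
        stop("label set must be a named integer vector with codes 0..(A-1)")
    invisible(labels)
}

#' Validate a SNP map
#'
#' A SNP map is a data.frame with columns \code{snp_id} (unique),
#' \code{chrom}, \code{pos_bp} (1-based physical position, strictly
#' increasing within a chromosome) and \code{gpos_M} (genetic position in
#' Morgans, optionally \code{NA}, non-decreasing within a chromosome).
#'
#' @param map A data.frame to validate.
#' @return The map, invisibly, or an error describing the violation.
#' @export
validateSnpMap <- function(map) {
    need <- c("snp_id", "chrom", "pos_bp", "gpos_M")
    if (!is.data.frame(map) || !all(need %in% names(map)))
        stop("SNP map must be a data.frame with columns ",
             paste(need, collapse = ", "))
    if (anyDuplicated(map$snp_id)) stop("snp_id values must be unique")
    if (any(map$pos_bp < 1L)) stop("pos_bp must be >= 1")
    for (ch in unique(map$chrom)) {
        i <- map$chrom == ch
        p <- map$pos_bp[i]
        if (is.unsorted(p, strictly = TRUE))
            stop("pos_bp must be strictly increasing within chromosome ", ch)
        g <- map$gpos_M[i]
        g <- g[!is.na(g)]
        if (length(g) && is.unsorted(g))
            stop("gpos_M must be non-decreasing within chromosome ", ch)
        if (length(g) && any(g < 0)) stop("gpos_M must be >= 0")
    }
    invisible(map)
}

#' Local-ancestry call matrix
#'
#' Container for per-haplotype, per-SNP ancestry calls from a local-ancestry
#' inference tool such as LAMP-LD, together with the SNP map and label set.
#' Rows are haplotypes (two consecutive rows per diploid individual), columns
#' are SNPs in map order. Missing calls are not supported: post-QC ancestry
#' matrices are complete, and an \code{NA} is treated as a data error.
#'
#' @slot calls Integer matrix, haplotypes x SNPs, of ancestry codes.
#' @slot snpMap SNP map data.frame (see \code{\link{validateSnpMap}}).
#' @slot labels Named integer vector of ancestry codes
#'   (see \code{\link{ancestryLabels}}).
#' @slot sampleIds Character vector of diploid individual ids; haplotypes
#'   2j-1 and 2j belong to individual j.
#' @slot sex Optional per-individual sex labels (metadata only; never used
#'   in computation).
#' @export
setClass("AncestryCalls", representation(
    calls = "matrix",
    snpMap = "data.frame",
    labels = "integer",
    sampleIds = "character",
    sex = "character"
))

setValidity("AncestryCalls", function(object) {
    m <- object@calls
    if (!is.integer(m)) return("calls must be an integer matrix")
    if (anyNA(m)) return("missing ancestry calls are not supported")
    if (nrow(m) %% 2L != 0L) return("haplotype count must be even (2 per individual)")
    if (nrow(m) != 2L * length(object@sampleIds))
        return("need exactly 2 haplotypes per sample id")
    if (ncol(m) != nrow(object@snpMap))
        return("number of call columns must equal SNP map length")
    codes <- unname(object@labels)
    bad <- !(m %in% codes)
    if (any(bad)) return("calls contain codes outside the label set")
    if (length(object@sex) && length(object@sex) != length(object@sampleIds))
        return("sex must have one entry per individual")
    tryCatch({
        validateSnpMap(object@snpMap)
        .checkLabels(object@labels)
        TRUE
    }, error = function(e) conditionMessage(e))
})

#' Construct an AncestryCalls object
#'
#' @param calls Integer matrix of ancestry codes, haplotypes x SNPs.
#' @param snpMap SNP map data.frame; a missing \code{gpos_M} column is added
#'   as \code{NA}.
#' @param labels Label set from \code{\link{ancestryLabels}}.
#' @param sampleIds Individual ids; defaults to \code{ind1..indn}.
#' @param sex Optional per-individual sex labels.
#' @return An \code{AncestryCalls} object.
#' @examples
#' map <- data.frame(snp_id = c("s1", "s2"), chrom = "1",
#'                   pos_bp = c(100L, 200L), gpos_M = NA_real_)
#' ancestryCalls(matrix(0L, 2, 2), map)
#' @export
ancestryCalls <- function(calls, snpMap, labels = ancestryLabels(),
                          sampleIds = NULL, sex = character()) {
    storage.mode(calls) <- "integer"
    if (is.null(snpMap$gpos_M)) snpMap$gpos_M <- NA_real_
    if (is.null(sampleIds))
        sampleIds <- paste0("ind", seq_len(nrow(calls) / 2))
    new("AncestryCalls", calls = calls, snpMap = snpMap,
        labels = labels, sampleIds = as.character(sampleIds), sex = sex)
}

#' Genome model for tract simulation
#'
#' Ordered chromosomes with genetic (Morgans) and physical (bp) lengths.
#'
#' @slot chroms data.frame with columns \code{name}, \code{length_M},
#'   \code{length_bp}.
#' @export
setClass("GenomeModel", representation(chroms = "data.frame"))

setValidity("GenomeModel", function(object) {
    d <- object@chroms
    if (!all(c("name", "length_M", "length_bp") %in% names(d)))
        return("chroms needs columns name, length_M, length_bp")
    if (any(d$length_M <= 0) || any(d$length_bp <= 0))
        return("chromosome lengths must be positive")
    if (anyDuplicated(d$name)) return("chromosome names must be unique")
    TRUE
})

#' Construct a genome model
#'
#' @param lengthM Numeric vector of per-chromosome genetic lengths (Morgans).
#' @param lengthBp Integer vector of physical lengths (bp); defaults to a
#'   uniform 1 cM/Mb map (\code{lengthM * 1e8}).
#' @param names Chromosome names; default \code{"chr1"..}.
#' @return A \code{GenomeModel}.
#' @examples
#' genomeModel(rep(0.2, 4))
#' @export
genomeModel <- function(lengthM, lengthBp = round(lengthM * 1e8),
                        names = paste0("chr", seq_along(lengthM))) {
    new("GenomeModel", chroms = data.frame(
        name = as.character(names), length_M = as.numeric(lengthM),
        length_bp = as.numeric(lengthBp), stringsAsFactors = FALSE))
}

#' Single-pulse admixture scenario
#'
#' Demographic parameters of the neutral simulation: founding admixture
#' proportions, time since the pulse, effective size, and sample size.
#' Defaults are the genome-wide LAMP-LD ancestry means of an admixed Chilean
#' population (EUR 0.521, NAM 0.442, AFR 0.037) with the shortest of the
#' plausible admixture times (T = 10 generations, Ne = 4500 diploids) and a
#' sample of 185 diploids (370 haplotypes).
#'
#' @slot proportions Named numeric, founding proportions (sum to 1).
#' @slot T Integer, generations since the admixture pulse.
#' @slot Ne Integer, constant diploid effective population size.
#' @slot nSample Integer, diploids sampled at generation T.
#' @slot mating \code{"hermaphrodite"} or \code{"two_sex"}.
#' @slot nFemale Integer, females per generation in two-sex mode.
#' @export
setClass("AdmixtureConfig", representation(
    proportions = "numeric", T = "integer", Ne = "integer",
    nSample = "integer", mating = "character", nFemale = "integer"
))

setValidity("AdmixtureConfig", function(object) {
    p <- object@proportions
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9)
        return("proportions must be named, non-negative, and sum to 1")
    if (object@T < 0L) return("T must be >= 0")
    if (object@Ne < 2L) return("Ne must be > 1")
    if (object@nSample < 1L || object@nSample > object@Ne)
        return("need 1 <= nSample <= Ne")
    if (!object@mating %in% c("hermaphrodite", "two_sex"))
        return("mating must be 'hermaphrodite' or 'two_sex'")
    if (object@mating == "two_sex" &&
        (object@nFemale < 1L || object@nFemale >= object@Ne))
        return("two-sex mode needs 0 < nFemale < Ne")
    TRUE
})

#' Construct an admixture scenario
#'
#' @param proportions Named numeric founding proportions; normalized to sum
#'   to 1.
#' @param T Generations since the single admixture pulse.
#' @param Ne Diploid effective population size.
#' @param nSample Diploids sampled at the end.
#' @param mating \code{"hermaphrodite"} (default; selfing allowed) or
#'   \code{"two_sex"}. Sex labels never affect autosomal ancestry; the
#'   two-sex mode exists for demographic fidelity only.
#' @param nFemale Females per generation in two-sex mode (default Ne/2,
#'   an equal-ratio breeding pool).
#' @return An \code{AdmixtureConfig}.
#' @examples
#' admixtureConfig()
#' admixtureConfig(T = 15, Ne = 7000)
#' @export
admixtureConfig <- function(proportions = c(EUR = 0.521, NAM = 0.442,
                                            AFR = 0.037),
                            T = 10, Ne = 4500, nSample = 185,
                            mating = c("hermaphrodite", "two_sex"),
                            nFemale = NULL) {
    mating <- match.arg(mating)
    proportions <- proportions / sum(proportions)
    if (is.null(nFemale)) nFemale <- floor(Ne / 2)
    new("AdmixtureConfig", proportions = proportions, T = as.integer(T),
        Ne = as.integer(Ne), nSample = as.integer(nSample), mating = mating,
        nFemale = as.integer(nFemale))
}

#' Simulated admixed sample
#'
#' Tract genomes of the haplotypes sampled at the end of a forward
#' simulation. Tracts are stored flat (ends, ancestry codes, offsets) for
#' speed; use \code{\link{tracts}} for a per-haplotype interval table and
#' \code{\link{projectTractsToSnps}} to obtain ancestry calls at SNPs.
#'
#' @slot ends,anc,off Flat tract storage (internal layout).
#' @slot nHap Number of sampled haplotypes (2 x nSample).
#' @slot config The \code{AdmixtureConfig} used.
#' @slot genome The \code{GenomeModel} used.
#' @slot realizedProportions Realized founder-haplotype ancestry fractions.
#' @slot sampleIds Ids of the sampled diploids.
#' @slot sex Sex labels of the sampled diploids (two-sex mode) or empty.
#' @export
setClass("SimulatedSample", representation(
    ends = "numeric", anc = "integer", off = "integer", nHap = "integer",
    config = "AdmixtureConfig", genome = "GenomeModel",
    realizedProportions = "numeric", sampleIds = "character",
    sex = "character"
))

#' Per-SNP ancestry deviation scan result
#'
#' @slot table data.frame with one row per SNP: \code{snp_id}, \code{chrom},
#'   \code{pos_bp}, \code{p_hat}, \code{z}, \code{p_value},
#'   \code{significant}.
#' @slot targetLabel Ancestry tested for excess.
#' @slot p0Used Null proportion actually used.
#' @slot K Number of haplotypes.
#' @slot alpha Significance threshold.
#' @slot statistic,tail Test variant used.
#' @export
setClass("ScanResult", representation(
    table = "data.frame", targetLabel = "character", p0Used = "numeric",
    K = "integer", alpha = "numeric", statistic = "character",
    tail = "character"
))

#' Neutral-null replicate summary
#'
#' Per-replicate record of the SNP with the largest ancestry deviation in a
#' neutral forward simulation, and the resulting genome-wide verdict.
#'
#' @slot replicates data.frame with one row per replicate: \code{replicate},
#'   \code{seed}, \code{snp_id}, \code{p_hat}, \code{p0}, \code{z},
#'   \code{p_value}.
#' @slot alpha Threshold the scan uses.
#' @slot minP Minimum max-deviation p-value across replicates.
#' @slot anyBelowAlpha TRUE if any replicate breached alpha.
#' @export
setClass("NullSummary", representation(
    replicates = "data.frame", alpha = "numeric", minP = "numeric",
    anyBelowAlpha = "logical"
))
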