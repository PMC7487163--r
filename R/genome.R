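#' Default simulation genome and SNP map
#'
#' Builds the default scan genome: 189 chromosomes of 0.2 Morgans each
#' (total 37.8 M, close to the human autosomal map) on a uniform 1 cM/Mb
#' physical scale, with \code{nSnps} SNP positions drawn uniformly over the
#' physical genome and projected to genetic coordinates. A literal
#' 20-Morgan-per-chromosome genome is available via \code{chromMorgans}.
#'
#' @param nSnps Number of SNP positions to draw (>= 1).
#' @param seed Integer seed; the map is deterministic given the seed.
#' @param nChrom Number of chromosomes (default 189).
#' @param chromMorgans Genetic length per chromosome in Morgans (default
#'   0.2).
#' @return A list with elements \code{genome} (a \code{GenomeModel}) and
#'   \code{snpMap} (a SNP map with \code{gpos_M} filled).
#' @examples
#' g <- defaultGenome(1000, seed = 1)
#' nrow(g$snpMap)
#' @export
defaultGenome <- function(nSnps, seed = 1L, nChrom = 189L,
                          chromMorgans = 0.2) {
    stopifnot(nSnps >= 1, nChrom >= 1, chromMorgans > 0)
    genome <- genomeModel(rep(chromMorgans, nChrom))
    set.seed(seed)
    ch <- genome@chroms
    tot <- sum(ch$length_bp)
    repeat {
        g <- runif(nSnps, 0, tot)
        cumBp <- cumsum(ch$length_bp)
        ci <- findInterval(g, c(0, cumBp), rightmost.closed = TRUE)
        pos <- ceiling(g - c(0, cumBp)[ci])
        pos[pos < 1] <- 1L
        ord <- order(ci, pos)
        ci <- ci[ord]; pos <- pos[ord]
        if (!any(duplicated(cbind(ci, pos)))) break
    }
    map <- data.frame(snp_id = sprintf("snp%06d", seq_len(nSnps)),
                      chrom = ch$name[ci], pos_bp = as.integer(pos),
                      gpos_M = NA_real_, stringsAsFactors = FALSE)
    map <- physicalToGenetic(map, genome)
    list(genome = genome, snpMap = map)
}

#' Project physical to genetic positions
#'
#' Fills \code{gpos_M} by linear scaling within each chromosome
#' (\code{gpos_M = length_M * pos_bp / length_bp}), i.e. a uniform
#' recombination map. Order-preserving by construction.
#'
#' @param snpMap SNP map data.frame.
#' @param genome A \code{GenomeModel} containing every chromosome the map
#'   mentions.
#' @return The map with \code{gpos_M} filled.
#' @export
physicalToGenetic <- function(snpMap, genome) {
    stopifnot(is(genome, "GenomeModel"))
    validateSnpMap(snpMap)
    ch <- genome@chroms
    i <- match(snpMap$chrom, ch$name)
    if (anyNA(i))
        stop("chromosome not in genome model: ",
             snpMap$chrom[which(is.na(i))[1]])
    if (any(snpMap$pos_bp > ch$length_bp[i]))
        stop("pos_bp exceeds chromosome physical length")
    snpMap$gpos_M <- ch$length_M[i] * snpMap$pos_bp / ch$length_bp[i]
    snpMap
}
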