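.FORMAT_VERSION <- "v1"

#' Read a SNP map
#'
#' Reads a 4-column tab-separated SNP map (snp_id, chrom, pos_bp, gpos_M;
#' gpos_M may be NA). Lines starting with '#' are comments.
#'
#' @param path File path.
#' @return A validated SNP map data.frame.
#' @export
readSnpMap <- function(path) {
    map <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      colClasses = c("character", "character", "integer",
                                     "numeric"), stringsAsFactors = FALSE)
    need <- c("snp_id", "chrom", "pos_bp", "gpos_M")
    if (!identical(names(map), need))
        stop("SNP map must have columns ", paste(need, collapse = ", "))
    validateSnpMap(map)
    map
}

#' Write a SNP map
#'
#' @param map SNP map data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSnpMap <- function(map, path) {
    validateSnpMap(map)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# AdmixScan snpmap ", .FORMAT_VERSION), con)
    write.table(map[, c("snp_id", "chrom", "pos_bp", "gpos_M")], con,
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read local-ancestry calls
#'
#' Two on-disk dialects are supported.
#' \describe{
#'   \item{tsv}{A header row (\code{sample_id} then the snp ids), then one
#'     row per haplotype: the individual's id followed by one ancestry code
#'     per SNP. Two consecutive rows with the same id form one diploid.}
#'   \item{lampld}{One line per individual: a whitespace-free string of two
#'     ancestry digits per SNP (first haplotype's digit, then the second's,
#'     SNP by SNP), as produced by LAMP-LD-style tools. The layout carries
#'     no sample ids; default ids \code{ind1..indn} are assigned.}
#' }
#' The dialect is always explicit — the reader never guesses.
#'
#' @param path File path.
#' @param dialect \code{"tsv"} or \code{"lampld"}.
#' @param snpMap SNP map the calls correspond to (column count is checked).
#' @param labels Label set (\code{\link{ancestryLabels}}).
#' @return An \code{\link{AncestryCalls}} object.
#' @export
readAncestryCalls <- function(path, dialect = c("tsv", "lampld"), snpMap,
                              labels = ancestryLabels()) {
    dialect <- match.arg(dialect)
    .checkLabels(labels)
    nSnp <- nrow(snpMap)
    codes <- unname(labels)
    if (dialect == "lampld") {
        lines <- readLines(path)
        lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
        if (!length(lines)) stop("no call lines in ", path)
        mats <- vector("list", length(lines))
        for (li in seq_along(lines)) {
            ch <- strsplit(lines[li], "", fixed = TRUE)[[1]]
            if (length(ch) != 2L * nSnp)
                stop("line ", li, ": expected ", 2L * nSnp,
                     " ancestry digits, found ", length(ch))
            v <- suppressWarnings(as.integer(ch))
            bad <- which(is.na(v) | !(v %in% codes))
            if (length(bad))
                stop("line ", li, ", column ", bad[1],
                     ": invalid ancestry code '", ch[bad[1]], "'")
            mats[[li]] <- rbind(v[seq(1L, 2L * nSnp, by = 2L)],
                                v[seq(2L, 2L * nSnp, by = 2L)])
        }
        m <- do.call(rbind, mats)
        return(ancestryCalls(m, snpMap, labels))
    }
    tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      colClasses = "character", check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (names(tab)[1] != "sample_id")
        stop("tsv dialect: first column must be sample_id")
    if (!identical(names(tab)[-1], snpMap$snp_id))
        stop("tsv dialect: header snp ids do not match the SNP map (",
             ncol(tab) - 1L, " vs ", nSnp, " SNPs)")
    if (nrow(tab) %% 2L != 0L)
        stop("tsv dialect: need an even number of haplotype rows")
    ids <- tab$sample_id
    pair <- matrix(ids, nrow = 2L)
    if (any(pair[1, ] != pair[2, ]))
        stop("tsv dialect: consecutive haplotype rows must share a sample_id")
    raw <- as.matrix(tab[, -1, drop = FALSE])
    m <- suppressWarnings(matrix(as.integer(raw), nrow = nrow(raw)))
    bad <- which(is.na(m) | !(m %in% codes), arr.ind = TRUE)
    if (nrow(bad))
        stop("row ", bad[1, 1], ", column ", bad[1, 2],
             ": invalid ancestry code '", raw[bad[1, 1], bad[1, 2]], "'")
    ancestryCalls(m, snpMap, labels, sampleIds = pair[1, ])
}

#' Write local-ancestry calls
#'
#' Inverse of \code{\link{readAncestryCalls}}: writing then reading with the
#' same dialect reproduces the call matrix exactly (and the sample ids for
#' the tsv dialect; the lampld layout has no id field).
#'
#' @param x An \code{AncestryCalls} object.
#' @param path Output path.
#' @param dialect \code{"tsv"} or \code{"lampld"}.
#' @return \code{path}, invisibly.
#' @export
writeAncestryCalls <- function(x, path, dialect = c("tsv", "lampld")) {
    dialect <- match.arg(dialect)
    stopifnot(is(x, "AncestryCalls"))
    validObject(x)
    m <- x@calls
    if (ncol(m) == 0L || nrow(m) == 0L)
        stop("refusing to write an empty call matrix")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# AdmixScan calls ", .FORMAT_VERSION, " dialect=",
                      dialect), con)
    if (dialect == "lampld") {
        nInd <- nrow(m) / 2L
        for (j in seq_len(nInd)) {
            inter <- rbind(m[2L * j - 1L, ], m[2L * j, ])
            writeLines(paste(inter, collapse = ""), con)
        }
    } else {
        tab <- cbind(sample_id = rep(x@sampleIds, each = 2L),
                     as.data.frame(m))
        names(tab)[-1] <- x@snpMap$snp_id
        write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Target-ancestry dosage matrix
#'
#' Collapses haplotype calls to the per-individual count of target-ancestry
#' alleles: X[j, i] in {0, 1, 2} is the number of haplotypes of individual j
#' carrying the target ancestry at SNP i. Summing dosage matrices over all
#' labels gives the constant 2.
#'
#' @param x An \code{AncestryCalls} object.
#' @param targetLabel Ancestry name to count (default \code{"EUR"}).
#' @return Integer matrix, individuals x SNPs, with sample ids as row names
#'   and snp ids as column names; attribute \code{target} records the label.
#' @examples
#' map <- data.frame(snp_id = "s1", chrom = "1", pos_bp = 1L, gpos_M = NA)
#' ac <- ancestryCalls(matrix(c(0L, 1L), 2, 1), map)
#' dosage(ac, "EUR")  # one EUR allele
#' @export
dosage <- function(x, targetLabel = "EUR") {
    stopifnot(is(x, "AncestryCalls"))
    if (!targetLabel %in% names(x@labels))
        stop("unknown ancestry label: ", targetLabel)
    code <- x@labels[[targetLabel]]
    ind <- (x@calls == code) * 1L
    odd <- seq(1L, nrow(ind), by = 2L)
    X <- ind[odd, , drop = FALSE] + ind[odd + 1L, , drop = FALSE]
    dimnames(X) <- list(x@sampleIds, x@snpMap$snp_id)
    attr(X, "target") <- targetLabel
    X
}
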