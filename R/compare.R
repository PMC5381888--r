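## canonical bin-pair identity keys (coordinates, so tables from separate
## runs on the same locus map are comparable)
.pairKeys <- function(tab) {
    paste(tab$chrom1, tab$start1, tab$chrom2, tab$start2, sep = ":")
}

.checkComparable <- function(tableA, tableB) {
    widthA <- unique(tableA$end1 - tableA$start1)
    widthB <- unique(tableB$end1 - tableB$start1)
    if (length(widthA) > 0L && length(widthB) > 0L &&
        max(widthA) != max(widthB))
        stop("interaction tables use different bin sizes")
    chrsA <- unique(c(tableA$chrom1, tableA$chrom2))
    chrsB <- unique(c(tableB$chrom1, tableB$chrom2))
    if (length(chrsA) && length(chrsB) &&
        length(intersect(chrsA, chrsB)) == 0L)
        stop("interaction tables share no chromosomes")
    invisible(TRUE)
}

## strict within-table ranking: qvalue, then pvalue, then bin identity
.rankOrder <- function(tab, by = c("qvalue", "readCount")) {
    by <- match.arg(by)
    if (by == "qvalue")
        order(tab$qvalue, tab$pvalue, tab$chrom1, tab$start1,
              tab$chrom2, tab$start2)
    else
        order(-tab$readCount, tab$chrom1, tab$start1, tab$chrom2, tab$start2)
}

#' Overlap of significant interactions between two tables
#'
#' Counts interactions flagged significant in each table and the overlap on
#' canonical bin-pair identity. Symmetric in A and B.
#'
#' @param tableA,tableB interaction tables from [callInteractions()] on the
#'   same locus map (same bin size and chromosome set).
#' @return list with `nA`, `nB`, `nOverlap`.
#' @export
overlapSignificant <- function(tableA, tableB) {
    .checkComparable(tableA, tableB)
    keysA <- .pairKeys(tableA[tableA$significant, , drop = FALSE])
    keysB <- .pairKeys(tableB[tableB$significant, , drop = FALSE])
    list(nA = length(keysA), nB = length(keysB),
         nOverlap = length(intersect(keysA, keysB)))
}

#' Rank concordance of interactions between replicates
#'
#' Spearman rank correlation of the two tables' interaction rankings over
#' their common pairs — by default the interactions significant in both
#' tables, matching how replicate agreement is usually assessed. Within each
#' table, interactions are ranked by q-value, ties broken by p-value and then
#' by bin identity; the correlation itself uses average ranks.
#'
#' @param tableA,tableB interaction tables on the same locus map.
#' @param universe pairs to correlate over: `"significant"` in both tables
#'   (default) or all `"common"` pairs present in both tables.
#' @return Spearman's rho, or `NA` (with a warning) when fewer than 2 common
#'   pairs exist.
#' @export
rankConcordance <- function(tableA, tableB,
                            universe = c("significant", "common")) {
    .checkComparable(tableA, tableB)
    universe <- match.arg(universe)
    if (universe == "significant") {
        tableA <- tableA[tableA$significant, , drop = FALSE]
        tableB <- tableB[tableB$significant, , drop = FALSE]
    }
    keysA <- .pairKeys(tableA)
    keysB <- .pairKeys(tableB)
    common <- intersect(keysA, keysB)
    if (length(common) < 2L) {
        warning("fewer than 2 common pairs; rank concordance undefined")
        return(NA_real_)
    }
    rankA <- integer(nrow(tableA)); rankA[.rankOrder(tableA)] <- seq_len(nrow(tableA))
    rankB <- integer(nrow(tableB)); rankB[.rankOrder(tableB)] <- seq_len(nrow(tableB))
    stats::cor(rankA[match(common, keysA)], rankB[match(common, keysB)],
               method = "spearman")
}

#' Top-k overlap curve between two interaction rankings
#'
#' For each k, the fraction of the top-k interactions of A (ranked by
#' q-value, or by raw read count) that also appear in the top-k of B.
#' Symmetric whenever both tables have at least k entries.
#'
#' @param tableA,tableB interaction tables on the same locus map.
#' @param k integer vector of cutoffs; values exceeding either table size
#'   are dropped with a warning.
#' @param rankBy `"qvalue"` (default) or `"readCount"`.
#' @return data.frame with columns `k` and `fraction`.
#' @export
topKOverlap <- function(tableA, tableB, k, rankBy = c("qvalue", "readCount")) {
    .checkComparable(tableA, tableB)
    rankBy <- match.arg(rankBy)
    kmax <- min(nrow(tableA), nrow(tableB))
    if (any(k > kmax)) {
        warning("dropping k values exceeding table size (", kmax, ")")
        k <- k[k <= kmax]
    }
    keysA <- .pairKeys(tableA)[.rankOrder(tableA, rankBy)]
    keysB <- .pairKeys(tableB)[.rankOrder(tableB, rankBy)]
    frac <- vapply(k, function(kk) {
        length(intersect(keysA[seq_len(kk)], keysB[seq_len(kk)])) / kk
    }, numeric(1))
    data.frame(k = as.integer(k), fraction = frac)
}
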