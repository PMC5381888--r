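#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width tileGenome
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlevels "seqlengths<-" "seqlevels<-"
#' @importFrom S4Vectors mcols "mcols<-"
NULL

## contiguity/tiling check shared by LocusMap and FragmentMap validity
.checkTiling <- function(gr, what) {
    sl <- seqlengths(gr)
    if (any(is.na(sl)))
        return(sprintf("%s: seqlengths must be set for all chromosomes", what))
    for (chr in seqlevels(gr)) {
        g <- gr[as.character(seqnames(gr)) == chr]
        if (length(g) == 0L)
            return(sprintf("%s: chromosome %s has no intervals", what, chr))
        s <- start(g); e <- end(g)
        if (is.unsorted(s, strictly = TRUE))
            return(sprintf("%s: intervals on %s not sorted", what, chr))
        if (s[1L] != 1L)
            return(sprintf("%s: first interval on %s does not start at the chromosome start", what, chr))
        if (length(g) > 1L && any(s[-1L] != e[-length(e)] + 1L))
            return(sprintf("%s: intervals on %s are not contiguous", what, chr))
        if (e[length(e)] != sl[[chr]])
            return(sprintf("%s: intervals on %s do not reach the chromosome end", what, chr))
    }
    TRUE
}

#' LocusMap: fixed-width genomic bins
#'
#' Ordered fixed-width bins (the tested loci) tiling each chromosome. All bins
#' have width `binSize` except possibly the last bin of each chromosome, which
#' is truncated at the chromosome end. Bin indices are dense `1..L` in
#' (chromosome order, start) order, with chromosome order taken from the input.
#'
#' @slot bins a [GenomicRanges::GRanges] with seqlengths set, tiling the genome.
#' @slot binSize bin width in base pairs.
#' @seealso [makeBins()], [locusIndex()]
#' @export
setClass("LocusMap",
    representation(bins = "GRanges", binSize = "numeric"),
    validity = function(object) {
        msg <- .checkTiling(object@bins, "LocusMap")
        if (!isTRUE(msg)) return(msg)
        if (length(object@binSize) != 1L || object@binSize <= 0)
            return("binSize must be a single positive number")
        w <- width(object@bins)
        chr <- as.character(seqnames(object@bins))
        last <- !duplicated(chr, fromLast = TRUE)
        if (any(w[!last] != object@binSize))
            return("all non-terminal bins must have width binSize")
        if (any(w[last] > object@binSize))
            return("terminal bins must not exceed binSize")
        TRUE
    })

#' FragmentMap: restriction fragments from in-silico digestion
#'
#' Ordered restriction fragments tiling each chromosome, as produced by
#' cutting at every occurrence of the enzyme recognition motif (offset by
#' `cutOffset` bases into the motif). Fragment indices are dense `1..n` in
#' (chromosome order, start) order.
#'
#' @slot fragments a [GenomicRanges::GRanges] with seqlengths set, tiling the
#'   genome.
#' @slot motif recognition motif (uppercase A/C/G/T).
#' @slot cutOffset 0-based offset of the cut site within the motif.
#' @seealso [digestGenome()]
#' @export
setClass("FragmentMap",
    representation(fragments = "GRanges", motif = "character",
                   cutOffset = "integer"),
    validity = function(object) {
        msg <- .checkTiling(object@fragments, "FragmentMap")
        if (!isTRUE(msg)) return(msg)
        if (!grepl("^[ACGTN]+$", object@motif))
            return("motif must be a non-empty uppercase A/C/G/T string (N = unknown)")
        if (object@cutOffset < 0L || object@cutOffset > nchar(object@motif))
            return("cutOffset must lie within [0, nchar(motif)]")
        TRUE
    })

#' BinnedContacts: sparse symmetric binned contact counts
#'
#' Sparse symmetric counts \eqn{n_{j,h}} of filtered read pairs over canonical
#' bin pairs (j <= h), together with per-bin mapped end counts
#' \eqn{reads_j} and the total filtered pair count N. The identities
#' \eqn{\sum_{j \le h} n_{j,h} = N}, \eqn{reads_j = \sum_{h \ne j} n_{j,h} +
#' 2 n_{j,j}} and \eqn{\sum_j reads_j = 2N} are enforced by the validity
#' method: a self pair contributes both of its ends to the same bin.
#'
#' @slot loci the [LocusMap-class] the counts are binned on.
#' @slot counts data.frame with integer columns `j`, `h` (1-based bin indices,
#'   j <= h) and `count` (> 0), sorted by (j, h).
#' @slot ends numeric vector of per-bin mapped end counts \eqn{reads_j}.
#' @slot N total number of read pairs.
#' @seealso [binContacts()], [computeCoverage()], [callInteractions()]
#' @export
setClass("BinnedContacts",
    representation(loci = "LocusMap", counts = "data.frame", ends = "numeric",
                   N = "numeric"),
    validity = function(object) {
        cnt <- object@counts
        if (!all(c("j", "h", "count") %in% names(cnt)))
            return("counts must have columns j, h, count")
        L <- length(object@loci@bins)
        if (length(object@ends) != L)
            return("ends must have one entry per bin")
        if (nrow(cnt) > 0L) {
            if (any(cnt$j > cnt$h)) return("counts must be canonical (j <= h)")
            if (any(cnt$j < 1L) || any(cnt$h > L))
                return("bin indices out of range")
            if (any(cnt$count <= 0)) return("stored counts must be positive")
            key <- (as.numeric(cnt$j) - 1) * L + cnt$h
            if (is.unsorted(key, strictly = TRUE))
                return("counts must be sorted by (j, h) without duplicates")
        }
        if (sum(cnt$count) != object@N)
            return("sum of counts must equal N")
        ends <- numeric(L)
        if (nrow(cnt) > 0L) {
            agg <- rowsum(c(cnt$count, cnt$count), c(cnt$j, cnt$h))
            ends[as.integer(rownames(agg))] <- agg[, 1L]
        }
        if (!isTRUE(all.equal(ends, unname(object@ends))))
            return("ends inconsistent with counts (reads_j identity violated)")
        TRUE
    })

#' BiasProfile: per-bin coverage bias weights for simulation
#'
#' Normalised per-bin weights \eqn{w_j \ge 0}, \eqn{\sum_j w_j = 1}, used as
#' the categorical end distribution of the random-ligation simulator. The
#' weights emulate the heterogeneous coverage produced by GC content,
#' mappability and restriction-fragment density in real libraries.
#'
#' @slot loci the [LocusMap-class] the weights refer to.
#' @slot weights numeric vector of normalised per-bin weights.
#' @slot shape gamma shape parameter used to generate the weights (NA when the
#'   weights were supplied directly).
#' @slot seed RNG seed used to generate the weights (NA when supplied).
#' @seealso [simulateBiasProfile()], [simulateRandomLigation()]
#' @export
setClass("BiasProfile",
    representation(loci = "LocusMap", weights = "numeric", shape = "numeric",
                   seed = "numeric"),
    validity = function(object) {
        if (length(object@weights) != length(object@loci@bins))
            return("weights must have one entry per bin")
        if (any(object@weights < 0)) return("weights must be non-negative")
        if (abs(sum(object@weights) - 1) > 1e-12)
            return("weights must sum to 1 (within 1e-12)")
        TRUE
    })

#' FilterStats: read-pair filtering tallies
#'
#' Counts of read pairs removed and retained by duplicate removal and the
#' artefact filter. The categories partition the input:
#' `duplicates + sameFragment + proximity + retained = input`, and
#' `cis + trans = retained`.
#'
#' @slot input number of input read pairs.
#' @slot duplicates exact-duplicate pairs removed.
#' @slot sameFragment pairs with both ends on one restriction fragment
#'   (self-ligations) removed.
#' @slot proximity cis pairs closer than the minimum distance removed
#'   (dangling ends, re-ligations, incomplete digestion products).
#' @slot retained pairs kept for analysis.
#' @slot cis retained pairs with both ends on one chromosome.
#' @slot trans retained pairs linking different chromosomes.
#' @seealso [filterArtefacts()]
#' @export
setClass("FilterStats",
    representation(input = "integer", duplicates = "integer",
                   sameFragment = "integer", proximity = "integer",
                   retained = "integer", cis = "integer", trans = "integer"),
    validity = function(object) {
        v <- c(object@duplicates, object@sameFragment, object@proximity,
               object@retained)
        if (any(v < 0L) || object@input < 0L) return("counts must be non-negative")
        if (sum(v) != object@input)
            return("duplicates + sameFragment + proximity + retained must equal input")
        if (object@cis + object@trans != object@retained)
            return("cis + trans must equal retained")
        TRUE
    })

setMethod("show", "LocusMap", function(object) {
    sl <- seqlengths(object@bins)
    cat(sprintf("LocusMap: %d bins of %s bp over %d chromosome(s)\n",
                length(object@bins), format(object@binSize, big.mark = ","),
                length(sl)))
})

setMethod("show", "FragmentMap", function(object) {
    cat(sprintf("FragmentMap: %d fragments (%s, cut offset %d) over %d chromosome(s)\n",
                length(object@fragments), object@motif, object@cutOffset,
                length(seqlengths(object@fragments))))
})

setMethod("show", "BinnedContacts", function(object) {
    cat(sprintf("BinnedContacts: %s pairs over %d bins (%d non-empty bin pairs)\n",
                format(object@N, big.mark = ","), length(object@loci@bins),
                nrow(object@counts)))
})

setMethod("show", "BiasProfile", function(object) {
    w <- object@weights
    cat(sprintf("BiasProfile: %d bins, CV = %.3f (gamma shape %s, seed %s)\n",
                length(w), stats::sd(w) / mean(w),
                format(object@shape), format(object@seed)))
})

setMethod("show", "FilterStats", function(object) {
    cat("Read-pair filtering:\n")
    cat(sprintf("  input pairs       %d\n", object@input))
    cat(sprintf("  duplicates        %d\n", object@duplicates))
    cat(sprintf("  same fragment     %d\n", object@sameFragment))
    cat(sprintf("  < min distance    %d\n", object@proximity))
    cat(sprintf("  retained          %d (cis %d / trans %d)\n",
                object@retained, object@cis, object@trans))
})
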