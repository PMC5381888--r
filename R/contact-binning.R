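## aggregate canonical (j, h) index pairs into a sorted sparse count frame
.aggregatePairKeys <- function(j, h, L) {
    if (length(j) == 0L)
        return(data.frame(j = integer(), h = integer(), count = integer()))
    key <- (as.numeric(j) - 1) * L + h      # exact for L^2 < 2^53
    r <- rle(sort(key, method = "radix"))
    data.frame(j = as.integer((r$values - 1) %/% L) + 1L,
               h = as.integer((r$values - 1) %% L) + 1L,
               count = r$lengths)
}

.newContacts <- function(loci, counts, ends, N) {
    new("BinnedContacts", loci = loci, counts = counts,
        ends = as.numeric(ends), N = as.numeric(N))
}

#' Aggregate filtered read pairs into binned contacts
#'
#' Each read pair increments exactly one canonical bin pair (j <= h), with
#' each end assigned to the bin containing its 0-based leftmost mapped
#' position. Per-bin end counts \eqn{reads_j} accumulate both ends of every
#' pair, so a self pair (both ends in one bin) contributes 2 to that bin and
#' \eqn{\sum_j reads_j = 2N}.
#'
#' @param pairs filtered read-pair data.frame (see [filterArtefacts()]).
#' @param loci a [LocusMap-class].
#' @param onMissing `"drop"` pairs on chromosomes absent from the map with a
#'   warning (default), or `"error"`.
#' @return a [BinnedContacts-class].
#' @examples
#' lm <- makeBins(c(chr1 = 2e6), 1e6)
#' p <- data.frame(chrom1 = "chr1", pos1 = c(0, 1.5e6), strand1 = "+",
#'                 chrom2 = "chr1", pos2 = c(1.2e6, 1.9e6), strand2 = "-")
#' binContacts(p, lm)
#' @export
binContacts <- function(pairs, loci, onMissing = c("drop", "error")) {
    onMissing <- match.arg(onMissing)
    known <- names(seqlengths(loci@bins))
    bad <- !(pairs$chrom1 %in% known & pairs$chrom2 %in% known)
    if (any(bad)) {
        if (onMissing == "error")
            stop(sum(bad), " pair(s) on chromosomes absent from the LocusMap")
        warning("dropping ", sum(bad),
                " pair(s) on chromosomes absent from the LocusMap")
        pairs <- pairs[!bad, , drop = FALSE]
    }
    L <- nLoci(loci)
    i1 <- locusIndex(loci, pairs$chrom1, pairs$pos1)
    i2 <- locusIndex(loci, pairs$chrom2, pairs$pos2)
    counts <- .aggregatePairKeys(pmin(i1, i2), pmax(i1, i2), L)
    ends <- tabulate(i1, L) + tabulate(i2, L)
    .newContacts(loci, counts, ends, nrow(pairs))
}

#' Relative coverage per bin
#'
#' The relative coverage of locus j is \eqn{r_j = reads_j / 2N}: the fraction
#' of all mapped read ends falling in bin j. It absorbs all known and unknown
#' per-locus biases and satisfies \eqn{\sum_j r_j = 1}.
#'
#' @param contacts a [BinnedContacts-class] with N > 0.
#' @return numeric vector of per-bin relative coverages.
#' @export
computeCoverage <- function(contacts) {
    stopifnot(is(contacts, "BinnedContacts"))
    if (contacts@N <= 0) stop("empty dataset: N = 0, coverage undefined")
    contacts@ends / (2 * contacts@N)
}

#' Merge two binned-contact accumulations
#'
#' Adds counts, end counts and totals of two [BinnedContacts-class] objects
#' built on the identical [LocusMap-class]. Chunked accumulation followed by
#' `combineContacts()` equals single-pass binning regardless of chunk
#' boundaries.
#'
#' @param x,y [BinnedContacts-class] objects on the same locus map.
#' @return a [BinnedContacts-class].
#' @export
combineContacts <- function(x, y) {
    stopifnot(is(x, "BinnedContacts"), is(y, "BinnedContacts"))
    if (!identical(seqlengths(x@loci@bins), seqlengths(y@loci@bins)) ||
        x@loci@binSize != y@loci@binSize)
        stop("contacts must share an identical LocusMap")
    L <- nLoci(x@loci)
    cnt <- rbind(x@counts, y@counts)
    if (nrow(cnt) > 0L) {
        key <- (as.numeric(cnt$j) - 1) * L + cnt$h
        agg <- rowsum(cnt$count, key)
        keys <- as.numeric(rownames(agg))
        o <- order(keys)
        counts <- data.frame(j = as.integer((keys[o] - 1) %/% L) + 1L,
                             h = as.integer((keys[o] - 1) %% L) + 1L,
                             count = as.vector(agg)[o])
    } else counts <- x@counts
    .newContacts(x@loci, counts, x@ends + y@ends, x@N + y@N)
}

#' Fraction of trans contacts
#'
#' Fraction of binned read pairs whose two ends lie on different chromosomes.
#' In a pure random-ligation library this approaches
#' \eqn{1 - \sum_c W_c^2} with \eqn{W_c} the chromosome coverage weights
#' (93-95\% for a mammalian karyotype), whereas real Hi-C libraries are
#' dominated by cis contacts.
#'
#' @param contacts a [BinnedContacts-class].
#' @return fraction in \[0, 1\].
#' @export
transFraction <- function(contacts) {
    stopifnot(is(contacts, "BinnedContacts"))
    if (contacts@N == 0) return(NA_real_)
    chrs <- as.character(seqnames(contacts@loci@bins))
    cnt <- contacts@counts
    sum(cnt$count[chrs[cnt$j] != chrs[cnt$h]]) / contacts@N
}

#' Export sparse contact triples
#'
#' Tab-delimited `bin_j`, `bin_h`, `count` (1-based canonical bin indices,
#' j <= h) with a `#`-prefixed header.
#'
#' @param contacts a [BinnedContacts-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeContactTriples <- function(contacts, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#bin_j\tbin_h\tcount", con)
    utils::write.table(contacts@counts, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
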