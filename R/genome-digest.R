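#' In-silico restriction digestion of a genome
#'
#' Cuts each chromosome at every occurrence of the enzyme recognition motif,
#' `cutOffset` bases into the motif, and returns the resulting ordered
#' fragment map. Matching is case-insensitive, on the forward strand only
#' (sufficient for palindromic sites such as HindIII AAGCTT or NcoI CCATGG;
#' a non-palindromic motif would additionally require the reverse strand and
#' is not supported). Ambiguous bases (N) never match, and motif occurrences
#' may not overlap: the search resumes after a full motif, matching
#' restriction-enzyme semantics.
#'
#' @param sequences a named [Biostrings::DNAStringSet] or named character
#'   vector of chromosome sequences. Chromosome order is preserved.
#' @param motif recognition motif, A/C/G/T only (e.g. `"AAGCTT"`).
#' @param cutOffset 0-based offset of the cut within the motif (HindIII cuts
#'   A^AGCTT, i.e. offset 1).
#' @return a [FragmentMap-class]. Empty chromosomes are skipped with a warning.
#' @examples
#' fm <- digestGenome(c(chrT = "GGGAAGCTTCCCAAGCTTGGG"), "AAGCTT", 1)
#' fragments(fm)
#' @export
digestGenome <- function(sequences, motif, cutOffset) {
    motif <- toupper(as.character(motif))
    if (length(motif) != 1L || !grepl("^[ACGT]+$", motif))
        stop("motif must be a single non-empty A/C/G/T string")
    cutOffset <- as.integer(cutOffset)
    if (is.na(cutOffset) || cutOffset < 0L || cutOffset > nchar(motif))
        stop("cutOffset must lie within [0, nchar(motif)]")
    if (is.character(sequences))
        sequences <- Biostrings::DNAStringSet(toupper(sequences))
    if (length(sequences) == 0L) stop("sequences must be non-empty")
    if (is.null(names(sequences)) || anyNA(names(sequences)) ||
        any(names(sequences) == ""))
        stop("sequences must be named by chromosome")
    empty <- Biostrings::width(sequences) == 0L
    if (any(empty)) {
        warning("skipping empty chromosome(s): ",
                paste(names(sequences)[empty], collapse = ", "))
        sequences <- sequences[!empty]
        if (length(sequences) == 0L) stop("all chromosomes empty")
    }
    pat <- Biostrings::DNAString(motif)
    mlen <- nchar(motif)
    frags <- lapply(seq_along(sequences), function(i) {
        len <- Biostrings::width(sequences)[i]
        hits <- start(Biostrings::matchPattern(pat, sequences[[i]], fixed = TRUE))
        # drop overlapping occurrences (greedy left-to-right)
        keep <- integer(0)
        prevEnd <- 0L
        for (s in hits) {
            if (s > prevEnd) { keep <- c(keep, s); prevEnd <- s + mlen - 1L }
        }
        cuts <- (keep - 1L) + cutOffset          # 0-based cut positions
        cuts <- cuts[cuts > 0L & cuts < len]
        list(starts0 = c(0L, cuts), ends0 = c(cuts, len))
    })
    chrom <- rep(names(sequences), lengths(lapply(frags, `[[`, "starts0")))
    gr <- GRanges(chrom,
                  IRanges(unlist(lapply(frags, `[[`, "starts0")) + 1L,
                          unlist(lapply(frags, `[[`, "ends0"))))
    sl <- stats::setNames(Biostrings::width(sequences), names(sequences))
    seqlevels(gr) <- names(sequences)
    seqlengths(gr) <- sl
    new("FragmentMap", fragments = gr, motif = motif, cutOffset = cutOffset)
}

#' Tile chromosomes into fixed-width bins
#'
#' Builds the map of loci tested for interaction: dense fixed-width bins
#' tiling each chromosome, the last bin of a chromosome truncated at the
#' chromosome end. Chromosome order is taken from the input (not re-sorted),
#' giving deterministic bin indexing.
#'
#' @param chromSizes named numeric vector of chromosome lengths (bp), or a
#'   path accepted by [readChromSizes()].
#' @param binSize bin width in base pairs (e.g. `1e6`, `5e5`, `1e5`).
#' @return a [LocusMap-class].
#' @examples
#' makeBins(c(chr1 = 3e6, chr2 = 2e6), 1e6)
#' @export
makeBins <- function(chromSizes, binSize) {
    if (is.character(chromSizes) && length(chromSizes) == 1L)
        chromSizes <- readChromSizes(chromSizes)
    if (is.null(names(chromSizes)) || any(names(chromSizes) == ""))
        stop("chromSizes must be named by chromosome")
    if (any(chromSizes <= 0)) stop("chromosome lengths must be positive")
    if (length(binSize) != 1L || binSize <= 0) stop("binSize must be positive")
    gr <- tileGenome(chromSizes, tilewidth = binSize,
                     cut.last.tile.in.chrom = TRUE)
    new("LocusMap", bins = gr, binSize = as.numeric(binSize))
}

## shared position->index lookup against a tiling GRanges
.tilingIndex <- function(gr, chrom, pos, what) {
    chrom <- as.character(chrom)
    pos <- as.numeric(pos)
    n <- max(length(chrom), length(pos))
    chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
    sl <- seqlengths(gr)
    bad <- !(chrom %in% names(sl))
    if (any(bad))
        stop("unknown chromosome(s) in ", what, ": ",
             paste(unique(chrom[bad]), collapse = ", "))
    if (any(pos < 0 | pos >= sl[chrom]))
        stop("position out of chromosome range in ", what)
    chrs <- as.character(seqnames(gr))
    starts0 <- split(start(gr) - 1, chrs)
    offset <- cumsum(c(0L, table(factor(chrs, levels = unique(chrs)))))
    names(offset) <- c(unique(chrs), "")
    out <- integer(n)
    for (chr in unique(chrom)) {
        sel <- chrom == chr
        out[sel] <- offset[[chr]] + findInterval(pos[sel], starts0[[chr]])
    }
    out
}

#' @rdname locusIndex
#' @export
setMethod("locusIndex", "LocusMap", function(map, chrom, pos) {
    .tilingIndex(map@bins, chrom, pos, "LocusMap")
})

#' @rdname locusIndex
#' @export
setMethod("locusIndex", "FragmentMap", function(map, chrom, pos) {
    .tilingIndex(map@fragments, chrom, pos, "FragmentMap")
})

#' Read a chromosome-sizes table
#'
#' Two tab-delimited columns: chromosome name and length in bp. Lines starting
#' with `#` are ignored. Order of appearance is preserved.
#'
#' @param path file path.
#' @return named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             comment.char = "#",
                             colClasses = c("character", "numeric"))
    stats::setNames(tab[[2L]], tab[[1L]])
}

#' Write or read a fragment map as BED
#'
#' BED uses 0-based half-open coordinates; columns are chrom, start, end,
#' fragment id (`frag_<index>`). `readFragmentsBed()` needs the enzyme motif
#' and cut offset back (they are not representable in BED) and validates that
#' the intervals tile their chromosomes.
#'
#' @param x a [FragmentMap-class].
#' @param path file path.
#' @param motif,cutOffset enzyme annotation to attach on read-back.
#' @return `writeFragmentsBed()` returns `path` invisibly;
#'   `readFragmentsBed()` a [FragmentMap-class].
#' @export
writeFragmentsBed <- function(x, path) {
    stopifnot(is(x, "FragmentMap"))
    gr <- x@fragments
    tab <- data.frame(chrom = as.character(seqnames(gr)),
                      start = start(gr) - 1, end = end(gr),
                      name = paste0("frag_", seq_along(gr)))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeFragmentsBed
#' @export
readFragmentsBed <- function(path, motif = "NNNNNN", cutOffset = 0L) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             comment.char = "#")
    chrom <- as.character(tab[[1L]])
    gr <- GRanges(chrom, IRanges(tab[[2L]] + 1, tab[[3L]]))
    seqlevels(gr) <- unique(chrom)
    ends <- vapply(split(tab[[3L]], factor(chrom, levels = unique(chrom))),
                   max, numeric(1))
    seqlengths(gr) <- ends
    new("FragmentMap", fragments = gr, motif = toupper(motif),
        cutOffset = as.integer(cutOffset))
}
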