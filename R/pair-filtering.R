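## canonicalize: end 1 <= end 2 under (chromosome name, position) ordering
.canonicalizePairs <- function(p) {
    swap <- p$chrom2 < p$chrom1 |
        (p$chrom2 == p$chrom1 & p$pos2 < p$pos1)
    if (any(swap)) {
        tmp <- p[swap, c("chrom2", "pos2", "strand2")]
        p[swap, c("chrom2", "pos2", "strand2")] <-
            p[swap, c("chrom1", "pos1", "strand1")]
        p[swap, c("chrom1", "pos1", "strand1")] <- tmp
    }
    p
}

.pairCols <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")

#' Read mapped Hi-C read pairs
#'
#' Ingests one mapped ditag per pair from either a tab-delimited pairs text
#' file (columns chrom1, pos1, strand1, chrom2, pos2, strand2; positions are
#' 0-based leftmost mapped bases; `#`-prefixed header lines allowed) or a
#' name-paired SAM/BAM alignment file (one record per read end, mates sharing
#' the read name). Pairs are canonicalized so that end 1 precedes end 2 under
#' (chromosome name, position) ordering. Orphan alignments (no mate, or more
#' than two primary records per name) are counted and skipped with a warning,
#' as are unmapped ends and ends below the mapping-quality threshold.
#'
#' @param path input file.
#' @param format `"pairs"`, `"sam"`, `"bam"`, or `"auto"` (by file extension;
#'   anything not ending in .sam/.bam is treated as pairs text).
#' @param mapq minimum mapping quality for alignment input (default 0).
#' @return data.frame with columns chrom1, pos1, strand1, chrom2, pos2,
#'   strand2 (positions 0-based).
#' @seealso [filterArtefacts()], [writePairsFile()]
#' @export
readPairs <- function(path, format = c("auto", "pairs", "sam", "bam"),
                      mapq = 0) {
    format <- match.arg(format)
    if (format == "auto") {
        format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam"
                  else if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam"
                  else "pairs"
    }
    if (format == "pairs") .readPairsText(path) else .readPairsSam(path, format, mapq)
}

.readPairsText <- function(path) {
    lines <- readLines(path)
    keep <- !startsWith(lines, "#") & nzchar(lines)
    lineno <- which(keep)
    if (length(lineno) == 0L)
        return(data.frame(chrom1 = character(), pos1 = numeric(),
                          strand1 = character(), chrom2 = character(),
                          pos2 = numeric(), strand2 = character()))
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    nfield <- lengths(parts)
    if (any(nfield < 6L))
        stop("malformed pairs line ", lineno[which(nfield < 6L)[1L]],
             ": expected 6 tab-separated fields")
    m <- matrix(unlist(lapply(parts, `[`, 1:6)), ncol = 6L, byrow = TRUE)
    pos1 <- suppressWarnings(as.numeric(m[, 2L]))
    pos2 <- suppressWarnings(as.numeric(m[, 5L]))
    bad <- is.na(pos1) | is.na(pos2) | !(m[, 3L] %in% c("+", "-")) |
        !(m[, 6L] %in% c("+", "-"))
    if (any(bad))
        stop("malformed pairs line ", lineno[which(bad)[1L]],
             ": bad position or strand field")
    .canonicalizePairs(data.frame(
        chrom1 = m[, 1L], pos1 = pos1, strand1 = m[, 3L],
        chrom2 = m[, 4L], pos2 = pos2, strand2 = m[, 6L]))
}

.readPairsSam <- function(path, format, mapq) {
    bam <- if (format == "sam") {
        Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
    } else path
    res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "strand", "pos", "mapq"),
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                      isSecondaryAlignment = FALSE,
                                      isSupplementaryAlignment = FALSE)))[[1L]]
    ok <- is.na(res$mapq) | res$mapq >= mapq
    qname <- res$qname[ok]
    tab <- table(qname)
    paired <- names(tab)[tab == 2L]
    nOrphan <- sum(tab != 2L)
    if (nOrphan > 0L)
        warning(nOrphan, " read name(s) without exactly one mate; skipped")
    sel <- qname %in% paired
    o <- order(qname[sel])
    chrom <- as.character(res$rname[ok][sel][o])
    pos <- res$pos[ok][sel][o] - 1      # SAM 1-based -> 0-based
    strand <- as.character(res$strand[ok][sel][o])
    first <- seq(1L, by = 2L, length.out = length(o) / 2L)
    .canonicalizePairs(data.frame(
        chrom1 = chrom[first], pos1 = pos[first], strand1 = strand[first],
        chrom2 = chrom[first + 1L], pos2 = pos[first + 1L],
        strand2 = strand[first + 1L]))
}

#' Write read pairs as pairs text
#'
#' Tab-delimited chrom1, pos1, strand1, chrom2, pos2, strand2 with positions
#' 0-based, preceded by a `#`-prefixed column header.
#'
#' @param pairs read-pair data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePairsFile <- function(pairs, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#chrom1\tpos1\tstrand1\tchrom2\tpos2\tstrand2", con)
    utils::write.table(
        data.frame(pairs$chrom1, format(pairs$pos1, scientific = FALSE, trim = TRUE),
                   pairs$strand1, pairs$chrom2,
                   format(pairs$pos2, scientific = FALSE, trim = TRUE),
                   pairs$strand2),
        con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Remove exact duplicate read pairs
#'
#' PCR amplification produces exact copies of ditags; at most one pair is kept
#' per exact key (chrom1, pos1, strand1, chrom2, pos2, strand2), the first
#' occurrence deterministically. Pairs must be canonicalized (as returned by
#' [readPairs()]).
#'
#' @param pairs canonicalized read-pair data.frame.
#' @return list with `pairs` (deduplicated) and `nRemoved`.
#' @export
removeDuplicates <- function(pairs) {
    if (nrow(pairs) == 0L) return(list(pairs = pairs, nRemoved = 0L))
    key <- do.call(paste, c(pairs[.pairCols], sep = "\r"))
    dup <- duplicated(key)
    list(pairs = pairs[!dup, , drop = FALSE], nRemoved = sum(dup))
}

#' Annotate read pairs with restriction fragments
#'
#' Adds `frag1` and `frag2` columns: the [FragmentMap-class] index of the
#' fragment containing each end.
#'
#' @param pairs read-pair data.frame.
#' @param fragMap a [FragmentMap-class].
#' @param onMissing what to do with pairs whose chromosome is absent from the
#'   fragment map: `"drop"` them with a warning (default) or raise an
#'   `"error"`.
#' @return the pairs with `frag1`, `frag2` columns added.
#' @export
annotateFragments <- function(pairs, fragMap, onMissing = c("drop", "error")) {
    onMissing <- match.arg(onMissing)
    known <- names(seqlengths(fragMap@fragments))
    bad <- !(pairs$chrom1 %in% known & pairs$chrom2 %in% known)
    if (any(bad)) {
        if (onMissing == "error")
            stop(sum(bad), " pair(s) on chromosomes absent from the FragmentMap")
        warning("dropping ", sum(bad),
                " pair(s) on chromosomes absent from the FragmentMap")
        pairs <- pairs[!bad, , drop = FALSE]
    }
    pairs$frag1 <- locusIndex(fragMap, pairs$chrom1, pairs$pos1)
    pairs$frag2 <- locusIndex(fragMap, pairs$chrom2, pairs$pos2)
    pairs
}

#' Filter Hi-C ligation artefacts
#'
#' Removes self-ligations, dangling ends, re-ligations and incomplete
#' digestion products by discarding read pairs that map to the same
#' restriction fragment (at any separation) or, on the same chromosome, lie
#' within `minDistance` base pairs of each other (strict `<`; a pair at
#' exactly `minDistance` is retained). Distance is measured between the two
#' 0-based leftmost mapped positions; strand is ignored by this rule. Trans
#' pairs are never removed.
#'
#' @param pairs fragment-annotated read pairs (see [annotateFragments()]).
#' @param minDistance minimum cis separation in bp (default 10000).
#' @param nDuplicates duplicate count already removed upstream, folded into
#'   the returned [FilterStats-class].
#' @return list with `pairs` (retained) and `stats` (a [FilterStats-class];
#'   its `input` is `nrow(pairs) + nDuplicates`).
#' @examples
#' fm <- digestGenome(c(chrT = strrep("A", 30)), "AAGCTT", 1)  # no cut sites
#' p <- data.frame(chrom1 = "chrT", pos1 = 0, strand1 = "+",
#'                 chrom2 = "chrT", pos2 = 20, strand2 = "-")
#' filterArtefacts(annotateFragments(p, fm))$stats
#' @export
filterArtefacts <- function(pairs, minDistance = 10000, nDuplicates = 0L) {
    if (length(minDistance) != 1L || is.na(minDistance) || minDistance < 0)
        stop("minDistance must be a single non-negative number")
    if (!all(c("frag1", "frag2") %in% names(pairs)))
        stop("pairs must carry frag1/frag2 annotations (annotateFragments)")
    cis <- pairs$chrom1 == pairs$chrom2
    sameFrag <- cis & pairs$frag1 == pairs$frag2
    prox <- !sameFrag & cis & abs(pairs$pos1 - pairs$pos2) < minDistance
    keep <- !sameFrag & !prox
    stats <- new("FilterStats",
                 input = nrow(pairs) + as.integer(nDuplicates),
                 duplicates = as.integer(nDuplicates),
                 sameFragment = as.integer(sum(sameFrag)),
                 proximity = as.integer(sum(prox)),
                 retained = as.integer(sum(keep)),
                 cis = as.integer(sum(keep & cis)),
                 trans = as.integer(sum(keep & !cis)))
    list(pairs = pairs[keep, , drop = FALSE], stats = stats)
}

#' Export filter statistics
#'
#' @param stats a [FilterStats-class].
#' @return a named list of the tallies (suitable for
#'   [jsonlite::write_json()]).
#' @export
filterStatsList <- function(stats) {
    list(input_pairs = stats@input,
         duplicate_pairs = stats@duplicates,
         same_fragment_pairs = stats@sameFragment,
         proximity_removed_pairs = stats@proximity,
         retained_pairs = stats@retained,
         cis_pairs = stats@cis,
         trans_pairs = stats@trans)
}
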