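#' Random-ligation probability for a bin pair
#'
#' Probability that a single spurious (randomly ligated) read pair links two
#' distinct loci j and h: \eqn{p_{j,h} = 2 r_j r_h f_{random}}, the product of
#' the loci's relative coverages with a factor 2 for the two end assignments
#' of an unordered pair. `fRandom`, the fraction of library read pairs arising
#' from spurious ligations, defaults to the conservative upper bound 1.
#'
#' @param rj,rh relative coverages of the two loci (vectorized).
#' @param fRandom spurious-ligation fraction in (0, 1].
#' @return per-trial probabilities in \[0, 1\].
#' @export
expectedProbability <- function(rj, rh, fRandom = 1) {
    if (length(fRandom) != 1L || fRandom <= 0 || fRandom > 1)
        stop("fRandom must be a single value in (0, 1]")
    if (any(rj < 0 | rj > 1) || any(rh < 0 | rh > 1))
        stop("relative coverages must lie in [0, 1]")
    2 * rj * rh * fRandom
}

#' Upper-tail binomial p-value
#'
#' \eqn{P(X \ge n)} for \eqn{X \sim Binomial(N, p)}: the probability of
#' observing n or more read pairs between two loci by chance in a dataset of
#' N pairs. Computed through the upper-tail cumulative distribution (the
#' regularized incomplete beta), which stays accurate deep in the tail for
#' N ~ 1e8 and p ~ 1e-12, where naive `1 - CDF` would lose all precision.
#'
#' @param n observed counts (vectorized), 0 <= n <= N.
#' @param N total number of read pairs (Bernoulli trials).
#' @param p per-trial probabilities (vectorized against n).
#' @return p-values; exactly 1 when n = 0, exactly 0 when p = 0 and n >= 1.
#' @examples
#' binomialPvalue(1, 10, 0.1)   # 1 - 0.9^10
#' @export
binomialPvalue <- function(n, N, p) {
    if (length(N) != 1L || is.na(N) || N < 0) stop("N must be a single count >= 0")
    if (any(n < 0 | n > N)) stop("n must satisfy 0 <= n <= N")
    if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
    stats::pbinom(n - 1, size = N, prob = p, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment over an implicit test universe
#'
#' Step-up BH q-values \eqn{q_{(i)} = \min_{k \ge i} p_{(k)} m / k} (capped at
#' 1) where the total test count m may exceed the number of supplied p-values:
#' untested bin pairs (zero observed count) carry p = 1 implicitly and never
#' need to be materialized, because a padded p = 1 contributes a candidate
#' \eqn{m/k \ge 1} that the cap already enforces. The result is identical to
#' running BH on the list padded with `m - length(pvals)` ones.
#'
#' @param pvals p-values of the tested pairs.
#' @param m total number of tests (>= `length(pvals)`), e.g. `L*(L-1)/2`.
#' @return q-values in the input order; ties in p receive equal q.
#' @export
bhAdjust <- function(pvals, m) {
    s <- length(pvals)
    if (length(m) != 1L || is.na(m) || m < s)
        stop("m must be a single count >= length(pvals)")
    if (s == 0L) return(numeric(0))
    if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
    o <- order(pvals)
    q <- pvals[o] * (m / seq_len(s))
    q <- pmin(rev(cummin(rev(q))), 1)
    out <- numeric(s)
    out[o] <- q
    out
}

#' Log2 observed-over-expected ratio
#'
#' Effect size of an interaction: \eqn{R = \log_2(n / (p N))}, the observed
#' pair count over its random-ligation expectation. `NA` when n = 0 (the
#' declared convention for untestable ratios).
#'
#' @param n observed counts.
#' @param N total read pairs (> 0).
#' @param p per-trial probabilities.
#' @return log2 ratios, NA where n = 0.
#' @export
logRatio <- function(n, N, p) {
    if (length(N) != 1L || N <= 0) stop("N must be a single positive count")
    if (any(p == 0 & n > 0))
        stop("observed reads on a zero-coverage pair: accounting error")
    ifelse(n > 0, log2(n / (p * N)), NA_real_)
}

#' Call statistically significant interactions
#'
#' For every canonical off-diagonal bin pair with at least one observed read
#' pair (or every pair when `testZeroPairs`), computes the random-ligation
#' probability \eqn{p_{j,h} = 2 r_j r_h f_{random}}, the upper-tail binomial
#' p-value of the observed count, the BH q-value over the full universe of
#' \eqn{m = L(L-1)/2} bin-pair tests, and the log2 observed/expected ratio.
#' Self pairs (j = h) are never tested; their null mass \eqn{r_j^2} is exactly
#' the probability excluded from the off-diagonal universe and is reported by
#' [nullNormalization()]. A pair is significant when its q-value is strictly
#' below `fdr`.
#'
#' @param contacts a [BinnedContacts-class] with N > 0.
#' @param fdr false discovery rate threshold (default 0.05).
#' @param fRandom spurious-ligation fraction in (0, 1] (default 1, the
#'   conservative upper bound).
#' @param removeAdjacent drop pairs of adjacent bins on the same chromosome
#'   before testing (as done when comparing against methods that discard
#'   them); default off.
#' @param testZeroPairs also enumerate pairs with zero observed counts
#'   (p-value 1); off by default, since zero-count pairs are handled
#'   analytically by the BH universe `m`.
#' @param LPolicy bins counted in L: `"all"` bins in the map (default; the
#'   universe of tests includes zero-coverage loci) or `"nonzero"` coverage
#'   bins only.
#' @return data.frame sorted by (qvalue, pvalue, bin1, bin2) with columns
#'   chrom1, start1, end1, chrom2, start2, end2 (0-based half-open), bin1,
#'   bin2 (1-based indices), readCount, expected, logObsExp, pvalue, qvalue,
#'   significant. The number of tests `m` and the locus count `L` are
#'   attached as attributes.
#' @examples
#' lm <- makeBins(c(chr1 = 4e6), 1e6)
#' p <- data.frame(chrom1 = "chr1", pos1 = c(0, 5e5, 2.2e6), strand1 = "+",
#'                 chrom2 = "chr1", pos2 = c(3.1e6, 3.4e6, 3.9e6), strand2 = "-")
#' callInteractions(binContacts(p, lm))
#' @export
callInteractions <- function(contacts, fdr = 0.05, fRandom = 1,
                             removeAdjacent = FALSE, testZeroPairs = FALSE,
                             LPolicy = c("all", "nonzero")) {
    stopifnot(is(contacts, "BinnedContacts"))
    LPolicy <- match.arg(LPolicy)
    if (length(fdr) != 1L || fdr <= 0 || fdr >= 1)
        stop("fdr must be a single value in (0, 1)")
    loci <- contacts@loci
    Lmap <- nLoci(loci)
    N <- contacts@N
    if (N <= 0) stop("empty dataset: N = 0")
    r <- computeCoverage(contacts)
    cnt <- contacts@counts
    off <- cnt[cnt$j < cnt$h, , drop = FALSE]
    if (testZeroPairs) {
        if (Lmap > 5000L)
            stop("testZeroPairs enumerates L(L-1)/2 pairs; refusing for L > 5000")
        jv <- rep.int(seq_len(Lmap - 1L), (Lmap - 1L):1L)
        hv <- sequence((Lmap - 1L):1L, from = 2:Lmap)
        key <- (as.numeric(jv) - 1) * Lmap + hv
        n <- numeric(length(key))
        n[match((as.numeric(off$j) - 1) * Lmap + off$h, key)] <- off$count
        off <- data.frame(j = jv, h = hv, count = n)
    }
    chrs <- as.character(seqnames(loci@bins))
    if (removeAdjacent && nrow(off) > 0L) {
        adj <- off$h == off$j + 1L & chrs[off$j] == chrs[off$h]
        off <- off[!adj, , drop = FALSE]
    }
    L <- if (LPolicy == "all") Lmap else sum(contacts@ends > 0)
    m <- L * (L - 1) / 2
    if (nrow(off) > m)
        stop("more tested pairs than the BH universe m; check LPolicy")
    p <- expectedProbability(r[off$j], r[off$h], fRandom)
    pval <- binomialPvalue(off$count, N, p)
    qval <- bhAdjust(pval, m)
    bstart <- start(loci@bins) - 1
    bend <- end(loci@bins)
    res <- data.frame(
        chrom1 = chrs[off$j], start1 = bstart[off$j], end1 = bend[off$j],
        chrom2 = chrs[off$h], start2 = bstart[off$h], end2 = bend[off$h],
        bin1 = off$j, bin2 = off$h,
        readCount = off$count, expected = p * N,
        logObsExp = logRatio(off$count, N, p),
        pvalue = pval, qvalue = qval,
        significant = qval < fdr)
    o <- order(res$qvalue, res$pvalue, res$bin1, res$bin2)
    res <- res[o, , drop = FALSE]
    rownames(res) <- NULL
    attr(res, "m") <- m
    attr(res, "L") <- L
    attr(res, "binSize") <- loci@binSize
    attr(res, "fdr") <- fdr
    res
}

#' Null normalization identity
#'
#' Diagnostic for the coverage bookkeeping: returns \eqn{\sum_j r_j},
#' the off-diagonal null mass \eqn{\sum_{j<h} 2 r_j r_h}, and the diagonal
#' mass \eqn{\sum_j r_j^2}. The first is 1 and the last two sum to 1 (within
#' floating-point error) on any dataset; the diagonal mass is the probability
#' excluded from significance testing.
#'
#' @param contacts a [BinnedContacts-class] with N > 0.
#' @return named list with `sumR`, `offDiagonalMass`, `diagonalMass`.
#' @export
nullNormalization <- function(contacts) {
    r <- computeCoverage(contacts)
    s <- sum(r)
    diagMass <- sum(r^2)
    list(sumR = s, offDiagonalMass = s^2 - diagMass, diagonalMass = diagMass)
}

## 6-significant-digit formatting; p/q switch to scientific below 1e-4
.fmtFloat <- function(x) {
    out <- formatC(x, digits = 6, format = "g")
    out[is.na(x)] <- "NA"
    out
}
.fmtP <- function(x) {
    out <- ifelse(x < 1e-4, formatC(x, digits = 5, format = "e"),
                  formatC(x, digits = 6, format = "g"))
    out[is.na(x)] <- "NA"
    out
}

#' Write or read an interaction table
#'
#' Tab-delimited with header `chr1 start1 end1 chr2 start2 end2 readCount
#' expected logObsExp pvalue qvalue significant`; coordinates 0-based
#' half-open, floats at 6 significant digits, p/q-values in scientific
#' notation below 1e-4.
#'
#' @param interactions result of [callInteractions()].
#' @param path file path.
#' @return `writeInteractions()` returns `path` invisibly;
#'   `readInteractions()` a data.frame.
#' @export
writeInteractions <- function(interactions, path) {
    coord <- function(x) format(x, scientific = FALSE, trim = TRUE)
    tab <- data.frame(
        chr1 = interactions$chrom1, start1 = coord(interactions$start1),
        end1 = coord(interactions$end1), chr2 = interactions$chrom2,
        start2 = coord(interactions$start2), end2 = coord(interactions$end2),
        readCount = interactions$readCount,
        expected = .fmtFloat(interactions$expected),
        logObsExp = .fmtFloat(interactions$logObsExp),
        pvalue = .fmtP(interactions$pvalue),
        qvalue = .fmtP(interactions$qvalue),
        significant = interactions$significant)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writeInteractions
#' @export
readInteractions <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    names(tab)[names(tab) == "chr1"] <- "chrom1"
    names(tab)[names(tab) == "chr2"] <- "chrom2"
    tab
}
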