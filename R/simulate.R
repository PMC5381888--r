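## categorical sampling via inverse CDF; breaks = cumsum(weights)
.sampleCategorical <- function(breaks, n) {
    idx <- findInterval(stats::runif(n), breaks) + 1L
    pmin(idx, length(breaks))      # guard cumsum rounding at the top end
}

#' Simulate a per-bin coverage bias profile
#'
#' Draws per-bin weights i.i.d. from a gamma distribution with the given
#' shape (scale-free, since the weights are normalised to sum to 1). The
#' gamma family reproduces the right-skewed heterogeneity of real Hi-C
#' coverage, whose drivers include GC content, mappability and
#' restriction-fragment density; smaller shape means stronger heterogeneity
#' (coefficient of variation \eqn{1/\sqrt{shape}}), and in the large-shape
#' limit the weights approach uniform.
#'
#' @param loci a [LocusMap-class].
#' @param shape gamma shape parameter (> 0); default 1 (exponential weights,
#'   CV = 1).
#' @param seed RNG seed; identical seeds reproduce the profile exactly.
#' @return a [BiasProfile-class].
#' @export
simulateBiasProfile <- function(loci, shape = 1, seed = 1L) {
    stopifnot(is(loci, "LocusMap"))
    if (length(shape) != 1L || shape <= 0) stop("shape must be positive")
    set.seed(seed)
    w <- stats::rgamma(nLoci(loci), shape = shape)
    new("BiasProfile", loci = loci, weights = w / sum(w),
        shape = as.numeric(shape), seed = as.numeric(seed))
}

#' A bias profile with weights proportional to bin widths
#'
#' Uniform coverage per base pair: each bin's weight is its width over the
#' genome length, so chromosome weights are proportional to chromosome
#' lengths. Useful for studying the trans fraction of a random-ligation
#' library, which equals \eqn{1 - \sum_c W_c^2} in expectation.
#'
#' @param loci a [LocusMap-class].
#' @return a [BiasProfile-class].
#' @export
uniformBiasProfile <- function(loci) {
    stopifnot(is(loci, "LocusMap"))
    w <- as.numeric(width(loci@bins))
    new("BiasProfile", loci = loci, weights = w / sum(w),
        shape = NA_real_, seed = NA_real_)
}

#' Simulate a pure random-ligation library
#'
#' Draws the two ends of each read pair independently from the categorical
#' per-bin distribution of the bias profile — exactly the independence
#' assumption of the coverage-product binomial null, with no distance decay
#' and no true interactions — and accumulates canonical bin-pair counts.
#' Deterministic per seed; generation is chunked but the stream is identical
#' for any chunk size.
#'
#' @param profile a [BiasProfile-class].
#' @param nPairs number of read pairs to draw.
#' @param seed RNG seed.
#' @param chunkSize pairs drawn per chunk (memory knob, does not affect the
#'   result).
#' @return a [BinnedContacts-class] with `N = nPairs`.
#' @export
simulateRandomLigation <- function(profile, nPairs, seed = 1L,
                                   chunkSize = 5e6) {
    stopifnot(is(profile, "BiasProfile"))
    nPairs <- as.numeric(nPairs)
    if (length(nPairs) != 1L || is.na(nPairs) || nPairs < 0)
        stop("nPairs must be a single count >= 0")
    loci <- profile@loci
    L <- nLoci(loci)
    breaks <- cumsum(profile@weights)
    set.seed(seed)
    dense <- L <= 5000L
    acc <- if (dense) integer(L * L) else NULL
    sparse <- list()
    ends <- integer(L)
    remaining <- nPairs
    while (remaining > 0) {
        nc <- min(remaining, chunkSize)
        # two consecutive uniforms per pair: the consumed RNG stream, and so
        # the result, is identical for any chunk size
        u <- stats::runif(2 * nc)
        e1 <- pmin(findInterval(u[seq.int(1L, 2L * nc, 2L)], breaks) + 1L, L)
        e2 <- pmin(findInterval(u[seq.int(2L, 2L * nc, 2L)], breaks) + 1L, L)
        ends <- ends + tabulate(e1, L) + tabulate(e2, L)
        j <- pmin(e1, e2); h <- pmax(e1, e2)
        if (dense) {
            acc <- acc + tabulate((j - 1L) * L + h, L * L)
        } else {
            sparse[[length(sparse) + 1L]] <- .aggregatePairKeys(j, h, L)
        }
        remaining <- remaining - nc
    }
    counts <- if (dense) {
        nz <- which(acc > 0L)
        data.frame(j = as.integer((nz - 1L) %/% L) + 1L,
                   h = as.integer((nz - 1L) %% L) + 1L,
                   count = acc[nz])
    } else if (length(sparse) > 0L) {
        all <- do.call(rbind, sparse)
        key <- (as.numeric(all$j) - 1) * L + all$h
        agg <- rowsum(all$count, key)
        keys <- as.numeric(rownames(agg))
        o <- order(keys)
        data.frame(j = as.integer((keys[o] - 1) %/% L) + 1L,
                   h = as.integer((keys[o] - 1) %% L) + 1L,
                   count = as.vector(agg)[o])
    } else data.frame(j = integer(), h = integer(), count = integer())
    .newContacts(loci, counts, ends, nPairs)
}

#' Build a spike-in truth set
#'
#' Samples `n` distinct off-diagonal bin pairs uniformly and assigns them a
#' common enrichment multiplier, for use with [simulateWithSpikeins()].
#'
#' @param loci a [LocusMap-class].
#' @param n number of spiked pairs.
#' @param enrichment multiplier e >= 1 applied to each spiked pair's null
#'   weight.
#' @param seed RNG seed.
#' @return data.frame with columns `j`, `h` (j < h) and `e`.
#' @export
sampleSpikeins <- function(loci, n, enrichment, seed = 1L) {
    stopifnot(is(loci, "LocusMap"))
    L <- nLoci(loci)
    nOff <- L * (L - 1) / 2
    if (n > nOff) stop("more spikes than off-diagonal pairs")
    set.seed(seed)
    # uniform over off-diagonal pair indices
    idx <- sample(nOff, n)
    jv <- rep.int(seq_len(L - 1L), (L - 1L):1L)
    hv <- sequence((L - 1L):1L, from = 2:L)
    data.frame(j = jv[idx], h = hv[idx], e = as.numeric(enrichment))
}

#' Simulate a library with spiked-in true interactions
#'
#' The null pair law of [simulateRandomLigation()] — unnormalised weight
#' \eqn{2 w_j w_h} for j < h and \eqn{w_j^2} on the diagonal — is multiplied
#' by the enrichment e on each spiked pair and renormalised; `nPairs` pairs
#' are then drawn from the resulting categorical distribution over bin pairs.
#' With all e = 1 this reduces exactly to the random-ligation law. The truth
#' set is returned unchanged for downstream sensitivity scoring.
#'
#' @param profile a [BiasProfile-class].
#' @param nPairs number of read pairs.
#' @param spikes data.frame with columns `j`, `h` (distinct pairs, j < h,
#'   within the locus map) and `e` (finite multipliers >= 1); see
#'   [sampleSpikeins()].
#' @param seed RNG seed.
#' @param chunkSize draws per chunk.
#' @return list with `contacts` (a [BinnedContacts-class]) and `truth`
#'   (the spikes, unchanged).
#' @export
simulateWithSpikeins <- function(profile, nPairs, spikes, seed = 1L,
                                 chunkSize = 5e6) {
    stopifnot(is(profile, "BiasProfile"))
    loci <- profile@loci
    L <- nLoci(loci)
    if (L > 5000L)
        stop("spike-in simulation enumerates all bin pairs; L > 5000 unsupported")
    if (!all(c("j", "h", "e") %in% names(spikes)))
        stop("spikes must have columns j, h, e")
    if (any(spikes$j >= spikes$h) || any(spikes$j < 1L) || any(spikes$h > L))
        stop("spiked pairs must satisfy 1 <= j < h <= L")
    if (any(!is.finite(spikes$e)) || any(spikes$e < 1))
        stop("enrichment multipliers must be finite and >= 1")
    skey <- (as.numeric(spikes$j) - 1) * L + spikes$h
    if (anyDuplicated(skey)) stop("spiked pairs must be distinct")
    w <- profile@weights
    jv <- rep.int(seq_len(L), L:1L)
    hv <- sequence(L:1L, from = seq_len(L))
    q <- ifelse(jv == hv, w[jv]^2, 2 * w[jv] * w[hv])
    pos <- match(skey, (as.numeric(jv) - 1) * L + hv)
    q[pos] <- q[pos] * spikes$e
    breaks <- cumsum(q / sum(q))
    set.seed(seed)
    nPairs <- as.numeric(nPairs)
    acc <- integer(length(q))
    remaining <- nPairs
    while (remaining > 0) {
        nc <- min(remaining, chunkSize)
        acc <- acc + tabulate(.sampleCategorical(breaks, nc), length(q))
        remaining <- remaining - nc
    }
    nz <- which(acc > 0L)
    counts <- data.frame(j = jv[nz], h = hv[nz], count = acc[nz])
    ends <- numeric(L)
    if (nrow(counts) > 0L) {
        agg <- rowsum(c(counts$count, counts$count), c(counts$j, counts$h))
        ends[as.integer(rownames(agg))] <- agg[, 1L]
    }
    list(contacts = .newContacts(loci, counts, ends, nPairs), truth = spikes)
}

#' Emit simulated contacts as a synthetic pairs file
#'
#' Expands binned counts back into individual read pairs, drawing each end's
#' position uniformly within its bin and strands at random, so the whole
#' pipeline (parsing, filtering, binning) can be exercised without real data.
#' Binning the emitted file on the same locus map reproduces the input counts
#' exactly. Intended for small fixtures; the expansion is dense in `N`.
#'
#' @param contacts a [BinnedContacts-class].
#' @param path output pairs file.
#' @param seed RNG seed for positions and strands.
#' @return `path`, invisibly.
#' @export
writeSimulatedPairs <- function(contacts, path, seed = 1L) {
    stopifnot(is(contacts, "BinnedContacts"))
    cnt <- contacts@counts
    gr <- contacts@loci@bins
    set.seed(seed)
    j <- rep.int(cnt$j, cnt$count)
    h <- rep.int(cnt$h, cnt$count)
    n <- length(j)
    start0 <- start(gr) - 1
    wid <- width(gr)
    chrs <- as.character(seqnames(gr))
    p1 <- start0[j] + floor(stats::runif(n) * wid[j])
    p2 <- start0[h] + floor(stats::runif(n) * wid[h])
    pairs <- .canonicalizePairs(data.frame(
        chrom1 = chrs[j], pos1 = p1,
        strand1 = sample(c("+", "-"), n, replace = TRUE),
        chrom2 = chrs[h], pos2 = p2,
        strand2 = sample(c("+", "-"), n, replace = TRUE)))
    writePairsFile(pairs, path)
}
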