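# Shared fixtures, built in code.

# two-chromosome toy locus map: chrA 3 Mb + chrB 2 Mb at 1 Mb -> 5 bins
toyLocusMap <- function() makeBins(c(chrA = 3e6, chrB = 2e6), 1e6)

# toy genome with HindIII sites at known positions
toyGenome <- function() {
    c(chrT = "GGGAAGCTTCCCAAGCTTGGG",           # sites at 0-based 3 and 12
      chrU = strrep("ACGT", 10))                 # no sites, 40 bp
}

fixturePath <- function(file)
    system.file("extdata", file, package = "HiCbinom", mustWork = TRUE)

# independent brute-force binomial upper tail: log-space pmf summation
bruteTail <- function(n, N, p) {
    if (n == 0) return(1)
    if (p == 0) return(0)
    i <- n:N
    sum(exp(lchoose(N, i) + i * log(p) + (N - i) * log1p(-p)))
}

# random canonicalized cis/trans pair table on the toy genome coordinates
randomPairs <- function(n, seed) {
    set.seed(seed)
    chroms <- c("chrA", "chrB")
    sizes <- c(chrA = 3e6, chrB = 2e6)
    c1 <- sample(chroms, n, replace = TRUE)
    c2 <- sample(chroms, n, replace = TRUE)
    df <- data.frame(chrom1 = c1, pos1 = floor(runif(n) * sizes[c1]),
                     strand1 = sample(c("+", "-"), n, TRUE),
                     chrom2 = c2, pos2 = floor(runif(n) * sizes[c2]),
                     strand2 = sample(c("+", "-"), n, TRUE))
    swap <- df$chrom2 < df$chrom1 | (df$chrom1 == df$chrom2 & df$pos2 < df$pos1)
    tmp <- df[swap, c("chrom2", "pos2", "strand2")]
    df[swap, c("chrom2", "pos2", "strand2")] <- df[swap, c("chrom1", "pos1", "strand1")]
    df[swap, c("chrom1", "pos1", "strand1")] <- tmp
    rownames(df) <- NULL
    df
}

# BinnedContacts assembled directly from a sparse count list
contactsFromCounts <- function(loci, j, h, count) {
    L <- nLoci(loci)
    o <- order((j - 1) * L + h)
    cnt <- data.frame(j = as.integer(j[o]), h = as.integer(h[o]),
                      count = as.integer(count[o]))
    ends <- numeric(L)
    agg <- rowsum(c(cnt$count, cnt$count), c(cnt$j, cnt$h))
    ends[as.integer(rownames(agg))] <- agg[, 1]
    new("BinnedContacts", loci = loci, counts = cnt, ends = ends,
        N = sum(cnt$count))
}
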