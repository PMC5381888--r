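test_that("expectedProbability is the coverage product with factor 2", {
    expect_equal(expectedProbability(0.1, 0.2), 0.04)
    expect_equal(expectedProbability(0, 0.2), 0)
    expect_equal(expectedProbability(0.1, 0.2, fRandom = 0.5), 0.02)
    expect_error(expectedProbability(0.1, 0.2, fRandom = 0), "fRandom")
    expect_error(expectedProbability(1.2, 0.2), "coverages")
})

test_that("binomialPvalue boundary cases are exact", {
    expect_identical(binomialPvalue(0, 10, 0.3), 1)
    expect_identical(binomialPvalue(0, 0, 0.3), 1)
    expect_identical(binomialPvalue(3, 10, 0), 0)
    expect_equal(binomialPvalue(1, 10, 0.1), 1 - 0.9^10, tolerance = 1e-14)
    expect_error(binomialPvalue(11, 10, 0.1), "n must")
    expect_error(binomialPvalue(1, 10, 1.1), "p must")
})

test_that("binomialPvalue matches brute-force pmf summation", {
    # frozen value from the summation oracle: N = 10000, p = 2e-4, n = 8
    expect_equal(binomialPvalue(8, 10000, 2e-4), 1.0950011292143e-3,
                 tolerance = 1e-10)
    for (N in c(10, 100, 1000)) {
        for (p in c(1e-6, 1e-3, 0.05, 0.5)) {
            ns <- unique(pmin(N, c(0, 1, 2, 5, ceiling(N * p) + c(0, 3))))
            for (n in ns)
                expect_equal(binomialPvalue(n, N, p), bruteTail(n, N, p),
                             tolerance = 1e-10)
        }
    }
})

test_that("binomialPvalue stays finite and ordered deep in the tail", {
    # N ~ 1e8, p ~ 1e-12: naive 1 - CDF would underflow to 0 long before n = 5
    ps <- binomialPvalue(1:5, 1e8, 1e-12)
    expect_true(all(ps > 0))
    expect_true(all(diff(log(ps)) < -5))
    expect_equal(ps[1], -expm1(1e8 * log1p(-1e-12)), tolerance = 1e-12)
})

test_that("p-values are monotone in n and in p", {
    p <- binomialPvalue(0:20, 100, 0.05)
    expect_true(all(diff(p) < 0))
    grid <- c(1e-6, 1e-4, 1e-2, 0.1, 0.5)
    expect_true(all(diff(binomialPvalue(rep(3, 5), 100, grid)) > 0))
})

test_that("bhAdjust equals BH on the materialized padded list", {
    expect_equal(bhAdjust(0.01, 1), 0.01)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03), 6), rep(0.06, 3))
    expect_equal(bhAdjust(rep(1, 4), 10), rep(1, 4))
    set.seed(99)
    for (i in 1:25) {
        s <- sample(1:40, 1)
        m <- s + sample(0:60, 1)
        p <- round(runif(s), 3)            # rounding forces ties
        expect_equal(bhAdjust(p, m),
                     p.adjust(c(p, rep(1, m - s)), "BH")[seq_len(s)])
    }
    expect_error(bhAdjust(c(0.1, 0.2), 1), "m must")
})

test_that("q-values are valid: ordered with p, never below p", {
    set.seed(7)
    p <- runif(50)
    q <- bhAdjust(p, 200)
    expect_true(all(q >= p))
    o <- order(p)
    expect_true(all(diff(q[o]) >= 0))
})

test_that("logRatio measures log2 observed over expected", {
    expect_equal(logRatio(40, 1000, 0.04), 0)
    expect_equal(logRatio(80, 1000, 0.04), 1)
    expect_true(is.na(logRatio(0, 1000, 0.04)))
    expect_error(logRatio(3, 1000, 0), "zero-coverage")
})

test_that("callInteractions reproduces a scripted oracle on the 4-locus fixture", {
    lm <- makeBins(c(chr1 = 4e6), 1e6)
    bc <- contactsFromCounts(lm, j = c(1, 2, 1, 3), h = c(2, 3, 4, 3),
                             count = c(3, 5, 2, 1))
    res <- callInteractions(bc)
    # oracle: direct evaluation of the model formulas + padded-BH via p.adjust
    r <- c(5, 8, 7, 2) / 22
    N <- 11
    oj <- c(1, 2, 1); oh <- c(2, 3, 4)     # off-diagonal tested pairs
    on <- c(3, 5, 2)
    op <- 2 * r[oj] * r[oh]
    opv <- vapply(seq_along(on), function(i) bruteTail(on[i], N, op[i]),
                  numeric(1))
    oqv <- p.adjust(c(opv, rep(1, 6 - 3)), "BH")[1:3]
    oR <- log2(on / (op * N))
    expect_equal(nrow(res), 3L)            # the (3,3) self pair is never tested
    expect_equal(attr(res, "m"), 6)
    key <- paste(res$bin1, res$bin2)
    idx <- match(paste(oj, oh), key)
    expect_equal(res$readCount[idx], on)
    expect_equal(res$expected[idx], op * N, tolerance = 1e-12)
    expect_equal(res$pvalue[idx], opv, tolerance = 1e-12)
    expect_equal(res$qvalue[idx], oqv, tolerance = 1e-12)
    expect_equal(res$logObsExp[idx], oR, tolerance = 1e-12)
    expect_true(all(diff(res$qvalue) >= 0))    # sorted output
})

test_that("callInteractions options: zero pairs, adjacency, L policy, empty input", {
    lm <- makeBins(c(chr1 = 3e6, chr2 = 2e6), 1e6)
    bc <- contactsFromCounts(lm, j = c(1, 1), h = c(2, 4), count = c(4, 6))
    expect_equal(nrow(callInteractions(bc)), 2L)
    all10 <- callInteractions(bc, testZeroPairs = TRUE)
    expect_equal(nrow(all10), 10L)
    expect_true(all(all10$pvalue[all10$readCount == 0] == 1))
    # adjacent same-chromosome pair (1,2) removed; (3,4) spans chromosomes
    noAdj <- callInteractions(bc, removeAdjacent = TRUE, testZeroPairs = TRUE)
    expect_equal(nrow(noAdj), 10L - 3L)
    expect_false(any(noAdj$bin1 == 1 & noAdj$bin2 == 2))
    expect_true(any(noAdj$bin1 == 3 & noAdj$bin2 == 4))
    # L policy: only 3 bins carry reads
    resNz <- callInteractions(bc, LPolicy = "nonzero")
    expect_equal(attr(resNz, "L"), 3)
    expect_equal(attr(resNz, "m"), 3)
    empty <- contactsFromCounts(lm, integer(), integer(), integer())
    expect_error(callInteractions(empty), "N = 0")
})

test_that("scaling counts up can only strengthen enriched pairs", {
    lm <- makeBins(c(chr1 = 4e6), 1e6)
    bc <- contactsFromCounts(lm, j = c(1, 1, 2), h = c(2, 3, 3),
                             count = c(30, 5, 10))
    bc10 <- contactsFromCounts(lm, j = c(1, 1, 2), h = c(2, 3, 3),
                               count = 10 * c(30, 5, 10))
    r1 <- callInteractions(bc); r10 <- callInteractions(bc10)
    key <- paste(r1$bin1, r1$bin2)
    idx <- match(key, paste(r10$bin1, r10$bin2))
    enriched <- r1$readCount > r1$expected
    expect_true(all(r10$pvalue[idx][enriched] <= r1$pvalue[enriched]))
})

test_that("null normalization identity holds on arbitrary contacts", {
    lm <- toyLocusMap()
    bc <- binContacts(randomPairs(1000, seed = 13), lm)
    nn <- nullNormalization(bc)
    expect_equal(nn$sumR, 1, tolerance = 1e-12)
    expect_equal(nn$offDiagonalMass + nn$diagonalMass, 1, tolerance = 1e-12)
})

test_that("interaction tables round-trip through the text format", {
    lm <- toyLocusMap()
    bc <- binContacts(randomPairs(500, seed = 21), lm)
    res <- callInteractions(bc)
    f <- tempfile()
    writeInteractions(res, f)
    hdr <- strsplit(readLines(f, n = 1), "\t")[[1]]
    expect_equal(hdr, c("chr1", "start1", "end1", "chr2", "start2", "end2",
                        "readCount", "expected", "logObsExp", "pvalue",
                        "qvalue", "significant"))
    back <- readInteractions(f)
    expect_equal(nrow(back), nrow(res))
    expect_equal(back$start1, res$start1)
    expect_equal(back$readCount, res$readCount)
    expect_equal(back$pvalue, res$pvalue, tolerance = 1e-5)
})
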