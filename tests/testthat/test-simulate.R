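bigMap <- function(L) makeBins(c(chrS = L * 1e6), 1e6)

test_that("bias profiles are normalized, seeded, and shape-controlled", {
    lm <- bigMap(1000)
    p1 <- simulateBiasProfile(lm, shape = 1, seed = 5)
    p2 <- simulateBiasProfile(lm, shape = 1, seed = 5)
    expect_identical(biasWeights(p1), biasWeights(p2))
    expect_equal(sum(biasWeights(p1)), 1, tolerance = 1e-12)
    # gamma CV = 1/sqrt(shape): empirical CV ~ 1 at shape 1
    w <- biasWeights(p1)
    expect_equal(sd(w) / mean(w), 1, tolerance = 0.15)
    # large-shape limit approaches uniform weights
    pu <- simulateBiasProfile(lm, shape = 1e6, seed = 5)
    expect_lt(max(abs(biasWeights(pu) * 1000 - 1)), 0.01)
    expect_error(simulateBiasProfile(lm, shape = 0), "shape")
})

test_that("random ligation conserves pairs and is seed-deterministic", {
    lm <- bigMap(50)
    prof <- simulateBiasProfile(lm, shape = 1, seed = 2)
    sim <- simulateRandomLigation(prof, 20000, seed = 3)
    expect_equal(totalPairs(sim), 20000)
    expect_equal(sum(contactCounts(sim)$count), 20000)
    expect_equal(sum(endCounts(sim)), 40000)
    sim2 <- simulateRandomLigation(prof, 20000, seed = 3)
    expect_identical(contactCounts(sim), contactCounts(sim2))
    expect_equal(nrow(contactCounts(simulateRandomLigation(prof, 0))), 0L)
})

test_that("chunk boundaries do not change the simulated stream", {
    lm <- bigMap(30)
    prof <- simulateBiasProfile(lm, shape = 1, seed = 9)
    a <- simulateRandomLigation(prof, 10000, seed = 1, chunkSize = 10000)
    b <- simulateRandomLigation(prof, 10000, seed = 1, chunkSize = 1234)
    expect_identical(contactCounts(a), contactCounts(b))
})

test_that("uniform weights give the closed-form pair expectation", {
    L <- 20
    lm <- bigMap(L)
    prof <- uniformBiasProfile(lm)
    n <- 200000
    sim <- simulateRandomLigation(prof, n, seed = 4)
    # fixed unordered off-diagonal pair: expectation 2n/B^2, sd ~ sqrt
    exp1 <- 2 * n / L^2
    cnt <- contactCounts(sim)
    obs <- cnt$count[cnt$j == 3 & cnt$h == 11]
    expect_lt(abs(obs - exp1), 4 * sqrt(exp1))
})

test_that("trans fraction follows 1 - sum(Wc^2) for length-proportional weights", {
    lm <- makeBins(fixturePath("mm9.chrom.sizes"), 1e6)
    prof <- uniformBiasProfile(lm)
    sizes <- readChromSizes(fixturePath("mm9.chrom.sizes"))
    Wc <- sizes / sum(sizes)
    f <- 1 - sum(Wc^2)
    expect_gt(f, 0.93)        # mouse karyotype lands in the low-to-mid 90s
    expect_lt(f, 0.96)
    n <- 500000
    sim <- simulateRandomLigation(prof, n, seed = 6)
    expect_lt(abs(transFraction(sim) - f), 4 * sqrt(f * (1 - f) / n))
})

test_that("spike-in law reduces to the null when all multipliers are 1", {
    lm <- bigMap(25)
    prof <- simulateBiasProfile(lm, shape = 2, seed = 8)
    spikes <- data.frame(j = c(1L, 2L), h = c(5L, 9L), e = 1)
    n <- 300000
    ss <- simulateWithSpikeins(prof, n, spikes, seed = 10)
    expect_equal(totalPairs(ss$contacts), n)
    expect_identical(ss$truth, spikes)
    w <- biasWeights(prof)
    # closed-form expectations of the null pair law
    for (pr in list(c(1, 5), c(2, 9), c(3, 3))) {
        lambda <- if (pr[1] == pr[2]) n * w[pr[1]]^2 else
            n * 2 * w[pr[1]] * w[pr[2]]
        cnt <- contactCounts(ss$contacts)
        obs <- sum(cnt$count[cnt$j == pr[1] & cnt$h == pr[2]])
        expect_lt(abs(obs - lambda), 4 * sqrt(lambda) + 1)
    }
})

test_that("spiked pairs match their renormalized closed-form expectation", {
    lm <- bigMap(100)
    prof <- simulateBiasProfile(lm, shape = 1, seed = 12)
    spikes <- sampleSpikeins(lm, 10, enrichment = 20, seed = 13)
    n <- 1e6
    ss <- simulateWithSpikeins(prof, n, spikes, seed = 14)
    w <- biasWeights(prof)
    qnull <- outer(w, w)
    qjh <- 2 * qnull[upper.tri(qnull)]
    tot <- sum(w^2) + sum(qjh) + sum(2 * w[spikes$j] * w[spikes$h] * (spikes$e - 1))
    cnt <- contactCounts(ss$contacts)
    key <- (cnt$j - 1) * 100 + cnt$h
    for (i in seq_len(nrow(spikes))) {
        lambda <- n * 20 * 2 * w[spikes$j[i]] * w[spikes$h[i]] / tot
        obs <- sum(cnt$count[key == (spikes$j[i] - 1) * 100 + spikes$h[i]])
        expect_lt(abs(obs - lambda), 4 * sqrt(lambda) + 1)
    }
    expect_error(simulateWithSpikeins(prof, 10, data.frame(j = 1, h = 101, e = 2)),
                 "j < h")
    expect_error(simulateWithSpikeins(prof, 10, data.frame(j = 1, h = 2, e = 0.5)),
                 "multipliers")
})

test_that("simulated contacts round-trip through a synthetic pairs file", {
    lm <- toyLocusMap()
    prof <- simulateBiasProfile(lm, shape = 1, seed = 15)
    sim <- simulateRandomLigation(prof, 2000, seed = 16)
    f <- tempfile(fileext = ".pairs")
    writeSimulatedPairs(sim, f, seed = 17)
    rebinned <- binContacts(readPairs(f), lm)
    expect_equal(contactCounts(rebinned), contactCounts(sim))
    expect_equal(endCounts(rebinned), endCounts(sim))
})
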