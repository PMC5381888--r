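toyFragMap <- function()
    readFragmentsBed(fixturePath("filter_fixture_fragments.bed"),
                     motif = "AAGCTT", cutOffset = 1)

test_that("pairs text parsing and canonicalization", {
    f <- tempfile()
    writeLines(c("#chrom1\tpos1\tstrand1\tchrom2\tpos2\tstrand2",
                 "chr1\t100\t+\tchr2\t200\t-",
                 "chr2\t200\t-\tchr1\t100\t+",     # swapped ends
                 "chr1\t500\t-\tchr1\t100\t+"), f) # swapped cis
    p <- readPairs(f)
    expect_equal(nrow(p), 3L)
    expect_equal(p$chrom1, c("chr1", "chr1", "chr1"))
    expect_equal(p$pos1, c(100, 100, 100))
    expect_identical(p[1, ], p[2, ], ignore_attr = TRUE)
    expect_equal(p$strand1[3], "+")                # strands travel with ends
    writeLines("chr1\t100\t+\tchr2\tnope\t-", f)
    expect_error(readPairs(f), "line 1")
    writeLines("chr1\t100\t+", f)
    expect_error(readPairs(f), "6 tab-separated")
})

test_that("name-paired SAM alignments become read pairs, orphans are skipped", {
    sam <- tempfile(fileext = ".sam")
    writeLines(c(
        "@HD\tVN:1.6\tSO:queryname",
        "@SQ\tSN:chrA\tLN:100000",
        "@SQ\tSN:chrB\tLN:60000",
        # r1: chrA:101(+) / chrB:201(-)  (SAM 1-based)
        "r1\t0\tchrA\t101\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
        "r1\t16\tchrB\t201\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
        # r2: both ends chrA, second low mapq
        "r2\t0\tchrA\t501\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
        "r2\t16\tchrA\t901\t5\t10M\t*\t0\t0\tACGTACGTAC\t*",
        # r3: orphan
        "r3\t0\tchrA\t701\t60\t10M\t*\t0\t0\tACGTACGTAC\t*"), sam)
    expect_warning(p <- readPairs(sam, mapq = 0), "without exactly one mate")
    expect_equal(nrow(p), 2L)
    expect_equal(p$pos1, c(100, 500))              # 0-based conversion
    expect_equal(p$chrom2[1], "chrB")
    expect_equal(p$strand2, c("-", "-"))
    # mapq threshold orphans r2 as well
    expect_warning(p10 <- readPairs(sam, mapq = 10), "without exactly one mate")
    expect_equal(nrow(p10), 1L)
})

test_that("removeDuplicates keeps the first occurrence per exact key", {
    p <- data.frame(chrom1 = "chrA", pos1 = c(1, 1, 1), strand1 = c("+", "+", "-"),
                    chrom2 = "chrB", pos2 = 2, strand2 = "-")
    dd <- removeDuplicates(p)
    expect_equal(dd$nRemoved, 1L)                   # strand1 differs -> kept
    expect_equal(nrow(dd$pairs), 2L)
    empty <- removeDuplicates(p[0, ])
    expect_equal(empty$nRemoved, 0L)
    expect_equal(nrow(empty$pairs), 0L)
})

test_that("annotateFragments assigns containing-fragment indices", {
    fm <- toyFragMap()
    p <- data.frame(chrom1 = c("chrA", "chrA"), pos1 = c(5, 41000),
                    strand1 = "+", chrom2 = c("chrA", "chrA"),
                    pos2 = c(25000, 69000), strand2 = "-")
    a <- annotateFragments(p, fm)
    expect_equal(a$frag1, c(1L, 3L))
    expect_equal(a$frag2, c(2L, 3L))
    p$chrom2[2] <- "chrZ"
    expect_warning(a2 <- annotateFragments(p, fm), "dropping 1")
    expect_equal(nrow(a2), 1L)
    expect_error(annotateFragments(p, fm, onMissing = "error"), "absent")
})

test_that("artefact filter removes same-fragment and close cis pairs, never trans", {
    fm <- toyFragMap()
    p <- data.frame(
        chrom1 = c("chrA", "chrA", "chrA", "chrA"),
        pos1 = c(41000, 39000, 35000, 1000), strand1 = "+",
        chrom2 = c("chrA", "chrA", "chrA", "chrB"),
        pos2 = c(69000, 40500, 45000, 50000), strand2 = "-")
    # same fragment at 28 kb | cis 1.5 kb across fragments |
    # cis exactly 10 kb across fragments | trans
    flt <- filterArtefacts(annotateFragments(p, fm), minDistance = 10000)
    s <- flt$stats
    expect_equal(s@sameFragment, 1L)
    expect_equal(s@proximity, 1L)
    expect_equal(s@retained, 2L)
    expect_equal(s@cis, 1L)        # the exact-10kb pair is retained (strict <)
    expect_equal(s@trans, 1L)
    expect_error(filterArtefacts(annotateFragments(p, fm), minDistance = -1),
                 "minDistance")
})

test_that("filtering is idempotent and order-invariant", {
    fm <- toyFragMap()
    p <- annotateFragments(readPairs(fixturePath("filter_fixture.pairs")), fm)
    dd <- removeDuplicates(p)
    flt <- filterArtefacts(dd$pairs, nDuplicates = dd$nRemoved)
    again <- filterArtefacts(flt$pairs)
    expect_equal(again$stats@sameFragment, 0L)
    expect_equal(again$stats@proximity, 0L)
    expect_equal(again$stats@retained, flt$stats@retained)
    set.seed(1)
    perm <- p[sample(nrow(p)), ]
    dd2 <- removeDuplicates(perm)
    flt2 <- filterArtefacts(dd2$pairs, nDuplicates = dd2$nRemoved)
    for (slot in c("input", "duplicates", "sameFragment", "proximity",
                   "retained", "cis", "trans"))
        expect_equal(methods::slot(flt2$stats, slot),
                     methods::slot(flt$stats, slot))
})

test_that("FilterStats conservation is enforced by the class", {
    expect_error(new("FilterStats", input = 5L, duplicates = 1L,
                     sameFragment = 1L, proximity = 1L, retained = 1L,
                     cis = 1L, trans = 0L), "must equal input")
    expect_error(new("FilterStats", input = 4L, duplicates = 1L,
                     sameFragment = 1L, proximity = 1L, retained = 1L,
                     cis = 1L, trans = 1L), "cis \\+ trans")
})

test_that("pairs survive a write/read round trip", {
    p <- randomPairs(50, seed = 3)
    f <- tempfile()
    writePairsFile(p, f)
    back <- readPairs(f)
    expect_equal(back, p, ignore_attr = TRUE)
})
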