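#' Full interaction-calling pipeline
#'
#' Runs read ingestion, optional duplicate removal, fragment annotation and
#' artefact filtering, contact binning and binomial interaction calling in
#' one deterministic pass: fixed inputs and configuration give byte-identical
#' output tables.
#'
#' Without a fragment map the same-fragment rule cannot be evaluated; only
#' the cis-distance rule is applied and `sameFragment` is reported as 0.
#'
#' @param pairs path to a pairs/SAM/BAM file, or a read-pair data.frame from
#'   [readPairs()].
#' @param loci a [LocusMap-class], or a named vector / file of chromosome
#'   sizes combined with `binSize`.
#' @param fragMap optional [FragmentMap-class] for same-fragment filtering.
#' @param binSize bin width when `loci` is given as chromosome sizes.
#' @param minDistance minimum cis separation (bp) for the artefact filter.
#' @param dedupe remove exact duplicate pairs first (default TRUE).
#' @param mapq minimum mapping quality for alignment input.
#' @param fdr,fRandom,removeAdjacent,testZeroPairs,LPolicy passed to
#'   [callInteractions()].
#' @return list of class `"hicbinomRun"` with elements `interactions`,
#'   `stats` ([FilterStats-class]), `contacts` ([BinnedContacts-class]),
#'   `qc` (see [qcReport()]) and `config` (the effective configuration).
#' @export
runCall <- function(pairs, loci, fragMap = NULL, binSize = 1e6,
                    minDistance = 10000, dedupe = TRUE, mapq = 0,
                    fdr = 0.05, fRandom = 1, removeAdjacent = FALSE,
                    testZeroPairs = FALSE, LPolicy = "all") {
    config <- list(binSize = binSize, minDistance = minDistance,
                   dedupe = dedupe, mapq = mapq, fdr = fdr,
                   fRandom = fRandom, removeAdjacent = removeAdjacent,
                   testZeroPairs = testZeroPairs, LPolicy = LPolicy)
    if (is.character(pairs)) pairs <- readPairs(pairs, mapq = mapq)
    if (!is(loci, "LocusMap")) loci <- makeBins(loci, binSize)
    nDup <- 0L
    if (dedupe) {
        dd <- removeDuplicates(pairs)
        pairs <- dd$pairs
        nDup <- dd$nRemoved
    }
    if (!is.null(fragMap)) {
        pairs <- annotateFragments(pairs, fragMap)
    } else {
        pairs$frag1 <- seq_len(nrow(pairs))    # no map: same-fragment rule off
        pairs$frag2 <- -seq_len(nrow(pairs))
    }
    flt <- filterArtefacts(pairs, minDistance = minDistance,
                           nDuplicates = nDup)
    contacts <- binContacts(flt$pairs, loci)
    interactions <- callInteractions(contacts, fdr = fdr, fRandom = fRandom,
                                     removeAdjacent = removeAdjacent,
                                     testZeroPairs = testZeroPairs,
                                     LPolicy = LPolicy)
    res <- list(interactions = interactions, stats = flt$stats,
                contacts = contacts,
                qc = qcReport(flt$stats, contacts, interactions),
                config = config)
    class(res) <- "hicbinomRun"
    res
}

#' @export
print.hicbinomRun <- function(x, ...) {
    show(x$stats)
    cat(sprintf("Tests: m = %s over L = %d loci; %d significant interaction(s) at FDR %g\n",
                format(x$qc$m, big.mark = ","), x$qc$L,
                x$qc$n_significant, attr(x$interactions, "fdr")))
    invisible(x)
}

#' Quality-control report for a pipeline run
#'
#' Summarises filtering tallies, the cis/trans split, coverage dispersion
#' (coefficient of variation of the relative coverages), the size of the test
#' universe and the significant-interaction count. A zero significant count
#' is flagged with a library-quality note: libraries dominated by spurious
#' ligations yield near-uniform p-values and few or no significant calls.
#'
#' @param stats a [FilterStats-class].
#' @param contacts a [BinnedContacts-class].
#' @param interactions result of [callInteractions()].
#' @return named list of QC quantities (JSON-ready apart from `note`).
#' @export
qcReport <- function(stats, contacts, interactions) {
    r <- if (contacts@N > 0) computeCoverage(contacts) else numeric(0)
    nSig <- sum(interactions$significant)
    qc <- c(filterStatsList(stats),
            list(cis_fraction = if (stats@retained > 0)
                     stats@cis / stats@retained else NA_real_,
                 trans_fraction = if (stats@retained > 0)
                     stats@trans / stats@retained else NA_real_,
                 coverage_cv = if (length(r) && mean(r) > 0)
                     stats::sd(r) / mean(r) else NA_real_,
                 L = attr(interactions, "L"),
                 m = attr(interactions, "m"),
                 n_tested = nrow(interactions),
                 n_significant = nSig))
    if (nSig == 0L)
        qc$note <- paste("no significant interactions: consistent with a",
                         "random-ligation-dominated (poor quality) library")
    qc
}

#' Write a QC report
#'
#' @param qc list from [qcReport()].
#' @param path output path; written as JSON, with a plain-text `key: value`
#'   rendering alongside when `text = TRUE`.
#' @param text also write `<path>.txt`.
#' @return `path`, invisibly.
#' @export
writeQcReport <- function(qc, path, text = TRUE) {
    jsonlite::write_json(qc, path, auto_unbox = TRUE, digits = NA)
    if (text) {
        lines <- vapply(names(qc), function(k)
            paste0(k, ": ", format(qc[[k]])), character(1))
        writeLines(lines, paste0(path, ".txt"))
    }
    invisible(path)
}

#' Coverage independence of the interaction ranking
#'
#' Diagnostic for residual coverage bias in the calls: loci are split into
#' quartiles of relative coverage, the full universe of \eqn{L(L-1)/2} tested
#' bin pairs into quartiles of significance rank, and each pair is assigned
#' to the coverage quartile of each of its two loci. For a well-calibrated
#' model the rank-quartile composition within every coverage quartile is near
#' 25\% each.
#'
#' The ranking covers the observed interactions (pairs with at least one read
#' pair), which is what an interaction list contains; unobserved pairs are
#' indistinguishably tied at p = 1 and carry no ranking information. Note
#' that conditioning on n >= 1 is itself coverage-dependent in a correctly
#' calibrated null — a low-expectation pair that is observed at all tends to
#' rank high — so residual deviation of a few percentage points in the
#' extreme coverage quartiles is expected even for a perfectly specified
#' model under strong coverage heterogeneity.
#'
#' @param interactions result of [callInteractions()].
#' @param contacts the [BinnedContacts-class] they were called on.
#' @return 4 x 4 matrix of proportions; rows are coverage quartiles (low to
#'   high, rows sum to 1), columns are significance-rank quartiles (top
#'   ranked first).
#' @export
coverageIndependence <- function(interactions, contacts) {
    stopifnot(is(contacts, "BinnedContacts"))
    r <- computeCoverage(contacts)
    L <- length(r)
    covQ <- ceiling(4 * rank(r, ties.method = "first") / L)
    n <- nrow(interactions)
    if (n == 0L) stop("no tested interactions")
    # interactions arrive sorted by significance rank; each contributes to
    # the coverage quartile of both of its loci
    rankQ <- ceiling(4 * seq_len(n) / n)
    cb <- c(covQ[interactions$bin1], covQ[interactions$bin2])
    tab <- table(factor(cb, levels = 1:4), factor(c(rankQ, rankQ), levels = 1:4))
    prop <- prop.table(tab, margin = 1)
    matrix(as.numeric(prop), 4, 4,
           dimnames = list(coverage = paste0("covQ", 1:4),
                           rank = paste0("rankQ", 1:4)))
}
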