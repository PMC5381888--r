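#' Accessors for HiCbinom classes
#'
#' Small accessor generics: `bins()` and `binSize()` for [LocusMap-class],
#' `fragments()` for [FragmentMap-class], `nLoci()` for the number of bins,
#' `locusMap()`, `contactCounts()`, `endCounts()` and `totalPairs()` for
#' [BinnedContacts-class], and `biasWeights()` for [BiasProfile-class].
#'
#' @param x an object of the documented class.
#' @return `bins()` and `fragments()` return a `GRanges`; `binSize()`,
#'   `nLoci()` and `totalPairs()` a single number; `contactCounts()` a
#'   data.frame with columns `j`, `h`, `count`; `endCounts()` and
#'   `biasWeights()` a numeric vector with one entry per bin; `locusMap()` a
#'   [LocusMap-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))
#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @rdname accessors
#' @export
setGeneric("locusMap", function(x) standardGeneric("locusMap"))
#' @rdname accessors
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))
#' @rdname accessors
#' @export
setGeneric("endCounts", function(x) standardGeneric("endCounts"))
#' @rdname accessors
#' @export
setGeneric("totalPairs", function(x) standardGeneric("totalPairs"))
#' @rdname accessors
#' @export
setGeneric("biasWeights", function(x) standardGeneric("biasWeights"))

#' Map genomic positions to locus or fragment indices
#'
#' Returns, for each (chromosome, position) pair, the 1-based index of the
#' unique interval of `map` that contains it. Positions are 0-based genomic
#' offsets under half-open interval semantics: a position equal to an
#' interval's (0-based) start maps to that interval; a position equal to its
#' end maps to the next one.
#'
#' @param map a [LocusMap-class] or [FragmentMap-class].
#' @param chrom character vector of chromosome names.
#' @param pos numeric vector of 0-based positions, recycled against `chrom`.
#' @return integer vector of 1-based interval indices.
#' @examples
#' lm <- makeBins(c(chr1 = 2500000), 1e6)
#' locusIndex(lm, "chr1", c(0, 999999, 1000000, 2499999))
#' @export
setGeneric("locusIndex", function(map, chrom, pos) standardGeneric("locusIndex"))

#' @rdname accessors
#' @export
setMethod("bins", "LocusMap", function(x) x@bins)
#' @rdname accessors
#' @export
setMethod("binSize", "LocusMap", function(x) x@binSize)
#' @rdname accessors
#' @export
setMethod("nLoci", "LocusMap", function(x) length(x@bins))
#' @rdname accessors
#' @export
setMethod("fragments", "FragmentMap", function(x) x@fragments)
#' @rdname accessors
#' @export
setMethod("nLoci", "FragmentMap", function(x) length(x@fragments))
#' @rdname accessors
#' @export
setMethod("locusMap", "BinnedContacts", function(x) x@loci)
#' @rdname accessors
#' @export
setMethod("contactCounts", "BinnedContacts", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("endCounts", "BinnedContacts", function(x) x@ends)
#' @rdname accessors
#' @export
setMethod("totalPairs", "BinnedContacts", function(x) x@N)
#' @rdname accessors
#' @export
setMethod("locusMap", "BiasProfile", function(x) x@loci)
#' @rdname accessors
#' @export
setMethod("biasWeights", "BiasProfile", function(x) x@weights)
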