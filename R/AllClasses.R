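#' @import methods
#' @importFrom GenomicRanges GRanges start end width seqnames strand
#' @importFrom IRanges IRanges
NULL

## ---------------------------------------------------------------------------
## PrimerPair
## ---------------------------------------------------------------------------

#' Bisulfite PCR primer pair
#'
#' A pair of primers designed against the bisulfite-converted top strand of a
#' genomic region. The forward primer matches the converted strand directly;
#' the reverse primer's reverse complement matches the converted strand
#' downstream of the forward footprint. IUPAC codes Y and R are allowed so
#' that a primer overlapping a CpG can amplify both methylated (C retained)
#' and unmethylated (C read as T) templates.
#'
#' @slot forward character. Forward primer sequence (5'->3').
#' @slot reverse character. Reverse primer sequence (5'->3').
#' @slot label character. Identifier for the pair.
#'
#' @seealso [insilicoPcr()], [readPrimerPairs()]
#' @export
setClass("PrimerPair",
    representation(forward = "character", reverse = "character",
                   label = "character"))

setValidity("PrimerPair", function(object) {
    msg <- character()
    for (side in c("forward", "reverse")) {
        p <- slot(object, side)
        if (length(p) != 1L || is.na(p) || !nzchar(p))
            msg <- c(msg, sprintf("'%s' must be a single non-empty string", side))
        else {
            if (nchar(p) < 15L)
                msg <- c(msg, sprintf("'%s' primer must be at least 15 nt", side))
            if (grepl("[^ACGTYR]", p))
                msg <- c(msg, sprintf("'%s' primer has characters outside {A,C,G,T,Y,R}", side))
        }
    }
    if (length(object@label) != 1L)
        msg <- c(msg, "'label' must be a single string")
    if (length(msg)) msg else TRUE
})

#' @param forward,reverse primer sequences (5'->3'), characters in
#'   \{A,C,G,T,Y,R\}, length >= 15.
#' @param label identifier for the pair.
#' @return A `PrimerPair` object.
#' @examples
#' PrimerPair("GAATTTGGGTTTTTATTTTTTAGG", "CCAAACCCTAAAACTAACTCTCTC", "miR34b")
#' @rdname PrimerPair-class
#' @export
PrimerPair <- function(forward, reverse, label = "primer_pair") {
    new("PrimerPair", forward = toupper(as.character(forward)),
        reverse = toupper(as.character(reverse)), label = as.character(label))
}

#' @rdname PrimerPair-class
#' @param object,x a `PrimerPair`.
#' @export
setGeneric("forwardPrimer", function(x) standardGeneric("forwardPrimer"))
#' @rdname PrimerPair-class
#' @export
setGeneric("reversePrimer", function(x) standardGeneric("reversePrimer"))
#' @rdname PrimerPair-class
#' @export
setMethod("forwardPrimer", "PrimerPair", function(x) x@forward)
#' @rdname PrimerPair-class
#' @export
setMethod("reversePrimer", "PrimerPair", function(x) x@reverse)

setMethod("show", "PrimerPair", function(object) {
    cat("PrimerPair '", object@label, "'\n", sep = "")
    cat("  forward: 5'-", object@forward, "-3' (", nchar(object@forward), " nt)\n", sep = "")
    cat("  reverse: 5'-", object@reverse, "-3' (", nchar(object@reverse), " nt)\n", sep = "")
})

## ---------------------------------------------------------------------------
## AmpliconHit
## ---------------------------------------------------------------------------

#' In-silico bisulfite PCR product
#'
#' The result of placing a [PrimerPair] on a reference sequence: the
#' primer-inclusive amplicon interval in native (unconverted) coordinates,
#' its length, and the positions of the CpG cytosines of the native sequence
#' that fall inside the amplicon.
#'
#' Coordinates are 1-based and inclusive ([GenomicRanges::GRanges]
#' convention).
#'
#' @slot interval `GRanges` of length 1, the primer-inclusive amplicon.
#' @slot ampliconLength integer, product length in bp.
#' @slot cpgSites integer vector, native positions of CpG 'C's inside the
#'   amplicon, strictly increasing.
#' @slot isUnique logical, TRUE when both primer placements were unique.
#'
#' @seealso [insilicoPcr()]
#' @export
setClass("AmpliconHit",
    representation(interval = "GRanges", ampliconLength = "integer",
                   cpgSites = "integer", isUnique = "logical"))

setValidity("AmpliconHit", function(object) {
    msg <- character()
    if (length(object@interval) != 1L)
        msg <- c(msg, "'interval' must contain exactly one range")
    else {
        if (object@ampliconLength != GenomicRanges::width(object@interval))
            msg <- c(msg, "'ampliconLength' must equal the interval width")
        s <- GenomicRanges::start(object@interval)
        e <- GenomicRanges::end(object@interval)
        if (length(object@cpgSites)) {
            if (is.unsorted(object@cpgSites, strictly = TRUE))
                msg <- c(msg, "'cpgSites' must be strictly increasing")
            if (min(object@cpgSites) < s || max(object@cpgSites) + 1L > e)
                msg <- c(msg, "'cpgSites' must lie within the amplicon (CpG 'G' included)")
        }
    }
    if (length(msg)) msg else TRUE
})

#' @rdname AmpliconHit-class
#' @param x an `AmpliconHit`.
#' @export
setGeneric("ampliconRange", function(x) standardGeneric("ampliconRange"))
#' @rdname AmpliconHit-class
#' @export
setGeneric("ampliconLength", function(x) standardGeneric("ampliconLength"))
#' @rdname AmpliconHit-class
#' @export
setGeneric("cpgSites", function(x) standardGeneric("cpgSites"))
#' @rdname AmpliconHit-class
#' @export
setMethod("ampliconRange", "AmpliconHit", function(x) x@interval)
#' @rdname AmpliconHit-class
#' @export
setMethod("ampliconLength", "AmpliconHit", function(x) x@ampliconLength)
#' @rdname AmpliconHit-class
#' @export
setMethod("cpgSites", "AmpliconHit", function(x) x@cpgSites)

setMethod("show", "AmpliconHit", function(object) {
    iv <- object@interval
    cat("AmpliconHit: ", as.character(GenomicRanges::seqnames(iv)), ":",
        GenomicRanges::start(iv), "-", GenomicRanges::end(iv),
        " (", object@ampliconLength, " bp, ",
        length(object@cpgSites), " CpG sites, ",
        if (object@isUnique) "unique" else "non-unique", ")\n", sep = "")
})

## ---------------------------------------------------------------------------
## CloneMatrix
## ---------------------------------------------------------------------------

#' Clones-by-CpG-sites methylation call matrix
#'
#' The computational form of a bisulfite clone-sequencing figure: one row per
#' sequenced clone, one column per CpG site of the amplicon. Calls are coded
#' 1 (methylated: clone read C at the CpG cytosine), 0 (unmethylated: clone
#' read T) or NA (ambiguous: any other base). Each clone carries its
#' bisulfite conversion rate, the fraction of non-CpG reference cytosines
#' read as T, used for quality control.
#'
#' @slot sampleId character, sample identifier.
#' @slot sampleClass character, sample class label (e.g. "melanocyte",
#'   "stage3", "primary", "nevus").
#' @slot sitePositions integer, native 1-based positions of the CpG 'C's
#'   (one per column).
#' @slot calls integer matrix, clones x sites, values in \{1, 0, NA\}.
#' @slot conversionRates numeric, per-clone bisulfite conversion rate in
#'   \[0, 1\] (NA when the amplicon has no non-CpG cytosines to judge from).
#'
#' @seealso [callMethylation()], [siteFrequencies()],
#'   [classifyHypermethylation()], [renderCloneMatrix()]
#' @export
setClass("CloneMatrix",
    representation(sampleId = "character", sampleClass = "character",
                   calls = "matrix", sitePositions = "integer",
                   conversionRates = "numeric"))

setValidity("CloneMatrix", function(object) {
    msg <- character()
    if (length(object@sampleId) != 1L) msg <- c(msg, "'sampleId' must be a single string")
    if (length(object@sampleClass) != 1L) msg <- c(msg, "'sampleClass' must be a single string")
    cl <- object@calls
    if (!is.matrix(cl) || nrow(cl) < 1L)
        msg <- c(msg, "'calls' must be a matrix with at least one clone row")
    else {
        if (ncol(cl) != length(object@sitePositions))
            msg <- c(msg, "number of call columns must equal length(sitePositions)")
        if (nrow(cl) != length(object@conversionRates))
            msg <- c(msg, "one conversion rate per clone row is required")
        bad <- !(cl %in% c(0L, 1L) | is.na(cl))
        if (any(bad)) msg <- c(msg, "'calls' values must be 1, 0 or NA")
    }
    if (length(object@sitePositions) &&
        is.unsorted(object@sitePositions, strictly = TRUE))
        msg <- c(msg, "'sitePositions' must be strictly increasing")
    cr <- object@conversionRates
    if (any(!is.na(cr) & (cr < 0 | cr > 1)))
        msg <- c(msg, "'conversionRates' must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @param calls integer matrix (clones x sites) of \{1, 0, NA\} calls.
#' @param sitePositions integer vector of native CpG 'C' positions.
#' @param sampleId,sampleClass sample identifier and class label.
#' @param conversionRates per-clone conversion rates; defaults to NA
#'   (unknown) for every clone.
#' @return A `CloneMatrix` object.
#' @rdname CloneMatrix-class
#' @export
CloneMatrix <- function(calls, sitePositions, sampleId = "sample",
                        sampleClass = "unknown",
                        conversionRates = rep(NA_real_, nrow(calls))) {
    calls <- as.matrix(calls)
    storage.mode(calls) <- "integer"
    if (is.null(rownames(calls)))
        rownames(calls) <- sprintf("clone%02d", seq_len(nrow(calls)))
    new("CloneMatrix", sampleId = as.character(sampleId),
        sampleClass = as.character(sampleClass), calls = calls,
        sitePositions = as.integer(sitePositions),
        conversionRates = as.numeric(conversionRates))
}

#' @rdname CloneMatrix-class
#' @param x a `CloneMatrix`.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname CloneMatrix-class
#' @export
setGeneric("sampleClass", function(x) standardGeneric("sampleClass"))
#' @rdname CloneMatrix-class
#' @export
setGeneric("methCalls", function(x) standardGeneric("methCalls"))
#' @rdname CloneMatrix-class
#' @export
setGeneric("sitePositions", function(x) standardGeneric("sitePositions"))
#' @rdname CloneMatrix-class
#' @export
setGeneric("conversionRates", function(x) standardGeneric("conversionRates"))
#' @rdname CloneMatrix-class
#' @export
setMethod("sampleId", "CloneMatrix", function(x) x@sampleId)
#' @rdname CloneMatrix-class
#' @export
setMethod("sampleClass", "CloneMatrix", function(x) x@sampleClass)
#' @rdname CloneMatrix-class
#' @export
setMethod("methCalls", "CloneMatrix", function(x) x@calls)
#' @rdname CloneMatrix-class
#' @export
setMethod("sitePositions", "CloneMatrix", function(x) x@sitePositions)
#' @rdname CloneMatrix-class
#' @export
setMethod("conversionRates", "CloneMatrix", function(x) x@conversionRates)

#' @rdname CloneMatrix-class
#' @export
setMethod("nrow", "CloneMatrix", function(x) nrow(x@calls))
#' @rdname CloneMatrix-class
#' @export
setMethod("ncol", "CloneMatrix", function(x) ncol(x@calls))

setMethod("show", "CloneMatrix", function(object) {
    cat("CloneMatrix for sample '", object@sampleId, "' (class: ",
        object@sampleClass, ")\n", sep = "")
    cat("  ", nrow(object@calls), " clones x ", ncol(object@calls),
        " CpG sites\n", sep = "")
    freq <- suppressWarnings(mean(object@calls, na.rm = TRUE))
    cat("  overall methylation frequency: ",
        if (is.nan(freq)) "undefined" else sprintf("%.3f", freq), "\n", sep = "")
})
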