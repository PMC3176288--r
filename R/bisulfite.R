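#' Find CpG dinucleotide sites on the plus strand
#'
#' Returns the positions of the 'C' of every "CG" dinucleotide within the
#' given window. Both bases of the dinucleotide must lie inside the window.
#' Sites are called on the plus strand only: bisulfite PCR sequences one
#' converted strand per amplicon.
#'
#' @param seq a DNA sequence (character, `DNAString` or length-1
#'   `DNAStringSet`).
#' @param start,end 1-based inclusive window bounds; default the whole
#'   sequence.
#' @return Integer vector of 1-based 'C' positions, ascending (empty when
#'   the window holds no CpG).
#' @examples
#' findCpgSites("TACGTCACG")  # 3, 8
#' @export
findCpgSites <- function(seq, start = 1L, end = NULL) {
    s <- asDnaCharacter(seq)
    n <- nchar(s)
    if (is.null(end)) end <- n
    start <- as.integer(start); end <- as.integer(end)
    if (start < 1L || end > n || start > end)
        stop("window [", start, ", ", end, "] is outside the sequence (length ", n, ")")
    hits <- gregexpr("CG", s, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) return(integer(0))
    pos <- as.integer(hits)
    pos[pos >= start & pos + 1L <= end]
}

#' In-silico bisulfite conversion
#'
#' Deaminates cytosines the way sodium bisulfite chemistry does: every
#' non-CpG 'C' is read as 'T' with probability `efficiency`; a CpG 'C' is
#' protected when methylated and otherwise converted with the same
#' probability. All other bases are untouched. With `efficiency = 1` the
#' conversion is deterministic.
#'
#' @param seq a DNA sequence (character, `DNAString` or length-1 set).
#' @param methState logical/integer vector of per-CpG methylation flags,
#'   indexed by [findCpgSites()] over `seq` (1 = methylated).
#' @param efficiency conversion probability in \[0, 1\]; 1 by default.
#' @param seed optional integer; when given, conversion failures are drawn
#'   from a private seeded stream and the caller's RNG is untouched.
#' @return The converted sequence as a character string.
#' @examples
#' bisulfiteConvert("TACGTCACG", c(0, 0))  # "TATGTTATG"
#' bisulfiteConvert("TACGTCACG", c(1, 1))  # "TACGTTACG"
#' @export
bisulfiteConvert <- function(seq, methState, efficiency = 1, seed = NULL) {
    s <- asDnaCharacter(seq)
    if (length(efficiency) != 1L || is.na(efficiency) ||
        efficiency < 0 || efficiency > 1)
        stop("'efficiency' must be a single value in [0, 1]")
    cpg <- findCpgSites(s)
    methState <- as.integer(methState)
    if (length(methState) != length(cpg))
        stop("'methState' has length ", length(methState),
             " but the sequence has ", length(cpg), " CpG sites")
    if (efficiency == 0) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    isC <- ch == "C"
    convertible <- which(isC)
    protected <- cpg[methState == 1L]
    convertible <- setdiff(convertible, protected)
    if (length(convertible)) {
        withSeed(seed, {
            doConvert <- if (efficiency >= 1) rep(TRUE, length(convertible))
                         else stats::runif(length(convertible)) < efficiency
            ch[convertible[doConvert]] <- "T"
        })
    }
    paste(ch, collapse = "")
}

# fully converted plus strand used as the primer-matching template:
# non-CpG C -> T, CpG C -> Y (degenerate C/T: methylation-independent match)
convertedTemplate <- function(s) {
    cpg <- findCpgSites(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    ch[ch == "C"] <- "T"
    ch[cpg] <- "Y"
    paste(ch, collapse = "")
}

#' In-silico bisulfite PCR
#'
#' Places a [PrimerPair] on a reference sequence and returns the
#' primer-inclusive amplicon. When `bisulfite = TRUE` (the default) the
#' matching template is the fully converted plus strand with CpG cytosines
#' as the degenerate base Y, so primers amplify regardless of methylation
#' state, as a well-designed bisulfite pair does. Matching is exact (zero
#' mismatches) up to IUPAC degeneracy; zero placements raise a not-found
#' error and multiple placements an ambiguity error rather than a silent
#' best-hit choice.
#'
#' @param seq the reference sequence (character, `DNAString`, or length-1
#'   named `DNAStringSet`; the name is used as the sequence name).
#' @param primers a [PrimerPair].
#' @param bisulfite match against the converted template (TRUE) or the
#'   native sequence (FALSE).
#' @param seqName sequence name for the returned interval; defaults to the
#'   FASTA name when available.
#' @return An [AmpliconHit]. CpG sites are reported on the native sequence
#'   and are therefore independent of `bisulfite`.
#' @export
insilicoPcr <- function(seq, primers, bisulfite = TRUE, seqName = NULL) {
    if (is.null(seqName)) {
        seqName <- if (methods::is(seq, "DNAStringSet") &&
                       !is.null(names(seq))) names(seq)[1L] else "ref"
    }
    s <- asDnaCharacter(seq)
    template <- if (bisulfite) convertedTemplate(s) else s
    tmpl <- Biostrings::DNAString(template)

    fwd <- Biostrings::matchPattern(Biostrings::DNAString(forwardPrimer(primers)),
                                    tmpl, fixed = FALSE)
    if (length(fwd) == 0L)
        stop("forward primer '", primers@label, "' not found on the template")
    if (length(fwd) > 1L)
        stop("forward primer '", primers@label, "' has ", length(fwd),
             " placements: ambiguous amplification")
    fStart <- Biostrings::start(fwd)[1L]
    fEnd <- Biostrings::end(fwd)[1L]

    revFoot <- Biostrings::reverseComplement(
        Biostrings::DNAString(reversePrimer(primers)))
    rev <- Biostrings::matchPattern(revFoot, tmpl, fixed = FALSE)
    downstream <- Biostrings::start(rev) > fEnd
    if (sum(downstream) == 0L)
        stop("reverse primer '", primers@label,
             "' has no footprint downstream of the forward primer")
    if (sum(downstream) > 1L)
        stop("reverse primer '", primers@label, "' has ", sum(downstream),
             " downstream placements: ambiguous amplification")
    rEnd <- Biostrings::end(rev)[downstream][1L]

    len <- rEnd - fStart + 1L
    allCpg <- findCpgSites(s)
    inside <- allCpg[allCpg >= fStart & allCpg + 1L <= rEnd]
    new("AmpliconHit",
        interval = GenomicRanges::GRanges(seqName,
            IRanges::IRanges(fStart, rEnd), strand = "+"),
        ampliconLength = as.integer(len),
        cpgSites = as.integer(inside), isUnique = TRUE)
}

#' Call per-clone CpG methylation by positional comparison
#'
#' Compares a Sanger-sequenced clone of a bisulfite amplicon with the
#' native reference amplicon, position by position. At each CpG cytosine a
#' clone 'C' is called methylated, 'T' unmethylated, anything else
#' ambiguous. The clone's bisulfite conversion rate is the fraction of
#' non-CpG reference cytosines read as 'T', the standard quality measure
#' for incomplete conversion. Clones are assumed full-length and indel-free
#' (synthetic clones are generated that way); a length mismatch is an
#' error, the caller must trim to the amplicon.
#'
#' @param cloneSeq the clone sequence (same length as `nativeRef`).
#' @param nativeRef the native (unconverted) amplicon sequence.
#' @param cpgOffsets 1-based positions of the CpG 'C's within the amplicon;
#'   defaults to [findCpgSites()] of `nativeRef`.
#' @param cloneId identifier carried into the result.
#' @return A list with `cloneId`, `calls` (integer vector over CpG sites:
#'   1/0/NA), and `conversionRate` (NA when the amplicon has no non-CpG C).
#' @examples
#' callMethylation("TACGTTATG", "TACGTCACG")  # calls 1, 0; rate 1
#' @export
callMethylation <- function(cloneSeq, nativeRef, cpgOffsets = NULL,
                            cloneId = "clone") {
    clone <- asDnaCharacter(cloneSeq, "cloneSeq")
    ref <- asDnaCharacter(nativeRef, "nativeRef")
    if (nchar(clone) != nchar(ref))
        stop("clone length (", nchar(clone), ") differs from amplicon length (",
             nchar(ref), "); trim the clone to the amplicon first")
    if (is.null(cpgOffsets)) cpgOffsets <- findCpgSites(ref)
    cpgOffsets <- as.integer(cpgOffsets)
    refCh <- strsplit(ref, "", fixed = TRUE)[[1L]]
    clCh <- strsplit(clone, "", fixed = TRUE)[[1L]]
    if (any(refCh[cpgOffsets] != "C"))
        stop("'cpgOffsets' must point at reference cytosines")
    calls <- ifelse(clCh[cpgOffsets] == "C", 1L,
             ifelse(clCh[cpgOffsets] == "T", 0L, NA_integer_))
    nonCpgC <- setdiff(which(refCh == "C"), cpgOffsets)
    rate <- if (length(nonCpgC)) mean(clCh[nonCpgC] == "T") else NA_real_
    list(cloneId = cloneId, calls = as.integer(calls), conversionRate = rate)
}

#' Assemble a clone matrix from per-clone calls
#'
#' @param callList list of results from [callMethylation()].
#' @param sitePositions native positions of the CpG sites (columns).
#' @param sampleId,sampleClass sample metadata.
#' @return A [CloneMatrix].
#' @export
buildCloneMatrix <- function(callList, sitePositions, sampleId = "sample",
                             sampleClass = "unknown") {
    if (!length(callList)) stop("no clones supplied")
    calls <- do.call(rbind, lapply(callList, `[[`, "calls"))
    rownames(calls) <- vapply(callList, `[[`, character(1), "cloneId")
    CloneMatrix(calls, sitePositions, sampleId, sampleClass,
                conversionRates = vapply(callList, `[[`, numeric(1),
                                         "conversionRate"))
}

#' Per-site methylation frequencies of a clone matrix
#'
#' For every CpG site, the fraction methylated / (methylated +
#' unmethylated); ambiguous calls are excluded from both numerator and
#' denominator. Clones whose bisulfite conversion rate falls below
#' `minConversion` are flagged and excluded by default (standard bisulfite
#' quality control); clones with an undefined rate are kept.
#'
#' @param x a [CloneMatrix].
#' @param minConversion conversion-rate QC threshold (default 0.95).
#' @param applyQc exclude low-conversion clones (default TRUE).
#' @return A list with `siteFrequency` (numeric per site, `NaN` where every
#'   retained clone is ambiguous), `meanFrequency` (mean over defined
#'   sites), `undefinedSites` (indices flagged all-ambiguous),
#'   `clonesUsed` and `clonesExcluded` (row names).
#' @export
siteFrequencies <- function(x, minConversion = 0.95, applyQc = TRUE) {
    stopifnot(methods::is(x, "CloneMatrix"))
    calls <- methCalls(x)
    keep <- if (applyQc) {
        cr <- conversionRates(x)
        is.na(cr) | cr >= minConversion
    } else rep(TRUE, nrow(calls))
    if (!any(keep))
        stop("all clones excluded by the conversion-rate QC (< ",
             minConversion, ")")
    m <- calls[keep, , drop = FALSE]
    nMeth <- colSums(m == 1L, na.rm = TRUE)
    nCalled <- colSums(!is.na(m))
    freq <- ifelse(nCalled > 0L, nMeth / nCalled, NaN)
    undef <- which(nCalled == 0L)
    if (length(undef))
        warning("site(s) ", paste(undef, collapse = ", "),
                " are ambiguous in every retained clone")
    list(siteFrequency = as.numeric(freq),
         meanFrequency = mean(freq[nCalled > 0L]),
         undefinedSites = undef,
         clonesUsed = rownames(calls)[keep],
         clonesExcluded = rownames(calls)[!keep])
}

#' Classify a sample as hyper- or hypomethylated
#'
#' A sample is called hypermethylated when the mean per-site methylation
#' frequency of its clones, over the non-excluded sites, reaches
#' `threshold`. By default the first two CpG sites near the 5' end are
#' excluded: in this assay design those sites are methylated even in
#' keratinocytes and normal skin and so carry no tumour signal. Both the
#' exclusion list and the threshold are configurable; the threshold default
#' of 0.3 separates the near-zero frequencies of melanocyte-like samples
#' from the near-one frequencies of hypermethylated melanoma samples with a
#' wide margin.
#'
#' @param x a [CloneMatrix].
#' @param threshold mean-frequency threshold in (0, 1); default 0.3.
#' @param excludeSites integer site indices (columns) ignored in the mean;
#'   default `c(2, 3)`. Indices outside the matrix are ignored.
#' @param ... passed to [siteFrequencies()] (QC options).
#' @return A list with `classification` ("hypermethylated" or
#'   "hypomethylated"), `meanFrequency`, `threshold` and `excludedSites`.
#' @export
classifyHypermethylation <- function(x, threshold = 0.3,
                                     excludeSites = c(2L, 3L), ...) {
    stopifnot(methods::is(x, "CloneMatrix"))
    if (length(threshold) != 1L || threshold <= 0 || threshold >= 1)
        stop("'threshold' must lie in (0, 1)")
    sf <- siteFrequencies(x, ...)
    keep <- setdiff(seq_along(sf$siteFrequency), as.integer(excludeSites))
    keep <- keep[!is.nan(sf$siteFrequency[keep])]
    if (!length(keep))
        stop("all sites are excluded or undefined; cannot classify")
    m <- mean(sf$siteFrequency[keep])
    list(classification = if (m >= threshold) "hypermethylated"
                          else "hypomethylated",
         meanFrequency = m, threshold = threshold,
         excludedSites = intersect(as.integer(excludeSites),
                                   seq_along(sf$siteFrequency)))
}

#' Render a clone matrix as a lollipop-style diagram
#'
#' Text rendering: one row per clone, one column per site; `#` methylated,
#' `-` unmethylated, `?` ambiguous. Site positions are annotated in native
#' coordinates. Use [plotCloneMatrix()] for the graphical version.
#'
#' @param x a [CloneMatrix] with at least one clone and one site.
#' @return Character vector of diagram lines, invisibly; also printed.
#' @export
renderCloneMatrix <- function(x) {
    stopifnot(methods::is(x, "CloneMatrix"))
    calls <- methCalls(x)
    if (nrow(calls) == 0L || ncol(calls) == 0L)
        stop("cannot render an empty clone matrix")
    glyph <- matrix("?", nrow(calls), ncol(calls))
    glyph[!is.na(calls) & calls == 1L] <- "#"
    glyph[!is.na(calls) & calls == 0L] <- "-"
    idw <- max(nchar(rownames(calls)))
    lines <- c(
        sprintf("%s (%s): sites at %s", sampleId(x), sampleClass(x),
                paste(sitePositions(x), collapse = ",")),
        vapply(seq_len(nrow(calls)), function(i)
            sprintf("%-*s %s", idw, rownames(calls)[i],
                    paste(glyph[i, ], collapse = "")), character(1)))
    cat(lines, sep = "\n")
    invisible(lines)
}

#' Plot a clone matrix in the bisulfite-figure convention
#'
#' Filled circles are methylated calls, open circles unmethylated, grey
#' crosses ambiguous; one row per clone.
#'
#' @param x a [CloneMatrix].
#' @param main plot title; defaults to the sample id.
#' @return Invisibly, `NULL`. Called for its side effect.
#' @export
plotCloneMatrix <- function(x, main = NULL) {
    stopifnot(methods::is(x, "CloneMatrix"))
    calls <- methCalls(x)
    if (nrow(calls) == 0L || ncol(calls) == 0L)
        stop("cannot plot an empty clone matrix")
    if (is.null(main))
        main <- sprintf("%s (%s)", sampleId(x), sampleClass(x))
    nr <- nrow(calls); nc <- ncol(calls)
    graphics::plot(NA, xlim = c(0.5, nc + 0.5), ylim = c(nr + 0.5, 0.5),
                   xlab = "CpG site", ylab = "clone", main = main,
                   axes = FALSE)
    graphics::axis(1, at = seq_len(nc), labels = sitePositions(x),
                   las = 2, cex.axis = 0.7)
    graphics::axis(2, at = seq_len(nr), labels = rownames(calls),
                   las = 1, cex.axis = 0.7)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        v <- calls[i, j]
        if (is.na(v))
            graphics::points(j, i, pch = 4, col = "grey60")
        else
            graphics::points(j, i, pch = 21,
                             bg = if (v == 1L) "black" else "white")
    }
    invisible(NULL)
}
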