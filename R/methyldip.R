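#' Interval-level RPKM for capture-enrichment coverage
#'
#' The interval analogue of the gene-level score: with fragment-count
#' semantics (reads assigned to an interval are supplied directly),
#' `RPKM = reads * 1e9 / (intervalLength * librarySize)`. Invariant under
#' proportional scaling of all fragment counts and the library size.
#'
#' @param reads fragments assigned to the interval (vectorised).
#' @param intervalLength interval length in bp (> 0, vectorised).
#' @param librarySize total mapped fragments in the library (> 0).
#' @return Numeric RPKM values.
#' @examples
#' intervalRpkm(200, 250, 1e6)  # 800
#' @export
intervalRpkm <- function(reads, intervalLength, librarySize) {
    stopIfNegative(reads, "reads")
    if (any(intervalLength <= 0)) stop("'intervalLength' must be positive")
    if (length(librarySize) != 1L || !is.finite(librarySize) || librarySize <= 0)
        stop("'librarySize' must be a single positive number")
    reads * 1e9 / (intervalLength * librarySize)
}

#' Compare Methyl-DIP enrichment across conditions over CpG islands
#'
#' For each island, computes the interval RPKM in every condition's capture
#' library and the pseudo-count enrichment ratio of `case` over `control`:
#' `(rpkm_case + pseudo) / (rpkm_control + pseudo)`. Output rows follow the
#' island input order.
#'
#' @param tracks named list of per-condition coverage tracks, each a list
#'   with `intervals` (data.frame: `seq`, `start`, `end`, `reads`; 1-based
#'   inclusive, as from [readFragmentCounts()]) and `librarySize`. Every
#'   island must be present in every track.
#' @param islands a [GenomicRanges::GRanges] of CpG islands (or a
#'   data.frame with `seq`, `start`, `end`).
#' @param case,control condition names (entries of `tracks`) used for the
#'   ratio; default the first two tracks.
#' @param pseudo pseudo-count for the ratio (default 1.0).
#' @return A data.frame with island coordinates, one `rpkm_<condition>`
#'   column per track, and `ratio`.
#' @export
compareEnrichment <- function(tracks, islands, case = NULL, control = NULL,
                              pseudo = 1) {
    if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
        stop("'tracks' must be a named list of conditions")
    if (is.null(case)) case <- names(tracks)[1L]
    if (is.null(control)) control <- names(tracks)[2L]
    for (cond in c(case, control))
        if (!cond %in% names(tracks))
            stop("condition '", cond, "' is missing from 'tracks'")
    if (methods::is(islands, "GRanges")) {
        isl <- data.frame(
            seq = as.character(GenomicRanges::seqnames(islands)),
            start = GenomicRanges::start(islands),
            end = GenomicRanges::end(islands))
        if (!is.null(islands$name)) isl$name <- islands$name
    } else {
        isl <- as.data.frame(islands)
        if (!all(c("seq", "start", "end") %in% names(isl)))
            stop("'islands' must be a GRanges or have columns seq/start/end")
    }
    len <- isl$end - isl$start + 1L
    if (any(len <= 0)) stop("zero-length island interval")
    out <- isl
    for (cond in names(tracks)) {
        tr <- tracks[[cond]]
        key <- paste(tr$intervals$seq, tr$intervals$start, tr$intervals$end)
        idx <- match(paste(isl$seq, isl$start, isl$end), key)
        if (anyNA(idx))
            stop("condition '", cond, "' lacks coverage for island(s) ",
                 paste(which(is.na(idx)), collapse = ", "))
        out[[paste0("rpkm_", cond)]] <-
            intervalRpkm(tr$intervals$reads[idx], len, tr$librarySize)
    }
    out$ratio <- (out[[paste0("rpkm_", case)]] + pseudo) /
                 (out[[paste0("rpkm_", control)]] + pseudo)
    out
}
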