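#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count * 1e9 / (geneLength * librarySize)`. Vectorised over
#' `count` and `geneLength`.
#'
#' @param count uniquely mapped reads assigned to the feature.
#' @param geneLength exonic feature length in bp (> 0).
#' @param librarySize total uniquely mapped reads in the library (> 0).
#' @return Numeric RPKM values.
#' @examples
#' computeRpkm(50, 2000, 1e6)  # 25
#' @export
computeRpkm <- function(count, geneLength, librarySize) {
    stopIfNegative(count, "count")
    if (any(geneLength <= 0)) stop("'geneLength' must be positive")
    if (length(librarySize) != 1L || !is.finite(librarySize) || librarySize <= 0)
        stop("'librarySize' must be a single positive number")
    count * 1e9 / (geneLength * librarySize)
}

#' Signed pseudo-count fold change
#'
#' The ratio `r = (case + pseudo) / (control + pseudo)` reported in the
#' symmetric signed convention: `+r` when `r >= 1` and `-1/r` when `r < 1`,
#' so a doubling is +2 and a halving is -2 and thresholds like "+/-1.5"
#' read directly. The pseudo-count (1.0 by default) avoids division by zero
#' and damps fold changes at low RPKM.
#'
#' @param case,control non-negative RPKM values (vectorised).
#' @param pseudo pseudo-count added to both (default 1.0).
#' @return Signed fold changes; never inside (-1, 1), and exactly +1 at
#'   equality.
#' @examples
#' foldChange(4, 1.5)  # +2
#' foldChange(1.5, 4)  # -2
#' @export
foldChange <- function(case, control, pseudo = 1) {
    stopIfNegative(case, "case"); stopIfNegative(control, "control")
    r <- (case + pseudo) / (control + pseudo)
    ifelse(r >= 1, r, -1 / r)
}

#' Merge two mapping pipelines into a direction-agreement consensus
#'
#' Each mapper contributes per-gene case and control RPKM. A gene's
#' direction is `up` when both mappers' signed fold changes exceed +1,
#' `down` when both are below -1, and `discordant` otherwise (a fold change
#' of exactly +1 -- no change -- never supports a direction). The
#' corroborated fold change is the conservative choice: the smaller
#' magnitude of the two mappers' fold changes, with the shared sign. The
#' transcript delta is the mean over mappers of (case - control) RPKM.
#' Concordant genes are ordered by |corroborated fold change| descending
#' (ties broken by gene id so re-runs are byte-identical); discordant genes
#' follow, ordered by gene id.
#'
#' @param records1,records2 data.frames with columns `gene_id`,
#'   `rpkm_case`, `rpkm_control`, one per mapping pipeline. A gene absent
#'   from one mapper is treated as 0 RPKM there.
#' @param pseudo fold-change pseudo-count (default 1.0).
#' @param dropAllZero drop genes with zero RPKM in both conditions of both
#'   mappers before ranking (default TRUE): their fold change is exactly +1
#'   and they carry no signal.
#' @return A data.frame with `gene_id`, per-mapper RPKM columns, `fc_1`,
#'   `fc_2`, `corroborated_fc` (NA for discordant genes),
#'   `transcript_delta` and `direction`.
#' @export
consensusMerge <- function(records1, records2, pseudo = 1,
                           dropAllZero = TRUE) {
    need <- c("gene_id", "rpkm_case", "rpkm_control")
    for (nm in c("records1", "records2")) {
        df <- get(nm)
        if (!all(need %in% names(df)))
            stop("'", nm, "' must have columns ", paste(need, collapse = ", "))
        if (anyDuplicated(df$gene_id))
            stop("duplicate gene_id in '", nm, "'")
    }
    m <- merge(records1[need], records2[need], by = "gene_id", all = TRUE,
               suffixes = c("_1", "_2"))
    for (col in setdiff(names(m), "gene_id"))
        m[[col]][is.na(m[[col]])] <- 0
    if (dropAllZero) {
        allZero <- m$rpkm_case_1 == 0 & m$rpkm_control_1 == 0 &
                   m$rpkm_case_2 == 0 & m$rpkm_control_2 == 0
        m <- m[!allZero, , drop = FALSE]
    }
    m$fc_1 <- foldChange(m$rpkm_case_1, m$rpkm_control_1, pseudo)
    m$fc_2 <- foldChange(m$rpkm_case_2, m$rpkm_control_2, pseudo)
    up <- m$fc_1 > 1 & m$fc_2 > 1
    down <- m$fc_1 < -1 & m$fc_2 < -1
    m$direction <- ifelse(up, "up", ifelse(down, "down", "discordant"))
    m$corroborated_fc <- ifelse(up | down,
        sign(m$fc_1) * pmin(abs(m$fc_1), abs(m$fc_2)), NA_real_)
    m$transcript_delta <- ((m$rpkm_case_1 - m$rpkm_control_1) +
                           (m$rpkm_case_2 - m$rpkm_control_2)) / 2
    conc <- m$direction != "discordant"
    ordC <- order(-abs(m$corroborated_fc[conc]), m$gene_id[conc])
    ordD <- order(m$gene_id[!conc])
    out <- rbind(m[conc, , drop = FALSE][ordC, , drop = FALSE],
                 m[!conc, , drop = FALSE][ordD, , drop = FALSE])
    rownames(out) <- NULL
    out
}

#' Default fold-change / transcript-delta cutoff sets
#'
#' Three screens are supported, each a pair (fold-change threshold,
#' transcript-delta threshold): the two-sided differential-expression
#' screen for open reading frames (|FC| >= 1.5, |delta| >= 10), the miRNA
#' up-regulation screen (FC >= +1.5, delta >= +1.3) and the
#' target-candidate down-regulation screen (FC <= -1.2, delta <= -2.0).
#' All six numbers are data, not logic: override any of them here.
#'
#' @return A named list of `list(fc = , delta = )` pairs for roles
#'   `de_orf`, `de_mirna` and `target_screen`.
#' @export
defaultCutoffs <- function() {
    list(de_orf = list(fc = 1.5, delta = 10.0),
         de_mirna = list(fc = 1.5, delta = 1.3),
         target_screen = list(fc = -1.2, delta = -2.0))
}

#' Apply screen-specific cutoffs to consensus records
#'
#' Discordant genes never pass. `de_orf` is two-sided on magnitudes;
#' `de_mirna` keeps up-regulated genes only; `target_screen` keeps
#' down-regulated genes only (signed thresholds).
#'
#' @param records output of [consensusMerge()].
#' @param role one of `"de_orf"`, `"de_mirna"`, `"target_screen"`.
#' @param cutoffs a cutoff set as from [defaultCutoffs()].
#' @return The subset of `records` passing the screen, with a
#'   `passes_cutoffs` column (all TRUE), in consensus order.
#' @export
applyCutoffs <- function(records, role = c("de_orf", "de_mirna",
                                           "target_screen"),
                         cutoffs = defaultCutoffs()) {
    role <- match.arg(role)
    cut <- cutoffs[[role]]
    if (is.null(cut)) stop("no cutoffs defined for role '", role, "'")
    fc <- records$corroborated_fc
    delta <- records$transcript_delta
    conc <- records$direction != "discordant" & !is.na(fc)
    pass <- switch(role,
        de_orf = conc & abs(fc) >= abs(cut$fc) & abs(delta) >= abs(cut$delta),
        de_mirna = conc & fc >= abs(cut$fc) & delta >= abs(cut$delta),
        target_screen = conc & fc <= -abs(cut$fc) & delta <= -abs(cut$delta))
    out <- records[pass, , drop = FALSE]
    out$passes_cutoffs <- rep(TRUE, nrow(out))
    rownames(out) <- NULL
    out
}

#' Intersect down-regulated genes with a ranked target list
#'
#' Keeps the records whose gene id appears within the top `topN` ranks of
#' the predicted-target list, preserving the consensus ordering and
#' attaching each gene's target rank.
#'
#' @param downRecords records from
#'   `applyCutoffs(..., role = "target_screen")`.
#' @param targets ranked target list (data.frame with `rank`, `gene_id`,
#'   as from [readTargetList()]).
#' @param topN rank cutoff (default 500).
#' @return The intersected records with a `target_rank` column; empty when
#'   nothing intersects.
#' @export
filterTargets <- function(downRecords, targets, topN = 500) {
    if (!all(c("rank", "gene_id") %in% names(targets)))
        stop("'targets' must have columns rank and gene_id")
    top <- targets[targets$rank <= topN, , drop = FALSE]
    keep <- downRecords$gene_id %in% top$gene_id
    out <- downRecords[keep, , drop = FALSE]
    out$target_rank <- top$rank[match(out$gene_id, top$gene_id)]
    rownames(out) <- NULL
    out
}

#' Run the full dual-mapper consensus pipeline from count tables
#'
#' Convenience wrapper: computes per-mapper RPKM from counts, merges the
#' two pipelines with [consensusMerge()] and, when a role is given, applies
#' the corresponding cutoffs.
#'
#' @param genes data.frame with `gene_id` and `length` (bp); a `biotype`
#'   column is carried through if present.
#' @param case1,ctrl1,case2,ctrl2 count tables as returned by
#'   [readCountsTsv()]: lists with `counts` (named vector) and
#'   `librarySize`. Mapper 1 supplies `case1`/`ctrl1`.
#' @param role optional screen role passed to [applyCutoffs()].
#' @param pseudo fold-change pseudo-count.
#' @param cutoffs cutoff set for `role`.
#' @return Consensus records ([consensusMerge()]) or, when `role` is given,
#'   the screened subset.
#' @export
runConsensus <- function(genes, case1, ctrl1, case2, ctrl2, role = NULL,
                         pseudo = 1, cutoffs = defaultCutoffs()) {
    if (!all(c("gene_id", "length") %in% names(genes)))
        stop("'genes' must have columns gene_id and length")
    rpkmOf <- function(tbl) {
        cnt <- tbl$counts[match(genes$gene_id, names(tbl$counts))]
        cnt[is.na(cnt)] <- 0
        computeRpkm(cnt, genes$length, tbl$librarySize)
    }
    rec1 <- data.frame(gene_id = genes$gene_id, rpkm_case = rpkmOf(case1),
                       rpkm_control = rpkmOf(ctrl1))
    rec2 <- data.frame(gene_id = genes$gene_id, rpkm_case = rpkmOf(case2),
                       rpkm_control = rpkmOf(ctrl2))
    cons <- consensusMerge(rec1, rec2, pseudo = pseudo)
    if ("biotype" %in% names(genes))
        cons$biotype <- genes$biotype[match(cons$gene_id, genes$gene_id)]
    if (is.null(role)) cons else applyCutoffs(cons, role, cutoffs)
}
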