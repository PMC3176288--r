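#' Percent of input cells bound over time (adhesion assay)
#'
#' For each timepoint, the percent of seeded cells still attached:
#' `100 * bound / inputCells`, summarised as mean and SEM over replicates
#' (SEM = sample standard deviation / sqrt(n), n - 1 denominator).
#'
#' @param series data.frame with columns `timepoint` and `bound`
#'   (replicate rows per timepoint).
#' @param inputCells number of cells seeded per well.
#' @return A data.frame with `timepoint`, `mean_percent`, `sem`, `n`,
#'   ordered by timepoint.
#' @examples
#' percentBound(data.frame(timepoint = 5, bound = c(125000, 125000)),
#'              inputCells = 250000)
#' @export
percentBound <- function(series, inputCells) {
    if (!all(c("timepoint", "bound") %in% names(series)))
        stop("'series' must have columns timepoint and bound")
    if (length(inputCells) != 1L || inputCells <= 0)
        stop("'inputCells' must be a single positive count")
    if (any(series$bound < 0 | series$bound > inputCells))
        stop("bound counts must lie in [0, inputCells]")
    pct <- 100 * series$bound / inputCells
    tp <- sort(unique(series$timepoint))
    out <- do.call(rbind, lapply(tp, function(t) {
        v <- pct[series$timepoint == t]
        data.frame(timepoint = t, mean_percent = mean(v),
                   sem = if (length(v) >= 2L) stats::sd(v) / sqrt(length(v))
                         else NA_real_,
                   n = length(v))
    }))
    rownames(out) <- NULL
    out
}

#' Percent invasion through a Matrigel membrane
#'
#' `100 * mean(cells invading through the coated insert) / mean(wild-type
#' cells migrating through the control membrane)`.
#'
#' @param testCounts replicate counts of invading cells.
#' @param controlCounts replicate counts of wild-type cells migrating
#'   through the uncoated control membrane.
#' @return Percent invasion (scalar).
#' @examples
#' percentInvasion(c(27, 27, 27), c(50, 50, 50))  # 54
#' @export
percentInvasion <- function(testCounts, controlCounts) {
    stopIfNegative(testCounts, "testCounts")
    stopIfNegative(controlCounts, "controlCounts")
    cm <- mean(controlCounts)
    if (cm <= 0) stop("control migration mean must be positive")
    100 * mean(testCounts) / cm
}

#' Wound-closure percentages from denuded-area measurements
#'
#' For each replicate, closure at time t is `100 * (1 - area(t) / area(0))`
#' so closure(0) = 0 and a fully closed wound is 100. The complementary
#' area-remaining percentage (`100 * area(t) / area(0)`), as plotted in
#' scratch-assay figures, is reported alongside to keep the two labellings
#' explicit: they differ only by 100 - x but flipping them flips the
#' conclusion. Wound expansion (area above the initial area) appears as
#' negative closure. Units cancel, so the result is invariant under
#' rescaling of the area measurements.
#'
#' @param series data.frame with columns `timepoint`, `replicate`, `area`;
#'   the first timepoint must be 0 with a positive area per replicate.
#' @return A list with `perReplicate` (timepoint, replicate,
#'   closure_percent, area_remaining_percent) and `summary` (per-timepoint
#'   mean and SEM of closure).
#' @examples
#' woundClosure(data.frame(timepoint = c(0, 8, 16, 24), replicate = 1,
#'                         area = c(100, 60, 20, 0)))$summary
#' @export
woundClosure <- function(series) {
    if (!all(c("timepoint", "replicate", "area") %in% names(series)))
        stop("'series' must have columns timepoint, replicate and area")
    if (min(series$timepoint) != 0)
        stop("the series must include the 0 h timepoint")
    if (any(series$area < 0)) stop("areas must be non-negative")
    per <- do.call(rbind, lapply(split(series, series$replicate), function(d) {
        d <- d[order(d$timepoint), , drop = FALSE]
        a0 <- d$area[d$timepoint == 0][1L]
        if (is.na(a0) || a0 <= 0)
            stop("replicate ", d$replicate[1L], " has no positive initial area")
        data.frame(timepoint = d$timepoint, replicate = d$replicate,
                   closure_percent = 100 * (1 - d$area / a0),
                   area_remaining_percent = 100 * d$area / a0)
    }))
    rownames(per) <- NULL
    tp <- sort(unique(per$timepoint))
    summ <- do.call(rbind, lapply(tp, function(t) {
        v <- per$closure_percent[per$timepoint == t]
        data.frame(timepoint = t, mean_closure = mean(v),
                   sem = if (length(v) >= 2L) stats::sd(v) / sqrt(length(v))
                         else NA_real_,
                   n = length(v))
    }))
    rownames(summ) <- NULL
    list(perReplicate = per, summary = summ)
}

# all distinct assignments of N ranks into groups of the given sizes;
# returns the H statistic for each assignment
kwEnumerate <- function(r, sizes, tieCorrection, N) {
    H <- numeric(0)
    recurse <- function(remaining, sizesLeft) {
        if (length(sizesLeft) == 1L) {
            rbar <- mean(r[remaining])
            return(sum(length(remaining) * (rbar - (N + 1) / 2)^2))
        }
        picks <- utils::combn(remaining, sizesLeft[1L], simplify = FALSE)
        unlist(lapply(picks, function(p) {
            rbar <- mean(r[p])
            base <- length(p) * (rbar - (N + 1) / 2)^2
            base + recurse(setdiff(remaining, p), sizesLeft[-1L])
        }))
    }
    ss <- recurse(seq_len(N), sizes)
    (12 / (N * (N + 1))) * ss / tieCorrection
}

#' Kruskal-Wallis rank-sum test with exact small-sample p-values
#'
#' The H statistic is computed from midranks with the standard tie
#' correction. The p-value comes from the chi-square approximation with
#' k - 1 degrees of freedom when every group has at least 5 observations;
#' below that (the typical triplicate assay) the chi-square approximation
#' is dubious and the exact permutation distribution over all distinct
#' assignments of the observations to the group sizes is enumerated
#' instead. When every observation is identical, H = 0 and p = 1.
#'
#' @param x list of numeric vectors (one per group), or a numeric vector
#'   with grouping factor `g`.
#' @param g grouping factor when `x` is a vector.
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   `NULL` (default) applies the every-group-at-least-5 rule. Enumeration
#'   is capped at 500000 assignments, above which the chi-square
#'   approximation is used with a warning.
#' @return An object of class `htest` with `statistic` (H), `parameter`
#'   (df), `p.value` and `method`.
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskalWallis <- function(x, g = NULL, exact = NULL) {
    if (is.list(x)) {
        groups <- lapply(x, as.numeric)
    } else {
        if (is.null(g)) stop("supply a list of groups or both 'x' and 'g'")
        groups <- split(as.numeric(x), g)
    }
    if (length(groups) < 2L) stop("at least two groups are required")
    sizes <- lengths(groups)
    if (any(sizes < 1L)) stop("every group needs at least one observation")
    v <- unlist(groups, use.names = FALSE)
    N <- length(v)
    if (N < 3L) stop("at least 3 observations in total are required")
    k <- length(groups)
    dname <- paste(length(groups), "groups")

    if (length(unique(v)) == 1L) {
        res <- list(statistic = c(H = 0), parameter = c(df = k - 1),
                    p.value = 1, method = "Kruskal-Wallis rank sum test (degenerate)",
                    data.name = dname)
        class(res) <- "htest"
        return(res)
    }

    r <- rank(v)  # midranks
    grp <- rep(seq_len(k), sizes)
    tab <- table(v)
    tieCorr <- 1 - sum(tab^3 - tab) / (N^3 - N)
    rbar <- tapply(r, grp, mean)
    H <- (12 / (N * (N + 1))) * sum(sizes * (rbar - (N + 1) / 2)^2) / tieCorr

    if (is.null(exact)) exact <- any(sizes < 5L)
    nAssign <- exp(lgamma(N + 1) - sum(lgamma(sizes + 1)))
    if (exact && nAssign > 5e5) {
        warning("exact enumeration over ", round(nAssign),
                " assignments is too large; using the chi-square approximation")
        exact <- FALSE
    }
    if (exact) {
        Hall <- kwEnumerate(r, sizes, tieCorr, N)
        p <- mean(Hall >= H - 1e-8)
        method <- "Kruskal-Wallis rank sum test (exact permutation)"
    } else {
        p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
        method <- "Kruskal-Wallis rank sum test (chi-square approximation)"
    }
    res <- list(statistic = c(H = H), parameter = c(df = k - 1),
                p.value = p, method = method, data.name = dname)
    class(res) <- "htest"
    res
}

#' Comparative-Ct relative quantification
#'
#' Standard delta-delta-Ct analysis: per group,
#' `dCt = Ct_target - Ct_control`; against the calibrator group,
#' `ddCt = dCt - dCt_calibrator`; the relative quantity is
#' `RQ = 2^(-ddCt)` (1 for the calibrator itself).
#'
#' @param ct data.frame with columns `group`, `ct_target`, `ct_control`
#'   (replicate rows are averaged within group). Ct values must lie in
#'   (0, 40\].
#' @param calibrator name of the calibrator group.
#' @return A data.frame with `group`, `dct`, `ddct`, `rq`.
#' @examples
#' ct <- data.frame(group = c("calib", "test"),
#'                  ct_target = c(25, 24), ct_control = c(20, 20))
#' relativeQuantity(ct, "calib")  # test RQ = 2
#' @export
relativeQuantity <- function(ct, calibrator) {
    if (!all(c("group", "ct_target", "ct_control") %in% names(ct)))
        stop("'ct' must have columns group, ct_target and ct_control")
    vals <- c(ct$ct_target, ct$ct_control)
    if (any(vals <= 0 | vals > 40))
        stop("Ct values must lie in (0, 40]")
    if (!calibrator %in% ct$group)
        stop("calibrator group '", calibrator, "' not present")
    grp <- unique(as.character(ct$group))
    dct <- vapply(grp, function(gp) {
        d <- ct[ct$group == gp, ]
        mean(d$ct_target) - mean(d$ct_control)
    }, numeric(1))
    ddct <- dct - dct[[calibrator]]
    data.frame(group = grp, dct = as.numeric(dct), ddct = as.numeric(ddct),
               rq = 2^(-as.numeric(ddct)), row.names = NULL)
}
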