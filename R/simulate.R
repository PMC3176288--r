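#' Generate a synthetic reference with a CpG island and flanking primers
#'
#' Builds a random background sequence with a low (about 1 percent) CpG
#' dinucleotide density, plants a CpG island carrying exactly `islandCpg`
#' CpG dinucleotides, and designs a CpG-free bisulfite primer pair flanking
#' the island, so that amplification is independent of methylation state.
#' The primers are derived from the fully converted top strand of their
#' footprints (every C read as T); the amplicon interior outside the island
#' is kept CpG-free so the amplicon contains exactly the island's CpG
#' sites. The construction is validated by running [insilicoPcr()] on the
#' result: a non-unique placement or a wrong CpG count is an error, never a
#' silent retry. Deterministic given `seed`.
#'
#' @param length total reference length in bp (default 3000).
#' @param islandCpg number of CpG dinucleotides in the island (default 22,
#'   the typical size of a miRNA-promoter island in this assay design).
#' @param islandLength island length in bp (default 237).
#' @param primerLength primer length (default 24).
#' @param primerGap gap between each primer footprint and the island
#'   (default 20 bp).
#' @param seed integer seed.
#' @param seqName name of the reference sequence.
#' @return A list with `reference` (named character), `island` (`GRanges`),
#'   `primers` ([PrimerPair]), `amplicon` ([AmpliconHit]),
#'   `nativeAmplicon` (character) and `cpgOffsets` (1-based CpG positions
#'   within the amplicon).
#' @export
genReference <- function(length = 3000L, islandCpg = 22L,
                         islandLength = 237L, primerLength = 24L,
                         primerGap = 20L, seed = 1L, seqName = "synthRef") {
    length <- as.integer(length); islandCpg <- as.integer(islandCpg)
    islandLength <- as.integer(islandLength)
    if (islandCpg > 0 && islandLength < 2L * islandCpg)
        stop("an island of ", islandLength, " bp cannot hold ", islandCpg,
             " CpG dinucleotides")
    ampLen <- 2L * primerLength + 2L * primerGap + islandLength
    if (ampLen + 200L > length)
        stop("reference too short for the amplicon layout")
    withSeed(seed, {
        ch <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                     prob = c(0.3, 0.2, 0.2, 0.3))
        islandStart <- (length - islandLength) %/% 2L
        islandEnd <- islandStart + islandLength - 1L
        fStart <- islandStart - primerGap - primerLength
        rEnd <- islandEnd + primerGap + primerLength
        # thin background CpGs to ~1% dinucleotide density; strip them
        # entirely inside the amplicon so its CpG content is the island's
        repeat {
            cg <- which(ch[-length] == "C" & ch[-1L] == "G")
            if (!base::length(cg)) break
            inAmp <- cg >= fStart - 1L & cg <= rEnd
            inIsland <- cg >= islandStart & cg + 1L <= islandEnd
            drop <- (inAmp & !inIsland) | inIsland |
                    (!inAmp & stats::runif(base::length(cg)) > 0.16)
            if (!any(drop)) break
            ch[cg[drop] + 1L] <- "A"
        }
        # plant exactly islandCpg CpG dinucleotides, evenly spaced
        if (islandCpg > 0L) {
            at <- islandStart +
                round((seq_len(islandCpg) - 0.5) * islandLength / islandCpg) - 1L
            ch[at] <- "C"; ch[at + 1L] <- "G"
        }
        seqStr <- paste(ch, collapse = "")
        fwdFoot <- substr(seqStr, fStart, fStart + primerLength - 1L)
        revFoot <- substr(seqStr, rEnd - primerLength + 1L, rEnd)
        fwdPrimer <- chartr("C", "T", fwdFoot)
        revPrimer <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(chartr("C", "T", revFoot))))
        primers <- PrimerPair(fwdPrimer, revPrimer,
                              label = paste0(seqName, "_pair"))
        hit <- insilicoPcr(seqStr, primers, bisulfite = TRUE,
                           seqName = seqName)
        if (base::length(cpgSites(hit)) != islandCpg)
            stop("generated amplicon holds ", base::length(cpgSites(hit)),
                 " CpG sites, expected ", islandCpg)
        ampStart <- GenomicRanges::start(ampliconRange(hit))
        ampEnd <- GenomicRanges::end(ampliconRange(hit))
        list(reference = stats::setNames(seqStr, seqName),
             island = GenomicRanges::GRanges(seqName,
                 IRanges::IRanges(islandStart, islandEnd), strand = "+",
                 name = "cpg_island"),
             primers = primers, amplicon = hit,
             nativeAmplicon = substr(seqStr, ampStart, ampEnd),
             cpgOffsets = cpgSites(hit) - ampStart + 1L)
    })
}

#' Default per-class CpG methylation probabilities
#'
#' Benign classes (melanocyte, keratinocyte, early-stage lines, nevus,
#' normal skin) sit near zero; advanced-stage classes near one; a
#' demethylating-agent series decreases with dose. Configuration, not
#' constants.
#'
#' @return Named numeric vector of per-site methylation probabilities.
#' @export
defaultMethylationClasses <- function() {
    c(melanocyte = 0.02, keratinocyte = 0.02, stage1 = 0.02, stage2 = 0.02,
      stage3 = 0.90, stage4 = 0.90, nevus = 0.02, normal_skin = 0.02,
      primary = 0.90, regional = 0.90, distant = 0.90, nodal = 0.02)
}

#' Simulate a bisulfite clone-sequencing cohort
#'
#' For every sample, draws per-clone, per-site methylation states
#' Bernoulli(p_class), bisulfite-converts the native amplicon at the given
#' efficiency and emits the converted amplicon as that clone's sequence.
#' Conversion failures use one seeded stream per clone (seed + global
#' clone index), so every clone is individually reproducible. The drawn
#' states are recorded in a machine-readable truth table; downstream
#' recovery tests read truth only from it.
#'
#' @param reference a layout from [genReference()] (or a compatible list
#'   with `nativeAmplicon` and `cpgOffsets`).
#' @param samples data.frame with columns `sample_id`, `class` and
#'   `meth_prob` (per-site methylation probability); optional `clone_count`
#'   column overrides `cloneCount` per sample.
#' @param cloneCount clones sequenced per sample (default 9, the cell-line
#'   design; patient samples use 6).
#' @param conversionEfficiency bisulfite conversion probability
#'   (default 0.99).
#' @param seed integer seed.
#' @return A list with `clones` ([Biostrings::DNAStringSet], names
#'   `sample=<id> class=<class> clone=<k>`), `truth` (data.frame:
#'   sample_id, class, clone, site, position, methylated) and the
#'   `reference` passed in.
#' @export
genCloneCohort <- function(reference, samples,
                           cloneCount = 9L, conversionEfficiency = 0.99,
                           seed = 1L) {
    if (!all(c("sample_id", "class", "meth_prob") %in% names(samples)))
        stop("'samples' needs columns sample_id, class and meth_prob")
    if (any(samples$meth_prob < 0 | samples$meth_prob > 1))
        stop("methylation probabilities must lie in [0, 1]")
    amp <- reference$nativeAmplicon
    offs <- reference$cpgOffsets
    nSites <- length(offs)
    seqs <- character(0); nms <- character(0)
    truth <- vector("list", nrow(samples))
    cloneIdx <- 0L
    for (i in seq_len(nrow(samples))) {
        nClones <- if ("clone_count" %in% names(samples))
            as.integer(samples$clone_count[i]) else as.integer(cloneCount)
        p <- samples$meth_prob[i]
        rows <- vector("list", nClones)
        for (k in seq_len(nClones)) {
            cloneIdx <- cloneIdx + 1L
            cloneSeed <- seed + cloneIdx
            res <- withSeed(cloneSeed, {
                states <- stats::rbinom(nSites, 1L, p)
                list(states = states,
                     seq = bisulfiteConvert(amp, states,
                                            conversionEfficiency))
            })
            seqs <- c(seqs, res$seq)
            nms <- c(nms, sprintf("sample=%s class=%s clone=%d",
                                  samples$sample_id[i], samples$class[i], k))
            rows[[k]] <- data.frame(
                sample_id = samples$sample_id[i], class = samples$class[i],
                clone = k, site = seq_len(nSites), position = offs,
                methylated = res$states)
        }
        truth[[i]] <- do.call(rbind, rows)
    }
    list(clones = Biostrings::DNAStringSet(stats::setNames(seqs, nms)),
         truth = do.call(rbind, truth), reference = reference)
}

#' Call clone matrices back from a simulated (or real) clone set
#'
#' Groups clone sequences by their `sample=` header field, calls
#' methylation per clone against the native amplicon and assembles one
#' [CloneMatrix] per sample.
#'
#' @param clones a `DNAStringSet` with names
#'   `sample=<id> class=<class> clone=<k>`.
#' @param reference layout with `nativeAmplicon` and `cpgOffsets` (as from
#'   [genReference()]).
#' @return Named list of [CloneMatrix] objects, one per sample.
#' @export
callCloneCohort <- function(clones, reference) {
    nms <- names(clones)
    field <- function(key) sub(sprintf(".*%s=(\\S+).*", key), "\\1", nms)
    sample <- field("sample"); class <- field("class"); clone <- field("clone")
    offs <- reference$cpgOffsets
    amp <- reference$nativeAmplicon
    positions <- if (!is.null(reference$amplicon))
        cpgSites(reference$amplicon) else offs
    out <- lapply(split(seq_along(clones), sample), function(idx) {
        callList <- lapply(idx, function(j)
            callMethylation(as.character(clones[[j]]), amp, offs,
                            cloneId = sprintf("clone%02d",
                                              as.integer(clone[j]))))
        buildCloneMatrix(callList, positions,
                         sampleId = sample[idx[1L]],
                         sampleClass = class[idx[1L]])
    })
    out[unique(sample)]
}

#' Simulate dual-mapper RNA-seq count tables with planted DE genes
#'
#' Emulates the dual-pipeline study design: one biological truth (per-gene
#' expected expression, with a planted set of differentially expressed
#' genes) observed by two mapping pipelines, each through its own per-gene
#' multiplicative lognormal factor (shared between conditions within a
#' mapper, so it models mapper bias, not condition signal) and its own
#' library size. Counts are negative binomial with the given dispersion
#' (`dispersion = 0` gives Poisson counts). Baseline expression is a
#' zero-inflated lognormal: a silent fraction of genes at negligible RPKM
#' and an expressed fraction around 1 RPKM; planted genes are placed at
#' moderate-to-high baseline so the delta screen is meaningful. Library
#' sizes are raw reads times a mapping rate times a per-mapper unique
#' fraction, mirroring typical short-read mapper statistics.
#'
#' @param nGenes number of genes (default 2000).
#' @param nPlanted number of planted DE genes (default 50).
#' @param plantedFc optional numeric vector of signed fold changes for the
#'   planted genes; by default magnitudes are uniform in
#'   `plantedFcRange` with random sign.
#' @param plantedFcRange magnitude range for the default planted fold
#'   changes (default c(3, 8)).
#' @param plantedRpkmRange baseline RPKM range for planted genes
#'   (default c(20, 100)).
#' @param silentFraction fraction of genes essentially unexpressed
#'   (default 0.6).
#' @param dispersion negative-binomial dispersion (default 0.1; 0 gives
#'   Poisson).
#' @param mapperSigma sd of the per-gene per-mapper lognormal factor
#'   (default 0.1).
#' @param rawReads sequenced reads per library before mapping
#'   (default 3e7).
#' @param mappingRate fraction of reads mapped (default 0.63).
#' @param uniqueFraction named per-mapper unique-mapping fractions
#'   (defaults 0.89 and 0.83 for pipelines 1 and 2).
#' @param mirnaFraction fraction of genes given the `mirna` biotype with
#'   short lengths (default 0.05).
#' @param seed integer seed.
#' @return A list with `genes` (gene_id, length, biotype), `mappers` (per
#'   pipeline: `case`, `control` count tables as
#'   `list(counts, librarySize)`), and `truth` (gene_id, planted,
#'   true_fc, base_rpkm).
#' @export
genCountTables <- function(nGenes = 2000L, nPlanted = 50L, plantedFc = NULL,
                           plantedFcRange = c(3, 8),
                           plantedRpkmRange = c(20, 100),
                           silentFraction = 0.6, dispersion = 0.1,
                           mapperSigma = 0.1, rawReads = 3e7,
                           mappingRate = 0.63,
                           uniqueFraction = c(pipeline_1 = 0.89,
                                              pipeline_2 = 0.83),
                           mirnaFraction = 0.05, seed = 1L) {
    nGenes <- as.integer(nGenes); nPlanted <- as.integer(nPlanted)
    if (nPlanted > nGenes) stop("more planted genes than genes")
    withSeed(seed, {
        geneId <- sprintf("gene%05d", seq_len(nGenes))
        isMir <- stats::runif(nGenes) < mirnaFraction
        len <- ifelse(isMir,
                      pmax(60L, round(stats::rnorm(nGenes, 85, 10))),
                      pmin(pmax(round(stats::rlnorm(nGenes, log(1500), 0.6)),
                                200L), 20000L))
        silent <- stats::runif(nGenes) < silentFraction
        baseRpkm <- ifelse(silent, stats::rlnorm(nGenes, -4, 1),
                           stats::rlnorm(nGenes, 0, 1.0))
        planted <- sample.int(nGenes, nPlanted)
        baseRpkm[planted] <- stats::runif(nPlanted, plantedRpkmRange[1L],
                                          plantedRpkmRange[2L])
        if (is.null(plantedFc)) {
            mag <- stats::runif(nPlanted, plantedFcRange[1L],
                                plantedFcRange[2L])
            plantedFc <- sample(c(-1, 1), nPlanted, replace = TRUE) * mag
        }
        if (length(plantedFc) != nPlanted)
            stop("'plantedFc' must have length nPlanted")
        if (any(abs(plantedFc) < 1))
            stop("planted fold-change magnitudes must be >= 1")
        trueFc <- rep(1, nGenes)
        trueFc[planted] <- plantedFc
        mult <- rep(1, nGenes)
        mult[planted] <- ifelse(plantedFc > 0, plantedFc, 1 / abs(plantedFc))

        mappers <- list()
        for (m in names(uniqueFraction)) {
            factor <- stats::rlnorm(nGenes, 0, mapperSigma)
            libs <- round(rawReads * mappingRate * uniqueFraction[[m]] *
                          stats::runif(2L, 0.95, 1.05))
            muCtrl <- baseRpkm * len / 1e3 * libs[2L] / 1e6 * factor
            muCase <- baseRpkm * mult * len / 1e3 * libs[1L] / 1e6 * factor
            draw <- function(mu) {
                if (dispersion <= 0) stats::rpois(nGenes, mu)
                else stats::rnbinom(nGenes, mu = mu, size = 1 / dispersion)
            }
            mappers[[m]] <- list(
                case = list(counts = stats::setNames(draw(muCase), geneId),
                            librarySize = libs[1L]),
                control = list(counts = stats::setNames(draw(muCtrl), geneId),
                               librarySize = libs[2L]))
        }
        list(genes = data.frame(gene_id = geneId, length = len,
                                biotype = ifelse(isMir, "mirna", "orf")),
             mappers = mappers,
             truth = data.frame(gene_id = geneId,
                                planted = seq_len(nGenes) %in% planted,
                                true_fc = trueFc, base_rpkm = baseRpkm))
    })
}

# truncated-normal fragment lengths on [lo, hi] by resampling
rtruncnorm <- function(n, mean, sd, lo, hi) {
    out <- stats::rnorm(n, mean, sd)
    bad <- which(out < lo | out > hi)
    while (length(bad)) {
        out[bad] <- stats::rnorm(length(bad), mean, sd)
        bad <- bad[out[bad] < lo | out[bad] > hi]
    }
    out
}

#' Default CpG-island layout for Methyl-DIP simulation
#'
#' Ten equal-length islands evenly spaced on one synthetic chromosome.
#'
#' @param nIslands number of islands (default 10).
#' @param islandLength island length in bp (default 500).
#' @param spacing distance between island starts (default 8000 bp).
#' @param seqName chromosome name.
#' @return A `GRanges` of islands.
#' @export
defaultDipIslands <- function(nIslands = 10L, islandLength = 500L,
                              spacing = 8000L, seqName = "synthChr") {
    starts <- 2000L + (seq_len(nIslands) - 1L) * spacing
    GenomicRanges::GRanges(seqName,
        IRanges::IRanges(starts, width = islandLength), strand = "+",
        name = sprintf("island%02d", seq_len(nIslands)))
}

#' Simulate Methyl-DIP fragment capture over CpG islands
#'
#' Models the methylated-DNA enrichment step: genomic fragments with
#' truncated-normal lengths (mean 250 bp on \[50, 400\]) are placed
#' uniformly; each fragment's methylated-CpG content is Poisson around
#' (island overlap x island CpG density x methylation level, plus a small
#' background term); a fragment is captured with logistic probability in
#' its methylated-CpG count (single-fraction elution as a per-fragment
#' Bernoulli). Any overlap assigns a captured fragment to an island. With
#' `noise = FALSE` the generator returns deterministic expected counts
#' (integrating the placement and length distributions on a grid), the
#' zero-noise regime in which enrichment ratios are exactly monotone in
#' the generating methylation levels.
#'
#' @param islands `GRanges` of CpG islands (default [defaultDipIslands()]).
#' @param levels named list: one numeric vector (or scalar) of per-island
#'   methylation levels in \[0, 1\] per condition.
#' @param nFragments fragments sheared per condition before capture
#'   (default 2e5).
#' @param genomeLength synthetic genome length (default: derived from the
#'   islands, plus margin).
#' @param islandCpgDensity CpG dinucleotides per bp inside islands
#'   (default 0.1).
#' @param backgroundRate expected methylated-CpG count per fragment from
#'   non-island sequence (default 0.1).
#' @param captureIntercept,captureSlope logistic capture parameters
#'   (defaults -4 and 0.6: an unmethylated fragment is captured with
#'   probability ~0.018, one with 10 methylated CpGs ~0.88).
#' @param fragmentMean,fragmentSd,fragmentRange fragment-length model
#'   (defaults 250, 80, \[50, 400\]).
#' @param noise draw fragments stochastically (TRUE) or return expected
#'   counts (FALSE).
#' @param seed integer seed (used when `noise = TRUE`).
#' @return A list with `tracks` (named per-condition
#'   `list(intervals, librarySize)`, consumable by [compareEnrichment()])
#'   and `truth` (data.frame of generating levels per island and
#'   condition).
#' @export
genDipFragments <- function(islands = defaultDipIslands(), levels,
                            nFragments = 2e5, genomeLength = NULL,
                            islandCpgDensity = 0.1, backgroundRate = 0.1,
                            captureIntercept = -4, captureSlope = 0.6,
                            fragmentMean = 250, fragmentSd = 80,
                            fragmentRange = c(50, 400),
                            noise = TRUE, seed = 1L) {
    nIsl <- length(islands)
    if (is.null(genomeLength))
        genomeLength <- max(GenomicRanges::end(islands)) + 5000L
    lev <- lapply(levels, function(v) {
        v <- rep_len(as.numeric(v), nIsl)
        if (any(v < 0 | v > 1)) stop("methylation levels must lie in [0, 1]")
        v
    })
    islStart <- GenomicRanges::start(islands)
    islEnd <- GenomicRanges::end(islands)
    islSeq <- as.character(GenomicRanges::seqnames(islands))
    islDf <- data.frame(seq = islSeq, start = islStart, end = islEnd,
                        name = if (!is.null(islands$name)) islands$name
                               else sprintf("island%02d", seq_len(nIsl)))

    tracks <- list()
    for (cond in names(lev)) {
        m <- lev[[cond]]
        if (noise) {
            res <- withSeed(seed + match(cond, names(lev)) - 1L, {
                starts <- floor(stats::runif(nFragments, 1, genomeLength))
                lens <- round(rtruncnorm(nFragments, fragmentMean, fragmentSd,
                                         fragmentRange[1L], fragmentRange[2L]))
                ends <- pmin(starts + lens - 1, genomeLength)
                frIr <- IRanges::IRanges(starts, ends)
                islIr <- IRanges::IRanges(islStart, islEnd)
                ov <- IRanges::findOverlaps(frIr, islIr)
                qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
                ovBp <- pmin(ends[qh], islEnd[sh]) -
                        pmax(starts[qh], islStart[sh]) + 1
                lambda <- rep(backgroundRate, nFragments)
                lambda[qh] <- lambda[qh] + ovBp * islandCpgDensity * m[sh]
                methCount <- stats::rpois(nFragments, lambda)
                pCap <- stats::plogis(captureIntercept +
                                      captureSlope * methCount)
                captured <- stats::runif(nFragments) < pCap
                reads <- vapply(seq_len(nIsl), function(i)
                    sum(captured[qh[sh == i]]), numeric(1))
                list(reads = reads, lib = sum(captured))
            })
        } else {
            # expected counts on a placement x length grid
            qs <- seq(0.05, 0.95, by = 0.1)
            lens <- round(stats::qnorm(
                stats::pnorm(fragmentRange[1L], fragmentMean, fragmentSd) +
                qs * (stats::pnorm(fragmentRange[2L], fragmentMean, fragmentSd) -
                      stats::pnorm(fragmentRange[1L], fragmentMean, fragmentSd)),
                fragmentMean, fragmentSd))
            perIsland <- vapply(seq_len(nIsl), function(i) {
                tot <- 0
                for (L in lens) {
                    ss <- (islStart[i] - L + 1L):islEnd[i]
                    ovBp <- pmin(ss + L - 1, islEnd[i]) -
                            pmax(ss, islStart[i]) + 1
                    lambda <- backgroundRate + ovBp * islandCpgDensity * m[i]
                    tot <- tot + sum(stats::plogis(captureIntercept +
                                                   captureSlope * lambda))
                }
                tot / length(lens) * nFragments / genomeLength
            }, numeric(1))
            bgCapture <- stats::plogis(captureIntercept +
                                       captureSlope * backgroundRate)
            lib <- nFragments * bgCapture + sum(perIsland)
            res <- list(reads = perIsland, lib = lib)
        }
        iv <- islDf
        iv$reads <- res$reads
        tracks[[cond]] <- list(intervals = iv, librarySize = res$lib)
    }
    truth <- do.call(rbind, lapply(names(lev), function(cond)
        data.frame(island = islDf$name, condition = cond,
                   level = lev[[cond]])))
    list(tracks = tracks, truth = truth)
}

#' Simulate adhesion, invasion and wound-healing assay data
#'
#' Control (vector-only) trajectories follow simple saturating kinetics:
#' adhesion is a hyperbolic rise of the bound fraction, wound closure is
#' linear in time until complete, invasion counts are Poisson around a
#' control mean. The engineered (miRNA-expressing) line scales adhesion
#' capacity, invasion mean and wound-closure rate by the given effect
#' multipliers (all < 1 reproduces the reduced-adhesion, reduced-invasion,
#' reduced-motility direction). Multiplicative lognormal replicate noise is
#' applied to adhesion and wound measurements; the generating multipliers
#' are recorded as truth.
#'
#' @param adhesionEffect,invasionEffect,woundRateEffect effect multipliers
#'   of the engineered line versus control (defaults 0.6, 0.5, 0.5).
#' @param replicates replicate wells per condition (default 3).
#' @param noiseCv replicate noise coefficient of variation (default 0.1).
#' @param inputCells cells seeded per adhesion well (default 250000).
#' @param adhesionTimepoints minutes (default c(5, 15, 30, 45, 60)).
#' @param woundTimepoints hours (default 0 to 24 by 4).
#' @param invasionMean control-membrane migration mean count
#'   (default 200).
#' @param controlAdhesionMax saturating bound fraction of the control line
#'   (default 0.8).
#' @param controlWoundHours hours for the control wound to close fully
#'   (default 20).
#' @param seed integer seed.
#' @return A list with `adhesion` (cell_line, timepoint, replicate, bound,
#'   input_cells), `invasion` (sample, replicate, count, role), `wound`
#'   (sample, timepoint, replicate, area) and `truth` (the multipliers).
#' @export
genAssayData <- function(adhesionEffect = 0.6, invasionEffect = 0.5,
                         woundRateEffect = 0.5, replicates = 3L,
                         noiseCv = 0.1, inputCells = 250000L,
                         adhesionTimepoints = c(5, 15, 30, 45, 60),
                         woundTimepoints = seq(0, 24, by = 4),
                         invasionMean = 200,
                         controlAdhesionMax = 0.8,
                         controlWoundHours = 20, seed = 1L) {
    if (any(c(adhesionEffect, invasionEffect, woundRateEffect) <= 0))
        stop("effect multipliers must be positive")
    withSeed(seed, {
        lines <- c(vector_only = 1, mir_expressing = NA)
        noise <- function(n) stats::rlnorm(n, -noiseCv^2 / 2, noiseCv)

        adh <- do.call(rbind, lapply(names(lines), function(ln) {
            eff <- if (ln == "vector_only") 1 else adhesionEffect
            do.call(rbind, lapply(adhesionTimepoints, function(t) {
                frac <- controlAdhesionMax * t / (t + 15) * eff
                bound <- pmin(round(inputCells * frac *
                                    noise(replicates)), inputCells)
                data.frame(cell_line = ln, timepoint = t,
                           replicate = seq_len(replicates), bound = bound,
                           input_cells = inputCells)
            }))
        }))

        inv <- rbind(
            data.frame(sample = "wild_type", replicate = seq_len(replicates),
                       count = stats::rpois(replicates, invasionMean),
                       role = "control_membrane"),
            do.call(rbind, lapply(names(lines), function(ln) {
                eff <- if (ln == "vector_only") 1 else invasionEffect
                data.frame(sample = ln, replicate = seq_len(replicates),
                           count = stats::rpois(replicates,
                                                invasionMean * eff),
                           role = "test")
            })))

        area0 <- 100
        wnd <- do.call(rbind, lapply(names(lines), function(ln) {
            eff <- if (ln == "vector_only") 1 else woundRateEffect
            rate <- eff / controlWoundHours
            do.call(rbind, lapply(seq_len(replicates), function(r) {
                frac <- pmax(0, 1 - rate * woundTimepoints)
                area <- area0 * frac * ifelse(woundTimepoints == 0, 1,
                                              noise(length(woundTimepoints)))
                data.frame(sample = ln, timepoint = woundTimepoints,
                           replicate = r, area = area)
            }))
        }))

        list(adhesion = adh, invasion = inv, wound = wnd,
             truth = list(adhesionEffect = adhesionEffect,
                          invasionEffect = invasionEffect,
                          woundRateEffect = woundRateEffect))
    })
}
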