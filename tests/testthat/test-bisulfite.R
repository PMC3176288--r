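test_that("CpG sites are found where CG dinucleotides lie", {
  expect_equal(findCpgSites("TACGTCACG"), c(3L, 8L))
  expect_equal(findCpgSites("AAAA"), integer(0))
  # window bounds: both bases must be inside
  expect_equal(findCpgSites("TACGTCACG", start = 4, end = 9), 8L)
  expect_equal(findCpgSites("TACGTCACG", start = 1, end = 8), 3L)
  expect_error(findCpgSites("ACGT", start = 0, end = 4), "outside")
  expect_error(findCpgSites("ACGT", start = 1, end = 5), "outside")
})

test_that("CpG scan matches a brute-force adjacent-pair oracle", {
  set.seed(11)
  for (i in 1:5) {
    s <- randomDna(1000)
    expect_identical(findCpgSites(s), bruteCpgScan(s))
  }
})

test_that("bisulfite conversion protects methylated CpGs only", {
  expect_equal(bisulfiteConvert("TACGTCACG", c(0, 0)), "TATGTTATG")
  expect_equal(bisulfiteConvert("TACGTCACG", c(1, 1)), "TACGTTACG")
  expect_equal(bisulfiteConvert("TACGTCACG", c(1, 0)), "TACGTTATG")
  # efficiency 0 is the identity
  expect_equal(bisulfiteConvert("TACGTCACG", c(0, 0), efficiency = 0),
               "TACGTCACG")
  expect_error(bisulfiteConvert("TACGTCACG", c(0, 0, 1)), "length")
})

test_that("full conversion of an unmethylated molecule leaves no cytosine", {
  set.seed(21)
  for (i in 1:10) {
    s <- randomDna(300)
    conv <- bisulfiteConvert(s, rep(0, length(findCpgSites(s))))
    expect_false(grepl("C", conv, fixed = TRUE))
  }
})

test_that("seeded conversion is reproducible and leaves the caller RNG alone", {
  s <- randomDna(500)
  st <- rep(0, length(findCpgSites(s)))
  a <- bisulfiteConvert(s, st, efficiency = 0.9, seed = 7)
  b <- bisulfiteConvert(s, st, efficiency = 0.9, seed = 7)
  expect_identical(a, b)
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(bisulfiteConvert(s, st, efficiency = 0.9, seed = 7))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("in-silico PCR arithmetic, errors and CpG reporting are correct", {
  # hand-built template: CpG-free 20-nt primer sites at known offsets
  set.seed(33)
  fwd <- "ATTGGTTGATTGGATTAGGT"         # C-free: identical after conversion
  rev_foot <- "AGGTTGATTAGGTGGATTGA"
  middle <- "TTTTTACGTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTCGTTT"
  template <- paste0(strrep("A", 9), fwd, middle, rev_foot, strrep("T", 15))
  revPrimer <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rev_foot)))
  pp <- PrimerPair(fwd, revPrimer, "toy")
  hit <- insilicoPcr(template, pp, bisulfite = TRUE)
  expect_s4_class(hit, "AmpliconHit")
  expect_equal(GenomicRanges::start(ampliconRange(hit)), 10)
  expect_equal(ampliconLength(hit), 20 + nchar(middle) + 20)
  # interior CpGs reported on the native sequence, bisulfite flag irrelevant
  expect_equal(cpgSites(hit), cpgSites(insilicoPcr(template, pp,
                                                   bisulfite = FALSE)))
  expect_length(cpgSites(hit), 2)

  # missing reverse footprint
  noRev <- paste0(strrep("A", 9), fwd, middle, strrep("T", 20))
  expect_error(insilicoPcr(noRev, pp), "reverse primer")
  # duplicated forward placement is ambiguous, not silently resolved
  dup <- paste0(template, strrep("G", 5), fwd, strrep("A", 30))
  expect_error(insilicoPcr(dup, pp), "ambiguous")
})

test_that("primers overlapping a CpG amplify both methylation states", {
  set.seed(34)
  fwd_foot <- "ATTGGTTGATCGGATTAGGT"    # contains one CpG
  rev_foot <- "AGGTTGATTAGGTGGATTGA"
  template <- paste0(strrep("A", 10), fwd_foot, strrep("T", 60), rev_foot,
                     strrep("A", 10))
  # degenerate Y at the CpG cytosine matches converted C or T
  fwdPrimer <- "ATTGGTTGATYGGATTAGGT"
  pp <- PrimerPair(fwdPrimer, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rev_foot))), "degenerate")
  hit <- insilicoPcr(template, pp, bisulfite = TRUE)
  expect_equal(ampliconLength(hit), 20 + 60 + 20)
})

test_that("methylation calls come from positional comparison", {
  res <- callMethylation("TACGTTATG", "TACGTCACG")
  expect_equal(res$calls, c(1L, 0L))
  expect_equal(res$conversionRate, 1)

  # clone identical to the fully converted reference: all unmethylated
  ref <- "TACGTCACG"
  conv <- bisulfiteConvert(ref, c(0, 0))
  expect_equal(callMethylation(conv, ref)$calls, c(0L, 0L))

  # a non-C/T base at a CpG site is ambiguous
  resA <- callMethylation("TAAGTTATG", "TACGTCACG")
  expect_true(is.na(resA$calls[1]))
  expect_equal(resA$calls[2], 0L)

  expect_error(callMethylation("TACG", "TACGTCACG"), "length")
})

test_that("conversion rate flags incompletely converted clones", {
  ref <- "TACGTCACT"  # one CpG (position 3), non-CpG Cs at 6 and 8
  partial <- "TACGTCATT"  # position 6 unconverted, 8 converted
  expect_equal(callMethylation(partial, ref)$conversionRate, 0.5)
  # no non-CpG C to judge from
  expect_true(is.na(callMethylation("ACGT", "ACGT")$conversionRate))
})

test_that("calling inverts conversion exactly at efficiency 1", {
  set.seed(55)
  for (i in 1:20) {
    ref <- randomDna(200)
    sites <- findCpgSites(ref)
    if (!length(sites)) next
    states <- rbinom(length(sites), 1, 0.5)
    clone <- bisulfiteConvert(ref, states)
    expect_identical(callMethylation(clone, ref)$calls, as.integer(states))
    expect_equal(callMethylation(clone, ref)$conversionRate,
                 if (length(setdiff(which(strsplit(ref, "")[[1]] == "C"),
                                    sites))) 1 else NA_real_)
  }
})

test_that("site frequencies exclude ambiguous calls and QC failures", {
  calls <- rbind(c(1L, 1L), c(1L, 0L), c(1L, NA), c(1L, 1L),
                 c(1L, 0L), c(1L, 1L))
  cm <- CloneMatrix(calls, c(10L, 20L), "s1", "primary",
                    conversionRates = rep(1, 6))
  sf <- siteFrequencies(cm)
  expect_equal(sf$siteFrequency, c(1, 3 / 5))

  # all nine methylated / none methylated
  cm9 <- CloneMatrix(matrix(1L, 9, 3), c(1L, 5L, 9L),
                     conversionRates = rep(1, 9))
  expect_equal(siteFrequencies(cm9)$siteFrequency, c(1, 1, 1))
  cm0 <- CloneMatrix(matrix(0L, 9, 3), c(1L, 5L, 9L),
                     conversionRates = rep(1, 9))
  expect_equal(siteFrequencies(cm0)$meanFrequency, 0)

  # low-conversion clone dropped by default, kept when QC is off
  calls2 <- rbind(c(1L, 1L), c(0L, 0L), c(0L, 0L))
  cm2 <- CloneMatrix(calls2, c(2L, 4L), conversionRates = c(0.5, 1, 1))
  expect_equal(siteFrequencies(cm2)$siteFrequency, c(0, 0))
  expect_equal(siteFrequencies(cm2, applyQc = FALSE)$siteFrequency,
               c(1 / 3, 1 / 3))
  expect_equal(siteFrequencies(cm2)$clonesExcluded, "clone01")

  # a site ambiguous in every clone is flagged
  cm3 <- CloneMatrix(rbind(c(1L, NA), c(0L, NA)), c(2L, 4L),
                     conversionRates = c(1, 1))
  expect_warning(sf3 <- siteFrequencies(cm3), "ambiguous in every")
  expect_equal(sf3$undefinedSites, 2L)
  expect_true(is.nan(sf3$siteFrequency[2]))
})

test_that("hypermethylation classification thresholds the mean frequency", {
  hi <- CloneMatrix(matrix(1L, 6, 22), seq(10L, 220L, by = 10L),
                    conversionRates = rep(1, 6))
  lo <- CloneMatrix(matrix(0L, 6, 22), seq(10L, 220L, by = 10L),
                    conversionRates = rep(1, 6))
  expect_equal(classifyHypermethylation(hi)$classification, "hypermethylated")
  expect_equal(classifyHypermethylation(lo)$classification, "hypomethylated")
  expect_equal(classifyHypermethylation(hi)$excludedSites, c(2L, 3L))

  # excluded 5'-end sites do not drag a hypomethylated sample up
  calls <- matrix(0L, 6, 22)
  calls[, 2:3] <- 1L  # the keratinocyte-style sites
  kerat <- CloneMatrix(calls, seq(10L, 220L, by = 10L),
                       conversionRates = rep(1, 6))
  expect_equal(classifyHypermethylation(kerat)$meanFrequency, 0)
  expect_gt(classifyHypermethylation(kerat,
                                     excludeSites = integer(0))$meanFrequency, 0)

  one <- CloneMatrix(matrix(1L, 3, 1), 5L, conversionRates = rep(1, 3))
  expect_error(classifyHypermethylation(one, excludeSites = 1L), "excluded")
  expect_error(classifyHypermethylation(hi, threshold = 0), "threshold")
})

test_that("clone-matrix rendering follows the figure conventions", {
  cm <- CloneMatrix(rbind(c(1L, 1L, 1L), c(1L, 1L, 1L)), c(3L, 9L, 15L),
                    "wm", "stage3", conversionRates = c(1, 1))
  capture.output(lines <- renderCloneMatrix(cm))
  expect_length(lines, 3)          # header + 2 clones
  expect_match(lines[2], "###$")
  cmMix <- CloneMatrix(rbind(c(1L, 0L, NA)), 1:3 * 2L,
                       conversionRates = 1)
  capture.output(mixLines <- renderCloneMatrix(cmMix))
  expect_match(mixLines[2], "#-\\?$")
})

test_that("clone-matrix validity catches malformed objects", {
  expect_error(CloneMatrix(rbind(c(2L, 0L)), c(1L, 3L)), "values")
  expect_error(CloneMatrix(rbind(c(1L, 0L)), c(1L, 3L),
                           conversionRates = c(1, 1)), "conversion")
  expect_error(CloneMatrix(rbind(c(1L, 0L)), c(3L, 1L)), "increasing")
})
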