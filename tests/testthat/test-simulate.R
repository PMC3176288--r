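test_that("generated references carry the requested island CpG content", {
  ref <- genReference(seed = 3)
  island <- ref$island
  sites <- findCpgSites(ref$reference,
                        GenomicRanges::start(island),
                        GenomicRanges::end(island))
  expect_length(sites, 22)
  expect_length(cpgSites(ref$amplicon), 22)
  # amplicon interior CpGs are exactly the island CpGs
  expect_identical(cpgSites(ref$amplicon), sites)
  # primers are CpG-free so amplification is methylation-independent
  expect_false(grepl("CG", forwardPrimer(ref$primers), fixed = TRUE))

  refNone <- genReference(islandCpg = 0, seed = 3)
  expect_length(cpgSites(refNone$amplicon), 0)

  expect_identical(genReference(seed = 8)$reference,
                   genReference(seed = 8)$reference)
  expect_error(genReference(islandCpg = 200, islandLength = 100),
               "cannot hold")
})

test_that("clone cohorts close the loop at extreme methylation rates", {
  ref <- genReference(seed = 3)
  samples <- data.frame(sample_id = c("all", "none"),
                        class = c("stage3", "melanocyte"),
                        meth_prob = c(1, 0))
  cohort <- genCloneCohort(ref, samples, cloneCount = 4,
                           conversionEfficiency = 1, seed = 10)
  mats <- callCloneCohort(cohort$clones, ref)
  expect_true(all(methCalls(mats[["all"]]) == 1L))
  expect_true(all(methCalls(mats[["none"]]) == 0L))
  expect_equal(conversionRates(mats[["all"]]), rep(1, 4))
  # truth table records every drawn state
  expect_equal(nrow(cohort$truth), 2 * 4 * 22)
  expect_true(all(cohort$truth$methylated[cohort$truth$sample_id == "all"]
                  == 1))
})

test_that("clone generation is deterministic and clone-wise seeded", {
  ref <- genReference(seed = 3)
  samples <- data.frame(sample_id = "s", class = "stage3", meth_prob = 0.5)
  a <- genCloneCohort(ref, samples, cloneCount = 6, seed = 20)
  b <- genCloneCohort(ref, samples, cloneCount = 6, seed = 20)
  expect_identical(as.character(a$clones), as.character(b$clones))
  expect_identical(a$truth, b$truth)
  c <- genCloneCohort(ref, samples, cloneCount = 6, seed = 21)
  expect_false(identical(as.character(a$clones), as.character(c$clones)))
})

test_that("calls on simulated clones match the recorded truth exactly", {
  ref <- genReference(seed = 5)
  samples <- data.frame(sample_id = "mix", class = "primary",
                        meth_prob = 0.5)
  cohort <- genCloneCohort(ref, samples, cloneCount = 6,
                           conversionEfficiency = 1, seed = 30)
  calls <- methCalls(callCloneCohort(cohort$clones, ref)$mix)
  truth <- cohort$truth
  for (k in 1:6) {
    expect_identical(as.integer(calls[k, ]),
                     truth$methylated[truth$clone == k])
  }
})

test_that("count tables are reproducible with planted truth recorded", {
  a <- genCountTables(nGenes = 200, nPlanted = 10, seed = 41)
  b <- genCountTables(nGenes = 200, nPlanted = 10, seed = 41)
  expect_identical(a$mappers$pipeline_1$case$counts,
                   b$mappers$pipeline_1$case$counts)
  expect_identical(a$truth, b$truth)
  expect_equal(sum(a$truth$planted), 10)
  expect_true(all(abs(a$truth$true_fc[a$truth$planted]) >= 3))
  expect_true(all(a$truth$true_fc[!a$truth$planted] == 1))
})

test_that("noise-free planted fold changes pass through the pipeline", {
  sim <- genCountTables(nGenes = 300, nPlanted = 12, dispersion = 0,
                        mapperSigma = 0, plantedFc = rep(3, 12), seed = 42)
  cons <- runConsensus(sim$genes,
                       sim$mappers$pipeline_1$case,
                       sim$mappers$pipeline_1$control,
                       sim$mappers$pipeline_2$case,
                       sim$mappers$pipeline_2$control)
  planted <- sim$truth$gene_id[sim$truth$planted]
  got <- cons$corroborated_fc[match(planted, cons$gene_id)]
  # planted baseline is high-expression, so the pseudo-count barely bites
  expect_true(all(abs(got - 3) < 0.35))
  expect_true(all(cons$direction[match(planted, cons$gene_id)] == "up"))
})

test_that("capture enrichment reflects generating methylation levels", {
  dip <- genDipFragments(levels = list(tumour = 0.9, normal = 0.02),
                         seed = 51)
  res <- compareEnrichment(dip$tracks, defaultDipIslands(),
                           "tumour", "normal")
  expect_true(all(res$ratio > 1))
  # capture slope 0: methylation cannot influence expected island counts
  flat <- genDipFragments(levels = list(tumour = 0.9, normal = 0.02),
                          captureSlope = 0, noise = FALSE)
  resFlat <- compareEnrichment(flat$tracks, defaultDipIslands(),
                               "tumour", "normal")
  expect_equal(resFlat$ratio, rep(1, 10), tolerance = 1e-9)

  expect_identical(
    genDipFragments(levels = list(a = 0.5, b = 0.1), seed = 5)$tracks$a,
    genDipFragments(levels = list(a = 0.5, b = 0.1), seed = 5)$tracks$a)
  expect_error(genDipFragments(levels = list(a = 1.5, b = 0)), "levels")
})

test_that("assay generator reproduces the requested effect directions", {
  ad <- genAssayData(seed = 61)
  expect_identical(ad$adhesion, genAssayData(seed = 61)$adhesion)

  # engineered line binds fewer cells at every timepoint (mean over reps)
  adh <- ad$adhesion
  for (t in unique(adh$timepoint)) {
    vo <- mean(adh$bound[adh$cell_line == "vector_only" &
                         adh$timepoint == t])
    mir <- mean(adh$bound[adh$cell_line == "mir_expressing" &
                          adh$timepoint == t])
    expect_lt(mir, vo)
  }

  # a slower wound-closure rate leaves more open area at the endpoint
  wc <- function(ln) {
    d <- ad$wound[ad$wound$sample == ln, ]
    res <- woundClosure(d)$summary
    res$mean_closure[res$timepoint == max(res$timepoint)]
  }
  expect_lt(wc("mir_expressing"), wc("vector_only"))
  expect_equal(wc("vector_only"), 100, tolerance = 5)  # closes by ~20 h

  expect_error(genAssayData(invasionEffect = 0), "positive")
})
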