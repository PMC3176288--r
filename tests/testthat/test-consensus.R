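test_that("RPKM follows the reads-per-kilobase-per-million formula", {
  expect_equal(computeRpkm(0, 1000, 1e6), 0)
  expect_equal(computeRpkm(50, 2000, 1e6), 25)
  # scale invariance: doubling count and library leaves RPKM unchanged
  expect_equal(computeRpkm(100, 2000, 2e6), computeRpkm(50, 2000, 1e6))
  expect_error(computeRpkm(10, 0, 1e6), "positive")
  expect_error(computeRpkm(10, 1000, 0), "positive")
})

test_that("signed pseudo-count fold change follows the symmetric convention", {
  expect_equal(foldChange(4, 1.5), 2)
  expect_equal(foldChange(1.5, 4), -2)
  expect_equal(foldChange(7, 7), 1)
  expect_equal(foldChange(0, 0), 1)   # pseudo-count rescues zero RPKM
  expect_error(foldChange(-1, 2), "non-negative")
})

test_that("fold change is antisymmetric and never inside the unit gap", {
  set.seed(13)
  a <- runif(200, 0, 50); b <- runif(200, 0, 50)
  expect_equal(foldChange(a, b), -foldChange(b, a))
  expect_true(all(abs(foldChange(a, b)) >= 1))
})

test_that("consensus direction requires agreement and is conservative", {
  r1 <- data.frame(gene_id = c("up", "disc", "flat", "down"),
                   rpkm_case = c(9, 9, 3, 1.5),
                   rpkm_control = c(4, 4, 3, 4))
  r2 <- data.frame(gene_id = c("up", "disc", "flat", "down"),
                   rpkm_case = c(19, 1.5, 5, 1),
                   rpkm_control = c(4, 4, 5, 3))
  cons <- consensusMerge(r1, r2)
  cons <- cons[match(c("up", "disc", "flat", "down"), cons$gene_id), ]
  # fold changes: up = (+2, +4) -> corroborated +2 (smaller magnitude)
  expect_equal(cons$direction, c("up", "discordant", "discordant", "down"))
  expect_equal(cons$corroborated_fc[1], 2)
  # down = (-2, -2): corroborated keeps the shared sign
  expect_equal(cons$corroborated_fc[4], -2)
  expect_true(is.na(cons$corroborated_fc[2]))
  # a no-change gene (+1, +1) is discordant, not directional
  expect_equal(cons$direction[3], "discordant")
  # corroborated magnitude never exceeds either mapper's
  conc <- cons[!is.na(cons$corroborated_fc), ]
  expect_true(all(abs(conc$corroborated_fc) <=
                  pmin(abs(conc$fc_1), abs(conc$fc_2)) + 1e-12))
})

test_that("consensus handles missing genes, duplicates and all-zero rows", {
  r1 <- data.frame(gene_id = c("a", "b"), rpkm_case = c(4, 5),
                   rpkm_control = c(1.5, 0))
  r2 <- data.frame(gene_id = c("a", "zeroed"), rpkm_case = c(4, 0),
                   rpkm_control = c(1.5, 0))
  cons <- consensusMerge(r1, r2)
  # gene absent from one mapper counts as zero there; b had signal in
  # mapper 1 only -> fc_2 computed on zeros = +1 -> discordant
  expect_true("b" %in% cons$gene_id)
  expect_equal(cons$direction[cons$gene_id == "b"], "discordant")
  # all-zero genes are dropped entirely
  expect_false("zeroed" %in% cons$gene_id)

  dup <- rbind(r1, r1[1, ])
  expect_error(consensusMerge(dup, r2), "duplicate")
})

test_that("ranking is by corroborated magnitude with deterministic ties", {
  r1 <- data.frame(gene_id = c("g1", "g3", "g2"),
                   rpkm_case = c(9, 9, 19),
                   rpkm_control = c(4, 4, 4))
  r2 <- r1
  cons <- consensusMerge(r1, r2)
  expect_equal(cons$gene_id, c("g2", "g1", "g3"))
  expect_identical(consensusMerge(r1, r2), cons)  # re-runs identical
})

test_that("screen cutoffs match the stated thresholds per role", {
  rec <- data.frame(
    gene_id = c("weakFc", "weakDelta", "goodOrf", "target", "upMir",
                "downMir"),
    corroborated_fc = c(1.4, -2.0, 2.1, -1.5, 1.6, -1.6),
    transcript_delta = c(50, -9, 12, -3, 1.4, -1.4),
    direction = c("up", "down", "up", "down", "up", "down"))
  orf <- applyCutoffs(rec, "de_orf")
  expect_equal(orf$gene_id, "goodOrf")    # 1.4 fails FC; -9 fails delta
  mir <- applyCutoffs(rec, "de_mirna")    # up-screen only
  expect_setequal(mir$gene_id, c("goodOrf", "upMir"))
  expect_false(any(c("weakFc", "downMir") %in% mir$gene_id))
  tgt <- applyCutoffs(rec, "target_screen")
  expect_true(all(c("weakDelta", "target") %in% tgt$gene_id))
  expect_false("downMir" %in% tgt$gene_id)  # delta -1.4 above -2.0
  expect_error(applyCutoffs(rec, "other"), "arg")
})

test_that("target filtering is a rank-limited set intersection", {
  down <- data.frame(gene_id = c("t1", "x1", "t2", "x2"),
                     corroborated_fc = c(-3, -2.5, -2, -1.8),
                     transcript_delta = c(-20, -15, -10, -8),
                     direction = "down")
  targets <- data.frame(rank = c(1, 400, 501, 777),
                        gene_id = c("t1", "t2", "x1", "zzz"))
  out <- filterTargets(down, targets, topN = 500)
  expect_equal(out$gene_id, c("t1", "t2"))      # consensus order kept
  expect_equal(out$target_rank, c(1, 400))
  expect_equal(nrow(filterTargets(down[0, ], targets)), 0)
})

test_that("planted top-500 targets are recovered exactly by intersection", {
  # 19 planted target genes among the down-regulated records
  set.seed(99)
  planted <- sprintf("tgt%02d", 1:19)
  others <- sprintf("bg%03d", 1:40)
  down <- data.frame(gene_id = sample(c(planted, others)),
                     corroborated_fc = -2, transcript_delta = -10,
                     direction = "down")
  targets <- data.frame(rank = 1:600,
                        gene_id = c(planted, sprintf("pad%03d", 1:581)))
  out <- filterTargets(down, targets, topN = 500)
  expect_setequal(out$gene_id, planted)
})

test_that("the count-table pipeline wrapper reproduces a hand RPKM chain", {
  genes <- data.frame(gene_id = c("a", "b"), length = c(1000, 2000),
                      biotype = c("orf", "mirna"))
  mk <- function(a, b, lib) list(counts = c(a = a, b = b), librarySize = lib)
  cons <- runConsensus(genes, case1 = mk(100, 0, 1e6),
                       ctrl1 = mk(25, 0, 1e6),
                       case2 = mk(200, 0, 2e6), ctrl2 = mk(50, 0, 2e6))
  a <- cons[cons$gene_id == "a", ]
  expect_equal(a$rpkm_case_1, 100)
  expect_equal(a$fc_1, (100 + 1) / (25 + 1))
  expect_equal(a$direction, "up")
  expect_equal(a$biotype, "orf")
  expect_false("b" %in% cons$gene_id)  # all-zero gene dropped
})
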