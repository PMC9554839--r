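test_that("leniency weights follow i^(1/leniency)", {
  expect_equal(leniencyWeights(3, 1), c(1, 2, 3))
  expect_equal(leniencyWeights(2, 10), c(1, 2^0.1), tolerance = 1e-12)
  expect_equal(leniencyWeights(2, 10)[2], 1.0718, tolerance = 1e-4)
  # flattens toward 1 as leniency grows
  expect_equal(leniencyWeights(5, 1e9), rep(1, 5), tolerance = 1e-6)
  w <- leniencyWeights(6, 2.5)
  expect_true(all(diff(w) > 0))
  expect_error(leniencyWeights(3, 0), "positive")
  expect_error(leniencyWeights(3, -1), "positive")
})

test_that("consensus classification reproduces the worked two-hit example", {
  hits <- data.frame(genome_id = "g1",
                     lineage = c("F1;G1", "F1;G2"),
                     score = c(100, 50))
  tab <- consensusScoreTable(hits, leniency = 1)
  got <- setNames(tab$score, tab$prefix)
  expect_equal(got[["F1"]], 150)
  expect_equal(got[["F1;G1"]], 200)
  expect_equal(got[["F1;G2"]], 100)
  a1 <- consensusGenomeClassification(hits, leniency = 1)
  expect_identical(a1$lineage, "F1;G1")
  expect_identical(a1$level, 2L)
  # high leniency flattens the depth reward and the coarser rank wins
  a10 <- consensusGenomeClassification(hits, leniency = 10)
  expect_identical(a10$lineage, "F1")
  tab10 <- consensusScoreTable(hits, leniency = 10)
  got10 <- setNames(tab10$score, tab10$prefix)
  expect_equal(got10[["F1;G1"]], 107.18, tolerance = 1e-3)
  expect_equal(got10[["F1;G2"]], 53.59, tolerance = 1e-3)
})

test_that("unanimous hits assign the full lineage at any leniency", {
  hits <- data.frame(genome_id = "g", lineage = "A;B;C;D",
                     score = c(10, 20, 5))
  for (len in c(0.5, 1, 3, 100)) {
    a <- consensusGenomeClassification(hits, leniency = len)
    expect_identical(a$lineage, "A;B;C;D")
    expect_identical(a$level, 4L)
  }
})

test_that("prefix scores match the brute-force enumerator on random tables", {
  set.seed(23)
  for (rep in 1:20) {
    nHits <- sample(5:100, 1)
    depth <- sample(2:7, 1)
    # random lineage tree: at each level pick among a few labels
    lineages <- vapply(seq_len(nHits), function(i)
      paste(paste0("L", seq_len(depth), ".",
                   sample(2, depth, replace = TRUE)), collapse = ";"),
      character(1))
    scores <- runif(nHits, 1, 200)
    leniency <- sample(c(0.5, 1, 2, 8), 1)
    want <- bruteForcePrefixScores(lineages, scores, leniency)
    hits <- data.frame(genome_id = "g", lineage = lineages, score = scores)
    got <- consensusScoreTable(hits, leniency)
    m <- merge(want, got, by = "prefix")
    expect_equal(nrow(m), nrow(want))
    expect_equal(m$score.x, m$score.y, tolerance = 1e-9)
  }
})

test_that("assignment depth is non-increasing in leniency", {
  set.seed(91)
  for (rep in 1:30) {
    nHits <- sample(5:40, 1)
    depth <- sample(3:6, 1)
    lineages <- vapply(seq_len(nHits), function(i)
      paste(paste0("T", seq_len(depth), ".",
                   sample(3, depth, replace = TRUE)), collapse = ";"),
      character(1))
    hits <- data.frame(genome_id = "g", lineage = lineages,
                       score = runif(nHits, 1, 100))
    levels <- vapply(c(0.25, 0.5, 1, 2, 4, 16, 256), function(len)
      consensusGenomeClassification(hits, len)$level, integer(1))
    expect_true(all(diff(levels) <= 0))
  }
})

test_that("assignments are invariant to rescaling all scores", {
  set.seed(5)
  lineages <- c("A;B;C", "A;B;D", "A;E", "A;B;C")
  hits <- data.frame(genome_id = "g", lineage = lineages,
                     score = runif(4, 10, 50))
  base <- consensusGenomeClassification(hits, 1.5)
  for (k in c(0.01, 3, 1000)) {
    h2 <- hits; h2$score <- h2$score * k
    scaled <- consensusGenomeClassification(h2, 1.5)
    expect_identical(scaled$lineage, base$lineage)
    expect_equal(scaled$score, base$score * k, tolerance = 1e-9)
  }
})

test_that("marker noise cutoffs drop hits, and empty genomes flag unclassified", {
  hits <- data.frame(genome_id = "g",
                     lineage = c("A;B", "A;C"),
                     score = c(40, 90),
                     marker_id = c("m1", "m2"))
  a <- consensusGenomeClassification(hits, 1,
                                     scoreCutoffs = c(m1 = 50, m2 = 50))
  expect_identical(a$lineage, "A;C")
  all_out <- consensusGenomeClassification(
    hits, 1, scoreCutoffs = c(m1 = 1e6, m2 = 1e6))
  expect_false(all_out$classified)
  expect_true(is.na(all_out$lineage))
  expect_identical(all_out$level, 0L)
})

test_that("cluster consensus pools member hits", {
  hits1 <- data.frame(genome_id = "g1", lineage = c("F;Ga"), score = 100)
  hits2 <- data.frame(genome_id = "g2", lineage = c("F;Gb"), score = 100)
  cm <- clusterSLC(c("g1", "g2"),
                   data.frame(genome_a = "g1", genome_b = "g2", ani = 97))
  pooled <- consensusClusterClassification(rbind(hits1, hits2), cm, 1)
  # equal genus-level mass on both branches ties family (1*200) with each
  # genus (2*100); the tie backs off to the shared family
  expect_identical(pooled$lineage, "F")
  tab <- consensusScoreTable(rbind(hits1, hits2), 1)
  expect_equal(tab$score[tab$prefix == "F"], 200)
  # cluster of one genome equals the genome's own assignment
  cm1 <- clusterSLC("g1", data.frame(genome_a = character(),
                                     genome_b = character(), ani = numeric()))
  solo <- consensusClusterClassification(hits1, cm1, 1)
  own <- consensusGenomeClassification(hits1, 1)
  expect_identical(solo$lineage, own$lineage)
  expect_identical(solo$level, own$level)
  # duplicate hit tables double all scores but keep the assignment
  dup <- rbind(hits1, transform(hits1, genome_id = "g2"))
  cmD <- clusterSLC(c("g1", "g2"),
                    data.frame(genome_a = "g1", genome_b = "g2", ani = 99))
  dupOut <- consensusClusterClassification(dup, cmD, 1)
  expect_identical(dupOut$lineage, own$lineage)
  expect_equal(dupOut$score, own$score * 2)
})

test_that("two genomes diverging at genus with equal mass assign at family", {
  hits <- rbind(
    data.frame(genome_id = "g1", lineage = "F;G1", score = 60),
    data.frame(genome_id = "g2", lineage = "F;G2", score = 60))
  cm <- clusterSLC(c("g1", "g2"),
                   data.frame(genome_a = "g1", genome_b = "g2", ani = 98))
  out <- consensusClusterClassification(hits, cm, leniency = 1)
  expect_identical(out$lineage, "F")
  expect_identical(out$level, 1L)
})

test_that("consensus habitat takes the plurality with tie and missing handling", {
  h <- consensusHabitat(c("marine", "marine", "host"))
  expect_identical(h$habitat, "marine")
  expect_equal(h$support, 2 / 3)
  expect_false(h$tie)

  t <- consensusHabitat(c("a", "b"))
  expect_identical(t$habitat, "a")
  expect_equal(t$support, 0.5)
  expect_true(t$tie)

  s <- consensusHabitat("marine")
  expect_equal(s$support, 1)

  miss <- consensusHabitat(c(NA, NA))
  expect_false(miss$known)
  expect_true(is.na(miss$habitat))
  # missing labels are excluded from the vote
  mixed <- consensusHabitat(c("soil", NA, "soil", "marine"))
  expect_equal(mixed$support, 2 / 3)
  expect_error(consensusHabitat(character()), "empty")
})
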