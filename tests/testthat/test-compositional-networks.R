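test_that("CLR rows sum to zero with the 1/m^2 pseudo-count", {
  x <- matrix(c(1, 2, 4), 1)
  out <- clrTransform(x)
  expect_equal(attr(out, "pseudo_count"), 1 / 9)
  want <- log(c(1, 2, 4) + 1 / 9) - mean(log(c(1, 2, 4) + 1 / 9))
  expect_equal(unname(out[1, ]), want, tolerance = 1e-12)
  expect_equal(sum(out), 0, tolerance = 1e-12)
  # constant row maps to zeros
  expect_equal(unname(clrTransform(matrix(c(3, 3, 3), 1))[1, ]),
               rep(0, 3), tolerance = 1e-12)
  # feature permutation equivariance
  set.seed(1)
  m <- matrix(rpois(40, 10), 4, 10)
  perm <- sample(10)
  expect_equal(clrTransform(m)[, perm],
               unname(clrTransform(m[, perm])), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(clrTransform(matrix(1, 2, 1)), "at least 2")
  # rows sum to zero on random matrices
  expect_equal(rowSums(clrTransform(m)), rep(0, 4), tolerance = 1e-9)
})

test_that("Aitchison distance is the Euclidean norm of CLR differences", {
  m <- clrTransform(rbind(c(1, 2, 4), c(2, 2, 2)))
  expect_equal(aitchisonDistance(m[1, ], m[1, ]), 0)
  expect_equal(aitchisonDistance(m[1, ], m[2, ]),
               aitchisonDistance(m[2, ], m[1, ]))
  expect_equal(aitchisonDistance(m[1, ], m[2, ]),
               sqrt(sum((m[1, ] - m[2, ])^2)), tolerance = 1e-12)
  expect_error(aitchisonDistance(1:3, 1:4), "mismatch")
})

test_that("Aitchison distance satisfies metric axioms on random fixtures", {
  set.seed(33)
  counts <- matrix(rpois(8 * 12, 20), 8, 12)
  clr <- clrTransform(counts)
  d <- as.matrix(aitchisonDist(counts))
  expect_equal(unname(diag(d)), rep(0, 8))
  expect_equal(d, t(d))
  for (rep in 1:50) {
    ijk <- sample(8, 3)
    expect_lte(d[ijk[1], ijk[3]],
               d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + 1e-9)
  }
  # dist matches the row-pair definition
  expect_equal(d[1, 2], aitchisonDistance(clr[1, ], clr[2, ]),
               tolerance = 1e-12)
})

test_that("rho proportionality agrees across both algebraic forms", {
  expect_equal(rhoProportionality(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(rhoProportionality(c(1, 2, 3, 4), -c(1, 2, 3, 4)), -1)
  set.seed(9)
  for (rep in 1:50) {
    x <- rnorm(10); y <- rnorm(10)
    got <- rhoProportionality(x, y)
    covForm <- 2 * cov(x, y) / (var(x) + var(y))
    expect_equal(got, covForm, tolerance = 1e-12)
    expect_gte(got, -1); expect_lte(got, 1)
    expect_equal(got, rhoProportionality(y, x), tolerance = 1e-12)
  }
  expect_warning(out <- rhoProportionality(rep(1, 5), rep(2, 5)),
                 "zero total variance")
  expect_true(is.na(out))
  expect_error(rhoProportionality(1:2, 1:2), "3 samples")
})

test_that("degenerate ensemble equals the plain pairwise-rho network", {
  set.seed(14)
  counts <- matrix(rpois(6 * 5, 30), 6, 5,
                   dimnames = list(paste0("s", 1:6), paste0("f", 1:5)))
  plainNet <- ensembleNetwork(counts, nIterations = 1, resample = FALSE)
  clr <- clrTransform(counts)
  r <- rhoMatrix(plainNet)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(r[i, j], rhoProportionality(clr[, i], clr[, j]),
                 tolerance = 1e-12)
  # perfectly proportional features: rho 1 at any iteration count
  prop <- cbind(counts, f6 = 3 * counts[, "f1"])
  # CLR breaks exact proportionality via the pseudo-count; use identical
  # columns which survive it exactly
  dup <- cbind(counts, f6 = counts[, "f1"])
  net <- ensembleNetwork(dup, nIterations = 25, seed = 7)
  expect_equal(rhoMatrix(net)["f1", "f6"], 1, tolerance = 1e-9)
})

test_that("ensemble networks are seed-deterministic and converge to plain rho", {
  fx <- makeCountsFixture(fixtureSpec(seed = 55, nSamples = 30,
                                      nFeatures = 8))
  a <- ensembleNetwork(fx$countsA, nIterations = 50, seed = 123)
  b <- ensembleNetwork(fx$countsA, nIterations = 50, seed = 123)
  expect_identical(rhoMatrix(a), rhoMatrix(b))
  expect_identical(a@seed, 123L)
  c2 <- ensembleNetwork(fx$countsA, nIterations = 50, seed = 124)
  expect_false(identical(rhoMatrix(a), rhoMatrix(c2)))
  # ensemble mean approaches the plain network as iterations grow
  plain <- rhoMatrix(ensembleNetwork(fx$countsA, nIterations = 1,
                                     resample = FALSE))
  big <- rhoMatrix(ensembleNetwork(fx$countsA, nIterations = 400,
                                   seed = 9))
  expect_lt(max(abs(big - plain)), 0.15)
  expect_error(ensembleNetwork(fx$countsA[1:3, ], seed = 1), "4 samples")
  expect_error(ensembleNetwork(fx$countsA, nIterations = 5), "seed")
})

test_that("differential edges need positive rho in both conditions and |D| >= 0.1", {
  feats <- c("x", "y", "z")
  mk <- function(vals, cond) {
    r <- diag(1, 3); dimnames(r) <- list(feats, feats)
    r[upper.tri(r)] <- vals
    r[lower.tri(r)] <- t(r)[lower.tri(r)]
    new("AssociationNetwork", condition = cond, rho = r,
        nIterations = 1L, seed = NA_integer_)
  }
  # pairs (x,y), (x,z), (y,z)
  netA <- mk(c(0.5, 0.5, 0.42), "mature")
  netB <- mk(c(0.3, -0.2, 0.38), "early")
  out <- differentialNetwork(netA, netB)
  # kept: (x,y) D=0.2; dropped: (x,z) negative in B; (y,z) |D|=0.04
  expect_equal(nrow(out), 1)
  expect_identical(out$source, "x")
  expect_identical(out$target, "y")
  expect_equal(out$diff, 0.2)
  # sign of D is preserved for B-strengthened edges
  out2 <- differentialNetwork(netB, netA)
  expect_equal(out2$diff, -0.2)
  badB <- mk(c(0.3, 0.3, 0.3), "early")
  rownames(badB@rho)[1] <- "w"
  expect_error(differentialNetwork(netA, badB), "feature set")
})

test_that("prevalence filter keeps features present in >= 40% of samples", {
  m <- matrix(0, 10, 3, dimnames = list(NULL, c("keep", "drop", "zero")))
  m[1:4, "keep"] <- 5
  m[1:3, "drop"] <- 5
  out <- prevalenceFilter(m)
  expect_identical(colnames(out), "keep")
  expect_identical(colnames(prevalenceFilter(m, 0)), colnames(m))
})

test_that("rho dissimilarity feeds average-linkage clustering deterministically", {
  feats <- paste0("f", 1:4)
  r <- diag(1, 4); dimnames(r) <- list(feats, feats)
  r["f1", "f2"] <- r["f2", "f1"] <- 1      # dissimilarity 0, merged first
  r["f3", "f4"] <- r["f4", "f3"] <- -1     # dissimilarity 2
  r["f1", "f3"] <- r["f3", "f1"] <- 0.5
  r["f1", "f4"] <- r["f4", "f1"] <- 0.2
  r["f2", "f3"] <- r["f3", "f2"] <- 0.5
  r["f2", "f4"] <- r["f4", "f2"] <- 0.2
  net <- new("AssociationNetwork", condition = "c", rho = r,
             nIterations = 1L, seed = NA_integer_)
  out <- rhoDissimilarityLinkage(net)
  expect_equal(out$dissimilarity["f1", "f2"], 0)
  expect_equal(out$dissimilarity["f3", "f4"], 2)
  expect_equal(range(out$dissimilarity), c(0, 2))
  # hand-traced average linkage: (f1,f2) at 0; f3 joins at 0.5; f4 joins
  # the (f1,f2,f3) cluster at mean(0.8, 0.8, 2) = 1.2
  expect_equal(out$tree$height, c(0, 0.5, 1.2), tolerance = 1e-12)
  first <- out$tree$merge[1, ]
  expect_setequal(out$tree$labels[-first], c("f1", "f2"))
})

test_that("planted differential pairs carry strong one-condition signal", {
  fx <- makeCountsFixture(fixtureSpec(seed = 77, nSamples = 40,
                                      nFeatures = 12,
                                      latentCorrelation = 0.9))
  netA <- ensembleNetwork(fx$countsA, nIterations = 1, resample = FALSE,
                          condition = "A")
  netB <- ensembleNetwork(fx$countsB, nIterations = 1, resample = FALSE,
                          condition = "B")
  i <- fx$plantedPairs[1, 1]; j <- fx$plantedPairs[1, 2]
  rhoA <- rhoMatrix(netA)[i, j]
  rhoB <- rhoMatrix(netB)[i, j]
  # the latent factor induces strong proportionality in A only, so the
  # pair's differential connectivity clears the 0.1 edge filter
  expect_gt(rhoA, 0.5)
  expect_lt(abs(rhoB), 0.5)
  expect_gte(abs(rhoA - rhoB), 0.1)
})

test_that("edge tables write as TSV", {
  e <- data.frame(source = "a", target = "b", rho_a = 0.5, rho_b = 0.3,
                  diff = 0.2)
  f <- tempfile(fileext = ".tsv")
  writeEdgeTable(e, f)
  back <- utils::read.delim(f)
  expect_equal(back$diff, 0.2)
})
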