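test_that("context matrix increments one cell per usable SNV", {
  ref <- c(chr1 = "ATCAGTGAA")
  # C>T at forward TCA, and G>A at forward TGA (reverse-strand TCA):
  # both land in the T[C>T]A channel
  mt <- attachContext(mutationTable("S1", "chr1", c(3L, 7L),
                                    c("C", "G"), c("T", "A")),
                      ref, flank = 1)
  cm <- buildContextMatrix(mt)
  expect_equal(sum(contextCounts(cm)), 2L)
  expect_equal(contextCounts(cm)[1, "T[C>T]A"], 2L)
})

test_that("context matrix row sums and channels match a naive rescan", {
  ref <- simReference(5000, 0.5, 51)
  sim <- plantMutations(ref, nSamples = 6, mutsPerSample = 170,
                        apobecWeight = 0.5, seed = 52)
  mt <- attachContext(sim$muts, ref, flank = 5)
  cm <- buildContextMatrix(mt)
  expect_equal(unname(rowSums(contextCounts(cm))), rep(170, 6))
  oracle <- naiveContextMatrix(mt, as.character(ref[[1]]))
  expect_identical(unname(contextCounts(cm)), unname(oracle))
})

test_that("NMF recovers planted well-separated profiles", {
  P <- matrix(0, 96, 3)
  P[1:32, 1] <- 1; P[33:64, 2] <- 1; P[65:96, 3] <- 1
  P <- sweep(P, 2, colSums(P), "/")
  H <- simExposures(30, 3, 2000, seed = 61)$H
  cm <- simSignatureCounts(P, H, seed = 61)
  cand <- extractSignatures(cm, kRange = 3, nRestarts = 5, seed = 62)
  Q <- signatureProfiles(cand[["3"]])
  expect_true(all(greedyMatchCosines(Q, P) >= 0.9))
  expect_equal(unname(colSums(Q)), rep(1, 3), tolerance = 1e-8)
})

test_that("rank-1 input gives cophenetic 1 and near-noise reconstruction", {
  P <- matrix(1 / 96, 96, 1)
  H <- matrix(3000, 20, 1)
  cm <- simSignatureCounts(P, H, seed = 63)
  cand <- extractSignatures(cm, kRange = 1, nRestarts = 2, seed = 64)
  expect_equal(copheneticCoefficient(cand[["1"]]), 1)
  fit <- fitExposuresNNLS(cm, cand[["1"]])
  # residual per sample at multinomial-noise scale (<< signal norm)
  expect_lt(median(exposureResiduals(fit)),
            0.2 * sqrt(sum(contextCounts(cm)[1, ]^2)))
})

test_that("extraction is reproducible and permutation-equivariant", {
  P <- exampleCatalog()[, 1:2]
  H <- simExposures(12, 2, 800, seed = 65)$H
  cm <- simSignatureCounts(P, H, seed = 65)
  a <- extractSignatures(cm, kRange = 2, nRestarts = 3, seed = 66)
  b <- extractSignatures(cm, kRange = 2, nRestarts = 3, seed = 66)
  expect_identical(signatureProfiles(a[["2"]]), signatureProfiles(b[["2"]]))
  expect_identical(attr(a, "exposures"), attr(b, "exposures"))

  # permuting sample rows permutes exposures and leaves profiles intact
  perm <- c(5:12, 1:4)
  cmp <- new("ContextMatrix96", counts = contextCounts(cm)[perm, ],
             excluded = excludedCounts(cm))
  fitA <- fitExposuresNNLS(cm, a[["2"]])
  fitP <- fitExposuresNNLS(cmp, a[["2"]])
  expect_equal(unname(exposures(fitP)), unname(exposures(fitA)[perm, ]))
})

test_that("reconstruction error decreases weakly with rank", {
  P <- exampleCatalog()[, c(1, 2, 4)]
  H <- simExposures(24, 3, 1500, seed = 67)$H
  cm <- simSignatureCounts(P, H, seed = 67)
  cand <- extractSignatures(cm, kRange = 1:4, nRestarts = 4, seed = 68)
  res <- vapply(cand, function(s)
    sum(exposureResiduals(fitExposuresNNLS(cm, s))), numeric(1))
  expect_true(all(diff(res) <= 1e-6))
})

test_that("rank selection finds the first significant cophenetic drop", {
  expect_equal(selectRank(c(`2` = 0.99, `3` = 0.98, `4` = 0.80,
                            `5` = 0.78)), 3L)
  # no significant drop: argmax fallback, ties toward smaller k
  expect_equal(selectRank(c(`2` = 0.95, `3` = 0.95, `4` = 0.94)), 2L)
  expect_warning(got <- selectRank(c(`4` = 0.9)), "fewer than 2")
  expect_equal(got, 4L)
})

test_that("annotation picks the maximal-cosine catalog entry", {
  cat96 <- exampleCatalog()
  sig <- new("SignatureSet", profiles = cat96[, "SynAPOBEC", drop = FALSE],
             cophenetic = 1,
             annotations = S4Vectors::DataFrame(signature = character(),
                                                best_match = character(),
                                                cosine = numeric()))
  ann <- signatureAnnotations(annotateSignatures(sig, cat96))
  expect_equal(ann$best_match, "SynAPOBEC")
  expect_equal(ann$cosine, 1.000)

  # disjoint support -> unassigned at cosine 0
  orth <- matrix(0, 96, 1); orth[96, 1] <- 1
  colnames(orth) <- "Sig1"; rownames(orth) <- channelLabels()
  sig2 <- new("SignatureSet", profiles = orth, cophenetic = 1,
              annotations = ann[0, ])
  narrow <- cat96[, "SynAPOBEC", drop = FALSE]
  ann2 <- signatureAnnotations(annotateSignatures(sig2, narrow))
  expect_equal(ann2$best_match, "unassigned")
  expect_equal(ann2$cosine, 0)

  # noisy multinomial copy of a catalog profile is matched back, and the
  # cosine agrees with an explicit dot-product computation
  set.seed(71)
  noisy <- as.numeric(rmultinom(1, 2000, cat96[, "SynDeamination"]))
  noisy <- noisy / sum(noisy)
  prof <- matrix(noisy, 96, 1, dimnames = list(channelLabels(), "Sig1"))
  sig3 <- new("SignatureSet", profiles = prof, cophenetic = 1,
              annotations = ann[0, ])
  ann3 <- signatureAnnotations(annotateSignatures(sig3, cat96))
  expect_equal(ann3$best_match, "SynDeamination")
  byHand <- sum(noisy * cat96[, "SynDeamination"]) /
    (sqrt(sum(noisy^2)) * sqrt(sum(cat96[, "SynDeamination"]^2)))
  expect_equal(ann3$cosine, round(byHand, 3), tolerance = 1e-12)
})

test_that("the bundled catalog TSV reads back as a valid stochastic catalog", {
  path <- system.file("extdata", "synthetic_sbs_catalog.tsv",
                      package = "ApobecSig")
  cat96 <- readSignatureCatalog(path)
  expect_identical(rownames(cat96), channelLabels())
  expect_equal(unname(colSums(cat96)), rep(1, ncol(cat96)),
               tolerance = 1e-6)
  expect_equal(cat96, exampleCatalog(), tolerance = 1e-9)
})

test_that("NNLS is exact on solvable inputs and matches an independent solver", {
  skip_if_not_installed("pracma")
  P <- exampleCatalog()
  h <- c(500, 300, 0, 150)
  v <- as.numeric(P %*% h)
  V <- matrix(v, 1, 96, dimnames = list("S1", channelLabels()))
  fit <- fitExposuresNNLS(V, P)
  expect_equal(unname(exposures(fit)[1, ]), h, tolerance = 1e-6)

  # orthogonal-support target: zero exposures, residual = ||v||
  v0 <- numeric(96); v0[96] <- 10
  P2 <- P[, 1:2]; P2[96, ] <- 0
  P2 <- sweep(P2, 2, colSums(P2), "/")
  V0 <- matrix(v0, 1, 96, dimnames = list("S1", channelLabels()))
  fit0 <- fitExposuresNNLS(V0, P2)
  expect_equal(unname(exposures(fit0)[1, ]), c(0, 0))
  expect_equal(exposureResiduals(fit0), 10)

  # 50 noisy samples agree with pracma's Lawson-Hanson to 1e-8
  set.seed(72)
  for (s in 1:50) {
    v <- as.numeric(P %*% runif(4, 0, 400)) + abs(rnorm(96, 0, 2))
    mine <- ApobecSig:::.nnls(P, v)
    theirs <- pracma::lsqnonneg(P, v)$x
    expect_equal(mine, theirs, tolerance = 1e-8)
  }
})

test_that("zero-count samples get zero exposures and zero residual", {
  V <- matrix(0, 2, 96, dimnames = list(c("A", "B"), channelLabels()))
  V[1, 1] <- 100
  fit <- fitExposuresNNLS(V, exampleCatalog())
  expect_equal(unname(exposures(fit)[2, ]), rep(0, 4))
  expect_equal(exposureResiduals(fit)[2], 0)
})
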