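test_that("ssGSEA is rank-based: location and monotone-transform invariant", {
  sim <- simExpression(nGenes = 200, groupSizes = c(5, 5), seed = 91)
  sets <- list(s1 = rownames(sim$expr)[1:20],
               s2 = rownames(sim$expr)[50:80])
  base <- ssgseaScore(sim$expr, sets)

  shifted <- sim$expr
  shifted[, 3] <- shifted[, 3] + 7   # constant per-sample shift
  expect_equal(ssgseaScore(shifted, sets), base)

  mono <- 2^sim$expr                  # strictly monotone transform
  expect_equal(ssgseaScore(mono, sets), base)
})

test_that("ssGSEA handles degenerate and undersized sets", {
  sim <- simExpression(nGenes = 50, groupSizes = c(3, 3), seed = 92)
  # the all-genes set gives a defined, sample-independent score
  allSet <- list(all = rownames(sim$expr))
  sc <- ssgseaScore(sim$expr, allSet)
  expect_true(all(is.finite(sc)))
  expect_equal(diff(range(sc)), 0)
  # sets with < 2 matched genes are skipped with a warning
  expect_warning(
    got <- ssgseaScore(sim$expr, c(allSet, list(tiny = "G0001"))),
    "tiny")
  expect_equal(rownames(got), "all")
  expect_error(
    suppressWarnings(ssgseaScore(sim$expr, list(tiny = "G0001"))),
    "no usable")
})

test_that("a planted +2 log2 shift separates groups by ssGSEA", {
  hits <- 0
  for (rep in 1:10) {
    set <- sprintf("G%04d", 1:25)
    sim <- simExpression(nGenes = 400, groupSizes = c(15, 15),
                         shiftSets = list(up = set), effect = 2,
                         seed = 900 + rep)
    sc <- ssgseaScore(sim$expr, list(up = set))[1, ]
    if (min(sc[sim$groups == "A"]) > max(sc[sim$groups == "B"]))
      hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("CYT score is the geometric mean of PRF1 and GZMA", {
  expr <- matrix(c(4, 16, 9, 9), 2, 2,
                 dimnames = list(c("PRF1", "GZMA"), c("S1", "S2")))
  attr(expr, "scale") <- "linear"
  sc <- cytScore(expr, eps = 0)
  expect_equal(unname(sc), c(8, 9))
  # symmetry in the two genes
  expr2 <- expr[c("GZMA", "PRF1"), ]
  rownames(expr2) <- c("PRF1", "GZMA")
  expect_equal(unname(cytScore(expr2, scale = "linear", eps = 0)),
               unname(sc))
  # zero expression floors at eps
  expr0 <- expr; expr0[] <- 0
  expect_equal(unname(cytScore(expr0, scale = "linear")), c(0.01, 0.01))
  # log2 input is back-transformed
  exprL <- log2(expr)
  expect_equal(unname(cytScore(exprL, scale = "log2", eps = 0)), c(8, 9))
  # a missing gene is named
  expect_error(cytScore(expr[1, , drop = FALSE], scale = "linear"),
               "GZMA")
})

test_that("linear risk signatures are affine dot products with a median split", {
  expr <- matrix(c(3, 1, 5, 2), 2, 2,
                 dimnames = list(c("A", "B"), c("S1", "S2")))
  sig <- c(A = 1, B = -1)
  res <- applyLinearSignature(expr, sig)
  expect_equal(res$score, c(2, 3))
  expect_equal(res$group, c("low", "high"))
  # scaling coefficients scales scores; the median split is unchanged
  res2 <- applyLinearSignature(expr, sig * 2)
  expect_equal(res2$score, res$score * 2)
  expect_equal(res2$group, res$group)
  # absent genes contribute zero with a warning
  expect_warning(res3 <- applyLinearSignature(expr, c(sig, ZZZ = 5)),
                 "ZZZ")
  expect_equal(res3$score, res$score)
  expect_error(applyLinearSignature(expr, c(QQ = 1)), "no signature genes")
})

test_that("a risk split planted with shorter survival yields HR > 1", {
  set.seed(93)
  sim <- simExpression(nGenes = 100, groupSizes = c(20, 20),
                       shiftSets = list(risk = sprintf("G%04d", 1:10)),
                       effect = 2, seed = 94)
  sig <- setNames(rep(1, 10), sprintf("G%04d", 1:10))
  res <- applyLinearSignature(sim$expr, sig)
  # exponential survival, rate x3 in the high-score group
  rate <- ifelse(res$group == "high", 3, 1)
  time <- rexp(nrow(res), rate)
  fit <- survival::coxph(survival::Surv(time) ~ I(res$group == "high"))
  expect_gt(exp(coef(fit)), 1)
})

test_that("expression, GMT and signature readers round-trip", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  sim <- simExpression(nGenes = 20, groupSizes = c(2, 2), seed = 95)
  tab <- data.frame(gene = rownames(sim$expr), sim$expr,
                    check.names = FALSE)
  write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readExpressionMatrix(tmp)
  expect_equal(unname(back), unname(sim$expr), tolerance = 1e-12)
  expect_equal(attr(back, "scale"), "log2")

  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tG0001\tG0002\tG0003",
               "setB\tdesc\tG0004\tG0005"), gmt)
  sets <- readGMT(gmt)
  expect_equal(sets$setA, c("G0001", "G0002", "G0003"))

  sigf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tcoefficient", "TP53\t0.5", "RB1\t-0.25"), sigf)
  expect_equal(readLinearSignature(sigf), c(TP53 = 0.5, RB1 = -0.25))
  writeLines(c("gene\tcoefficient", "TP53\t0"), sigf)
  expect_error(readLinearSignature(sigf), "nonzero")
})
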