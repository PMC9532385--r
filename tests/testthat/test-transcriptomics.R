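test_that("samples are labeled by nearest voxel and gray-mask membership", {
  g <- makeGrid(c(6, 6, 6))
  hub <- rep(FALSE, nVoxels(g))
  hub[10] <- TRUE
  co <- rbind(coordsMm(g)[10, ],          # dead center of a hub voxel
              coordsMm(g)[11, ] + 0.4,    # near a non-hub voxel center
              c(500, 0, 0))               # far outside the array
  expect_equal(labelSamples(co, hub, g), c("hub", "nonhub", "excluded"))
})

test_that("an information-free classifier performs at chance", {
  g <- makeGrid(c(10, 10, 10))
  expr <- simulateExpression(60, 90, 40, 0, effect = 0, grid = g,
                             seed = 51)
  rep <- trainBoostedProtocol(expr, nTrainPerClass = 40L,
                              nRepetitions = 20L, cvFolds = 0L,
                              maxRounds = 20L, learningRate = 0.3,
                              seed = 52)
  expect_gt(rep$meanAccuracy, 40)
  expect_lt(rep$meanAccuracy, 60)
})

test_that("planted informative genes rise to the top of the contributions", {
  g <- makeGrid(c(10, 10, 10))
  expr <- simulateExpression(80, 120, 60, 15, effect = 1.2, grid = g,
                             seed = 53)
  rep <- trainBoostedProtocol(expr, nTrainPerClass = 50L,
                              nRepetitions = 20L, cvFolds = 3L,
                              maxRounds = 40L, patience = 10L,
                              learningRate = 0.2, seed = 54)
  expect_gt(rep$meanAccuracy, 60)
  top <- names(sort(rep$geneContribution, decreasing = TRUE))[1:15]
  informative <- sprintf("gene%05d", 1:15)
  expect_gte(mean(top %in% informative), 0.8)
  # split-half reproducibility of the log contributions of the top genes
  # (a small floor keeps zero-vs-tiny noise from dominating the log scale)
  repA <- trainBoostedProtocol(expr, 50L, 25L, 0L, 30L,
                               learningRate = 0.2, seed = 55)
  repB <- trainBoostedProtocol(expr, 50L, 25L, 0L, 30L,
                               learningRate = 0.2, seed = 56)
  keep <- names(sort(repA$geneContribution + repB$geneContribution,
                     decreasing = TRUE))[1:30]
  expect_gt(cor(log10(repA$geneContribution[keep] + 1e-3),
                log10(repB$geneContribution[keep] + 1e-3)), 0.9)
})

test_that("the SVM sweep separates planted signal and guards inputs", {
  g <- makeGrid(c(10, 10, 10))
  expr <- simulateExpression(50, 80, 40, 10, effect = 2, grid = g,
                             seed = 57)
  rep <- trainBoostedProtocol(expr, 30L, 10L, 0L, 25L,
                              learningRate = 0.2, seed = 58)
  sweep <- svmTopnSweep(expr, rep$geneContribution,
                        rep$sampleCorrectRate, nRange = c(5L, 10L),
                        task = "easiest", cvFolds = 5L, seed = 59)
  expect_equal(sweep$n, c(5L, 10L))
  expect_true(all(sweep$accuracy > 70))
  hard <- svmTopnSweep(expr, rep$geneContribution,
                       rep$sampleCorrectRate, nRange = 10L,
                       task = "hardest", cvFolds = 5L, seed = 60)
  expect_lte(hard$accuracy[1], sweep$accuracy[2] + 10)
  expect_error(svmTopnSweep(expr, rep$geneContribution,
                            rep$sampleCorrectRate, nRange = 500L),
               "gene count")
})

test_that("gene-set PC1 matches an eigen oracle and its invariances", {
  g <- makeGrid(c(8, 8, 8))
  expr <- simulateExpression(40, 50, 30, 0, effect = 0, grid = g,
                             seed = 61)
  X <- exprValues(expr)
  set <- colnames(X)[3:22]
  got <- genesetPc1(expr, set, "s")
  ctr <- scale(X[, set], center = TRUE, scale = FALSE)
  ev <- eigen(cov(ctr))
  score <- as.numeric(ctr %*% ev$vectors[, 1])
  if (cor(score, rowMeans(X[, set])) < 0) score <- -score
  score <- (score - min(score)) / (max(score) - min(score))
  expect_equal(unname(got$score), score, tolerance = 1e-8)
  expect_equal(got$explainedVariance,
               ev$values[1] / sum(ev$values), tolerance = 1e-8)
  expect_true(all(got$score >= 0 & got$score <= 1))
  # gene order and per-gene constants do not change the score
  got2 <- genesetPc1(expr, rev(set), "s")
  expect_equal(got2$score, got$score, tolerance = 1e-8)
  expr2 <- expr
  SummarizedExperiment::assay(expr2)[set[1], ] <-
    SummarizedExperiment::assay(expr2)[set[1], ] + 100
  expect_equal(genesetPc1(expr2, set, "s")$score, got$score,
               tolerance = 1e-8)
  # single-gene set collapses to min-max scaling of that gene
  one <- genesetPc1(expr, set[1], "s")
  v <- X[, set[1]]
  expect_equal(unname(one$score),
               unname((v - min(v)) / (max(v) - min(v))),
               tolerance = 1e-8)
  expect_equal(one$explainedVariance, 1)
  # two perfectly correlated genes: PC1 explains everything
  expr3 <- expr
  SummarizedExperiment::assay(expr3)[set[2], ] <-
    2 * SummarizedExperiment::assay(expr3)[set[1], ]
  expect_equal(genesetPc1(expr3, set[1:2], "s")$explainedVariance, 1)
  expect_error(genesetPc1(expr, c("nope1", "nope2")), "no gene")
})

test_that("trajectories smooth, difference and flag against the MAD band", {
  days <- seq(60, 15000, length.out = 60)
  # noiseless quadratic trend is recovered closely
  x <- log2(days)
  quad <- 0.1 * (x - 9)^2
  cur <- trajectoryCurve(days, quad, bandwidth = 0.5)
  ref <- 0.1 * (cur$log2Days - 9)^2
  expect_lt(sqrt(mean((cur$fit - ref)^2)) / diff(range(ref)), 0.02)
  # constant scores give a flat curve and no flags at zero difference
  flat <- trajectoryCurve(days, rep(1, 60))
  expect_true(all(abs(flat$fit - 1) < 1e-12))
  reg <- matrix(rnorm(8 * 60, sd = 0.3), 8, 60)
  dif <- trajectoryDifference(flat, flat, reg, x)
  expect_true(all(dif$difference == 0))
  expect_true(!any(dif$exceeds))
  # identical groups differ nowhere even with a nonzero band
  cur2 <- trajectoryCurve(days, quad + rnorm(60, 0, 0.05))
  dif2 <- trajectoryDifference(cur2, cur2, reg, x)
  expect_true(all(dif2$difference == 0))
  expect_error(trajectoryCurve(days[1:3], quad[1:3]), "insufficient")
})

test_that("parcels become hubs only above half coverage", {
  parcels <- rep(c("A", "B", "C"), times = c(10, 10, 4))
  hub <- c(rep(TRUE, 6), rep(FALSE, 4),    # A: 60%
           rep(TRUE, 5), rep(FALSE, 5),    # B: exactly 50%
           rep(FALSE, 4))                  # C: 0%
  expect_equal(assignParcelHubs(parcels, hub), "A")
  # random fixture against a counting oracle
  set.seed(71)
  pl <- sample(1:6, 300, replace = TRUE)
  hb <- runif(300) < 0.5
  oracle <- names(which(tapply(hb, as.character(pl), mean) > 0.5))
  expect_setequal(assignParcelHubs(pl, hb), oracle)
})
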