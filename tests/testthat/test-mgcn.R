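test_that("graph Laplacians match hand-computed small cases", {
  # 3-node path graph
  A <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  op <- normalizedLaplacian(A)
  expect_equal(op$D, c(1, 2, 1))
  expect_equal(op$L, rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))

  # complete graph K3: normalized-Laplacian spectrum {0, 1.5, 1.5}
  K3 <- matrix(1, 3, 3) - diag(3)
  ev <- sort(eigen(normalizedLaplacian(K3)$Lnorm, symmetric = TRUE)$values)
  expect_equal(ev, c(0, 1.5, 1.5), tolerance = 1e-10)

  set.seed(40)
  for (r in 1:5) {
    A <- randomAdjacency(6)
    op <- normalizedLaplacian(A)
    evs <- eigen(op$Lnorm, symmetric = TRUE)$values
    expect_lt(abs(min(evs)), 1e-8)          # constant-vector kernel
    expect_true(all(evs <= 2 + 1e-8))
    expect_equal(op$P, t(op$P), tolerance = 1e-10)
  }
  iso <- rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0))
  expect_error(normalizedLaplacian(iso), "isolated node.*3")
})

test_that("K = 1 Chebyshev layer equals the dense spectral convolution", {
  # oracle: eigendecompose the renormalized operator P = U (1 - lambda) U'
  # and filter in the spectral basis with g(lambda) = 1 - lambda.
  set.seed(41)
  for (r in 1:10) {
    S <- sample(4:8, 1)
    A <- randomAdjacency(S)
    op <- normalizedLaplacian(A)
    x <- matrix(rnorm(S * 3), S, 3)
    W <- matrix(rnorm(3 * 2), 3, 2)
    LP <- diag(S) - op$P           # renormalized-graph Laplacian
    e <- eigen(LP, symmetric = TRUE)
    dense <- e$vectors %*% diag(1 - e$values) %*% t(e$vectors) %*% x %*% W
    expect_equal(chebGraphConv(x, op, W, K = 1L), dense, tolerance = 1e-6)
  }
})

test_that("identity graphs, weight linearity and order checks", {
  S <- 5
  op <- normalizedLaplacian(diag(S))   # A = I so P = I
  x <- matrix(rnorm(S * 4), S, 4)
  expect_equal(chebGraphConv(x, op, diag(4), K = 1L), x, tolerance = 1e-12)
  W <- matrix(rnorm(8), 4, 2)
  expect_equal(chebGraphConv(x, op, 2 * W, K = 1L),
               2 * chebGraphConv(x, op, W, K = 1L), tolerance = 1e-12)
  expect_error(chebGraphConv(x, op, W, K = 3L), "K must be 1 or 2")
  expect_error(chebGraphConv(x, op, list(W, W), K = 2L), "three weight")
})

test_that("training fits separable graphs and is seed-deterministic", {
  g <- separableGraphs(60, seed = 5)
  labels <- graphLabels(g)
  cfg <- trainConfig(epochs = 200L, seed = 3L)
  model <- trainMgcn(g, labels, cfg)
  pred <- predictTrials(model, g)
  expect_gte(mean(pred$label == labels), 0.95)
  expect_true(all(abs(rowSums(cbind(pred$pStrong, pred$pWeak)) - 1) < 1e-8))

  model2 <- trainMgcn(g, labels, cfg)
  expect_identical(model@lossTrace, model2@lossTrace)
  expect_length(model@lossTrace, 200L)
  # dropout off is also bit-stable
  cfg0 <- trainConfig(epochs = 50L, seed = 9L, dropout = 0)
  expect_identical(trainMgcn(g, labels, cfg0)@lossTrace,
                   trainMgcn(g, labels, cfg0)@lossTrace)

  expect_error(trainMgcn(g, rep("strong", length(g)), cfg), "single class")
})

test_that("prediction is deterministic and order-invariant", {
  g <- separableGraphs(30, seed = 6)
  model <- trainMgcn(g, graphLabels(g), trainConfig(epochs = 80L, seed = 1L))
  p1 <- predictTrials(model, g)
  p2 <- predictTrials(model, g)
  expect_identical(p1, p2)
  perm <- sample(length(g))
  p3 <- predictTrials(model, g[perm])
  expect_equal(p3$pStrong, p1$pStrong[perm], tolerance = 1e-12)
  expect_true(all(p1$label %in% c("strong", "weak")))
})

test_that("node relabeling leaves pooled outputs unchanged", {
  g <- separableGraphs(12, seed = 7)
  model <- trainMgcn(g, graphLabels(g), trainConfig(epochs = 30L, seed = 2L))
  perm <- sample(19)
  permuteTriple <- function(tr) {
    lapply(tr, function(dg) DomainGraph(nodeFeatures(dg)[perm, , drop = FALSE],
                                        adjacency(dg)[perm, perm],
                                        graphDomain(dg), dg@annotation))
  }
  gPerm <- lapply(g, permuteTriple)
  pOrig <- predictTrials(model, g)
  pPerm <- predictTrials(model, gPerm)
  expect_equal(pPerm$pStrong, pOrig$pStrong, tolerance = 1e-6)
})

test_that("permuted labels give chance-level held-out accuracy", {
  set.seed(50)
  g <- separableGraphs(90, seed = 8)
  labels <- sample(graphLabels(g))           # break the label-feature link
  trainIdx <- 1:60
  testIdx <- 61:90
  model <- trainMgcn(g[trainIdx], labels[trainIdx],
                     trainConfig(epochs = 120L, seed = 4L))
  acc <- mean(predictTrials(model, g[testIdx])$label == labels[testIdx])
  # with no label-feature link, accuracy stays inside the 99% binomial
  # band around the majority-class rate of the held-out set
  majority <- max(table(labels[testIdx])) / 30
  band <- stats::qbinom(c(0.005, 0.995), 30, majority) / 30
  expect_gte(acc, band[1] - 1e-9)
  expect_lte(acc, band[2] + 1e-9)
})

test_that("training configuration is validated", {
  expect_error(trainConfig(chebOrder = 3), "1 or 2")
  expect_error(trainConfig(dropout = 1), "dropout")
  expect_error(trainConfig(learningRate = 0), "positive")
})
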