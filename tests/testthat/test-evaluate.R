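test_that("vote counting follows the majority with low-index ties", {
  acts <- rep(1:3, each = 10)
  preds <- rep("weak", 30)
  preds[acts == 1][1:8] <- "strong"
  preds[acts == 2][1:3] <- "strong"
  v <- voteAction(preds, acts)
  expect_identical(v$chosen, 1L)
  expect_identical(unname(v$votes), c(8L, 3L, 0L))
  expect_false(v$tie)

  tiePreds <- rep("weak", 30)
  tiePreds[acts == 1][1:5] <- "strong"
  tiePreds[acts == 2][1:5] <- "strong"
  vt <- voteAction(tiePreds, acts)
  expect_identical(vt$chosen, 1L)
  expect_true(vt$tie)

  allWeak <- voteAction(rep("weak", 30), acts)
  expect_identical(allWeak$chosen, 1L)
  expect_true(allWeak$tie)
  expect_error(voteAction(character(0), integer(0)), "empty")
})

test_that("confusion metrics match the hand-worked table", {
  # 25 strong / 50 weak design, perfect predictions
  truth <- rep(c("strong", "weak"), c(25, 50))
  perfect <- confusionAndMetrics(truth, truth)
  expect_identical(unname(perfect$counts), c(25L, 0L, 50L, 0L))
  expect_equal(unname(perfect$metrics[c("F1", "sensitivity", "specificity",
                                        "accuracy", "kappa")]),
               c(1, 1, 1, 100, 1))

  # TP=19, FN=6, FP=14, TN=36
  counts <- c(TP = 19, FP = 14, TN = 36, FN = 6)
  m <- metricsFromCounts(counts)$metrics
  expect_equal(unname(m[["accuracy"]]), 100 * 55 / 75, tolerance = 1e-10)
  expect_equal(unname(m[["sensitivity"]]), 19 / 25)
  expect_equal(unname(m[["specificity"]]), 36 / 50)
  expect_equal(unname(m[["F1"]]), 38 / (38 + 14 + 6), tolerance = 1e-10)
  # p_e = ((25)(33) + (50)(42)) / 75^2 = 0.52
  expect_equal(kappaScore(counts), (55 / 75 - 0.52) / (1 - 0.52),
               tolerance = 1e-10)
  expect_equal(kappaScore(counts), 4 / 9, tolerance = 1e-12)
  expect_equal(round(kappaScore(counts), 4), 0.4444)

  # all-weak predictions: sensitivity 0, specificity 1, F1 undefined
  allWeak <- confusionAndMetrics(rep("weak", 75), truth)
  expect_equal(unname(allWeak$metrics[["sensitivity"]]), 0)
  expect_equal(unname(allWeak$metrics[["specificity"]]), 1)
  expect_true(is.nan(allWeak$metrics[["F1"]]))
  expect_true("F1" %in% allWeak$undefined)
  expect_error(confusionAndMetrics("strong", c("strong", "weak")),
               "length mismatch")
})

test_that("kappa identities hold", {
  expect_equal(kappaScore(c(TP = 30, FP = 0, TN = 45, FN = 0)), 1)
  # independent predictions: cells equal products of marginals
  expect_equal(kappaScore(c(TP = 20, FP = 20, TN = 30, FN = 30)), 0,
               tolerance = 1e-12)
  # degenerate one-cell table
  expect_true(is.nan(kappaScore(c(TP = 10, FP = 0, TN = 0, FN = 0))))
  # metric identities on random tables
  set.seed(70)
  for (i in 1:10) {
    cts <- c(TP = sample(0:20, 1), FP = sample(0:20, 1),
             TN = sample(1:20, 1), FN = sample(0:20, 1))
    m <- metricsFromCounts(cts)$metrics
    if (!is.nan(m[["sensitivity"]])) {
      expect_equal(m[["sensitivity"]] * (cts[["TP"]] + cts[["FN"]]),
                   cts[["TP"]], tolerance = 1e-12)
    }
    expect_equal(m[["accuracy"]], 100 * (cts[["TP"]] + cts[["TN"]]) /
                   sum(cts), tolerance = 1e-12)
  }
})

test_that("clustering coefficient equals exhaustive triangle counting", {
  K4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(clusteringCoefficient(K4)$C, 1)
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(clusteringCoefficient(star)$C, 0)

  bruteForce <- function(B) {
    n <- nrow(B)
    Ci <- numeric(n)
    for (i in seq_len(n)) {
      nb <- which(B[i, ] == 1)
      k <- length(nb)
      if (k < 2) next
      tri <- 0
      for (a in nb) for (b in nb) if (a < b && B[a, b] == 1) tri <- tri + 1
      Ci[i] <- tri / (k * (k - 1) / 2)
    }
    mean(Ci)
  }
  set.seed(71)
  for (r in 1:20) {
    n <- sample(4:8, 1)
    B <- matrix(rbinom(n * n, 1, 0.45), n)
    B <- pmax(B, t(B))
    diag(B) <- 0
    expect_equal(clusteringCoefficient(B)$C, bruteForce(B))
  }
  expect_error(clusteringCoefficient(K4, threshold = 0), "threshold")
})

test_that("clustering coefficient agrees with igraph on binary graphs", {
  skip_if_not_installed("igraph")
  set.seed(72)
  for (r in 1:10) {
    n <- sample(5:9, 1)
    B <- matrix(rbinom(n * n, 1, 0.5), n)
    B <- pmax(B, t(B))
    diag(B) <- 0
    gi <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
    ref <- igraph::transitivity(gi, type = "localundirected", isolates = "zero")
    ref[is.nan(ref)] <- 0
    expect_equal(clusteringCoefficient(B)$Ci, ref, tolerance = 1e-12)
  }
})

test_that("proportional thresholding binarizes weighted graphs sensibly", {
  set.seed(73)
  A <- randomAdjacency(10)
  res <- clusteringCoefficient(A, threshold = 0.3)
  offKept <- sum(res$binary[row(res$binary) != col(res$binary)])
  expect_gte(offKept / (10 * 9), 0.29)       # ties at the cutoff are kept
  expect_true(all(res$binary %in% c(0, 1)))
  expect_gte(res$C, 0)
  expect_lte(res$C, 1)
})

test_that("strong/weak network contrast reports symmetric means and a p-value", {
  set.seed(74)
  mkTriple <- function(subject, label, boost) {
    A <- randomAdjacency(8)
    if (label == "strong") {
      A <- pmin(A + boost, 1)
      diag(A) <- 1
    }
    meta <- list(subject = subject, action = 1, label = label)
    list(time = DomainGraph(matrix(rnorm(8), 8, 1), A, "time", meta),
         frequency = DomainGraph(matrix(rnorm(8), 8, 1), A, "frequency", meta),
         spatial = DomainGraph(matrix(rnorm(8), 8, 1), A, "spatial", meta))
  }
  graphs <- c(lapply(1:12, function(i) mkTriple(1 + i %% 2,
                                                if (i <= 6) "strong" else "weak",
                                                0.3)))
  res <- compareStrongWeakNetworks(graphs, nPermutations = 200L, seed = 2L)
  for (dom in c("time", "frequency", "spatial")) {
    expect_equal(res[[dom]]$meanStrong, t(res[[dom]]$meanStrong))
    expect_equal(unname(diag(res[[dom]]$meanStrong)), rep(1, 8))
    expect_gte(res[[dom]]$p, 1 / 201)
    expect_lte(res[[dom]]$p, 1)
  }
})

test_that("null condition contrast rejects at roughly the nominal rate", {
  set.seed(75)
  pvals <- vapply(1:30, function(run) {
    graphs <- lapply(1:10, function(i) {
      A <- randomAdjacency(7)
      meta <- list(subject = 1 + i %% 2, action = 1,
                   label = if (i <= 5) "strong" else "weak")
      list(time = DomainGraph(matrix(rnorm(7), 7, 1), A, "time", meta),
           frequency = DomainGraph(matrix(rnorm(7), 7, 1), A, "frequency",
                                   meta),
           spatial = DomainGraph(matrix(rnorm(7), 7, 1), A, "spatial", meta))
    })
    compareStrongWeakNetworks(graphs, nPermutations = 99L,
                              seed = run)$time$p
  }, 0)
  # under the null the rejection rate at alpha = 0.2 stays near 0.2
  expect_lte(mean(pvals < 0.2), 0.5)
  expect_gte(mean(pvals < 0.2), 0.0)
  expect_gt(mean(pvals), 0.25)   # p-values not concentrated at 0
})

test_that("LOSO on the tiny cohort produces coherent, reproducible reports", {
  coh <- tinyCohort()
  labelings <- list(assignActionLabels(c(80, 60, 55), 1L),
                    assignActionLabels(c(55, 82, 60), 2L),
                    assignActionLabels(c(60, 55, 84), 3L))
  # align synthetic truth with the injected labelings
  for (k in 1:3) labelings[[k]]@strongAction <- coh[[k]]$trueStrongAction
  cfg <- trainConfig(epochs = 40L, seed = 1L)
  reps <- losoCv(coh, cfg, labelings = labelings)
  expect_length(reps, 3L)
  expect_identical(vapply(reps, function(r) r@subject, 0L), 1:3)
  for (r in reps) {
    expect_identical(sum(confusionCounts(r)), length(r@predictions))
    expect_identical(r@chosenAction,
                     voteAction(r@predictions,
                                annotations(coh[[r@subject]]$cognitive)$action)$chosen)
  }
  reps2 <- losoCv(coh, cfg, labelings = labelings)
  expect_identical(lapply(reps, reportMetrics), lapply(reps2, reportMetrics))
  sm <- cohortSummary(reps)
  expect_identical(unname(sum(sm$counts)), 36L)
  expect_true(sm$recoveryTrue >= 0 && sm$recoveryTrue <= 1)
  # multi-seed path reuses the cache and returns one report set per seed
  multi <- losoCv(coh, cfg, labelings = labelings, trainSeeds = c(1L, 2L))
  expect_named(multi, c("seed1", "seed2"))
  expect_identical(lapply(multi$seed1, reportMetrics),
                   lapply(reps, reportMetrics))
  expect_error(losoCv(coh[1], cfg), "at least 2")
})
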