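test_that("block averaging reproduces closed-form block means", {
  const <- matrix(3.5, 19, 1000)
  expect_equal(downsampleAverage(const), matrix(3.5, 19, 40))

  ramp <- matrix(rep(1:1000, each = 19), 19, byrow = FALSE)
  ramp <- matrix(1:1000, 19, 1000, byrow = TRUE)
  ds <- downsampleAverage(ramp)
  expect_identical(dim(ds), c(19L, 40L))
  # k-th 25-block of 1..1000 has mean 25(k-1) + 13
  expect_equal(ds[1, ], 25 * (0:39) + 13)
  expect_error(downsampleAverage(matrix(1, 19, 999)), "not divisible")
})

test_that("PCC adjacency matches a two-pass covariance oracle", {
  corOracle <- function(a, b) {
    num <- sum((a - mean(a)) * (b - mean(b)))
    den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    abs(num / den)
  }
  x <- rbind(c(1, 2, 3), c(1, 3, 2))
  A <- pccAdjacency(x)
  expect_equal(A[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(A[1, 2], corOracle(x[1, ], x[2, ]), tolerance = 1e-12)

  set.seed(10)
  for (r in 1:5) {
    m <- matrix(rnorm(24), 4, 6)
    A <- pccAdjacency(m)
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(A[i, j], corOracle(m[i, ], m[j, ]), tolerance = 1e-10)
    }
    expect_equal(A, t(A))
    expect_true(all(A >= 0 & A <= 1 + 1e-12))
    expect_equal(unname(diag(A)), rep(1, 4))
  }
  # self and sign-flip
  y <- matrix(rnorm(20), 2, 10)
  y[2, ] <- -y[1, ]
  expect_equal(unname(pccAdjacency(y)[1, 2]), 1, tolerance = 1e-12)
  expect_error(pccAdjacency(rbind(rnorm(5), rep(1, 5))), "zero-variance")
})

test_that("band decomposition concentrates energy in the right band", {
  fs <- 1000
  t <- seq_len(1000) / fs
  energy <- function(m) sum(m^2)
  sig <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 10 * t))
  bands <- bandDecompose(sig, fs)
  e <- vapply(bands, energy, 0)
  expect_gt(e[["8-13"]] / sum(e), 0.9)

  sig2 <- rbind(sin(2 * pi * 2 * t), sin(2 * pi * 2 * t))
  e2 <- vapply(bandDecompose(sig2, fs), energy, 0)
  expect_identical(names(which.max(e2)), "1-4")

  z <- vapply(bandDecompose(matrix(0, 2, 500), fs), energy, 0)
  expect_true(all(z == 0))
  expect_error(bandDecompose(sig, fs = 30), "at least 40")
})

test_that("Welch band features behave like power", {
  fs <- 1000
  t <- seq_len(1000) / fs
  zero <- bandDecompose(matrix(0, 3, 1000) +
                          1e-300 * 0, fs)  # exactly zero signal
  expect_true(all(welchPsd(zero) == 0))

  sig <- matrix(rnorm(3 * 1000, sd = 0.01), 3, 1000)
  sig[1, ] <- sig[1, ] + sin(2 * pi * 10 * t)
  psd <- welchPsd(bandDecompose(sig, fs))
  expect_identical(dim(psd), c(3L, 4L))
  expect_true(all(psd >= 0))
  expect_gt(psd[1, "8-13"], 3 * max(psd[1, c("1-4", "4-8", "13-20")]))

  psd2 <- welchPsd(bandDecompose(2 * sig, fs))
  expect_equal(unname(psd2), unname(4 * psd), tolerance = 1e-8)
})

test_that("PLV is 1 for locked phases and near 0 for independent ones", {
  fs <- 1000
  t <- seq_len(2000) / fs
  same <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 10 * t))
  bands <- bandDecompose(same, fs)
  A <- plvAdjacency(bands)
  expect_equal(unname(A[1, 2]), 1, tolerance = 1e-6)

  # equal frequency, fixed phase offset pi/3: constant phase difference.
  # Feed the band-limited pair directly (single-band structure).
  offs <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 10 * t + pi / 3))
  bl <- list(`8-13` = offs)
  attr(bl, "bands") <- list(`8-13` = c(8, 13))
  attr(bl, "fs") <- fs
  class(bl) <- "BandSignals"
  expect_equal(unname(plvAdjacency(bl)[1, 2]), 1, tolerance = 1e-3)

  # independent random phase sequences, T = 10000:
  # E|mean of unit phasors| ~ sqrt(pi / (4 T)) ~ 0.009
  set.seed(77)
  ph <- matrix(runif(2 * 10000, 0, 2 * pi), 2)
  expect_lt(plvFromPhases(ph)[1, 2], 0.05)

  flat <- list(`8-13` = matrix(1, 2, 100))
  attr(flat, "bands") <- list(`8-13` = c(8, 13))
  attr(flat, "fs") <- fs
  class(flat) <- "BandSignals"
  expect_error(plvAdjacency(flat), "constant")
})

test_that("PLV is invariant to amplitude scaling", {
  set.seed(8)
  sig <- matrix(rnorm(2 * 1000), 2)
  b1 <- bandDecompose(sig, 1000)
  sig2 <- sig * c(5, 0.1)
  b2 <- bandDecompose(sig2, 1000)
  expect_equal(plvAdjacency(b1), plvAdjacency(b2), tolerance = 1e-8)
})

test_that("CSP diagonalizes both classes and orders filters", {
  set.seed(20)
  # two channels, variance concentrated along orthogonal directions
  mk <- function(n, sds) lapply(seq_len(n), function(i)
    rbind(rnorm(500, sd = sds[1]), rnorm(500, sd = sds[2])))
  strong <- mk(20, c(3, 0.3))
  weak <- mk(20, c(0.3, 3))
  model <- fitCsp(strong, weak)
  W <- cspFilters(model)
  vs <- mean(vapply(strong, function(m) var((W %*% m)[1, ]), 0))
  vw <- mean(vapply(weak, function(m) var((W %*% m)[1, ]), 0))
  expect_gt(vs / vw, 10)
  ev <- cspEigenvalues(model)
  expect_true(all(diff(ev) <= 1e-12))

  # simultaneous diagonalization: class variances sum to 1 per filter
  C1 <- mdgcn:::meanNormalizedCovariance(strong)
  C2 <- mdgcn:::meanNormalizedCovariance(weak)
  D1 <- W %*% C1 %*% t(W)
  D2 <- W %*% C2 %*% t(W)
  expect_lt(max(abs(D1[row(D1) != col(D1)])), 1e-8)
  expect_lt(max(abs(D2[row(D2) != col(D2)])), 1e-8)
  expect_equal(unname(diag(D1) + diag(D2)), rep(1, 2), tolerance = 1e-8)

  same <- fitCsp(strong, strong)
  expect_equal(cspEigenvalues(same), rep(0.5, 2), tolerance = 1e-8)
})

test_that("CSP spatial features are ordered log variance shares", {
  set.seed(21)
  csp <- tinyCsp()
  prepped <- tinyPreppedCognitive()
  coh <- tinyCohort()
  strongIdx <- which(annotations(prepped[[2]])$action ==
                       coh[[2]]$trueStrongAction)
  f <- cspSpatialFeature(trialMatrix(prepped[[2]], strongIdx[1]), csp)
  expect_identical(dim(f), c(19L, 1L))
  # log of normalized variance: shares sum to 1
  expect_equal(sum(exp(f)), 1, tolerance = 1e-10)
  # strong-class trials load the top-ranked filter over the bottom one
  fmeans <- rowMeans(vapply(strongIdx, function(i)
    as.numeric(cspSpatialFeature(trialMatrix(prepped[[2]], i), csp)),
    numeric(19)))
  expect_gt(fmeans[1], fmeans[19])
  expect_error(cspSpatialFeature(matrix(0, 19, 100), csp), "degenerate")
  expect_error(cspSpatialFeature(matrix(1, 5, 100), csp), "channels")
})

test_that("Manhattan-distance adjacency matches hand arithmetic", {
  A <- mdAdjacency(c(0.1, 0.5, 0.9))
  expect_equal(A[1, 2], 1)
  expect_equal(A[1, 3], 0)
  expect_equal(A[2, 3], 1)
  expect_equal(unname(diag(A)), rep(1, 3))
  expect_equal(A, t(A))

  set.seed(30)
  s <- rnorm(19)
  A1 <- mdAdjacency(s)
  A2 <- mdAdjacency(2.5 * s + 7)   # affine invariance
  expect_equal(A1, A2, tolerance = 1e-10)
  expect_true(min(A1) == 0 && max(offDiag <- A1[row(A1) != col(A1)]) == 1)
  expect_warning(uni <- mdAdjacency(rep(0.3, 4)), "identical")
  expect_true(all(uni == 1))
})

test_that("multi-domain graph triples have the architecture's shapes", {
  prepped <- tinyPreppedCognitive()[[1]]
  g <- buildMultidomainGraphs(prepped, tinyCsp())
  expect_length(g, nTrials(prepped))
  expect_identical(dim(nodeFeatures(g[[1]]$time)), c(19L, 40L))
  expect_identical(dim(nodeFeatures(g[[1]]$frequency)), c(19L, 4L))
  expect_identical(dim(nodeFeatures(g[[1]]$spatial)), c(19L, 1L))
  for (dom in c("time", "frequency", "spatial")) {
    A <- adjacency(g[[1]][[dom]])
    expect_identical(dim(A), c(19L, 19L))
    expect_equal(A, t(A))
    expect_true(all(A >= 0 & A <= 1 + 1e-12))
    expect_identical(g[[2]][[dom]]@annotation$action,
                     annotations(prepped)$action[2])
  }
  g2 <- buildMultidomainGraphs(prepped, tinyCsp())
  expect_identical(adjacency(g[[3]]$frequency), adjacency(g2[[3]]$frequency))
})
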