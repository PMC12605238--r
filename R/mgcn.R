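# Three-branch spectral graph convolutional classifier.
#
# Each domain branch: GC(f_in -> 32) + ReLU + dropout, GC(32 -> 16) +
# ReLU + dropout, global mean pool over the 19 nodes. The 3 x 16
# pooled features are concatenated, batch-standardized, and mapped by a
# dense layer + softmax to strong/weak probabilities.
#
# Training is full-batch: all trials' node features are stacked into one
# (N*S) x f matrix and the per-trial propagation matrices into one
# sparse block-diagonal operator, so an epoch is a handful of large
# matrix products.

#' Graph spectral operators for one adjacency
#'
#' Computes the degree vector, combinatorial Laplacian \code{L = D - A},
#' symmetric normalized Laplacian
#' \code{Lnorm = I - D^(-1/2) A D^(-1/2)} (eigenvalues in [0, 2]) and the
#' renormalized propagation matrix
#' \code{P = Dt^(-1/2) (A + I) Dt^(-1/2)} used by the first-order
#' convolution.
#'
#' @param A symmetric nonnegative adjacency matrix.
#' @return list with elements \code{A}, \code{D} (degree vector),
#'   \code{L}, \code{Lnorm}, \code{P}.
#' @export
normalizedLaplacian <- function(A) {
  A <- as.matrix(A)
  stopIfNotSymmetric(A)
  if (min(A) < 0) stop("adjacency must be nonnegative")
  D <- rowSums(A)
  if (any(D == 0)) {
    stop("isolated node(s) with zero degree: ",
         paste(which(D == 0), collapse = ", "))
  }
  S <- nrow(A)
  L <- diag(D) - A
  dmh <- 1 / sqrt(D)
  Lnorm <- diag(S) - (dmh * A) %*% diag(dmh)
  Lnorm <- (Lnorm + t(Lnorm)) / 2
  At <- A + diag(S)
  dt <- 1 / sqrt(rowSums(At))
  P <- (dt * At) %*% diag(dt)
  P <- (P + t(P)) / 2
  list(A = A, D = D, L = L, Lnorm = Lnorm, P = P)
}

#' Chebyshev spectral graph convolution of one trial
#'
#' Order K = 1 applies the renormalized first-order propagation
#' \code{P \%*\% x \%*\% W}. Order K = 2 evaluates the Chebyshev
#' expansion \code{sum_m Tm(Ls) x Wm} with the scaled Laplacian
#' \code{Ls = Lnorm - I} (the normalized-Laplacian eigenvalue bound 2 is
#' used instead of a per-graph eigensolve).
#'
#' @param x node feature matrix (S x f_in).
#' @param op a \code{\link{normalizedLaplacian}} result.
#' @param weights for K = 1 a single f_in x f_out matrix (or list of 1);
#'   for K = 2 a list of three f_in x f_out matrices (orders 0, 1, 2).
#' @param K Chebyshev order, 1 or 2.
#' @return S x f_out matrix.
#' @export
chebGraphConv <- function(x, op, weights, K = 1L) {
  x <- as.matrix(x)
  if (!K %in% c(1L, 2L)) stop("K must be 1 or 2")
  if (!is.list(weights)) weights <- list(weights)
  if (K == 1L) {
    if (length(weights) != 1L) stop("K = 1 expects a single weight matrix")
    return(op$P %*% x %*% weights[[1]])
  }
  if (length(weights) != 3L) stop("K = 2 expects three weight matrices")
  Ls <- op$Lnorm - diag(nrow(op$Lnorm))
  T1x <- Ls %*% x
  T2x <- 2 * (Ls %*% T1x) - x
  x %*% weights[[1]] + T1x %*% weights[[2]] + T2x %*% weights[[3]]
}

#' Training configuration for the multi-domain GCN
#'
#' Defaults follow the reference scheme 1-40-0.5: first-order Chebyshev
#' convolution, 40-point time features, dropout 0.5, learning rate 0.001
#' for 1000 epochs.
#'
#' @param learningRate Adam step size.
#' @param epochs training epochs (full-batch).
#' @param chebOrder Chebyshev order, 1 or 2.
#' @param dropout dropout rate after each GC layer.
#' @param seed seed for weight initialization and dropout masks.
#' @param classWeighting if TRUE, inverse-frequency class weights in the
#'   cross-entropy (default FALSE: unweighted).
#' @return validated list of class \code{TrainConfig}.
#' @export
trainConfig <- function(learningRate = 0.001, epochs = 1000L,
                        chebOrder = 1L, dropout = 0.5, seed = 1L,
                        classWeighting = FALSE) {
  if (!chebOrder %in% c(1L, 2L)) stop("chebOrder must be 1 or 2")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (learningRate <= 0) stop("learningRate must be positive")
  structure(list(learningRate = learningRate, epochs = as.integer(epochs),
                 chebOrder = as.integer(chebOrder), dropout = dropout,
                 seed = as.integer(seed), classWeighting = classWeighting),
            class = "TrainConfig")
}

# --- internal: stacked-batch machinery ------------------------------------

DOMAINS <- c("time", "frequency", "spatial")

# Stack a list of per-trial graph triples into per-domain big matrices:
# X ((N*S) x f), the horizontally concatenated per-trial propagation
# blocks (P for K=1, Ls = Lnorm - I for K=2), and the propagated
# layer-1 inputs Tm X, which are constant across epochs and so
# precomputed once.
stackGraphs <- function(graphs, K) {
  S <- nrow(nodeFeatures(graphs[[1]]$time))
  n <- length(graphs)
  out <- list(n = n, S = S)
  for (dom in DOMAINS) {
    Xs <- lapply(graphs, function(g) nodeFeatures(g[[dom]]))
    ops <- lapply(graphs, function(g) {
      op <- normalizedLaplacian(adjacency(g[[dom]]))
      if (K == 1L) op$P else op$Lnorm - diag(S)
    })
    X <- do.call(rbind, Xs)
    BX <- do.call(rbind, lapply(seq_len(n),
                                function(i) ops[[i]] %*% Xs[[i]]))
    PX <- if (K == 1L) {
      list(BX)
    } else {
      T2 <- do.call(rbind, lapply(seq_len(n), function(i)
        2 * (ops[[i]] %*% BX[((i - 1) * S + 1):(i * S), , drop = FALSE])))
      list(X, BX, T2 - X)
    }
    out[[dom]] <- list(X = X, Bcat = do.call(cbind, ops), PX = PX)
  }
  out
}

# y = blockdiag(B_1 ... B_n) %*% H with the blocks concatenated in Bcat.
blockMulR <- function(Bcat, H, S) {
  n <- ncol(Bcat) / S
  out <- H
  for (t in seq_len(n)) {
    rows <- ((t - 1) * S + 1):(t * S)
    out[rows, ] <- Bcat[, rows, drop = FALSE] %*% H[rows, , drop = FALSE]
  }
  out
}

glorotUniform <- function(fin, fout) {
  a <- sqrt(6 / (fin + fout))
  matrix(runif(fin * fout, -a, a), fin, fout)
}

initBranch <- function(fin, K) {
  norder <- if (K == 1L) 1L else 3L
  list(W1 = lapply(seq_len(norder), function(m) glorotUniform(fin, 32L)),
       W2 = lapply(seq_len(norder), function(m) glorotUniform(32L, 16L)))
}

initParams <- function(fins, K) {
  branches <- lapply(fins, initBranch, K = K)
  names(branches) <- DOMAINS
  list(branches = branches,
       bn = list(gamma = rep(1, 48), beta = rep(0, 48),
                 runMean = rep(0, 48), runVar = rep(1, 48)),
       dense = list(W = glorotUniform(48L, 2L), b = rep(0, 2)))
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Deterministic eval-mode forward pass over a stacked batch: dropout
# off, running batch-standardization statistics.
mgcnForwardEval <- function(params, stk, K) {
  n <- stk$n
  S <- stk$S
  pooled <- vector("list", length(DOMAINS))
  names(pooled) <- DOMAINS
  for (dom in DOMAINS) {
    br <- params$branches[[dom]]
    PX <- stk[[dom]]$PX
    Z1 <- PX[[1]] %*% br$W1[[1]]
    if (K == 2L) {
      Z1 <- Z1 + PX[[2]] %*% br$W1[[2]] + PX[[3]] %*% br$W1[[3]]
    }
    H1 <- pmax(Z1, 0)
    Bcat <- stk[[dom]]$Bcat
    Z2 <- if (K == 1L) {
      blockMulR(Bcat, H1, S) %*% br$W2[[1]]
    } else {
      T1 <- blockMulR(Bcat, H1, S)
      T2 <- 2 * blockMulR(Bcat, T1, S) - H1
      H1 %*% br$W2[[1]] + T1 %*% br$W2[[2]] + T2 %*% br$W2[[3]]
    }
    H2 <- pmax(Z2, 0)
    pooled[[dom]] <- rowsum(H2, rep(seq_len(n), each = S)) / S
  }
  u <- do.call(cbind, pooled)
  eps <- 1e-5
  xhat <- sweep(sweep(u, 2, params$bn$runMean),
                2, sqrt(params$bn$runVar + eps), `/`)
  y <- sweep(sweep(xhat, 2, params$bn$gamma, `*`), 2, params$bn$beta, `+`)
  logits <- sweep(y %*% params$dense$W, 2, params$dense$b, `+`)
  list(probs = softmaxRows(logits), pooled = u)
}

#' Train the multi-domain GCN
#'
#' Full-batch Adam on the softmax cross-entropy for \code{cfg$epochs}
#' epochs. Weight initialization and the per-epoch dropout masks are
#' drawn from one stream seeded by \code{cfg$seed}, so identical data +
#' config reproduce the loss trace exactly. The numerical core is
#' compiled (RcppArmadillo); graphs are stacked once into block-sparse
#' operators so an epoch costs a handful of large matrix products.
#'
#' @param graphs list of per-trial graph triples
#'   (\code{\link{buildMultidomainGraphs}} output).
#' @param labels character/factor per-trial labels, values
#'   \code{"strong"} or \code{"weak"}.
#' @param cfg a \code{\link{trainConfig}}.
#' @return a fitted \linkS4class{MGCNModel}.
#' @export
trainMgcn <- function(graphs, labels, cfg = trainConfig()) {
  labels <- as.character(labels)
  lev <- c("strong", "weak")
  if (!all(labels %in% lev)) stop("labels must be \'strong\' or \'weak\'")
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class")
  if (length(labels) != length(graphs))
    stop("one label per trial required")
  K <- cfg$chebOrder
  stk <- stackGraphs(graphs, K)
  n <- stk$n
  yIdx <- match(labels, lev)
  w <- rep(1, n)
  if (cfg$classWeighting) {
    tab <- table(factor(labels, lev))
    w <- n / (2 * as.numeric(tab[labels]))
  }
  fins <- vapply(DOMAINS, function(d) ncol(stk[[d]]$X), 0L)

  withSeed(cfg$seed, {
    params <- initParams(fins, K)
    fit <- .mgcnTrainCore(
      pxList = lapply(DOMAINS, function(d) stk[[d]]$PX),
      bList = lapply(DOMAINS, function(d) stk[[d]]$Bcat),
      y = yIdx, sampleWeight = w,
      w1Init = lapply(DOMAINS, function(d) params$branches[[d]]$W1),
      w2Init = lapply(DOMAINS, function(d) params$branches[[d]]$W2),
      gamma = params$bn$gamma, beta = params$bn$beta,
      denseW = params$dense$W, denseB = params$dense$b,
      epochs = cfg$epochs, lr = cfg$learningRate,
      dropout = cfg$dropout, K = K, S = stk$S)
    for (di in seq_along(DOMAINS)) {
      params$branches[[DOMAINS[di]]]$W1 <- fit$W1[[di]]
      params$branches[[DOMAINS[di]]]$W2 <- fit$W2[[di]]
    }
    params$bn$gamma <- as.numeric(fit$gamma)
    params$bn$beta <- as.numeric(fit$beta)
    params$bn$runMean <- as.numeric(fit$runMean)
    params$bn$runVar <- as.numeric(fit$runVar)
    params$dense$W <- fit$denseW
    params$dense$b <- as.numeric(fit$denseB)
    new("MGCNModel", params = params, config = unclass(cfg),
        lossTrace = as.numeric(fit$loss), classLevels = lev)
  })
}

#' Predict strong/weak labels for trials
#'
#' Deterministic eval-mode forward pass (dropout off, running
#' batch-standardization statistics).
#'
#' @param model a fitted \linkS4class{MGCNModel}.
#' @param graphs list of per-trial graph triples.
#' @return data.frame with columns \code{label}, \code{pStrong},
#'   \code{pWeak}, plus the trials' subject/action annotations.
#' @export
predictTrials <- function(model, graphs) {
  K <- model@config$chebOrder
  stk <- stackGraphs(graphs, K)
  fw <- mgcnForwardEval(model@params, stk, K)
  lab <- model@classLevels[max.col(fw$probs, ties.method = "first")]
  data.frame(
    label = lab,
    pStrong = fw$probs[, 1],
    pWeak = fw$probs[, 2],
    subject = vapply(graphs, function(g) g$time@annotation$subject, 0),
    action = vapply(graphs, function(g) g$time@annotation$action, 0))
}
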