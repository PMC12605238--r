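# Ground-truth strong/weak action labeling from MI data.
#
# Per action: CSP spatial filters (2 pairs) on 8-30 Hz filtered MI
# epochs, 4 log-variance features per trial, then a 4-100-50-10-2
# feed-forward network decoding left vs right hand under stratified
# ten-fold cross-validation. The action with the highest mean decoding
# accuracy is the subject's "strong" action.

#' Fit the MI common spatial pattern model
#'
#' Full CSP decomposition of the left/right class covariances; the top
#' and bottom \code{nPairs} filters (the most discriminative pair ends
#' of the eigenvalue spectrum) are retained, giving 4 features for the
#' default 2 pairs.
#'
#' @param leftTrials,rightTrials lists of channels x samples matrices
#'   (8-30 Hz filtered).
#' @param nPairs filter pairs to retain (default 2).
#' @param ... passed to \code{\link{fitCsp}}.
#' @return a \linkS4class{CSPModel} with \code{2 * nPairs} selected
#'   filters.
#' @export
fitMiCsp <- function(leftTrials, rightTrials, nPairs = 2L, ...) {
  model <- fitCsp(leftTrials, rightTrials, classes = c("left", "right"), ...)
  S <- nrow(model@filters)
  if (2L * nPairs > S) stop("nPairs too large for ", S, " channels")
  ev <- model@eigenvalues
  if (max(abs(ev - 0.5)) < 1e-6) {
    warning("classes indistinguishable: all whitened eigenvalues = 0.5")
  }
  model@selected <- as.integer(c(seq_len(nPairs), S - nPairs + seq_len(nPairs)))
  model
}

#' Extract MI CSP features for one trial
#'
#' Log of each selected CSP component's share of total projected
#' variance; a 4-vector for the default two filter pairs.
#'
#' @param trial channels x samples matrix.
#' @param model a \code{\link{fitMiCsp}} result.
#' @return numeric feature vector of length \code{length(selected)}.
#' @export
extractMiFeatures <- function(trial, model) {
  as.numeric(cspSpatialFeature(trial, model))
}

# --- feed-forward network ---------------------------------------------------

initDnn <- function(sizes) {
  L <- length(sizes) - 1L
  lapply(seq_len(L), function(l) {
    a <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    list(W = matrix(runif(sizes[l] * sizes[l + 1], -a, a),
                    sizes[l], sizes[l + 1]),
         b = rep(0, sizes[l + 1]))
  })
}

dnnForward <- function(layers, X) {
  acts <- list(X)
  L <- length(layers)
  H <- X
  for (l in seq_len(L)) {
    Z <- sweep(H %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    H <- if (l < L) 1 / (1 + exp(-Z)) else softmaxRows(Z)
    acts[[l + 1L]] <- H
  }
  list(probs = H, acts = acts)
}

# Full-batch Adam with decoupled L2 weight decay on a sigmoid MLP with
# softmax output.
trainDnn <- function(X, y, sizes = c(4L, 100L, 50L, 10L, 2L),
                     epochs = 200L, lr = 0.01, decay = 0.05, seed = 1L) {
  n <- nrow(X)
  onehot <- matrix(0, n, sizes[length(sizes)])
  onehot[cbind(seq_len(n), y)] <- 1
  withSeed(seed, {
    layers <- initDnn(sizes)
    L <- length(layers)
    adam <- lapply(layers, function(l)
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
    for (ep in seq_len(epochs)) {
      fw <- dnnForward(layers, X)
      delta <- (fw$probs - onehot) / n
      for (l in rev(seq_len(L))) {
        gW <- crossprod(fw$acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          a <- fw$acts[[l]]
          delta <- (delta %*% t(layers[[l]]$W)) * a * (1 - a)
        }
        st <- adam[[l]]
        st$mW <- 0.9 * st$mW + 0.1 * gW
        st$vW <- 0.999 * st$vW + 0.001 * gW^2
        st$mb <- 0.9 * st$mb + 0.1 * gb
        st$vb <- 0.999 * st$vb + 0.001 * gb^2
        corr1 <- 1 - 0.9^ep
        corr2 <- 1 - 0.999^ep
        layers[[l]]$W <- layers[[l]]$W * (1 - lr * decay) -
          lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + 1e-8)
        layers[[l]]$b <- layers[[l]]$b -
          lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + 1e-8)
        adam[[l]] <- st
      }
    }
    layers
  })
}

#' Stratified k-fold cross-validated DNN decoding accuracy
#'
#' Splits the trials into \code{folds} stratified folds (equal left and
#' right counts per fold; 72 training / 8 test trials for the default
#' 80-trial, ten-fold design), trains the 4-100-50-10-2 sigmoid network
#' per fold and returns the mean test accuracy in percent.
#'
#' @param features trials x 4 feature matrix.
#' @param labels character vector, \code{"left"} / \code{"right"}.
#' @param folds number of folds (default 10).
#' @param epochs,lr,decay DNN training parameters (supervised learning
#'   rate 0.01, L2 weight decay 0.05 by default).
#' @param seed seed controlling the fold partition and weight
#'   initialization.
#' @return list with \code{meanAcc} (percent) and per-fold accuracies
#'   \code{foldAcc}.
#' @export
trainEvalDnnCv <- function(features, labels, folds = 10L, epochs = 200L,
                           lr = 0.01, decay = 0.05, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  lev <- c("left", "right")
  if (!all(labels %in% lev)) stop("labels must be 'left' or 'right'")
  idxL <- which(labels == "left")
  idxR <- which(labels == "right")
  if (length(idxL) != length(idxR))
    stop("unbalanced input: ", length(idxL), " left vs ",
         length(idxR), " right trials")
  if (length(idxL) %% folds != 0L)
    stop("class size must be divisible by the number of folds")
  # standardize features on the whole set (scale only; CV is over the DNN)
  mu <- colMeans(features)
  sdv <- apply(features, 2, sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(features, 2, mu), 2, sdv, `/`)
  perFold <- length(idxL) %/% folds
  foldAcc <- numeric(folds)
  withSeed(mixSeed(seed, 7L), {
    permL <- sample(idxL)
    permR <- sample(idxR)
    for (f in seq_len(folds)) {
      sel <- ((f - 1L) * perFold + 1L):(f * perFold)
      testIdx <- c(permL[sel], permR[sel])
      trainIdx <- setdiff(seq_along(labels), testIdx)
      layers <- trainDnn(Xs[trainIdx, , drop = FALSE],
                         match(labels[trainIdx], lev),
                         epochs = epochs, lr = lr, decay = decay,
                         seed = mixSeed(seed, 100L + f))
      pred <- max.col(dnnForward(layers, Xs[testIdx, , drop = FALSE])$probs,
                      ties.method = "first")
      foldAcc[f] <- mean(lev[pred] == labels[testIdx])
    }
  })
  list(meanAcc = 100 * mean(foldAcc), foldAcc = 100 * foldAcc)
}

#' Assign strong/weak action labels from per-action accuracies
#'
#' The action with the highest mean MI decoding accuracy is strong; all
#' others are weak. Ties are broken toward the lowest action index with
#' a warning.
#'
#' @param accuracies numeric vector of per-action mean MI-ACC (percent).
#' @param subject subject identifier stored in the result.
#' @return an \linkS4class{ActionLabeling}.
#' @export
assignActionLabels <- function(accuracies, subject = 1L) {
  if (length(accuracies) < 2L) stop("need at least 2 actions")
  best <- max(accuracies)
  winners <- which(accuracies == best)
  tie <- length(winners) > 1L
  if (tie) {
    warning("tied maximum MI-ACC among actions ",
            paste(winners, collapse = ", "), "; taking the lowest index")
  }
  new("ActionLabeling", subject = as.integer(subject),
      accuracy = as.numeric(accuracies), strongAction = as.integer(winners[1]),
      tie = tie)
}

#' Label one subject's actions from their MI data
#'
#' Runs the full ground-truth pipeline: MI preprocessing (8-30 Hz,
#' 5th-order zero-phase band-pass), per-action CSP + feature extraction,
#' ten-fold cross-validated DNN decoding, and strong/weak assignment.
#'
#' @param subjectData a \code{\link{simulateSubject}}-style list with
#'   elements \code{subject} and \code{mi}, or an \linkS4class{EEGEpochs}
#'   of MI trials.
#' @param folds,epochs,lr,decay passed to \code{\link{trainEvalDnnCv}}.
#' @param seed evaluation seed.
#' @param preprocess set FALSE when the epochs are already filtered.
#' @return an \linkS4class{ActionLabeling}.
#' @export
labelSubject <- function(subjectData, folds = 10L, epochs = 200L,
                         lr = 0.01, decay = 0.05, seed = 1L,
                         preprocess = TRUE) {
  if (is(subjectData, "EEGEpochs")) {
    mi <- subjectData
    subject <- annotations(mi)$subject[1]
  } else {
    mi <- subjectData$mi
    subject <- subjectData$subject
  }
  if (preprocess) mi <- preprocessMi(mi, channels = channelNames(mi))
  ann <- annotations(mi)
  acts <- sort(unique(ann$action))
  acc <- numeric(length(acts))
  for (ai in seq_along(acts)) {
    a <- acts[ai]
    li <- which(ann$action == a & ann$hand == "left")
    ri <- which(ann$action == a & ann$hand == "right")
    csp <- fitMiCsp(lapply(li, function(i) trialMatrix(mi, i)),
                    lapply(ri, function(i) trialMatrix(mi, i)))
    idx <- c(li, ri)
    feats <- t(vapply(idx, function(i)
      extractMiFeatures(trialMatrix(mi, i), csp), numeric(4)))
    res <- trainEvalDnnCv(feats, ann$hand[idx], folds = folds,
                          epochs = epochs, lr = lr, decay = decay,
                          seed = mixSeed(seed, subject * 10L + a))
    acc[ai] <- res$meanAcc
  }
  names(acc) <- paste0("action", acts)
  assignActionLabels(acc, subject)
}

#' Per-trial strong/weak labels for a subject's cognitive trials
#'
#' @param cognitiveEpochs the subject's cognitive \linkS4class{EEGEpochs}.
#' @param labeling the subject's \linkS4class{ActionLabeling}.
#' @return character vector (\code{"strong"}/\code{"weak"}), one per trial.
#' @export
cognitiveTrialLabels <- function(cognitiveEpochs, labeling) {
  ifelse(annotations(cognitiveEpochs)$action == labeling@strongAction,
         "strong", "weak")
}
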