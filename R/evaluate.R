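# Subject-independent evaluation: LOSO cross-validation, majority
# voting over per-trial predictions, confusion-based metrics, Cohen's
# kappa and clustering-coefficient network contrasts.

#' Majority vote over per-trial strong predictions
#'
#' Counts the \code{"strong"} predictions per action; the action with
#' the most strong votes is chosen. Ties (including the all-weak
#' degenerate case) resolve to the lowest action index and set the tie
#' flag.
#'
#' @param predictions character vector of \code{"strong"}/\code{"weak"}
#'   per-trial predictions.
#' @param actions integer action index per trial.
#' @param nActions total number of actions (defaults to
#'   \code{max(actions)}).
#' @return list with \code{chosen}, \code{votes} (named integer) and
#'   \code{tie}.
#' @export
voteAction <- function(predictions, actions, nActions = max(actions)) {
  if (length(predictions) != length(actions)) stop("length mismatch")
  if (length(predictions) == 0L) stop("empty prediction set")
  votes <- vapply(seq_len(nActions), function(a)
    sum(predictions == "strong" & actions == a), 0L)
  names(votes) <- paste0("action", seq_len(nActions))
  best <- max(votes)
  winners <- which(votes == best)
  list(chosen = as.integer(winners[1]), votes = votes,
       tie = length(winners) > 1L)
}

#' Confusion counts and classification metrics
#'
#' \code{"strong"} is the positive class. Returns TP/FP/TN/FN together
#' with F1, sensitivity, specificity and accuracy (percent). Ratios
#' with zero denominator are returned as NaN and listed in the
#' \code{undefined} field rather than silently coerced to 0.
#'
#' @param predictions,truth equal-length character vectors with values
#'   \code{"strong"}/\code{"weak"}.
#' @return list with \code{counts} (named integer TP, FP, TN, FN),
#'   \code{metrics} (named numeric) and \code{undefined} (character).
#' @export
confusionAndMetrics <- function(predictions, truth) {
  if (length(predictions) != length(truth)) stop("length mismatch")
  ok <- c("strong", "weak")
  if (!all(predictions %in% ok) || !all(truth %in% ok))
    stop("labels must be 'strong' or 'weak'")
  counts <- c(TP = sum(predictions == "strong" & truth == "strong"),
              FP = sum(predictions == "strong" & truth == "weak"),
              TN = sum(predictions == "weak" & truth == "weak"),
              FN = sum(predictions == "weak" & truth == "strong"))
  metricsFromCounts(counts)
}

#' Metrics from confusion counts
#'
#' @param counts named integer vector with TP, FP, TN, FN.
#' @return list as in \code{\link{confusionAndMetrics}}.
#' @export
metricsFromCounts <- function(counts) {
  TP <- counts[["TP"]]; FP <- counts[["FP"]]
  TN <- counts[["TN"]]; FN <- counts[["FN"]]
  total <- TP + FP + TN + FN
  if (total == 0) stop("empty confusion table")
  ratio <- function(num, den) if (den == 0) NaN else num / den
  f1 <- if (TP + FP == 0 || TP + FN == 0) NaN else 2 * TP / (2 * TP + FP + FN)
  metrics <- c(F1 = f1,
               sensitivity = ratio(TP, TP + FN),
               specificity = ratio(TN, FP + TN),
               accuracy = 100 * (TP + TN) / total,
               kappa = kappaScore(counts))
  undefined <- names(metrics)[is.nan(metrics)]
  out <- as.integer(c(TP, FP, TN, FN))
  names(out) <- c("TP", "FP", "TN", "FN")
  list(counts = out, metrics = metrics, undefined = undefined)
}

#' Cohen's kappa from confusion counts
#'
#' \code{kappa = (p_o - p_e) / (1 - p_e)} with the chance agreement
#' \code{p_e} from the row/column marginal products. Degenerate tables
#' with \code{p_e = 1} return NaN.
#'
#' @param counts named integer vector with TP, FP, TN, FN.
#' @return kappa in [-1, 1], or NaN for degenerate tables.
#' @export
kappaScore <- function(counts) {
  TP <- counts[["TP"]]; FP <- counts[["FP"]]
  TN <- counts[["TN"]]; FN <- counts[["FN"]]
  total <- TP + FP + TN + FN
  if (total == 0) stop("empty confusion table")
  po <- (TP + TN) / total
  pe <- ((TP + FN) * (TP + FP) + (FP + TN) * (FN + TN)) / total^2
  if (1 - pe == 0) return(NaN)
  (po - pe) / (1 - pe)
}

#' Clustering coefficient of a (weighted) network
#'
#' The weighted adjacency is binarized by proportional thresholding:
#' the top \code{threshold} fraction of strictly positive off-diagonal
#' weights become edges (ties at the cutoff are kept, so an already
#' binary graph passes through unchanged). Each node's local
#' coefficient is the number of edges among its neighbors divided by
#' \code{k (k - 1) / 2}; nodes with degree < 2 contribute 0. The global
#' coefficient is the mean over nodes.
#'
#' @param A symmetric adjacency matrix.
#' @param threshold retained proportion of off-diagonal weights,
#'   in (0, 1); default 0.3.
#' @return list with \code{C} (global mean), \code{Ci} (per node) and
#'   \code{binary} (the thresholded adjacency).
#' @export
clusteringCoefficient <- function(A, threshold = 0.3) {
  A <- as.matrix(A)
  if (nrow(A) == 0L) stop("empty graph")
  stopIfNotSymmetric(A, tol = 1e-8)
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  off <- offDiagonal(A)
  cut <- as.numeric(quantile(off, 1 - threshold, type = 7))
  B <- (A >= cut & A > 0) * 1
  diag(B) <- 0
  B <- pmax(B, t(B))
  n <- nrow(B)
  Ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(B[i, ] > 0)
    k <- length(nb)
    if (k >= 2L) {
      Ci[i] <- sum(B[nb, nb]) / 2 / (k * (k - 1) / 2)
    }
  }
  list(C = mean(Ci), Ci = Ci, binary = B)
}

#' Strong-vs-weak mean networks and clustering-coefficient contrast
#'
#' Averages per-trial adjacencies by condition within each domain and
#' tests the difference in mean clustering coefficient (computed on
#' per-trial graphs) with a two-sided permutation test that shuffles
#' condition labels within subject.
#'
#' @param graphs list of per-trial graph triples with \code{label} and
#'   \code{subject} in their annotations (see
#'   \code{\link{buildMultidomainGraphs}}).
#' @param labels optional character vector overriding the stored labels.
#' @param nPermutations permutation count (default 1000).
#' @param threshold passed to \code{\link{clusteringCoefficient}}.
#' @param seed permutation seed.
#' @return per-domain list with mean adjacencies (\code{meanStrong},
#'   \code{meanWeak}), mean per-trial clustering coefficients
#'   (\code{Cstrong}, \code{Cweak}), the observed difference and the
#'   permutation \code{p}.
#' @export
compareStrongWeakNetworks <- function(graphs, labels = NULL,
                                      nPermutations = 1000L,
                                      threshold = 0.3, seed = 1L) {
  if (is.null(labels)) {
    labels <- vapply(graphs, function(g) g$time@annotation$label, "")
  }
  subjects <- vapply(graphs, function(g) g$time@annotation$subject, 0)
  if (length(unique(subjects)) < 2L) stop("need at least 2 subjects")
  if (!all(labels %in% c("strong", "weak"))) stop("bad labels")
  out <- list()
  for (dom in DOMAINS) {
    As <- lapply(graphs, function(g) adjacency(g[[dom]]))
    Ctrial <- vapply(As, function(A)
      clusteringCoefficient(A, threshold)$C, 0)
    isStrong <- labels == "strong"
    meanStrong <- Reduce(`+`, As[isStrong]) / sum(isStrong)
    meanWeak <- Reduce(`+`, As[!isStrong]) / sum(!isStrong)
    obs <- mean(Ctrial[isStrong]) - mean(Ctrial[!isStrong])
    perm <- withSeed(mixSeed(seed, match(dom, DOMAINS)), {
      vapply(seq_len(nPermutations), function(p) {
        lab <- labels
        for (s in unique(subjects)) {
          i <- which(subjects == s)
          lab[i] <- lab[i][sample(length(i))]
        }
        st <- lab == "strong"
        mean(Ctrial[st]) - mean(Ctrial[!st])
      }, 0)
    })
    pval <- (1 + sum(abs(perm) >= abs(obs))) / (1 + nPermutations)
    out[[dom]] <- list(meanStrong = meanStrong, meanWeak = meanWeak,
                       Cstrong = mean(Ctrial[isStrong]),
                       Cweak = mean(Ctrial[!isStrong]),
                       difference = obs, p = pval)
  }
  out
}

# Build the per-trial labeled graph set for a list of subjects, reusing
# one cognitive CSP model. Returns list(graphs, labels).
subjectGraphs <- function(prepped, labelings, csp, downsamplePoints = 40L) {
  graphs <- list()
  labels <- character(0)
  for (k in seq_along(prepped)) {
    lab <- cognitiveTrialLabels(prepped[[k]], labelings[[k]])
    g <- buildMultidomainGraphs(prepped[[k]], csp,
                                downsamplePoints = downsamplePoints,
                                labels = lab)
    graphs <- c(graphs, g)
    labels <- c(labels, lab)
  }
  list(graphs = graphs, labels = labels)
}

#' Leave-one-subject-out cross-validation of the full pipeline
#'
#' For each held-out subject: every training subject's cognitive trials
#' are labeled strong/weak from that subject's own MI data; the
#' cognitive CSP model and the multi-domain GCN are fitted on training
#' subjects only; the held-out subject's trials are predicted and
#' majority-voted into a personalized action. MI-derived labels of the
#' held-out subject are used solely for evaluation.
#'
#' @param cohort list of subject datasets (\code{\link{simulateCohort}}
#'   output or equivalents with \code{subject}, \code{cognitive},
#'   \code{mi} and optionally \code{trueStrongAction}).
#' @param cfg a \code{\link{trainConfig}} for the GCN.
#' @param labelings optional precomputed list of
#'   \linkS4class{ActionLabeling} (skips the MI pipeline).
#' @param trainSeeds optional integer vector of training seeds; when
#'   given, the expensive fold-invariant graph cache is reused and a
#'   named list of report lists (one per seed) is returned.
#' @param dnnEpochs epochs for the MI labeling DNN.
#' @param downsamplePoints time-feature points per channel.
#' @param seed labeling seed.
#' @param verbose print per-fold progress.
#' @return list of \linkS4class{PredictionReport}, one per subject.
#' @export
losoCv <- function(cohort, cfg = trainConfig(), labelings = NULL,
                   dnnEpochs = 200L, downsamplePoints = 40L, seed = 1L,
                   verbose = FALSE, trainSeeds = NULL) {
  multiSeed <- !is.null(trainSeeds)
  if (!multiSeed) trainSeeds <- cfg$seed
  nsub <- length(cohort)
  if (nsub < 2L) stop("LOSO requires at least 2 subjects")
  if (is.null(labelings)) {
    labelings <- lapply(cohort, labelSubject, epochs = dnnEpochs, seed = seed)
  }
  prepped <- lapply(cohort, function(s) preprocessCognitive(s$cognitive))

  # Per-subject cache of everything that does not depend on the fold:
  # trial matrices, time- and frequency-domain graphs, MI-derived trial
  # labels and per-class normalized-covariance sums for the CSP model.
  cache <- lapply(seq_len(nsub), function(k) {
    ep <- prepped[[k]]
    lab <- cognitiveTrialLabels(ep, labelings[[k]])
    ann <- annotations(ep)
    fs <- samplingRate(ep)
    trials <- lapply(seq_len(nTrials(ep)), function(i) trialMatrix(ep, i))
    tf <- lapply(seq_len(nTrials(ep)), function(i) {
      tr <- trials[[i]]
      meta <- list(subject = ann$subject[i], action = ann$action[i],
                   label = lab[i])
      xt <- downsampleAverage(tr, downsamplePoints)
      bands <- bandDecompose(tr, fs)
      list(time = DomainGraph(xt, pccAdjacency(xt), "time", meta),
           frequency = DomainGraph(welchPsd(bands), plvAdjacency(bands),
                                   "frequency", meta),
           meta = meta)
    })
    ncov <- lapply(trials, function(m) {
      m <- m - rowMeans(m)
      C <- tcrossprod(m)
      C / sum(diag(C))
    })
    strongIdx <- which(lab == "strong")
    list(trials = trials, tf = tf, lab = lab,
         covStrong = Reduce(`+`, ncov[strongIdx]),
         covWeak = Reduce(`+`, ncov[-strongIdx]),
         nStrong = length(strongIdx),
         nWeak = nTrials(ep) - length(strongIdx))
  })
  assemble <- function(k, csp) {
    lapply(seq_along(cache[[k]]$tf), function(i) {
      g <- cache[[k]]$tf[[i]]
      xs <- cspSpatialFeature(cache[[k]]$trials[[i]], csp)
      list(time = g$time, frequency = g$frequency,
           spatial = DomainGraph(xs, mdAdjacency(xs), "spatial", g$meta))
    })
  }

  reports <- lapply(trainSeeds, function(s) vector("list", nsub))
  names(reports) <- paste0("seed", trainSeeds)
  for (test in seq_len(nsub)) {
    trainIdx <- setdiff(seq_len(nsub), test)
    # cognitive CSP on training subjects only
    C1 <- Reduce(`+`, lapply(cache[trainIdx], `[[`, "covStrong")) /
      sum(vapply(cache[trainIdx], `[[`, 0L, "nStrong"))
    C2 <- Reduce(`+`, lapply(cache[trainIdx], `[[`, "covWeak")) /
      sum(vapply(cache[trainIdx], `[[`, 0L, "nWeak"))
    csp <- fitCspFromCov(C1, C2, channelNames = channelNames(prepped[[1]]))
    trainGraphs <- do.call(c, lapply(trainIdx, assemble, csp = csp))
    trainLabels <- do.call(c, lapply(cache[trainIdx], `[[`, "lab"))
    testGraphs <- assemble(test, csp)
    ann <- annotations(prepped[[test]])
    truthLab <- cache[[test]]$lab
    for (si in seq_along(trainSeeds)) {
      cfgS <- cfg
      cfgS$seed <- trainSeeds[si]
      model <- trainMgcn(trainGraphs, trainLabels, cfgS)
      pred <- predictTrials(model, testGraphs)
      vote <- voteAction(pred$label, ann$action)
      cm <- confusionAndMetrics(pred$label, truthLab)
      reports[[si]][[test]] <- new("PredictionReport",
        subject = as.integer(cohort[[test]]$subject),
        predictions = pred$label, votes = as.integer(vote$votes),
        chosenAction = vote$chosen, voteTie = vote$tie,
        strongActionMi = labelings[[test]]@strongAction,
        strongActionTrue = if (is.null(cohort[[test]]$trueStrongAction))
          NA_integer_ else as.integer(cohort[[test]]$trueStrongAction),
        confusion = cm$counts, metrics = cm$metrics)
      if (verbose) {
        message(sprintf("fold %d/%d seed %d: chose action %d (ACC %.1f%%)",
                        test, nsub, trainSeeds[si], vote$chosen,
                        cm$metrics[["accuracy"]]))
      }
    }
  }
  if (multiSeed) reports else reports[[1]]
}

#' Cohort-level summary of LOSO reports
#'
#' @param reports list of \linkS4class{PredictionReport}.
#' @return list with the pooled confusion counts, pooled metrics,
#'   per-subject metric table, and the fractions of subjects whose
#'   voted action matches the MI-derived and (when available) the
#'   simulated strong action.
#' @export
cohortSummary <- function(reports) {
  counts <- Reduce(`+`, lapply(reports, confusionCounts))
  names(counts) <- c("TP", "FP", "TN", "FN")
  pooled <- metricsFromCounts(counts)
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(subject = r@subject, chosen = r@chosenAction,
               strongMi = r@strongActionMi, strongTrue = r@strongActionTrue,
               voteTie = r@voteTie, t(r@metrics))
  }))
  matchMi <- mean(tab$chosen == tab$strongMi)
  matchTrue <- if (all(is.na(tab$strongTrue))) NA_real_ else
    mean(tab$chosen == tab$strongTrue, na.rm = TRUE)
  list(counts = counts, metrics = pooled$metrics,
       undefined = pooled$undefined, perSubject = tab,
       recoveryMi = matchMi, recoveryTrue = matchTrue)
}
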