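# Per-trial multi-domain brain networks from cognitive epochs.
#
# Three graphs per trial, all over the same 19 channels:
#   time:      block-averaged waveform features + |Pearson r| adjacency
#   frequency: band-limited Welch PSD features + phase-locking adjacency
#   spatial:   CSP log-variance features + normalized-Manhattan adjacency

#' Block-average time-domain features
#'
#' Reduces each channel to \code{npoints} values, the k-th being the mean
#' of the k-th consecutive block of \code{samples/npoints} raw samples.
#' With the default factor of 40 a 19 x 1000 trial becomes a 19 x 40
#' feature matrix.
#'
#' @param trial channels x samples numeric matrix.
#' @param npoints number of retained points per channel (default 40).
#' @return channels x npoints matrix.
#' @export
downsampleAverage <- function(trial, npoints = 40L) {
  trial <- as.matrix(trial)
  ns <- ncol(trial)
  if (ns %% npoints != 0L) {
    stop("sample count ", ns, " not divisible into ", npoints, " blocks")
  }
  block <- ns %/% npoints
  G <- matrix(0, ns, npoints)
  G[cbind(seq_len(ns), rep(seq_len(npoints), each = block))] <- 1 / block
  out <- trial %*% G
  rownames(out) <- rownames(trial)
  out
}

#' Absolute-Pearson-correlation adjacency
#'
#' Edge weight between channels h1 and h2 is the absolute Pearson
#' correlation of their feature rows; the diagonal is 1.
#'
#' @param x channels x features matrix.
#' @return symmetric channels x channels matrix with entries in [0, 1].
#' @export
pccAdjacency <- function(x) {
  x <- as.matrix(x)
  v <- apply(x, 1L, var)
  if (any(v <= 0)) {
    stop("zero-variance channel row(s): ",
         paste(which(v <= 0), collapse = ", "))
  }
  A <- abs(cor(t(x)))
  diag(A) <- 1
  A <- (A + t(A)) / 2
  dimnames(A) <- list(rownames(x), rownames(x))
  A
}

#' Decompose a trial into four canonical frequency bands
#'
#' Zero-phase band-pass reconstruction at 1-4, 4-8, 8-13 and 13-20 Hz
#' (delta/theta/alpha/beta ranges used throughout the pipeline).
#'
#' @param trial channels x samples matrix.
#' @param fs sampling rate, Hz (>= 40).
#' @param order Butterworth order per band (default 4).
#' @return list of class \code{BandSignals}: four channels x samples
#'   matrices named \code{"1-4"}, \code{"4-8"}, \code{"8-13"},
#'   \code{"13-20"}, with band edges in \code{attr(, "bands")}.
#' @export
bandDecompose <- function(trial, fs, order = 4L) {
  if (fs < 40) stop("fs must be at least 40 Hz (band edges up to 20 Hz)")
  bands <- list(`1-4` = c(1, 4), `4-8` = c(4, 8),
                `8-13` = c(8, 13), `13-20` = c(13, 20))
  out <- lapply(bands, function(b)
    zeroPhaseBandpass(trial, fs, b[1], b[2], order))
  attr(out, "bands") <- bands
  attr(out, "fs") <- fs
  class(out) <- "BandSignals"
  out
}

#' Welch power-spectral-density band features
#'
#' For every channel and band, the mean Welch PSD (Hann window,
#' \code{min(256, samples)}-sample segments, 50\% overlap) over that
#' band's frequency range. Yields the 19 x 4 frequency-domain node
#' feature matrix.
#'
#' @param bands a \code{\link{bandDecompose}} result.
#' @param nperseg Welch segment length (samples).
#' @return channels x 4 nonnegative matrix.
#' @export
welchPsd <- function(bands, nperseg = 256L) {
  edges <- attr(bands, "bands")
  fs <- attr(bands, "fs")
  nch <- nrow(bands[[1]])
  out <- matrix(0, nch, length(bands),
                dimnames = list(rownames(bands[[1]]), names(bands)))
  for (b in seq_along(bands)) {
    lohi <- edges[[b]]
    for (h in seq_len(nch)) {
      w <- welchVector(bands[[b]][h, ], fs, nperseg)
      sel <- w$freq >= lohi[1] & w$freq <= lohi[2]
      if (!any(sel)) sel <- which.min(abs(w$freq - mean(lohi)))
      out[h, b] <- mean(w$psd[sel])
    }
  }
  out
}

#' Phase-locking-value adjacency
#'
#' Instantaneous phases come from the analytic (Hilbert) signal of each
#' band-limited channel; PLV(h1, h2) is the modulus of the time-averaged
#' unit phasor of the phase difference. The returned adjacency is the
#' mean PLV over the four bands (aggregation selectable), with unit
#' diagonal.
#'
#' @param bands a \code{\link{bandDecompose}} result.
#' @param aggregate \code{"mean"} (default) or \code{"max"} over bands,
#'   or a band name for a single-band adjacency.
#' @return symmetric channels x channels matrix with entries in [0, 1].
#' @export
plvAdjacency <- function(bands, aggregate = "mean") {
  perBand <- lapply(bands, function(sig) {
    sig <- as.matrix(sig)
    if (any(apply(sig, 1L, function(v) max(v) - min(v)) == 0)) {
      stop("constant channel signal: instantaneous phase undefined")
    }
    z <- analyticSignal(sig)
    plvFromPhases(Arg(z))
  })
  A <- if (aggregate == "mean") {
    Reduce(`+`, perBand) / length(perBand)
  } else if (aggregate == "max") {
    Reduce(pmax, perBand)
  } else if (aggregate %in% names(bands)) {
    perBand[[aggregate]]
  } else {
    stop("unknown PLV aggregation: ", aggregate)
  }
  diag(A) <- 1
  A
}

#' Phase-locking value from instantaneous phase sequences
#'
#' PLV(h1, h2) is the modulus of the time-averaged unit phasor of the
#' phase difference between the two channels: 1 for a constant phase
#' offset, near \code{sqrt(pi / (4 T))} in expectation for independent
#' uniform phases.
#'
#' @param phases channels x samples matrix of instantaneous phases
#'   (radians).
#' @return symmetric channels x channels PLV matrix, unit diagonal.
#' @export
plvFromPhases <- function(phases) {
  phases <- as.matrix(phases)
  if (ncol(phases) < 2L) stop("need at least 2 samples")
  ph <- exp(1i * phases)
  plv <- Mod(ph %*% Conj(t(ph))) / ncol(phases)
  plv <- pmin(plv, 1)
  diag(plv) <- 1
  (plv + t(plv)) / 2
}

# Trace-normalized spatial covariance averaged over trials.
meanNormalizedCovariance <- function(trials) {
  covs <- lapply(trials, function(m) {
    m <- as.matrix(m)
    m <- m - rowMeans(m)
    C <- tcrossprod(m)
    C / sum(diag(C))
  })
  Reduce(`+`, covs) / length(covs)
}

#' Fit common spatial patterns
#'
#' Joint diagonalization of the two class-average normalized spatial
#' covariances: whitening by the composite covariance followed by an
#' eigendecomposition of the whitened first-class covariance. Filter
#' rows are ordered by descending eigenvalue, so the first rows maximize
#' class-1 variance and the last rows class-2 variance; for every filter
#' the two whitened class variances sum to 1.
#'
#' @param class1Trials,class2Trials lists of channels x samples matrices.
#' @param channelNames channel labels (defaults to rownames of the first
#'   trial).
#' @param classes length-2 character naming the classes.
#' @param ridge regularization added to the composite covariance when it
#'   is near-singular (a message is emitted).
#' @return a \linkS4class{CSPModel} with all \code{S} filters selected.
#' @export
fitCsp <- function(class1Trials, class2Trials, channelNames = NULL,
                   classes = c("strong", "weak"), ridge = 1e-8) {
  if (length(class1Trials) < 2L || length(class2Trials) < 2L)
    stop("need at least 2 trials per class")
  if (is.null(channelNames)) {
    channelNames <- rownames(class1Trials[[1]])
  }
  fitCspFromCov(meanNormalizedCovariance(class1Trials),
                meanNormalizedCovariance(class2Trials),
                channelNames = channelNames, classes = classes,
                ridge = ridge)
}

# CSP from class-average normalized covariances (shared core).
fitCspFromCov <- function(C1, C2, channelNames = NULL,
                          classes = c("strong", "weak"), ridge = 1e-8) {
  Cc <- C1 + C2
  ev <- eigen(Cc, symmetric = TRUE)
  if (min(ev$values) < ridge * max(ev$values)) {
    message("rank-deficient composite covariance: applying ridge ", ridge)
    Cc <- Cc + ridge * max(ev$values) * diag(nrow(Cc))
    ev <- eigen(Cc, symmetric = TRUE)
  }
  whiten <- diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  S1 <- whiten %*% C1 %*% t(whiten)
  S1 <- (S1 + t(S1)) / 2
  eb <- eigen(S1, symmetric = TRUE)
  W <- t(eb$vectors) %*% whiten
  if (is.null(channelNames)) channelNames <- as.character(seq_len(nrow(W)))
  new("CSPModel", filters = W, eigenvalues = eb$values,
      channelNames = channelNames, classes = classes,
      selected = seq_len(nrow(W)))
}

#' CSP spatial node features for one trial
#'
#' Projects the trial through the selected CSP filters and returns the
#' log of each component's share of total projected variance: a column
#' vector, one value per filter (19 x 1 for the full cognitive model).
#'
#' @param trial channels x samples matrix.
#' @param model a fitted \linkS4class{CSPModel} over the same channels.
#' @return \code{length(selected)} x 1 matrix.
#' @export
cspSpatialFeature <- function(trial, model) {
  trial <- as.matrix(trial)
  if (nrow(trial) != ncol(model@filters)) {
    stop("trial has ", nrow(trial), " channels but model expects ",
         ncol(model@filters))
  }
  proj <- model@filters[model@selected, , drop = FALSE] %*% trial
  v <- apply(proj, 1L, var)
  if (sum(v) <= 0) stop("degenerate trial: zero projected variance")
  matrix(log(v / sum(v)), ncol = 1L)
}

#' Normalized-Manhattan-distance adjacency of spatial features
#'
#' Raw edge distance is |s_h1 - s_h2|; off-diagonal distances are min-max
#' normalized into [0, 1] and converted to similarities (1 - normalized
#' distance), so a larger weight means a stronger connection, consistent
#' with the other domains. Diagonal is 1.
#'
#' @param s numeric vector or one-column matrix of per-channel features.
#' @return symmetric matrix with entries in [0, 1].
#' @export
mdAdjacency <- function(s) {
  s <- as.numeric(s)
  L <- abs(outer(s, s, `-`))
  off <- offDiagonal(L)
  rng <- max(off) - min(off)
  if (rng == 0) {
    warning("all spatial features identical: uniform adjacency of 1")
    A <- matrix(1, length(s), length(s))
    return(A)
  }
  A <- 1 - (L - min(off)) / rng
  diag(A) <- 1
  pmin(pmax(A, 0), 1)
}

#' Build per-trial time/frequency/spatial brain networks
#'
#' For every trial of preprocessed cognitive epochs, constructs the
#' three \linkS4class{DomainGraph}s: time (block-averaged features +
#' |PCC|), frequency (band PSD + PLV) and spatial (CSP log-variance +
#' normalized Manhattan similarity). Trial annotations are propagated.
#'
#' @param epochs preprocessed cognitive \linkS4class{EEGEpochs}.
#' @param csp a \linkS4class{CSPModel} fitted on training-subject trials
#'   only (never on the evaluation subject).
#' @param downsamplePoints retained time points per channel (default 40).
#' @param plvAggregate band aggregation for \code{\link{plvAdjacency}}.
#' @param labels optional per-trial labels stored in the annotations.
#' @return list with one element per trial, each a list of
#'   \code{time}, \code{frequency}, \code{spatial} graphs.
#' @export
buildMultidomainGraphs <- function(epochs, csp, downsamplePoints = 40L,
                                   plvAggregate = "mean", labels = NULL) {
  ann <- annotations(epochs)
  fs <- samplingRate(epochs)
  lapply(seq_len(nTrials(epochs)), function(i) {
    tr <- trialMatrix(epochs, i)
    meta <- list(subject = ann$subject[i], action = ann$action[i],
                 label = if (is.null(labels)) NA_character_ else labels[i])
    xt <- downsampleAverage(tr, downsamplePoints)
    bands <- bandDecompose(tr, fs)
    xf <- welchPsd(bands)
    xs <- cspSpatialFeature(tr, csp)
    list(time = DomainGraph(xt, pccAdjacency(xt), "time", meta),
         frequency = DomainGraph(xf, plvAdjacency(bands, plvAggregate),
                                 "frequency", meta),
         spatial = DomainGraph(xs, mdAdjacency(xs), "spatial", meta))
  })
}

#' Export a trial's domain graphs as CSV
#'
#' Writes one adjacency and one feature file per domain, named
#' \code{subject<j>_action<a>_trial<t>_<domain>_{adjacency,features}.csv}.
#'
#' @param graphs output of \code{\link{buildMultidomainGraphs}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
exportGraphsCsv <- function(graphs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(graphs)) {
    for (dom in names(graphs[[i]])) {
      g <- graphs[[i]][[dom]]
      stem <- sprintf("subject%s_action%s_trial%03d_%s",
                      g@annotation$subject, g@annotation$action, i, dom)
      pA <- file.path(dir, paste0(stem, "_adjacency.csv"))
      pX <- file.path(dir, paste0(stem, "_features.csv"))
      write.csv(adjacency(g), pA, row.names = FALSE)
      write.csv(nodeFeatures(g), pX, row.names = FALSE)
      paths <- c(paths, pA, pX)
    }
  }
  invisible(paths)
}
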