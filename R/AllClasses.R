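#' @import methods
#' @importFrom stats cor fft mvfft rnorm runif var quantile sd rbinom
#'   binom.test
#' @importFrom utils write.csv read.csv head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib mdgcn, .registration = TRUE
NULL

#' Epoched multi-channel EEG
#'
#' Container for trial-segmented EEG: a \code{trials x channels x samples}
#' numeric array plus sampling rate, ordered channel names and per-trial
#' annotations (task, action index, cued hand, subject id).
#'
#' @slot data numeric array, \code{trials x channels x samples}, microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelNames character vector, one 10-20 label per channel axis
#'   entry.
#' @slot annotations \code{data.frame} with one row per trial and columns
#'   \code{task} (\code{"cognitive"} or \code{"mi"}), \code{action}
#'   (integer index), \code{hand} (\code{"left"}, \code{"right"} or
#'   \code{"none"}) and \code{subject}.
#' @exportClass EEGEpochs
setClass("EEGEpochs",
  representation(data = "array", fs = "numeric",
                 channelNames = "character", annotations = "data.frame"))

setValidity("EEGEpochs", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a trials x channels x samples array")
  if (length(object@channelNames) != d[2])
    return("channelNames length must equal the channel axis")
  if (anyDuplicated(object@channelNames))
    return("duplicated channel names")
  if (nrow(object@annotations) != d[1])
    return("annotations must have one row per trial")
  need <- c("task", "action", "hand", "subject")
  if (!all(need %in% names(object@annotations)))
    return(paste("annotations must contain columns:",
                 paste(need, collapse = ", ")))
  if (length(object@fs) != 1L || object@fs <= 0) return("fs must be > 0")
  TRUE
})

#' Construct an EEGEpochs object
#'
#' @param data \code{trials x channels x samples} numeric array.
#' @param fs sampling rate (Hz).
#' @param channelNames ordered channel labels.
#' @param annotations per-trial annotation \code{data.frame}; missing
#'   columns are filled with defaults.
#' @return An \linkS4class{EEGEpochs} object.
#' @export
EEGEpochs <- function(data, fs, channelNames, annotations = NULL) {
  ntrial <- dim(data)[1]
  if (is.null(annotations)) annotations <- data.frame(row.names = seq_len(ntrial))
  if (is.null(annotations$task)) annotations$task <- "cognitive"
  if (is.null(annotations$action)) annotations$action <- 1L
  if (is.null(annotations$hand)) annotations$hand <- "none"
  if (is.null(annotations$subject)) annotations$subject <- 1L
  new("EEGEpochs", data = data, fs = as.numeric(fs),
      channelNames = as.character(channelNames), annotations = annotations)
}

#' @describeIn EEGEpochs number of trials
#' @param x,object an \code{EEGEpochs} object.
#' @export
nTrials <- function(x) dim(x@data)[1]

#' @describeIn EEGEpochs number of channels
#' @export
nChannels <- function(x) dim(x@data)[2]

#' @describeIn EEGEpochs samples per trial
#' @export
nSamples <- function(x) dim(x@data)[3]

#' @describeIn EEGEpochs sampling rate in Hz
#' @export
samplingRate <- function(x) x@fs

#' @describeIn EEGEpochs ordered channel labels
#' @export
channelNames <- function(x) x@channelNames

#' @describeIn EEGEpochs per-trial annotation data.frame
#' @export
annotations <- function(x) x@annotations

#' @describeIn EEGEpochs the raw data array
#' @export
epochsData <- function(x) x@data

#' Extract one trial as a channels x samples matrix
#' @param x an \linkS4class{EEGEpochs} object.
#' @param i trial index.
#' @return numeric matrix with channel names as rownames.
#' @export
trialMatrix <- function(x, i) {
  m <- x@data[i, , , drop = FALSE]
  dim(m) <- dim(x@data)[2:3]
  rownames(m) <- x@channelNames
  m
}

setMethod("show", "EEGEpochs", function(object) {
  d <- dim(object@data)
  cat(sprintf("EEGEpochs: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@fs))
  cat("  channels:", paste(head(object@channelNames, 8), collapse = " "),
      if (d[2] > 8) "..." else "", "\n")
  tk <- table(object@annotations$task)
  cat("  tasks:", paste(names(tk), tk, sep = "=", collapse = " "), "\n")
})

#' Single-domain brain network for one trial
#'
#' A graph over EEG channels: node feature matrix \code{x} (S x f) and
#' weighted adjacency \code{A} (S x S, symmetric, entries in [0, 1]).
#'
#' @slot x node feature matrix (channels x features).
#' @slot A weighted adjacency matrix.
#' @slot domain \code{"time"}, \code{"frequency"} or \code{"spatial"}.
#' @slot annotation list with per-trial metadata (subject, action, label).
#' @exportClass DomainGraph
setClass("DomainGraph",
  representation(x = "matrix", A = "matrix", domain = "character",
                 annotation = "list"))

setValidity("DomainGraph", function(object) {
  S <- nrow(object@x)
  if (!identical(dim(object@A), c(S, S)))
    return("A must be S x S with S = nrow(x)")
  if (!object@domain %in% c("time", "frequency", "spatial"))
    return("domain must be time, frequency or spatial")
  if (any(!is.finite(object@A))) return("A has non-finite entries")
  if (max(abs(object@A - t(object@A))) > 1e-10) return("A not symmetric")
  if (min(object@A) < -1e-12 || max(object@A) > 1 + 1e-12)
    return("A entries must lie in [0, 1]")
  TRUE
})

#' Construct a DomainGraph
#'
#' @param x node feature matrix (channels x features).
#' @param A symmetric weighted adjacency, entries in [0, 1].
#' @param domain \code{"time"}, \code{"frequency"} or \code{"spatial"}.
#' @param annotation per-trial metadata list.
#' @return A \linkS4class{DomainGraph}.
#' @export
DomainGraph <- function(x, A, domain, annotation = list()) {
  new("DomainGraph", x = as.matrix(x), A = as.matrix(A), domain = domain,
      annotation = annotation)
}

#' @describeIn DomainGraph node feature matrix
#' @param g a \code{DomainGraph}.
#' @export
nodeFeatures <- function(g) g@x

#' @describeIn DomainGraph weighted adjacency matrix
#' @export
adjacency <- function(g) g@A

#' @describeIn DomainGraph domain tag
#' @export
graphDomain <- function(g) g@domain

setMethod("show", "DomainGraph", function(object) {
  cat(sprintf("DomainGraph [%s]: %d nodes, %d features/node\n",
              object@domain, nrow(object@x), ncol(object@x)))
})

#' Common spatial pattern model
#'
#' Spatial filters from the generalized eigendecomposition of two class
#' covariance matrices. Rows of \code{filters} are ordered by descending
#' eigenvalue (share of first-class variance in whitened space), so the
#' top rows maximize first-class variance and the bottom rows the
#' second class's.
#'
#' @slot filters filter matrix (rows = spatial filters).
#' @slot eigenvalues whitened first-class variance per filter, descending.
#' @slot channelNames channel set the model was fitted on.
#' @slot classes length-2 character, fitted class names in order.
#' @slot selected indices of filters retained for feature extraction.
#' @exportClass CSPModel
setClass("CSPModel",
  representation(filters = "matrix", eigenvalues = "numeric",
                 channelNames = "character", classes = "character",
                 selected = "integer"))

setValidity("CSPModel", function(object) {
  if (length(object@eigenvalues) != nrow(object@filters))
    return("one eigenvalue per filter row required")
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    return("eigenvalues must be in descending order")
  if (length(object@classes) != 2L) return("exactly two classes")
  TRUE
})

setMethod("show", "CSPModel", function(object) {
  cat(sprintf("CSPModel (%s vs %s): %d filters over %d channels, %d selected\n",
              object@classes[1], object@classes[2], nrow(object@filters),
              length(object@channelNames), length(object@selected)))
  cat("  eigenvalues:", paste(sprintf("%.3f", head(object@eigenvalues, 6)),
                              collapse = " "), "\n")
})

#' @describeIn CSPModel the spatial filter matrix (rows = filters)
#' @param m a \code{CSPModel}.
#' @export
cspFilters <- function(m) m@filters

#' @describeIn CSPModel whitened-space eigenvalues, descending
#' @export
cspEigenvalues <- function(m) m@eigenvalues

#' Trained multi-domain GCN
#'
#' Holds the three graph-convolution branch weights, the output block
#' (batch-standardization statistics + dense layer), the training
#' configuration and the per-epoch loss trace.
#'
#' @slot params list of branch and output-block parameters.
#' @slot config the \code{trainConfig} list used for training.
#' @slot lossTrace numeric vector, one cross-entropy value per epoch.
#' @slot classLevels label levels, \code{c("strong", "weak")}.
#' @exportClass MGCNModel
setClass("MGCNModel",
  representation(params = "list", config = "list", lossTrace = "numeric",
                 classLevels = "character"))

setMethod("show", "MGCNModel", function(object) {
  cat(sprintf(
    "MGCNModel: 3 branches (f_in = %s) -> 32 -> 16, concat 48 -> dense 2\n",
    paste(vapply(object@params$branches, function(b) nrow(b$W1[[1]]), 0),
          collapse = "/")))
  cat(sprintf("  trained %d epochs, final loss %.4f, K = %d\n",
              length(object@lossTrace),
              if (length(object@lossTrace)) tail(object@lossTrace, 1) else NA,
              object@config$chebOrder))
})

#' Per-subject strong/weak action labeling
#'
#' Result of the MI ground-truth pipeline: mean left-vs-right MI decoding
#' accuracy per action and the derived strong action (argmax accuracy).
#'
#' @slot subject subject identifier.
#' @slot accuracy named numeric, mean MI decoding accuracy (\%) per action.
#' @slot strongAction integer index of the strong action.
#' @slot tie TRUE when the maximum accuracy was tied (lowest index taken).
#' @exportClass ActionLabeling
setClass("ActionLabeling",
  representation(subject = "integer", accuracy = "numeric",
                 strongAction = "integer", tie = "logical"))

setValidity("ActionLabeling", function(object) {
  if (length(object@accuracy) < 2L) return("need at least two actions")
  if (object@strongAction < 1L ||
      object@strongAction > length(object@accuracy))
    return("strongAction out of range")
  TRUE
})

setMethod("show", "ActionLabeling", function(object) {
  cat(sprintf("ActionLabeling subject %d: strong action %d%s\n",
              object@subject, object@strongAction,
              if (object@tie) " (tie, lowest index)" else ""))
  cat("  MI-ACC (%):", paste(sprintf("%.1f", object@accuracy),
                             collapse = " "), "\n")
})

#' @describeIn ActionLabeling index of the strong action
#' @param x an \code{ActionLabeling}.
#' @export
strongAction <- function(x) x@strongAction

#' @describeIn ActionLabeling per-action mean MI accuracy (percent)
#' @export
actionAccuracy <- function(x) x@accuracy

#' Per-subject LOSO prediction report
#'
#' @slot subject held-out subject id.
#' @slot predictions character vector of per-trial predictions
#'   (\code{"strong"}/\code{"weak"}).
#' @slot votes integer strong-vote count per action.
#' @slot chosenAction action selected by majority voting.
#' @slot voteTie TRUE if the vote was tied (lowest index taken).
#' @slot strongActionMi strong action per the subject's own MI labeling.
#' @slot strongActionTrue simulated ground-truth strong action (NA for
#'   real data).
#' @slot confusion named integer vector TP/FP/TN/FN against MI-derived
#'   trial labels.
#' @slot metrics named numeric: F1, sensitivity, specificity, accuracy
#'   (\%), kappa. Undefined ratios are NaN.
#' @exportClass PredictionReport
setClass("PredictionReport",
  representation(subject = "integer", predictions = "character",
                 votes = "integer", chosenAction = "integer",
                 voteTie = "logical", strongActionMi = "integer",
                 strongActionTrue = "integer", confusion = "integer",
                 metrics = "numeric"))

setMethod("show", "PredictionReport", function(object) {
  cat(sprintf(
    "PredictionReport subject %d: chosen action %d (MI truth %d%s)\n",
    object@subject, object@chosenAction, object@strongActionMi,
    if (!is.na(object@strongActionTrue))
      sprintf(", simulated truth %d", object@strongActionTrue) else ""))
  cat("  votes:", paste(object@votes, collapse = "/"),
      " ACC:", sprintf("%.1f%%", object@metrics[["accuracy"]]),
      " kappa:", sprintf("%.3f", object@metrics[["kappa"]]), "\n")
})

#' @describeIn PredictionReport action chosen by voting
#' @param x a \code{PredictionReport}.
#' @export
chosenAction <- function(x) x@chosenAction

#' @describeIn PredictionReport confusion counts (TP, FP, TN, FN)
#' @export
confusionCounts <- function(x) x@confusion

#' @describeIn PredictionReport evaluation metrics vector
#' @export
reportMetrics <- function(x) x@metrics
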