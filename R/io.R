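# File I/O: EDF import/export, pipeline configuration and provenance.

edfPad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  sprintf("%-*s", width, x)
}

#' Write a continuous recording (or epochs) to EDF
#'
#' Plain EDF: 16-bit samples with per-channel physical scaling. Epoched
#' data are concatenated trial by trial in order. Data are split into
#' 1-second records when the sample count divides evenly by \code{fs},
#' otherwise a single record holds the whole recording.
#'
#' @param x channels x samples numeric matrix, or an
#'   \linkS4class{EEGEpochs} (trials concatenated).
#' @param path output file.
#' @param fs sampling rate (taken from the object for epochs).
#' @param channelNames channel labels (rownames / object labels by
#'   default).
#' @return invisibly, \code{path}.
#' @export
writeEdf <- function(x, path, fs = NULL, channelNames = NULL) {
  if (is(x, "EEGEpochs")) {
    fs <- samplingRate(x)
    channelNames <- mdgcn::channelNames(x)
    d <- epochsData(x)
    x <- matrix(aperm(d, c(2, 3, 1)), nrow = dim(d)[2])
  }
  x <- as.matrix(x)
  if (is.null(channelNames)) channelNames <- rownames(x)
  if (is.null(channelNames)) channelNames <- paste0("CH", seq_len(nrow(x)))
  nch <- nrow(x)
  n <- ncol(x)
  if (n %% fs == 0) {
    spr <- as.integer(fs)
    nrec <- n %/% fs
    recDur <- 1
  } else {
    spr <- n
    nrec <- 1L
    recDur <- n / fs
  }
  physMin <- apply(x, 1, min)
  physMax <- apply(x, 1, max)
  physMax[physMax <= physMin] <- physMin[physMax <= physMin] + 1
  digMin <- -32768
  digMax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edfPad("0", 8), edfPad("X X X X", 80), edfPad("Startdate X X X X", 80),
    edfPad("01.01.26", 8), edfPad("00.00.00", 8),
    edfPad(256 * (1 + nch), 8), edfPad("", 44),
    edfPad(nrec, 8), edfPad(format(recDur, digits = 10), 8), edfPad(nch, 4),
    paste(vapply(channelNames, edfPad, "", width = 16), collapse = ""),
    paste(rep(edfPad("", 80), nch), collapse = ""),
    paste(rep(edfPad("uV", 8), nch), collapse = ""),
    paste(vapply(physMin, function(v) edfPad(format(v, digits = 7), 8), ""),
          collapse = ""),
    paste(vapply(physMax, function(v) edfPad(format(v, digits = 7), 8), ""),
          collapse = ""),
    paste(rep(edfPad(digMin, 8), nch), collapse = ""),
    paste(rep(edfPad(digMax, 8), nch), collapse = ""),
    paste(rep(edfPad("", 80), nch), collapse = ""),
    paste(rep(edfPad(spr, 8), nch), collapse = ""),
    paste(rep(edfPad("", 32), nch), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  gain <- (digMax - digMin) / (physMax - physMin)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (h in seq_len(nch)) {
      dig <- round((x[h, cols] - physMin[h]) * gain[h] + digMin)
      writeBin(as.integer(pmin(pmax(dig, digMin), digMax)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Minimal EDF reader: all signals must share one sampling rate.
#' Channel labels are uppercased to match the 10-20 montage labels used
#' in configuration.
#'
#' @param path EDF file.
#' @param requireChannels channel labels that must be present (error
#'   names any that are missing).
#' @param expectFs if given, error on a sampling-rate mismatch (no
#'   silent resampling).
#' @return list with \code{data} (channels x samples), \code{fs} and
#'   \code{channelNames}.
#' @export
readEdf <- function(path, requireChannels = NULL, expectFs = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("malformed EDF header (version '", version, "')")
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (is.na(nrec) || is.na(nch) || nch < 1) stop("malformed EDF header")
  labs <- toupper(vapply(seq_len(nch), function(i) rd(16), ""))
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)
  physMin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(80)
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("signals with differing sampling rates are not supported")
  fs <- spr[1] / recDur
  x <- matrix(0, nch, nrec * spr[1])
  for (r in seq_len(nrec)) {
    for (h in seq_len(nch)) {
      dig <- readBin(con, "integer", n = spr[h], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- physMin[h] + (dig - digMin[h]) *
        (physMax[h] - physMin[h]) / (digMax[h] - digMin[h])
      x[h, ((r - 1L) * spr[h] + 1L):(r * spr[h])] <- phys
    }
  }
  rownames(x) <- labs
  if (!is.null(requireChannels)) {
    miss <- setdiff(toupper(requireChannels), labs)
    if (length(miss)) {
      stop("EDF file lacks required channel(s): ",
           paste(miss, collapse = ", "))
    }
  }
  if (!is.null(expectFs) && abs(fs - expectFs) > 1e-9) {
    stop("sampling-rate mismatch: file has ", fs, " Hz, expected ",
         expectFs, " Hz (no silent resampling)")
  }
  list(data = x, fs = fs, channelNames = labs)
}

#' Re-epoch a continuous recording
#'
#' @param continuous a \code{\link{readEdf}}-style list.
#' @param epochSamples samples per epoch (must divide the recording).
#' @param annotations per-trial annotation data.frame.
#' @return an \linkS4class{EEGEpochs}.
#' @export
epochsFromContinuous <- function(continuous, epochSamples,
                                 annotations = NULL) {
  x <- continuous$data
  n <- ncol(x)
  if (n %% epochSamples != 0L)
    stop("recording length not a multiple of the epoch length")
  ntrial <- n %/% epochSamples
  arr <- array(0, c(ntrial, nrow(x), epochSamples))
  for (i in seq_len(ntrial)) {
    arr[i, , ] <- x[, ((i - 1L) * epochSamples + 1L):(i * epochSamples)]
  }
  EEGEpochs(arr, continuous$fs, continuous$channelNames, annotations)
}

# --- pipeline configuration -------------------------------------------------

#' Default pipeline configuration
#'
#' Nested configuration covering every stage; the defaults reproduce
#' the reference scheme 1-40-0.5 (first-order Chebyshev convolution,
#' 40-point time features, dropout 0.5).
#'
#' @param seed master seed.
#' @return nested list of class \code{PipelineConfig}.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    simulation = list(nSubjects = 10L, nActions = 3L, fs = 1000,
                      cognitiveTrialsPerAction = 25L,
                      miTrialsPerAction = 80L,
                      couplingStrong = 0.8, couplingWeak = 0.3,
                      bandpowerShift = 0.5,
                      erdDepthStrong = 0.6, erdDepthWeak = 0.2,
                      noiseSd = 1),
    preprocessing = list(cognitiveFilter = list(low = 0.5, high = 20,
                                                order = 3),
                         miFilter = list(low = 8, high = 30, order = 5),
                         baseline = c(0, 0.2), cropWindow = c(0.2, 1.2)),
    network = list(downsamplePoints = 40L, welchSegment = 256L,
                   plvAggregate = "mean"),
    model = list(learningRate = 0.001, epochs = 1000L, chebOrder = 1L,
                 dropout = 0.5, classWeighting = FALSE),
    labeling = list(folds = 10L, dnnEpochs = 200L, lr = 0.01,
                    decay = 0.05),
    evaluation = list(clusteringThreshold = 0.3, nPermutations = 1000L))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys at every nesting level and enforces the
#' hyperparameter grid: Chebyshev order in \{1, 2\}, time-feature
#' points in \{20, 40, 60\}, dropout in \{0.25, 0.5\}.
#'
#' @param cfg nested configuration list (e.g. parsed from YAML/JSON).
#' @return the validated config, with defaults filled in, invisibly
#'   classed as \code{PipelineConfig}.
#' @export
validatePipelineConfig <- function(cfg) {
  ref <- unclass(defaultPipelineConfig())
  merge <- function(def, usr, path = "") {
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown)) {
      stop("unknown config key(s) at ", if (nzchar(path)) path else "top level",
           ": ", paste(unknown, collapse = ", "))
    }
    for (k in names(usr)) {
      def[[k]] <- if (is.list(def[[k]]) && is.list(usr[[k]])) {
        merge(def[[k]], usr[[k]], paste0(path, k, "."))
      } else {
        usr[[k]]
      }
    }
    def
  }
  out <- merge(ref, unclass(cfg))
  if (!out$model$chebOrder %in% c(1, 2))
    stop("model.chebOrder must be 1 or 2")
  if (!out$network$downsamplePoints %in% c(20, 40, 60))
    stop("network.downsamplePoints must be one of 20, 40, 60")
  if (!out$model$dropout %in% c(0.25, 0.5))
    stop("model.dropout must be 0.25 or 0.5")
  if (out$evaluation$clusteringThreshold <= 0 ||
      out$evaluation$clusteringThreshold >= 1)
    stop("evaluation.clusteringThreshold must lie in (0, 1)")
  class(out) <- "PipelineConfig"
  out
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file ending in .yaml/.yml (requires the yaml package) or
#'   .json.
#' @return validated \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext)
  }
  validatePipelineConfig(raw)
}

#' Stable hash of a configuration
#'
#' 32-bit FNV-1a over the canonical JSON serialization; identical
#' configurations hash identically across sessions.
#'
#' @param cfg any serializable list.
#' @return 8-hex-digit character hash.
#' @export
configHash <- function(cfg) {
  sortRec <- function(x) {
    if (is.list(x) && !is.null(names(x))) {
      x <- x[order(names(x))]
      lapply(x, sortRec)
    } else x
  }
  fnvHash(as.character(jsonlite::toJSON(sortRec(unclass(cfg)),
                                        auto_unbox = TRUE, digits = NA)))
}

#' Append a provenance record to a run log
#'
#' One JSON line per stage with timestamp, stage name, seed, config
#' hash and package version.
#'
#' @param dir output directory (created if needed).
#' @param stage stage name.
#' @param cfg the configuration in force.
#' @param seed the seed in force.
#' @return invisibly, the log path.
#' @export
appendRunLog <- function(dir, stage, cfg, seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(dir, "run-log.jsonl")
  rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stage = stage, seed = seed, configHash = configHash(cfg),
              package = as.character(utils::packageVersion("mdgcn")))
  cat(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE)), "\n",
      file = log, append = TRUE, sep = "")
  invisible(log)
}
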