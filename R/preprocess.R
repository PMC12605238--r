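# Signal conditioning: zero-phase Butterworth band-pass filtering,
# baseline correction, channel selection and epoch cropping.

#' Band-pass filter specification
#'
#' @param low,high band edges in Hz (0 < low < high < fs/2).
#' @param order Butterworth order (the filter is applied forward and
#'   backward, so effective attenuation doubles).
#' @return list of class \code{FilterSpec}.
#' @export
filterSpec <- function(low, high, order) {
  if (order < 1) stop("order must be >= 1")
  if (!(low > 0 && low < high)) stop("require 0 < low < high")
  structure(list(low = low, high = high, order = as.integer(order),
                 family = "butterworth"), class = "FilterSpec")
}

#' Zero-phase Butterworth band-pass filtering of epochs
#'
#' Each channel of each trial is filtered forward and backward
#' (zero phase) with odd-reflection padding at the epoch edges. The
#' cognitive default is a 3rd-order 0.5-20 Hz band, the MI default a
#' 5th-order 8-30 Hz band.
#'
#' @param epochs an \linkS4class{EEGEpochs} object.
#' @param spec a \code{\link{filterSpec}}; alternatively pass
#'   \code{low}, \code{high}, \code{order} directly.
#' @param low,high,order used when \code{spec} is NULL.
#' @return filtered \linkS4class{EEGEpochs}, same shape and annotations.
#' @export
bandpassFilter <- function(epochs, spec = NULL, low = 0.5, high = 20,
                           order = 3) {
  if (is.null(spec)) spec <- filterSpec(low, high, order)
  fs <- samplingRate(epochs)
  if (spec$high >= fs / 2) {
    stop("high edge ", spec$high, " Hz >= Nyquist frequency ", fs / 2, " Hz")
  }
  d <- epochs@data
  out <- d
  for (i in seq_len(dim(d)[1])) {
    m <- d[i, , , drop = FALSE]
    dim(m) <- dim(d)[2:3]
    out[i, , ] <- zeroPhaseBandpass(m, fs, spec$low, spec$high, spec$order)
  }
  initialize(epochs, data = out)
}

#' Baseline correction
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' from the whole trace.
#'
#' @param epochs an \linkS4class{EEGEpochs}.
#' @param baseline length-2 numeric, window in seconds from epoch start
#'   (default the first 0.2 s).
#' @return baseline-corrected \linkS4class{EEGEpochs}.
#' @export
baselineCorrect <- function(epochs, baseline = c(0, 0.2)) {
  fs <- samplingRate(epochs)
  ns <- nSamples(epochs)
  i0 <- round(baseline[1] * fs) + 1L
  i1 <- round(baseline[2] * fs)
  if (i1 < i0) stop("empty baseline window")
  if (i0 < 1L || i1 > ns) stop("baseline window outside the epoch")
  d <- epochs@data
  bl <- apply(d[, , i0:i1, drop = FALSE], c(1, 2), mean)
  initialize(epochs, data = d - array(bl, dim(d)))
}

#' Select and reorder channels
#'
#' @param epochs an \linkS4class{EEGEpochs}.
#' @param names ordered channel labels to keep; output channel order
#'   matches \code{names} exactly.
#' @return subsetted \linkS4class{EEGEpochs}.
#' @export
selectChannels <- function(epochs, names) {
  idx <- match(names, channelNames(epochs))
  if (anyNA(idx)) {
    stop("channel(s) not present: ",
         paste(names[is.na(idx)], collapse = ", "))
  }
  initialize(epochs, data = epochs@data[, idx, , drop = FALSE],
             channelNames = channelNames(epochs)[idx])
}

#' Crop epochs to a time window
#'
#' @param epochs an \linkS4class{EEGEpochs}.
#' @param t0,t1 window in seconds from epoch start; the output has
#'   \code{round((t1 - t0) * fs)} samples. The cognitive default
#'   \code{crop(0.2, 1.2)} drops the pre-stimulus baseline, leaving
#'   1000 samples at 1000 Hz.
#' @return cropped \linkS4class{EEGEpochs}.
#' @export
cropEpochs <- function(epochs, t0, t1) {
  fs <- samplingRate(epochs)
  ns <- nSamples(epochs)
  if (!(t0 >= 0 && t0 < t1)) stop("require 0 <= t0 < t1")
  i0 <- round(t0 * fs) + 1L
  i1 <- round(t1 * fs)
  if (i1 > ns) stop("crop window extends past the epoch end")
  initialize(epochs, data = epochs@data[, , i0:i1, drop = FALSE])
}

#' Standard cognitive preprocessing chain
#'
#' Band-pass 0.5-20 Hz (3rd order, zero phase) on the full 1.2 s epoch,
#' baseline correction over the first 0.2 s, then cropping to the final
#' 1 s analysis window. Accepts externally artifact-cleaned data; no
#' ICA is applied here.
#'
#' @param epochs raw cognitive \linkS4class{EEGEpochs} (1.2 s trials).
#' @param channels channel set to retain (default the 19-channel montage).
#' @return preprocessed \linkS4class{EEGEpochs}, 1 s trials.
#' @export
preprocessCognitive <- function(epochs, channels = COGNITIVE_CHANNELS) {
  epochs <- selectChannels(epochs, channels)
  epochs <- bandpassFilter(epochs, filterSpec(0.5, 20, 3))
  epochs <- baselineCorrect(epochs, c(0, 0.2))
  cropEpochs(epochs, 0.2, nSamples(epochs) / samplingRate(epochs))
}

#' Standard MI preprocessing chain
#'
#' Band-pass 8-30 Hz (5th order, zero phase) over the sensorimotor
#' montage; captures the mu (8-13 Hz) and beta (13-30 Hz) rhythms used
#' by CSP.
#'
#' @param epochs raw MI \linkS4class{EEGEpochs}.
#' @param channels channel set to retain (default the 12-channel montage).
#' @return preprocessed \linkS4class{EEGEpochs}.
#' @export
preprocessMi <- function(epochs, channels = MI_CHANNELS) {
  epochs <- selectChannels(epochs, channels)
  bandpassFilter(epochs, filterSpec(8, 30, 5))
}
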