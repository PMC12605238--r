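# Synthetic EEG cohort generator.
#
# Emulates the acquisition design the pipeline expects: per subject,
# 3 actions x 25 cognitive trials (19 channels, 1.2 s at 1000 Hz, the
# first 0.2 s pre-stimulus) and 3 actions x 80 MI trials (12 channels,
# 6 s, 40 left / 40 right). Exactly one "strong" action per subject
# carries (a) stronger inter-channel oscillatory coupling and an
# alpha/beta power boost in cognitive trials and (b) a deeper
# lateralized mu-rhythm ERD in MI trials.

#' Default cognitive-task channel montage (19 channels)
#' @export
COGNITIVE_CHANNELS <- c("FZ", "FC3", "FCZ", "FC4", "C5", "C3", "C1", "CZ",
                        "C2", "C4", "C6", "CP3", "CP4", "PO3", "POZ", "PO4",
                        "O1", "OZ", "O2")

#' Default MI-task channel montage (12 channels)
#' @export
MI_CHANNELS <- c("FC3", "FCZ", "FC4", "C5", "C3", "C1", "CZ", "C2", "C4",
                 "C6", "CP3", "CP4")

# Approximate 2-D 10-20 scalp coordinates (unit head radius), used for
# distance-decaying source mixing weights.
electrodeLayout <- function() {
  data.frame(
    channel = c("FZ", "FC3", "FCZ", "FC4", "C5", "C3", "C1", "CZ", "C2",
                "C4", "C6", "CP3", "CP4", "PO3", "POZ", "PO4", "O1", "OZ",
                "O2"),
    x = c(0.00, -0.35, 0.00, 0.35, -0.80, -0.50, -0.25, 0.00, 0.25,
          0.50, 0.80, -0.40, 0.40, -0.35, 0.00, 0.35, -0.30, 0.00, 0.30),
    y = c(0.55, 0.30, 0.30, 0.30, 0.00, 0.00, 0.00, 0.00, 0.00,
          0.00, 0.00, -0.30, -0.30, -0.60, -0.60, -0.60, -0.85, -0.85,
          -0.85),
    stringsAsFactors = FALSE)
}

#' Simulation specification
#'
#' Bundles every generator parameter with validated defaults. The
#' defaults are the package's reference study conditions: 10 subjects,
#' 3 actions, 25 cognitive + 80 MI trials per action at 1000 Hz, a
#' 0.8-vs-0.3 source-coupling contrast, a 50\% alpha/beta band-power
#' boost for the strong action, and mu-ERD depths of 0.6 (strong) vs
#' 0.2 (weak).
#'
#' @param nSubjects number of subjects (>= 2 for LOSO).
#' @param nActions number of candidate actions.
#' @param fs sampling rate, Hz.
#' @param cognitiveTrialsPerAction cognitive trials per action.
#' @param miTrialsPerAction MI trials per action (half left, half right).
#' @param cognitiveChannels,miChannels montages; defaults are the 19- and
#'   12-channel sensorimotor/visual sets.
#' @param couplingStrong,couplingWeak shared-source mixing gain in [0, 1]
#'   for strong- and weak-action cognitive trials.
#' @param bandpowerShift relative alpha/beta power boost for the strong
#'   action (power scaled by \code{1 + bandpowerShift}).
#' @param erdDepthStrong,erdDepthWeak fractional contralateral mu-power
#'   attenuation during MI, in [0, 1].
#' @param noiseSd background-noise innovation scale (arbitrary microvolt
#'   units).
#' @param seed integer master seed; identical specs give bit-identical
#'   cohorts.
#' @return A validated list of class \code{SimulationSpec}.
#' @export
simulationSpec <- function(nSubjects = 10L, nActions = 3L, fs = 1000,
                           cognitiveTrialsPerAction = 25L,
                           miTrialsPerAction = 80L,
                           cognitiveChannels = COGNITIVE_CHANNELS,
                           miChannels = MI_CHANNELS,
                           couplingStrong = 0.8, couplingWeak = 0.3,
                           bandpowerShift = 0.5,
                           erdDepthStrong = 0.6, erdDepthWeak = 0.2,
                           noiseSd = 1, seed = 1L) {
  spec <- list(nSubjects = as.integer(nSubjects),
               nActions = as.integer(nActions), fs = fs,
               cognitiveTrialsPerAction = as.integer(cognitiveTrialsPerAction),
               miTrialsPerAction = as.integer(miTrialsPerAction),
               cognitiveChannels = cognitiveChannels,
               miChannels = miChannels,
               couplingStrong = couplingStrong, couplingWeak = couplingWeak,
               bandpowerShift = bandpowerShift,
               erdDepthStrong = erdDepthStrong, erdDepthWeak = erdDepthWeak,
               noiseSd = noiseSd, seed = as.integer(seed))
  if (spec$couplingWeak < 0 || spec$couplingStrong < spec$couplingWeak)
    stop("require couplingStrong >= couplingWeak >= 0")
  if (spec$couplingStrong > 1) stop("coupling gains must lie in [0, 1]")
  for (p in c("erdDepthStrong", "erdDepthWeak")) {
    if (spec[[p]] < 0 || spec[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  if (spec$miTrialsPerAction %% 2L != 0L)
    stop("miTrialsPerAction must be even (half left / half right)")
  if (!all(spec$miChannels %in% spec$cognitiveChannels))
    stop("miChannels must be a subset of the layout channels")
  if (spec$bandpowerShift < 0) stop("bandpowerShift must be >= 0")
  class(spec) <- "SimulationSpec"
  spec
}

# AR(1) (phi = 0.95) plus low-amplitude white noise: a cheap 1/f-like
# background. Returns channels x samples.
backgroundNoise <- function(nch, ns, sd) {
  phi <- 0.95
  innov <- matrix(rnorm(nch * ns, sd = sd), nch, ns)
  ar <- matrix(0, nch, ns)
  ar[, 1] <- innov[, 1] / sqrt(1 - phi^2)
  for (t in 2:ns) ar[, t] <- phi * ar[, t - 1] + innov[, t]
  ar + matrix(rnorm(nch * ns, sd = 0.3 * sd), nch, ns)
}

# Narrow-band source: sinusoid with a slow random-walk phase jitter.
jitteredOscillation <- function(freq, n, fs, jitterSd = 0.05) {
  phase <- 2 * pi * freq * seq_len(n) / fs + runif(1, 0, 2 * pi) +
    cumsum(rnorm(n, sd = jitterSd))
  sin(phase)
}

# Mixing weight of each channel for a source centred on one electrode,
# decaying with 2-D inter-electrode distance.
spatialWeights <- function(channels, centre, lambda = 0.6) {
  lay <- electrodeLayout()
  idx <- match(channels, lay$channel)
  c0 <- match(centre, lay$channel)
  d <- sqrt((lay$x[idx] - lay$x[c0])^2 + (lay$y[idx] - lay$y[c0])^2)
  exp(-d / lambda)
}

# One cognitive trial (channels x samples). Sources are silent during the
# 0.2 s pre-stimulus baseline.
simulateCognitiveTrial <- function(spec, strong) {
  ns <- round(1.2 * spec$fs)
  nbase <- round(0.2 * spec$fs)
  nch <- length(spec$cognitiveChannels)
  x <- backgroundNoise(nch, ns, spec$noiseSd)
  gain <- if (strong) spec$couplingStrong else spec$couplingWeak
  boost <- if (strong) sqrt(1 + spec$bandpowerShift) else 1
  bands <- list(theta = list(freq = 6, centre = "FCZ", amp = 4),
                alpha = list(freq = 10, centre = "C3", amp = 4 * boost),
                beta = list(freq = 16, centre = "C4", amp = 4 * boost))
  active <- (nbase + 1L):ns
  for (b in bands) {
    src <- jitteredOscillation(b$freq, length(active), spec$fs)
    w <- spatialWeights(spec$cognitiveChannels, b$centre)
    x[, active] <- x[, active] + (gain * b$amp * w) %o% src
  }
  x
}

# One MI trial (channels x samples): a mu rhythm over both sensorimotor
# strips, attenuated contralaterally to the cued hand by the action's ERD
# depth. Each hemisphere's mu amplitude fluctuates from trial to trial
# (log-normal, sigma = 0.4), so decoding accuracy is limited by ERD
# depth rather than saturating -- mirroring the 60-90% accuracies
# typical of real left/right MI decoding.
simulateMiTrial <- function(spec, hand, erd) {
  ns <- round(6 * spec$fs)
  nch <- length(spec$miChannels)
  x <- backgroundNoise(nch, ns, spec$noiseSd)
  leftHemi <- spec$miChannels %in% c("FC3", "C5", "C3", "C1", "CP3")
  rightHemi <- spec$miChannels %in% c("FC4", "C2", "C4", "C6", "CP4")
  amp <- rep(2, nch)           # midline channels get the base amplitude
  amp[leftHemi] <- 4 * exp(rnorm(1, 0, 0.4))
  amp[rightHemi] <- 4 * exp(rnorm(1, 0, 0.4))
  contra <- if (hand == "left") rightHemi else leftHemi
  amp[contra] <- amp[contra] * sqrt(1 - erd)
  src <- jitteredOscillation(10, ns, spec$fs)
  indep <- 0.3 * matrix(rnorm(nch * ns), nch, ns)  # per-channel mu jitter
  x + amp * (rep(1, nch) %o% src) + indep
}

#' Simulate one subject's cognitive and MI datasets
#'
#' All randomness is drawn from a per-subject stream derived from
#' \code{spec$seed} and \code{subjectId}, so subjects are reproducible
#' independently of cohort order.
#'
#' @param spec a \code{\link{simulationSpec}}.
#' @param subjectId integer subject identifier.
#' @param strongAction index of this subject's strong action.
#' @return list with elements \code{subject}, \code{cognitive}
#'   (\linkS4class{EEGEpochs}), \code{mi} (\linkS4class{EEGEpochs}) and
#'   \code{trueStrongAction}.
#' @export
simulateSubject <- function(spec, subjectId, strongAction) {
  if (strongAction < 1L || strongAction > spec$nActions)
    stop("strongAction must lie in 1..nActions")
  withSeed(mixSeed(spec$seed, subjectId), {
    nsCog <- round(1.2 * spec$fs)
    nCog <- spec$nActions * spec$cognitiveTrialsPerAction
    cog <- array(0, c(nCog, length(spec$cognitiveChannels), nsCog))
    cogAction <- integer(nCog)
    k <- 0L
    for (a in seq_len(spec$nActions)) {
      for (tr in seq_len(spec$cognitiveTrialsPerAction)) {
        k <- k + 1L
        cog[k, , ] <- simulateCognitiveTrial(spec, strong = (a == strongAction))
        cogAction[k] <- a
      }
    }
    cogEp <- EEGEpochs(cog, spec$fs, spec$cognitiveChannels,
                       data.frame(task = "cognitive", action = cogAction,
                                  hand = "none", subject = subjectId))

    nsMi <- round(6 * spec$fs)
    nMi <- spec$nActions * spec$miTrialsPerAction
    half <- spec$miTrialsPerAction %/% 2L
    mi <- array(0, c(nMi, length(spec$miChannels), nsMi))
    miAction <- integer(nMi)
    miHand <- character(nMi)
    k <- 0L
    for (a in seq_len(spec$nActions)) {
      erd <- if (a == strongAction) spec$erdDepthStrong else spec$erdDepthWeak
      for (h in c("left", "right")) {
        for (tr in seq_len(half)) {
          k <- k + 1L
          mi[k, , ] <- simulateMiTrial(spec, h, erd)
          miAction[k] <- a
          miHand[k] <- h
        }
      }
    }
    miEp <- EEGEpochs(mi, spec$fs, spec$miChannels,
                      data.frame(task = "mi", action = miAction,
                                 hand = miHand, subject = subjectId))
    list(subject = as.integer(subjectId), cognitive = cogEp, mi = miEp,
         trueStrongAction = as.integer(strongAction))
  })
}

#' Simulate a cohort of subjects
#'
#' Strong actions are assigned from a seeded stream by shuffling a
#' balanced repetition of the action indices, so that with
#' \code{nSubjects >= nActions} every action is some subject's strong
#' action.
#'
#' @param spec a \code{\link{simulationSpec}}.
#' @return list of per-subject datasets (see \code{\link{simulateSubject}}).
#' @export
simulateCohort <- function(spec) {
  if (spec$nSubjects < 2L)
    stop("need at least 2 subjects (leave-one-subject-out requires >= 2)")
  assign <- withSeed(mixSeed(spec$seed, 0L),
                     sample(rep_len(seq_len(spec$nActions), spec$nSubjects)))
  lapply(seq_len(spec$nSubjects), function(s)
    simulateSubject(spec, s, assign[s]))
}
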