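#' Generate a pseudo-random binary bar stimulus
#'
#' Independent equiprobable dark (-1) / bright (+1) bars per frame; seeded
#' and reproducible.
#'
#' @param nBars,nFrames stimulus geometry.
#' @param frameRate presentation rate, Hz.
#' @param seed RNG seed.
#' @return a [StimulusEnsemble-class] with raw alphabet and zero counts.
#' @export
makeBarStimulus <- function(nBars, nFrames, frameRate = 60, seed = 1) {
  set.seed(seed)
  frames <- matrix(sample(c(-1, 1), nBars * nFrames, replace = TRUE),
                   nBars, nFrames)
  stimulusEnsemble(frames, frameRate = frameRate, basis = "raw")
}

#' LIF parameters
#'
#' @param tauM membrane time constant (ms).
#' @param vRest,vReset,vThresh resting, reset, threshold potentials.
#' @param refrac absolute refractory period (ms).
#' @param dt integration step (ms).
#' @param noiseSd per-step Gaussian membrane noise.
#' @return a [LIFParams-class].
#' @export
lifParams <- function(tauM = 20, vRest = 0, vReset = 0, vThresh = 1,
                      refrac = 2, dt = 1, noiseSd = 0.02) {
  new("LIFParams", tauM = tauM, vRest = vRest, vReset = vReset,
      vThresh = vThresh, refrac = refrac, dt = dt, noiseSd = noiseSd)
}

#' Depressing synapse constructor and update
#'
#' \code{depressingSynapse} builds a synapse state; \code{depressingUpdate}
#' advances it over \code{dt} milliseconds of recovery
#' (dR/dt = (1 - R) / tauRec, integrated exactly) and then, if a presynaptic
#' spike arrives, releases \code{weight * u * R} and depletes the resource to
#' \code{R (1 - u)}.
#'
#' @param u release fraction per spike.
#' @param tauRec recovery time constant (ms).
#' @param weight synaptic weight.
#' @param R initial resource.
#' @return \code{depressingSynapse}: a [DepressingSynapse-class];
#'   \code{depressingUpdate}: list with the updated synapse and the
#'   \code{released} amplitude (zero without a spike).
#' @export
depressingSynapse <- function(u = 0.9, tauRec = 200, weight = 1, R = 1) {
  new("DepressingSynapse", u = u, tauRec = tauRec, weight = weight, R = R)
}

#' @rdname depressingSynapse
#' @param syn a [DepressingSynapse-class].
#' @param dt elapsed time since the last update (ms).
#' @param presynapticSpike logical.
#' @export
depressingUpdate <- function(syn, dt, presynapticSpike = FALSE) {
  R <- 1 - (1 - syn@R) * exp(-dt / syn@tauRec)
  released <- 0
  if (presynapticSpike) {
    released <- syn@weight * syn@u * R
    R <- R * (1 - syn@u)
  }
  syn@R <- R
  list(syn = syn, released = released)
}

#' Feedforward complex-cell network configuration
#'
#' Nine (by default) LIF input cells with one shared spatiotemporal RF
#' template, each shifted by one bar, drive a LIF output cell through
#' excitatory depressing synapses (u = 0.9, tauRec = 200 ms). The template is
#' center-surround along bars and biphasic in time. \code{preset
#' "two-plain"} keeps only bank positions 4 and 6 and disables depression,
#' approximating a cell driven by a two-dimensional stimulus subspace.
#'
#' @param nInputs number of input cells.
#' @param nBars stimulus bars.
#' @param positions center bar per input; defaults to a centered bank
#'   shifted by one bar per input.
#' @param template spatiotemporal RF template (bars x frames, last column is
#'   the current frame).
#' @param inputGain drive scaling.
#' @param synWeight synaptic weight onto the output cell.
#' @param depression enable short-term depression.
#' @param u,tauRec depression parameters.
#' @param lif [LIFParams-class] shared by all cells.
#' @return a [NetworkConfig-class].
#' @export
networkConfig <- function(nInputs = 9, nBars = 16, positions = NULL,
                          template = defaultRfTemplate(),
                          inputGain = 1.6, synWeight = 0.9,
                          depression = TRUE, u = 0.9, tauRec = 200,
                          lif = lifParams()) {
  if (is.null(positions))
    positions <- (nBars - nInputs) %/% 2L + seq_len(nInputs)
  new("NetworkConfig", nBars = as.integer(nBars),
      positions = as.integer(positions), template = template,
      inputGain = inputGain, synWeight = synWeight,
      depression = depression, u = u, tauRec = tauRec, lif = lif)
}

#' @rdname networkConfig
#' @param preset "nine-depressing" or "two-plain".
#' @param ... overrides passed on to \code{networkConfig}.
#' @export
presetNetwork <- function(preset = c("nine-depressing", "two-plain"), ...) {
  preset <- match.arg(preset)
  bank <- (16L - 9L) %/% 2L + seq_len(9L)  # the nine-RF bank on 16 bars
  if (preset == "nine-depressing")
    networkConfig(nInputs = 9, depression = TRUE, ...)
  else
    networkConfig(nInputs = 2, positions = bank[c(4, 6)],
                  depression = FALSE, ...)
}

#' @rdname networkConfig
#' @export
defaultRfTemplate <- function() {
  ## center-surround along bars, biphasic in time (previous frame, current
  ## frame)
  spatial <- c(-0.5, 1, -0.5)
  temporal <- c(-0.35, 1)
  outer(spatial, temporal)
}

## Per-frame drive of every input cell: cross-correlation of the raw
## stimulus with the (shifted) template; template column w is the current
## frame, earlier columns are previous frames.
inputDrive <- function(cfg, S) {
  Tm <- cfg@template
  half <- (nrow(Tm) - 1L) %/% 2L
  nf <- ncol(S)
  wT <- ncol(Tm)
  D <- matrix(0, length(cfg@positions), nf)
  for (i in seq_along(cfg@positions)) {
    p <- cfg@positions[i]
    for (cc in seq_len(wT)) {
      lagBack <- wT - cc  # 0 for the current frame
      fs <- (1L + lagBack):nf
      block <- crossprod(Tm[, cc], S[p + (-half:half), fs - lagBack,
                                     drop = FALSE])
      D[i, fs] <- D[i, fs] + as.vector(block)
    }
  }
  cfg@inputGain * D
}

#' Simulate the feedforward complex-cell network
#'
#' Each input LIF cell is driven by its shifted RF template filtering of the
#' raw stimulus; input spikes reach the output LIF through excitatory
#' (optionally depressing) synapses as instantaneous membrane kicks; output
#' spikes are binned at the frame rate.
#'
#' @param cfg a [NetworkConfig-class].
#' @param stimulus a raw-basis [StimulusEnsemble-class].
#' @param seed RNG seed for the membrane noise.
#' @return the stimulus ensemble with the output spike counts filled in;
#'   attributes \code{inputRatesHz} and \code{outputRateHz} carry rate
#'   diagnostics. Warns when the network stays silent.
#' @export
simulateComplexNetwork <- function(cfg, stimulus, seed = 1) {
  if (stimulus@basis != "raw")
    stop("the network is driven by the raw (-1/+1) stimulus")
  S <- stimulus@frames
  half <- (nrow(cfg@template) - 1L) %/% 2L
  if (nrow(S) < max(cfg@positions) + half)
    stop("stimulus has too few bars for the configured RF bank")
  D <- inputDrive(cfg, S)
  nf <- ncol(S)
  lif <- cfg@lif
  nSteps <- round(nf * 1000 / stimulus@frameRate / lif@dt)
  frameOfStep <- pmin(floor((seq_len(nSteps) - 1) * lif@dt *
                              stimulus@frameRate / 1000) + 1L, nf)
  set.seed(seed)
  sim <- lifNetworkCpp(D, as.integer(frameOfStep), lif@dt, lif@tauM,
                       lif@vRest, lif@vReset, lif@vThresh, lif@refrac,
                       lif@noiseSd, cfg@depression, cfg@u, cfg@tauRec,
                       cfg@synWeight)
  secs <- nf / stimulus@frameRate
  if (sim$outputSpikes == 0)
    warning(sprintf(paste0("silent network: input rates %s Hz, no output",
                           " spikes"),
                    paste(round(sim$inputSpikes / secs, 1), collapse = ", ")))
  out <- stimulusEnsemble(S, counts = as.numeric(sim$counts),
                          frameRate = stimulus@frameRate, basis = "raw")
  attr(out, "inputRatesHz") <- sim$inputSpikes / secs
  attr(out, "outputRateHz") <- sim$outputSpikes / secs
  out
}

#' Generate Poisson spikes from an LN or context model
#'
#' Per-frame Poisson counts with rate \code{f(z_i)}, where z is the model's
#' similarity score of the window ending at the frame; frames with incomplete
#' stimulus history get zero counts. Rates above 1e4 are clipped with a
#' warning.
#'
#' @param rf RF vector (LN case); its length divided by the bar count gives
#'   the number of lags.
#' @param params a [ContextModel-class] (context case).
#' @param nonlinearity function mapping score to a nonnegative rate
#'   (expected spikes per frame).
#' @param stimulus a [StimulusEnsemble-class] (any basis; used as-is).
#' @param seed RNG seed.
#' @param w0 bias added to the LN score.
#' @return the stimulus ensemble with Poisson counts filled in.
#' @export
generateLnPoisson <- function(rf, nonlinearity, stimulus, seed = 1, w0 = 0) {
  nb <- nrow(stimulus@frames)
  nLags <- length(rf) / nb
  if (nLags != round(nLags)) stop("rf length is not a multiple of nBars")
  model <- contextModel(nb, as.integer(nLags), w0 = w0, rf = rf)
  generateContextPoisson(model, nonlinearity, stimulus, seed)
}

#' @rdname generateLnPoisson
#' @export
generateContextPoisson <- function(params, nonlinearity, stimulus,
                                   seed = 1) {
  design <- buildLaggedDesign(stimulus, params@nLags)
  z <- similarityScores(params, design)
  rate <- nonlinearity(z)
  if (any(rate < 0)) stop("nonlinearity produced negative rates")
  if (any(rate > 1e4)) {
    warning("rates above 1e4 clipped")
    rate <- pmin(rate, 1e4)
  }
  set.seed(seed)
  counts <- numeric(ncol(stimulus@frames))
  counts[design@sampleFrames] <- stats::rpois(length(rate), rate)
  stimulusEnsemble(stimulus@frames, counts = counts,
                   frameRate = stimulus@frameRate, basis = stimulus@basis)
}
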