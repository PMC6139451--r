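#' @import methods
NULL

#' Stimulus-response ensemble
#'
#' Container for a bar-stimulus movie and the per-frame spike counts it
#' evoked. Frames are stored one per column, so the matrix is
#' \code{nBars x nFrames}. Raw stimuli use the alphabet \{-1, +1\} (dark,
#' bright); after applying a basis function (see [applyBasis()]) entries are
#' \{0, 1\}.
#'
#' @slot frames numeric matrix, bars by frames.
#' @slot counts nonnegative integer spike counts, one per frame.
#' @slot frameRate presentation rate in Hz.
#' @slot basis one of "raw", "bright", "dark", "bright+dark".
#' @export
setClass("StimulusEnsemble",
  representation(frames = "matrix", counts = "numeric",
                 frameRate = "numeric", basis = "character"),
  prototype(frameRate = 60, basis = "raw"))

setValidity("StimulusEnsemble", function(object) {
  msg <- character()
  if (nrow(object@frames) < 1L) msg <- c(msg, "need at least one bar")
  if (length(object@counts) != ncol(object@frames))
    msg <- c(msg, "counts length must equal the number of frames")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be nonnegative integers")
  vals <- unique(as.vector(object@frames))
  alph <- if (object@basis == "raw") c(-1, 1) else c(0, 1)
  if (!all(vals %in% alph))
    msg <- c(msg, sprintf("frame entries must lie in {%s} for basis '%s'",
                          paste(alph, collapse = ", "), object@basis))
  if (length(msg)) msg else TRUE
})

#' Lagged design matrix
#'
#' Each row is a bars-by-lags stimulus window flattened column-major (bar
#' index varies fastest within each lag block; the most recent frame occupies
#' the rightmost, i.e. last, lag block). Row \code{i} is paired with the
#' spike count of the window's last frame, recorded in \code{sampleFrames}.
#'
#' @slot X design matrix, samples by (bars * lags).
#' @slot y spike count per sample.
#' @slot frames the source frame matrix (kept for context-window lookups).
#' @slot nBars,nLags window geometry.
#' @slot sampleFrames index of the last (most recent) frame of each row's
#'   window in \code{frames}.
#' @slot frameRate Hz.
#' @slot basis basis tag inherited from the ensemble.
#' @export
setClass("LaggedDesign",
  representation(X = "matrix", y = "numeric", frames = "matrix",
                 nBars = "integer", nLags = "integer",
                 sampleFrames = "integer", frameRate = "numeric",
                 basis = "character"))

setValidity("LaggedDesign", function(object) {
  msg <- character()
  if (nrow(object@X) != length(object@y))
    msg <- c(msg, "one count per design row required")
  if (ncol(object@X) != object@nBars * object@nLags)
    msg <- c(msg, "design width must be nBars * nLags")
  if (length(object@sampleFrames) != nrow(object@X))
    msg <- c(msg, "one sampleFrames entry per row required")
  if (length(msg)) msg else TRUE
})

#' Context-window geometry
#'
#' Defines the local window used to gather the context vector around a
#' stimulus element. The origin is the cell of the window that is aligned
#' with the element itself; its coefficient in any context field is
#' structurally fixed to zero so the field contains interaction terms only.
#'
#' @slot height window extent in bars.
#' @slot width window extent in lags (frames).
#' @slot origin integer (row, col) of the origin inside the window.
#' @slot pad value used for cells falling outside the stimulus; zero by
#'   default so out-of-bounds cells contribute nothing to dot products.
#' @export
setClass("ContextWindowSpec",
  representation(height = "integer", width = "integer",
                 origin = "integer", pad = "numeric"),
  prototype(pad = 0))

setValidity("ContextWindowSpec", function(object) {
  o <- object@origin
  if (length(o) != 2L || o[1] < 1L || o[1] > object@height ||
      o[2] < 1L || o[2] > object@width)
    return("origin must lie inside the window")
  TRUE
})

#' Context field
#'
#' A local weighting window that multiplicatively gates receptive-field
#' elements according to the stimulus pattern surrounding them. The weight at
#' the window origin is always exactly zero. \code{rfAssignment} lists the RF
#' indices served by this field.
#'
#' @slot weights height-by-width weight matrix.
#' @slot spec the [ContextWindowSpec-class] geometry.
#' @slot rfAssignment integer RF indices gated by this field.
#' @export
setClass("ContextField",
  representation(weights = "matrix", spec = "ContextWindowSpec",
                 rfAssignment = "integer"))

setValidity("ContextField", function(object) {
  msg <- character()
  sp <- object@spec
  if (!all(dim(object@weights) == c(sp@height, sp@width)))
    msg <- c(msg, "weights must match the window geometry")
  if (object@weights[sp@origin[1], sp@origin[2]] != 0)
    msg <- c(msg, "origin weight must be exactly zero")
  if (length(msg)) msg else TRUE
})

#' Context model parameters
#'
#' Bias, vectorized receptive field, and zero or more context fields. The RF
#' is stored flattened in the same column-major order as design rows;
#' \code{matrix(rf, nBars, nLags)} recovers the bars-by-lags field.
#' \code{rfBlocks} records the grid blocks the RF is composed of (a single
#' bars-by-lags block normally; two stacked blocks for the
#' space-time-intensity basis) and is used to build smoothness regularizers.
#'
#' @slot w0 scalar bias.
#' @slot rf numeric vector of length nBars * nLags.
#' @slot cfs list of [ContextField-class] objects with disjoint assignments
#'   jointly covering all RF indices (when any field is present).
#' @slot nBars,nLags RF grid geometry (bars doubled under the intensity
#'   basis).
#' @slot rfBlocks list of c(rows, cols) grid blocks.
#' @export
setClass("ContextModel",
  representation(w0 = "numeric", rf = "numeric", cfs = "list",
                 nBars = "integer", nLags = "integer", rfBlocks = "list"))

setValidity("ContextModel", function(object) {
  msg <- character()
  if (length(object@rf) != object@nBars * object@nLags)
    msg <- c(msg, "rf length must equal nBars * nLags")
  if (length(object@cfs)) {
    idx <- unlist(lapply(object@cfs, function(cf) cf@rfAssignment))
    if (anyDuplicated(idx))
      msg <- c(msg, "context-field assignments must be disjoint")
    if (!setequal(idx, seq_along(object@rf)))
      msg <- c(msg, "context-field assignments must cover all RF indices")
  }
  if (length(msg)) msg else TRUE
})

#' Solver configuration for the alternating algorithm
#'
#' @slot family "linear", "logistic" or "poisson"; determines both the
#'   subproblem loss and the model nonlinearity (identity, logistic,
#'   exponential).
#' @slot C regularization strength used while iterating to convergence.
#' @slot regKind "l2" or "laplacian".
#' @slot tol inner (Newton) solver tolerance.
#' @slot convRel relative loss-decrease threshold declaring outer-loop
#'   convergence (1e-4, i.e. 0.01 percent).
#' @slot cvFolds folds for the final cross-validated choice of C.
#' @slot cvGrid candidate C values for cross-validation.
#' @slot maxOuter safety cap on outer iterations.
#' @slot seed RNG seed for jittered initialization.
#' @export
setClass("SolverConfig",
  representation(family = "character", C = "numeric", regKind = "character",
                 tol = "numeric", convRel = "numeric", cvFolds = "integer",
                 cvGrid = "numeric", maxOuter = "integer", seed = "integer"),
  prototype(C = 0.1, convRel = 1e-4))

setValidity("SolverConfig", function(object) {
  msg <- character()
  if (!object@family %in% c("linear", "logistic", "poisson"))
    msg <- c(msg, "unknown family")
  if (object@C <= 0) msg <- c(msg, "C must be positive")
  if (object@convRel <= 0) msg <- c(msg, "convRel must be positive")
  if (length(msg)) msg else TRUE
})

#' Fitted context model
#'
#' @slot params the fitted [ContextModel-class].
#' @slot lossTrace regularized training loss after every outer iteration at
#'   fixed C (non-increasing).
#' @slot chosenC named list with the cross-validated C for the RF and CF
#'   steps of the final iteration.
#' @slot flipped whether a sign-flip restart was performed.
#' @slot family subproblem family used.
#' @slot converged logical.
#' @export
setClass("ContextFit",
  representation(params = "ContextModel", lossTrace = "numeric",
                 chosenC = "list", flipped = "logical", family = "character",
                 converged = "logical"))

#' Spike-triggered statistics
#'
#' Count-weighted spike-triggered average (STA) and covariance (STC) of a
#' design; samples contribute once per spike.
#'
#' @slot sta STA vector.
#' @slot stc STC matrix (covariance about the STA).
#' @slot nSpikes total spike count.
#' @slot stimulusVariance per-dimension variance of the full ensemble.
#' @export
setClass("SpikeTriggeredStats",
  representation(sta = "numeric", stc = "matrix", nSpikes = "numeric",
                 stimulusVariance = "numeric"))

setValidity("SpikeTriggeredStats", function(object) {
  if (max(abs(object@stc - t(object@stc))) > 1e-8)
    return("STC matrix must be symmetric")
  TRUE
})

#' Bank of linear filters
#'
#' @slot filters filter columns (orthonormal for kinds "stc" and "istac").
#' @slot values per-filter eigenvalues (stc/null) or marginal information in
#'   bits (istac); zero-length when not applicable.
#' @slot kind one of "stc", "null", "istac", "mid".
#' @slot center,scale the per-dimension standardization under which the
#'   filters were estimated; applied before projecting new designs.
#' @export
setClass("FilterBank",
  representation(filters = "matrix", values = "numeric", kind = "character",
                 center = "numeric", scale = "numeric"),
  prototype(center = 0, scale = 1))

setValidity("FilterBank", function(object) {
  if (object@kind %in% c("stc", "istac", "null")) {
    B <- object@filters
    if (max(abs(crossprod(B) - diag(ncol(B)))) > 1e-8)
      return("filters must be orthonormal for this kind")
  }
  TRUE
})

#' Quadratic-nonlinear (maximum-noise-entropy) model
#'
#' Full quadratic form (intercept, v, J) from the logistic maximum-likelihood
#' fit and, after low-rank selection, the retained unit-norm filters with
#' their coefficients. The similarity score of a selected model is
#' \code{z = intercept + sum_m lambda_m * (x' w_m)^2} over "J" filters plus
#' \code{lambda_m * (x' w_m)} over the optional "v" filter.
#'
#' @slot intercept scalar c.
#' @slot v linear coefficient vector.
#' @slot J symmetric quadratic coefficient matrix.
#' @slot filters unit-norm selected filters (0 columns before selection).
#' @slot lambdas coefficient per selected filter (eigenvalue for "J"
#'   filters, linear coefficient for the "v" filter).
#' @slot sources "J" or "v" per selected filter.
#' @export
setClass("QNModel",
  representation(intercept = "numeric", v = "numeric", J = "matrix",
                 filters = "matrix", lambdas = "numeric",
                 sources = "character"))

setValidity("QNModel", function(object) {
  msg <- character()
  if (length(object@J) && max(abs(object@J - t(object@J))) > 1e-10)
    msg <- c(msg, "J must be symmetric")
  if (ncol(object@filters) &&
      any(abs(sqrt(colSums(object@filters^2)) - 1) > 1e-8))
    msg <- c(msg, "selected filters must be unit norm")
  if (length(msg)) msg else TRUE
})

#' Histogram of similarity scores
#'
#' Shared-edge histograms of all scores (\code{pZ}) and of scores weighted by
#' spike count (\code{pZSpike}); both are normalized probability masses.
#' At most two dimensions.
#'
#' @slot edges list of bin-edge vectors, one per dimension.
#' @slot pZ,pZSpike probability arrays (vector or matrix).
#' @slot pSpike mean spike count per frame.
#' @export
setClass("ScoreDistribution",
  representation(edges = "list", pZ = "array", pZSpike = "array",
                 pSpike = "numeric"))

setValidity("ScoreDistribution", function(object) {
  msg <- character()
  if (abs(sum(object@pZ) - 1) > 1e-8) msg <- c(msg, "pZ must sum to one")
  if (abs(sum(object@pZSpike) - 1) > 1e-8)
    msg <- c(msg, "pZSpike must sum to one")
  if (length(object@edges) > 2L)
    msg <- c(msg, "histogram estimation supports at most two dimensions")
  if (length(msg)) msg else TRUE
})

#' Histogram nonlinearity
#'
#' Per-bin spike rate obtained via Bayes' rule,
#' f(z) = P(spike) P(z | spike) / P(z), with empty bins inheriting the
#' global mean rate. Out-of-range scores clamp to the edge bins.
#'
#' @slot edges list of bin-edge vectors.
#' @slot f rate array (expected spike count per frame, per bin).
#' @slot meanRate mean training rate.
#' @slot bins bins per dimension.
#' @export
setClass("NonlinearityHistogram",
  representation(edges = "list", f = "array", meanRate = "numeric",
                 bins = "integer"))

#' Bias-corrected information estimate
#'
#' @slot resolutions histogram resolutions (bins per dimension).
#' @slot naive naive information per resolution (bits).
#' @slot bias estimated finite-sample bias per resolution (bits).
#' @slot corrected naive minus bias, per resolution.
#' @slot value mean of the corrected values (the reported estimate).
#' @slot method "null" (null-feature) or "qe" (quadratic extrapolation).
#' @export
setClass("InfoEstimate",
  representation(resolutions = "integer", naive = "numeric", bias = "numeric",
                 corrected = "numeric", value = "numeric", method = "character"))

setValidity("InfoEstimate", function(object) {
  if (max(abs(object@corrected - (object@naive - object@bias))) > 1e-10)
    return("corrected must equal naive minus bias")
  TRUE
})

#' Cross-validation report
#'
#' @slot model model name.
#' @slot table per-fold data.frame with columns fold, ITrain, ITest, rTrain,
#'   rTest.
#' @slot summary named numeric: meanITest, seITest, meanRTest, seRTest,
#'   meanITrain, meanRTrain.
#' @export
setClass("EvalReport",
  representation(model = "character", table = "data.frame",
                 summary = "numeric"))

#' Leaky integrate-and-fire parameters
#'
#' Membrane potential is integrated as dV = dt/tauM * (-V + I) + noise, with
#' a spike emitted at V >= threshold, reset to vReset, and an absolute
#' refractory period.
#'
#' @slot tauM membrane time constant, ms.
#' @slot vRest,vReset,vThresh resting, reset and threshold potentials
#'   (dimensionless units; threshold > reset).
#' @slot refrac absolute refractory period, ms.
#' @slot dt integration step, ms.
#' @slot noiseSd standard deviation of the per-step Gaussian membrane noise.
#' @export
setClass("LIFParams",
  representation(tauM = "numeric", vRest = "numeric", vReset = "numeric",
                 vThresh = "numeric", refrac = "numeric", dt = "numeric",
                 noiseSd = "numeric"))

setValidity("LIFParams", function(object) {
  msg <- character()
  if (object@vThresh <= object@vReset)
    msg <- c(msg, "threshold must exceed reset")
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (length(msg)) msg else TRUE
})

#' Depressing synapse state
#'
#' Tsodyks-Markram style short-term depression: a presynaptic spike releases
#' weight * u * R and depletes the resource to R * (1 - u); between spikes
#' the resource recovers as dR/dt = (1 - R) / tauRec.
#'
#' @slot u release fraction per spike, in (0, 1].
#' @slot tauRec recovery time constant, ms.
#' @slot weight synaptic weight.
#' @slot R current resource level in [0, 1].
#' @export
setClass("DepressingSynapse",
  representation(u = "numeric", tauRec = "numeric", weight = "numeric",
                 R = "numeric"),
  prototype(R = 1))

setValidity("DepressingSynapse", function(object) {
  msg <- character()
  if (object@u <= 0 || object@u > 1) msg <- c(msg, "u must be in (0, 1]")
  if (object@R < 0 || object@R > 1) msg <- c(msg, "R must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Feedforward complex-cell network configuration
#'
#' Input LIF cells with one shared spatiotemporal RF template, each shifted
#' by one bar, drive an output LIF cell through excitatory (optionally
#' depressing) synapses.
#'
#' @slot nBars stimulus bars.
#' @slot positions center bar of each input cell's template.
#' @slot template spatial-by-temporal RF template (bars by frames); applied
#'   to the raw (-1/+1) stimulus.
#' @slot inputGain drive scaling for input cells.
#' @slot synWeight synaptic weight onto the output cell.
#' @slot depression logical; disable for constant-amplitude synapses.
#' @slot u,tauRec depression parameters (release fraction, recovery ms).
#' @slot lif [LIFParams-class] shared by all cells.
#' @export
setClass("NetworkConfig",
  representation(nBars = "integer", positions = "integer",
                 template = "matrix", inputGain = "numeric",
                 synWeight = "numeric", depression = "logical",
                 u = "numeric", tauRec = "numeric", lif = "LIFParams"))

setValidity("NetworkConfig", function(object) {
  half <- (nrow(object@template) - 1L) %/% 2L
  if (any(object@positions - half < 1L) ||
      any(object@positions + half > object@nBars))
    return("template must fit inside the bar range at every position")
  TRUE
})
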