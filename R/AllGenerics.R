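#' Similarity scores of a model on a design
#'
#' Projects every design row through the model to its (possibly
#' multidimensional) similarity score. For a [ContextModel-class] this is the
#' context-gated score
#' \deqn{z_i = w_0 + \sum_l \sum_{j \in ctx_l} w^{rf}_j x_{ij}
#'       (1 + \sum_k w^{cf_l}_k \tilde x_{ijk}),}
#' for a [FilterBank-class] the per-filter projections, and for a selected
#' [QNModel-class] the low-rank quadratic score.
#'
#' @param model a fitted model object.
#' @param design a [LaggedDesign-class].
#' @return numeric vector (one column models) or matrix of scores.
#' @export
setGeneric("similarityScores",
           function(model, design) standardGeneric("similarityScores"))

#' Number of model parameters
#'
#' Counts filter/field parameters, excluding the bias term and the
#' structurally fixed context-field origin, so that equal-complexity model
#' comparisons can be asserted.
#'
#' @param model a model object.
#' @return integer.
#' @export
setGeneric("parameterCount",
           function(model) standardGeneric("parameterCount"))

#' @rdname accessors
#' @export
setGeneric("spikeCounts", function(x) standardGeneric("spikeCounts"))

#' @rdname accessors
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' Accessors
#'
#' Small accessors for the package's containers.
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nBars", function(x) standardGeneric("nBars"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname accessors
#' @export
setMethod("spikeCounts", "StimulusEnsemble", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("spikeCounts", "LaggedDesign", function(x) x@y)

#' @rdname accessors
#' @export
setMethod("designMatrix", "LaggedDesign", function(x) x@X)

#' @rdname accessors
#' @export
setMethod("nBars", "StimulusEnsemble", function(x) nrow(x@frames))

#' @rdname accessors
#' @export
setMethod("nBars", "LaggedDesign", function(x) x@nBars)

#' @rdname accessors
#' @export
setMethod("nFrames", "StimulusEnsemble", function(x) ncol(x@frames))

#' @rdname accessors
#' @export
setMethod("frameRate", "StimulusEnsemble", function(x) x@frameRate)

#' @rdname accessors
#' @export
setMethod("frameRate", "LaggedDesign", function(x) x@frameRate)

#' Subset design rows
#'
#' @param x a [LaggedDesign-class].
#' @param i row indices.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "LaggedDesign", function(x, i, j, ..., drop = FALSE) {
  new("LaggedDesign", X = x@X[i, , drop = FALSE], y = x@y[i],
      frames = x@frames, nBars = x@nBars, nLags = x@nLags,
      sampleFrames = x@sampleFrames[i], frameRate = x@frameRate,
      basis = x@basis)
})

setMethod("show", "StimulusEnsemble", function(object) {
  cat(sprintf("StimulusEnsemble: %d bars x %d frames at %g Hz (basis '%s')\n",
              nrow(object@frames), ncol(object@frames), object@frameRate,
              object@basis))
  cat(sprintf("  total spikes: %d, mean rate %.3f per frame\n",
              as.integer(sum(object@counts)), mean(object@counts)))
})

setMethod("show", "LaggedDesign", function(object) {
  cat(sprintf("LaggedDesign: %d samples x %d (%d bars x %d lags), basis '%s'\n",
              nrow(object@X), ncol(object@X), object@nBars, object@nLags,
              object@basis))
})

setMethod("show", "ContextModel", function(object) {
  cat(sprintf("ContextModel: %d x %d RF, %d context field(s)\n",
              object@nBars, object@nLags, length(object@cfs)))
  for (cf in object@cfs)
    cat(sprintf("  CF %d x %d (origin %d,%d) gating %d RF elements\n",
                cf@spec@height, cf@spec@width, cf@spec@origin[1],
                cf@spec@origin[2], length(cf@rfAssignment)))
})

setMethod("show", "ContextFit", function(object) {
  cat(sprintf("ContextFit (%s): %d outer iterations, final loss %.6g%s\n",
              object@family, length(object@lossTrace),
              utils::tail(object@lossTrace, 1),
              if (object@flipped) ", sign-flipped" else ""))
  show(object@params)
})

setMethod("show", "FilterBank", function(object) {
  cat(sprintf("FilterBank (%s): %d filters of dimension %d\n",
              object@kind, ncol(object@filters), nrow(object@filters)))
})

setMethod("show", "QNModel", function(object) {
  cat(sprintf("QNModel: d = %d, %d selected filter(s)%s\n",
              length(object@v), ncol(object@filters),
              if (ncol(object@filters))
                sprintf(" [%s]", paste(object@sources, collapse = ", "))
              else ""))
})

setMethod("show", "InfoEstimate", function(object) {
  cat(sprintf("InfoEstimate (%s): %.4f bits (mean over %d resolutions)\n",
              object@method, object@value, length(object@resolutions)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport [%s]: I(test) = %.3f +/- %.3f bits, r(test) = %.3f\n",
              object@model, object@summary["meanITest"],
              object@summary["seITest"], object@summary["meanRTest"]))
})
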