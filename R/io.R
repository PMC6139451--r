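#' Read and write stimulus-response data as CSV
#'
#' The frame matrix is stored with one frame per column (bars as rows), the
#' counts as a single column; both without headers.
#'
#' @param ensemble a [StimulusEnsemble-class].
#' @param framesPath,countsPath CSV file paths.
#' @param frameRate,basis metadata for reading (CSV stores none).
#' @return \code{readStimulusCsv}: a [StimulusEnsemble-class].
#' @export
writeStimulusCsv <- function(ensemble, framesPath, countsPath) {
  utils::write.table(ensemble@frames, framesPath, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(ensemble@counts, countsPath, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(ensemble)
}

#' @rdname writeStimulusCsv
#' @export
readStimulusCsv <- function(framesPath, countsPath, frameRate = 60,
                            basis = "raw") {
  frames <- as.matrix(utils::read.csv(framesPath, header = FALSE))
  dimnames(frames) <- NULL
  counts <- utils::read.csv(countsPath, header = FALSE)[[1]]
  stimulusEnsemble(frames, counts = counts, frameRate = frameRate,
                   basis = basis)
}

#' Save or load a model as JSON
#'
#' Context models, filter banks, and quadratic models are serialized with
#' their geometry and an optional provenance record (family, regularization,
#' seed, and so on).
#'
#' @param model a [ContextModel-class], [FilterBank-class], or
#'   [QNModel-class].
#' @param path output file.
#' @param provenance named list stored alongside the parameters.
#' @return \code{loadModel}: the reconstructed model (provenance in
#'   attribute \code{provenance}).
#' @export
saveModel <- function(model, path, provenance = list()) {
  obj <- if (is(model, "ContextModel")) {
    list(type = "ContextModel", w0 = model@w0, rf = model@rf,
         nBars = model@nBars, nLags = model@nLags,
         rfBlocks = model@rfBlocks,
         cfs = lapply(model@cfs, function(cf) list(
           weights = as.vector(cf@weights),
           height = cf@spec@height, width = cf@spec@width,
           origin = cf@spec@origin, pad = cf@spec@pad,
           rfAssignment = cf@rfAssignment)))
  } else if (is(model, "FilterBank")) {
    list(type = "FilterBank", filters = as.vector(model@filters),
         d = nrow(model@filters), m = ncol(model@filters),
         values = model@values, kind = model@kind, center = model@center,
         scale = model@scale)
  } else if (is(model, "QNModel")) {
    list(type = "QNModel", intercept = model@intercept, v = model@v,
         J = as.vector(model@J), d = length(model@v),
         filters = as.vector(model@filters), m = ncol(model@filters),
         lambdas = model@lambdas, sources = model@sources)
  } else stop("unsupported model type")
  obj$provenance <- provenance
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  out <- switch(obj$type,
    ContextModel = {
      cfs <- lapply(obj$cfs, function(cf) {
        spec <- contextWindowSpec(cf$height, cf$width, cf$origin, cf$pad)
        contextField(spec, cf$rfAssignment,
                     matrix(cf$weights, cf$height, cf$width))
      })
      blocks <- if (is.matrix(obj$rfBlocks))
        lapply(seq_len(nrow(obj$rfBlocks)), function(i) obj$rfBlocks[i, ])
      else obj$rfBlocks
      contextModel(obj$nBars, obj$nLags, w0 = obj$w0, rf = obj$rf,
                   cfs = cfs, rfBlocks = blocks)
    },
    FilterBank = new("FilterBank",
                     filters = matrix(obj$filters, obj$d, obj$m),
                     values = as.numeric(obj$values %||% numeric(0)),
                     kind = obj$kind,
                     center = obj$center, scale = obj$scale),
    QNModel = new("QNModel", intercept = obj$intercept, v = obj$v,
                  J = matrix(obj$J, obj$d, obj$d),
                  filters = matrix(obj$filters %||% numeric(0), obj$d,
                                   obj$m %||% 0),
                  lambdas = as.numeric(obj$lambdas %||% numeric(0)),
                  sources = as.character(obj$sources %||% character(0))),
    stop("unknown model type in ", path))
  attr(out, "provenance") <- obj$provenance
  out
}
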