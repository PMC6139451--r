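#' Construct a stimulus-response ensemble
#'
#' @param frames bars-by-frames matrix; raw stimuli use -1 (dark) / +1
#'   (bright), basis-encoded stimuli 0/1.
#' @param counts per-frame spike counts (default all zero, for pure stimuli).
#' @param frameRate presentation rate, Hz.
#' @param basis alphabet tag; see [applyBasis()].
#' @return a [StimulusEnsemble-class].
#' @export
stimulusEnsemble <- function(frames, counts = rep(0, ncol(frames)),
                             frameRate = 60, basis = "raw") {
  new("StimulusEnsemble", frames = frames, counts = as.numeric(counts),
      frameRate = frameRate, basis = basis)
}

#' Re-encode a raw bar stimulus with intensity basis functions
#'
#' The bright basis codes a bright bar (+1) as 1 and a dark bar (-1) as 0;
#' the dark basis does the reverse. "bright+dark" stacks the dark encoding
#' under the bright one, doubling the bar dimension and producing a
#' space-time-intensity input on which dark and bright sensitivity can be
#' expressed separately. "raw" passes through.
#'
#' @param framesRaw matrix with entries in \{-1, +1\}, or a
#'   [StimulusEnsemble-class] with basis "raw".
#' @param basis "bright", "dark", "bright+dark" or "raw".
#' @return object of the same kind as the input, re-encoded.
#' @export
applyBasis <- function(framesRaw, basis = c("bright", "dark", "bright+dark",
                                            "raw")) {
  basis <- match.arg(basis)
  if (is(framesRaw, "StimulusEnsemble")) {
    out <- applyBasis(framesRaw@frames, basis)
    return(new("StimulusEnsemble", frames = out, counts = framesRaw@counts,
               frameRate = framesRaw@frameRate, basis = basis))
  }
  if (!all(framesRaw %in% c(-1, 1)))
    stop("raw frames must be coded -1 (dark) / +1 (bright)")
  switch(basis,
         raw = framesRaw,
         bright = (framesRaw + 1) / 2,
         dark = (1 - framesRaw) / 2,
         `bright+dark` = rbind((framesRaw + 1) / 2, (1 - framesRaw) / 2))
}

#' Build the lagged design matrix
#'
#' Slides a bars-by-\code{nLags} window over the frame matrix. Row \code{i}
#' covers frames \code{i .. i + nLags - 1}, flattened column-major (bars vary
#' fastest within each lag block; the most recent frame is the last block)
#' and is paired with the spike count at the window's last frame. Frames with
#' incomplete history are dropped, giving \code{nFrames - nLags + 1} rows.
#'
#' @param ensemble a [StimulusEnsemble-class].
#' @param nLags window length in frames.
#' @return a [LaggedDesign-class].
#' @export
buildLaggedDesign <- function(ensemble, nLags) {
  S <- ensemble@frames
  nLags <- as.integer(nLags)
  nb <- nrow(S); nf <- ncol(S)
  if (nLags > nf) stop("nLags exceeds the number of frames")
  n <- nf - nLags + 1L
  sampleFrames <- seq.int(nLags, nf)
  X <- laggedFromFrames(S, nLags, sampleFrames)
  new("LaggedDesign", X = X, y = ensemble@counts[sampleFrames], frames = S,
      nBars = nb, nLags = nLags, sampleFrames = sampleFrames,
      frameRate = ensemble@frameRate, basis = ensemble@basis)
}

## Rows of the lagged design for arbitrary window-end frames.
laggedFromFrames <- function(S, nLags, sampleFrames) {
  laggedRowsCpp(S, as.integer(nLags), as.integer(sampleFrames))
}

#' Context-window specification
#'
#' @param height,width window extent in bars and lags.
#' @param origin integer (row, col) of the origin cell; defaults to the
#'   spatially centered row and the column three elements from the right
#'   edge (leaving two lags of future context to the right of the origin).
#' @param pad value used outside the stimulus bounds.
#' @return a [ContextWindowSpec-class].
#' @export
contextWindowSpec <- function(height = 9, width = 9,
                              origin = c((height + 1) %/% 2,
                                         max(1, width - 2)),
                              pad = 0) {
  new("ContextWindowSpec", height = as.integer(height),
      width = as.integer(width), origin = as.integer(origin), pad = pad)
}

#' Extract the context vector around one window element
#'
#' Returns the window-sized stimulus patch positioned so that the window's
#' origin coincides with the addressed element of the addressed sample.
#' Cells outside the stimulus take the window's pad value. The origin cell
#' itself is part of the returned patch but its coefficient in any context
#' field is fixed at zero, so it never contributes to a score.
#'
#' @param ensemble a [StimulusEnsemble-class] (or [LaggedDesign-class]).
#' @param sampleIndex design row index (window ending at frame
#'   \code{sampleIndex + nLags - 1}).
#' @param elementIndex flattened (bar, lag) index within the sample's window.
#' @param window a [ContextWindowSpec-class].
#' @param nLags window length used to build the design (taken from the
#'   design when one is supplied).
#' @return numeric vector of length height * width, flattened column-major.
#' @export
extractContextVector <- function(ensemble, sampleIndex, elementIndex, window,
                                 nLags = NULL) {
  if (is(ensemble, "LaggedDesign")) {
    S <- ensemble@frames; nb <- ensemble@nBars; nLags <- ensemble@nLags
    lastFrame <- ensemble@sampleFrames[sampleIndex]
  } else {
    S <- ensemble@frames; nb <- nrow(S)
    if (is.null(nLags)) stop("nLags required with a StimulusEnsemble")
    lastFrame <- sampleIndex + nLags - 1L
  }
  if (elementIndex < 1L || elementIndex > nb * nLags)
    stop("elementIndex outside the sample window")
  bar <- (elementIndex - 1L) %% nb + 1L
  lag <- (elementIndex - 1L) %/% nb + 1L
  frame <- lastFrame - nLags + lag
  if (is.na(frame) || frame < 1L || frame > ncol(S))
    stop("sampleIndex outside the design")
  rows <- bar + seq_len(window@height) - window@origin[1]
  cols <- frame + seq_len(window@width) - window@origin[2]
  patch <- matrix(window@pad, window@height, window@width)
  okR <- rows >= 1L & rows <= nb
  okC <- cols >= 1L & cols <= ncol(S)
  patch[okR, okC] <- S[rows[okR], cols[okC], drop = FALSE]
  as.vector(patch)
}

## Stimulus-wide cross-correlation with a context field: M[b, f] equals the
## dot product between the field and the patch centered (at the field origin)
## on stimulus cell (b, f). Out-of-bounds cells contribute pad (zero).
contextMap <- function(S, cf) {
  sp <- cf@spec
  W <- cf@weights
  nb <- nrow(S); nf <- ncol(S)
  M <- matrix(0, nb, nf)
  nz <- which(W != 0, arr.ind = TRUE)
  for (q in seq_len(nrow(nz))) {
    r <- nz[q, 1]; cc <- nz[q, 2]
    dr <- r - sp@origin[1]; dc <- cc - sp@origin[2]
    bs <- max(1L, 1L - dr):min(nb, nb - dr)   # destination rows
    fs <- max(1L, 1L - dc):min(nf, nf - dc)   # destination cols
    M[bs, fs] <- M[bs, fs] + W[r, cc] * S[bs + dr, fs + dc, drop = FALSE]
  }
  if (sp@pad != 0) {
    ## non-zero padding adds a border-dependent constant; handled explicitly
    ones <- matrix(1, nb, nf)
    Mpad <- matrix(0, nb, nf)
    for (q in seq_len(nrow(nz))) {
      r <- nz[q, 1]; cc <- nz[q, 2]
      dr <- r - sp@origin[1]; dc <- cc - sp@origin[2]
      inb <- matrix(0, nb, nf)
      bs <- max(1L, 1L - dr):min(nb, nb - dr)
      fs <- max(1L, 1L - dc):min(nf, nf - dc)
      inb[bs, fs] <- 1
      Mpad <- Mpad + W[r, cc] * (ones - inb)
    }
    M <- M + sp@pad * Mpad
  }
  M
}
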