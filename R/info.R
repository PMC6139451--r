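## Bin assignment with shared edges; out-of-range values clamp to edge bins.
binIndex <- function(z, edges) {
  b <- findInterval(z, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(b, 1L), length(edges) - 1L)
}

makeEdges <- function(z, bins) {
  lo <- min(z); hi <- max(z)
  if (hi <= lo) c(lo - 0.5, lo + 0.5)
  else seq(lo, hi, length.out = bins + 1L)
}

#' Histogram the similarity scores of all frames and of spike events
#'
#' \code{pZ} weights every sample equally; \code{pZSpike} weights sample i by
#' its spike count. Both use shared edges spanning the observed score range.
#' A constant score occupies a single bin (and carries zero information).
#'
#' @param z score vector, or a matrix with at most two columns.
#' @param counts per-sample spike counts; their sum must be positive.
#' @param bins bins per dimension.
#' @return a [ScoreDistribution-class].
#' @export
scoreDistribution <- function(z, counts, bins = 20) {
  z <- as.matrix(z)
  if (ncol(z) > 2L)
    stop("histogram estimation supports at most two score dimensions")
  if (sum(counts) <= 0) stop("no spikes: cannot form P(z | spike)")
  n <- nrow(z)
  edges <- lapply(seq_len(ncol(z)), function(j) makeEdges(z[, j], bins))
  nb <- vapply(edges, function(e) length(e) - 1L, 1L)
  idx <- binIndex(z[, 1], edges[[1]])
  if (ncol(z) == 2L)
    idx <- idx + (binIndex(z[, 2], edges[[2]]) - 1L) * nb[1]
  total <- prod(nb)
  pz <- tabulate(idx, total) / n
  w <- counts / sum(counts)
  pzs <- numeric(total)
  agg <- rowsum(w, idx)
  pzs[as.integer(rownames(agg))] <- agg
  dm <- if (ncol(z) == 2L) nb else nb[1]
  new("ScoreDistribution", edges = edges, pZ = array(pz, dm),
      pZSpike = array(pzs, dm), pSpike = mean(counts))
}

#' Single-spike information of a score distribution
#'
#' \deqn{I = \sum_b P(z_b | spike) \log_2 \frac{P(z_b | spike)}{P(z_b)}}
#' in bits; bins with zero spike-conditional mass contribute nothing. Any bin
#' with spike mass necessarily has marginal mass (spike samples are a subset
#' of all samples); this is asserted.
#'
#' @param dist a [ScoreDistribution-class].
#' @return bits.
#' @export
singleSpikeInfo <- function(dist) {
  pz <- as.vector(dist@pZ)
  pzs <- as.vector(dist@pZSpike)
  occ <- pzs > 0
  stopifnot(all(pz[occ] > 0))
  sum(pzs[occ] * log2(pzs[occ] / pz[occ]))
}

#' Average number of occupied histogram bins
#'
#' The mean of the nonzero-bin counts of P(z) and P(z | spike); the
#' abscissa of the finite-sample bias curve.
#'
#' @param dist a [ScoreDistribution-class].
#' @return numeric.
#' @export
effectiveBins <- function(dist) {
  mean(c(sum(dist@pZ > 0), sum(dist@pZSpike > 0)))
}

## Shared core of the information gradient: one score dimension.
## R: n x p matrix whose row i is the gradient of z_i w.r.t. the parameters.
infoGradCore1 <- function(z, counts, R, bins) {
  edges <- makeEdges(z, bins)
  nb <- length(edges) - 1L
  b <- binIndex(z, edges)
  n <- length(z)
  pz <- tabulate(b, nb) / n
  pzs <- numeric(nb)
  agg <- rowsum(counts / sum(counts), b)
  pzs[as.integer(rownames(agg))] <- agg
  ratio <- ifelse(pz > 0, pzs / pz, 0)
  delta <- if (nb > 1L) diff(edges)[1] else 1
  dr <- numeric(nb)
  if (nb >= 3L) dr[2:(nb - 1)] <- (ratio[3:nb] - ratio[1:(nb - 2)]) /
    (2 * delta)
  if (nb >= 2L) {
    dr[1] <- (ratio[2] - ratio[1]) / delta
    dr[nb] <- (ratio[nb] - ratio[nb - 1]) / delta
  }
  p <- ncol(R)
  M <- matrix(0, nb, p); MS <- matrix(0, nb, p)
  cnt <- tabulate(b, nb)
  spw <- numeric(nb)
  aggS <- rowsum(counts, b)
  spw[as.integer(rownames(aggS))] <- aggS
  aggM <- rowsum(R, b)
  M[as.integer(rownames(aggM)), ] <- aggM
  aggMS <- rowsum(R * counts, b)
  MS[as.integer(rownames(aggMS)), ] <- aggMS
  occ <- cnt > 0
  M[occ, ] <- M[occ, , drop = FALSE] / cnt[occ]
  sp <- spw > 0
  MS[sp, ] <- MS[sp, , drop = FALSE] / spw[sp]
  MS[!sp, ] <- M[!sp, , drop = FALSE]  # no spikes: zero contribution
  drop(crossprod(pz * dr * occ, MS - M)) / log(2)
}

## Two score dimensions; Rlist gives the per-dimension gradient rows.
## Returns a list of parameter gradients, one per dimension.
infoGradCore2 <- function(z, counts, Rlist, bins) {
  edges <- lapply(1:2, function(j) makeEdges(z[, j], bins))
  nb <- vapply(edges, function(e) length(e) - 1L, 1L)
  b1 <- binIndex(z[, 1], edges[[1]])
  b2 <- binIndex(z[, 2], edges[[2]])
  id <- b1 + (b2 - 1L) * nb[1]
  n <- nrow(z)
  total <- prod(nb)
  pz <- tabulate(id, total) / n
  pzs <- numeric(total)
  agg <- rowsum(counts / sum(counts), id)
  pzs[as.integer(rownames(agg))] <- agg
  ratio <- matrix(ifelse(pz > 0, pzs / pz, 0), nb[1], nb[2])
  deltas <- vapply(edges, function(e) if (length(e) > 2) diff(e)[1] else 1, 1)
  dr1 <- matrix(0, nb[1], nb[2]); dr2 <- dr1
  if (nb[1] >= 3L)
    dr1[2:(nb[1] - 1), ] <- (ratio[3:nb[1], ] - ratio[1:(nb[1] - 2), ]) /
      (2 * deltas[1])
  if (nb[1] >= 2L) {
    dr1[1, ] <- (ratio[2, ] - ratio[1, ]) / deltas[1]
    dr1[nb[1], ] <- (ratio[nb[1], ] - ratio[nb[1] - 1, ]) / deltas[1]
  }
  if (nb[2] >= 3L)
    dr2[, 2:(nb[2] - 1)] <- (ratio[, 3:nb[2]] - ratio[, 1:(nb[2] - 2)]) /
      (2 * deltas[2])
  if (nb[2] >= 2L) {
    dr2[, 1] <- (ratio[, 2] - ratio[, 1]) / deltas[2]
    dr2[, nb[2]] <- (ratio[, nb[2]] - ratio[, nb[2] - 1]) / deltas[2]
  }
  cnt <- tabulate(id, total)
  spw <- numeric(total)
  aggS <- rowsum(counts, id)
  spw[as.integer(rownames(aggS))] <- aggS
  occ <- cnt > 0
  lapply(seq_along(Rlist), function(j) {
    R <- Rlist[[j]]
    M <- matrix(0, total, ncol(R)); MS <- M
    aggM <- rowsum(R, id)
    M[as.integer(rownames(aggM)), ] <- aggM
    aggMS <- rowsum(R * counts, id)
    MS[as.integer(rownames(aggMS)), ] <- aggMS
    M[occ, ] <- M[occ, , drop = FALSE] / cnt[occ]
    sp <- spw > 0
    MS[sp, ] <- MS[sp, , drop = FALSE] / spw[sp]
    MS[!sp, ] <- M[!sp, , drop = FALSE]
    dr <- as.vector(if (j == 1L) dr1 else dr2)
    drop(crossprod(pz * dr * occ, MS - M)) / log(2)
  })
}

#' Gradient of the single-spike information
#'
#' Bin-wise estimate of
#' \deqn{\nabla I = \int \frac{P(z)}{\ln 2}
#'   \left[\langle\nabla z | z, spike\rangle - \langle\nabla z | z\rangle
#'   \right] \frac{d}{dz}\frac{P(z|spike)}{P(z)} \, dz,}
#' with the ratio derivative approximated by finite differences across bins
#' and conditional mean gradients computed per bin. For a filter bank the
#' score gradient per filter is the (standardized) stimulus itself; for a
#' context model it is the RF/CF design rows. Empty bins are skipped.
#'
#' @param model a [FilterBank-class] or [ContextModel-class].
#' @param design a [LaggedDesign-class].
#' @param counts spike counts (from the design when omitted).
#' @param bins histogram resolution used for the gradient.
#' @return for a filter bank, a matrix shaped like the filters; for a context
#'   model, a list with elements \code{rf} (vector) and \code{cfs} (list of
#'   weight matrices with zero origin).
#' @export
infoGradient <- function(model, design, counts = NULL, bins = 15) {
  y <- if (is.null(counts)) design@y else counts
  if (is(model, "FilterBank")) {
    z <- projectDesign(model, design@X)
    Xs <- design@X
    if (length(model@center)) Xs <- sweep(Xs, 2, model@center)
    if (length(model@scale)) Xs <- sweep(Xs, 2, model@scale, "/")
    if (ncol(z) == 1L) {
      g <- infoGradCore1(z[, 1], y, Xs, bins)
      return(matrix(g, ncol = 1))
    }
    if (ncol(z) > 2L) stop("histogram gradients support at most two filters")
    gl <- infoGradCore2(z, y, list(Xs, Xs), bins)
    return(cbind(gl[[1]], gl[[2]]))
  }
  if (is(model, "ContextModel")) {
    z <- similarityScores(model, design)
    Arf <- rfDesignRows(model, design)
    blocks <- list(rf = Arf)
    for (l in seq_along(model@cfs))
      blocks[[length(blocks) + 1L]] <- cfDesignRows(model, design, l)
    R <- do.call(cbind, blocks)
    g <- infoGradCore1(z, y, R, bins)
    d <- length(model@rf)
    out <- list(rf = g[seq_len(d)], cfs = list())
    at <- d
    for (l in seq_along(model@cfs)) {
      sp <- model@cfs[[l]]@spec
      k <- sp@height * sp@width
      gm <- matrix(g[at + seq_len(k)], sp@height, sp@width)
      gm[sp@origin[1], sp@origin[2]] <- 0  # origin stays structurally zero
      out$cfs[[l]] <- gm
      at <- at + k
    }
    return(out)
  }
  stop("unsupported model type")
}

## Flatten / apply parameter updates for midAscent.
midTheta <- function(model) {
  if (is(model, "FilterBank")) return(as.vector(model@filters))
  c(model@rf, unlist(lapply(model@cfs, function(cf) as.vector(cf@weights))))
}
midApply <- function(model, theta) {
  if (is(model, "FilterBank")) {
    B <- matrix(theta, nrow(model@filters), ncol(model@filters))
    nrm <- sqrt(colSums(B^2))
    nrm[nrm == 0] <- 1
    model@filters <- sweep(B, 2, nrm, "/")
    model@kind <- "mid"
    return(model)
  }
  d <- length(model@rf)
  model@rf <- theta[seq_len(d)]
  at <- d
  for (l in seq_along(model@cfs)) {
    sp <- model@cfs[[l]]@spec
    k <- sp@height * sp@width
    W <- matrix(theta[at + seq_len(k)], sp@height, sp@width)
    W[sp@origin[1], sp@origin[2]] <- 0
    model@cfs[[l]]@weights <- W
    at <- at + k
  }
  model
}
midGradVec <- function(model, design, bins) {
  g <- infoGradient(model, design, bins = bins)
  if (is(model, "FilterBank")) return(as.vector(g))
  c(g$rf, unlist(lapply(g$cfs, as.vector)))
}

#' Maximally informative refinement by gradient ascent on information
#'
#' Refines an initial model (filter bank or context model) by ascending the
#' single-spike information of its training scores, with early stopping on a
#' validation set: the returned model is the iterate (including the
#' initialization) with the highest validation information, so refinement is
#' never worse than the starting point by that measure. Step length is
#' \code{stepSize * ||theta|| / ||gradient||} with geometric backoff whenever
#' a step would lower the training information.
#'
#' @param model initial [FilterBank-class] (at most two filters) or
#'   [ContextModel-class].
#' @param designTrain,designVal training and validation
#'   [LaggedDesign-class] data.
#' @param bins ascent histogram resolution (coarser than evaluation to tame
#'   gradient noise).
#' @param stepSize relative step length.
#' @param maxSteps ascent cap.
#' @param evalBins resolution used for the train/validation information
#'   bookkeeping.
#' @return refined model of the same class, with attributes
#'   \code{trainInfo} and \code{valInfo}.
#' @export
midAscent <- function(model, designTrain, designVal, bins = 15,
                      stepSize = 0.05, maxSteps = 200, evalBins = bins) {
  infoOf <- function(m, design) {
    z <- if (is(m, "FilterBank")) similarityScores(m, design)
         else similarityScores(m, design)
    singleSpikeInfo(scoreDistribution(z, design@y, evalBins))
  }
  cur <- model
  trainI <- infoOf(cur, designTrain)
  best <- list(model = cur, val = infoOf(cur, designVal))
  for (it in seq_len(maxSteps)) {
    g <- midGradVec(cur, designTrain, bins)
    gn <- sqrt(sum(g^2))
    if (!is.finite(gn)) stop("non-finite information gradient")
    if (gn < 1e-12) break
    th <- midTheta(cur)
    alpha <- stepSize * max(sqrt(sum(th^2)), 1e-8) / gn
    ok <- FALSE
    for (bt in 1:12) {
      cand <- midApply(cur, th + alpha * g)
      tI <- infoOf(cand, designTrain)
      if (tI >= trainI - 1e-12) { ok <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!ok) break
    cur <- cand
    trainI <- tI
    val <- infoOf(cur, designVal)
    if (val > best$val) best <- list(model = cur, val = val)
  }
  out <- best$model
  attr(out, "trainInfo") <- infoOf(out, designTrain)
  attr(out, "valInfo") <- best$val
  out
}
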