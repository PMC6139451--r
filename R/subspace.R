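#' Spike-triggered average and covariance
#'
#' Count-weighted moments of the spike-eliciting design rows: each sample
#' contributes \code{y_i} times, so
#' \deqn{\mu = \frac{1}{N_{spikes}} \sum_i y_i x_i, \qquad
#'       \Lambda = \frac{1}{N_{spikes}} \sum_i y_i (x_i - \mu)(x_i - \mu)'.}
#' Spike-triggered analyses assume a whitened, mean-centered stimulus; use
#' \code{center/scale} (the default standardizes, which whitens i.i.d. binary
#' bars exactly) or pass \code{center = FALSE, scale = FALSE} for raw
#' moments.
#'
#' @param design a [LaggedDesign-class], or a plain design matrix.
#' @param counts spike counts (taken from the design when omitted).
#' @param center,scale standardize columns before computing moments (logical,
#'   or explicit numeric vectors).
#' @return a [SpikeTriggeredStats-class]; the standardization used is
#'   attached as attributes \code{center} and \code{scale}.
#' @export
spikeTriggeredStats <- function(design, counts = NULL, center = TRUE,
                                scale = TRUE) {
  X <- if (is(design, "LaggedDesign")) design@X else design
  y <- if (is.null(counts)) design@y else counts
  if (sum(y) <= 0) stop("cannot form spike-triggered statistics: no spikes")
  ctr <- if (isTRUE(center)) colMeans(X) else if (isFALSE(center))
    rep(0, ncol(X)) else center
  scl <- if (isTRUE(scale)) {
    s <- sqrt(colMeans(X^2) - colMeans(X)^2)
    ifelse(s > 0, s, 1)
  } else if (isFALSE(scale)) rep(1, ncol(X)) else scale
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  nSpikes <- sum(y)
  mu <- drop(crossprod(Xs, y)) / nSpikes
  Xc <- sweep(Xs, 2, mu)
  Lam <- crossprod(Xc * sqrt(y)) / nSpikes
  Lam <- (Lam + t(Lam)) / 2
  v <- colMeans(Xs^2) - colMeans(Xs)^2
  out <- new("SpikeTriggeredStats", sta = mu, stc = Lam, nSpikes = nSpikes,
             stimulusVariance = v)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

## Rank STC eigenvectors by |eigenvalue - stimulus variance|.
stcRanked <- function(stats, decreasing) {
  e <- eigen(stats@stc, symmetric = TRUE)
  dev <- abs(e$values - mean(stats@stimulusVariance))
  ord <- order(dev, decreasing = decreasing)
  list(vectors = e$vectors[, ord, drop = FALSE], values = e$values[ord])
}

#' STC filters and null features
#'
#' \code{stcFilters} returns the \code{n} eigenvectors of the STC matrix
#' whose eigenvalues deviate most from the stimulus variance (capturing both
#' excitatory, eigenvalue much larger, and suppressive, much smaller,
#' directions). \code{nullFilters} returns the \code{n} eigenvectors with
#' eigenvalues closest to the stimulus variance; they carry no
#' stimulus-response information and are used to estimate the histogram
#' information bias.
#'
#' @param stats a [SpikeTriggeredStats-class].
#' @param n number of filters.
#' @return a [FilterBank-class] with the eigenvalues in \code{values}.
#' @export
stcFilters <- function(stats, n) {
  d <- nrow(stats@stc)
  if (n > d) stop("cannot extract more filters than dimensions")
  r <- stcRanked(stats, decreasing = TRUE)
  new("FilterBank", filters = r$vectors[, seq_len(n), drop = FALSE],
      values = r$values[seq_len(n)], kind = "stc",
      center = attr(stats, "center") %||% 0,
      scale = attr(stats, "scale") %||% 1)
}

#' @rdname stcFilters
#' @export
nullFilters <- function(stats, n) {
  d <- nrow(stats@stc)
  if (n > d) stop("cannot extract more filters than dimensions")
  r <- stcRanked(stats, decreasing = FALSE)
  new("FilterBank", filters = r$vectors[, seq_len(n), drop = FALSE],
      values = r$values[seq_len(n)], kind = "null",
      center = attr(stats, "center") %||% 0,
      scale = attr(stats, "scale") %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn similarityScores per-filter projections of the (standardized)
#'   design rows; a matrix with one column per filter.
#' @export
setMethod("similarityScores", signature("FilterBank", "LaggedDesign"),
  function(model, design) {
    projectDesign(model, design@X)
  })

projectDesign <- function(bank, X) {
  Xs <- X
  if (length(bank@center)) Xs <- sweep(Xs, 2, bank@center)
  if (length(bank@scale)) Xs <- sweep(Xs, 2, bank@scale, "/")
  Xs %*% bank@filters
}

#' Gaussian information of a subspace (iSTAC objective)
#'
#' Under a whitened Gaussian stimulus and a Gaussian spike-triggered
#' ensemble, the single-spike information carried by the subspace spanned by
#' the orthonormal columns of \code{B} is
#' \deqn{I(B) = \frac{Tr(B'(\Lambda + \mu\mu')B) - \ln|B'\Lambda B| - m}
#'       {2 \ln 2}}
#' bits -- the KL divergence between N(B'mu, B'Lambda B) and the N(0, I)
#' prior. The analytic gradient is
#' \eqn{\nabla I = ((\Lambda + \mu\mu')B - \Lambda B (B'\Lambda B)^{-1}) /
#' \ln 2}.
#'
#' @param B matrix with orthonormal columns.
#' @param stats a [SpikeTriggeredStats-class] (from a whitened design).
#' @return bits (objective) or a gradient matrix of the shape of \code{B}.
#' @export
istacObjective <- function(B, stats) {
  B <- as.matrix(B)
  m <- ncol(B)
  M <- stats@stc + tcrossprod(stats@sta)
  S <- crossprod(B, stats@stc %*% B)
  ld <- determinant(S, logarithm = TRUE)
  if (ld$sign <= 0) stop("B' Lambda B is singular")
  (sum(diag(crossprod(B, M %*% B))) - as.numeric(ld$modulus) - m) /
    (2 * log(2))
}

#' @rdname istacObjective
#' @export
istacGradient <- function(B, stats) {
  B <- as.matrix(B)
  M <- stats@stc + tcrossprod(stats@sta)
  S <- crossprod(B, stats@stc %*% B)
  (M %*% B - stats@stc %*% B %*% solve(S)) / log(2)
}

## Orthonormalize v against the columns of B (Gram-Schmidt) and normalize.
orthoTo <- function(v, B) {
  if (!is.null(B) && ncol(B)) v <- v - B %*% crossprod(B, v)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(NULL)
  v / nv
}

#' Greedy iSTAC subspace search
#'
#' Adds filters one at a time: each new column is initialized from the best
#' of the STA direction and the leading STC eigenvectors (orthonormalized
#' against the filters found so far) and optimized by projected gradient
#' ascent with re-orthonormalization. Columns are ordered by their marginal
#' information contribution, stored in \code{values} (bits).
#'
#' @param stats a [SpikeTriggeredStats-class] from an (approximately)
#'   whitened design; a warning is raised when the ensemble variance is far
#'   from one.
#' @param m number of filters.
#' @param maxSteps,tol ascent cap and improvement tolerance per column.
#' @return a [FilterBank-class] of kind "istac".
#' @export
istacFit <- function(stats, m, maxSteps = 500, tol = 1e-6) {
  d <- length(stats@sta)
  if (mean(abs(stats@stimulusVariance - 1)) > 0.2)
    warning("design does not look whitened; iSTAC assumes unit variance")
  ranked <- stcRanked(stats, decreasing = TRUE)
  B <- NULL
  info <- numeric(0)
  prevObj <- 0
  for (j in seq_len(m)) {
    cands <- list()
    sta <- orthoTo(stats@sta, B)
    if (!is.null(sta)) cands <- c(cands, list(sta))
    for (q in seq_len(min(5, ncol(ranked$vectors)))) {
      v <- orthoTo(ranked$vectors[, q], B)
      if (!is.null(v)) cands <- c(cands, list(v))
    }
    objs <- vapply(cands, function(v) istacObjective(cbind(B, v), stats), 1)
    b <- cands[[which.max(objs)]]
    obj <- max(objs)
    step <- 0.1
    for (it in seq_len(maxSteps)) {
      G <- istacGradient(cbind(B, b), stats)
      g <- G[, ncol(G)]
      bNew <- orthoTo(b + step * g, B)
      if (is.null(bNew)) break
      objNew <- istacObjective(cbind(B, bNew), stats)
      if (objNew > obj) {
        if (objNew - obj < tol) { b <- bNew; obj <- objNew; break }
        b <- bNew; obj <- objNew
        step <- step * 1.2
      } else {
        step <- step / 2
        if (step < 1e-10) break
      }
    }
    B <- cbind(B, b)
    info <- c(info, obj - prevObj)
    prevObj <- obj
  }
  new("FilterBank", filters = B, values = info, kind = "istac",
      center = attr(stats, "center") %||% 0,
      scale = attr(stats, "scale") %||% 1)
}
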