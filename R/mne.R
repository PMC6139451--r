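#' Fit a quadratic-nonlinear model by maximum noise entropy
#'
#' Logistic model of spiking with linear and quadratic stimulus terms,
#' \eqn{z_i = c + x_i'v + x_i' J x_i}, fitted by minimizing the weighted
#' logistic loss (signed targets, multi-spike samples weighted by their
#' count) with an l2 penalty on v and J. Matching the mean rate and the
#' first- and second-order stimulus-response correlations is equivalent to
#' this maximum-likelihood problem. Quadratic features are formed on the fly
#' inside the objective and gradient -- the N x d^2 feature matrix is never
#' materialized -- and optimization uses L-BFGS with the analytic gradient.
#' J is returned exactly symmetric (scores are invariant under
#' symmetrization).
#'
#' @param design a [LaggedDesign-class] or design matrix.
#' @param counts spike counts (from the design when omitted).
#' @param C regularization strength on the data term.
#' @param maxit L-BFGS iteration cap.
#' @return a [QNModel-class] with empty filter selection.
#' @export
mneFit <- function(design, counts = NULL, C = 1, maxit = 500) {
  X <- if (is(design, "LaggedDesign")) design@X else design
  y <- if (is.null(counts)) design@y else counts
  n <- nrow(X); d <- ncol(X)
  yt <- ifelse(y == 0, -1, 1)
  beta <- pmax(y, 1)
  unpack <- function(th) {
    list(c = th[1], v = th[1 + seq_len(d)],
         J = matrix(th[-seq_len(1 + d)], d, d))
  }
  scoreOf <- function(p) p$c + drop(X %*% p$v) + rowSums((X %*% p$J) * X)
  fn <- function(th) {
    p <- unpack(th)
    z <- scoreOf(p)
    C * sum(beta * log1pexp(-yt * z)) + 0.5 * (sum(p$v^2) + sum(p$J^2))
  }
  gr <- function(th) {
    p <- unpack(th)
    z <- scoreOf(p)
    r <- C * beta * (stats::plogis(yt * z) - 1) * yt
    gJ <- crossprod(X, X * r)
    c(sum(r), drop(crossprod(X, r)) + p$v, as.vector(gJ) + as.vector(p$J))
  }
  th0 <- numeric(1 + d + d * d)
  opt <- stats::optim(th0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  p <- unpack(opt$par)
  J <- (p$J + t(p$J)) / 2
  new("QNModel", intercept = p$c, v = p$v, J = J,
      filters = matrix(0, d, 0), lambdas = numeric(0),
      sources = character(0))
}

## Low-rank quadratic score from selected filters:
## z = intercept + sum_{m: J} lambda_m (x'w_m)^2 + sum_{m: v} lambda_m (x'w_m)
qnScore <- function(model, X) {
  z <- rep(model@intercept, nrow(X))
  if (!ncol(model@filters)) {
    return(z + drop(X %*% model@v) + rowSums((X %*% model@J) * X))
  }
  P <- X %*% model@filters
  for (m in seq_along(model@lambdas)) {
    z <- z + if (model@sources[m] == "J") model@lambdas[m] * P[, m]^2
             else model@lambdas[m] * P[, m]
  }
  z
}

#' @describeIn similarityScores low-rank quadratic score (or the full
#'   quadratic form before selection).
#' @export
setMethod("similarityScores", signature("QNModel", "LaggedDesign"),
  function(model, design) qnScore(model, design@X))

#' Select low-rank filters from a fitted quadratic model
#'
#' Takes the \code{nFilters - 1} eigenvectors of J with the largest absolute
#' eigenvalues, projects them out of v, and chooses the final filter as
#' either the v-residual or the next eigenvector -- whichever yields the
#' higher single-spike information of the resulting score.
#'
#' @param model a [QNModel-class] from [mneFit()].
#' @param nFilters number of filters to retain (>= 1).
#' @param design,counts data used to score the two candidates.
#' @param infoFn function(z, counts) returning information; defaults to the
#'   naive histogram single-spike information at 20 bins.
#' @return a [QNModel-class] with \code{filters}, \code{lambdas},
#'   \code{sources} filled in.
#' @export
lowrankSelect <- function(model, nFilters, design, counts = NULL,
                          infoFn = NULL) {
  if (nFilters < 1) stop("nFilters must be at least 1")
  X <- if (is(design, "LaggedDesign")) design@X else design
  y <- if (is.null(counts)) design@y else counts
  if (is.null(infoFn))
    infoFn <- function(z, yy) singleSpikeInfo(scoreDistribution(z, yy, 20))
  e <- eigen(model@J, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)
  keep <- ord[seq_len(nFilters - 1)]
  B <- e$vectors[, keep, drop = FALSE]
  lam <- e$values[keep]
  vres <- model@v
  if (ncol(B)) vres <- vres - drop(B %*% crossprod(B, model@v))
  vn <- sqrt(sum(vres^2))

  candidate <- function(filters, lambdas, sources) {
    m <- model
    m@filters <- filters; m@lambdas <- lambdas; m@sources <- sources
    m
  }
  cands <- list()
  if (vn > 1e-12)
    cands$v <- candidate(cbind(B, vres / vn), c(lam, vn),
                         c(rep("J", ncol(B)), "v"))
  nxt <- ord[nFilters]
  if (!is.na(nxt))
    cands$J <- candidate(cbind(B, e$vectors[, nxt]), c(lam, e$values[nxt]),
                         c(rep("J", ncol(B)), "J"))
  if (!length(cands)) stop("no candidate final filter available")
  infos <- vapply(cands, function(m) infoFn(qnScore(m, X), y), 1)
  cands[[which.max(infos)]]
}

#' Refine selected low-rank filters by gradient descent
#'
#' Gradient descent on the weighted logistic loss of the low-rank score,
#' using
#' \eqn{\nabla L(w_v) = \Gamma'\Gamma w_v + C \sum_i \beta_i
#' [\sigma(\tilde y_i z_i) - 1] \tilde y_i x_i} and
#' \eqn{\nabla L(w_{m,J}) = \Gamma'\Gamma w_{m,J} + C \sum_i \beta_i
#' [\sigma(\tilde y_i z_i) - 1] \tilde y_i\, 2 \lambda_m (x_i'w_{m,J}) x_i}
#' with \eqn{\Gamma = I}. The regularization strength and the stopping point
#' are chosen on a hold-out validation set; each accepted step does not
#' increase the training loss (backtracking line search). If no refinement
#' improves the validation loss the pre-refinement model is returned with
#' attribute \code{refined = FALSE}. The intercept is kept fixed.
#'
#' @param model a selected [QNModel-class] (from [lowrankSelect()]).
#' @param design,counts training data.
#' @param validation list(design=, counts=) hold-out data.
#' @param CGrid candidate regularization strengths.
#' @param maxSteps gradient steps per candidate.
#' @param checkEvery validate every this many accepted steps.
#' @return a refined [QNModel-class]; filters are re-normalized to unit norm
#'   with the scale absorbed into the coefficients.
#' @export
refineFilters <- function(model, design, counts = NULL, validation,
                          CGrid = 10^seq(-2, 1, length.out = 4),
                          maxSteps = 100, checkEvery = 5) {
  X <- if (is(design, "LaggedDesign")) design@X else design
  y <- if (is.null(counts)) design@y else counts
  Xv <- if (is(validation$design, "LaggedDesign")) validation$design@X
        else validation$design
  yv <- validation$counts %||%
    (if (is(validation$design, "LaggedDesign")) validation$design@y else
       stop("validation counts required"))
  yt <- ifelse(y == 0, -1, 1); beta <- pmax(y, 1)
  ytv <- ifelse(yv == 0, -1, 1); betav <- pmax(yv, 1)
  nf <- ncol(model@filters)

  dataLoss <- function(W, XX, ytt, bb) {
    z <- lowrankZ(W, XX)
    sum(bb * log1pexp(-ytt * z))
  }
  lowrankZ <- function(W, XX) {
    z <- rep(model@intercept, nrow(XX))
    P <- XX %*% W
    for (m in seq_len(nf)) {
      z <- z + if (model@sources[m] == "J") model@lambdas[m] * P[, m]^2
               else model@lambdas[m] * P[, m]
    }
    z
  }
  gradient <- function(W, C) {
    z <- lowrankZ(W, X)
    r <- C * beta * (stats::plogis(yt * z) - 1) * yt
    P <- X %*% W
    G <- W  # Gamma = I penalty gradient
    for (m in seq_len(nf)) {
      G[, m] <- G[, m] + if (model@sources[m] == "J")
        drop(crossprod(X, r * 2 * model@lambdas[m] * P[, m]))
      else model@lambdas[m] * drop(crossprod(X, r))
    }
    G
  }

  W0 <- model@filters
  best <- list(W = W0, val = dataLoss(W0, Xv, ytv, betav), C = NA)
  for (C in CGrid) {
    W <- W0
    trainLoss <- C * dataLoss(W, X, yt, beta) + 0.5 * sum(W^2)
    step <- 1e-3
    diverged <- 0L
    accepted <- 0L
    for (it in seq_len(maxSteps)) {
      G <- gradient(W, C)
      ok <- FALSE
      for (bt in 1:20) {
        WNew <- W - step * G
        lossNew <- C * dataLoss(WNew, X, yt, beta) + 0.5 * sum(WNew^2)
        if (is.finite(lossNew) && lossNew <= trainLoss) { ok <- TRUE; break }
        step <- step / 2
      }
      if (!ok) { diverged <- diverged + 1L; if (diverged > 3L) break
                 next }
      W <- WNew; trainLoss <- lossNew
      step <- step * 1.5
      accepted <- accepted + 1L
      if (accepted %% checkEvery == 0L) {
        val <- dataLoss(W, Xv, ytv, betav)
        if (val < best$val) best <- list(W = W, val = val, C = C)
      }
    }
    val <- dataLoss(W, Xv, ytv, betav)
    if (val < best$val) best <- list(W = W, val = val, C = C)
  }

  out <- model
  refined <- !identical(best$W, W0)
  if (refined) {
    W <- best$W
    for (m in seq_len(nf)) {
      nm <- sqrt(sum(W[, m]^2))
      if (nm > 0) {
        out@lambdas[m] <- out@lambdas[m] *
          if (out@sources[m] == "J") nm^2 else nm
        W[, m] <- W[, m] / nm
      }
    }
    out@filters <- W
  }
  attr(out, "refined") <- refined
  attr(out, "chosenC") <- best$C
  out
}

#' Two-filter LN fit with multiple starting points
#'
#' Information ascent on a histogram estimate of single-spike information is
#' non-convex, and a single starting subspace can converge to a local
#' optimum well below the attainable value. This fits [midAscent()] from
#' several standard starting points — the top spike-triggered-covariance
#' filters, the Gaussian information-maximizing subspace, and the leading
#' low-rank filters of a maximum-noise-entropy quadratic model fitted on
#' standardized inputs (both the [lowrankSelect()] choice and, when that
#' choice includes the linear term, the pure top quadratic eigenvectors) —
#' and keeps the run with the highest validation information.
#'
#' @param designTrain,designVal training and validation [LaggedDesign-class]
#'   blocks; ascent steps use the training block, starting-point selection
#'   and early stopping use the validation block.
#' @param nFilters number of filters (1 or 2; histogram information
#'   estimates support at most two dimensions).
#' @param bins,maxSteps histogram resolution and step budget passed to
#'   [midAscent()].
#' @param mneC logistic-loss weight of the maximum-noise-entropy start.
#' @param stats optional precomputed [spikeTriggeredStats()] of
#'   \code{designTrain}.
#' @return the best [FilterBank-class] by validation information, with
#'   attributes \code{initKind} (\code{"stc"}, \code{"istac"}, \code{"mne"}
#'   or \code{"mneJ"}) and the \code{trainInfo}/\code{valInfo} attributes
#'   set by [midAscent()].
#' @export
fitBestLn <- function(designTrain, designVal, nFilters = 2, bins = 15,
                      maxSteps = 300, mneC = 1, stats = NULL) {
  if (is.null(stats)) stats <- spikeTriggeredStats(designTrain)
  inits <- list(stc = stcFilters(stats, nFilters),
                istac = istacFit(stats, nFilters))
  Xs <- scale(designTrain@X)
  qn <- mneFit(Xs, designTrain@y, C = mneC)
  toBank <- function(Fs) {
    Fm <- sweep(Fs, 1, attr(Xs, "scaled:scale"), "/")
    Fm <- sweep(Fm, 2, sqrt(colSums(Fm^2)), "/")
    new("FilterBank", filters = Fm, values = numeric(0), kind = "mne")
  }
  sel <- lowrankSelect(qn, nFilters, Xs, designTrain@y)
  inits$mne <- toBank(sel@filters)
  ## pure quadratic subspace: for phase-invariant cells the linear residual
  ## that lowrankSelect may prefer on training information is often noise
  if (any(sel@sources != "J")) {
    e <- eigen(qn@J, symmetric = TRUE)
    ord <- order(abs(e$values), decreasing = TRUE)
    inits$mneJ <- toBank(e$vectors[, ord[seq_len(nFilters)], drop = FALSE])
  }
  best <- NULL
  for (nm in names(inits)) {
    fit <- midAscent(inits[[nm]], designTrain, designVal, bins = bins,
                     maxSteps = maxSteps)
    if (is.null(best) || attr(fit, "valInfo") > attr(best, "valInfo")) {
      best <- fit
      attr(best, "initKind") <- nm
    }
  }
  best
}
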