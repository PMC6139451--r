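#' Construct a context model
#'
#' @param nBars,nLags RF grid geometry (bars doubled for the intensity
#'   basis).
#' @param w0 bias.
#' @param rf RF vector (defaults to zeros).
#' @param cfs list of [ContextField-class]; empty for a traditional LN score.
#' @param rfBlocks list of c(rows, cols) blocks the RF grid is composed of;
#'   defaults to the single full grid.
#' @return a [ContextModel-class].
#' @export
contextModel <- function(nBars, nLags, w0 = 0,
                         rf = rep(0, nBars * nLags), cfs = list(),
                         rfBlocks = list(c(nBars, nLags))) {
  new("ContextModel", w0 = w0, rf = rf, cfs = cfs,
      nBars = as.integer(nBars), nLags = as.integer(nLags),
      rfBlocks = rfBlocks)
}

#' Construct a context field
#'
#' @param spec a [ContextWindowSpec-class].
#' @param rfAssignment RF indices gated by this field.
#' @param weights weight matrix (defaults to zeros); the origin entry is
#'   forced to zero.
#' @return a [ContextField-class].
#' @export
contextField <- function(spec, rfAssignment,
                         weights = matrix(0, spec@height, spec@width)) {
  weights[spec@origin[1], spec@origin[2]] <- 0
  new("ContextField", weights = weights, spec = spec,
      rfAssignment = as.integer(rfAssignment))
}

#' Default context-model initialization for a design
#'
#' One context field per requested context, with RF indices split into
#' \code{nCf} contiguous bar blocks (for \code{nCf = 2} on an
#' intensity-doubled design this is the bright/dark split).
#'
#' @param design a [LaggedDesign-class].
#' @param nCf number of context fields.
#' @param window shared [ContextWindowSpec-class].
#' @return a [ContextModel-class] with zero fields.
#' @export
contextModelInit <- function(design, nCf = 1, window = contextWindowSpec()) {
  nb <- design@nBars; nl <- design@nLags
  d <- nb * nl
  if (nCf == 0)
    return(contextModel(nb, nl))
  barGroups <- split(seq_len(nb),
                     ceiling(seq_len(nb) / (nb / nCf)))
  cfs <- lapply(barGroups, function(bars) {
    idx <- as.vector(outer(bars, (seq_len(nl) - 1L) * nb, `+`))
    contextField(window, sort(idx))
  })
  blocks <- if (nCf == 2 && nb %% 2 == 0)
    list(c(nb %/% 2, nl), c(nb %/% 2, nl)) else list(c(nb, nl))
  contextModel(nb, nl, cfs = unname(cfs), rfBlocks = blocks)
}

#' @describeIn similarityScores context-gated score, computed from the
#'   RF-linear representation (the field-gated design rows times the RF).
#' @export
setMethod("similarityScores", signature("ContextModel", "LaggedDesign"),
  function(model, design) {
    A <- rfDesignRows(model, design)
    as.vector(model@w0 + A %*% model@rf)
  })

#' RF-step design rows
#'
#' Row \code{i} holds the gradient of the similarity score with respect to
#' the RF vector, \eqn{\partial z_i / \partial w^{rf}_j = x_{ij} (1 + \sum_k
#' w^{cf_l}_k \tilde x_{ijk})}. With the context fields fixed the score is
#' exactly \code{w0 + A[i, ] \%*\% rf}; with all fields zero this is the raw
#' design matrix.
#'
#' @param model a [ContextModel-class] (its context fields are used).
#' @param design a [LaggedDesign-class].
#' @return samples-by-(bars * lags) matrix.
#' @export
rfDesignRows <- function(model, design) {
  if (ncol(design@X) != length(model@rf))
    stop("design and model dimensions disagree")
  A <- design@X
  for (cf in model@cfs) {
    if (all(cf@weights == 0)) next
    M <- contextMap(design@frames, cf)
    XM <- laggedFromFrames(design@frames * M, design@nLags,
                           design@sampleFrames)
    A[, cf@rfAssignment] <- A[, cf@rfAssignment] +
      XM[, cf@rfAssignment, drop = FALSE]
  }
  A
}

#' CF-step design rows
#'
#' Row \code{i}, column \code{k} holds \eqn{\partial z_i / \partial
#' w^{cf_l}_k = \sum_{j \in ctx_l} w^{rf}_j \tilde x_{ijk} x_{ij}}. With the
#' RF fixed, \code{z = k_i + sum_l A_l \%*\% wcf_l} where
#' \code{k_i = w0 + rf' x_i}. The origin column is returned (it multiplies a
#' weight that is always zero).
#'
#' @param model a [ContextModel-class] (its RF is used).
#' @param design a [LaggedDesign-class].
#' @param l which context field.
#' @return samples-by-(height * width) matrix, columns in the field's
#'   column-major cell order.
#' @export
cfDesignRows <- function(model, design, l = 1) {
  cf <- model@cfs[[l]]
  if (length(cf@rfAssignment) == 0L)
    stop("context field ", l, " has an empty RF assignment")
  sp <- cf@spec
  S <- design@frames
  nb <- design@nBars; nl <- design@nLags; nf <- ncol(S)
  Wl <- matrix(0, nb, nl)
  Wl[cf@rfAssignment] <- model@rf[cf@rfAssignment]
  if (sp@pad == 0)
    return(cfRowsCpp(S, Wl, as.integer(design@sampleFrames),
                     sp@height, sp@width, sp@origin[1], sp@origin[2]))
  ## general pad value: reference implementation over shifted products
  n <- length(design@sampleFrames)
  A <- matrix(0, n, sp@height * sp@width)
  base <- design@sampleFrames - nl
  for (k in seq_len(ncol(A))) {
    r <- (k - 1L) %% sp@height + 1L
    cc <- (k - 1L) %/% sp@height + 1L
    dr <- r - sp@origin[1]; dc <- cc - sp@origin[2]
    ## P[b, f] = S[b, f] * xtilde value at offset (dr, dc)
    P <- sp@pad * S
    bs <- max(1L, 1L - dr):min(nb, nb - dr)
    fs <- max(1L, 1L - dc):min(nf, nf - dc)
    P[bs, fs] <- S[bs, fs, drop = FALSE] * S[bs + dr, fs + dc, drop = FALSE]
    G <- crossprod(Wl, P)                   # lags x frames
    ak <- numeric(n)
    for (t in seq_len(nl)) ak <- ak + G[t, base + t]
    A[, k] <- ak
  }
  A
}

#' Build a regularization matrix for a field grid
#'
#' "l2" returns the identity. "laplacian" returns the two-dimensional
#' discrete Laplace operator on the field grid (4-neighbour stencil; each row
#' is degree * w - sum of in-grid neighbours, so interior rows are the
#' 5-point stencil, boundary rows its one-sided reductions, and constant
#' fields are annihilated). Multiple blocks give a block-diagonal operator so
#' smoothing never crosses block seams.
#'
#' @param kind "l2" or "laplacian".
#' @param fieldShape c(rows, cols), or a list of such blocks.
#' @return square matrix over the concatenated field coordinates.
#' @export
makeRegularizer <- function(kind = c("l2", "laplacian"), fieldShape) {
  kind <- match.arg(kind)
  if (is.list(fieldShape)) {
    blocks <- lapply(fieldShape, function(s) makeRegularizer(kind, s))
    d <- sum(vapply(blocks, nrow, 1L))
    G <- matrix(0, d, d)
    at <- 0L
    for (B in blocks) {
      idx <- at + seq_len(nrow(B))
      G[idx, idx] <- B
      at <- at + nrow(B)
    }
    return(G)
  }
  h <- fieldShape[1]; w <- fieldShape[2]
  d <- h * w
  if (kind == "l2") return(diag(d))
  G <- matrix(0, d, d)
  idx <- function(r, cc) (cc - 1L) * h + r
  for (cc in seq_len(w)) for (r in seq_len(h)) {
    i <- idx(r, cc)
    nbrs <- c(if (r > 1) idx(r - 1, cc), if (r < h) idx(r + 1, cc),
              if (cc > 1) idx(r, cc - 1), if (cc < w) idx(r, cc + 1))
    G[i, i] <- length(nbrs)
    G[i, nbrs] <- -1
  }
  G
}

#' Solve the linear (identity-nonlinearity) subproblem analytically
#'
#' Minimizes \eqn{C \sum_i (y_i - k_i - A_i w)^2 + \frac12 \|\Gamma w\|^2},
#' whose solution is
#' \eqn{w = (A'A + \frac{1}{2C}\Gamma'\Gamma)^{-1} A'(y - k)}. A singular
#' system with no regularization is solved by pseudoinverse and flagged.
#'
#' @param A design rows (augment with a ones column yourself to solve a
#'   bias).
#' @param y responses.
#' @param k per-sample constants.
#' @param C regularization strength.
#' @param Gamma regularization matrix (may be all-zero).
#' @return list with elements \code{w} and \code{flagged}.
#' @export
solveLinearSubproblem <- function(A, y, k, C, Gamma) {
  if (length(k) == 1L) k <- rep(k, length(y))
  H <- crossprod(A) + crossprod(Gamma) / (2 * C)
  b <- crossprod(A, y - k)
  w <- tryCatch(drop(solve(H, b)), error = function(e) NULL)
  if (is.null(w))
    list(w = drop(MASS::ginv(H) %*% b), flagged = TRUE)
  else
    list(w = w, flagged = FALSE)
}

## Numerically stable log(1 + exp(x)).
log1pexp <- function(x) ifelse(x > 35, x, log1p(exp(pmin(x, 35))))

## Subproblem data losses (no regularization term).
subproblemDataLoss <- function(z, y, family) {
  switch(family,
         linear = sum((y - z)^2),
         logistic = {
           yt <- ifelse(y == 0, -1, 1)
           beta <- pmax(y, 1)
           sum(beta * log1pexp(-yt * z))
         },
         poisson = sum(exp(pmin(z, 500)) - y * z))
}

#' Solve a logistic or Poisson subproblem by Newton's method
#'
#' Minimizes the weighted logistic loss
#' \eqn{C \sum_i \beta_i \log(1 + e^{-\tilde y_i z_i}) + \frac12\|\Gamma
#' w\|^2} or the Poisson loss \eqn{C \sum_i (e^{z_i} - y_i z_i) +
#' \frac12\|\Gamma w\|^2}, with \eqn{z_i = k_i + A_i w}. The per-sample
#' constant \code{k} is what distinguishes these from off-the-shelf GLM
#' solvers. For the logistic family, signed targets are
#' \eqn{\tilde y_i = -1} iff \eqn{y_i = 0} and the weights
#' \eqn{\beta_i = \max(y_i, 1)} count multi-spike samples multiple times.
#' Uses analytic gradient and Hessian with step halving; non-finite losses
#' trigger step halving and, after bounded retries, a convergence error.
#'
#' @inheritParams solveLinearSubproblem
#' @param family "logistic" or "poisson".
#' @param tol stop when the gradient norm falls below \code{tol} times its
#'   initial value (or in absolute terms for tiny problems).
#' @param maxit Newton iteration cap.
#' @param init optional warm start.
#' @return list with elements \code{w}, \code{loss}, \code{iterations},
#'   \code{converged}.
#' @export
solveGlmSubproblem <- function(A, y, k, C, Gamma, family = c("logistic",
                               "poisson"), tol = 1e-3, maxit = 100,
                               init = NULL) {
  family <- match.arg(family)
  if (length(k) == 1L) k <- rep(k, length(y))
  d <- ncol(A)
  w <- if (is.null(init)) numeric(d) else init
  GtG <- crossprod(Gamma)
  yt <- ifelse(y == 0, -1, 1)
  beta <- pmax(y, 1)
  lossOf <- function(w) {
    z <- k + drop(A %*% w)
    C * subproblemDataLoss(z, y, family) + 0.5 * sum((Gamma %*% w)^2)
  }
  gradHess <- function(w) {
    z <- k + drop(A %*% w)
    if (family == "logistic") {
      s <- stats::plogis(yt * z)
      g <- drop(GtG %*% w) + C * drop(crossprod(A, beta * (s - 1) * yt))
      wts <- beta * s * (1 - s)
    } else {
      ez <- exp(pmin(z, 500))
      g <- drop(GtG %*% w) + C * drop(crossprod(A, ez - y))
      wts <- ez
    }
    H <- GtG + C * crossprod(A * sqrt(wts))
    list(g = g, H = H)
  }
  loss <- lossOf(w)
  if (!is.finite(loss)) stop("non-finite loss at the initial point")
  g0norm <- NULL
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    gh <- gradHess(w)
    gn <- sqrt(sum(gh$g^2))
    if (is.null(g0norm)) g0norm <- max(gn, 1e-12)
    if (gn <= tol * max(g0norm, 1)) { converged <- TRUE; break }
    step <- tryCatch(drop(solve(gh$H, gh$g)),
                     error = function(e) drop(MASS::ginv(gh$H) %*% gh$g))
    alpha <- 1
    ok <- FALSE
    for (half in 1:40) {
      wNew <- w - alpha * step
      lossNew <- lossOf(wNew)
      if (is.finite(lossNew) && lossNew <= loss + 1e-12 * abs(loss)) {
        ok <- TRUE; break
      }
      alpha <- alpha / 2
    }
    if (!ok) {
      if (!is.finite(lossOf(w)))
        stop("subproblem solver failed to recover a finite loss")
      converged <- TRUE  # no descent direction progress left
      break
    }
    if (loss - lossNew <= 1e-12 * max(1, abs(loss)) && it > 1L) {
      w <- wNew; loss <- lossNew; converged <- TRUE; break
    }
    w <- wNew; loss <- lossNew
  }
  list(w = w, loss = loss, iterations = it, converged = converged)
}
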