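#' Solver configuration
#'
#' @param family subproblem family: "linear", "logistic" or "poisson"
#'   (identity, logistic, exponential nonlinearity).
#' @param C regularization strength used while iterating to convergence.
#' @param regKind "l2" or "laplacian" (smooth) regularization.
#' @param tol inner Newton tolerance.
#' @param convRel outer-loop convergence threshold on the relative loss
#'   decrease; 1e-4 is the 0.01 percent rule.
#' @param cvFolds folds for the final cross-validated choice of C.
#' @param cvGrid candidate C grid (log-spaced, ascending).
#' @param maxOuter outer iteration safety cap.
#' @param seed seed for the jittered context-field initialization.
#' @return a [SolverConfig-class].
#' @export
solverConfig <- function(family = "poisson", C = 0.1, regKind = "laplacian",
                         tol = 1e-3, convRel = 1e-4, cvFolds = 5,
                         cvGrid = 10^seq(-3, 2, length.out = 11),
                         maxOuter = 100, seed = 1) {
  ## the slot is assigned after construction: an argument named "C" would
  ## partially match new()'s Class formal
  cfg <- new("SolverConfig", family = family, regKind = regKind, tol = tol,
             convRel = convRel, cvFolds = as.integer(cvFolds),
             cvGrid = sort(cvGrid), maxOuter = as.integer(maxOuter),
             seed = as.integer(seed))
  cfg@C <- C
  validObject(cfg)
  cfg
}

## Pad a regularizer with an unpenalized leading bias coordinate.
padBias <- function(Gamma) {
  d <- nrow(Gamma)
  G <- matrix(0, d + 1, d + 1)
  G[-1, -1] <- Gamma
  G
}

## Solve one convex subproblem (any family) for z = k + A w.
solveSubproblem <- function(A, y, k, C, Gamma, family, tol, init = NULL) {
  if (family == "linear") {
    solveLinearSubproblem(A, y, k, C, Gamma)
  } else {
    solveGlmSubproblem(A, y, k, C, Gamma, family = family, tol = tol,
                       init = init)
  }
}

## Joint regularized training loss of the full context model.
contextLoss <- function(model, design, family, C, GammaRf, GammaCf) {
  z <- similarityScores(model, design)
  pen <- 0.5 * sum((GammaRf %*% model@rf)^2)
  for (l in seq_along(model@cfs)) {
    wfree <- cfFreeWeights(model@cfs[[l]])
    pen <- pen + 0.5 * sum((GammaCf[[l]] %*% wfree)^2)
  }
  C * subproblemDataLoss(z, design@y, family) + pen
}

## Context-field weights with the origin coordinate removed / restored.
cfOriginIndex <- function(spec) (spec@origin[2] - 1L) * spec@height +
  spec@origin[1]
cfFreeWeights <- function(cf) as.vector(cf@weights)[-cfOriginIndex(cf@spec)]
cfSetFreeWeights <- function(cf, wfree) {
  w <- numeric(cf@spec@height * cf@spec@width)
  w[-cfOriginIndex(cf@spec)] <- wfree
  cf@weights <- matrix(w, cf@spec@height, cf@spec@width)
  cf
}

## Cross-validated choice of C for one subproblem; contiguous folds, held-out
## unregularized data loss, ties resolved toward the smallest (strongest) C.
## For the linear family the per-fold Gram matrices are formed once and
## reused across the whole C grid.
cvChooseC <- function(A, y, k, Gamma, family, grid, folds, tol, init) {
  n <- nrow(A)
  foldId <- cut(seq_len(n), folds, labels = FALSE)
  score <- matrix(0, length(grid), folds)
  GtG <- crossprod(Gamma)
  for (f in seq_len(folds)) {
    tr <- foldId != f
    Ah <- A[!tr, , drop = FALSE]
    if (family == "linear") {
      AtA <- crossprod(A[tr, , drop = FALSE])
      Atb <- crossprod(A[tr, , drop = FALSE], y[tr] - k[tr])
      for (ci in seq_along(grid)) {
        w <- tryCatch(drop(solve(AtA + GtG / (2 * grid[ci]), Atb)),
                      error = function(e)
                        drop(MASS::ginv(AtA + GtG / (2 * grid[ci])) %*% Atb))
        zHeld <- k[!tr] + drop(Ah %*% w)
        score[ci, f] <- subproblemDataLoss(zHeld, y[!tr], family) / sum(!tr)
      }
    } else {
      for (ci in seq_along(grid)) {
        fit <- solveGlmSubproblem(A[tr, , drop = FALSE], y[tr], k[tr],
                                  grid[ci], Gamma, family = family,
                                  tol = tol, init = init)
        zHeld <- k[!tr] + drop(Ah %*% fit$w)
        score[ci, f] <- subproblemDataLoss(zHeld, y[!tr], family) / sum(!tr)
      }
    }
  }
  grid[which.min(rowMeans(score))]  # ascending grid: ties take the smallest C
}

## One RF step: solve for (w0, rf) with the context fields fixed.
## Returns the updated model and its new training scores.
rfStepSolve <- function(model, design, family, C, GammaRf, tol) {
  A <- cbind(1, rfDesignRows(model, design))
  G <- padBias(GammaRf)
  fit <- solveSubproblem(A, design@y, rep(0, nrow(A)), C, G, family, tol,
                         init = c(model@w0, model@rf))
  model@w0 <- fit$w[1]
  model@rf <- fit$w[-1]
  list(model = model, z = drop(A %*% fit$w))
}

## One CF step: solve all context fields jointly with the RF fixed.
cfStepSolve <- function(model, design, family, C, GammaCf, tol) {
  if (!length(model@cfs))
    return(list(model = model,
                z = model@w0 + drop(design@X %*% model@rf)))
  blocks <- lapply(seq_along(model@cfs), function(l) {
    Acf <- cfDesignRows(model, design, l)
    Acf[, -cfOriginIndex(model@cfs[[l]]@spec), drop = FALSE]
  })
  A <- do.call(cbind, blocks)
  dks <- vapply(blocks, ncol, 1L)
  G <- makeBlockDiag(GammaCf)
  k <- model@w0 + drop(design@X %*% model@rf)
  init <- unlist(lapply(model@cfs, cfFreeWeights))
  fit <- solveSubproblem(A, design@y, k, C, G, family, tol, init = init)
  at <- 0L
  for (l in seq_along(model@cfs)) {
    idx <- at + seq_len(dks[l])
    model@cfs[[l]] <- cfSetFreeWeights(model@cfs[[l]], fit$w[idx])
    at <- at + dks[l]
  }
  list(model = model, z = k + drop(A %*% fit$w))
}

makeBlockDiag <- function(mats) {
  d <- sum(vapply(mats, nrow, 1L))
  G <- matrix(0, d, d)
  at <- 0L
  for (B in mats) {
    idx <- at + seq_len(nrow(B))
    G[idx, idx] <- B
    at <- at + nrow(B)
  }
  G
}

#' Fit a context model by alternating convex subproblems
#'
#' Alternates between solving for the RF (context fields fixed) and for the
#' context fields (RF fixed), each a convex linear, logistic, or Poisson
#' regression, at fixed \code{C}, until the relative decrease of the joint
#' regularized training loss falls below \code{convRel}. One additional
#' iteration is then performed in which \code{C} is chosen independently for
#' the RF and CF steps by \code{cvFolds}-fold cross-validation on the
#' training data. The RF is initialized from a regularized GLM fit with all
#' context fields at zero; fields start from zero plus a tiny seeded jitter.
#' The context-field origin weight is zero after every step.
#'
#' @param design a [LaggedDesign-class] (training rows).
#' @param init a [ContextModel-class] giving field shapes and assignments;
#'   defaults to a single 9x9 field gating every RF element.
#' @param cfg a [SolverConfig-class].
#' @param cv run the final cross-validated iteration (disable for speed in
#'   inner loops).
#' @return a [ContextFit-class].
#' @export
alternatingFit <- function(design, init = NULL, cfg = solverConfig(),
                           cv = TRUE) {
  model <- if (is.null(init)) contextModelInit(design) else init
  family <- cfg@family
  GammaRf <- makeRegularizer(cfg@regKind, model@rfBlocks)
  GammaCf <- lapply(model@cfs, function(cf) {
    G <- makeRegularizer(cfg@regKind, c(cf@spec@height, cf@spec@width))
    oi <- cfOriginIndex(cf@spec)
    G[-oi, -oi, drop = FALSE]
  })

  if (all(model@rf == 0)) {
    cfs0 <- model@cfs
    model@cfs <- lapply(model@cfs, function(cf) { cf@weights[] <- 0; cf })
    model <- rfStepSolve(model, design, family, cfg@C, GammaRf, cfg@tol)$model
    model@cfs <- cfs0
  }
  if (length(model@cfs) &&
      all(vapply(model@cfs, function(cf) all(cf@weights == 0), TRUE))) {
    set.seed(cfg@seed)
    model@cfs <- lapply(model@cfs, function(cf) {
      cfSetFreeWeights(cf, stats::rnorm(cf@spec@height * cf@spec@width - 1L,
                                        sd = 1e-3))
    })
  }

  penaltyOf <- function(model) {
    pen <- 0.5 * sum((GammaRf %*% model@rf)^2)
    for (l in seq_along(model@cfs))
      pen <- pen + 0.5 * sum((GammaCf[[l]] %*% cfFreeWeights(
        model@cfs[[l]]))^2)
    pen
  }
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (iter in seq_len(cfg@maxOuter)) {
    model <- rfStepSolve(model, design, family, cfg@C, GammaRf, cfg@tol)$model
    stepCf <- cfStepSolve(model, design, family, cfg@C, GammaCf, cfg@tol)
    model <- stepCf$model
    cur <- cfg@C * subproblemDataLoss(stepCf$z, design@y, family) +
      penaltyOf(model)
    trace <- c(trace, cur)
    if (is.finite(prev) && cur > prev + max(1e-8, 1e-6 * abs(prev)))
      stop(sprintf(paste0("training loss increased between outer iterations",
                          " (%.8g -> %.8g at iteration %d)"),
                   prev, cur, iter))
    if (is.finite(prev) && (prev - cur) < cfg@convRel * abs(prev)) {
      converged <- TRUE
      break
    }
    prev <- cur
  }

  chosenC <- list(rf = cfg@C, cf = cfg@C)
  if (cv) {
    A <- cbind(1, rfDesignRows(model, design))
    Crf <- cvChooseC(A, design@y, rep(0, nrow(A)), padBias(GammaRf), family,
                     cfg@cvGrid, cfg@cvFolds, cfg@tol,
                     init = c(model@w0, model@rf))
    model <- rfStepSolve(model, design, family, Crf, GammaRf, cfg@tol)$model
    chosenC$rf <- Crf
    if (length(model@cfs)) {
      blocks <- lapply(seq_along(model@cfs), function(l) {
        Acf <- cfDesignRows(model, design, l)
        Acf[, -cfOriginIndex(model@cfs[[l]]@spec), drop = FALSE]
      })
      Acf <- do.call(cbind, blocks)
      kvec <- model@w0 + drop(design@X %*% model@rf)
      Ccf <- cvChooseC(Acf, design@y, kvec, makeBlockDiag(GammaCf), family,
                       cfg@cvGrid, cfg@cvFolds, cfg@tol,
                       init = unlist(lapply(model@cfs, cfFreeWeights)))
      model <- cfStepSolve(model, design, family, Ccf, GammaCf, cfg@tol)$model
      chosenC$cf <- Ccf
    }
  }

  new("ContextFit", params = model, lossTrace = trace, chosenC = chosenC,
      flipped = FALSE, family = family, converged = converged)
}

#' Flip field signs and re-optimize when the RF is dominantly negative
#'
#' RF and CF parameters multiply each other, so complementary solutions with
#' flipped signs exist. For a consistent sign convention, when the RF's most
#' negative entry exceeds its most positive in magnitude, all RF and CF signs
#' are negated and the alternating fit is rerun to completion from that
#' point.
#'
#' @param result a [ContextFit-class].
#' @param design the training [LaggedDesign-class].
#' @param cfg the [SolverConfig-class] used for the original fit.
#' @param cv as in [alternatingFit()].
#' @return a [ContextFit-class] with the \code{flipped} flag set when a
#'   restart happened.
#' @export
flipAndRestart <- function(result, design, cfg, cv = TRUE) {
  rf <- result@params@rf
  if (!(abs(min(rf)) > max(rf))) return(result)
  model <- result@params
  model@rf <- -model@rf
  model@cfs <- lapply(model@cfs, function(cf) {
    cf@weights <- -cf@weights
    cf@weights[cf@spec@origin[1], cf@spec@origin[2]] <- 0
    cf
  })
  out <- alternatingFit(design, init = model, cfg = cfg, cv = cv)
  out@flipped <- TRUE
  out
}

#' Fit a double-CF context model on the space-time-intensity basis
#'
#' Stage 1 fits a single context field shared by the whole (bright plus dark)
#' RF; stage 2 refits with two fields -- one gating the bright half of the RF
#' and one the dark half -- initialized from the stage-1 solution duplicated
#' across both fields.
#'
#' @param design a [LaggedDesign-class] built with the "bright+dark" basis.
#' @param cfg a [SolverConfig-class].
#' @param window shared [ContextWindowSpec-class].
#' @param cv as in [alternatingFit()].
#' @return list with elements \code{fit} (the stage-2 [ContextFit-class]),
#'   \code{stage1}, and \code{init} (the stage-2 initial model).
#' @export
fitDoubleCfIntensity <- function(design, cfg = solverConfig(),
                                 window = contextWindowSpec(), cv = TRUE) {
  if (design@basis != "bright+dark")
    stop("design must be built with the concatenated bright+dark basis")
  nb <- design@nBars; nl <- design@nLags
  blocks <- list(c(nb %/% 2L, nl), c(nb %/% 2L, nl))
  init1 <- contextModel(nb, nl,
                        cfs = list(contextField(window, seq_len(nb * nl))),
                        rfBlocks = blocks)
  fit1 <- alternatingFit(design, init = init1, cfg = cfg, cv = cv)

  half <- nb %/% 2L
  brightIdx <- as.vector(outer(seq_len(half), (seq_len(nl) - 1L) * nb, `+`))
  darkIdx <- as.vector(outer(half + seq_len(half), (seq_len(nl) - 1L) * nb,
                             `+`))
  shared <- fit1@params@cfs[[1]]@weights
  init2 <- fit1@params
  init2@cfs <- list(contextField(window, brightIdx, shared),
                    contextField(window, darkIdx, shared))
  fit2 <- alternatingFit(design, init = init2, cfg = cfg, cv = cv)
  list(fit = fit2, stage1 = fit1, init = init2)
}

#' Fit a traditional (single-filter) LN model as a GLM
#'
#' The context model with zero context fields: one regularized linear,
#' logistic, or Poisson regression for the RF and bias, including the final
#' cross-validated choice of C.
#'
#' @inheritParams alternatingFit
#' @return a [ContextFit-class] with no context fields.
#' @export
fitTraditionalLn <- function(design, cfg = solverConfig(), cv = TRUE) {
  init <- contextModel(design@nBars, design@nLags)
  alternatingFit(design, init = init, cfg = cfg, cv = cv)
}

#' @describeIn parameterCount RF elements plus free (non-origin) CF cells;
#'   the bias is excluded.
#' @export
setMethod("parameterCount", "ContextModel", function(model) {
  length(model@rf) + sum(vapply(model@cfs, function(cf)
    cf@spec@height * cf@spec@width - 1L, 1L))
})

#' @describeIn parameterCount total filter coefficients.
#' @export
setMethod("parameterCount", "FilterBank", function(model) {
  as.integer(length(model@filters))
})

#' @describeIn parameterCount coefficients of the selected low-rank filters
#'   (or of v and J before selection).
#' @export
setMethod("parameterCount", "QNModel", function(model) {
  if (ncol(model@filters)) as.integer(length(model@filters))
  else as.integer(length(model@v) + length(model@J))
})
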