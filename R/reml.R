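#' Restricted log-likelihood at given variance components
#'
#' Computes the REML log-likelihood of the phenotypes under the social (or
#' classical) animal model through the mixed-model-equation identity
#' `log|V| + log|X' V^-1 X| = log|R| + log|G| + log|M|`, where `M` is the
#' full coefficient matrix of the mixed-model equations.  The constant
#' `-(n - p)/2 log(2 pi)` is included, so likelihood differences between
#' nested fits are directly comparable and the value matches the dense
#' `V`-based formula.
#'
#' @inheritParams assemble_mme
#' @param C_logdet log-determinant of the relationship matrix `C` whose
#'   inverse is `Cinv` (for `A` this is the `"logdet"` attribute of
#'   [make_Ainv()]).
#' @return REML log-likelihood (scalar).
#' @export
reml_loglik <- function(design, vc, Cinv, C_logdet = attr(Cinv, "logdet")) {
  if (is.null(C_logdet)) stop("C_logdet is required")
  sys <- assemble_mme(design, vc, Cinv)
  n <- sys$n; p <- sys$p
  np <- length(design$ped_ids)
  q_env <- c(length(design$sym_levels), length(design$litter_ids),
             length(design$litter_ids), length(design$eI_ids))
  logdetG <- if (vc$model == "INDIRECT") {
    Sg <- .sigma_g(vc)
    dSg <- det(Sg)
    if (dSg <= 0) stop("2x2 genetic covariance is not positive definite")
    np * log(dSg) + 2 * C_logdet
  } else {
    np * log(vc$aD) + C_logdet
  }
  logdetG <- logdetG + sum(q_env * log(c(vc$u, vc$lD, vc$lI, vc$eI)))
  logdetR <- n * log(vc$eD)
  logdetM <- as.numeric(Matrix::determinant(sys$M, logarithm = TRUE)$modulus)
  sol <- as.numeric(Matrix::solve(sys$M, sys$rhs))
  yPy <- sum(design$y^2) / vc$eD - sum(sol * as.numeric(sys$rhs))
  -0.5 * ((n - p) * log(2 * pi) + logdetR + logdetG + logdetM + yPy)
}

## Dense-V REML engine --------------------------------------------------

## n x n derivative matrices dV/dtheta_k over the phenotyped records;
## constant across iterations.
.reml_kernels <- function(design, A, model) {
  pidx <- match(design$phen_ids, design$ped_ids)
  K <- list()
  K$aD <- A[pidx, pidx, drop = FALSE]
  if (model == "INDIRECT") {
    ZIt <- Matrix::t(design$Z_I)
    M1 <- as.matrix(A[pidx, , drop = FALSE] %*% ZIt)
    K$aI <- as.matrix(design$Z_I %*% (A %*% ZIt))
    K$aDI <- M1 + t(M1)
  }
  K$u <- as.matrix(Matrix::tcrossprod(design$W))
  K$lD <- as.matrix(Matrix::tcrossprod(design$Q_D))
  K$lI <- as.matrix(Matrix::tcrossprod(design$Q_I))
  K$eI <- as.matrix(Matrix::tcrossprod(design$R_I))
  K$eD <- diag(length(pidx))
  ord <- if (model == "INDIRECT") c("aD", "aI", "aDI", "u", "lD", "lI", "eI", "eD")
         else c("aD", "u", "lD", "lI", "eI", "eD")
  K[ord]
}

## kernels as an n^2 x k matrix: V and the trace sums become single BLAS
## calls instead of k n x n temporaries
.dense_V <- function(theta, KM, n) {
  matrix(KM %*% theta, n, n)
}

## log-likelihood and solve pieces from dense V; NULL if V not PD
.dense_ll <- function(V, X, y) {
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(NULL)
  n <- length(y); p <- ncol(X)
  sv <- function(b) backsolve(cV, backsolve(cV, b, transpose = TRUE))
  Viy <- sv(y)
  ViX <- sv(X)
  XtViX <- crossprod(X, ViX)
  cX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cX)) return(NULL)
  bhat <- backsolve(cX, backsolve(cX, crossprod(X, Viy), transpose = TRUE))
  Py <- Viy - ViX %*% bhat
  ll <- -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(cV))) +
                  2 * sum(log(diag(cX))) + sum(y * Py))
  list(ll = ll, cV = cV, ViX = ViX, XtViX = XtViX, Py = as.numeric(Py))
}

## Dense engine: explicit V, P and elementwise trace sums; the reference
## implementation used as an oracle for the sparse engine.
.engine_dense <- function(design, A, model, ys, X) {
  n <- length(ys)
  K <- .reml_kernels(design, A, model)
  KM <- vapply(K, as.numeric, numeric(n * n))
  at <- function(theta) .dense_ll(.dense_V(theta, KM, n), X, ys)
  grad_ai <- function(theta, state) {
    Vi <- chol2inv(state$cV)
    Pm <- Vi - state$ViX %*% solve(state$XtViX, t(state$ViX))
    Py <- state$Py
    Fm <- vapply(K, function(k) as.numeric(k %*% Py), numeric(n))
    tr_PK <- as.numeric(crossprod(KM, as.numeric(Pm)))
    gr <- -0.5 * (tr_PK - as.numeric(crossprod(Fm, Py)))
    PF <- Pm %*% Fm
    AI <- 0.5 * crossprod(Fm, PF)
    list(gr = gr, AI = (AI + t(AI)) / 2)
  }
  list(at = at, grad_ai = grad_ai, pnames = names(K))
}

.project_theta <- function(theta, model, lb = 1e-8) {
  vidx <- setdiff(names(theta), "aDI")
  theta[vidx] <- pmax(theta[vidx], lb)
  if (model == "INDIRECT") {
    bound <- 0.99 * sqrt(theta[["aD"]] * theta[["aI"]])
    theta[["aDI"]] <- sign(theta[["aDI"]]) * min(abs(theta[["aDI"]]), bound)
  }
  theta
}

#' Estimate variance components by average-information REML
#'
#' Maximises the restricted likelihood of the social (or classical) animal
#' model with the numerator relationship matrix as genetic covariance
#' structure.  Updates are average-information (quasi-Newton) steps taken
#' on log-variances (the genetic covariance on its natural scale), with
#' per-coordinate step caps and Levenberg-Marquardt damping; EM-type steps
#' are used for burn-in and as a fallback.  Variances are kept above a
#' small positive bound and the 2x2 genetic covariance inside its
#' positive-definite region; convergence is assessed on the gradient with
#' active bounds excluded, or on the relative log-likelihood change.
#'
#' Two computational engines are available.  The `"sparse"` engine (the
#' default whenever `Ainv` is supplied) works entirely on the sparse
#' mixed-model equations: the log-likelihood via the determinant identity,
#' and the gradient traces via the selected inverse of the sparse Cholesky
#' factor (Takahashi equations), in the style of the average-information
#' algorithms used by dedicated breeding-value software.  The `"dense"`
#' engine forms the phenotypic covariance matrix explicitly and is
#' practical up to a few thousand phenotyped animals; it serves as the
#' reference implementation.
#'
#' Internally the phenotype is scaled to unit variance, so `tol` applies
#' to a standardized gradient; estimates and standard errors are returned
#' on the original scale.
#'
#' @param design an `ige_design` from [build_design()].
#' @param A dense numerator relationship matrix over `design$ped_ids`
#'   (dense engine).
#' @param model `"INDIRECT"` or `"CLASSIC"`.
#' @param start optional `ige_vc` of starting values; by default each
#'   non-residual term starts at 10% of the phenotypic variance, the
#'   genetic covariance at zero, and the residual takes the remainder.
#' @param tol convergence tolerance on the standardized gradient;
#'   convergence is also declared when the relative log-likelihood change
#'   falls below 1e-9.
#' @param max_iter iteration cap.
#' @param n_em_burnin EM iterations taken before the first AI step; EM
#'   moves badly started components onto the right scale, after which the
#'   AI updates converge quadratically.
#' @param verbose print per-iteration progress.
#' @param engine `"auto"` (sparse when `Ainv` is given), `"sparse"` or
#'   `"dense"`.
#' @param Ainv sparse inverse numerator relationship matrix (sparse
#'   engine), as from [make_Ainv()].
#' @param A_logdet log-determinant of A (defaults to the attribute carried
#'   by `Ainv`).
#' @return List with `vc` (an `ige_vc`), `se` (standard errors from the
#'   inverse AI matrix), `loglik`, `converged`, `iterations` and `trace`
#'   (per-iteration log-likelihood, gradient norm and step type).
#' @export
ai_reml <- function(design, A = NULL, model = c("INDIRECT", "CLASSIC"),
                    start = NULL, tol = 1e-6, max_iter = 200L,
                    n_em_burnin = 3L, verbose = FALSE,
                    engine = c("auto", "sparse", "dense"),
                    Ainv = NULL, A_logdet = attr(Ainv, "logdet")) {
  model <- match.arg(model)
  engine <- match.arg(engine)
  if (engine == "auto") {
    ## with grouped animals the MME factor carries pen cliques, so up to a
    ## few thousand records the explicit-V engine is faster than the
    ## selected-inverse route; beyond that only the sparse engine scales
    engine <- if (!is.null(A) && length(design$y) <= 4000) "dense" else "sparse"
  }
  y <- design$y
  X <- design$X
  n <- length(y)
  s2y <- stats::var(y)
  ys <- y / sqrt(s2y)
  eng <- if (engine == "dense") {
    if (is.null(A)) stop("dense engine needs the dense relationship matrix A")
    if (n > 4000) stop("dense AI-REML engine is limited to 4000 phenotyped animals")
    .engine_dense(design, A, model, ys, X)
  } else {
    if (is.null(Ainv)) stop("sparse engine needs Ainv (see make_Ainv)")
    if (is.null(A_logdet)) stop("sparse engine needs A_logdet")
    .engine_sparse(design, Ainv, A_logdet, model, ys, X)
  }
  pnames <- eng$pnames
  qk <- c(aD = length(design$ped_ids), aI = length(design$ped_ids),
          aDI = NA, u = length(design$sym_levels),
          lD = length(design$litter_ids), lI = length(design$litter_ids),
          eI = length(design$eI_ids), eD = n)[pnames]
  if (is.null(start)) {
    nv <- length(pnames) - 1 - (model == "INDIRECT")  # non-residual variances
    theta <- stats::setNames(rep(0.1, length(pnames)), pnames)
    if (model == "INDIRECT") theta[["aDI"]] <- 0
    theta[["eD"]] <- 1 - 0.1 * nv
  } else {
    theta <- unlist(start[pnames]) / s2y
  }
  theta <- .project_theta(theta, model)
  state <- eng$at(theta)
  if (is.null(state)) stop("starting values give a non-positive-definite system")
  trace <- list()
  converged <- FALSE
  it <- 0L
  AI <- diag(length(theta))
  repeat {
    it <- it + 1L
    ga <- eng$grad_ai(theta, state)
    gr <- ga$gr
    AI <- ga$AI
    ## KKT-aware gradient: ignore outward gradients on active bounds
    kkt <- gr
    at_lb <- pnames != "aDI" & theta <= 1.5e-8
    kkt[at_lb & gr < 0] <- 0
    cov_clamped <- FALSE
    if (model == "INDIRECT") {
      bound <- 0.99 * sqrt(theta[["aD"]] * theta[["aI"]])
      ci <- which(pnames == "aDI")
      cov_clamped <- bound < 1e-6 ||
        (abs(theta[["aDI"]]) >= 0.999 * bound &&
           sign(theta[["aDI"]]) * gr[ci] > 0)
      if (cov_clamped) kkt[ci] <- 0
    }
    gnorm <- max(abs(kkt))
    trace[[it]] <- data.frame(iter = it, loglik = state$ll,
                              max_grad = gnorm, step = "AI")
    if (verbose)
      message(sprintf("it %2d  logL %.8f  max|grad| %.3g", it, state$ll, gnorm))
    if (gnorm < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    vidx <- pnames != "aDI"
    ## active set: variances pinned at the lower bound with an outward
    ## gradient stay fixed this iteration, as does a clamped covariance
    free <- vidx & !(theta <= 1.5e-8 & gr < 0)
    if (model == "INDIRECT") free[which(pnames == "aDI")] <- !cov_clamped
    accepted <- FALSE
    if (it > n_em_burnin && any(free)) {
      ## AI step on log-variances (covariance on the natural scale); a
      ## Levenberg-Marquardt ridge grows until the step improves the
      ## likelihood, degrading gracefully to scaled gradient ascent when
      ## the AI matrix is ill-conditioned near a boundary
      J <- ifelse(vidx, pmax(theta, 1e-6), 1)[free]
      g_t <- gr[free] * J
      AI_t <- AI[free, free, drop = FALSE] * tcrossprod(J)
      dA <- pmax(diag(AI_t), 1e-12)
      lambda <- 1e-6
      for (h in seq_len(14)) {
        delta <- tryCatch(solve(AI_t + lambda * diag(dA, nrow = length(dA)), g_t),
                          error = function(e) NULL)
        if (!is.null(delta)) {
          cand <- theta
          dfull <- numeric(length(theta)); dfull[free] <- delta
          ## cap each log-step at +/- log(10)
          dfull[vidx] <- pmin(pmax(dfull[vidx], -log(10)), log(10))
          cand[vidx] <- theta[vidx] * exp(dfull[vidx])
          if (model == "INDIRECT")
            cand[["aDI"]] <- theta[["aDI"]] + dfull[which(pnames == "aDI")]
          cand <- .project_theta(cand, model)
          st2 <- eng$at(cand)
          if (!is.null(st2) && st2$ll >= state$ll - 1e-10) {
            theta <- cand; state <- st2; accepted <- TRUE
            break
          }
        }
        lambda <- lambda * 10
      }
    }
    if (!accepted) {
      ## EM-type step for the variance parameters (burn-in and fallback)
      cand <- theta
      cand[vidx] <- theta[vidx] + 2 * theta[vidx]^2 / qk[vidx] * gr[vidx]
      cand[vidx] <- pmax(pmin(cand[vidx], 10 * theta[vidx]), theta[vidx] / 10)
      cand <- .project_theta(cand, model)
      st2 <- eng$at(cand)
      if (!is.null(st2) && st2$ll >= state$ll - 1e-10) {
        theta <- cand; state <- st2
        trace[[it]]$step <- "EM"
      } else if (it > n_em_burnin) {
        break  # no improving step available
      }
    }
    if (it > max(1L, n_em_burnin)) {
      dll <- abs(trace[[it]]$loglik - trace[[it - 1L]]$loglik)
      if (dll < 1e-9 * (1 + abs(state$ll))) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged && it >= max_iter)
    warning("AI-REML did not converge in ", max_iter, " iterations")
  se_std <- tryCatch(sqrt(diag(solve(AI))), error = function(e) rep(NA_real_, length(theta)))
  est <- theta * s2y
  se <- stats::setNames(se_std * s2y, pnames)
  vc <- if (model == "INDIRECT")
    vc_indirect(aD = est[["aD"]], aI = est[["aI"]], aDI = est[["aDI"]],
                u = est[["u"]], lD = est[["lD"]], lI = est[["lI"]],
                eI = est[["eI"]], eD = est[["eD"]])
  else
    vc_classic(aD = est[["aD"]], u = est[["u"]], lD = est[["lD"]],
               lI = est[["lI"]], eI = est[["eI"]], eD = est[["eD"]])
  ll_orig <- state$ll - 0.5 * (n - ncol(X)) * log(s2y)
  list(vc = vc, se = se, loglik = ll_orig, converged = converged,
       iterations = it, trace = do.call(rbind, trace))
}

#' Likelihood-ratio test of indirect genetic effects
#'
#' Compares the classical model against the model with indirect genetic
#' effects: the statistic is the difference in `-2 logL`, referred to a
#' chi-square with two degrees of freedom (indirect genetic variance and
#' direct-indirect covariance).
#'
#' @param classic,indirect fitted results with a `loglik` element (e.g.
#'   from [ai_reml()] or [solve_blup()]) or, directly, `-2 logL` values.
#' @return List with `minus2logL_classic`, `minus2logL_indirect`,
#'   `statistic`, `df` and `p_value`.
#' @export
lrt_ige <- function(classic, indirect) {
  m2 <- function(x) {
    if (is.numeric(x) && length(x) == 1) return(x)
    if (!is.null(x$loglik)) return(-2 * x$loglik)
    stop("cannot extract a log-likelihood")
  }
  mc <- m2(classic); mi <- m2(indirect)
  stat <- mc - mi
  if (stat < -1e-6)
    warning("negative likelihood-ratio statistic; a fit may not have converged")
  stat <- max(stat, 0)
  list(minus2logL_classic = mc, minus2logL_indirect = mi,
       statistic = stat, df = 2L,
       p_value = stats::pchisq(stat, df = 2, lower.tail = FALSE))
}
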