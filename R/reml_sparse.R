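## Sparse MME REML engine.
##
## Everything is computed from the mixed-model equations M s = W'y/eD with
## M = W'W/eD + blockdiag(0, G^-1):
##   - restricted log-likelihood via
##     log|V| + log|X'V^-1X| = log|R| + log|G| + log|M|;
##   - gradient traces via the identity Z'PZ = G^-1 - G^-1 C G^-1, where
##     C = M^-1, so that tr(P Z_k Z_k') needs only the trace of the
##     corresponding diagonal block of C (and, for the genetic block,
##     traces of A^-1 times blocks of C); those inverse entries come from
##     the selected inverse of the sparse Cholesky factor (Takahashi);
##   - the average-information matrix from the vectors f_k = V_k P y,
##     since P f_k is one extra multi-right-hand-side MME solve.
## The residual trace uses tr(P V) = n - p.
.engine_sparse <- function(design, Ainv, A_logdet, model, ys, X) {
  n <- length(ys)
  p <- ncol(X)
  blocks <- .random_blocks(design, model)
  Zall <- do.call(cbind, unname(blocks))
  Wfull <- cbind(methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix"),
                 Zall)
  WtW <- Matrix::forceSymmetric(Matrix::crossprod(Wfull))
  Wty <- as.numeric(Matrix::crossprod(Wfull, ys))
  yty <- sum(ys^2)
  sizes <- vapply(blocks, ncol, integer(1))
  np <- length(design$ped_ids)
  m <- p + sum(sizes)
  idx <- list(); st <- p
  for (nm in names(blocks)) {
    idx[[nm]] <- st + seq_len(sizes[[nm]])
    st <- st + sizes[[nm]]
  }
  pnames <- if (model == "INDIRECT")
    c("aD", "aI", "aDI", "u", "lD", "lI", "eI", "eD")
  else c("aD", "u", "lD", "lI", "eI", "eD")
  env_block <- c(u = "u", lD = "l_D", lI = "l_I", eI = "e_I")
  Ainv <- Matrix::forceSymmetric(Ainv)
  chA <- Matrix::Cholesky(Ainv, LDL = FALSE, perm = TRUE)
  Amult <- function(v) as.numeric(Matrix::solve(chA, v))
  AinvT <- methods::as(methods::as(Ainv, "generalMatrix"), "TsparseMatrix")

  sigma_inv <- function(theta) {
    if (model != "INDIRECT") return(NULL)
    Sg <- matrix(c(theta[["aD"]], theta[["aDI"]], theta[["aDI"]],
                   theta[["aI"]]), 2, 2)
    if (det(Sg) <= 0) return(NULL)
    Si <- solve(Sg)
    ## keep the cross-block pattern structurally present even at aDI = 0
    if (Si[1, 2] == 0) Si[1, 2] <- Si[2, 1] <- 1e-300
    Si
  }
  build_M <- function(theta) {
    Gg <- if (model == "INDIRECT") {
      Si <- sigma_inv(theta)
      if (is.null(Si)) return(NULL)
      Matrix::kronecker(Si, Ainv)
    } else Ainv / theta[["aD"]]
    pen <- Matrix::bdiag(c(list(Matrix::Matrix(0, p, p)), list(Gg),
                           lapply(c("u", "lD", "lI", "eI"), function(k)
                             Matrix::Diagonal(sizes[[env_block[[k]]]]) /
                               theta[[k]])))
    Matrix::forceSymmetric(WtW / theta[["eD"]] + pen)
  }
  logdetG <- function(theta) {
    qe <- sizes[c("u", "l_D", "l_I", "e_I")]
    base <- sum(qe * log(theta[c("u", "lD", "lI", "eI")]))
    if (model == "INDIRECT") {
      d <- theta[["aD"]] * theta[["aI"]] - theta[["aDI"]]^2
      base + np * log(d) + 2 * A_logdet
    } else base + np * log(theta[["aD"]]) + A_logdet
  }

  env <- new.env(parent = emptyenv())
  env$chM <- NULL
  env$pos <- NULL
  factorize <- function(M) {
    if (is.null(env$chM)) {
      env$chM <- tryCatch(Matrix::Cholesky(M, LDL = FALSE, super = FALSE,
                                           perm = TRUE),
                          error = function(e) NULL)
      env$chM
    } else {
      tryCatch(Matrix::.updateCHMfactor(env$chM, M, mult = 0),
               error = function(e) NULL)
    }
  }

  at <- function(theta) {
    M <- build_M(theta)
    if (is.null(M)) return(NULL)
    ch <- factorize(M)
    if (is.null(ch)) return(NULL)
    L <- methods::as(ch, "sparseMatrix")
    dpos <- L@p[seq_len(m)] + 1L
    dL <- L@x[dpos]
    if (any(!is.finite(dL)) || any(dL <= 0)) return(NULL)
    logdetM <- 2 * sum(log(dL))
    rhs <- Wty / theta[["eD"]]
    sol <- as.numeric(Matrix::solve(ch, rhs))
    yPy <- yty / theta[["eD"]] - sum(sol * rhs)
    ll <- -0.5 * ((n - p) * log(2 * pi) + n * log(theta[["eD"]]) +
                    logdetG(theta) + logdetM + yPy)
    if (!is.finite(ll)) return(NULL)
    list(ll = ll, ch = ch, L = L, sol = sol)
  }

  ## cache positions of required inverse entries in the factor pattern
  position_cache <- function(L, ch) {
    perm <- ch@perm + 1L
    iperm <- integer(m); iperm[perm] <- seq_len(m)
    dpos <- (L@p[seq_len(m)] + 1L)[iperm]   # zx position of C[i,i]
    out <- list(diag = dpos)
    if (model == "INDIRECT") {
      Lpos <- Matrix::sparseMatrix(i = L@i + 1L, p = L@p,
                                   x = seq_along(L@x), dims = dim(L))
      lookup <- function(i1, i2) {
        q1 <- iperm[i1]; q2 <- iperm[i2]
        r <- pmax(q1, q2); c <- pmin(q1, q2)
        pos <- Lpos[cbind(r, c)]
        if (any(pos == 0)) stop("inverse entry outside factor pattern")
        pos
      }
      a <- AinvT@i + 1L; b <- AinvT@j + 1L
      oD <- idx$a_D[1] - 1L; oI <- idx$a_I[1] - 1L
      out$w <- AinvT@x
      out$DD <- lookup(oD + b, oD + a)
      out$II <- lookup(oI + b, oI + a)
      out$DI <- lookup(oD + b, oI + a)
    } else {
      Lpos <- Matrix::sparseMatrix(i = L@i + 1L, p = L@p,
                                   x = seq_along(L@x), dims = dim(L))
      a <- AinvT@i + 1L; b <- AinvT@j + 1L
      oD <- idx$a_D[1] - 1L
      q1 <- iperm[oD + b]; q2 <- iperm[oD + a]
      pos <- Lpos[cbind(pmax(q1, q2), pmin(q1, q2))]
      if (any(pos == 0)) stop("inverse entry outside factor pattern")
      out$w <- AinvT@x
      out$DD <- pos
    }
    out
  }

  grad_ai <- function(theta, state) {
    ch <- state$ch; L <- state$L
    if (is.null(env$pos)) env$pos <- position_cache(L, ch)
    pos <- env$pos
    eD <- theta[["eD"]]
    Py <- as.numeric(ys - Wfull %*% state$sol) / eD
    ## f_k = V_k P y
    ZD <- design$Z_D; ZI <- design$Z_I
    tD <- as.numeric(Matrix::crossprod(ZD, Py))
    AtD <- Amult(tD)
    Fm <- matrix(0, n, length(pnames),
                 dimnames = list(NULL, pnames))
    Fm[, "aD"] <- as.numeric(ZD %*% AtD)
    if (model == "INDIRECT") {
      tI <- as.numeric(Matrix::crossprod(ZI, Py))
      AtI <- Amult(tI)
      Fm[, "aI"] <- as.numeric(ZI %*% AtI)
      Fm[, "aDI"] <- as.numeric(ZD %*% AtI) + as.numeric(ZI %*% AtD)
    }
    Fm[, "u"] <- as.numeric(design$W %*% Matrix::crossprod(design$W, Py))
    Fm[, "lD"] <- as.numeric(design$Q_D %*% Matrix::crossprod(design$Q_D, Py))
    Fm[, "lI"] <- as.numeric(design$Q_I %*% Matrix::crossprod(design$Q_I, Py))
    Fm[, "eI"] <- as.numeric(design$R_I %*% Matrix::crossprod(design$R_I, Py))
    Fm[, "eD"] <- Py
    ## selected inverse of the coefficient matrix
    zx <- takahashi_selected_inverse(L@p, L@i, L@x)
    dC <- zx[pos$diag]
    trPV <- stats::setNames(numeric(length(pnames)), pnames)
    for (k in c("u", "lD", "lI", "eI")) {
      q <- sizes[[env_block[[k]]]]
      trC <- sum(dC[idx[[env_block[[k]]]]])
      trPV[[k]] <- q / theta[[k]] - trC / theta[[k]]^2
    }
    if (model == "INDIRECT") {
      Si0 <- sigma_inv(theta)
      T_DD <- sum(pos$w * zx[pos$DD])
      T_II <- sum(pos$w * zx[pos$II])
      T_DI <- sum(pos$w * zx[pos$DI])
      Tm <- matrix(c(T_DD, T_DI, T_DI, T_II), 2, 2)
      dE <- list(aD = matrix(c(1, 0, 0, 0), 2, 2),
                 aDI = matrix(c(0, 1, 1, 0), 2, 2),
                 aI = matrix(c(0, 0, 0, 1), 2, 2))
      for (k in names(dE)) {
        E <- dE[[k]]
        SES <- Si0 %*% E %*% Si0
        trPV[[k]] <- np * sum(diag(Si0 %*% E)) - sum(SES * Tm)
      }
    } else {
      T_DD <- sum(pos$w * zx[pos$DD])
      trPV[["aD"]] <- np / theta[["aD"]] - T_DD / theta[["aD"]]^2
    }
    nonres <- setdiff(pnames, "eD")
    trPV[["eD"]] <- (n - p - sum(theta[nonres] * trPV[nonres])) / eD
    gr <- -0.5 * (trPV - as.numeric(crossprod(Fm, Py)))
    ## average information
    RHS <- Matrix::crossprod(Wfull, Fm) / eD
    S <- Matrix::solve(ch, RHS)
    PF <- (Fm - as.matrix(Wfull %*% S)) / eD
    AI <- 0.5 * crossprod(Fm, PF)
    list(gr = as.numeric(gr), AI = (AI + t(AI)) / 2)
  }

  list(at = at, grad_ai = grad_ai, pnames = pnames)
}
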