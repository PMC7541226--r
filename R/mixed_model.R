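#' Variance components for the indirect genetic (social) animal model
#'
#' Holds the eight (co)variance parameters of the model with both direct and
#' indirect genetic effects: direct genetic (`aD`), indirect genetic (`aI`),
#' their covariance (`aDI`, alternatively given as the genetic correlation
#' `rho`), sex-year-month (`u`), direct litter (`lD`), indirect litter
#' (`lI`), indirect environmental animal (`eI`) and residual (`eD`)
#' variances, all in squared phenotype units (g^2/day^2 for daily gain).
#'
#' @param aD direct genetic variance.
#' @param aI indirect genetic variance.
#' @param aDI direct-indirect genetic covariance; give either this or `rho`.
#' @param rho genetic correlation between direct and indirect effects.
#' @param u sex-year-month variance.
#' @param lD direct litter variance.
#' @param lI indirect litter variance.
#' @param eI indirect environmental animal variance.
#' @param eD residual variance.
#' @return An object of class `ige_vc` with `model = "INDIRECT"`.
#' @export
vc_indirect <- function(aD, aI, aDI = NULL, rho = NULL,
                        u, lD, lI, eI, eD) {
  if (is.null(aDI)) {
    if (is.null(rho)) stop("give either aDI or rho")
    aDI <- rho * sqrt(aD * aI)
  }
  vc <- list(model = "INDIRECT", aD = aD, aI = aI, aDI = aDI,
             u = u, lD = lD, lI = lI, eI = eI, eD = eD)
  .validate_vc(vc)
  structure(vc, class = "ige_vc")
}

#' Variance components for the classical animal model
#'
#' As [vc_indirect()] but without the indirect genetic variance and the
#' direct-indirect covariance; the indirect litter and indirect
#' environmental animal variances are retained, so that the classical and
#' indirect models differ only in the genetic part.
#'
#' @inheritParams vc_indirect
#' @return An object of class `ige_vc` with `model = "CLASSIC"`.
#' @export
vc_classic <- function(aD, u, lD, lI, eI, eD) {
  vc <- list(model = "CLASSIC", aD = aD, aI = 0, aDI = 0,
             u = u, lD = lD, lI = lI, eI = eI, eD = eD)
  .validate_vc(vc)
  structure(vc, class = "ige_vc")
}

.validate_vc <- function(vc) {
  vars <- c("aD", "aI", "u", "lD", "lI", "eI", "eD")
  bad <- vars[vapply(vars, function(v) vc[[v]] < 0, logical(1))]
  if (length(bad)) stop("negative variance component(s): ", paste(bad, collapse = ", "))
  if (vc$eD <= 0) stop("residual variance must be positive")
  if (vc$model == "INDIRECT" && abs(vc$aDI) > sqrt(vc$aD * vc$aI) + 1e-12)
    stop("|aDI| exceeds sqrt(aD * aI); genetic covariance not valid")
  invisible(vc)
}

#' @export
print.ige_vc <- function(x, ...) {
  cat("Variance components (", x$model, ")\n", sep = "")
  comps <- c(aD = "direct genetic", aI = "indirect genetic",
             aDI = "direct-indirect covariance", u = "sex-year-month",
             lD = "direct litter", lI = "indirect litter",
             eI = "indirect animal", eD = "residual")
  if (x$model == "CLASSIC") comps <- comps[!names(comps) %in% c("aI", "aDI")]
  for (k in names(comps))
    cat(sprintf("  %-28s %12.4g\n", comps[[k]], x[[k]]))
  if (x$model == "INDIRECT" && x$aI > 0)
    cat(sprintf("  %-28s %12.4f\n", "genetic correlation",
                x$aDI / sqrt(x$aD * x$aI)))
  invisible(x)
}

## 2x2 genetic covariance matrix of (direct, indirect) effects
.sigma_g <- function(vc) {
  matrix(c(vc$aD, vc$aDI, vc$aDI, vc$aI), 2, 2)
}

#' Build design matrices for the social animal model
#'
#' Assembles, over the phenotyped animals, the response and all design
#' matrices of the growth model: `X` (fixed: sex, year-by-month of birth
#' class, age-corrected starting weight, within-group starting-weight
#' deviation, time-averaged pen-mate count), `Z_D` (own additive effect),
#' `Z_I` (pen mates' indirect additive effects), `W` (random sex-year-month
#' class), `Q_D` (own litter), `Q_I` (per-litter counts of pen mates) and
#' `R_I` (pen mates' indirect environmental animal effects).  Pen mates are
#' all other members of the animal's group, including removed animals, which
#' appear as effect columns but contribute no phenotype record.
#'
#' Rank-deficient fixed-effect columns are dropped (with a message) so that
#' `X` has full column rank.
#'
#' @param herd a `herdbook` (see [build_herdbook()]).
#' @param ped a sorted `pedigree` covering every grouped animal; its order
#'   defines the genetic-effect columns.
#' @return A `ige_design` list with the response `y`, design matrices, the
#'   id vectors indexing each random-effect block, and the pen-mate map.
#' @export
build_design <- function(herd, ped) {
  .check_sorted(ped)
  if (any(!is.na(herd$adg) & is.na(herd$group)))
    stop("phenotyped animal(s) without a group")
  grouped <- herd[!is.na(herd$group), , drop = FALSE]
  if (!all(grouped$animal %in% ped$animal))
    stop("grouped animal(s) missing from the pedigree")
  phen <- grouped[!is.na(grouped$adg), , drop = FALSE]
  n <- nrow(phen)
  if (n == 0) stop("no phenotyped animals")
  ped_ids <- ped$animal
  eI_ids <- grouped$animal
  litter_ids <- sort(unique(grouped$litter))
  members <- split(grouped$animal, grouped$group)
  litter_of <- stats::setNames(grouped$litter, grouped$animal)
  mates <- lapply(seq_len(n), function(i)
    setdiff(members[[as.character(phen$group[i])]], phen$animal[i]))
  names(mates) <- phen$animal

  ## fixed effects: build with whatever factors have >= 2 levels
  terms <- c("sWghtAge", "sWghtDev", "avg_members")
  fac <- c("sex", "ym")
  fac <- fac[vapply(fac, function(f) length(unique(phen[[f]])) > 1, logical(1))]
  fml <- stats::reformulate(c(fac, terms))
  X <- stats::model.matrix(fml, data = phen)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    message("dropping rank-deficient fixed-effect column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }

  ind <- function(j, nlev) Matrix::sparseMatrix(
    i = seq_len(n), j = j, x = 1, dims = c(n, nlev))
  Z_D <- ind(match(phen$animal, ped_ids), length(ped_ids))
  colnames(Z_D) <- ped_ids
  mate_i <- rep(seq_len(n), lengths(mates))
  mate_id <- unlist(mates, use.names = FALSE)
  Z_I <- Matrix::sparseMatrix(i = mate_i, j = match(mate_id, ped_ids), x = 1,
                              dims = c(n, length(ped_ids)),
                              dimnames = list(NULL, ped_ids))
  sym_levels <- sort(unique(phen$sym))
  W <- ind(match(phen$sym, sym_levels), length(sym_levels))
  colnames(W) <- sym_levels
  Q_D <- ind(match(phen$litter, litter_ids), length(litter_ids))
  colnames(Q_D) <- litter_ids
  Q_I <- Matrix::sparseMatrix(i = mate_i, j = match(litter_of[mate_id], litter_ids),
                              x = 1, dims = c(n, length(litter_ids)),
                              dimnames = list(NULL, litter_ids))
  R_I <- Matrix::sparseMatrix(i = mate_i, j = match(mate_id, eI_ids), x = 1,
                              dims = c(n, length(eI_ids)),
                              dimnames = list(NULL, eI_ids))
  structure(list(y = phen$adg, X = X, Z_D = Z_D, Z_I = Z_I, W = W,
                 Q_D = Q_D, Q_I = Q_I, R_I = R_I,
                 ped_ids = ped_ids, phen_ids = phen$animal, eI_ids = eI_ids,
                 litter_ids = litter_ids, sym_levels = sym_levels,
                 mates = mates),
            class = "ige_design")
}

## random-effect blocks (design matrix, block length) in MME order
.random_blocks <- function(design, model) {
  if (model == "INDIRECT")
    list(a_D = design$Z_D, a_I = design$Z_I, u = design$W,
         l_D = design$Q_D, l_I = design$Q_I, e_I = design$R_I)
  else
    list(a_D = design$Z_D, u = design$W,
         l_D = design$Q_D, l_I = design$Q_I, e_I = design$R_I)
}

#' Assemble Henderson's mixed-model equations
#'
#' Builds the sparse symmetric coefficient matrix and right-hand side of the
#' mixed-model equations at fixed variance components.  The genetic block
#' uses `Sigma^-1 (x) C^-1` (Kronecker product of the inverted 2x2 genetic
#' covariance with the inverse relationship matrix) for the indirect model,
#' or `C^-1 / aD` for the classical model; the environmental blocks receive
#' identity-covariance ridge terms `1/sigma2_k`.
#'
#' @param design an `ige_design` from [build_design()].
#' @param vc an `ige_vc`; its `model` field selects the model.
#' @param Cinv sparse inverse relationship matrix (`A^-1` or `H^-1`) in the
#'   order of `design$ped_ids`.
#' @return List with coefficient matrix `M`, right-hand side `rhs`, and the
#'   index map of solution blocks.
#' @export
assemble_mme <- function(design, vc, Cinv) {
  model <- vc$model
  blocks <- .random_blocks(design, model)
  Zall <- do.call(cbind, unname(blocks))
  Wfull <- cbind(methods::as(Matrix::Matrix(design$X, sparse = TRUE), "CsparseMatrix"), Zall)
  M <- Matrix::crossprod(Wfull) / vc$eD
  rhs <- Matrix::crossprod(Wfull, design$y) / vc$eD
  p <- ncol(design$X)
  np <- length(design$ped_ids)
  if (model == "INDIRECT") {
    Sg <- .sigma_g(vc)
    if (det(Sg) <= 0) stop("2x2 genetic covariance is not positive definite")
    Gg <- Matrix::kronecker(solve(Sg), Cinv)
    pens <- list(Gg)
    rest <- c("u", "lD", "lI", "eI")
  } else {
    pens <- list(Cinv / vc$aD)
    rest <- c("u", "lD", "lI", "eI")
  }
  sizes <- vapply(blocks, ncol, integer(1))
  env_sizes <- sizes[c("u", "l_D", "l_I", "e_I")]
  for (k in seq_along(rest))
    pens <- c(pens, list(Matrix::Diagonal(env_sizes[k]) / vc[[rest[k]]]))
  Pen <- Matrix::bdiag(c(list(Matrix::Matrix(0, p, p)), pens))
  M <- M + Pen
  offs <- cumsum(c(p, sizes))
  index <- list(b = seq_len(p))
  st <- p
  for (nm in names(blocks)) {
    index[[nm]] <- st + seq_len(sizes[[nm]])
    st <- st + sizes[[nm]]
  }
  list(M = Matrix::forceSymmetric(M), rhs = rhs, index = index,
       model = model, p = p, n = length(design$y))
}

#' Solve the mixed-model equations (BLUE/BLUP)
#'
#' Sparse symmetric solve of the assembled equations; solutions are split
#' into the fixed-effect estimates and each random-effect block, and the
#' relative residual of the linear system is recorded.
#'
#' @inheritParams assemble_mme
#' @param C_logdet optional log-determinant of the relationship matrix `C`
#'   matching `Cinv`; when supplied the restricted log-likelihood at `vc` is
#'   stored in the fit (see [reml_loglik()]).
#' @return An `ige_fit` with elements `b`, `a_D`, `a_I` (indirect model
#'   only), `u`, `l_D`, `l_I`, `e_I`, the fitted `vc`, `loglik` (or NA) and
#'   `residual_norm`.
#' @export
solve_blup <- function(design, vc, Cinv, C_logdet = NULL) {
  sys <- assemble_mme(design, vc, Cinv)
  M <- sys$M
  sol <- tryCatch(
    as.numeric(Matrix::solve(M, sys$rhs)),
    error = function(e) stop("singular mixed-model equations; check for ",
                             "confounded effects (", conditionMessage(e), ")"))
  resid <- max(abs(as.numeric(M %*% sol) - as.numeric(sys$rhs))) /
    max(1, max(abs(as.numeric(sys$rhs))))
  out <- list(model = sys$model, vc = vc)
  nm_map <- list(b = colnames(design$X), a_D = design$ped_ids,
                 a_I = design$ped_ids, u = design$sym_levels,
                 l_D = design$litter_ids, l_I = design$litter_ids,
                 e_I = design$eI_ids)
  for (k in names(sys$index))
    out[[k]] <- stats::setNames(sol[sys$index[[k]]], nm_map[[k]])
  out$residual_norm <- resid
  out$loglik <- if (!is.null(C_logdet))
    reml_loglik(design, vc, Cinv, C_logdet) else NA_real_
  structure(out, class = "ige_fit")
}

#' @export
print.ige_fit <- function(x, ...) {
  cat("Social animal model fit (", x$model, ")\n", sep = "")
  cat("  fixed effects:   ", length(x$b), "\n")
  cat("  genetic effects: ", length(x$a_D),
      if (!is.null(x$a_I)) " (direct + indirect)" else " (direct)", "\n", sep = "")
  if (!is.na(x$loglik)) cat("  REML log-likelihood:", format(x$loglik), "\n")
  cat("  MME relative residual:", format(x$residual_norm, digits = 3), "\n")
  invisible(x)
}

#' Write mixed-model solutions as CSV
#'
#' One row per solution, keyed by effect type and level.
#'
#' @param fit an `ige_fit` from [solve_blup()].
#' @param path output CSV path.
#' @export
write_solutions <- function(fit, path) {
  blocks <- c("b", "a_D", "a_I", "u", "l_D", "l_I", "e_I")
  rows <- lapply(blocks, function(k) {
    v <- fit[[k]]
    if (is.null(v)) return(NULL)
    data.frame(effect = k, level = names(v), solution = unname(v))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export a design matrix in coordinate (triplet) text form
#'
#' @param M a (sparse) design matrix, e.g. an element of an `ige_design`.
#' @param path output CSV path with columns `i`, `j`, `value`.
#' @export
write_design <- function(M, path) {
  T <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
  utils::write.csv(data.frame(i = T@i + 1L, j = T@j + 1L, value = T@x),
                   path, row.names = FALSE)
  invisible(path)
}
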