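#' Forward (date-based) training/validation split
#'
#' Training data are the phenotyped animals in groups whose members were
#' *all* born before the cutoff date; validation data are the remaining
#' phenotyped animals.  Splitting whole groups keeps pen mates on one side,
#' so no validation animal contributes information to the training fit.
#'
#' @param herd a `herdbook`.
#' @param cutoff cutoff `Date`.
#' @return List with `train_ids`, `valid_ids` (phenotyped animals only) and
#'   the per-group assignment.
#' @export
forward_split <- function(herd, cutoff) {
  cutoff <- as.Date(cutoff)
  grouped <- herd[!is.na(herd$group), ]
  before <- tapply(grouped$birth_date < cutoff, grouped$group, all)
  gtrain <- names(before)[before]
  phen <- grouped[!is.na(grouped$adg), ]
  train <- phen$animal[phen$group %in% gtrain]
  valid <- setdiff(phen$animal, train)
  if (!length(train)) stop("empty training set; move the cutoff later")
  if (!length(valid)) stop("empty validation set; move the cutoff earlier")
  list(train_ids = train, valid_ids = valid,
       groups = data.frame(group = names(before), training = as.logical(before)))
}

#' Corrected phenotypes
#'
#' `y_c = y - X b`: observed phenotypes minus the estimated fixed effects.
#' By convention `b` comes from the full-data fit of the social model with
#' pedigree relationships, so all models are validated against the same
#' target.
#'
#' @param y phenotype vector.
#' @param X fixed-effect design matrix (rows matching `y`).
#' @param b fixed-effect solutions matching the columns of `X`.
#' @return Corrected phenotypes.
#' @export
corrected_phenotypes <- function(y, X, b) {
  if (length(b) != ncol(X)) stop("length(b) must equal ncol(X)")
  as.numeric(y - X %*% b)
}

#' Predicted genetic levels: direct and total genetic effects
#'
#' The direct genetic effect (DGE) of an animal is its own predicted
#' additive effect; its total genetic effect (TGE) adds the predicted
#' indirect effects of all its pen mates, `TGE_i = aD_i + sum_{j != i}
#' aI_j`, the genetic level expected to predict its phenotype in a social
#' setting.  TGE requires a fit of the indirect model.
#'
#' @param fit an `ige_fit` from [solve_blup()].
#' @param design the `ige_design` whose pen-mate map defines the groups
#'   (typically the full-data design, so every validation animal has its
#'   mates).
#' @param ids animals to evaluate (default: all phenotyped animals of the
#'   design).
#' @return Data frame with columns `animal`, `DGE` and (indirect model)
#'   `TGE`.
#' @export
genetic_levels <- function(fit, design, ids = design$phen_ids) {
  ids <- as.character(ids)
  dge <- fit$a_D[ids]
  out <- data.frame(animal = ids, DGE = unname(dge))
  if (fit$model == "INDIRECT") {
    if (is.null(fit$a_I)) stop("indirect fit lacks indirect solutions")
    mates <- design$mates[ids]
    if (any(lengths(mates) == 0))
      warning("animal(s) without pen mates: TGE equals DGE")
    out$TGE <- out$DGE + vapply(mates, function(m)
      sum(fit$a_I[m]), numeric(1))
  }
  out
}

#' Predictive performance (Pearson correlation)
#'
#' Sample correlation between corrected phenotypes and predicted genetic
#' levels over the validation animals.
#'
#' @param yc corrected phenotypes.
#' @param level predicted genetic levels (same animals, same order).
#' @return Pearson correlation.
#' @export
predictive_performance <- function(yc, level) {
  if (length(yc) < 3) stop("need at least 3 animals")
  if (stats::sd(yc) == 0 || stats::sd(level) == 0)
    stop("zero variance; correlation undefined")
  stats::cor(yc, level)
}

#' Prediction bias (regression slope)
#'
#' Ordinary least-squares slope of corrected phenotypes on predicted
#' genetic levels; 1 indicates unbiased dispersion of the predictions.
#'
#' @inheritParams predictive_performance
#' @return Regression slope.
#' @export
prediction_bias <- function(yc, level) {
  if (stats::sd(level) == 0) stop("zero variance in genetic levels")
  unname(stats::coef(stats::lm(yc ~ level))[2])
}

#' Hotelling-Williams test for two dependent correlations
#'
#' Tests whether two predictors correlate equally with a shared target:
#' given `r12 = cor(target, predictor A)`, `r13 = cor(target, predictor B)`
#' and `r23 = cor(A, B)` on `n` observations, Williams' statistic is
#'
#' `t = (r12 - r13) * sqrt((n - 1) (1 + r23) /
#'      (2 |R| (n - 1)/(n - 3) + rbar^2 (1 - r23)^3))`
#'
#' with `|R| = 1 - r12^2 - r13^2 - r23^2 + 2 r12 r13 r23`,
#' `rbar = (r12 + r13)/2`, referred to a t distribution with `n - 3`
#' degrees of freedom (two-sided).
#'
#' @param r12,r13 correlations of the two predictors with the target.
#' @param r23 correlation between the two predictors.
#' @param n number of observations (> 3).
#' @return List with `statistic`, `df` and `p_value`.
#' @export
hotelling_williams <- function(r12, r13, r23, n) {
  if (n <= 3) stop("n must exceed 3")
  if (any(abs(c(r12, r13, r23)) >= 1)) stop("correlations must be in (-1, 1)")
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  rbar <- (r12 + r13) / 2
  tstat <- (r12 - r13) * sqrt((n - 1) * (1 + r23) /
    (2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r23)^3))
  list(statistic = tstat, df = n - 3,
       p_value = 2 * stats::pt(abs(tstat), df = n - 3, lower.tail = FALSE))
}
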