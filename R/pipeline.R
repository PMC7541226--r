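#' Run the full social genetic evaluation
#'
#' Orchestrates the four named analyses from one call: `CLASSIC_PED` and
#' `INDIRECT_PED` (genetic effects predicted with the pedigree relationship
#' matrix A) and `CLASSIC_GEN` and `INDIRECT_GEN` (predicted with the
#' single-step matrix H at each blending weight in `w_grid`).  The stages
#' are: pedigree truncation and relationship matrices; SNP quality control,
#' the genomic relationship matrix, tuning and blending; variance-component
#' estimation by AI-REML with A as genetic covariance structure (the
#' single-step matrix is used for prediction only, as genomic estimation of
#' variance components is known to shrink them); the likelihood-ratio test
#' for indirect genetic effects; heritability summaries; and forward
#' validation with corrected phenotypes, predictive correlations and
#' prediction bias across the blending-weight grid.
#'
#' @param ped a `pedigree` (or data frame coercible with [as_pedigree()])
#'   covering all grouped animals.
#' @param herd a `herdbook` from [build_herdbook()].
#' @param geno optional dosage matrix (animals x SNPs, NA missing).
#' @param map optional SNP map (`snp`, `chrom`) for sex-chromosome-aware QC.
#' @param w_grid blending weights for the genomic analyses; the
#'   conventional grid is 5% steps from 0.05 to 0.95 plus 0.99.
#' @param cutoff forward-validation cutoff date: training groups are those
#'   whose members were all born before it.
#' @param vc_classic,vc_indirect optional `ige_vc` objects; when `NULL`
#'   they are estimated by [ai_reml()] on the full data.
#' @param generations pedigree truncation horizon (meioses before the
#'   grouped animals).
#' @param correct_with `"full"` (default): corrected phenotypes use fixed
#'   effects from the full-data indirect fit with A; `"training"`: from
#'   the training-data fit.
#' @param reml_args extra arguments passed to [ai_reml()].
#' @param validate run the forward-validation stage (skipped when `FALSE`,
#'   e.g. for variance-component-only analyses).
#' @param verbose log stage progress and counts.
#' @return An `ige_run` list: relationship summaries (`n_bar`, `r`),
#'   estimated or supplied variance components with standard errors, the
#'   likelihood-ratio test, the heritability table, the validation split,
#'   the performance table (one row per analysis and weight) and the
#'   corrected phenotypes.
#' @export
run_ige <- function(ped, herd, geno = NULL, map = NULL,
                    w_grid = c(seq(0.05, 0.95, by = 0.05), 0.99),
                    cutoff = as.Date("2018-01-01"),
                    vc_classic = NULL, vc_indirect = NULL,
                    generations = 5L,
                    correct_with = c("full", "training"),
                    reml_args = list(), validate = TRUE, verbose = TRUE) {
  correct_with <- match.arg(correct_with)
  say <- function(...) if (verbose) message(...)
  if (!inherits(ped, "pedigree")) ped <- as_pedigree(ped)
  grouped <- herd$animal[!is.na(herd$group)]
  say("pedigree: truncating to ", generations, " generations before ",
      length(grouped), " grouped animals")
  ped_t <- truncate_pedigree(ped, grouped, generations)
  A <- make_A(ped_t)
  Ainv <- make_Ainv(ped_t, f = attr(A, "F"))
  n_bar <- group_sizes(herd[!is.na(herd$group), ])$n_bar
  r_bar <- as.numeric(mean_group_relatedness(
    A, data.frame(animal = herd$animal[!is.na(herd$group)],
                  group = herd$group[!is.na(herd$group)])))
  say(sprintf("pedigree: %d animals; mean group size %.2f; mean pen relatedness %.3f",
              nrow(ped_t), n_bar, r_bar))

  gen <- NULL
  if (!is.null(geno)) {
    qc <- snp_qc(geno, ped_t, map)
    say(sprintf("genotypes: %d of %d SNPs pass QC on %d animals",
                ncol(qc$genotypes), ncol(geno), nrow(geno)))
    freq <- colMeans(qc$genotypes, na.rm = TRUE) / 2
    imp <- impute_mean(qc$genotypes)
    ids_g <- intersect(rownames(imp), ped_t$animal)
    G <- vanraden_G(imp[ids_g, , drop = FALSE], freq)
    A22 <- A[ids_g, ids_g]
    Gstar <- tune_G(G, A22)
    gen <- list(ids = ids_g, Gstar = Gstar, A22 = A22, qc = qc$report)
  }

  design_full <- build_design(herd, ped_t)
  if (is.null(vc_indirect) || is.null(vc_classic)) {
    say("REML: estimating variance components with A (both models)")
    fitC <- do.call(ai_reml, c(list(design_full, A = A, model = "CLASSIC",
                                    Ainv = Ainv), reml_args))
    ## warm-start the social model at the classical optimum with a small
    ## social variance: the nested fit can then only improve
    startI <- vc_indirect(aD = fitC$vc$aD, aI = 1e-4 * fitC$vc$aD, aDI = 0,
                          u = fitC$vc$u, lD = fitC$vc$lD, lI = fitC$vc$lI,
                          eI = fitC$vc$eI, eD = fitC$vc$eD)
    fitI <- do.call(ai_reml, c(list(design_full, A = A, model = "INDIRECT",
                                    Ainv = Ainv, start = startI), reml_args))
    vc_classic <- fitC$vc; vc_indirect <- fitI$vc
    se <- list(classic = fitC$se, indirect = fitI$se)
    lrt <- lrt_ige(fitC, fitI)
  } else {
    se <- NULL
    lrt <- NULL
  }
  summary_table <- vc_table(vc_classic, vc_indirect, n_bar, r_bar)

  out <- list(ped = ped_t, n_bar = n_bar, r = r_bar,
              vc_classic = vc_classic, vc_indirect = vc_indirect,
              se = se, lrt = lrt, summary = summary_table,
              herd = herd, design_full = design_full,
              Ainv = Ainv, A_logdet = attr(Ainv, "logdet"),
              gen = gen, cutoff = as.Date(cutoff),
              correct_with = correct_with)
  class(out) <- "ige_run"
  if (!validate) return(out)

  say("validation: forward split at ", format(as.Date(cutoff)))
  out <- prepare_validation(out)
  say(sprintf("validation: %d training / %d validation animals",
              length(out$split$train_ids), length(out$split$valid_ids)))
  out$performance <- w_sweep(out, w_grid)
  out
}

#' Prepare the forward-validation state of a run
#'
#' Splits the herd at the cutoff date, fits both models on the training
#' data with pedigree relationships, and computes corrected phenotypes for
#' the validation animals.
#'
#' @param run an `ige_run` (from [run_ige()], possibly with
#'   `validate = FALSE`).
#' @return The run with `split`, `fits` (pedigree-based training fits),
#'   `design_train` and `yc` (corrected phenotypes of validation animals)
#'   added.
#' @export
prepare_validation <- function(run) {
  herd <- run$herd
  split <- forward_split(herd, run$cutoff)
  herd_train <- herd
  herd_train$adg[herd_train$animal %in% split$valid_ids] <- NA_real_
  design_train <- build_design(herd_train, run$ped)
  fit_ped_c <- solve_blup(design_train, run$vc_classic, run$Ainv)
  fit_ped_i <- solve_blup(design_train, run$vc_indirect, run$Ainv)
  bfit <- if (run$correct_with == "full")
    solve_blup(run$design_full, run$vc_indirect, run$Ainv)
  else fit_ped_i
  phen_ids <- run$design_full$phen_ids
  yc_all <- corrected_phenotypes(run$design_full$y,
                                 run$design_full$X[, names(bfit$b), drop = FALSE],
                                 bfit$b)
  vi <- match(split$valid_ids, phen_ids)
  run$split <- split
  run$design_train <- design_train
  run$fits <- list(CLASSIC_PED = fit_ped_c, INDIRECT_PED = fit_ped_i)
  run$yc <- stats::setNames(yc_all[vi], split$valid_ids)
  run
}

.performance_row <- function(run, fit, label, covariance, w) {
  gl <- genetic_levels(fit, run$design_full, ids = run$split$valid_ids)
  yc <- run$yc
  row <- data.frame(model = label, covariance = covariance, w = w,
                    corr_DGE = predictive_performance(yc, gl$DGE),
                    corr_TGE = NA_real_,
                    bias_DGE = prediction_bias(yc, gl$DGE),
                    bias_TGE = NA_real_,
                    n = length(yc))
  if (!is.null(gl$TGE)) {
    row$corr_TGE <- predictive_performance(yc, gl$TGE)
    row$bias_TGE <- prediction_bias(yc, gl$TGE)
  }
  row
}

#' Sweep the genomic blending weight
#'
#' Re-predicts (never re-estimates) genetic effects at each blending weight
#' in the grid, re-forming the single-step H inverse and re-solving the
#' training mixed-model equations for both models, and records predictive
#' correlation and bias of direct and total genetic effects against the
#' corrected phenotypes of the validation animals.  Pedigree-based rows
#' (`w = NA`) are always included.
#'
#' @param run an `ige_run` with validation prepared (see
#'   [prepare_validation()]).
#' @param w_grid numeric vector of blending weights in `[0, 0.99]`.
#' @return A `PerformanceTable` data frame: model, covariance, w,
#'   `corr_DGE`, `corr_TGE`, `bias_DGE`, `bias_TGE`, n.
#' @export
w_sweep <- function(run, w_grid) {
  if (is.null(run$split)) run <- prepare_validation(run)
  perf <- rbind(.performance_row(run, run$fits$CLASSIC_PED, "CLASSIC", "A", NA),
                .performance_row(run, run$fits$INDIRECT_PED, "INDIRECT", "A", NA))
  if (!is.null(run$gen) && length(w_grid)) {
    for (w in w_grid) {
      Gw <- blend_G(run$gen$Gstar, run$gen$A22, w)
      Hinv <- make_Hinv(run$Ainv, run$gen$A22, Gw, run$gen$ids)
      fc <- solve_blup(run$design_train, run$vc_classic, Hinv)
      fi <- solve_blup(run$design_train, run$vc_indirect, Hinv)
      perf <- rbind(perf,
                    .performance_row(run, fc, "CLASSIC", "H", w),
                    .performance_row(run, fi, "INDIRECT", "H", w))
    }
  }
  rownames(perf) <- NULL
  perf
}

#' Plot predictive performance or bias against the blending weight
#'
#' Line plot of the chosen metric for direct and total genetic effects of
#' the genomic analyses across the blending-weight grid, with the
#' pedigree-based analyses drawn as horizontal reference lines.
#'
#' @param perf a performance table from [w_sweep()].
#' @param metric `"correlation"` or `"bias"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_w_sweep <- function(perf, metric = c("correlation", "bias"), ...) {
  metric <- match.arg(metric)
  cols <- if (metric == "correlation") c("corr_DGE", "corr_TGE") else
    c("bias_DGE", "bias_TGE")
  gen <- perf[perf$covariance == "H", ]
  ped <- perf[perf$covariance == "A", ]
  ww <- sort(unique(gen$w))
  series <- cbind(
    CLASSIC_DGE = gen[gen$model == "CLASSIC", cols[1]][order(gen$w[gen$model == "CLASSIC"])],
    INDIRECT_DGE = gen[gen$model == "INDIRECT", cols[1]][order(gen$w[gen$model == "INDIRECT"])],
    INDIRECT_TGE = gen[gen$model == "INDIRECT", cols[2]][order(gen$w[gen$model == "INDIRECT"])])
  graphics::matplot(ww, series, type = "b", pch = c(1, 16, 17),
                    lty = c(2, 1, 1),
                    xlab = "weight on genomic relationship matrix",
                    ylab = if (metric == "correlation")
                      "predictive correlation" else "regression slope", ...)
  graphics::abline(h = ped[ped$model == "INDIRECT", cols], lty = 3,
                   col = "grey50")
  graphics::legend("bottomright", colnames(series), pch = c(1, 16, 17),
                   lty = c(2, 1, 1), col = 1:3, bty = "n")
  invisible(series)
}

#' @export
print.ige_run <- function(x, ...) {
  cat("Social genetic evaluation\n")
  cat(sprintf("  groups: mean size %.2f, mean pen relatedness %.3f\n",
              x$n_bar, x$r))
  cat("  variance components (CLASSIC | INDIRECT):\n")
  tab <- x$summary
  for (i in seq_len(nrow(tab)))
    cat(sprintf("    %-12s %12.4g %12.4g\n", tab$quantity[i],
                tab$classic[i], tab$indirect[i]))
  if (!is.null(x$lrt))
    cat(sprintf("  LRT for indirect genetic effects: chi2 = %.3f, p = %.3f\n",
                x$lrt$statistic, x$lrt$p_value))
  if (!is.null(x$performance)) {
    cat("  predictive performance (validation n =", x$performance$n[1], "):\n")
    best <- x$performance[which.max(pmax(x$performance$corr_TGE,
                                         x$performance$corr_DGE, na.rm = TRUE)), ]
    cat(sprintf("    best: %s_%s at w = %s (corr = %.3f)\n", best$model,
                if (best$covariance == "A") "PED" else "GEN",
                format(best$w), max(best$corr_TGE, best$corr_DGE, na.rm = TRUE)))
  }
  invisible(x)
}
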