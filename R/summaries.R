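#' Total heritable variance under the social model
#'
#' With average group size `n_bar`, each animal's genes affect its own
#' phenotype once and the phenotypes of `n_bar - 1` pen mates, so the
#' variance usable by selection is
#' `aD + 2 (n_bar - 1) aDI + (n_bar - 1)^2 aI`.
#'
#' @param vc an `ige_vc` with `model = "INDIRECT"`.
#' @param n_bar average group size at test start (>= 1).
#' @return Total heritable variance, squared phenotype units.
#' @export
total_heritable_variance <- function(vc, n_bar) {
  if (vc$model != "INDIRECT") stop("total heritable variance requires the indirect model")
  if (n_bar < 1) stop("n_bar must be >= 1")
  m <- n_bar - 1
  vc$aD + 2 * m * vc$aDI + m^2 * vc$aI
}

#' Environmental variance
#'
#' `u + lD + (n_bar - 1) (lI + eI) + eD`: each animal is exposed to one
#' sex-year-month level, its own litter effect, the indirect litter and
#' indirect animal effects of its `n_bar - 1` mates, and its residual.
#'
#' @inheritParams total_heritable_variance
#' @param vc an `ige_vc` (either model).
#' @return Environmental variance, squared phenotype units.
#' @export
env_variance <- function(vc, n_bar) {
  if (n_bar < 1) stop("n_bar must be >= 1")
  vc$u + vc$lD + (n_bar - 1) * (vc$lI + vc$eI) + vc$eD
}

#' Phenotypic variance
#'
#' Classical model: `aD + env`.  Social model:
#' `aD + (n_bar - 1) aI + r (n_bar - 1) (2 aDI + (n_bar - 2) aI) + env`,
#' where `r` is the mean additive relatedness among pen mates: related mates
#' share genetic effects, which feeds the direct-indirect covariance and
#' indirect-indirect covariance into the phenotypic variance.
#'
#' @inheritParams env_variance
#' @param r mean within-pen relatedness in `[0, 1]` (ignored for the
#'   classical model).
#' @return Phenotypic variance, squared phenotype units.
#' @export
phenotypic_variance <- function(vc, n_bar, r = 0) {
  if (r < 0 || r > 1) stop("r must be in [0, 1]")
  env <- env_variance(vc, n_bar)
  if (vc$model == "CLASSIC") return(vc$aD + env)
  m <- n_bar - 1
  vc$aD + m * vc$aI + r * m * (2 * vc$aDI + (n_bar - 2) * vc$aI) + env
}

#' Direct and total heritability
#'
#' Direct heritability `h2 = aD / sigma2_p`; total heritability
#' `T2 = sigma2_TBV / sigma2_p` (social model only).  `T2` can exceed `h2`
#' when indirect genetic effects contribute heritable variance.
#'
#' @inheritParams phenotypic_variance
#' @return List with `h2`, `T2` (NA for the classical model), `sigma2_TBV`
#'   (NA for classical), `sigma2_env` and `sigma2_p`.
#' @export
heritabilities <- function(vc, n_bar, r = 0) {
  s2p <- phenotypic_variance(vc, n_bar, r)
  if (s2p <= 0) stop("phenotypic variance must be positive")
  s2env <- env_variance(vc, n_bar)
  if (vc$model == "INDIRECT") {
    s2tbv <- total_heritable_variance(vc, n_bar)
    list(h2 = vc$aD / s2p, T2 = s2tbv / s2p,
         sigma2_TBV = s2tbv, sigma2_env = s2env, sigma2_p = s2p)
  } else {
    list(h2 = vc$aD / s2p, T2 = NA_real_,
         sigma2_TBV = NA_real_, sigma2_env = s2env, sigma2_p = s2p)
  }
}

#' Variance-component and heritability report
#'
#' Side-by-side table of the estimated (co)variance components, phenotypic
#' variance, total heritable variance and heritabilities for the classical
#' and social models, in the layout conventional for growth-trait reports.
#'
#' @param classic an `ige_vc` with `model = "CLASSIC"` (or `NULL`).
#' @param indirect an `ige_vc` with `model = "INDIRECT"` (or `NULL`).
#' @param n_bar average group size at test start.
#' @param r mean within-pen relatedness.
#' @return Data frame with one row per quantity and one column per model.
#' @export
vc_table <- function(classic = NULL, indirect = NULL, n_bar, r) {
  col <- function(vc) {
    if (is.null(vc)) return(NULL)
    h <- heritabilities(vc, n_bar, r)
    rho <- if (vc$model == "INDIRECT" && vc$aI > 0)
      vc$aDI / sqrt(vc$aD * vc$aI) else NA_real_
    c(sigma2_aD = vc$aD,
      sigma2_aI = if (vc$model == "INDIRECT") vc$aI else NA_real_,
      rho_aDI = rho,
      sigma2_u = vc$u, sigma2_lD = vc$lD, sigma2_eD = vc$eD,
      sigma2_lI = vc$lI, sigma2_eI = vc$eI,
      sigma2_p = h$sigma2_p, sigma2_TBV = h$sigma2_TBV,
      h2 = h$h2, T2 = h$T2)
  }
  out <- data.frame(quantity = names(col(if (is.null(indirect)) classic else indirect)))
  if (!is.null(classic)) out$classic <- unname(col(classic))
  if (!is.null(indirect)) out$indirect <- unname(col(indirect))
  out
}
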