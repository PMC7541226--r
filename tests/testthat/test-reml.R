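test_that("the MME-identity log-likelihood equals the dense-V formula", {
  cfg <- sim_config_fixture()
  sim <- simulate_herd(cfg)
  des <- build_design(sim$herd, sim$ped)
  A <- make_A(sim$ped); Ai <- make_Ainv(sim$ped)
  vcc <- vc_classic(aD = 3339, u = 951, lD = 636, lI = 37.7, eI = 112.9,
                    eD = 10971)
  for (vc in list(cfg$vc, vcc)) {
    ll <- reml_loglik(des, vc, Ai)
    oracle <- dense_blup_oracle(des, vc, A)
    expect_equal(ll, oracle$loglik, tolerance = 1e-8)
  }
})

test_that("the restricted likelihood ignores translations along fixed effects", {
  cfg <- sim_config_fixture()
  sim <- simulate_herd(cfg)
  des <- build_design(sim$herd, sim$ped)
  Ai <- make_Ainv(sim$ped)
  ll1 <- reml_loglik(des, cfg$vc, Ai)
  set.seed(3)
  des2 <- des
  des2$y <- des$y + as.numeric(des$X %*% rnorm(ncol(des$X), 0, 50))
  expect_equal(reml_loglik(des2, cfg$vc, Ai), ll1, tolerance = 1e-7)
})

test_that("doubling every variance component shifts logL by its closed form", {
  cfg <- sim_config_fixture()
  sim <- simulate_herd(cfg)
  des <- build_design(sim$herd, sim$ped)
  A <- make_A(sim$ped); Ai <- make_Ainv(sim$ped)
  vc <- cfg$vc
  vc2 <- vc_indirect(aD = 2 * vc$aD, aI = 2 * vc$aI, aDI = 2 * vc$aDI,
                     u = 2 * vc$u, lD = 2 * vc$lD, lI = 2 * vc$lI,
                     eI = 2 * vc$eI, eD = 2 * vc$eD)
  n <- length(des$y); p <- ncol(des$X)
  yPy <- dense_blup_oracle(des, vc, A)$yPy
  expect_equal(reml_loglik(des, vc2, Ai) - reml_loglik(des, vc, Ai),
               -0.5 * ((n - p) * log(2) - yPy / 2), tolerance = 1e-8)
})

test_that("sparse and dense REML engines agree on likelihood, gradient and AI", {
  cfg <- sim_config_fixture()
  sim <- simulate_herd(cfg)
  des <- build_design(sim$herd, sim$ped)
  A <- make_A(sim$ped); Ai <- make_Ainv(sim$ped)
  ys <- des$y / sd(des$y)
  for (model in c("INDIRECT", "CLASSIC")) {
    ed <- igeblup:::.engine_dense(des, A, model, ys, des$X)
    es <- igeblup:::.engine_sparse(des, Ai, attr(Ai, "logdet"), model, ys,
                                   des$X)
    theta <- if (model == "INDIRECT")
      stats::setNames(c(0.15, 0.01, 0.002, 0.05, 0.08, 0.02, 0.03, 0.6),
                      ed$pnames)
    else stats::setNames(c(0.15, 0.05, 0.08, 0.02, 0.03, 0.6), ed$pnames)
    sd_ <- ed$at(theta); ss <- es$at(theta)
    expect_equal(ss$ll, sd_$ll, tolerance = 1e-9)
    gd <- ed$grad_ai(theta, sd_); gs <- es$grad_ai(theta, ss)
    expect_equal(gs$gr, gd$gr, tolerance = 1e-7)
    expect_equal(as.matrix(gs$AI), as.matrix(gd$AI), tolerance = 1e-7)
  }
})

test_that("the analytic REML gradient matches finite differences", {
  cfg <- sim_config_fixture()
  sim <- simulate_herd(cfg)
  des <- build_design(sim$herd, sim$ped)
  A <- make_A(sim$ped)
  ys <- des$y / sd(des$y)
  ed <- igeblup:::.engine_dense(des, A, "INDIRECT", ys, des$X)
  theta <- stats::setNames(c(0.15, 0.01, 0.002, 0.05, 0.08, 0.02, 0.03, 0.6),
                           ed$pnames)
  st <- ed$at(theta)
  gr <- ed$grad_ai(theta, st)$gr
  num <- vapply(seq_along(theta), function(k) {
    h <- 1e-6
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    (ed$at(tp)$ll - ed$at(tm)$ll) / (2 * h)
  }, numeric(1))
  expect_equal(gr, num, tolerance = 1e-4)
})

test_that("AI-REML recovers a strong social signal and sits at a stationary point", {
  cfg <- sim_config(n_litters = 60, n_sires = 25, n_dams = 50, seed = 5,
                    vc = vc_indirect(aD = 3349, aI = 400, rho = 0.3,
                                     u = 908, lD = 633, lI = 100, eI = 300,
                                     eD = 10989))
  sim <- simulate_herd(cfg)
  des <- build_design(sim$herd, sim$ped)
  Ai <- make_Ainv(sim$ped)
  fit <- ai_reml(des, Ainv = Ai, model = "INDIRECT")
  expect_true(fit$converged)
  ## estimates land within a few SEs of the generating values
  est <- unlist(fit$vc[c("aD", "aI", "u", "lD", "eD")])
  truth <- c(aD = 3349, aI = 400, u = 908, lD = 633, eD = 10989)
  se <- fit$se[c("aD", "aI", "u", "lD", "eD")]
  expect_true(all(abs(est - truth) < 4 * se + 1e-6))
  ## the likelihood never decreased along the accepted path
  expect_true(all(diff(fit$trace$loglik) > -1e-8))
  ## stationary: numerical gradient of the independent MME likelihood is
  ## small relative to the curvature scale
  s2y <- var(des$y)
  g_num <- vapply(c("aD", "u", "eD"), function(k) {
    h <- max(1e-5 * abs(fit$vc[[k]]), 1e-3)
    vp <- fit$vc; vp[[k]] <- vp[[k]] + h
    vm <- fit$vc; vm[[k]] <- vm[[k]] - h
    (reml_loglik(des, do.call(vc_indirect, vp[-1]), Ai) -
       reml_loglik(des, do.call(vc_indirect, vm[-1]), Ai)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g_num * s2y)), 0.05)
})

test_that("AI-REML shrinks the social variance when the data carry none", {
  cfg <- sim_config(n_litters = 60, n_sires = 25, n_dams = 50, seed = 7,
                    vc = vc_indirect(aD = 3349, aI = 0, aDI = 0, u = 908,
                                     lD = 633, lI = 19.1, eI = 97.4,
                                     eD = 10989))
  sim <- simulate_herd(cfg)
  des <- build_design(sim$herd, sim$ped)
  Ai <- make_Ainv(sim$ped)
  fit <- ai_reml(des, Ainv = Ai, model = "INDIRECT")
  ## the estimate sits near the zero boundary relative to its uncertainty
  expect_lt(fit$vc$aI, 2 * fit$se[["aI"]] + 1)
})

test_that("REML estimates are equivariant to phenotype rescaling", {
  cfg <- sim_config_fixture(n_litters = 24)
  sim <- simulate_herd(cfg)
  des <- build_design(sim$herd, sim$ped)
  Ai <- make_Ainv(sim$ped)
  f1 <- ai_reml(des, Ainv = Ai, model = "CLASSIC")
  des2 <- des
  des2$y <- 3 * des$y
  f2 <- ai_reml(des2, Ainv = Ai, model = "CLASSIC")
  for (k in c("aD", "u", "lD", "lI", "eI", "eD"))
    expect_equal(f2$vc[[k]], 9 * f1$vc[[k]], tolerance = 1e-6)
})

test_that("the likelihood-ratio test matches the chi-square with 2 df", {
  ## identical fits carry no evidence
  l0 <- lrt_ige(100, 100)
  expect_equal(l0$statistic, 0)
  expect_equal(l0$p_value, 1)
  ## the chi-square quantile identity at 2 df
  expect_equal(lrt_ige(5.991, 0)$p_value, 0.05, tolerance = 1e-3)
  ## a slightly better social fit
  res <- lrt_ige(119074.46, 119067.12)
  expect_equal(res$statistic, 7.34, tolerance = 1e-8)
  expect_equal(round(res$p_value, 3), 0.025)
  expect_warning(lrt_ige(99, 100 - 2e-6), "negative")
})
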