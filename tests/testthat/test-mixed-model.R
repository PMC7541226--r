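make_fixture <- function(seed = 42, ...) {
  cfg <- sim_config_fixture(seed = seed, ...)
  sim <- simulate_herd(cfg)
  list(cfg = cfg, sim = sim, des = build_design(sim$herd, sim$ped),
       A = make_A(sim$ped), Ai = make_Ainv(sim$ped))
}

test_that("design matrices mark self, pen mates and litters correctly", {
  fx <- make_fixture()
  des <- fx$des
  herd <- fx$sim$herd
  sizes <- table(herd$group)
  ## every Z_I row sums to the number of pen mates
  zi_sums <- Matrix::rowSums(des$Z_I)
  expect_equal(unname(zi_sums),
               unname(as.numeric(sizes[herd$group[match(des$phen_ids, herd$animal)]]) - 1))
  ## Z_D marks exactly the animal itself
  expect_equal(unname(Matrix::rowSums(des$Z_D)), rep(1, length(des$y)))
  ## Q_I counts mates per litter and matches Z_I row totals
  expect_equal(unname(Matrix::rowSums(des$Q_I)), unname(zi_sums))
  ## R_I has the same incidence pattern as Z_I (identity covariance)
  expect_equal(unname(Matrix::rowSums(des$R_I)), unname(zi_sums))
  ## X has full column rank
  expect_equal(qr(des$X)$rank, ncol(des$X))
  ## a phenotyped animal without a group is rejected
  bad <- herd; bad$group[1] <- NA
  expect_error(build_design(bad, fx$sim$ped), "without a group")
})

test_that("MME solutions equal the dense GLS/BLUP oracle for both models and structures", {
  fx <- make_fixture()
  des <- fx$des; A <- fx$A; Ai <- fx$Ai
  vci <- fx$cfg$vc
  vcc <- vc_classic(aD = 3339, u = 951, lD = 636, lI = 37.7, eI = 112.9,
                    eD = 10971)
  ## single-step structure from the fixture genotypes
  geno <- simulate_genotypes(fx$sim$ped, fx$cfg)
  qc <- snp_qc(geno$dosages, fx$sim$ped, geno$map)
  imp <- impute_mean(qc$genotypes)
  gid <- intersect(rownames(imp), fx$sim$ped$animal)
  G <- vanraden_G(imp[gid, ])
  A22 <- A[gid, gid]
  Gw <- blend_G(tune_G(G, A22), A22, 0.5)
  Hi <- make_Hinv(Ai, A22, Gw, gid)
  H <- solve(as.matrix(Hi))
  dimnames(H) <- dimnames(as.matrix(Hi))
  for (vc in list(vcc, vci)) {
    for (cov in c("A", "H")) {
      Cinv <- if (cov == "A") Ai else Hi
      Cd <- if (cov == "A") A else H
      fit <- solve_blup(des, vc, Cinv)
      oracle <- dense_blup_oracle(des, vc, Cd)
      expect_equal(unname(fit$b), oracle$b, tolerance = 1e-6)
      expect_equal(unname(fit_solution(fit)), oracle$u, tolerance = 1e-6)
      expect_lt(fit$residual_norm, 1e-8)
    }
  }
})

test_that("a vanishing genetic covariance makes the genetic block diagonal", {
  fx <- make_fixture()
  vc0 <- vc_indirect(aD = 3349, aI = 34.4, aDI = 0, u = 908, lD = 633,
                     lI = 19.1, eI = 97.4, eD = 10989)
  sys <- assemble_mme(fx$des, vc0, fx$Ai)
  M <- as.matrix(sys$M)
  cross <- M[sys$index$a_D, sys$index$a_I]
  zi_zd <- as.matrix(Matrix::crossprod(fx$des$Z_D, fx$des$Z_I)) / vc0$eD
  ## the only coupling left is the data part Z_D'Z_I/eD
  expect_equal(cross, zi_zd, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the social model collapses to the classical one as aI -> 0", {
  fx <- make_fixture()
  vcc <- vc_classic(aD = 3349, u = 908, lD = 633, lI = 19.1, eI = 97.4,
                    eD = 10989)
  vci <- vc_indirect(aD = 3349, aI = 1e-8, aDI = 0, u = 908, lD = 633,
                     lI = 19.1, eI = 97.4, eD = 10989)
  fc <- solve_blup(fx$des, vcc, fx$Ai)
  fi <- solve_blup(fx$des, vci, fx$Ai)
  expect_equal(fi$b, fc$b, tolerance = 1e-6)
  expect_equal(fi$a_D, fc$a_D, tolerance = 1e-6)
  expect_lt(max(abs(fi$a_I)), 1e-6)
})

test_that("solutions are invariant to the ordering of herd records", {
  fx <- make_fixture()
  herd <- fx$sim$herd
  set.seed(9)
  herd2 <- herd[sample(nrow(herd)), ]
  des2 <- build_design(herd2, fx$sim$ped)
  f1 <- solve_blup(fx$des, fx$cfg$vc, fx$Ai)
  f2 <- solve_blup(des2, fx$cfg$vc, fx$Ai)
  expect_equal(f1$a_D, f2$a_D, tolerance = 1e-8)
  expect_equal(f1$a_I, f2$a_I, tolerance = 1e-8)
})

test_that("random effects shrink to zero in the no-signal limit", {
  fx <- make_fixture()
  des <- fx$des
  ## phenotype generated exactly by the fixed effects
  des$y <- as.numeric(des$X %*% rnorm(ncol(des$X)))
  vc <- vc_indirect(aD = 1e-6, aI = 1e-8, aDI = 0, u = 1e-6, lD = 1e-6,
                    lI = 1e-8, eI = 1e-8, eD = 1e6)
  fit <- solve_blup(des, vc, fx$Ai)
  expect_lt(max(abs(c(fit$a_D, fit$a_I, fit$u, fit$l_D, fit$l_I, fit$e_I))),
            1e-6)
})
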