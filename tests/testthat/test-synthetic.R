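test_that("the generator is reproducible from configuration and seed alone", {
  cfg <- sim_config_fixture()
  s1 <- simulate_herd(cfg, genotypes = TRUE)
  s2 <- simulate_herd(cfg, genotypes = TRUE)
  expect_identical(s1$ped, s2$ped)
  expect_identical(s1$herd, s2$herd)
  expect_identical(s1$geno$dosages, s2$geno$dosages)
  expect_identical(s1$truth$a_D, s2$truth$a_D)
  ## a different seed changes the herd
  s3 <- simulate_herd(sim_config_fixture(seed = 43))
  expect_false(identical(s1$herd$adg, s3$herd$adg))
})

test_that("pens have the prescribed sizes and weight-sorted composition", {
  cfg <- sim_config(n_litters = 72, n_sires = 30, n_dams = 60, seed = 3)
  sim <- simulate_herd(cfg)
  herd <- sim$herd
  sizes <- table(herd$group)
  sex_of_pen <- tapply(herd$sex, herd$group, unique)
  expect_true(all(lengths(sex_of_pen) == 1))      # single-sex pens
  expect_true(all(sizes[sex_of_pen == "M"] == 10))
  expect_true(all(sizes[sex_of_pen == "F"] == 9))
  ## weight grouping: within-pen weight variance below the population's
  wvar <- tapply(herd$swght, herd$group, var)
  expect_lt(mean(wvar), var(herd$swght))
  ## entry dates within the two-week pen window
  spread <- tapply(as.numeric(herd$entry_date), herd$group,
                   function(x) diff(range(x)))
  expect_true(all(spread <= 13))
  ## pens draw from several litters and sires
  lit <- tapply(herd$litter, herd$group, function(x) length(unique(x)))
  expect_gt(mean(lit), 5)
})

test_that("gene dropping respects Mendelian inheritance", {
  cfg <- sim_config_fixture(missing_rate = 0)
  sim <- simulate_herd(cfg)
  geno <- simulate_genotypes(sim$ped, cfg, ids_genotyped = sim$ped$animal)
  D <- geno$dosages
  ped <- sim$ped
  kids <- ped[!is.na(ped$sire) & !is.na(ped$dam), ]
  gs <- D[kids$sire, , drop = FALSE]
  gd <- D[kids$dam, , drop = FALSE]
  gk <- D[kids$animal, , drop = FALSE]
  ## both parents homozygous reference -> offspring homozygous reference
  both0 <- gs == 0 & gd == 0
  expect_true(all(gk[both0] == 0))
  both2 <- gs == 2 & gd == 2
  expect_true(all(gk[both2] == 2))
  ## opposing homozygotes -> heterozygous offspring
  opp <- (gs == 0 & gd == 2) | (gs == 2 & gd == 0)
  expect_true(all(gk[opp] == 1))
})

test_that("realized genomic relationships track the pedigree expectation", {
  cfg <- sim_config(n_litters = 24, n_sires = 10, n_dams = 20,
                    n_generations = 3, n_snps = 2000, missing_rate = 0,
                    seed = 8)
  sim <- simulate_herd(cfg)
  geno <- simulate_genotypes(sim$ped, cfg, ids_genotyped = sim$ped$animal)
  A <- make_A(sim$ped)
  ids <- attr(sim$ped, "test_ids")
  G <- vanraden_G(geno$dosages[ids, ])
  Asub <- A[ids, ids]
  off <- upper.tri(Asub)
  expect_gt(cor(G[off], Asub[off]), 0.8)
})

test_that("phenotypes decompose exactly into the generating effects", {
  cfg <- sim_config_fixture()
  sim <- simulate_herd(cfg)
  herd <- sim$herd; tr <- sim$truth
  des <- build_design(herd, sim$ped)
  ## rebuild y through the design matrices and the stored true effects
  u <- tr$u[des$sym_levels]
  lD <- tr$l_D[des$litter_ids]
  lI <- tr$l_I[des$litter_ids]
  eI <- tr$e_I[des$eI_ids]
  ph <- herd[match(des$phen_ids, herd$animal), ]
  fixed <- cfg$mu + cfg$beta_sex * (ph$sex == "M") + tr$ym_eff[ph$ym] +
    cfg$beta_wage * ph$sWghtAge + cfg$beta_wdev * ph$sWghtDev +
    cfg$beta_members * ph$avg_members
  y_design <- as.numeric(
    fixed +
      des$Z_D %*% tr$a_D[des$ped_ids] + des$Z_I %*% tr$a_I[des$ped_ids] +
      des$W %*% u + des$Q_D %*% lD + des$Q_I %*% lI + des$R_I %*% eI)
  resid <- des$y - y_design
  ## what is left is the iid residual drawn by the generator
  expect_equal(unname(cor(des$y, y_design)) > 0.5, TRUE)
  expect_lt(abs(mean(resid)), 3 * sqrt(cfg$vc$eD / length(resid)) + 50)
  ## removals occur and drop the phenotype but not the pen membership
  cfg_r <- sim_config(n_litters = 72, n_sires = 30, n_dams = 60,
                      removal_rate = 0.3, seed = 4)
  sim_r <- simulate_herd(cfg_r)
  expect_gt(sum(is.na(sim_r$herd$adg)), 0)
  expect_true(all(!is.na(sim_r$herd$group)))
})

test_that("simulated social effects have the variance the group algebra predicts", {
  ## across replicates, the variance of the sum of pen mates' indirect
  ## effects is (n-1) aI + (n-1)(n-2) r aI approximately
  cfg <- sim_config_fixture()
  sim0 <- simulate_herd(cfg)
  A <- make_A(sim0$ped)
  herd <- sim0$herd
  groups <- data.frame(animal = herd$animal, group = herd$group)
  r <- as.numeric(mean_group_relatedness(A, groups))
  n_bar <- group_sizes(herd)$n_bar
  members <- split(herd$animal, herd$group)
  sums <- c()
  for (s in 1:40) {
    eff <- igeblup:::.simulate_effects(sim0$ped, cfg, seed = 5000 + s)
    sums <- c(sums, vapply(seq_len(nrow(herd)), function(i) {
      mates <- setdiff(members[[herd$group[i]]], herd$animal[i])
      sum(eff$a_I[mates])
    }, numeric(1)))
  }
  pred <- (n_bar - 1) * cfg$vc$aI + (n_bar - 1) * (n_bar - 2) * r * cfg$vc$aI
  expect_lt(abs(var(sums) - pred) / pred, 0.30)
})

test_that("a residual-only configuration produces white noise around fixed effects", {
  cfg <- sim_config_fixture(
    vc = vc_indirect(aD = 1e-12, aI = 0, aDI = 0, u = 1e-12, lD = 1e-12,
                     lI = 0, eI = 0, eD = 10989),
    sd_ym = 0)
  sim <- simulate_herd(cfg)
  herd <- sim$herd
  ph <- herd[!is.na(herd$adg), ]
  fixed <- cfg$mu + cfg$beta_sex * (ph$sex == "M") +
    cfg$beta_wage * ph$sWghtAge + cfg$beta_wdev * ph$sWghtDev +
    cfg$beta_members * ph$avg_members
  resid <- ph$adg - fixed
  expect_lt(abs(sd(resid) / sqrt(10989) - 1), 0.25)
  expect_lt(abs(mean(resid)), 3 * sqrt(10989 / nrow(ph)))
})
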