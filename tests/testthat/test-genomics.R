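test_that("Hardy-Weinberg chi-square test matches closed forms", {
  expect_equal(hwe_test(25, 50, 25), 1)
  ## all heterozygotes: chi-square equals n
  expect_equal(stats::qchisq(hwe_test(0, 100, 0), 1, lower.tail = FALSE), 100,
               tolerance = 1e-8)
  expect_lt(hwe_test(0, 100, 0), 1e-7)
  expect_lt(hwe_test(50, 0, 50), 1e-7)
  expect_true(is.na(hwe_test(0, 0, 0)))
  ## exact test agrees with the chi-square in a well-behaved case
  expect_lt(abs(hwe_test(30, 48, 22, method = "exact") -
                  hwe_test(30, 48, 22)), 0.15)
  expect_lt(hwe_test(50, 0, 50, method = "exact"), 1e-7)
})

test_that("Mendelian error rate counts opposing homozygotes in duos", {
  ped <- as_pedigree(data.frame(animal = c("p", paste0("k", 1:10)),
                                sire = c(NA, rep("p", 10)),
                                dam = NA))
  geno <- matrix(1, 11, 2, dimnames = list(ped$animal, c("s1", "s2")))
  ## snp1: parent 0, one child 2 -> 1 error in 10 duos
  geno[, 1] <- c(0, 2, rep(0, 9))
  ## snp2: heterozygous parent can never conflict
  geno[, 2] <- c(1, sample(0:2, 10, replace = TRUE))
  rate <- mendelian_error_rate(geno, ped)
  expect_equal(unname(rate[1]), 0.1)
  expect_equal(unname(rate[2]), 0)
  ## no genotyped relatives -> NA
  solo <- geno[1, , drop = FALSE]
  expect_true(all(is.na(mendelian_error_rate(solo, ped))))
})

test_that("SNP quality control applies each rule, waiving HWE on sex chromosomes", {
  set.seed(1)
  n <- 200
  good <- rbinom(n, 2, 0.4)
  geno <- cbind(
    ok = good,
    lowcall = replace(good, 1:21, NA),             # call rate 0.895
    mono = rep(0, n),                              # MAF 0
    hweauto = rep(1, n),                           # all het, autosome
    hwesex = rep(1, n)                             # all het, X chromosome
  )
  rownames(geno) <- sprintf("A%03d", 1:n)
  map <- data.frame(snp = colnames(geno), chrom = c("1", "1", "1", "2", "X"))
  res <- snp_qc(geno, map = map)
  kept <- res$report$kept
  names(kept) <- res$report$snp
  expect_true(kept[["ok"]])
  expect_false(kept[["lowcall"]])
  expect_false(kept[["mono"]])
  expect_false(kept[["hweauto"]])
  expect_true(kept[["hwesex"]])   # HWE rule not applied on X
  ## order independence
  perm <- sample(ncol(geno))
  res2 <- snp_qc(geno[, perm], map = map[perm, ])
  expect_setequal(colnames(res$genotypes), colnames(res2$genotypes))
  ## everything failing names the binding rule
  expect_error(snp_qc(geno[, "mono", drop = FALSE]), "binding rule")
  ## a per-call validity mask blanks calls before the rules run
  mask <- matrix(TRUE, nrow(geno), ncol(geno),
                 dimnames = dimnames(geno))
  mask[1:25, "ok"] <- FALSE          # drops its call rate below 0.90
  res3 <- snp_qc(geno, map = map, valid = mask)
  expect_false(res3$report$kept[res3$report$snp == "ok"])
})

test_that("mean imputation fills missing dosages with the SNP mean", {
  g <- matrix(c(0, 2, NA,
                1, 1, NA,
                0, 1, 2), 3, 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  out <- impute_mean(g)
  expect_equal(unname(out["c", "s1"]), 1)    # mean of {0, 2}
  expect_equal(unname(out["c", "s2"]), 1)    # all-heterozygote SNP
  expect_equal(out[, "s3"], g[, "s3"])       # complete SNP untouched
  expect_equal(sum(attr(out, "imputed")), 2)
  expect_error(impute_mean(matrix(NA_real_, 2, 1)), "call-rate")
})

test_that("VanRaden G matches hand arithmetic and its construction symmetries", {
  ## 1 SNP, p = 0.5, dosages 0/1/2: denominator 0.5
  g <- matrix(c(0, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  G <- vanraden_G(g)
  expect_equal(unname(G), matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3, 3))
  ## symmetric; duplicated animals give identical rows
  set.seed(2)
  g2 <- matrix(rbinom(40 * 25, 2, 0.3), 40, 25)
  rownames(g2) <- sprintf("A%02d", 1:40)
  g2[40, ] <- g2[1, ]
  G2 <- vanraden_G(g2)
  expect_equal(G2, t(G2))
  expect_equal(unname(G2[1, ]), unname(G2[40, ]))
  ## row means vanish when frequencies come from the same animals
  expect_lt(max(abs(rowMeans(G2))), 1e-10)
  expect_error(vanraden_G(matrix(0, 3, 2)), "polymorphic")
})

test_that("tuning G to A22 matches both means, with a closed-form check", {
  set.seed(3)
  Z <- matrix(rnorm(30), 10, 3)
  G <- tcrossprod(Z) / 3
  A22 <- diag(10) * 1.02 + 0.01
  Gs <- tune_G(G, A22)
  md <- function(M) mean(diag(M))
  mo <- function(M) (sum(M) - sum(diag(M))) / (nrow(M) * (nrow(M) - 1))
  expect_equal(md(Gs), md(A22), tolerance = 1e-12)
  expect_equal(mo(Gs), mo(A22), tolerance = 1e-12)
  ## closed-form 2x2 solve
  beta <- (md(A22) - mo(A22)) / (md(G) - mo(G))
  alpha <- mo(A22) - beta * mo(G)
  expect_equal(attr(Gs, "beta"), beta)
  expect_equal(attr(Gs, "alpha"), alpha)
  ## matrix already matching both means is unchanged
  G0 <- tune_G(A22, A22)
  expect_equal(attr(G0, "alpha"), 0, tolerance = 1e-12)
  expect_equal(attr(G0, "beta"), 1, tolerance = 1e-12)
})

test_that("blending interpolates between G and A22 and keeps PSD", {
  set.seed(4)
  Z <- matrix(rnorm(60), 12, 5)
  G <- tcrossprod(Z) / 5
  A22 <- diag(12)
  expect_equal(blend_G(G, A22, 0), A22)
  expect_equal(blend_G(G, A22, 0.5), (G + A22) / 2)
  expect_error(blend_G(G, A22, 1), "0.99")
  expect_error(blend_G(G, A22, -0.1), "0.99")
  for (w in c(seq(0.05, 0.95, by = 0.15), 0.99)) {
    ev <- eigen(blend_G(G, A22, w), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("single-step H inverse corrects only the genotyped block", {
  ped <- random_pedigree(20, seed = 5)
  A <- make_A(ped)
  Ai <- make_Ainv(ped)
  gid <- ped$animal[11:20]
  A22 <- A[gid, gid]
  set.seed(5)
  Gw <- A22 + 0.5 * tcrossprod(matrix(rnorm(100), 10, 10)) / 10
  Hi <- make_Hinv(Ai, A22, Gw, gid)
  D <- as.matrix(Hi - Ai)
  rownames(D) <- colnames(D) <- ped$animal
  others <- setdiff(ped$animal, gid)
  expect_lt(max(abs(D[others, ])), 1e-10)
  expect_equal(D[gid, gid], solve(Gw) - solve(A22), tolerance = 1e-8)
  ## w = 0 (Gw = A22) cancels the correction entirely
  Hi0 <- make_Hinv(Ai, A22, blend_G(Gw, A22, 0), gid)
  expect_lt(max(abs(as.matrix(Hi0 - Ai))), 1e-8)
})
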