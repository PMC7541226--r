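test_that("pedigree validation sorts parents first and flags problems", {
  ## founders stay in order
  ped <- as_pedigree(data.frame(animal = c("a", "b", "c"),
                                sire = NA, dam = NA))
  expect_equal(ped$animal, c("a", "b", "c"))
  ## child listed before its sire gets reordered
  ped <- as_pedigree(data.frame(animal = c("kid", "pa", "ma"),
                                sire = c("pa", NA, NA),
                                dam = c("ma", NA, NA)))
  expect_lt(which(ped$animal == "pa"), which(ped$animal == "kid"))
  ## parentage loop is an error naming the chain
  expect_error(as_pedigree(data.frame(animal = c("A", "B"),
                                      sire = c("B", "A"), dam = NA)),
               "cycle.*A.*B")
  ## absent parent auto-inserted as founder with a warning
  expect_warning(ped <- as_pedigree(data.frame(animal = "x", sire = "ghost",
                                               dam = NA)),
                 "founder")
  expect_true("ghost" %in% ped$animal)
  ## duplicate ids rejected
  expect_error(as_pedigree(data.frame(animal = c("a", "a"), sire = NA,
                                      dam = NA)), "duplicated")
})

test_that("truncation keeps ancestors within the meiosis horizon", {
  chain <- as_pedigree(data.frame(animal = paste0("g", 1:7),
                                  sire = c(NA, paste0("g", 1:6)),
                                  dam = NA))
  ## anchors only at horizon 0
  t0 <- truncate_pedigree(chain, "g7", 0)
  expect_equal(t0$animal, "g7")
  expect_true(is.na(t0$sire))
  ## 7-generation chain at horizon 5 keeps 6 animals
  t5 <- truncate_pedigree(chain, "g7", 5)
  expect_equal(sort(t5$animal), paste0("g", 2:7))
  expect_true(is.na(t5$sire[t5$animal == "g2"]))
  ## horizon >= depth is the identity
  t9 <- truncate_pedigree(chain, "g7", 9)
  expect_equal(t9$animal, chain$animal)
  expect_error(truncate_pedigree(chain, "g7", -1), ">= 0")
})

test_that("truncation is idempotent", {
  for (seed in 1:3) {
    ped <- random_pedigree(40, seed = seed)
    anchors <- utils::tail(ped$animal, 10)
    t1 <- truncate_pedigree(ped, anchors, 2)
    t2 <- truncate_pedigree(t1, anchors, 2)
    expect_identical(t1$animal, t2$animal)
    expect_identical(t1$sire, t2$sire)
    expect_identical(t1$dam, t2$dam)
  }
})

test_that("tabular A reproduces textbook relationships", {
  A <- make_A(toy_trio())
  expect_equal(A["s", "c"], 0.5)
  expect_equal(A["d", "c"], 0.5)
  expect_equal(diag(A), c(s = 1, d = 1, c = 1))
  ## full sibs from unrelated parents
  fs <- as_pedigree(data.frame(animal = c("s", "d", "x", "y"),
                               sire = c(NA, NA, "s", "s"),
                               dam = c(NA, NA, "d", "d")))
  expect_equal(make_A(fs)["x", "y"], 0.5)
  ## offspring of a full-sib mating is inbred with F = 0.25
  ib <- as_pedigree(data.frame(animal = c("s", "d", "x", "y", "z"),
                               sire = c(NA, NA, "s", "s", "x"),
                               dam = c(NA, NA, "d", "d", "y")))
  A <- make_A(ib)
  expect_equal(A["z", "z"], 1.25)
  expect_equal(unname(attr(A, "F")["z"]), 0.25)
})

test_that("A is symmetric positive semidefinite with diagonal >= 1", {
  for (seed in 1:4) {
    A <- make_A(random_pedigree(60, seed = seed))
    expect_equal(A, t(A))
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
    expect_true(all(diag(A) >= 1 - 1e-12))
  }
})

test_that("Henderson's sparse A-inverse is the exact inverse of A", {
  ## founders only: identity
  f <- as_pedigree(data.frame(animal = c("a", "b"), sire = NA, dam = NA))
  expect_equal(as.matrix(make_Ainv(f)), diag(2), ignore_attr = TRUE)
  ## trio against dense inversion
  trio <- toy_trio()
  expect_equal(as.matrix(make_Ainv(trio)), solve(make_A(trio)),
               ignore_attr = TRUE, tolerance = 1e-12)
  ## random pedigrees, including inbred ones
  for (seed in 1:4) {
    ped <- random_pedigree(150, seed = seed)
    A <- make_A(ped)
    Ai <- make_Ainv(ped)
    expect_lt(max(abs(as.matrix(Ai %*% A) - diag(nrow(A)))), 1e-8)
    ## log-determinant attribute matches the dense determinant
    expect_equal(attr(Ai, "logdet"),
                 as.numeric(determinant(A)$modulus), tolerance = 1e-8)
  }
})

test_that("mean pen relatedness averages off-diagonal pairs within pens", {
  ped <- as_pedigree(data.frame(animal = c("s", "d", "x", "y", "u", "v"),
                                sire = c(NA, NA, "s", "s", NA, NA),
                                dam = c(NA, NA, "d", "d", NA, NA)))
  A <- make_A(ped)
  ## pen of mutually unrelated animals
  g0 <- data.frame(animal = c("u", "v"), group = "p1")
  expect_equal(as.numeric(mean_group_relatedness(A, g0)), 0)
  ## pen of full sibs
  g1 <- data.frame(animal = c("x", "y"), group = "p1")
  expect_equal(as.numeric(mean_group_relatedness(A, g1)), 0.5)
  ## equal weight across pens, singleton skipped with warning
  g2 <- data.frame(animal = c("x", "y", "u", "v", "s"),
                   group = c("p1", "p1", "p2", "p2", "p3"))
  expect_warning(r <- mean_group_relatedness(A, g2), "singleton")
  expect_equal(as.numeric(r), mean(c(0.5, 0)))
})
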