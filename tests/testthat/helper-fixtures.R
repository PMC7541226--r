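## Small pedigrees and herds built in code for unit tests.

toy_trio <- function() {
  as_pedigree(data.frame(animal = c("s", "d", "c"),
                         sire = c(NA, NA, "s"),
                         dam = c(NA, NA, "d")))
}

## random valid pedigree: founders plus animals with parents drawn from
## earlier animals (by sex)
random_pedigree <- function(n, n_founders = max(4L, n %/% 5L), seed = 1) {
  set.seed(seed)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1:2] <- c("M", "F")
  sire <- dam <- rep(NA_character_, n)
  id <- sprintf("A%03d", seq_len(n))
  for (i in seq(n_founders + 1L, n)) {
    males <- which(sex[seq_len(i - 1L)] == "M")
    females <- which(sex[seq_len(i - 1L)] == "F")
    if (length(males)) sire[i] <- id[sample(males, 1)]
    if (length(females)) dam[i] <- id[sample(females, 1)]
  }
  as_pedigree(data.frame(animal = id, sire = sire, dam = dam, sex = sex))
}

## dense GLS/BLUP oracle: explicit V = sum Z G Z' + R
dense_blup_oracle <- function(design, vc, C) {
  Sg <- matrix(c(vc$aD, vc$aDI, vc$aDI, vc$aI), 2, 2)
  if (vc$model == "INDIRECT") {
    Gg <- rbind(cbind(Sg[1, 1] * C, Sg[1, 2] * C),
                cbind(Sg[2, 1] * C, Sg[2, 2] * C))
    Zg <- cbind(as.matrix(design$Z_D), as.matrix(design$Z_I))
  } else {
    Gg <- vc$aD * C
    Zg <- as.matrix(design$Z_D)
  }
  Zenv <- cbind(as.matrix(design$W), as.matrix(design$Q_D),
                as.matrix(design$Q_I), as.matrix(design$R_I))
  Genv <- diag(c(rep(vc$u, ncol(design$W)),
                 rep(vc$lD, ncol(design$Q_D)),
                 rep(vc$lI, ncol(design$Q_I)),
                 rep(vc$eI, ncol(design$R_I))))
  Z <- cbind(Zg, Zenv)
  G <- as.matrix(Matrix::bdiag(Gg, Genv))
  V <- Z %*% G %*% t(Z) + diag(length(design$y)) * vc$eD
  X <- design$X; y <- design$y
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- G %*% t(Z) %*% Vi %*% (y - X %*% b)
  n <- length(y); p <- ncol(X)
  Py <- Vi %*% (y - X %*% b)
  ll <- -0.5 * ((n - p) * log(2 * pi) +
                  as.numeric(determinant(V)$modulus) +
                  as.numeric(determinant(t(X) %*% Vi %*% X)$modulus) +
                  sum(y * Py))
  list(b = as.numeric(b), u = as.numeric(u), loglik = ll,
       yPy = sum(y * Py))
}

## stack the mixed-model solution of a fit in oracle order
fit_solution <- function(fit) {
  if (fit$model == "INDIRECT")
    c(fit$a_D, fit$a_I, fit$u, fit$l_D, fit$l_I, fit$e_I)
  else
    c(fit$a_D, fit$u, fit$l_D, fit$l_I, fit$e_I)
}
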