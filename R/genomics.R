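#' SNP quality-control thresholds
#'
#' Defaults follow routine practice for medium-density livestock chips:
#' per-SNP call rate above 90%, minor allele frequency above 1%, Mendelian
#' error rate below 0.1%, and a Hardy-Weinberg equilibrium p-value above
#' 1e-7 (the HWE rule is waived on sex chromosomes, where the autosomal
#' genotype-frequency expectation does not hold).
#'
#' @param call_rate minimum call rate (exclusive).
#' @param maf minimum minor allele frequency (exclusive).
#' @param mendel maximum Mendelian error rate (exclusive).
#' @param hwe_p minimum HWE p-value (exclusive).
#' @return List of thresholds.
#' @export
qc_thresholds <- function(call_rate = 0.90, maf = 0.01,
                          mendel = 0.001, hwe_p = 1e-7) {
  list(call_rate = call_rate, maf = maf, mendel = mendel, hwe_p = hwe_p)
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' One-degree-of-freedom goodness-of-fit chi-square of the observed genotype
#' counts against the expectation at the observed allele frequency, or the
#' exact conditional test (full enumeration of heterozygote counts given the
#' minor-allele count).
#'
#' @param n0,n1,n2 counts of dosage-0, heterozygous and dosage-2 genotypes.
#' @param method `"chisq"` (default) or `"exact"`.
#' @return p-value; `NA` if no genotypes are observed.
#' @export
hwe_test <- function(n0, n1, n2, method = c("chisq", "exact")) {
  method <- match.arg(method)
  n <- n0 + n1 + n2
  if (n == 0) return(NA_real_)
  if (method == "exact") return(.hwe_exact(n0, n1, n2))
  p <- (2 * n2 + n1) / (2 * n)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  o <- c(n0, n1, n2)
  keep <- e > 0
  stat <- sum((o[keep] - e[keep])^2 / e[keep])
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

## exact HWE: two-sided p as the summed probability of heterozygote counts
## no more likely than the observed one, conditional on allele counts
.hwe_exact <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- 2 * n2 + n1            # count of the dosage-coded allele
  nmin <- min(nA, 2 * n - nA)  # minor allele count
  hets <- seq.int(nmin %% 2, nmin, by = 2)
  lp <- vapply(hets, function(h) {
    hom1 <- (nmin - h) / 2
    hom2 <- n - h - hom1
    lgamma(n + 1) - lgamma(hom1 + 1) - lgamma(h + 1) - lgamma(hom2 + 1) +
      h * log(2) + lgamma(nmin + 1) + lgamma(2 * n - nmin + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  obs <- which(hets == n1)
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-10)]))
}

#' Per-SNP Mendelian error rate from parent-offspring duos
#'
#' Counts opposing-homozygote inconsistencies (parent dosage 0 with
#' offspring dosage 2, or vice versa) over all genotyped parent-offspring
#' duos, per SNP.  A SNP with no informative duo gets `NA` (and passes the
#' QC rule by convention).
#'
#' @param geno animals-by-SNPs dosage matrix (0/1/2, NA missing) with animal
#'   ids as rownames.
#' @param ped a sorted `pedigree`.
#' @return Numeric vector of error rates per SNP (NA where no checks).
#' @export
mendelian_error_rate <- function(geno, ped) {
  ids <- rownames(geno)
  duo_child <- character(0); duo_parent <- character(0)
  for (side in c("sire", "dam")) {
    p <- ped[[side]]
    ok <- !is.na(p) & ped$animal %in% ids & p %in% ids
    duo_child <- c(duo_child, ped$animal[ok])
    duo_parent <- c(duo_parent, p[ok])
  }
  if (!length(duo_child))
    return(rep(NA_real_, ncol(geno)))
  gc_ <- geno[duo_child, , drop = FALSE]
  gp_ <- geno[duo_parent, , drop = FALSE]
  inf <- !is.na(gc_) & !is.na(gp_)
  err <- inf & abs(gc_ - gp_) == 2
  checks <- colSums(inf)
  rate <- colSums(err) / checks
  rate[checks == 0] <- NA_real_
  rate
}

#' SNP quality control
#'
#' Applies, per SNP: call rate, minor allele frequency, Mendelian error rate
#' and Hardy-Weinberg filters (see [qc_thresholds()]).  The HWE rule is not
#' applied to SNPs on sex chromosomes.  Rules whose inputs are undefined
#' (e.g. no genotyped duos for the Mendelian check) pass by convention.
#'
#' @param geno animals-by-SNPs dosage matrix (0/1/2, NA missing), rownames
#'   animal ids, colnames SNP ids.
#' @param ped optional sorted `pedigree` for the Mendelian check; skipped
#'   when `NULL`.
#' @param map optional data frame with columns `snp` and `chrom`; sex
#'   chromosomes are identified by `chrom` in `sex_chroms`.
#' @param thresholds list from [qc_thresholds()].
#' @param sex_chroms chromosome labels treated as sex chromosomes.
#' @param hwe_method passed to [hwe_test()].
#' @param valid optional logical matrix of the same shape as `geno` marking
#'   per-call validity (e.g. from an upstream intensity-based call-quality
#'   screen); invalid calls are set missing before any rule is evaluated.
#' @return List with `genotypes` (filtered matrix) and `report` (one row per
#'   input SNP: call rate, MAF, Mendelian error rate, HWE p, per-rule flags
#'   and `kept`).
#' @export
snp_qc <- function(geno, ped = NULL, map = NULL, thresholds = qc_thresholds(),
                   sex_chroms = c("X", "Y"), hwe_method = "chisq",
                   valid = NULL) {
  if (!is.null(valid)) {
    stopifnot(is.logical(valid), all(dim(valid) == dim(geno)))
    geno[!valid] <- NA
  }
  m <- ncol(geno)
  snp <- colnames(geno)
  if (is.null(snp)) snp <- paste0("snp", seq_len(m))
  nobs <- colSums(!is.na(geno))
  call_rate <- nobs / nrow(geno)
  p <- colMeans(geno, na.rm = TRUE) / 2
  p[nobs == 0] <- NA_real_
  maf <- pmin(p, 1 - p)
  mend <- if (!is.null(ped)) mendelian_error_rate(geno, ped) else rep(NA_real_, m)
  n2 <- colSums(geno == 2, na.rm = TRUE)
  n1 <- colSums(geno == 1, na.rm = TRUE)
  n0 <- nobs - n1 - n2
  hwe <- vapply(seq_len(m), function(j) hwe_test(n0[j], n1[j], n2[j], hwe_method),
                numeric(1))
  on_sex <- rep(FALSE, m)
  if (!is.null(map)) {
    stopifnot(all(c("snp", "chrom") %in% names(map)))
    on_sex <- as.character(map$chrom[match(snp, map$snp)]) %in% sex_chroms
  }
  pass_cr <- call_rate > thresholds$call_rate
  pass_maf <- !is.na(maf) & maf > thresholds$maf
  pass_mend <- is.na(mend) | mend < thresholds$mendel
  pass_hwe <- on_sex | is.na(hwe) | hwe > thresholds$hwe_p
  kept <- pass_cr & pass_maf & pass_mend & pass_hwe
  report <- data.frame(snp = snp, call_rate = call_rate, maf = maf,
                       mendel_rate = mend, hwe_p = hwe, sex_chrom = on_sex,
                       pass_call_rate = pass_cr, pass_maf = pass_maf,
                       pass_mendel = pass_mend, pass_hwe = pass_hwe,
                       kept = kept, row.names = NULL)
  if (!any(kept)) {
    fails <- c(call_rate = sum(!pass_cr), maf = sum(!pass_maf),
               mendel = sum(!pass_mend), hwe = sum(!pass_hwe))
    stop("no SNP survives QC; most binding rule: ",
         names(fails)[which.max(fails)])
  }
  list(genotypes = geno[, kept, drop = FALSE], report = report)
}

#' Mean-dosage imputation of missing genotypes
#'
#' Replaces each missing dosage by the SNP's mean observed dosage
#' (real-valued).  Because the genomic relationship matrix is a second
#' moment of centred dosages, mean imputation leaves its expectation
#' unchanged; it is adequate once call-rate QC has bounded missingness.
#'
#' @param geno animals-by-SNPs dosage matrix.
#' @return Complete matrix with attribute `"imputed"`, a logical matrix
#'   marking imputed cells.
#' @export
impute_mean <- function(geno) {
  miss <- is.na(geno)
  if (any(colSums(!miss) == 0))
    stop("SNP(s) entirely missing; these should have failed call-rate QC")
  if (any(miss)) {
    mu <- colMeans(geno, na.rm = TRUE)
    idx <- which(miss, arr.ind = TRUE)
    geno[idx] <- mu[idx[, 2]]
  }
  structure(geno, imputed = miss)
}

#' VanRaden (Method 1) genomic relationship matrix
#'
#' `G = (M - 2P)(M - 2P)' / (2 * sum(p_k (1 - p_k)))`, with dosage columns
#' centred at twice the allele frequency.  Frequencies default to those
#' observed in the genotyped animals supplied.
#'
#' @param geno complete animals-by-SNPs dosage matrix (see [impute_mean()]).
#' @param freq optional per-SNP allele frequencies used for centring and
#'   scaling (e.g. computed before imputation).
#' @return Dense symmetric G with animal ids as dimnames.
#' @export
vanraden_G <- function(geno, freq = NULL) {
  if (is.null(freq)) freq <- colMeans(geno) / 2
  denom <- 2 * sum(freq * (1 - freq))
  if (denom <= 0) stop("sum p(1-p) is zero; no polymorphic SNPs")
  Z <- sweep(geno, 2L, 2 * freq)
  tcrossprod(Z) / denom
}

#' Tune G to the pedigree relationships of the genotyped animals
#'
#' Solves for scalars `alpha`, `beta` in `G* = alpha + beta G` such that the
#' mean diagonal and mean off-diagonal of `G*` equal those of `A22` (the
#' block of A for genotyped animals).  This places G and A on the same base
#' population before blending.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationship block for the same animals, same order.
#' @return Tuned matrix with attributes `"alpha"` and `"beta"`.
#' @export
tune_G <- function(G, A22) {
  stopifnot(all(dim(G) == dim(A22)))
  md <- function(M) mean(diag(M))
  mo <- function(M) {
    n <- nrow(M)
    if (n < 2) stop("need at least two animals")
    (sum(M) - sum(diag(M))) / (n * (n - 1))
  }
  dG <- md(G) - mo(G)
  if (abs(dG) < 1e-12)
    stop("degenerate tuning system: mean diagonal of G equals its mean off-diagonal")
  beta <- (md(A22) - mo(A22)) / dG
  alpha <- mo(A22) - beta * mo(G)
  structure(alpha + beta * G, alpha = alpha, beta = beta)
}

#' Blend the genomic and pedigree relationship matrices
#'
#' `Gw = w G* + (1 - w) A22`.  The blending weight acknowledges that marker
#' genotypes do not capture all genetic variance; `w = 0` returns the
#' pedigree relationships and also guarantees an invertible matrix.
#'
#' @param Gstar tuned genomic relationship matrix (see [tune_G()]).
#' @param A22 pedigree relationship block, same animals and order.
#' @param w blending weight in `[0, 0.99]`.
#' @return Blended matrix.
#' @export
blend_G <- function(Gstar, A22, w) {
  if (w < 0 || w > 0.99) stop("w must be in [0, 0.99]")
  w * Gstar + (1 - w) * A22
}

#' Sparse single-step H inverse
#'
#' `H^-1 = A^-1 + [[0, 0], [0, Gw^-1 - A22^-1]]`, where the correction acts
#' on the genotyped block.  Non-genotyped animals enter the evaluation
#' through the pedigree alone.
#'
#' @param Ainv sparse inverse of A (see [make_Ainv()]) with id dimnames.
#' @param A22 dense pedigree relationship block of the genotyped animals.
#' @param Gw blended genomic matrix for the same animals, same order.
#' @param ids_geno ids of the genotyped animals (must be rownames of both
#'   `A22` and `Gw` and present in `Ainv`).
#' @return Sparse symmetric H inverse in the order of `Ainv`.
#' @export
make_Hinv <- function(Ainv, A22, Gw, ids_geno = rownames(Gw)) {
  ids <- rownames(Ainv)
  if (!all(ids_geno %in% ids)) stop("genotyped ids must be a subset of pedigree ids")
  gi <- match(ids_geno, ids)
  Gwi <- tryCatch(solve(Gw), error = function(e)
    stop("Gw is singular; use a smaller w (larger pedigree share)"))
  corr <- Gwi - solve(A22)
  H <- methods::as(Ainv, "TsparseMatrix")
  C <- Matrix::sparseMatrix(i = rep(gi, times = length(gi)),
                            j = rep(gi, each = length(gi)),
                            x = as.numeric(t(corr)), dims = dim(Ainv),
                            dimnames = dimnames(Ainv))
  methods::as(Matrix::forceSymmetric((H + C + Matrix::t(H + C)) / 2),
              "CsparseMatrix")
}

#' Read a PLINK-RAW-style dosage table
#'
#' Whitespace-delimited text with columns `FID`, `IID` then one column per
#' SNP holding 0/1/2 dosages (`NA` for missing).  Extra PLINK columns
#' (`PAT`, `MAT`, `SEX`, `PHENOTYPE`) are dropped when present.
#'
#' @param path file path.
#' @return Dosage matrix, animals in rows (rownames from `IID`).
#' @export
read_plink_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE)
  drop <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"), names(df))
  ids <- as.character(df[["IID"]])
  M <- as.matrix(df[, setdiff(names(df), drop), drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- ids
  M
}

#' Read allele dosages from a VCF
#'
#' Converts the GT field to 0/1/2 alternate-allele dosages.  Requires the
#' `vcfR` package.
#'
#' @param path VCF file path.
#' @return Dosage matrix, animals in rows, SNP ids in columns.
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  dos <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_real_)
    a <- strsplit(sub(":.*", "", x), "[/|]")[[1]]
    if (any(a == ".")) return(NA_real_)
    sum(as.numeric(a) > 0)
  })
  t(dos)
}
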