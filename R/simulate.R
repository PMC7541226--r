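#' Configuration for the synthetic herd generator
#'
#' Defaults emulate a single nucleus herd performance-testing pigs for
#' average daily gain: about 1,600 litters from 384 sires and 1,179 dams,
#' pigs penned by sex in groups of 10 (males) or 9 (females) formed within
#' two-week entry cohorts by sorting on starting weight, around 1.4% of
#' pigs removed before test end, and 96% of penned pigs genotyped for a
#' medium-density SNP chip.  Phenotypes are generated under the social
#' animal model: the true (co)variance components default to estimates
#' typical for pen-housed finisher growth (direct genetic 3349, indirect
#' genetic 34.4 with genetic correlation 0.06, sex-year-month 908, direct
#' litter 633, indirect litter 19.1, indirect animal 97.4, residual 10989,
#' all g^2/day^2).
#'
#' Sires are drawn from a small per-cohort pool (`sires_per_cohort`), which
#' reproduces the herd-book pattern of pens containing pigs of roughly 7-8
#' litters and 6-7 sires.
#'
#' @param n_litters litters in the test generation.
#' @param litter_size mean number of test piglets per litter (Poisson).
#' @param n_sires,n_dams breeding animals per generation.
#' @param n_generations total generations including the test generation.
#' @param p_male probability a piglet is male.
#' @param pen_size_male,pen_size_female group sizes at test start.
#' @param litters_per_cohort litters farrowing per two-week entry cohort.
#' @param sires_per_cohort size of the sire pool serving one cohort.
#' @param start_date first cohort's farrowing date.
#' @param cohort_days days between cohorts.
#' @param mean_sage,sd_sage age at test start, days.
#' @param test_days nominal days on test.
#' @param removal_rate probability a penned pig is removed before test end.
#' @param genotyping_rate fraction of penned pigs genotyped.
#' @param missing_rate per-cell genotype missingness.
#' @param n_snps,n_chr SNP count and chromosome count for gene dropping.
#' @param freq_range range of founder allele frequencies (uniform).
#' @param sex_chr_frac fraction of SNPs labelled as sex-chromosome markers.
#' @param vc true variance components (an `ige_vc`, indirect model).
#' @param mu intercept of the phenotype, g/day.
#' @param beta_sex fixed effect of male sex, g/day.
#' @param beta_wage,beta_wdev,beta_members fixed regression coefficients on
#'   the starting-weight and stocking-density covariates.
#' @param sd_ym standard deviation of the fixed year-month class effects.
#' @param w_mu,w_gen_sd,w_lit_sd,w_res_sd starting-weight model: mean plus
#'   genetic (scaled direct effect), litter and residual components, kg.
#' @param seed integer seed governing every stochastic step.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_litters = 1595, litter_size = 7.16,
                       n_sires = 384, n_dams = 1179, n_generations = 4,
                       p_male = 0.562,
                       pen_size_male = 10, pen_size_female = 9,
                       litters_per_cohort = 24, sires_per_cohort = 22,
                       start_date = "2015-06-01", cohort_days = 14,
                       mean_sage = 75, sd_sage = 5, test_days = 60,
                       removal_rate = 0.0145,
                       genotyping_rate = 0.96, missing_rate = 0.005,
                       n_snps = 34123, n_chr = 2,
                       freq_range = c(0.05, 0.95), sex_chr_frac = 0.03,
                       vc = vc_indirect(aD = 3349, aI = 34.4, rho = 0.06,
                                        u = 908, lD = 633, lI = 19.1,
                                        eI = 97.4, eD = 10989),
                       mu = 1117.8, beta_sex = 40, beta_wage = 6,
                       beta_wdev = 4, beta_members = -8, sd_ym = 40,
                       w_mu = 30, w_gen_sd = 0.86, w_lit_sd = 1.2,
                       w_res_sd = 2.3,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$start_date <- as.Date(start_date)
  stopifnot(cfg$removal_rate >= 0, cfg$removal_rate <= 1,
            cfg$genotyping_rate >= 0, cfg$genotyping_rate <= 1,
            cfg$missing_rate >= 0, cfg$missing_rate <= 1,
            inherits(cfg$vc, "ige_vc"))
  structure(cfg, class = "sim_config")
}

#' Small preset configuration for unit-test fixtures
#'
#' About 60-70 penned pigs in two cohorts with 500 SNPs; runs in well under
#' a second.
#'
#' @param ... overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_fixture <- function(...) {
  defaults <- list(n_litters = 12, litter_size = 7, n_sires = 8, n_dams = 12,
                   n_generations = 3, litters_per_cohort = 6,
                   sires_per_cohort = 5, n_snps = 500, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

#' Simulate a multi-generation pedigree
#'
#' Discrete generations with random mating; the final (test) generation is
#' organised in litters, each litter sired from a small per-cohort sire
#' pool and nursed by one dam.  Ancestor generations carry no litter
#' labels.  The result is sorted with parents first.
#'
#' @param cfg a `sim_config`.
#' @param seed integer seed (default derived from `cfg$seed`).
#' @return A sorted `pedigree` with extra columns `generation` and `cohort`
#'   and attribute `"test_ids"` (the final-generation animals).
#' @export
simulate_pedigree <- function(cfg, seed = cfg$seed + 1L) {
  set.seed(seed)
  rows <- list()
  idc <- 0L
  new_ids <- function(k) sprintf("ID%06d", idc + seq_len(k))
  gen_animals <- function(k, sex, gen, sire = NA, dam = NA, litter = NA,
                          birth = as.Date(NA), cohort = NA) {
    ids <- new_ids(k)
    idc <<- idc + k
    data.frame(animal = ids, sire = sire, dam = dam, birth_date = birth,
               sex = sex, litter = litter, generation = gen, cohort = cohort,
               stringsAsFactors = FALSE)
  }
  anc_birth <- function(g) cfg$start_date - 400L * (cfg$n_generations - g)
  ## founders
  males <- gen_animals(cfg$n_sires, "M", 0L, birth = anc_birth(1))
  females <- gen_animals(cfg$n_dams, "F", 0L, birth = anc_birth(1))
  rows <- list(males, females)
  ## intermediate breeder generations
  n_anc <- cfg$n_generations - 1L
  for (g in seq_len(max(0L, n_anc - 1L))) {
    nm <- gen_animals(cfg$n_sires, "M", g,
                      sire = sample(males$animal, cfg$n_sires, replace = TRUE),
                      dam = sample(females$animal, cfg$n_sires, replace = TRUE),
                      birth = anc_birth(g + 1L))
    nf <- gen_animals(cfg$n_dams, "F", g,
                      sire = sample(males$animal, cfg$n_dams, replace = TRUE),
                      dam = sample(females$animal, cfg$n_dams, replace = TRUE),
                      birth = anc_birth(g + 1L))
    males <- nm; females <- nf
    rows <- c(rows, list(nm, nf))
  }
  ## test generation: litters in cohorts
  n_coh <- ceiling(cfg$n_litters / cfg$litters_per_cohort)
  lit_cohort <- rep(seq_len(n_coh), each = cfg$litters_per_cohort,
                    length.out = cfg$n_litters)
  lit_sire <- character(cfg$n_litters)
  for (co in seq_len(n_coh)) {
    pool <- sample(males$animal, min(cfg$sires_per_cohort, nrow(males)))
    idx <- which(lit_cohort == co)
    lit_sire[idx] <- sample(pool, length(idx), replace = TRUE)
  }
  lit_dam <- character(cfg$n_litters)
  ## dams reused across (not within) cohorts when litters outnumber dams
  draw <- sample(rep(females$animal, length.out = max(cfg$n_litters, nrow(females))))
  lit_dam <- draw[seq_len(cfg$n_litters)]
  lit_birth <- cfg$start_date + (lit_cohort - 1L) * cfg$cohort_days +
    sample(0:6, cfg$n_litters, replace = TRUE)
  sizes <- pmax(1L, stats::rpois(cfg$n_litters, cfg$litter_size))
  li <- rep(seq_len(cfg$n_litters), sizes)
  piglets <- gen_animals(sum(sizes),
                         sex = ifelse(stats::runif(sum(sizes)) < cfg$p_male, "M", "F"),
                         gen = n_anc,
                         sire = lit_sire[li], dam = lit_dam[li],
                         litter = sprintf("L%05d", li),
                         birth = lit_birth[li], cohort = lit_cohort[li])
  ped <- do.call(rbind, c(rows, list(piglets)))
  rownames(ped) <- NULL
  attr(ped, "sorted") <- TRUE
  attr(ped, "test_ids") <- piglets$animal
  class(ped) <- c("pedigree", "data.frame")
  ped
}

## Draw (direct, indirect) genetic effects ~ MVN(0, Sigma (x) A), plus the
## iid environmental effects, at the true variance components.
.simulate_effects <- function(ped, cfg, seed) {
  set.seed(seed)
  n <- nrow(ped)
  vc <- cfg$vc
  L <- chol(make_A(ped))  # upper: A = L'L
  Z <- matrix(stats::rnorm(2 * n), n, 2)
  a <- crossprod(L, Z)    # two iid N(0, A) columns
  aD <- sqrt(vc$aD) * a[, 1]
  aI <- if (vc$aI > 0)
    (vc$aDI / sqrt(vc$aD)) * a[, 1] +
      sqrt(max(0, vc$aI - vc$aDI^2 / vc$aD)) * a[, 2]
  else rep(0, n)
  list(a_D = stats::setNames(aD, ped$animal),
       a_I = stats::setNames(aI, ped$animal))
}

#' Simulate pen allocation and starting weights
#'
#' Starting weights are drawn with a genetic component (scaled direct
#' genetic effect), a litter component and noise.  Within each sex and
#' two-week entry cohort, pigs are ranked by weight and packed into pens of
#' `pen_size_male` or `pen_size_female` (heavy pigs penned with heavy
#' pigs); pigs left over after filling whole pens are not tested.  Entry
#' dates are the pigs' birth dates plus their starting age, capped at 13
#' days after the first pen entrant; removals occur at `removal_rate`.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param cfg a `sim_config`.
#' @param a_D optional named true direct genetic effects (for the
#'   weight-genetics correlation); standard-normal surrogate when absent.
#' @param seed integer seed.
#' @return Raw herd data frame (one row per penned pig) with columns
#'   animal, group, litter, sex, birth_date, entry_date, end_date,
#'   removal_date, sdate, swght, sage and adg (NA placeholder).
#' @export
simulate_groups <- function(ped, cfg, a_D = NULL, seed = cfg$seed + 3L) {
  set.seed(seed)
  test <- ped[ped$animal %in% attr(ped, "test_ids"), , drop = FALSE]
  nt <- nrow(test)
  zg <- if (is.null(a_D)) stats::rnorm(nt)
        else as.numeric(scale(a_D[test$animal]))
  lits <- unique(test$litter)
  zlit <- stats::setNames(stats::rnorm(length(lits)), lits)
  swght <- cfg$w_mu + cfg$w_gen_sd * zg + cfg$w_lit_sd * zlit[test$litter] +
    stats::rnorm(nt, 0, cfg$w_res_sd)
  sage <- round(stats::rnorm(nt, cfg$mean_sage, cfg$sd_sage))
  entry <- test$birth_date + sage
  group <- rep(NA_character_, nt)
  pen_counter <- 0L
  for (co in sort(unique(test$cohort))) {
    for (sx in c("M", "F")) {
      idx <- which(test$cohort == co & test$sex == sx)
      if (!length(idx)) next
      k <- if (sx == "M") cfg$pen_size_male else cfg$pen_size_female
      idx <- idx[order(swght[idx], decreasing = TRUE)]
      npen <- length(idx) %/% k
      if (npen == 0L) next
      take <- idx[seq_len(npen * k)]
      group[take] <- sprintf("P%05d", pen_counter + rep(seq_len(npen), each = k))
      pen_counter <- pen_counter + npen
    }
  }
  penned <- !is.na(group)
  herd <- data.frame(animal = test$animal, group = group, litter = test$litter,
                     sex = test$sex, birth_date = test$birth_date,
                     entry_date = entry, sage = sage, swght = swght,
                     stringsAsFactors = FALSE)[penned, ]
  ## entry no later than 13 days after the first pen entrant
  first <- stats::ave(as.numeric(herd$entry_date), herd$group, FUN = min)
  herd$entry_date <- as.Date(pmin(as.numeric(herd$entry_date), first + 13),
                             origin = "1970-01-01")
  herd$sage <- as.numeric(herd$entry_date - herd$birth_date)
  herd$sdate <- herd$entry_date
  last <- stats::ave(as.numeric(herd$entry_date), herd$group, FUN = max)
  endn <- last + cfg$test_days +
    stats::ave(seq_len(nrow(herd)), herd$group,
               FUN = function(i) rep(round(stats::rnorm(1, 0, 3)), length(i)))
  herd$end_date <- as.Date(endn, origin = "1970-01-01")
  rem <- stats::runif(nrow(herd)) < cfg$removal_rate
  off <- round(stats::runif(nrow(herd), 5,
                            pmax(6, as.numeric(herd$end_date - herd$entry_date) - 5)))
  herd$removal_date <- as.Date(ifelse(rem, as.numeric(herd$entry_date) + off, NA),
                               origin = "1970-01-01")
  herd$adg <- NA_real_
  rownames(herd) <- NULL
  herd
}

#' Simulate phenotypes under the social animal model
#'
#' Assembles average daily gain for every penned, non-removed pig as the
#' sum of the fixed effects (intercept, sex, year-month class, the
#' starting-weight covariates and the stocking-density covariate), its own
#' direct genetic and litter effects, the indirect genetic, indirect litter
#' and indirect animal effects of its pen mates, the sex-year-month effect
#' and a residual, all at the true variance components in `cfg$vc`.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param herd_raw raw herd frame from [simulate_groups()].
#' @param cfg a `sim_config`.
#' @param effects optional list with `a_D` and `a_I` (named by animal);
#'   drawn from `MVN(0, Sigma (x) A)` when absent.
#' @param seed integer seed.
#' @return List with `herd` (a `herdbook` including phenotypes) and `truth`
#'   (true genetic and environmental effects, fixed-effect values and the
#'   generating `vc`).
#' @export
simulate_phenotypes <- function(ped, herd_raw, cfg, effects = NULL,
                                seed = cfg$seed + 4L) {
  if (is.null(effects)) effects <- .simulate_effects(ped, cfg, cfg$seed + 2L)
  set.seed(seed)
  vc <- cfg$vc
  hb <- herd_raw
  hb$removed <- !is.na(hb$removal_date)
  mean_sage <- mean(hb$sage[!hb$removed])
  sWghtAge <- swght_age(hb$swght, hb$sage, mean_sage)
  gmd <- stats::ave(as.numeric(hb$sdate), hb$group)
  swd <- swght_date(hb$swght, hb$sage, as.numeric(hb$sdate), gmd)
  sWghtDev <- swd - stats::ave(swd, hb$group)
  avg_m <- avg_group_members(hb)
  ym <- format(hb$birth_date, "%Y-%m")
  sym <- paste(hb$sex, ym, sep = "-")
  ym_levels <- sort(unique(ym))
  ym_eff <- stats::setNames(stats::rnorm(length(ym_levels), 0, cfg$sd_ym), ym_levels)
  sym_levels <- sort(unique(sym))
  u <- stats::setNames(stats::rnorm(length(sym_levels), 0, sqrt(vc$u)), sym_levels)
  lits <- sort(unique(hb$litter))
  l_D <- stats::setNames(stats::rnorm(length(lits), 0, sqrt(vc$lD)), lits)
  l_I <- stats::setNames(stats::rnorm(length(lits), 0, sqrt(vc$lI)), lits)
  e_I <- stats::setNames(stats::rnorm(nrow(hb), 0, sqrt(vc$eI)), hb$animal)
  e_D <- stats::rnorm(nrow(hb), 0, sqrt(vc$eD))
  members <- split(hb$animal, hb$group)
  litter_of <- stats::setNames(hb$litter, hb$animal)
  a_D <- effects$a_D; a_I <- effects$a_I
  y <- numeric(nrow(hb))
  for (i in seq_len(nrow(hb))) {
    mates <- setdiff(members[[hb$group[i]]], hb$animal[i])
    y[i] <- cfg$mu +
      cfg$beta_sex * (hb$sex[i] == "M") +
      ym_eff[[ym[i]]] +
      cfg$beta_wage * sWghtAge[i] +
      cfg$beta_wdev * sWghtDev[i] +
      cfg$beta_members * avg_m[[i]] +
      a_D[[hb$animal[i]]] + sum(a_I[mates]) +
      u[[sym[i]]] + l_D[[hb$litter[i]]] + sum(l_I[litter_of[mates]]) +
      sum(e_I[mates]) + e_D[i]
  }
  hb$adg <- ifelse(hb$removed, NA_real_, y)
  herd <- build_herdbook(hb[, c("animal", "group", "litter", "sex",
                                "birth_date", "entry_date", "end_date",
                                "removal_date", "sdate", "swght", "sage",
                                "adg")],
                         mean_sage = mean_sage)
  truth <- list(vc = vc, a_D = a_D, a_I = a_I, u = u, l_D = l_D, l_I = l_I,
                e_I = e_I, ym_eff = ym_eff, latent_y = y)
  list(herd = herd, truth = truth)
}

#' Simulate SNP genotypes by gene dropping
#'
#' Founder haplotypes are drawn in Hardy-Weinberg proportions at uniform
#' base allele frequencies; descendant gametes are formed by dropping
#' parental haplotypes through the pedigree with one crossover per
#' chromosome per meiosis (uniform position).  Linkage realism beyond this
#' is unnecessary because the downstream analysis never uses map positions.
#' Penned pigs are genotyped at `genotyping_rate`; genotyped cells are
#' missing at `missing_rate`.  A fraction of markers is labelled as
#' sex-chromosome SNPs so the QC path can be exercised; their dosages are
#' generated like autosomal ones.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param cfg a `sim_config`.
#' @param ids_genotyped optional explicit set of animals to genotype;
#'   default samples penned-candidate (test) animals at `genotyping_rate`.
#' @param missing introduce per-cell missingness at `missing_rate`?
#' @param seed integer seed.
#' @return List with `dosages` (genotyped animals x SNPs, NA for missing)
#'   and `map` (snp, chrom, pos); the founder allele frequencies are
#'   attached as attribute `"freq"`.
#' @export
simulate_genotypes <- function(ped, cfg, ids_genotyped = NULL,
                               missing = TRUE, seed = cfg$seed + 5L) {
  set.seed(seed)
  n <- nrow(ped)
  m <- cfg$n_snps
  p <- stats::runif(m, cfg$freq_range[1], cfg$freq_range[2])
  chr <- sort(rep(seq_len(cfg$n_chr), length.out = m))
  chr_idx <- split(seq_len(m), chr)
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  pi_ <- .parent_index(ped)
  gamete <- function(j) {
    g <- integer(m)
    for (ci in chr_idx) {
      L <- length(ci)
      xo <- sample.int(L + 1L, 1L) - 1L
      pick <- sample(c(TRUE, FALSE), 1L)
      take1 <- if (pick) seq_len(xo) else setdiff(seq_len(L), seq_len(xo))
      sel <- logical(L); sel[take1] <- TRUE
      g[ci] <- ifelse(sel, H1[j, ci], H2[j, ci])
    }
    g
  }
  base_gamete <- function() stats::rbinom(m, 1L, p)
  for (i in seq_len(n)) {
    s <- pi_$si[i]; d <- pi_$di[i]
    H1[i, ] <- if (s > 0L) gamete(s) else base_gamete()
    H2[i, ] <- if (d > 0L) gamete(d) else base_gamete()
  }
  if (is.null(ids_genotyped)) {
    cand <- attr(ped, "test_ids")
    if (is.null(cand)) cand <- ped$animal
    keep <- stats::runif(length(cand)) < cfg$genotyping_rate
    ids_genotyped <- cand[keep]
  }
  gi <- match(ids_genotyped, ped$animal)
  D <- (H1 + H2)[gi, , drop = FALSE]
  storage.mode(D) <- "double"
  if (missing && cfg$missing_rate > 0) {
    miss <- stats::runif(length(D)) < cfg$missing_rate
    D[miss] <- NA_real_
  }
  snp <- sprintf("SNP%05d", seq_len(m))
  rownames(D) <- ids_genotyped
  colnames(D) <- snp
  chrom <- as.character(chr)
  if (cfg$sex_chr_frac > 0) {
    nx <- round(cfg$sex_chr_frac * m)
    if (nx > 0) chrom[(m - nx + 1L):m] <- "X"
  }
  map <- data.frame(snp = snp, chrom = chrom,
                    pos = stats::ave(seq_len(m), chrom, FUN = seq_along))
  structure(list(dosages = D, map = map), freq = p)
}

## Marker-causal genetic effects: per-SNP direct and indirect effects with
## the generating genetic correlation, applied to centred dosages and
## scaled so the test generation realises the target variances.  Used
## whenever genotypes are simulated, so that genomic relationships track
## the causal variants and single-step prediction can genuinely beat
## pedigree prediction.
.simulate_effects_markers <- function(ped, cfg, geno_full, seed) {
  set.seed(seed)
  vc <- cfg$vc
  D <- geno_full$dosages
  p <- attr(geno_full, "freq")
  Zc <- sweep(D, 2L, 2 * p)
  m <- ncol(D)
  rho <- if (vc$aD > 0 && vc$aI > 0) vc$aDI / sqrt(vc$aD * vc$aI) else 0
  aM <- stats::rnorm(m)
  bM <- rho * aM + sqrt(max(0, 1 - rho^2)) * stats::rnorm(m)
  gD <- as.numeric(Zc %*% aM)
  gI <- as.numeric(Zc %*% bM)
  test <- ped$animal %in% attr(ped, "test_ids")
  sc <- function(g, v) {
    if (v <= 0) return(g * 0)
    g * sqrt(v) / stats::sd(g[test])
  }
  list(a_D = stats::setNames(sc(gD, vc$aD), ped$animal),
       a_I = stats::setNames(sc(gI, vc$aI), ped$animal))
}

#' Simulate a complete herd: pedigree, genotypes, groups and phenotypes
#'
#' Orchestrates [simulate_pedigree()], [simulate_genotypes()], the
#' genetic-effect draw, [simulate_groups()] and [simulate_phenotypes()]
#' from one configuration and seed; rerunning with the same configuration
#' reproduces the herd exactly.  When genotypes are simulated the true
#' genetic effects are, by default, sums of per-SNP effects on the
#' gene-dropped dosages (so genomic relationships track the causal
#' variants); otherwise they are drawn from `MVN(0, Sigma (x) A)`.
#'
#' @param cfg a `sim_config`.
#' @param genotypes simulate SNP genotypes? (They are the slowest part.)
#' @param marker_causal draw the genetic effects from per-SNP effects
#'   rather than from the pedigree-based multivariate normal.
#' @return List with `ped`, `herd` (a `herdbook`), `truth`, and `geno`
#'   (NULL unless requested).
#' @export
simulate_herd <- function(cfg = sim_config(), genotypes = FALSE,
                          marker_causal = genotypes) {
  ped <- simulate_pedigree(cfg)
  geno <- NULL
  if (genotypes) {
    full <- simulate_genotypes(ped, cfg, ids_genotyped = ped$animal,
                               missing = FALSE)
    ## observed panel: penned candidates genotyped at genotyping_rate,
    ## with per-cell missingness
    set.seed(cfg$seed + 6L)
    cand <- attr(ped, "test_ids")
    keep <- cand[stats::runif(length(cand)) < cfg$genotyping_rate]
    D <- full$dosages[keep, , drop = FALSE]
    if (cfg$missing_rate > 0) {
      miss <- stats::runif(length(D)) < cfg$missing_rate
      D[miss] <- NA_real_
    }
    geno <- list(dosages = D, map = full$map)
  }
  effects <- if (genotypes && marker_causal)
    .simulate_effects_markers(ped, cfg, full, cfg$seed + 2L)
  else .simulate_effects(ped, cfg, cfg$seed + 2L)
  herd_raw <- simulate_groups(ped, cfg, a_D = effects$a_D)
  sim <- simulate_phenotypes(ped, herd_raw, cfg, effects = effects)
  list(ped = ped, herd = sim$herd, truth = sim$truth, geno = geno,
       cfg = cfg)
}
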