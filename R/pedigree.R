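#' Coerce a data frame to a validated, sorted pedigree
#'
#' A pedigree records, for each animal, its sire and dam (possibly unknown),
#' and optionally birth date, sex and litter.  The returned object is a
#' `data.frame` with class `"pedigree"`, ordered so that parents always
#' precede their offspring (a topological order of the parent map), which is
#' the order required by the tabular method and by Henderson's rules for the
#' inverse of the numerator relationship matrix.
#'
#' Unknown parents may be coded as `NA`, `"0"` or the empty string; they are
#' normalised to `NA`.  A parent id that never appears as an animal is
#' auto-inserted as a founder with a warning.  A parentage cycle (an animal
#' that is its own ancestor) is an error naming the offending chain.
#'
#' @param df data frame with columns `animal`, `sire`, `dam` and optionally
#'   `birth_date` (coercible to `Date`), `sex` (`"M"`/`"F"`) and `litter`.
#' @return A sorted `pedigree` object (a data frame); parents precede
#'   offspring.
#' @export
as_pedigree <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree needs columns: ", paste(need, collapse = ", "))
  ped <- data.frame(
    animal = as.character(df$animal),
    sire   = .norm_parent(df$sire),
    dam    = .norm_parent(df$dam),
    stringsAsFactors = FALSE
  )
  ped$birth_date <- if ("birth_date" %in% names(df)) as.Date(df$birth_date) else as.Date(NA)
  ped$sex    <- if ("sex" %in% names(df)) as.character(df$sex) else NA_character_
  ped$litter <- if ("litter" %in% names(df)) as.character(df$litter) else NA_character_
  if (anyDuplicated(ped$animal))
    stop("duplicated animal ids: ",
         paste(unique(ped$animal[duplicated(ped$animal)]), collapse = ", "))
  ## auto-insert missing parents as founders
  parents <- unique(stats::na.omit(c(ped$sire, ped$dam)))
  missing <- setdiff(parents, ped$animal)
  if (length(missing)) {
    warning(length(missing), " parent id(s) absent from pedigree; inserted as founders")
    add <- ped[rep.int(NA_integer_, length(missing)), ]
    add$animal <- missing
    ped <- rbind(add, ped)
    rownames(ped) <- NULL
  }
  sort_pedigree(structure(ped, class = c("pedigree", "data.frame")))
}

.norm_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
  x
}

#' Read a pedigree from CSV
#'
#' Expects columns `animal`, `sire`, `dam` and optionally `birth_date`
#' (ISO-8601), `sex` and `litter`; `"0"` or empty marks an unknown parent.
#'
#' @param path path to a CSV file.
#' @return A sorted [as_pedigree()] object.
#' @export
read_pedigree <- function(path) {
  as_pedigree(utils::read.csv(path, stringsAsFactors = FALSE,
                              colClasses = "character"))
}

#' Topologically sort a pedigree (parents before offspring)
#'
#' Kahn's algorithm on the parent map.  Errors on a parentage cycle, naming
#' the animals involved.
#'
#' @param ped a `pedigree` (or compatible data frame).
#' @return The pedigree reordered with parents first.
#' @export
sort_pedigree <- function(ped) {
  n <- nrow(ped)
  id <- ped$animal
  idx <- seq_len(n); names(idx) <- id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam),  0L, idx[ped$dam])
  ## children[i]: offspring of animal i
  deg <- integer(n)
  deg <- deg + (si > 0L) + (di > 0L)
  kids <- vector("list", n)
  for (p in list(si, di)) {
    has <- which(p > 0L)
    sp <- split(has, p[has])
    for (k in names(sp)) kids[[as.integer(k)]] <- c(kids[[as.integer(k)]], sp[[k]])
  }
  queue <- which(deg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, v)
    for (w in kids[[v]]) {
      deg[w] <- deg[w] - 1L
      if (deg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) < n) {
    left <- setdiff(seq_len(n), out)
    ## walk parent links among the leftovers to exhibit a cycle
    chain <- left[[1L]]
    repeat {
      nxt <- c(si[chain[length(chain)]], di[chain[length(chain)]])
      nxt <- nxt[nxt %in% left][1L]
      if (nxt %in% chain) {
        chain <- c(chain[which(chain == nxt)[1L]:length(chain)], nxt)
        break
      }
      chain <- c(chain, nxt)
    }
    stop("parentage cycle detected: ", paste(id[chain], collapse = " -> "))
  }
  res <- ped[out, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "sorted") <- TRUE
  class(res) <- c("pedigree", "data.frame")
  res
}

.check_sorted <- function(ped) {
  if (!isTRUE(attr(ped, "sorted"))) {
    idx <- seq_len(nrow(ped)); names(idx) <- ped$animal
    ok <- function(p) all(is.na(p) | idx[p] < idx)
    if (!ok(ped$sire) || !ok(ped$dam))
      stop("pedigree is not sorted with parents first; call sort_pedigree()")
  }
  invisible(ped)
}

#' Truncate a pedigree to ancestors within a generation horizon
#'
#' Keeps a set of anchor animals (typically the phenotyped ones) and every
#' ancestor reachable within `generations` meioses; parents of animals on the
#' horizon become unknown.  A horizon of five generations prior to the
#' phenotyped animals is the conventional depth for routine evaluations.
#'
#' @param ped a sorted `pedigree`.
#' @param anchor_ids character ids to anchor the truncation.
#' @param generations non-negative integer horizon in meioses (default 5).
#' @return The truncated, sorted pedigree.
#' @export
truncate_pedigree <- function(ped, anchor_ids, generations = 5L) {
  .check_sorted(ped)
  if (generations < 0) stop("generations must be >= 0")
  if (!all(anchor_ids %in% ped$animal))
    stop("anchor ids absent from pedigree")
  keep <- unique(as.character(anchor_ids))
  frontier <- keep
  g <- 0L
  while (g < generations && length(frontier)) {
    rows <- ped[ped$animal %in% frontier, c("sire", "dam")]
    par <- unique(stats::na.omit(c(rows$sire, rows$dam)))
    frontier <- setdiff(par, keep)
    keep <- c(keep, frontier)
    g <- g + 1L
  }
  res <- ped[ped$animal %in% keep, , drop = FALSE]
  ## parents beyond the horizon become unknown
  res$sire[!(res$sire %in% keep)] <- NA_character_
  res$dam [!(res$dam  %in% keep)] <- NA_character_
  rownames(res) <- NULL
  attr(res, "sorted") <- TRUE
  class(res) <- c("pedigree", "data.frame")
  res
}

.parent_index <- function(ped) {
  idx <- seq_len(nrow(ped)); names(idx) <- ped$animal
  list(
    si = ifelse(is.na(ped$sire), 0L, idx[ped$sire]),
    di = ifelse(is.na(ped$dam),  0L, idx[ped$dam])
  )
}

#' Numerator relationship matrix (tabular method)
#'
#' Computes the additive (numerator) relationship matrix A by the tabular
#' recursion: for animal i with parents s and d, `a_ij = (a_js + a_jd)/2`
#' for j earlier in the order, and `a_ii = 1 + a_sd/2`.  Diagonal elements
#' are `1 + F_i` with `F_i` the inbreeding coefficient.
#'
#' @param ped a sorted `pedigree`.
#' @return Dense symmetric matrix with animal ids as dimnames and attribute
#'   `"F"` (inbreeding coefficients).
#' @export
make_A <- function(ped) {
  .check_sorted(ped)
  pi <- .parent_index(ped)
  A <- tabular_a(as.integer(pi$si), as.integer(pi$di))
  dimnames(A) <- list(ped$animal, ped$animal)
  structure(A, F = stats::setNames(diag(A) - 1, ped$animal))
}

#' Inbreeding coefficients from the pedigree
#'
#' @param ped a sorted `pedigree`.
#' @return Named numeric vector of inbreeding coefficients F.
#' @export
inbreeding <- function(ped) attr(make_A(ped), "F")

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules accounting for inbreeding.  The Mendelian-sampling
#' variance of animal i is `d_i = 0.5 - 0.25 (F_s + F_d)` when both parents
#' are known, `0.75 - 0.25 F_p` with one known parent, and 1 for founders.
#' Each animal contributes `1/d_i` to (i,i), `-1/(2 d_i)` to (i, parent) and
#' `1/(4 d_i)` to each (parent, parent') cell.
#'
#' @param ped a sorted `pedigree`.
#' @param f optional precomputed inbreeding coefficients (named as animals).
#' @return A `dsCMatrix` (sparse symmetric) with attribute `"logdet"`, the
#'   log-determinant of A (`sum(log d_i)`).
#' @export
make_Ainv <- function(ped, f = NULL) {
  .check_sorted(ped)
  n <- nrow(ped)
  if (is.null(f)) f <- inbreeding(ped)
  f <- f[ped$animal]
  pi <- .parent_index(ped)
  si <- pi$si; di <- pi$di
  fs <- fd <- numeric(n)
  fs[si > 0L] <- f[si[si > 0L]]
  fd[di > 0L] <- f[di[di > 0L]]
  dvec <- ifelse(si > 0L & di > 0L, 0.5 - 0.25 * (fs + fd),
          ifelse(si > 0L | di > 0L, 0.75 - 0.25 * (fs + fd), 1))
  lam <- 1 / dvec
  ii <- list(); jj <- list(); xx <- list()
  push <- function(i, j, x) {
    k <- length(ii) + 1L
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x
  }
  irow <- seq_len(n)
  push(irow, irow, lam)
  for (p in list(si, di)) {
    has <- p > 0L
    push(irow[has], p[has], -0.5 * lam[has])
    push(p[has], irow[has], -0.5 * lam[has])
    push(p[has], p[has], 0.25 * lam[has])
  }
  both <- si > 0L & di > 0L
  push(si[both], di[both], 0.25 * lam[both])
  push(di[both], si[both], 0.25 * lam[both])
  M <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx), dims = c(n, n),
    dimnames = list(ped$animal, ped$animal), symmetric = FALSE
  )
  M <- methods::as(Matrix::forceSymmetric(M), "CsparseMatrix")
  attr(M, "logdet") <- sum(log(dvec))
  M
}

#' Mean within-pen additive relatedness
#'
#' For each pen, the mean of the off-diagonal relationship coefficients over
#' unordered pairs of members; pens are then averaged with equal weight.
#' This is the `r` entering the phenotypic-variance decomposition for
#' socially affected traits.  Pens with fewer than two members in A are
#' skipped with a warning.
#'
#' @param A relationship matrix with id dimnames (numerator or other).
#' @param groups data frame with columns `animal` and `group`.
#' @return Scalar mean relatedness; attribute `"per_group"` holds the pen
#'   means.
#' @export
mean_group_relatedness <- function(A, groups) {
  stopifnot(all(c("animal", "group") %in% names(groups)))
  ids <- rownames(A)
  if (!all(groups$animal %in% ids)) stop("grouped animals missing from A")
  per <- vapply(split(as.character(groups$animal), groups$group), function(m) {
    k <- length(m)
    if (k < 2L) return(NA_real_)
    sub <- A[m, m, drop = FALSE]
    (sum(sub) - sum(diag(sub))) / (k * (k - 1))
  }, numeric(1))
  if (anyNA(per)) {
    warning(sum(is.na(per)), " singleton pen(s) skipped")
    per <- per[!is.na(per)]
  }
  structure(mean(per), per_group = per)
}

#' Write a relationship matrix as 3-column sparse text
#'
#' @param A matrix (dense or sparse) with id dimnames.
#' @param path output file; columns `id_i`, `id_j`, `value`, lower triangle
#'   including the diagonal, zeros omitted.
#' @export
write_relmat <- function(A, path) {
  M <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"),
                   "TsparseMatrix")
  keep <- M@i >= M@j & M@x != 0
  df <- data.frame(id_i = rownames(M)[M@i[keep] + 1L],
                   id_j = colnames(M)[M@j[keep] + 1L],
                   value = M@x[keep])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
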