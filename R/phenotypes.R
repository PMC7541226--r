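#' Age-corrected starting weight
#'
#' Standardises observed starting weights to the mean starting age by a
#' linear growth approximation: `sWght - (sWght/sAge) * (sAge - mean_sage)`.
#' The ratio `sWght/sAge` is the animal's average growth rate from birth, so
#' the correction removes the expected weight gained (or not yet gained)
#' relative to an animal weighed at the mean age.
#'
#' @param swght observed starting weight, kg.
#' @param sage age at test start, days (> 0).
#' @param mean_sage mean starting age of the tested animals, days.
#' @return Corrected weight, kg.
#' @export
swght_age <- function(swght, sage, mean_sage) {
  if (any(sage <= 0)) stop("sAge must be positive")
  swght - (swght / sage) * (sage - mean_sage)
}

#' Date-standardised starting weight
#'
#' Standardises starting weights to one timepoint within a group:
#' `sWght - (sWght/sAge) * (sDate - group_mean_date)`, date differences in
#' days.  An animal weighed after its group's mean weighing date has its
#' expected extra gain removed.
#'
#' @param swght observed starting weight, kg.
#' @param sage age at test start, days (> 0).
#' @param sdate date the starting weight was observed (`Date` or numeric).
#' @param group_mean_date mean weighing date of the group.
#' @return Standardised weight, kg.
#' @export
swght_date <- function(swght, sage, sdate, group_mean_date) {
  if (any(sage <= 0)) stop("sAge must be positive")
  swght - (swght / sage) * as.numeric(sdate - group_mean_date)
}

#' Deviation of date-standardised weight from the group mean
#'
#' @param x date-standardised weights of one group (see [swght_date()]).
#' @return Deviations from the group mean; they sum to zero exactly.
#' @export
swght_dev <- function(x) {
  if (!length(x)) stop("empty group")
  x - mean(x)
}

#' Time-averaged number of pen mates
#'
#' For each grouped animal, the average number of other group members
#' present in the pen per day of the animal's own test period.  An animal's
#' presence window runs from its entry date to its removal date (if removed)
#' or the group's end date.  Used as a stocking-density covariate, since
#' removals reduce competition in the pen.
#'
#' @param herd data frame with columns `animal`, `group`, `entry_date`,
#'   `end_date` and optionally `removal_date` (NA when not removed).
#' @return Named numeric vector, heads/day, for every grouped animal.
#' @export
avg_group_members <- function(herd) {
  stopifnot(all(c("animal", "group", "entry_date", "end_date") %in% names(herd)))
  rem <- if ("removal_date" %in% names(herd)) herd$removal_date else rep(as.Date(NA), nrow(herd))
  start <- as.numeric(as.Date(herd$entry_date))
  stop_ <- as.numeric(as.Date(herd$end_date))
  stop_ <- ifelse(!is.na(rem), pmin(as.numeric(as.Date(rem)), stop_), stop_)
  out <- rep(NA_real_, nrow(herd))
  for (g in split(seq_len(nrow(herd)), herd$group)) {
    if (any(stop_[g] <= start[g])) stop("zero-length test window in group")
    ov <- outer(seq_along(g), seq_along(g), function(i, j) {
      pmax(0, pmin(stop_[g][i], stop_[g][j]) - pmax(start[g][i], start[g][j]))
    })
    diag(ov) <- 0
    out[g] <- rowSums(ov) / (stop_[g] - start[g])
  }
  stats::setNames(out, herd$animal)
}

#' Build the herd book: covariates, class labels and group structure
#'
#' Takes per-animal phenotype and grouping records and appends the model
#' covariates: age-corrected starting weight (`sWghtAge`), the within-group
#' deviation of date-standardised starting weight (`sWghtDev`), the
#' time-averaged number of pen mates (`avg_members`), the year-by-month of
#' birth class (`ym`) and the sex-year-month class (`sym`).  Removed animals
#' keep their covariates and group membership but have `adg = NA` and
#' contribute no phenotype record to the model.
#'
#' @param phen data frame with columns `animal`, `group`, `litter`, `sex`,
#'   `birth_date`, `entry_date`, `end_date`, `swght`, `sage`, `adg`, and
#'   optionally `removal_date`, `sdate` (weighing date; defaults to
#'   `entry_date`).
#' @param mean_sage mean starting age used by the age correction; defaults
#'   to the mean over phenotyped (non-removed) animals.
#' @return A `herdbook` data frame with covariate columns appended.
#' @export
build_herdbook <- function(phen, mean_sage = NULL) {
  need <- c("animal", "group", "litter", "sex", "birth_date", "entry_date",
            "end_date", "swght", "sage", "adg")
  if (!all(need %in% names(phen)))
    stop("herd book needs columns: ", paste(setdiff(need, names(phen)), collapse = ", "))
  hb <- phen
  hb$animal <- as.character(hb$animal)
  if (!"removal_date" %in% names(hb)) hb$removal_date <- as.Date(NA)
  if (!"sdate" %in% names(hb)) hb$sdate <- hb$entry_date
  for (cc in c("birth_date", "entry_date", "end_date", "removal_date", "sdate"))
    hb[[cc]] <- as.Date(hb[[cc]])
  hb$removed <- !is.na(hb$removal_date)
  if (any(hb$removed & !is.na(hb$adg)))
    hb$adg[hb$removed] <- NA_real_
  if (is.null(mean_sage)) mean_sage <- mean(hb$sage[!is.na(hb$adg)])
  hb$sWghtAge <- swght_age(hb$swght, hb$sage, mean_sage)
  gmd <- stats::ave(as.numeric(hb$sdate), hb$group)
  swd <- swght_date(hb$swght, hb$sage, as.numeric(hb$sdate), gmd)
  hb$sWghtDev <- swd - stats::ave(swd, hb$group)
  hb$avg_members <- avg_group_members(hb)
  ym <- format(hb$birth_date, "%Y-%m")
  hb$ym <- ym
  hb$sym <- paste(hb$sex, ym, sep = "-")
  attr(hb, "mean_sage") <- mean_sage
  class(hb) <- c("herdbook", "data.frame")
  hb
}

#' Group sizes at test start and their mean
#'
#' @param herd a herd book or any data frame with `animal` and `group`.
#' @return List with `sizes` (per group) and `n_bar` (unweighted mean group
#'   size at test start).
#' @export
group_sizes <- function(herd) {
  sizes <- table(herd$group)
  list(sizes = sizes, n_bar = mean(as.numeric(sizes)))
}

#' Summary statistics of the herd book
#'
#' Mean, SD, min and max of the phenotype and the model covariates over
#' phenotyped animals, in the layout conventional for growth-test reports.
#'
#' @param herd a `herdbook`.
#' @return Data frame of summary statistics.
#' @export
herd_summary <- function(herd) {
  ph <- herd[!is.na(herd$adg), ]
  vars <- list(`Average daily gain (g/day)` = ph$adg,
               `sWghtAge (kg)` = ph$sWghtAge,
               `sWghtDev (kg)` = ph$sWghtDev,
               `Average group members (heads/day)` = ph$avg_members)
  do.call(rbind, lapply(names(vars), function(v) {
    x <- vars[[v]]
    data.frame(variable = v, mean = mean(x), sd = stats::sd(x),
               min = min(x), max = max(x))
  }))
}
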