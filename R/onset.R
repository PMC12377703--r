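# Time-to-onset analysis: days from the earliest day-precision therapy
# start of the implicated (primary-suspect) drug to the adverse-event
# date, compared across age (>=65 vs <65) and sex strata with a two-sided
# Mann-Whitney rank-sum test (exact enumeration at small n, otherwise a
# tie-corrected normal approximation with continuity correction).

#' Per-report time to onset for one drug
#'
#' For every event-positive report with the drug as primary suspect,
#' onset = event date minus the earliest day-precision therapy start among
#' that report's primary-suspect entries of the drug.  Records are dropped
#' (with a reason code) when either date is below day precision or
#' missing, or when the event precedes the start.
#'
#' @param data a cleaned `faers_data`.
#' @param drug normalized drug name.
#' @param target_pt,target_code target event, as in [event_report_ids()].
#' @param age_cut years defining the high-age group (default 65).
#' @return list: `records` (data.frame `primaryid`, `drug`, `onset_days`,
#'   `age_group`, `sex`) and `drops` (data.frame `primaryid`, `reason`
#'   with reasons `no_therapy`, `partial_date`, `missing_event_date`,
#'   `negative_onset`).
#' @export
compute_onset <- function(data, drug, target_pt, target_code = NULL,
                          age_cut = 65) {
  ev <- event_report_ids(data, target_pt, target_code)
  dsub <- data$drugs[data$drugs$role == "PS" & data$drugs$name == drug &
                       data$drugs$primaryid %in% ev, , drop = FALSE]
  ids <- unique(dsub$primaryid)
  r <- data$reports[match(ids, data$reports$primaryid), , drop = FALSE]

  # earliest day-precision start among the drug's PS therapy rows
  key <- paste(data$therapies$primaryid, data$therapies$drug_seq)
  want <- paste(rep(dsub$primaryid, 1), dsub$seq)
  ther <- data$therapies[key %in% want, , drop = FALSE]
  has_ther <- ids %in% ther$primaryid
  day_ther <- ther[ther$start_precision == "day", , drop = FALSE]
  start <- rep(as.Date(NA), length(ids))
  if (nrow(day_ther)) {
    d <- partial_date_to_date(day_ther$start_date, day_ther$start_precision)
    agg <- tapply(d, day_ther$primaryid, min)
    start <- as.Date(agg[as.character(ids)],
                     origin = "1970-01-01")
  }
  event <- partial_date_to_date(r$event_date, r$event_precision)

  reason <- rep(NA_character_, length(ids))
  reason[!has_ther] <- "no_therapy"
  reason[is.na(reason) & is.na(start)] <- "partial_date"
  reason[is.na(reason) & r$event_precision != "day"] <-
    ifelse(r$event_precision[is.na(reason) & r$event_precision != "day"]
           == "missing", "missing_event_date", "partial_date")
  onset <- as.numeric(event - start)
  reason[is.na(reason) & onset < 0] <- "negative_onset"

  keep <- is.na(reason)
  age_group <- ifelse(is.na(r$age_years), "unknown",
                      ifelse(r$age_years >= age_cut, "high", "low"))
  records <- data.frame(
    primaryid = ids[keep], drug = drug,
    onset_days = onset[keep],
    age_group = age_group[keep], sex = r$sex[keep],
    stringsAsFactors = FALSE
  )
  drops <- data.frame(primaryid = ids[!keep], reason = reason[!keep],
                      stringsAsFactors = FALSE)
  list(records = records, drops = drops)
}

#' Order-statistic summary of onset times
#'
#' @param onset_days numeric vector of onset times (days).
#' @return one-row data.frame `n`, `mean`, `median`, `q1`, `q3` (type-7
#'   quartiles; the median of an even count is the midpoint of the central
#'   pair), or `NULL` when empty.
#' @export
summarize_onset <- function(onset_days) {
  onset_days <- onset_days[!is.na(onset_days)]
  if (!length(onset_days)) return(NULL)
  q <- stats::quantile(onset_days, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(n = length(onset_days), mean = mean(onset_days),
             median = q[2], q1 = q[1], q3 = q[3])
}

#' Two-sided Mann--Whitney rank-sum test
#'
#' `U` is the Mann--Whitney statistic of the first group computed from
#' midranks (`U_x + U_y = n_x n_y`).  When the combined sample has at most
#' `exact_max` observations and no ties, the two-sided p-value is computed
#' by exact enumeration of all group assignments of the ranks; otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction is used.  A group of size zero yields a not-testable marker.
#'
#' @param x,y numeric samples.
#' @param exact_max largest combined size for the exact null (default 16).
#' @return list `u`, `u_y`, `p_value`, `method` (`"exact"` or
#'   `"normal_approx"`), `testable`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
rank_sum_test <- function(x, y, exact_max = 16) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) {
    return(list(u = NA_real_, u_y = NA_real_, p_value = NA_real_,
                method = "none", testable = FALSE))
  }
  all_v <- c(x, y)
  rk <- rank(all_v)  # midranks
  u <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(all_v))
  n <- nx + ny
  if (!ties && n <= exact_max) {
    # enumerate every assignment of nx ranks out of 1..n
    combs <- utils::combn(n, nx)
    us <- colSums(matrix(seq_len(n)[combs], nrow = nx)) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    return(list(u = u, u_y = nx * ny - u, p_value = p, method = "exact",
                testable = TRUE))
  }
  mu <- nx * ny / 2
  tie_tab <- table(all_v)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) {
    return(list(u = u, u_y = nx * ny - u, p_value = 1,
                method = "normal_approx", testable = TRUE))
  }
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  p <- min(1, 2 * stats::pnorm(-z))
  list(u = u, u_y = nx * ny - u, p_value = p, method = "normal_approx",
       testable = TRUE)
}

#' Stratified onset comparison for one drug
#'
#' Splits a drug's onset records by age group (high = at or above the age
#' cut) or by sex, drops unknown-stratum records, and compares the two
#' strata with [rank_sum_test()] when both hold at least `min_per_group`
#' records.  The reported direction follows the rank comparison (which
#' group's mean rank is higher); a flag marks drugs where the mean and the
#' rank comparison disagree in direction.
#'
#' @param records onset records as from [compute_onset()]`$records` (may
#'   span several drugs).
#' @param by `"age"` or `"sex"`.
#' @param min_per_group minimum records per stratum (default 2).
#' @return data.frame: one row per drug with group sizes, means, medians,
#'   `u_statistic`, `p_value`, `significant` (p < 0.05), `direction`
#'   (label of the group with the higher mean rank), `mean_rank_disagree`,
#'   `status`.
#' @export
stratified_onset_analysis <- function(records, by = c("age", "sex"),
                                      min_per_group = 2) {
  by <- match.arg(by)
  groups <- if (by == "age") c("high", "low") else c("male", "female")
  var <- if (by == "age") "age_group" else "sex"
  one <- function(drug) {
    rec <- records[records$drug == drug & records[[var]] %in% groups, ,
                   drop = FALSE]
    gx <- rec$onset_days[rec[[var]] == groups[1]]
    gy <- rec$onset_days[rec[[var]] == groups[2]]
    base <- data.frame(
      drug = drug, stratum_variable = by,
      group1 = groups[1], group2 = groups[2],
      n1 = length(gx), n2 = length(gy),
      mean1 = if (length(gx)) mean(gx) else NA_real_,
      mean2 = if (length(gy)) mean(gy) else NA_real_,
      median1 = if (length(gx)) stats::median(gx) else NA_real_,
      median2 = if (length(gy)) stats::median(gy) else NA_real_,
      u_statistic = NA_real_, p_value = NA_real_, significant = FALSE,
      direction = NA_character_, mean_rank_disagree = FALSE,
      status = "ok", stringsAsFactors = FALSE
    )
    if (length(gx) < min_per_group || length(gy) < min_per_group) {
      base$status <- "insufficient_stratum_size"
      return(base)
    }
    ts <- rank_sum_test(gx, gy)
    base$u_statistic <- ts$u
    base$p_value <- ts$p_value
    base$significant <- !is.na(ts$p_value) && ts$p_value < 0.05
    rank_dir <- if (ts$u > length(gx) * length(gy) / 2) {
      groups[1]
    } else if (ts$u < length(gx) * length(gy) / 2) {
      groups[2]
    } else {
      "tie"
    }
    mean_dir <- if (base$mean1 > base$mean2) groups[1] else
      if (base$mean1 < base$mean2) groups[2] else "tie"
    base$direction <- rank_dir
    base$mean_rank_disagree <- rank_dir != mean_dir
    base
  }
  out <- do.call(rbind, lapply(unique(records$drug), one))
  if (is.null(out)) out <- data.frame(drug = character(0))
  rownames(out) <- NULL
  out
}
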