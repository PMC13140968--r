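#' Time to onset of an adverse event
#'
#' Onset is the day difference `EVENT_DT - START_DT`. Both dates must be
#' complete (day precision); otherwise the record is excluded as
#' `incomplete`. Events dated before treatment initiation are excluded as
#' `pre_treatment`. Exclusions are returned as values, never errors.
#'
#' @param event_dt,start_dt character vectors of raw FAERS date strings
#'   (vectorised, recycled to common length).
#' @return data.table with columns `onset_days` (integer, `NA` when
#'   excluded) and `status` (`"valid"`, `"pre_treatment"`, `"incomplete"`).
#' @examples
#' time_to_onset("20240301", "20240201")   # 29 days (leap February)
#' @export
time_to_onset <- function(event_dt, start_dt) {
  n <- max(length(event_dt), length(start_dt))
  ev <- faers_date_as_date(rep_len(event_dt, n))
  st <- faers_date_as_date(rep_len(start_dt, n))
  status <- rep("incomplete", n)
  onset <- rep(NA_integer_, n)
  both <- !is.na(ev) & !is.na(st)
  pre <- both & ev < st
  ok <- both & !pre
  status[pre] <- "pre_treatment"
  status[ok] <- "valid"
  onset[ok] <- as.integer(ev[ok] - st[ok])
  data.table::data.table(onset_days = onset, status = status)
}

.tto_breaks <- c(0, 30, 60, 90, 180, 360, Inf)
.tto_labels <- c("0-30", "31-60", "61-90", "91-180", "181-360", ">360")

#' Summarise time-to-onset records
#'
#' Median and quartiles use linear interpolation (`type = 7` by default; a
#' `type = 6` variant is available because published interquartile ranges
#' can depend on the convention). Onset days are binned into
#' 0--30, 31--60, 61--90, 91--180, 181--360 and >360 day intervals
#' (month = 30 days exactly).
#'
#' @param onset_days integer vector of valid onset times (days, >= 0).
#' @param quartile_type quantile algorithm, 7 (default) or 6.
#' @return list of class `tto_summary`: `n`, `median_days`, `q1_days`,
#'   `q3_days`, `bin_counts`, `bin_fractions`, `month1_fraction`.
#' @export
tto_summary <- function(onset_days, quartile_type = 7) {
  onset_days <- onset_days[!is.na(onset_days)]
  if (length(onset_days) == 0L) stop("no valid onset records", call. = FALSE)
  stopifnot(all(onset_days >= 0), quartile_type %in% c(6, 7))
  qs <- quantile(onset_days, c(0.25, 0.5, 0.75), type = quartile_type,
                 names = FALSE)
  bins <- table(cut(onset_days, breaks = .tto_breaks, labels = .tto_labels,
                    include.lowest = TRUE, right = TRUE))
  bin_counts <- setNames(as.integer(bins), .tto_labels)
  structure(list(n = length(onset_days), median_days = qs[2], q1_days = qs[1],
                 q3_days = qs[3], bin_counts = bin_counts,
                 bin_fractions = bin_counts / length(onset_days),
                 month1_fraction = bin_counts[["0-30"]] / length(onset_days)),
            class = "tto_summary")
}

#' @export
print.tto_summary <- function(x, ...) {
  cat(sprintf("Time to onset: n = %d, median %.1f days (IQR %.1f-%.1f)\n",
              x$n, x$median_days, x$q1_days, x$q3_days))
  cat(sprintf("  within first month: %.1f%%\n", 100 * x$month1_fraction))
  print(x$bin_counts)
  invisible(x)
}

#' Extract time-to-onset records for a cohort
#'
#' One record per report: the report-level `EVENT_DT` against the earliest
#' valid `START_DT` among the report's therapy rows (onset is measured from
#' initiation of the regimen).
#'
#' @param cases report-level data.table with `primaryid` and `event_dt`.
#' @param ther therapy data.table with `primaryid` and `start_dt`.
#' @return data.table `primaryid`, `onset_days`, `status`; accounting
#'   attribute `exclusions` with `n_input`, `n_valid`, `n_pre_treatment`,
#'   `n_incomplete`.
#' @export
cohort_tto <- function(cases, ther) {
  th <- data.table::as.data.table(ther)
  th[, stamp := faers_date_stamp(start_dt)]
  first <- th[!is.na(stamp), .(start_dt = start_dt[which.min(stamp)]),
              by = primaryid]
  dt <- merge(data.table::as.data.table(cases)[, .(primaryid, event_dt)],
              first, by = "primaryid", all.x = TRUE)
  res <- time_to_onset(dt$event_dt, dt$start_dt)
  out <- cbind(dt[, .(primaryid)], res)
  attr(out, "exclusions") <- c(
    n_input = nrow(out),
    n_valid = sum(out$status == "valid"),
    n_pre_treatment = sum(out$status == "pre_treatment"),
    n_incomplete = sum(out$status == "incomplete"))
  out
}

#' Per-stratum event term counts
#'
#' Stratifies reports by sex (`F`/`M`) or age bin (`<18`, `18-65`, `>65`)
#' and counts, within each stratum, the number of reports mentioning each
#' preferred term (descending). Reports with an unknown stratum are
#' excluded and tallied.
#'
#' @param cases report-level data.table with `primaryid`, `sex`, `age_bin`.
#' @param reac report-term pairs (`primaryid`, `pt`).
#' @param axis `"sex"` or `"age"`.
#' @return named list of data.tables (`pt`, `n`), one per stratum, with
#'   attribute `n_unknown`.
#' @export
stratify <- function(cases, reac, axis = c("sex", "age")) {
  axis <- match.arg(axis)
  cs <- data.table::as.data.table(cases)
  key <- if (axis == "sex") cs$sex else cs$age_bin
  strata <- if (axis == "sex") c("F", "M") else c("<18", "18-65", ">65")
  rc <- unique(data.table::as.data.table(reac)[, .(primaryid, pt)])
  out <- list()
  for (s in strata) {
    ids <- cs$primaryid[!is.na(key) & key == s]
    tab <- rc[primaryid %chin% ids, .(n = .N), by = pt]
    data.table::setorder(tab, -n, pt)
    out[[s]] <- tab
  }
  attr(out, "n_unknown") <- sum(is.na(key) | !(key %in% strata))
  out
}

#' Side-by-side comparison of two cohorts' term counts
#'
#' Takes the union of terms (missing terms count 0) and sorts by the
#' absolute count difference, descending.
#'
#' @param counts_a,counts_b data.tables (`term`, `n`) or named integer
#'   vectors.
#' @param labels column labels for the two cohorts.
#' @return data.table `term`, `<label_a>`, `<label_b>`, `difference`
#'   (a minus b), sorted by `abs(difference)` descending.
#' @export
compare_cohorts <- function(counts_a, counts_b,
                            labels = c("cohort_a", "cohort_b")) {
  as_dt <- function(x) {
    if (is.data.frame(x)) {
      dt <- data.table::as.data.table(x)
      data.table::setnames(dt, 1:2, c("term", "n"))
    } else dt <- data.table::data.table(term = names(x), n = as.integer(x))
    dt
  }
  m <- merge(as_dt(counts_a), as_dt(counts_b), by = "term", all = TRUE,
             suffixes = c("_a", "_b"))
  m[is.na(m)] <- 0L
  data.table::setnames(m, c("n_a", "n_b"), labels)
  m[, difference := get(labels[1]) - get(labels[2])]
  m[order(-abs(difference), term)]
}

#' Demographic and administrative summary of a report set
#'
#' Percentages are over all reports; missing values form their own
#' category. Weight bins are <50, 50--100 and >100 kg; yearly counts are
#' keyed by the FDA_DT year.
#'
#' @param cases report-level data.table from [build_cases()].
#' @param top_k number of countries to list individually.
#' @return list of data.tables: `sex`, `age`, `weight`, `country`,
#'   `occupation`, `outcomes`, `annual` (each with `n` and `pct`).
#' @export
demographics_summary <- function(cases, top_k = 10L) {
  cs <- data.table::as.data.table(cases)
  n_reports <- nrow(cs)
  pct_tab <- function(x) {
    tab <- data.table::as.data.table(table(category = x))
    data.table::setnames(tab, "N", "n")
    tab$pct <- 100 * tab$n / n_reports
    tab[order(-n)]
  }
  sex <- pct_tab(cs$sex)
  age <- pct_tab(factor(cs$age_bin, levels = c("<18", "18-65", ">65",
                                               "unknown")))
  wbin <- data.table::fcase(is.na(cs$weight_kg), "missing",
                            cs$weight_kg < 50, "<50",
                            cs$weight_kg <= 100, "50-100",
                            default = ">100")
  weight <- pct_tab(wbin)
  country <- pct_tab(cs$country)
  if (nrow(country) > top_k + 1L) {
    top <- country[category != "missing"][seq_len(top_k)]
    rest <- country[!category %in% c(top$category)]
    other <- rest[category != "missing",
                  .(category = "other", n = sum(n), pct = sum(pct))]
    miss <- rest[category == "missing"]
    country <- data.table::rbindlist(list(top, other, miss))
  }
  occupation <- pct_tab(cs$occp_cod)
  oc <- unlist(strsplit(cs$outcomes[nzchar(cs$outcomes)], ",", fixed = TRUE))
  codes <- c("DE", "LT", "HO", "DS", "CA", "OT")
  outcomes <- data.table::data.table(
    category = codes,
    n = as.integer(table(factor(oc, levels = codes))))
  outcomes$pct <- 100 * outcomes$n / n_reports
  yr <- parse_faers_date(cs$fda_dt)$year
  annual <- data.table::as.data.table(table(year = yr))
  data.table::setnames(annual, "N", "n")
  annual[, year := as.integer(year)]
  list(sex = sex, age = age, weight = weight, country = country,
       occupation = occupation, outcomes = outcomes, annual = annual[order(year)])
}
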