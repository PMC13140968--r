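#' FDA-recommended deduplication of FAERS reports
#'
#' FAERS carries multiple versions of the same safety report. Following the
#' FDA-recommended rule, rows are grouped by `CASEID`; within a case the
#' entry with the latest `FDA_DT` is retained, and ties on `FDA_DT` are
#' broken by keeping the highest `PRIMARYID`. Rows whose `caseid` is missing
#' or blank cannot be grouped and are retained unconditionally (and tallied).
#'
#' @param rows data.frame/data.table with columns `primaryid`, `caseid`,
#'   `fda_dt` (raw FAERS strings are fine).
#' @return character vector of retained `primaryid`s, with attributes
#'   `n_input`, `n_removed`, `n_unparseable_caseid`.
#' @examples
#' deduplicate(data.frame(primaryid = c("1", "2"), caseid = c("A", "A"),
#'                        fda_dt = c("20230101", "20230301")))
#' @export
deduplicate <- function(rows) {
  dt <- data.table::as.data.table(rows)[, .(primaryid, caseid, fda_dt)]
  dt[, primaryid := as.character(primaryid)]
  dt[, caseid := as.character(caseid)]
  bad_case <- is.na(dt$caseid) | !nzchar(trimws(dt$caseid))
  keep_always <- dt$primaryid[bad_case]
  dd <- dt[!bad_case]
  if (nrow(dd)) {
    dd[, stamp := suppressWarnings(as.numeric(fda_dt))]
    dd[is.na(stamp), stamp := -Inf]
    pid_num <- suppressWarnings(as.numeric(dd$primaryid))
    # numeric primaryid comparison where possible, lexical fallback
    dd[, pid_ord := if (anyNA(pid_num)) frank(primaryid, ties.method = "dense")
                    else pid_num]
    data.table::setorder(dd, caseid, stamp, pid_ord)
    retained <- dd[, .(primaryid = primaryid[.N]), by = caseid]$primaryid
  } else retained <- character(0)
  out <- unique(c(retained, keep_always))
  attr(out, "n_input") <- nrow(dt)
  attr(out, "n_removed") <- nrow(dt) - length(out)
  attr(out, "n_unparseable_caseid") <- sum(bad_case)
  out
}

#' Load a drug synonym dictionary
#'
#' The dictionary maps upper-case synonyms (brand names, generic names) to a
#' lower-case canonical ingredient. The packaged default covers the five
#' immune checkpoint inhibitors (durvalumab, pembrolizumab, ipilimumab,
#' atezolizumab, nivolumab), the three platinum agents (cisplatin,
#' carboplatin, oxaliplatin) and their common brand names; users may supply
#' their own two-column CSV (`synonym`, `ingredient`).
#'
#' @param path CSV path; default is the packaged dictionary.
#' @return A `drug_dictionary`: named character vector (names = upper-case
#'   synonyms) with attributes `ici` and `platinum` giving the two target
#'   ingredient sets.
#' @export
load_drug_dictionary <- function(path = system.file("extdata",
                                                    "drug_dictionary.csv",
                                                    package = "faersignal")) {
  dd <- data.table::fread(path, colClasses = "character")
  stopifnot(all(c("synonym", "ingredient") %in% names(dd)))
  map <- setNames(tolower(dd$ingredient), toupper(trimws(dd$synonym)))
  structure(map,
            ici = c("durvalumab", "pembrolizumab", "ipilimumab",
                    "atezolizumab", "nivolumab"),
            platinum = c("cisplatin", "carboplatin", "oxaliplatin"),
            class = "drug_dictionary")
}

#' Normalise a raw FAERS drug name to a canonical ingredient
#'
#' Upper-cases, trims, strips trailing punctuation and trailing dose tokens
#' (`"... 200 MG"` etc.), collapses whitespace, and looks the result up in
#' the dictionary. Unmatched names map to `"other"`.
#'
#' @param raw_name character vector of raw `DRUGNAME` values.
#' @param dict a `drug_dictionary` from [load_drug_dictionary()].
#' @return character vector of lower-case canonical ingredients or `"other"`.
#' @examples
#' dict <- load_drug_dictionary()
#' normalize_drug(c("PEMBROLIZUMAB", "KEYTRUDA.", "ASPIRIN"), dict)
#' @export
normalize_drug <- function(raw_name, dict) {
  x <- toupper(trimws(as.character(raw_name)))
  x <- gsub("\\s+", " ", x)
  # trailing dose tokens: "CISPLATIN 50 MG", "KEYTRUDA 200 MG/ML"
  x <- sub("( [0-9.]+ ?(MG|MCG|G|ML|MG/ML|MCG/ML|%))+$", "", x)
  x <- sub("[[:punct:]]+$", "", x)
  x <- trimws(x)
  out <- unname(dict[x])
  out[is.na(out)] <- "other"
  out
}

#' Assign each report to an exposure cohort
#'
#' Cohorts follow the primary-suspect screening convention: a report is
#' `combination` when at least one immune checkpoint inhibitor and at least
#' one platinum agent are both present at a suspect role (default `PS`
#' only); `ici_mono` when an ICI is a primary suspect and no platinum agent
#' appears in any suspect role (PS/SS); `platinum_mono` symmetrically;
#' otherwise `background`. Drugs listed only as concomitant (C) or
#' interacting (I) never confer exposure.
#'
#' @param drug data.table with columns `primaryid`, `drugname`, `role_cod`.
#' @param dict a `drug_dictionary`.
#' @param suspect_roles roles that define combination co-exposure: `"PS"`
#'   (default, strictest reading) or `"PS+SS"`.
#' @return data.table with columns `primaryid`, `cohort` (one label per
#'   distinct `primaryid` present in `drug`).
#' @export
assign_cohort <- function(drug, dict, suspect_roles = c("PS", "PS+SS")) {
  suspect_roles <- match.arg(suspect_roles)
  comb_roles <- if (suspect_roles == "PS") "PS" else c("PS", "SS")
  d <- data.table::as.data.table(drug)[, .(primaryid, drugname, role_cod)]
  d[, ingredient := normalize_drug(drugname, dict)]
  d[, role_cod := toupper(trimws(role_cod))]
  ici <- attr(dict, "ici")
  plat <- attr(dict, "platinum")
  flags <- d[, .(
    ici_comb  = any(ingredient %in% ici  & role_cod %in% comb_roles),
    plat_comb = any(ingredient %in% plat & role_cod %in% comb_roles),
    ici_ps    = any(ingredient %in% ici  & role_cod == "PS"),
    plat_ps   = any(ingredient %in% plat & role_cod == "PS"),
    ici_ss    = any(ingredient %in% ici  & role_cod %in% c("PS", "SS")),
    plat_ss   = any(ingredient %in% plat & role_cod %in% c("PS", "SS"))
  ), by = primaryid]
  flags[, cohort := data.table::fifelse(
    ici_comb & plat_comb, "combination",
    data.table::fifelse(ici_ps & !plat_ss, "ici_mono",
    data.table::fifelse(plat_ps & !ici_ss, "platinum_mono", "background")))]
  flags[, .(primaryid, cohort)]
}

#' Assemble deduplicated, cohort-labelled report cases
#'
#' Runs deduplication on the bundle's DEMO table, labels each retained
#' report with its exposure cohort, parses demographic fields (age in
#' years, sex, weight), and attaches outcome codes. Reports with no DRUG
#' rows are labelled `background`.
#'
#' @param bundle a `faers_bundle`.
#' @param dict a `drug_dictionary`.
#' @param suspect_roles see [assign_cohort()].
#' @return list with `cases` (report-level data.table: `primaryid`,
#'   `caseid`, `fda_dt`, `event_dt`, `age_years`, `age_bin`, `sex`,
#'   `weight_kg`, `country`, `occp_cod`, `cohort`, `outcomes`), `reac`
#'   (deduplicated reaction pairs `primaryid`, `pt`), `ther` (therapy rows
#'   of retained reports) and `dedup` (the retained-id vector with its
#'   accounting attributes).
#' @export
build_cases <- function(bundle, dict, suspect_roles = "PS") {
  retained <- deduplicate(bundle$demo)
  demo <- bundle$demo[primaryid %chin% retained]
  demo <- unique(demo, by = "primaryid")

  cohorts <- assign_cohort(bundle$drug[primaryid %chin% retained], dict,
                           suspect_roles)
  cases <- merge(demo, cohorts, by = "primaryid", all.x = TRUE)
  cases[is.na(cohort), cohort := "background"]

  cases[, age_years := age_in_years(get0_col(cases, "age"),
                                    get0_col(cases, "age_cod"))]
  cases[, age_bin := age_bin_label(age_years)]
  sx <- toupper(trimws(get0_col(cases, "sex")))
  cases[, sex := data.table::fifelse(sx %in% c("F", "M"), sx, "unknown")]
  cases[, weight_kg := weight_in_kg(get0_col(cases, "wt"),
                                    get0_col(cases, "wt_cod"))]
  cases[, country := up_or_missing(get0_col(cases, "occr_country"))]
  cases[, occp_cod := up_or_missing(get0_col(cases, "occp_cod"))]

  outc <- bundle$outc[primaryid %chin% retained]
  valid_outc <- c("DE", "LT", "HO", "DS", "CA", "OT")
  outc <- outc[toupper(trimws(outc_cod)) %in% valid_outc]
  outc_agg <- outc[, .(outcomes = paste(sort(unique(toupper(trimws(outc_cod)))),
                                        collapse = ",")), by = primaryid]
  cases <- merge(cases, outc_agg, by = "primaryid", all.x = TRUE)
  cases[is.na(outcomes), outcomes := ""]

  reac <- unique(bundle$reac[primaryid %chin% retained, .(primaryid, pt)])
  reac <- reac[nzchar(trimws(pt))]
  ther <- bundle$ther[primaryid %chin% retained]
  list(cases = cases, reac = reac, ther = ther, dedup = retained)
}

# --- demographic field helpers -------------------------------------------

get0_col <- function(dt, col) {
  if (col %in% names(dt)) dt[[col]] else rep(NA_character_, nrow(dt))
}

up_or_missing <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[is.na(x) | !nzchar(x)] <- "missing"
  x
}

#' Convert FAERS age values to years
#'
#' FAERS ages carry a unit code: `DEC` (decades), `YR` (years), `MON`
#' (months), `DY` (days). Unknown codes or unparseable values yield `NA`.
#'
#' @param age character/numeric vector of age values.
#' @param age_cod character vector of unit codes.
#' @return numeric vector of ages in years.
#' @export
age_in_years <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  u <- toupper(trimws(as.character(age_cod)))
  u[is.na(u)] <- ""
  mult <- rep(NA_real_, length(v))
  mult[u == "DEC"] <- 10
  mult[u %in% c("YR", "")] <- 1   # blank unit: FAERS default is years
  mult[u == "MON"] <- 1 / 12
  mult[u == "DY"] <- 1 / 365.25
  out <- v * mult
  out[!is.finite(out) | out < 0 | out > 120] <- NA_real_
  out
}

age_bin_label <- function(age_years) {
  data.table::fcase(
    is.na(age_years), "unknown",
    age_years < 18, "<18",
    age_years <= 65, "18-65",
    default = ">65")
}

weight_in_kg <- function(wt, wt_cod) {
  v <- suppressWarnings(as.numeric(wt))
  u <- toupper(trimws(as.character(wt_cod)))
  u[is.na(u)] <- ""
  mult <- rep(NA_real_, length(v))
  mult[u %in% c("KG", "")] <- 1
  mult[u == "LBS"] <- 0.45359237
  mult[u == "GMS"] <- 0.001
  out <- v * mult
  out[!is.finite(out) | out <= 0 | out > 700] <- NA_real_
  out
}
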