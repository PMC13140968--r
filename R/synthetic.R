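#' Default preferred-term catalogue for the synthetic reporting system
#'
#' A deterministic catalogue of event terms with per-report baseline
#' reporting probabilities: a set of real MedDRA preferred terms from the
#' oncology/immunotherapy safety domain (mapped to their primary System
#' Organ Class) plus `n_extra` synthetic filler terms (`PT_001`, ...)
#' spread over twenty synthetic SOCs with log-spaced baselines. Baselines
#' are fixed, not sampled, so the catalogue is identical across seeds.
#'
#' @param n_extra number of synthetic filler terms (default 240, keeping
#'   the catalogue above 200 terms for null-calibration studies).
#' @return data.table with columns `pt`, `soc`, `base_p`.
#' @export
default_pt_catalog <- function(n_extra = 240L) {
  real <- data.table::data.table(
    pt = c("Febrile neutropenia", "Anaemia", "Neutropenia", "Pyrexia",
           "Pneumonia", "Thrombocytopenia", "Acute kidney injury",
           "Myelosuppression", "Interstitial lung disease", "Hypothyroidism",
           "Colitis", "Myocarditis", "Immune-mediated hepatic disorder",
           "Neuropathy peripheral", "Malignant neoplasm progression"),
    soc = c("Blood and lymphatic system disorders",
            "Blood and lymphatic system disorders",
            "Blood and lymphatic system disorders",
            "General disorders and administration site conditions",
            "Infections and infestations",
            "Blood and lymphatic system disorders",
            "Renal and urinary disorders",
            "Blood and lymphatic system disorders",
            "Respiratory, thoracic and mediastinal disorders",
            "Endocrine disorders",
            "Gastrointestinal disorders",
            "Cardiac disorders",
            "Hepatobiliary disorders",
            "Nervous system disorders",
            "Neoplasms benign, malignant and unspecified"),
    base_p = c(0.004, 0.015, 0.008, 0.02, 0.012, 0.006, 0.009, 0.002,
               0.003, 0.004, 0.005, 0.001, 0.0008, 0.004, 0.02))
  if (n_extra > 0L) {
    extra <- data.table::data.table(
      pt = sprintf("PT_%03d", seq_len(n_extra)),
      soc = sprintf("SOC_%02d", (seq_len(n_extra) - 1L) %% 20L + 1L),
      base_p = exp(seq(log(0.01), log(0.0005), length.out = n_extra)))
    return(data.table::rbindlist(list(real, extra)))
  }
  real
}

#' Configure the synthetic spontaneous-reporting system
#'
#' Defines the full parameterisation of the simulated reporting system:
#' exposure mix, event catalogue with baseline reporting probabilities,
#' injected drug-event reporting-rate ratios, duplicate-version and
#' partial-date fractions, a log-normal onset model, and demographic
#' mixes. Reporting-rate ratios act multiplicatively on the per-report
#' event probability (capped at 0.99) -- a reporting-rate model, which is
#' the quantity disproportionality statistics estimate. Demographic mixes
#' default to the reporting pattern typical of an oncology combination
#' cohort (male-predominant, mostly over 65, reported largely by
#' physicians, median onset 38 days).
#'
#' @param n_reports number of distinct cases to simulate.
#' @param regimen_probs named probabilities for `combination`, `ici_mono`,
#'   `platinum_mono`, `background` (must sum to 1).
#' @param pt_catalog data.table (`pt`, `soc`, `base_p`).
#' @param associations data.frame (`exposure`, `pt`, `rr`) of injected
#'   reporting-rate ratios; `rr = 1` everywhere is the null system.
#' @param duplicate_fraction fraction of cases that also emit an earlier
#'   report version (exercises the latest-FDA_DT dedup branch).
#' @param duplicate_tie_fraction among duplicates, fraction sharing the
#'   original's FDA_DT (exercises the PRIMARYID tie-break).
#' @param partial_date_fraction fraction of reports whose EVENT_DT is
#'   truncated or corrupted.
#' @param pre_treatment_fraction fraction of reports with the event dated
#'   before therapy start.
#' @param onset_meanlog,onset_sdlog log-normal onset-time parameters in
#'   days (defaults give median 38 days, quartiles roughly 13 and 108).
#' @param sex_mix,age_mix,weight_mix,country_mix,occupation_mix,outcome_mix
#'   named categorical mixes (each must sum to 1).
#' @param background_drugs named sampling weights for non-target drugs.
#' @param seed integer RNG seed; a fixed seed makes generated output
#'   byte-identical across runs.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_reports = 10000L,
    regimen_probs = c(combination = 0.05, ici_mono = 0.10,
                      platinum_mono = 0.10, background = 0.75),
    pt_catalog = default_pt_catalog(),
    associations = data.frame(exposure = "combination",
                              pt = "Febrile neutropenia", rr = 8),
    duplicate_fraction = 0.10,
    duplicate_tie_fraction = 0.25,
    partial_date_fraction = 0.10,
    pre_treatment_fraction = 0.02,
    onset_meanlog = log(38),
    onset_sdlog = 1.54,
    sex_mix = c(F = 0.40, M = 0.526, unknown = 0.074),
    age_mix = c("<18" = 0.025, "18-65" = 0.369, ">65" = 0.421,
                unknown = 0.185),
    weight_mix = c("<50" = 0.043, "50-100" = 0.32, ">100" = 0.05,
                   missing = 0.587),
    country_mix = c(JP = 0.327, FR = 0.139, US = 0.124, other = 0.41),
    occupation_mix = c(MD = 0.628, PH = 0.08, CN = 0.08, OT = 0.114,
                       missing = 0.098),
    outcome_mix = c(HO = 0.366, DE = 0.163, LT = 0.05, DS = 0.03,
                    CA = 0.005, OT = 0.15, none = 0.236),
    background_drugs = c(ASPIRIN = 0.3, METFORMIN = 0.25,
                         ATORVASTATIN = 0.25, OMEPRAZOLE = 0.2),
    seed = 1L) {
  cfg <- list(n_reports = as.integer(n_reports),
              regimen_probs = regimen_probs,
              pt_catalog = data.table::as.data.table(pt_catalog),
              associations = as.data.frame(associations),
              duplicate_fraction = duplicate_fraction,
              duplicate_tie_fraction = duplicate_tie_fraction,
              partial_date_fraction = partial_date_fraction,
              pre_treatment_fraction = pre_treatment_fraction,
              onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
              sex_mix = sex_mix, age_mix = age_mix, weight_mix = weight_mix,
              country_mix = country_mix, occupation_mix = occupation_mix,
              outcome_mix = outcome_mix, background_drugs = background_drugs,
              seed = as.integer(seed))
  stopifnot(cfg$n_reports > 0,
            abs(sum(regimen_probs) - 1) < 1e-8,
            all(c("pt", "soc", "base_p") %in% names(cfg$pt_catalog)),
            all(cfg$pt_catalog$base_p >= 0 & cfg$pt_catalog$base_p <= 1),
            nrow(cfg$associations) == 0 || all(cfg$associations$rr >= 0),
            duplicate_fraction >= 0 && duplicate_fraction < 1,
            partial_date_fraction >= 0 && partial_date_fraction < 1,
            pre_treatment_fraction >= 0 && pre_treatment_fraction < 1)
  for (mx in c("sex_mix", "age_mix", "weight_mix", "country_mix",
               "occupation_mix", "outcome_mix"))
    stopifnot(abs(sum(cfg[[mx]]) - 1) < 1e-6)
  class(cfg) <- "synthetic_config"
  cfg
}

# ICI / platinum generic and brand vocabulary used by the generator
.sim_ici <- c("DURVALUMAB", "PEMBROLIZUMAB", "IPILIMUMAB", "ATEZOLIZUMAB",
              "NIVOLUMAB")
.sim_plat <- c("CISPLATIN", "CARBOPLATIN", "OXALIPLATIN")
.sim_brand <- c(DURVALUMAB = "IMFINZI", PEMBROLIZUMAB = "KEYTRUDA",
                IPILIMUMAB = "YERVOY", ATEZOLIZUMAB = "TECENTRIQ",
                NIVOLUMAB = "OPDIVO", CISPLATIN = "PLATINOL",
                CARBOPLATIN = "PARAPLATIN", OXALIPLATIN = "ELOXATIN")

#' Sample the exposure label of each simulated report
#'
#' @param config a `synthetic_config`.
#' @param n number of reports (default `config$n_reports`).
#' @return character vector of cohort labels.
#' @export
sample_exposures <- function(config, n = config$n_reports) {
  sample(names(config$regimen_probs), n, replace = TRUE,
         prob = config$regimen_probs)
}

#' Sample each report's event terms
#'
#' Every catalogue term is sampled independently per report with
#' probability `base_p * RR(exposure, pt)`, capped at 0.99.
#'
#' @param config a `synthetic_config`.
#' @param exposures character vector of cohort labels (one per report).
#' @return data.table (`report`, `pt`) of sampled report-term pairs.
#' @export
sample_events <- function(config, exposures) {
  n <- length(exposures)
  cat_ <- config$pt_catalog
  assoc <- config$associations
  hits <- vector("list", nrow(cat_))
  for (j in seq_len(nrow(cat_))) {
    p <- rep(cat_$base_p[j], n)
    if (nrow(assoc)) {
      aj <- assoc[assoc$pt == cat_$pt[j], , drop = FALSE]
      for (k in seq_len(nrow(aj)))
        p[exposures == aj$exposure[k]] <-
          cat_$base_p[j] * aj$rr[k]
    }
    p <- pmin(p, 0.99)
    idx <- which(runif(n) < p)
    if (length(idx))
      hits[[j]] <- data.table::data.table(report = idx, pt = cat_$pt[j])
  }
  out <- data.table::rbindlist(hits)
  if (nrow(out) == 0L)
    out <- data.table::data.table(report = integer(0), pt = character(0))
  data.table::setorder(out, report, pt)
  out
}

# quarter label ("2020Q1") and FAERS file suffix ("20Q1") for report i,
# one quarter per 25,000 reports
.sim_quarter <- function(i) {
  k <- (i - 1L) %/% 25000L
  sprintf("%dQ%d", 2020L + k %/% 4L, k %% 4L + 1L)
}

.quarter_start <- function(label) {
  y <- as.integer(substr(label, 1, 4))
  q <- as.integer(substr(label, 6, 6))
  as.Date(sprintf("%d-%02d-01", y, (q - 1L) * 3L + 1L))
}

#' Generate a synthetic FAERS reporting system in memory
#'
#' Simulates `n_reports` distinct cases -- exposure, events, demographics,
#' therapy and event dates, outcomes -- plus duplicate earlier report
#' versions, and assembles the five FAERS tables as they would be read
#' back from disk. The ground-truth manifest records every construction
#' count.
#'
#' @param config a `synthetic_config`.
#' @return list with data.tables `demo`, `drug`, `reac`, `ther`, `outc`,
#'   a `quarter` assignment per case, the per-case `truth` table
#'   (`primaryid`, `caseid`, `cohort`) and the `manifest` list.
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_reports
  caseid <- sprintf("%d", 10000000L + seq_len(n))
  primaryid <- paste0(caseid, "2")
  cohort <- sample_exposures(config)
  quarter <- .sim_quarter(seq_len(n))

  # --- demographics ------------------------------------------------------
  sex <- sample(names(config$sex_mix), n, TRUE, config$sex_mix)
  sex_field <- data.table::fifelse(sex == "unknown", "", sex)
  age_bin <- sample(names(config$age_mix), n, TRUE, config$age_mix)
  age_years <- data.table::fcase(
    age_bin == "<18", floor(runif(n, 1, 18)),
    age_bin == "18-65", floor(runif(n, 18, 66)),
    age_bin == ">65", floor(runif(n, 66, 91)),
    default = NA_real_)
  age <- as.character(age_years)
  age_cod <- data.table::fifelse(is.na(age_years), "", "YR")
  # a slice uses decade units where flooring to a decade keeps the bin
  dec_ok <- !is.na(age_years) &
    ((age_years >= 20 & age_years <= 60) | age_years >= 70)
  use_dec <- dec_ok & runif(n) < 0.15
  age[use_dec] <- as.character(floor(age_years[use_dec] / 10))
  age_cod[use_dec] <- "DEC"
  age[is.na(age_years)] <- ""
  wbin <- sample(names(config$weight_mix), n, TRUE, config$weight_mix)
  wt <- data.table::fcase(
    wbin == "<50", round(runif(n, 30, 49.5), 1),
    wbin == "50-100", round(runif(n, 50, 100), 1),
    wbin == ">100", round(runif(n, 100.5, 150), 1),
    default = NA_real_)
  wt_field <- data.table::fifelse(is.na(wt), "", as.character(wt))
  wt_cod <- data.table::fifelse(is.na(wt), "", "KG")
  country <- sample(names(config$country_mix), n, TRUE, config$country_mix)
  country <- data.table::fifelse(country == "other",
                                 sample(c("DE", "IT", "GB", "CN", "BR"), n,
                                        TRUE), country)
  occp <- sample(names(config$occupation_mix), n, TRUE,
                 config$occupation_mix)
  occp <- data.table::fifelse(occp == "missing", "", occp)

  # --- dates -------------------------------------------------------------
  q_start <- .quarter_start(quarter)
  fda_date <- q_start + floor(runif(n, 0, 90))
  start_date <- fda_date - floor(runif(n, 30, 400))
  onset <- round(rlnorm(n, config$onset_meanlog, config$onset_sdlog))
  pre_trt <- runif(n) < config$pre_treatment_fraction
  onset[pre_trt] <- -sample.int(30L, sum(pre_trt), replace = TRUE)
  event_date <- start_date + onset
  fmt <- function(d) format(d, "%Y%m%d")
  event_dt <- fmt(event_date)
  partial <- runif(n) < config$partial_date_fraction
  kind <- sample(c("month", "year", "invalid"), n, TRUE,
                 prob = c(0.5, 0.3, 0.2))
  event_dt[partial & kind == "month"] <-
    substr(event_dt[partial & kind == "month"], 1, 6)
  event_dt[partial & kind == "year"] <-
    substr(event_dt[partial & kind == "year"], 1, 4)
  event_dt[partial & kind == "invalid"] <-
    paste0(substr(event_dt[partial & kind == "invalid"], 1, 4), "1332")
  fda_dt <- fmt(fda_date)
  start_dt <- fmt(start_date)

  demo <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
    event_dt = event_dt, age = age, age_cod = age_cod, sex = sex_field,
    wt = wt_field, wt_cod = wt_cod, occr_country = country,
    occp_cod = occp)

  # --- drugs -------------------------------------------------------------
  pick <- function(v, k) v[sample.int(length(v), k, replace = TRUE)]
  ici_drug <- pick(.sim_ici, n)
  plat_drug <- pick(.sim_plat, n)
  n_conco <- sample(0:2, n, TRUE)
  dress <- function(name) {
    u <- runif(length(name))
    name <- data.table::fifelse(u < 0.3, unname(.sim_brand[name]), name)
    v <- runif(length(name))
    name <- data.table::fifelse(v < 0.05, paste0(name, "."),
             data.table::fifelse(v < 0.10, paste0(name, " 200 MG"), name))
    name
  }
  drug_rows <- list()
  is_comb <- cohort == "combination"
  is_ici <- cohort == "ici_mono"
  is_plat <- cohort == "platinum_mono"
  is_bg <- cohort == "background"
  add <- function(ids, names, role)
    data.table::data.table(primaryid = ids, drugname = names,
                           role_cod = role)
  drug_rows$ici_ps <- add(primaryid[is_comb | is_ici],
                          dress(ici_drug[is_comb | is_ici]), "PS")
  drug_rows$plat_ps <- add(primaryid[is_comb | is_plat],
                           dress(plat_drug[is_comb | is_plat]), "PS")
  drug_rows$bg_ps <- add(primaryid[is_bg],
                         pick(names(config$background_drugs), sum(is_bg)),
                         "PS")
  # a small background slice carries an ICI only as concomitant: must not
  # confer exposure
  ici_c <- is_bg & runif(n) < 0.02
  drug_rows$ici_c <- add(primaryid[ici_c], dress(ici_drug[ici_c]), "C")
  conco_idx <- rep(seq_len(n), n_conco)
  drug_rows$conco <- add(primaryid[conco_idx],
                         pick(names(config$background_drugs),
                              length(conco_idx)), "C")
  drug <- data.table::rbindlist(drug_rows)
  data.table::setorder(drug, primaryid, role_cod, drugname)

  # --- reactions ---------------------------------------------------------
  ev <- sample_events(config, cohort)
  reac <- data.table::data.table(primaryid = primaryid[ev$report],
                                 pt = ev$pt)

  # --- therapy and outcomes ---------------------------------------------
  ther <- data.table::data.table(primaryid = primaryid,
                                 dsg_drug_seq = "1", start_dt = start_dt)
  outc_code <- sample(names(config$outcome_mix), n, TRUE,
                      config$outcome_mix)
  has_outc <- outc_code != "none"
  outc <- data.table::data.table(primaryid = primaryid[has_outc],
                                 outc_cod = outc_code[has_outc])

  # --- duplicate earlier versions ----------------------------------------
  n_dup <- floor(config$duplicate_fraction * n)
  if (n_dup > 0) {
    dup_idx <- sample.int(n, n_dup)
    tie <- runif(n_dup) < config$duplicate_tie_fraction
    dup_fda <- fda_date[dup_idx] - sample(30:200, n_dup, TRUE)
    dup_fda[tie] <- fda_date[dup_idx][tie]   # same FDA_DT: tie-break branch
    dup_demo <- data.table::copy(demo[dup_idx])
    dup_pid <- paste0(caseid[dup_idx], "1")
    data.table::set(dup_demo, j = "primaryid", value = dup_pid)
    data.table::set(dup_demo, j = "fda_dt", value = fmt(dup_fda))
    dup_map <- setNames(dup_pid, primaryid[dup_idx])
    child_dup <- function(tb) {
      sel <- tb[primaryid %chin% names(dup_map)]
      if (nrow(sel)) sel[, primaryid := unname(dup_map[primaryid])]
      sel
    }
    drug <- data.table::rbindlist(list(drug, child_dup(drug)))
    reac <- data.table::rbindlist(list(reac, child_dup(reac)))
    ther <- data.table::rbindlist(list(ther, child_dup(ther)))
    outc <- data.table::rbindlist(list(outc, child_dup(outc)))
    dup_quarter <- quarter[dup_idx]
    demo <- data.table::rbindlist(list(demo, dup_demo))
    quarter <- c(quarter, dup_quarter)
  }

  truth <- data.table::data.table(primaryid = primaryid, caseid = caseid,
                                  cohort = cohort)
  assoc_counts <- NULL
  if (nrow(config$associations)) {
    assoc_counts <- config$associations
    assoc_counts$a_true <- vapply(seq_len(nrow(assoc_counts)), function(k) {
      ids <- primaryid[cohort == assoc_counts$exposure[k]]
      length(intersect(ids, reac$primaryid[reac$pt == assoc_counts$pt[k]]))
    }, numeric(1))
  }
  manifest <- list(
    seed = config$seed,
    n_reports = n,
    n_duplicates = n_dup,
    n_demo_rows = nrow(demo),
    n_drug_rows = nrow(drug),
    n_reac_rows = nrow(reac),
    n_ther_rows = nrow(ther),
    n_outc_rows = nrow(outc),
    n_dedup_expected = n,
    cohort_counts = as.list(table(cohort)),
    associations = assoc_counts,
    sex_mix = as.list(config$sex_mix),
    age_mix = as.list(config$age_mix),
    onset_meanlog = config$onset_meanlog,
    onset_sdlog = config$onset_sdlog)

  list(demo = demo, drug = drug, reac = reac, ther = ther, outc = outc,
       quarter = quarter, truth = truth, manifest = manifest)
}

#' Write a synthetic reporting system as FAERS quarterly files
#'
#' Splits the generated tables into one sub-directory per quarter (25,000
#' cases per quarter), writes the five "$"-delimited ASCII files per
#' quarter, the ground-truth manifest (`ground_truth.json`), and the
#' catalogue's PT-to-SOC map (`pt_soc_map.csv`).
#'
#' @param config a `synthetic_config`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the manifest list (with `quarter_dirs` added).
#' @export
generate_faers <- function(config, out_dir) {
  sim <- generate_reports(config)
  ok <- tryCatch({dir.create(out_dir, showWarnings = FALSE,
                             recursive = TRUE); TRUE},
                 error = function(e) FALSE)
  if (!ok || !dir.exists(out_dir))
    stop("output directory not writable: ", out_dir, call. = FALSE)
  quarters <- sort(unique(sim$quarter))
  dirs <- character(0)
  for (qt in quarters) {
    qdir <- file.path(out_dir, qt)
    dir.create(qdir, showWarnings = FALSE)
    suffix <- paste0(substr(qt, 3, 4), substr(qt, 5, 6))
    ids <- sim$demo$primaryid[sim$quarter == qt]
    for (tab in c("demo", "drug", "reac", "ther", "outc")) {
      rows <- sim[[tab]][primaryid %chin% ids]
      data.table::fwrite(rows,
                         file.path(qdir, paste0(toupper(tab), suffix, ".txt")),
                         sep = "$", quote = FALSE)
    }
    dirs <- c(dirs, qdir)
  }
  manifest <- sim$manifest
  manifest$quarter_dirs <- basename(dirs)
  jsonlite::write_json(manifest, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  data.table::fwrite(config$pt_catalog[, .(pt, soc)],
                     file.path(out_dir, "pt_soc_map.csv"))
  invisible(manifest)
}

#' Verify generated FAERS files against their ground-truth manifest
#'
#' Re-reads the quarter files with the package's FAERS reader and checks
#' every manifest count: per-table row counts, the number of cases
#' surviving deduplication, and per-association report counts.
#'
#' @param out_dir directory written by [generate_faers()].
#' @return list with `pass` (logical) and `diffs` (character vector naming
#'   each mismatching field, empty on pass).
#' @export
manifest_check <- function(out_dir) {
  mf <- jsonlite::read_json(file.path(out_dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  bundle <- read_faers_quarters(file.path(out_dir, mf$quarter_dirs))
  diffs <- character(0)
  chk <- function(field, got) {
    want <- mf[[field]]
    if (!isTRUE(all.equal(as.numeric(want), as.numeric(got))))
      diffs <<- c(diffs, sprintf("%s: manifest %s, files %s", field,
                                 want, got))
  }
  chk("n_demo_rows", nrow(bundle$demo))
  chk("n_drug_rows", nrow(bundle$drug))
  chk("n_reac_rows", nrow(bundle$reac))
  chk("n_ther_rows", nrow(bundle$ther))
  chk("n_outc_rows", nrow(bundle$outc))
  retained <- deduplicate(bundle$demo)
  chk("n_dedup_expected", length(retained))
  if (!is.null(mf$associations) && length(mf$associations)) {
    assoc <- as.data.frame(mf$associations)
    dict <- load_drug_dictionary()
    cohorts <- assign_cohort(bundle$drug[primaryid %chin% retained], dict)
    reac <- unique(bundle$reac[primaryid %chin% retained, .(primaryid, pt)])
    for (k in seq_len(nrow(assoc))) {
      ids <- cohorts$primaryid[cohorts$cohort == assoc$exposure[k]]
      got <- length(intersect(ids, reac$primaryid[reac$pt == assoc$pt[k]]))
      if (got != assoc$a_true[k])
        diffs <- c(diffs, sprintf("association %s/%s: manifest %d, files %d",
                                  assoc$exposure[k], assoc$pt[k],
                                  assoc$a_true[k], got))
    }
  }
  list(pass = length(diffs) == 0L, diffs = diffs)
}
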