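#' Load a PT-to-SOC map
#'
#' MedDRA is licensed, so the package ships a small stub map from preferred
#' terms to their primary System Organ Class covering the oncology /
#' immunotherapy safety vocabulary used here; any user-supplied two-column
#' CSV (`pt`, `soc`) is accepted in its place. Terms absent from the map
#' are reported under `"unmapped"`.
#'
#' @param path CSV path; default is the packaged stub map.
#' @return named character vector: names are PTs, values SOCs.
#' @export
load_meddra_map <- function(path = system.file("extdata",
                                               "stub_meddra_map.csv",
                                               package = "faersignal")) {
  mm <- data.table::fread(path, colClasses = "character")
  stopifnot(all(c("pt", "soc") %in% names(mm)))
  setNames(mm$soc, mm$pt)
}

#' Map preferred terms to System Organ Classes
#'
#' @param pt character vector of preferred terms.
#' @param map named vector from [load_meddra_map()].
#' @return character vector of SOCs, `"unmapped"` where unknown.
#' @export
map_pt_to_soc <- function(pt, map) {
  out <- unname(map[pt])
  out[is.na(out)] <- "unmapped"
  out
}

#' Assemble a pipeline run configuration
#'
#' @param input_dirs character vector of FAERS quarter directories.
#' @param output_dir directory for all result files.
#' @param dict_path drug dictionary CSV (default: packaged).
#' @param meddra_map_path PT-to-SOC CSV (default: packaged stub).
#' @param suspect_roles `"PS"` or `"PS+SS"` (combination co-exposure rule).
#' @param continuity +0.5 correction for zero-cell ROR tables.
#' @param yates Yates-corrected chi-square.
#' @param ic_variant `"shrinkage"` or `"bayes"`.
#' @param quartile_type 7 (default) or 6.
#' @param target_cohort cohort whose signals are tabulated.
#' @param seed integer seed recorded in provenance (the analysis itself is
#'   deterministic).
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dirs, output_dir,
                       dict_path = NULL, meddra_map_path = NULL,
                       suspect_roles = "PS", continuity = FALSE,
                       yates = FALSE, ic_variant = "shrinkage",
                       quartile_type = 7, target_cohort = "combination",
                       seed = 1L, log_level = "info") {
  stopifnot(length(input_dirs) >= 1, suspect_roles %in% c("PS", "PS+SS"),
            ic_variant %in% c("shrinkage", "bayes"),
            quartile_type %in% c(6, 7))
  missing_dirs <- input_dirs[!dir.exists(input_dirs)]
  if (length(missing_dirs))
    stop("input directory does not exist: ",
         paste(missing_dirs, collapse = ", "), call. = FALSE)
  structure(list(input_dirs = input_dirs, output_dir = output_dir,
                 dict_path = dict_path, meddra_map_path = meddra_map_path,
                 suspect_roles = suspect_roles, continuity = continuity,
                 yates = yates, ic_variant = ic_variant,
                 quartile_type = quartile_type,
                 target_cohort = target_cohort, seed = as.integer(seed),
                 log_level = log_level),
            class = "run_config")
}

#' Run the full pharmacovigilance pipeline
#'
#' Ingest, deduplicate, assign cohorts, compute PT- and SOC-level
#' disproportionality tables for the target cohort against all other
#' deduplicated reports, time-to-onset and subgroup summaries,
#' cohort-versus-monotherapy comparisons, demographics, and the screening
#' funnel. All outputs are written as CSV plus a provenance JSON recording
#' the variant flags and dictionary hashes; results are deterministic given
#' inputs and flags.
#'
#' @param cfg a `run_config`.
#' @param stages subset of
#'   `c("signals", "tto", "subgroups", "comparisons", "demographics")`.
#' @param signal_levels which signal tables to produce (`"PT"`, `"SOC"`).
#' @return Invisibly, a list with every computed table, the funnel, and the
#'   output file paths.
#' @export
run_full <- function(cfg, stages = c("signals", "tto", "subgroups",
                                     "comparisons", "demographics"),
                     signal_levels = c("PT", "SOC")) {
  stopifnot(inherits(cfg, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (identical(cfg$log_level, "info")) message(msg)
  }
  funnel <- data.table::data.table(stage = character(0), rows_in = integer(0),
                                   rows_out = integer(0),
                                   rows_excluded = integer(0),
                                   detail = character(0))
  add_stage <- function(stage, rows_in, rows_out, detail = "") {
    funnel <<- rbind(funnel, data.table::data.table(
      stage = stage, rows_in = as.integer(rows_in),
      rows_out = as.integer(rows_out),
      rows_excluded = as.integer(rows_in - rows_out), detail = detail))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      data.table::fwrite(funnel, file.path(cfg$output_dir, "funnel.csv"))
      writeLines(log_lines, file.path(cfg$output_dir, "run.log"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- ingest ------------------------------------------------------------
  bundle <- run_stage("ingest", read_faers_quarters(cfg$input_dirs))
  n_orphan <- sum(vapply(bundle$orphans, nrow, 0L))
  say("ingest: %d DEMO rows, %d malformed lines, %d orphan child rows",
      nrow(bundle$demo), sum(bundle$malformed), n_orphan)
  add_stage("ingest_demo", nrow(bundle$demo) + bundle$malformed[["DEMO"]],
            nrow(bundle$demo), "malformed lines rejected")
  add_stage("orphan_quarantine",
            nrow(bundle$drug) + nrow(bundle$reac) + nrow(bundle$ther) +
              nrow(bundle$outc) + n_orphan,
            nrow(bundle$drug) + nrow(bundle$reac) + nrow(bundle$ther) +
              nrow(bundle$outc),
            "child rows without a DEMO parent")

  dict <- load_drug_dictionary(cfg$dict_path %||%
                                 system.file("extdata", "drug_dictionary.csv",
                                             package = "faersignal"))
  meddra <- load_meddra_map(cfg$meddra_map_path %||%
                              system.file("extdata", "stub_meddra_map.csv",
                                          package = "faersignal"))

  # --- dedup + cohorts ----------------------------------------------------
  built <- run_stage("dedup_cohorts",
                     build_cases(bundle, dict, cfg$suspect_roles))
  cases <- built$cases
  add_stage("deduplicate", attr(built$dedup, "n_input"),
            length(built$dedup), "earlier report versions removed")
  say("dedup: %d -> %d reports; cohorts: %s",
      attr(built$dedup, "n_input"), nrow(cases),
      paste(names(table(cases$cohort)), table(cases$cohort),
            collapse = ", ", sep = "="))

  target_ids <- cases$primaryid[cases$cohort == cfg$target_cohort]
  bg_ids <- cases$primaryid[cases$cohort != cfg$target_cohort]
  reac <- built$reac
  results <- list(cases = cases, funnel = NULL)
  outputs <- character(0)
  wr <- function(x, name) {
    p <- file.path(cfg$output_dir, name)
    data.table::fwrite(x, p)
    outputs <<- c(outputs, p)
  }

  # --- signals ------------------------------------------------------------
  if ("signals" %in% stages) {
    if ("PT" %in% signal_levels) {
      co_pairs <- reac[primaryid %chin% target_ids,
                       .(primaryid, term = pt)]
      bg_pairs <- reac[primaryid %chin% bg_ids, .(primaryid, term = pt)]
      pt_tab <- run_stage("signals_pt",
                          signal_table(co_pairs, bg_pairs, level = "PT",
                                       continuity = cfg$continuity,
                                       yates = cfg$yates,
                                       ic_variant = cfg$ic_variant))
      say("signals: %d PTs, %d significant", nrow(pt_tab),
          sum(pt_tab$significant))
      results$pt_signals <- pt_tab
      wr(pt_tab, "pt_signals.csv")
    }
    if ("SOC" %in% signal_levels) {
      soc_co <- reac[primaryid %chin% target_ids,
                     .(primaryid, term = map_pt_to_soc(pt, meddra))]
      soc_bg <- reac[primaryid %chin% bg_ids,
                     .(primaryid, term = map_pt_to_soc(pt, meddra))]
      soc_tab <- run_stage("signals_soc",
                           signal_table(soc_co, soc_bg, level = "SOC",
                                        continuity = cfg$continuity,
                                        yates = cfg$yates,
                                        ic_variant = cfg$ic_variant,
                                        mgps_min_cells = 10L))
      say("signals: %d SOCs, %d significant", nrow(soc_tab),
          sum(soc_tab$significant))
      results$soc_signals <- soc_tab
      wr(soc_tab, "soc_signals.csv")
    }
  }

  # --- time to onset -------------------------------------------------------
  if ("tto" %in% stages) {
    tto <- run_stage("tto", cohort_tto(cases[cohort == cfg$target_cohort],
                                       built$ther))
    ex <- attr(tto, "exclusions")
    add_stage("tto_valid_dates", ex[["n_input"]], ex[["n_valid"]],
              sprintf("pre_treatment=%d, incomplete=%d",
                      ex[["n_pre_treatment"]], ex[["n_incomplete"]]))
    summ <- run_stage("tto", tto_summary(tto$onset_days[tto$status == "valid"],
                                         quartile_type = cfg$quartile_type))
    say("tto: n=%d, median %.0f days (IQR %.0f-%.0f), %.1f%% in month 1",
        summ$n, summ$median_days, summ$q1_days, summ$q3_days,
        100 * summ$month1_fraction)
    results$tto <- summ
    tto_dt <- data.table::data.table(
      statistic = c("n", "median_days", "q1_days", "q3_days",
                    paste0("bin_", names(summ$bin_counts))),
      value = c(summ$n, summ$median_days, summ$q1_days, summ$q3_days,
                unname(summ$bin_counts)))
    wr(tto_dt, "tto_summary.csv")
  }

  # --- subgroups -----------------------------------------------------------
  if ("subgroups" %in% stages) {
    tcases <- cases[cohort == cfg$target_cohort]
    treac <- reac[primaryid %chin% target_ids]
    for (axis in c("sex", "age")) {
      st <- run_stage("subgroups", stratify(tcases, treac, axis))
      flat <- data.table::rbindlist(
        lapply(names(st), function(s) cbind(stratum = s, st[[s]])))
      results[[paste0("subgroup_", axis)]] <- st
      wr(flat, sprintf("subgroup_%s.csv", axis))
    }
  }

  # --- cohort comparisons --------------------------------------------------
  if ("comparisons" %in% stages) {
    pt_counts <- function(ids)
      reac[primaryid %chin% ids, .(n = .N), by = .(term = pt)]
    for (other in c("ici_mono", "platinum_mono")) {
      cmp <- run_stage("comparisons", compare_cohorts(
        pt_counts(cases$primaryid[cases$cohort == other]),
        pt_counts(target_ids),
        labels = c(other, cfg$target_cohort)))
      results[[paste0("compare_", other)]] <- cmp
      wr(cmp, sprintf("cohort_comparison_%s.csv", other))
    }
  }

  # --- demographics --------------------------------------------------------
  if ("demographics" %in% stages) {
    dem <- run_stage("demographics",
                     demographics_summary(cases[cohort == cfg$target_cohort]))
    results$demographics <- dem
    flat <- data.table::rbindlist(
      lapply(c("sex", "age", "weight", "country", "occupation", "outcomes"),
             function(k) cbind(block = k, dem[[k]])), fill = TRUE)
    wr(flat, "demographics.csv")
    wr(dem$annual, "annual_counts.csv")
  }

  # --- funnel, log, provenance --------------------------------------------
  results$funnel <- funnel
  wr(funnel, "funnel.csv")
  writeLines(log_lines, file.path(cfg$output_dir, "run.log"))
  dict_file <- cfg$dict_path %||%
    system.file("extdata", "drug_dictionary.csv", package = "faersignal")
  map_file <- cfg$meddra_map_path %||%
    system.file("extdata", "stub_meddra_map.csv", package = "faersignal")
  provenance <- list(
    package_version = as.character(utils::packageVersion("faersignal")),
    input_dirs = cfg$input_dirs,
    suspect_roles = cfg$suspect_roles,
    continuity = cfg$continuity, yates = cfg$yates,
    ic_variant = cfg$ic_variant, quartile_type = cfg$quartile_type,
    target_cohort = cfg$target_cohort, seed = cfg$seed,
    drug_dictionary_md5 = unname(tools::md5sum(dict_file)),
    meddra_map_md5 = unname(tools::md5sum(map_file)))
  jsonlite::write_json(provenance,
                       file.path(cfg$output_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  results$outputs <- c(outputs, file.path(cfg$output_dir, "run.log"),
                       file.path(cfg$output_dir, "provenance.json"))
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- command-line interface -----------------------------------------------

.cli_usage <- paste(
  "usage: faersignal <command> [options]",
  "",
  "commands:",
  "  generate   write a synthetic FAERS fixture",
  "             --out DIR [--seed INT] [--n-reports INT] [--config YAML]",
  "  run        full pipeline",
  "             --input DIR[,DIR...] --out DIR [--config YAML]",
  "             [--map CSV] [--dict CSV] [--suspect-roles PS|PS+SS]",
  "  signals    disproportionality tables only (flags as for run,",
  "             plus [--level PT|SOC])",
  "  tto        time-to-onset summary only (flags as for run)",
  "  subgroups  subgroup tables only (flags as for run)",
  sep = "\n")

# parse "--flag value" pairs; returns list or NULL on malformed input
.parse_flags <- function(argv, allowed) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    f <- argv[i]
    if (!startsWith(f, "--") || i == length(argv)) return(NULL)
    key <- substring(f, 3)
    if (!(key %in% allowed)) return(NULL)
    out[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `generate`, `run`, `signals`, `tto`, `subgroups`. Options
#' may come from a YAML `--config` file (keys matching [run_config()] /
#' [synthetic_config()] arguments), with command-line flags taking
#' precedence. Returns the process exit code: 0 on success, 2 on usage or
#' configuration errors.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code.
#' @export
cli_main <- function(argv) {
  fail <- function(...) { message(...); message(.cli_usage); 2L }
  if (length(argv) == 0L) return(fail("no command given"))
  cmd <- argv[1L]
  rest <- argv[-1L]
  allowed <- c("config", "out", "seed", "n-reports", "input", "map", "dict",
               "suspect-roles", "level")
  flags <- .parse_flags(rest, allowed)
  if (is.null(flags)) return(fail("malformed or unknown option"))
  cfg_file <- list()
  if (!is.null(flags$config)) {
    if (!file.exists(flags$config))
      return(fail("config file not found: ", flags$config))
    cfg_file <- yaml::read_yaml(flags$config)
  }
  get_opt <- function(flag, key = flag, default = NULL)
    flags[[flag]] %||% cfg_file[[key]] %||% default

  if (cmd == "generate") {
    out <- get_opt("out", "output_dir")
    if (is.null(out)) return(fail("generate requires --out"))
    args <- cfg_file[intersect(names(cfg_file),
                               names(formals(synthetic_config)))]
    if (!is.null(get_opt("seed"))) args$seed <- as.integer(get_opt("seed"))
    if (!is.null(get_opt("n-reports", "n_reports")))
      args$n_reports <- as.integer(get_opt("n-reports", "n_reports"))
    cfg <- tryCatch(do.call(synthetic_config, args),
                    error = function(e) NULL)
    if (is.null(cfg)) return(fail("invalid generator configuration"))
    generate_faers(cfg, out)
    return(0L)
  }

  if (!(cmd %in% c("run", "signals", "tto", "subgroups")))
    return(fail("unknown command: ", cmd))

  input <- get_opt("input", "input_dirs")
  out <- get_opt("out", "output_dir")
  if (is.null(input) || is.null(out))
    return(fail(cmd, " requires --input and --out"))
  input <- unlist(strsplit(input, ",", fixed = TRUE))
  cfg <- tryCatch(run_config(
    input_dirs = input, output_dir = out,
    dict_path = get_opt("dict", "dict_path"),
    meddra_map_path = get_opt("map", "meddra_map_path"),
    suspect_roles = get_opt("suspect-roles", "suspect_roles", "PS"),
    seed = as.integer(get_opt("seed", default = 1L))),
    error = function(e) { message(conditionMessage(e)); NULL })
  if (is.null(cfg)) return(2L)
  stages <- switch(cmd,
                   run = c("signals", "tto", "subgroups", "comparisons",
                           "demographics"),
                   signals = "signals", tto = "tto", subgroups = "subgroups")
  levels <- toupper(get_opt("level", default = "PT,SOC"))
  levels <- unlist(strsplit(levels, ",", fixed = TRUE))
  if (!all(levels %in% c("PT", "SOC")))
    return(fail("--level must be PT, SOC or PT,SOC"))
  res <- tryCatch({ run_full(cfg, stages = stages, signal_levels = levels);
                    0L },
                  error = function(e) { message(conditionMessage(e)); 1L })
  res
}
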