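#' @section FAERS quarterly ASCII layout:
#' FAERS quarters ship as "$"-delimited text files with one header line and
#' no quoting convention; an embedded "$" inside a field therefore shifts the
#' field count and the line is counted malformed rather than guessed at.
#' Only the post-2012Q4 layout is supported.
#' @name faers_io
NULL

.faers_tables <- c("DEMO", "DRUG", "REAC", "THER", "OUTC")

.faers_required_cols <- list(
  DEMO = c("primaryid", "caseid", "fda_dt"),
  DRUG = c("primaryid", "drugname", "role_cod"),
  REAC = c("primaryid", "pt"),
  THER = c("primaryid", "start_dt"),
  OUTC = c("primaryid", "outc_cod")
)

# Read one "$"-delimited FAERS table. Returns list(data, n_malformed).
read_faers_table <- function(path, required_cols) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  # FAERS files contain stray non-UTF-8 bytes; replace rather than fail
  lines <- iconv(lines, "UTF-8", "UTF-8", sub = "�")
  if (length(lines) == 0L || !nzchar(lines[1L]))
    stop("unreadable header in ", path, call. = FALSE)
  header <- tolower(trimws(strsplit(lines[1L], "$", fixed = TRUE)[[1L]]))
  missing_cols <- setdiff(required_cols, header)
  if (length(missing_cols))
    stop("file ", basename(path), " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    dt <- data.table::as.data.table(
      setNames(rep(list(character(0)), length(header)), header))
    return(list(data = dt, n_malformed = 0L))
  }
  parts <- strsplit(body, "$", fixed = TRUE)
  nf <- lengths(parts)
  # a trailing empty field is dropped by strsplit; pad those lines
  short1 <- nf == length(header) - 1L & endsWith(body, "$")
  parts[short1] <- lapply(parts[short1], function(p) c(p, ""))
  nf[short1] <- length(header)
  good <- nf == length(header)
  mat <- do.call(rbind, parts[good])
  dt <- data.table::as.data.table(mat)
  data.table::setnames(dt, header)
  list(data = dt, n_malformed = sum(!good))
}

#' Read one FAERS quarter directory
#'
#' Locates the five in-scope tables (`DEMO*`, `DRUG*`, `REAC*`, `THER*`,
#' `OUTC*`; `.txt`, case-insensitive) under `path`, parses each as
#' "$"-delimited text, counts malformed lines (wrong field count), and
#' quarantines orphan child rows whose `primaryid` has no DEMO row. Orphans
#' are retained in the bundle for inspection but excluded from analysis.
#'
#' @param path directory containing the quarter's ASCII files.
#' @param quarter_label optional label such as `"2024Q1"`; inferred from the
#'   DEMO file name when possible.
#' @return A `faers_bundle`: list with data.tables `demo`, `drug`, `reac`,
#'   `ther`, `outc` (lower-case FAERS column names), `quarter_label`,
#'   `malformed` (named integer vector of rejected line counts) and
#'   `orphans` (named list of quarantined child rows).
#' @export
read_faers_quarter <- function(path, quarter_label = NULL) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  files <- list.files(path, full.names = TRUE)
  bundle <- list()
  malformed <- integer(0)
  for (tab in .faers_tables) {
    hit <- files[grepl(paste0("^", tab, ".*\\.txt$"), basename(files),
                       ignore.case = TRUE)]
    if (length(hit) == 0L)
      stop("missing mandatory FAERS file for table ", tab, " in ", path,
           call. = FALSE)
    parsed <- read_faers_table(hit[1L], .faers_required_cols[[tab]])
    bundle[[tolower(tab)]] <- parsed$data
    malformed[tab] <- parsed$n_malformed
  }
  if (is.null(quarter_label)) {
    demo_name <- basename(files[grepl("^DEMO", basename(files),
                                      ignore.case = TRUE)][1L])
    m <- regmatches(demo_name, regexpr("[0-9]{2}[Qq][1-4]", demo_name))
    quarter_label <- if (length(m)) paste0("20", toupper(m)) else "unknown"
  }
  known <- unique(bundle$demo$primaryid)
  orphans <- list()
  for (tab in c("drug", "reac", "ther", "outc")) {
    is_orphan <- !(bundle[[tab]]$primaryid %chin% known)
    orphans[[tab]] <- bundle[[tab]][is_orphan]
    bundle[[tab]] <- bundle[[tab]][!is_orphan]
  }
  structure(list(demo = bundle$demo, drug = bundle$drug, reac = bundle$reac,
                 ther = bundle$ther, outc = bundle$outc,
                 quarter_label = quarter_label, malformed = malformed,
                 orphans = orphans),
            class = "faers_bundle")
}

#' Read and concatenate several FAERS quarters
#'
#' @param paths character vector of quarter directories.
#' @return A single `faers_bundle` with row-bound tables; `quarter_label`
#'   collects the per-quarter labels, malformed and orphan counts are summed.
#' @export
read_faers_quarters <- function(paths) {
  bundles <- lapply(paths, read_faers_quarter)
  if (length(bundles) == 1L) return(bundles[[1L]])
  out <- list()
  for (tab in tolower(.faers_tables))
    out[[tab]] <- data.table::rbindlist(lapply(bundles, `[[`, tab),
                                        fill = TRUE)
  malformed <- Reduce(`+`, lapply(bundles, `[[`, "malformed"))
  orphans <- list()
  for (tab in c("drug", "reac", "ther", "outc"))
    orphans[[tab]] <- data.table::rbindlist(
      lapply(bundles, function(b) b$orphans[[tab]]), fill = TRUE)
  structure(list(demo = out$demo, drug = out$drug, reac = out$reac,
                 ther = out$ther, outc = out$outc,
                 quarter_label = vapply(bundles, `[[`, "", "quarter_label"),
                 malformed = malformed, orphans = orphans),
            class = "faers_bundle")
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat("FAERS bundle [", paste(x$quarter_label, collapse = ", "), "]\n",
      sep = "")
  for (tab in tolower(.faers_tables))
    cat(sprintf("  %-5s %8d rows\n", toupper(tab), nrow(x[[tab]])))
  if (any(x$malformed > 0))
    cat("  malformed lines:",
        paste(names(x$malformed), x$malformed, collapse = ", "), "\n")
  n_orph <- sum(vapply(x$orphans, nrow, 0L))
  if (n_orph > 0) cat("  quarantined orphan child rows:", n_orph, "\n")
  invisible(x)
}

#' Export a bundle's tables as normalised CSV
#'
#' @param bundle a `faers_bundle`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
export_bundle_csv <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tab in tolower(.faers_tables)) {
    p <- file.path(dir, paste0(tab, ".csv"))
    data.table::fwrite(bundle[[tab]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
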