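#' Parse FAERS date fields
#'
#' FAERS date columns (`FDA_DT`, `EVENT_DT`, `START_DT`, ...) hold digit
#' strings of varying completeness: `YYYYMMDD` (day precision), `YYYYMM`
#' (month precision) or `YYYY` (year precision). Anything else -- empty
#' fields, non-digits, impossible calendar dates such as `"20230230"`,
#' or years outside 1900--2100 -- is classified `invalid`. The function is
#' total: it never throws, and every input receives exactly one precision.
#'
#' @param raw character vector of raw date fields (coerced with
#'   `as.character`); `NA` is treated as empty.
#' @return A `data.frame` with one row per input and columns `raw`,
#'   `precision` (one of `"day"`, `"month"`, `"year"`, `"invalid"`),
#'   `year`, `month`, `day` (integer, `NA` where not determined).
#' @examples
#' parse_faers_date(c("20240215", "202402", "2024", "20230230", ""))
#' @export
parse_faers_date <- function(raw) {
  x <- trimws(as.character(raw))
  x[is.na(x)] <- ""
  n <- nchar(x)
  digits <- grepl("^[0-9]+$", x)

  year <- month <- day <- rep(NA_integer_, length(x))
  precision <- rep("invalid", length(x))

  y <- suppressWarnings(as.integer(substr(x, 1L, 4L)))
  y_ok <- !is.na(y) & y >= 1900L & y <= 2100L

  # year precision
  i <- digits & n == 4L & y_ok
  precision[i] <- "year"
  year[i] <- y[i]

  # month precision
  m <- suppressWarnings(as.integer(substr(x, 5L, 6L)))
  i <- digits & n == 6L & y_ok & !is.na(m) & m >= 1L & m <= 12L
  precision[i] <- "month"
  year[i] <- y[i]
  month[i] <- m[i]

  # day precision: must be a real calendar date
  i8 <- digits & n == 8L & y_ok
  if (any(i8)) {
    d <- suppressWarnings(as.Date(x[i8], format = "%Y%m%d"))
    ok <- !is.na(d) & format(d, "%Y%m%d") == x[i8]
    idx <- which(i8)[ok]
    precision[idx] <- "day"
    year[idx] <- as.integer(format(d[ok], "%Y"))
    month[idx] <- as.integer(format(d[ok], "%m"))
    day[idx] <- as.integer(format(d[ok], "%d"))
  }

  data.frame(raw = x, precision = precision, year = year, month = month,
             day = day, stringsAsFactors = FALSE)
}

#' Sortable numeric stamp for a FAERS date string
#'
#' Maps `YYYYMMDD` strings to their numeric value for ordering (the FDA
#' deduplication rule sorts on FDA_DT as a number). Non-8-digit or invalid
#' dates map to `NA`.
#'
#' @param raw character vector of raw date fields.
#' @return numeric vector, `NA` where the field is not a valid day-precision
#'   date.
#' @export
faers_date_stamp <- function(raw) {
  p <- parse_faers_date(raw)
  out <- rep(NA_real_, nrow(p))
  i <- p$precision == "day"
  out[i] <- p$year[i] * 10000 + p$month[i] * 100 + p$day[i]
  out
}

# Date object for day-precision fields, NA otherwise (internal).
faers_date_as_date <- function(raw) {
  p <- parse_faers_date(raw)
  out <- rep(as.Date(NA), nrow(p))
  i <- p$precision == "day"
  if (any(i)) out[i] <- as.Date(sprintf("%04d%02d%02d", p$year[i], p$month[i],
                                        p$day[i]), format = "%Y%m%d")
  out
}
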