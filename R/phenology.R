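#' Read an environmental time series
#'
#' Reads a CSV with a `timestamp` column (ISO dates or date-times; any
#' cadence from ~10 minutes to daily) and numeric columns such as bottom
#' seawater temperature (`BST`, degrees C) and chlorophyll-a concentration
#' (`chl_a`, mg/m^3). Timestamps must be strictly increasing; temperatures
#' outside -2..40 degrees C are rejected as physically implausible.
#'
#' @param path CSV path.
#' @return Data frame with a POSIXct `timestamp` column.
#' @export
read_env_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"timestamp" %in% names(df)) stop("env series needs a 'timestamp' column")
  ts <- suppressWarnings(as.POSIXct(df$timestamp, tz = "UTC"))
  if (any(is.na(ts))) stop("unparseable timestamps in env series")
  if (any(diff(as.numeric(ts)) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  df$timestamp <- ts
  if ("BST" %in% names(df) &&
      any(df$BST < -2 | df$BST > 40, na.rm = TRUE)) {
    stop("BST outside the plausible -2..40 degrees C range")
  }
  df
}

#' Monthly mean and standard deviation of an environmental series
#'
#' @param series data frame with a `timestamp` column (Date or POSIXct) and
#'   one or more numeric variables.
#' @return Data frame with one row per calendar month present in the data
#'   and, per variable, `<var>_mean` and `<var>_sd` (sample SD, n-1
#'   denominator; NA for single-observation months).
#' @examples
#' env <- data.frame(
#'   timestamp = as.Date("2019-01-01") + c(0, 10, 40, 50),
#'   BST = c(9, 10, 11, 13)
#' )
#' monthly_summary(env)
#' @export
monthly_summary <- function(series) {
  if (!nrow(series)) stop("empty environmental series")
  stopifnot("timestamp" %in% names(series))
  vars <- names(series)[vapply(series, is.numeric, logical(1))]
  if (!length(vars)) stop("no numeric variables to summarize")
  mon <- format(as.POSIXct(series$timestamp, tz = "UTC"), "%Y-%m")
  all_months <- format(seq(min(as.POSIXct(series$timestamp, tz = "UTC")),
                           max(as.POSIXct(series$timestamp, tz = "UTC")),
                           by = "month"), "%Y-%m")
  missing <- setdiff(all_months, unique(mon))
  if (length(missing)) {
    warning("months with no data omitted: ", paste(missing, collapse = ", "))
  }
  out <- data.frame(month = sort(unique(mon)))
  for (v in vars) {
    out[[paste0(v, "_mean")]] <-
      as.numeric(tapply(series[[v]], mon, mean, na.rm = TRUE)[out$month])
    out[[paste0(v, "_sd")]] <-
      as.numeric(tapply(series[[v]], mon, sd, na.rm = TRUE)[out$month])
  }
  out
}

# Valid maturity-stage codes on the 6-stage scale. Inactive gonads are
# sexually indistinguishable, so F1, M1 and indeterminate records all merge
# into the combined "F1/M1" code.
stage_codes <- function() {
  c("F1/M1", paste0("F", 2:5), paste0("M", 2:5),
    "F4A", "F4B", "M4A", "M4B")
}

normalize_stage_code <- function(stage) {
  s <- toupper(trimws(as.character(stage)))
  s[s %in% c("F1", "M1", "F1/M1", "M1/F1", "INDETERMINATE", "IND")] <- "F1/M1"
  s[s %in% c("F4", "M4")] <- NA  # ambiguous: 4A or 4B required
  bad <- !is.na(s) & !s %in% stage_codes()
  if (any(bad) || anyNA(s)) {
    stop("unknown maturity stage code(s): ",
         paste(unique(stage[bad | is.na(s)]), collapse = ", "),
         "; valid codes: ", paste(stage_codes(), collapse = ", "))
  }
  s
}

#' Monthly maturity-stage composition
#'
#' Tabulates the percentage of individuals in each maturity stage per month
#' (optionally per sex). Inactive and indeterminate records are reported
#' under the merged `F1/M1` code. Each month row sums to 100%.
#'
#' @param records data frame with columns `month` (any label), `stage`
#'   (6-stage scale codes) and optionally `sex`.
#' @param by_sex split the composition by sex (indeterminates form their
#'   own group).
#' @return A list of class `stage_composition` with `percent` (month x stage
#'   matrix or a data frame with a sex column) and `n` per month.
#' @examples
#' stage_composition(data.frame(month = "May", stage = c("F2", "F2", "F3")))
#' @export
stage_composition <- function(records, by_sex = FALSE) {
  stopifnot(all(c("month", "stage") %in% names(records)))
  records$stage <- normalize_stage_code(records$stage)
  if (by_sex && "sex" %in% names(records)) {
    grp <- interaction(records$month, records$sex, drop = TRUE, sep = " / ")
  } else {
    grp <- factor(records$month)
  }
  tab <- table(grp, records$stage)
  pct <- prop.table(tab, margin = 1) * 100
  structure(
    list(percent = as.data.frame.matrix(pct),
         n = as.integer(rowSums(tab)),
         months = rownames(tab)),
    class = "stage_composition"
  )
}

#' @export
print.stage_composition <- function(x, ...) {
  cat("Maturity-stage composition (% of individuals per month)\n")
  out <- round(x$percent, 1)
  out$n <- x$n
  print(out)
  invisible(x)
}
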