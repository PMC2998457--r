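#' madecrc: dual informant-network capture-recapture for maternal mortality
#'
#' The package implements the full MADE-IN/MADE-FOR estimation pipeline:
#' informant death listings are validated, deduplicated within and matched
#' across two networks, verified against follow-up visit outcomes, and the
#' verified overlap drives capture-recapture estimation of total
#' pregnancy-related deaths (PRDs), the coverage of each network, the maternal
#' mortality ratio (MMR) and the cost-efficiency of the survey. A simulator of
#' informant-based death capture supports validation and design experiments.
#'
#' @keywords internal
"_PACKAGE"

## valid values shared across the pipeline
MADECRC_NETWORKS <- c("kader", "rt")
MADECRC_STRATA <- c("urban", "rural", "rural_remote")

LISTING_COLUMNS <- c(
  "record_id", "network", "informant_id", "village_id", "stratum",
  "name", "age_years", "date_of_death", "assigned_prd", "relative_contact"
)

VERIFICATION_COLUMNS <- c(
  "consolidated_id", "death_confirmed", "true_eligible_prd", "visit_date"
)

#' Round half away from zero
#'
#' Presentation rounding used throughout report output: values are carried at
#' full precision internally and rounded half-away-from-zero only when printed
#' (so 121.5 reports as 122, -0.5 as -1). `base::round()` rounds half to even,
#' which does not match conventional report tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_out <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Define an eligibility window
#'
#' The reference period (and optionally the set of districts) within which a
#' verified pregnancy-related death counts as eligible. The window is closed on
#' both ends.
#'
#' @param start_date,end_date ISO-8601 dates (`YYYY-MM-DD`) or `Date`s.
#' @param districts optional character vector of eligible area identifiers.
#' @return an object of class `eligibility_window`.
#' @examples
#' eligibility_window("2004-01-01", "2005-12-31")
#' @export
eligibility_window <- function(start_date, end_date, districts = NULL) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date)) {
    stop("window dates must parse as YYYY-MM-DD", call. = FALSE)
  }
  if (!start_date < end_date) {
    stop("start_date must be before end_date", call. = FALSE)
  }
  structure(
    list(start_date = start_date, end_date = end_date, districts = districts),
    class = "eligibility_window"
  )
}

#' @export
print.eligibility_window <- function(x, ...) {
  cat(
    "Eligibility window:", format(x$start_date), "to", format(x$end_date),
    "(closed)\n"
  )
  if (!is.null(x$districts)) {
    cat("Districts:", paste(x$districts, collapse = ", "), "\n")
  }
  invisible(x)
}

# parse a date column leniently: returns Date with NA where unparseable,
# distinguishing "missing" (empty) from "malformed" via the malformed attribute
parse_date_col <- function(x) {
  x <- as.character(x)
  blank <- is.na(x) | !nzchar(trimws(x))
  out <- rep(as.Date(NA), length(x))
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x) & !blank
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  malformed <- !blank & (!ok | (ok & is.na(out)))
  attr(out, "malformed") <- malformed
  out
}

parse_logical01 <- function(x) {
  x <- trimws(tolower(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t", "yes")] <- TRUE
  out[x %in% c("0", "false", "f", "no")] <- FALSE
  out
}

#' Validate informant listing records
#'
#' Checks each listed death against the record invariants (known network,
#' village present, age in range, parseable date) and flags — without dropping —
#' records whose date of death falls outside the eligibility window: final
#' eligibility is decided only after the verification visit, so out-of-window
#' listings stay in the matching pool.
#'
#' @param records a data.frame in the listing layout (see
#'   [read_listing_csv()]); character columns are coerced.
#' @param window an [eligibility_window()].
#' @return a list with `records` (validated rows, typed columns, plus a logical
#'   `out_of_window` flag) and `rejections` (data.frame of `record_id`,
#'   `reason` for rows that violate invariants).
#' @examples
#' w <- eligibility_window("2004-01-01", "2005-12-31")
#' recs <- data.frame(
#'   record_id = "r1", network = "rt", informant_id = "i1",
#'   village_id = "v1", stratum = "urban", name = "sari dewi",
#'   age_years = 28, date_of_death = "2004-06-01", assigned_prd = 1,
#'   relative_contact = ""
#' )
#' validate_records(recs, w)
#' @export
validate_records <- function(records, window) {
  stopifnot(inherits(window, "eligibility_window"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) == 0) {
    empty <- empty_listing()
    return(list(records = empty, rejections = data.frame(
      record_id = character(), reason = character(),
      stringsAsFactors = FALSE
    )))
  }
  missing_cols <- setdiff(LISTING_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop(
      "listing is missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  records <- records[LISTING_COLUMNS]
  for (col in c(
    "record_id", "network", "informant_id", "village_id", "stratum",
    "name", "relative_contact"
  )) {
    records[[col]] <- as.character(records[[col]])
  }
  records$network <- tolower(records$network)
  records$stratum <- tolower(records$stratum)

  age <- suppressWarnings(as.numeric(records$age_years))
  age_given <- !is.na(records$age_years) & nzchar(trimws(as.character(records$age_years)))
  dod <- parse_date_col(records$date_of_death)
  malformed_date <- attr(dod, "malformed")
  prd <- parse_logical01(records$assigned_prd)

  reason <- character(nrow(records))
  reason[!(records$network %in% MADECRC_NETWORKS)] <- "unknown network value"
  reason[is.na(records$village_id) | !nzchar(trimws(records$village_id))] <-
    "missing village_id"
  reason[reason == "" & age_given & (is.na(age) | age < 0 | age > 120)] <-
    "age out of range"
  reason[reason == "" & malformed_date] <- "malformed date"
  reason[reason == "" & is.na(prd)] <- "assigned_prd not interpretable as 0/1"
  reason[reason == "" & !(records$stratum %in% MADECRC_STRATA)] <-
    "unknown stratum value"

  bad <- reason != ""
  rejections <- data.frame(
    record_id = records$record_id[bad], reason = reason[bad],
    stringsAsFactors = FALSE
  )
  keep <- records[!bad, , drop = FALSE]
  keep$age_years <- ifelse(age_given[!bad], as.integer(round(age[!bad])), NA_integer_)
  keep$date_of_death <- dod[!bad]
  keep$assigned_prd <- prd[!bad]
  keep$out_of_window <- !is.na(keep$date_of_death) &
    (keep$date_of_death < window$start_date | keep$date_of_death > window$end_date)
  rownames(keep) <- NULL
  list(records = keep, rejections = rejections)
}

empty_listing <- function() {
  data.frame(
    record_id = character(), network = character(), informant_id = character(),
    village_id = character(), stratum = character(), name = character(),
    age_years = integer(), date_of_death = as.Date(character()),
    assigned_prd = logical(), relative_contact = character(),
    out_of_window = logical(), stringsAsFactors = FALSE
  )
}

#' Read and write informant listing CSV files
#'
#' The listing dialect has one row per informant-reported death with a fixed
#' header: `record_id,network,informant_id,village_id,stratum,name,age_years,`
#' `date_of_death,assigned_prd,relative_contact`. Dates are ISO-8601,
#' `assigned_prd` is `0`/`1`, and missing age/date are empty fields. Writing a
#' validated listing and re-reading it round-trips field-for-field.
#'
#' @param path file path.
#' @param records a validated listing data.frame.
#' @return `read_listing_csv()` returns a raw (unvalidated) data.frame in the
#'   listing layout; `write_listing_csv()` returns `path` invisibly.
#' @export
read_listing_csv <- function(path) {
  df <- utils::read.csv(
    path,
    colClasses = "character", na.strings = NULL,
    fileEncoding = "UTF-8", stringsAsFactors = FALSE
  )
  missing_cols <- setdiff(LISTING_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop(
      "listing CSV missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  df[c(LISTING_COLUMNS, setdiff(names(df), LISTING_COLUMNS))]
}

#' @rdname read_listing_csv
#' @export
write_listing_csv <- function(records, path) {
  out <- as.data.frame(records, stringsAsFactors = FALSE)[LISTING_COLUMNS]
  out$age_years <- ifelse(is.na(out$age_years), "", as.character(out$age_years))
  out$date_of_death <- ifelse(
    is.na(out$date_of_death), "", format(as.Date(out$date_of_death), "%Y-%m-%d")
  )
  out$assigned_prd <- as.integer(as.logical(out$assigned_prd))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write verification-outcome CSV files
#'
#' Outcomes of the follow-up household visits, one row per consolidated death:
#' `consolidated_id,death_confirmed,true_eligible_prd,visit_date`. A death that
#' could not be confirmed as a real death can never be an eligible PRD; reading
#' enforces that invariant.
#'
#' @param path file path.
#' @param outcomes a data.frame with the verification columns.
#' @return `read_verification_csv()` returns a typed data.frame;
#'   `write_verification_csv()` returns `path` invisibly.
#' @export
read_verification_csv <- function(path) {
  df <- utils::read.csv(
    path,
    colClasses = "character", na.strings = NULL,
    fileEncoding = "UTF-8", stringsAsFactors = FALSE
  )
  missing_cols <- setdiff(VERIFICATION_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop(
      "verification CSV missing columns: ",
      paste(missing_cols, collapse = ", "), call. = FALSE
    )
  }
  visit_date <- parse_date_col(df$visit_date)
  attr(visit_date, "malformed") <- NULL
  out <- data.frame(
    consolidated_id = as.character(df$consolidated_id),
    death_confirmed = parse_logical01(df$death_confirmed),
    true_eligible_prd = parse_logical01(df$true_eligible_prd),
    visit_date = visit_date,
    stringsAsFactors = FALSE
  )
  bad <- !out$death_confirmed & out$true_eligible_prd
  if (any(bad, na.rm = TRUE)) {
    stop(
      "verification outcomes claim eligible PRD for unconfirmed deaths: ",
      paste(out$consolidated_id[which(bad)], collapse = ", "), call. = FALSE
    )
  }
  out
}

#' @rdname read_verification_csv
#' @export
write_verification_csv <- function(outcomes, path) {
  out <- as.data.frame(outcomes, stringsAsFactors = FALSE)
  if (is.null(out$visit_date)) out$visit_date <- as.Date(NA)
  out <- out[VERIFICATION_COLUMNS]
  out$death_confirmed <- as.integer(as.logical(out$death_confirmed))
  out$true_eligible_prd <- as.integer(as.logical(out$true_eligible_prd))
  out$visit_date <- ifelse(
    is.na(out$visit_date), "", format(as.Date(out$visit_date), "%Y-%m-%d")
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Dual-network capture summary
#'
#' The sufficient statistic of two-source capture-recapture: the number of
#' eligible deaths captured by network A (`n_a`, including those also captured
#' by B), by network B (`n_b`), and by both (`m`). The union
#' `n_a + n_b - m` is the number captured at least once. In the Indonesian
#' study, network A is the neighbourhood-head (RT) network and network B the
#' health-volunteer (kader) network.
#'
#' @param n_a,n_b,m non-negative integer counts with `m <= min(n_a, n_b)`.
#' @return an object of class `capture_summary`.
#' @examples
#' capture_summary(n_a = 103, n_b = 86, m = 73)
#' @export
capture_summary <- function(n_a, n_b, m) {
  vals <- c(n_a = n_a, n_b = n_b, m = m)
  if (any(is.na(vals)) || any(vals < 0) || any(vals != round(vals))) {
    stop("capture counts must be non-negative integers", call. = FALSE)
  }
  if (m > min(n_a, n_b)) {
    stop("m cannot exceed min(n_a, n_b)", call. = FALSE)
  }
  structure(
    list(
      n_a = as.integer(n_a), n_b = as.integer(n_b), m = as.integer(m),
      union = as.integer(n_a + n_b - m)
    ),
    class = "capture_summary"
  )
}

#' @export
print.capture_summary <- function(x, ...) {
  cat("Dual-network capture summary\n")
  cat(sprintf("  captured by A:    %d\n", x$n_a))
  cat(sprintf("  captured by B:    %d\n", x$n_b))
  cat(sprintf("  captured by both: %d\n", x$m))
  cat(sprintf("  union:            %d\n", x$union))
  invisible(x)
}

#' Build a capture summary from consolidated deaths
#'
#' Counts network capture over a consolidated death list, optionally restricted
#' by a filter (typically: verified eligible PRDs only). Network A is `"rt"`
#' and network B is `"kader"`, matching [capture_summary()].
#'
#' @param deaths a consolidated deaths data.frame (from [consolidate()]) with
#'   logical columns `captured_by_rt` and `captured_by_kader`.
#' @param keep optional logical vector (length `nrow(deaths)`) selecting the
#'   deaths to count.
#' @return a [capture_summary()].
#' @export
capture_summary_from_deaths <- function(deaths, keep = NULL) {
  if (!is.null(keep)) deaths <- deaths[keep, , drop = FALSE]
  capture_summary(
    n_a = sum(deaths$captured_by_rt),
    n_b = sum(deaths$captured_by_kader),
    m = sum(deaths$captured_by_rt & deaths$captured_by_kader)
  )
}
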