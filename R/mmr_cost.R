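#' Estimate live births from fertility rates and population
#'
#' Live births over the reference period are estimated by applying stratum
#' fertility rates (live births per woman-year) to the stratum populations of
#' women of reproductive age: `sum over strata of rate * population * years`.
#' A population survey is not required when such rates exist from census or
#' survey sources.
#'
#' @param fertility_rates named numeric vector of live births per woman-year,
#'   one per stratum.
#' @param populations named numeric vector of WRA population per stratum
#'   (names must match `fertility_rates`).
#' @param years years of exposure in the reference period.
#' @return estimated number of live births (numeric).
#' @examples
#' estimate_live_births(c(urban = 0.1), c(urban = 1000), years = 2)
#' @export
estimate_live_births <- function(fertility_rates, populations, years) {
  if (any(fertility_rates < 0) || any(populations < 0) || years < 0) {
    stop("fertility rates, populations and years must be non-negative", call. = FALSE)
  }
  if (!is.null(names(fertility_rates)) && !is.null(names(populations))) {
    if (!setequal(names(fertility_rates), names(populations))) {
      stop("fertility_rates and populations must cover the same strata", call. = FALSE)
    }
    populations <- populations[names(fertility_rates)]
  } else if (length(fertility_rates) != length(populations)) {
    stop("fertility_rates and populations must align", call. = FALSE)
  }
  sum(fertility_rates * populations * years)
}

#' Maternal mortality ratio
#'
#' `MMR = 100000 * PRD total / live births`. Given a Bayesian fit
#' ([bayesian_total()]), the transform is applied draw-wise so the posterior
#' mean, median and credible interval of the MMR map through the same
#' (monotone) transformation.
#'
#' @param prd_total a numeric death count or a `crc_bayes` fit.
#' @param live_births number of live births in the same period and area
#'   (must be positive).
#' @return for a numeric input, the MMR (deaths per 100,000 live births); for
#'   a `crc_bayes` input, a [posterior_summary()] of the MMR.
#' @examples
#' compute_mmr(627, 144470)
#' @export
compute_mmr <- function(prd_total, live_births) {
  if (is.na(live_births) || live_births <= 0) {
    stop("live_births must be positive", call. = FALSE)
  }
  if (inherits(prd_total, "crc_bayes")) {
    return(posterior_summary(
      1e5 * prd_total$draws[, "total"] / live_births,
      seed = prd_total$config$seed
    ))
  }
  if (inherits(prd_total, "posterior_summary")) {
    stop("pass the crc_bayes fit itself so the transform can act on draws",
      call. = FALSE
    )
  }
  1e5 * prd_total / live_births
}

#' Survey cost ledger
#'
#' Line items of survey expenditure, each attributed to the listing phase
#' (`made_in`), the verification phase (`made_for`), or `shared` between them.
#'
#' @param category character vector of line-item labels.
#' @param amount numeric expenditure per item (non-negative; currency is a
#'   label, no conversion is done).
#' @param attribution one of `"made_in"`, `"made_for"`, `"shared"` per item.
#' @param currency currency label.
#' @return a data.frame of class `cost_ledger`.
#' @export
cost_ledger <- function(category, amount, attribution, currency = "USD") {
  attribution <- match.arg(
    attribution, c("made_in", "made_for", "shared"), several.ok = TRUE
  )
  if (any(amount < 0)) stop("amounts must be non-negative", call. = FALSE)
  out <- data.frame(
    category = as.character(category), amount = as.numeric(amount),
    attribution = attribution, stringsAsFactors = FALSE
  )
  attr(out, "currency") <- currency
  class(out) <- c("cost_ledger", "data.frame")
  out
}

#' Read a cost ledger CSV
#'
#' Columns: `category,amount_usd,attribution`.
#'
#' @param path file path.
#' @return a [cost_ledger()].
#' @export
read_cost_ledger_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  cost_ledger(df$category, df$amount_usd, tolower(df$attribution))
}

#' Allocate shared costs between survey phases
#'
#' Items attributed to one phase fall to it directly; `shared` items (wages,
#' accommodation and similar general expenditure) are split in proportion to
#' the data-collector-days each phase consumed. Money is conserved exactly:
#' the two phase totals sum to the ledger grand total.
#'
#' @param ledger a [cost_ledger()].
#' @param effort_days named numeric vector `c(made_in = , made_for = )` of
#'   data-collector-days; required if any item is shared.
#' @return a list with `made_in`, `made_for`, `total`, and `by_category`
#'   (per-item allocation).
#' @examples
#' led <- cost_ledger(
#'   c("travel", "salary"), c(100, 50), c("made_in", "shared")
#' )
#' allocate_shared_costs(led, effort_days = c(made_in = 10, made_for = 10))
#' @export
allocate_shared_costs <- function(ledger, effort_days = NULL) {
  shared <- ledger$attribution == "shared"
  if (any(shared)) {
    if (is.null(effort_days) ||
      !all(c("made_in", "made_for") %in% names(effort_days))) {
      stop(
        "shared items require effort_days = c(made_in = , made_for = )",
        call. = FALSE
      )
    }
    w_in <- effort_days[["made_in"]] / sum(effort_days[c("made_in", "made_for")])
  } else {
    w_in <- 0.5
  }
  alloc_in <- ifelse(
    ledger$attribution == "made_in", ledger$amount,
    ifelse(shared, ledger$amount * w_in, 0)
  )
  alloc_for <- ledger$amount - alloc_in
  alloc_for[ledger$attribution == "made_in"] <- 0
  list(
    made_in = sum(alloc_in),
    made_for = sum(alloc_for),
    total = sum(ledger$amount),
    by_category = data.frame(
      category = ledger$category,
      made_in = alloc_in, made_for = alloc_for,
      stringsAsFactors = FALSE
    )
  )
}

#' Cost per woman-year of exposure
#'
#' The survey's unit cost: total cost divided by woman-years of exposure
#' (number of women of reproductive age times years of the reference period).
#' Reported to three decimals.
#'
#' @param total_cost total expenditure.
#' @param n_wra number of women of reproductive age in the area.
#' @param years years of exposure.
#' @return cost per woman-year (numeric, full precision; round for display).
#' @examples
#' cost_per_woman_year(154271, n_wra = 758000, years = 2)
#' @export
cost_per_woman_year <- function(total_cost, n_wra, years) {
  if (total_cost < 0) stop("total_cost must be non-negative", call. = FALSE)
  if (n_wra <= 0 || years <= 0) {
    stop("woman-years of exposure must be positive", call. = FALSE)
  }
  total_cost / (n_wra * years)
}
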