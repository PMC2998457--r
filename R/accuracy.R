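#' Confusion table of assigned versus verified PRD status
#'
#' Cross-tabulation of the informant-assigned pregnancy-related status against
#' the verified eligible-PRD status from the follow-up visit (the gold
#' standard): `tp` assigned and truly eligible, `fp` assigned but not, `fn`
#' eligible but not assigned, `tn` neither.
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return an object of class `confusion_table`.
#' @examples
#' confusion_table(tp = 23, fp = 8, fn = 2, tn = 156)
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  vals <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(vals)) || any(vals < 0) || any(vals != round(vals))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(
    list(
      tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn),
      n = as.integer(tp + fp + fn + tn)
    ),
    class = "confusion_table"
  )
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(
    c(x$tp, x$fn, x$fp, x$tn), 2, 2,
    dimnames = list(
      assigned = c("PRD", "not PRD"), verified = c("eligible", "not eligible")
    )
  )
  print(m)
  invisible(x)
}

#' Tabulate verification outcomes against assigned status
#'
#' Builds a [confusion_table()] from consolidated deaths and the outcomes of
#' their follow-up visits. Every death must have an outcome (in the pilot
#' every identified WRA death was visited); missing outcomes are an error that
#' lists the offending ids. The verified truth for an unconfirmed death is
#' "not an eligible PRD".
#'
#' @param deaths a data.frame with `consolidated_id` and an assigned-status
#'   column (default `assigned_prd_any`).
#' @param outcomes a verification data.frame (see [read_verification_csv()]).
#' @param assigned_col name of the logical assigned-status column in `deaths`.
#' @return a [confusion_table()].
#' @export
confusion_from_records <- function(deaths, outcomes,
                                   assigned_col = "assigned_prd_any") {
  if (nrow(deaths) == 0) return(confusion_table(0, 0, 0, 0))
  idx <- match(deaths$consolidated_id, outcomes$consolidated_id)
  if (anyNA(idx)) {
    stop(
      "deaths without a verification outcome: ",
      paste(deaths$consolidated_id[is.na(idx)], collapse = ", "),
      call. = FALSE
    )
  }
  truth <- outcomes$death_confirmed[idx] & outcomes$true_eligible_prd[idx]
  assigned <- as.logical(deaths[[assigned_col]])
  confusion_table(
    tp = sum(assigned & truth), fp = sum(assigned & !truth),
    fn = sum(!assigned & truth), tn = sum(!assigned & !truth)
  )
}

#' Diagnostic accuracy of informant-assigned PRD status
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`, each carried
#' as a `(value %, numerator, denominator)` triple. A metric whose denominator
#' is zero is explicitly undefined (`value` is `NA`, `undefined` is `TRUE`) —
#' never reported as 0. Values are exact; presentation is to one decimal.
#'
#' @param table a [confusion_table()].
#' @return an object of class `accuracy_metrics`: a list with elements
#'   `sensitivity`, `specificity`, `ppv`, `npv` (each `value`/`numerator`/
#'   `denominator`/`undefined`) plus `n`.
#' @examples
#' accuracy_metrics(confusion_table(23, 8, 2, 156))
#' @export
accuracy_metrics <- function(table) {
  stopifnot(inherits(table, "confusion_table"))
  one <- function(num, den) {
    list(
      value = if (den > 0) 100 * num / den else NA_real_,
      numerator = num, denominator = den, undefined = den == 0
    )
  }
  structure(
    list(
      sensitivity = one(table$tp, table$tp + table$fn),
      specificity = one(table$tn, table$tn + table$fp),
      ppv = one(table$tp, table$tp + table$fp),
      npv = one(table$tn, table$tn + table$fn),
      n = table$n
    ),
    class = "accuracy_metrics"
  )
}

format_metric <- function(m) {
  if (m$undefined) return("undefined")
  sprintf("%s (%d/%d)", format(round_half_out(m$value, 1)), m$numerator, m$denominator)
}

#' @export
print.accuracy_metrics <- function(x, ...) {
  cat(sprintf("n = %d\n", x$n))
  for (nm in c("sensitivity", "specificity", "ppv", "npv")) {
    cat(sprintf("  %-12s %s\n", nm, format_metric(x[[nm]])))
  }
  invisible(x)
}

# map a fine stratum onto the urban/rural dichotomy used in reporting
area_of_stratum <- function(stratum) {
  ifelse(stratum == "urban", "urban", "rural")
}

#' Stratified accuracy of assigned PRD status
#'
#' Accuracy metrics per stratum level plus a Total row. Stratifiers:
#'
#' * `network`: a death captured by both networks contributes to BOTH network
#'   rows, each with that network's own assigned status (so the network rows'
#'   n values sum to more than the total — the only convention consistent
#'   with per-network assignment);
#' * `year`: year of death (from the consolidated date); partitions deaths;
#' * `area`: urban versus rural (rural-remote counts as rural); partitions
#'   deaths.
#'
#' @param consolidation the result of [consolidate()] (`deaths` + `members`).
#' @param outcomes a verification data.frame covering every death.
#' @param by character vector of stratifiers among `"network"`, `"year"`,
#'   `"area"`.
#' @return a data.frame with one row per (stratification, level) and columns
#'   `n`, then `<metric>_pct`, `<metric>_num`, `<metric>_den` for the four
#'   metrics; the first row is the Total.
#' @export
stratified_metrics <- function(consolidation, outcomes,
                               by = c("network", "year", "area")) {
  unknown <- setdiff(by, c("network", "year", "area"))
  if (length(unknown)) {
    stop("unknown stratum key: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  deaths <- consolidation$deaths
  members <- consolidation$members

  row_from <- function(stratification, level, ct) {
    met <- accuracy_metrics(ct)
    out <- data.frame(
      stratification = stratification, level = level, n = met$n,
      stringsAsFactors = FALSE
    )
    for (nm in c("sensitivity", "specificity", "ppv", "npv")) {
      out[[paste0(nm, "_pct")]] <- met[[nm]]$value
      out[[paste0(nm, "_num")]] <- met[[nm]]$numerator
      out[[paste0(nm, "_den")]] <- met[[nm]]$denominator
    }
    out
  }

  rows <- list(row_from("total", "total", confusion_from_records(deaths, outcomes)))
  for (key in by) {
    if (key == "network") {
      for (net in MADECRC_NETWORKS) {
        mem <- members[members$network == net, , drop = FALSE]
        # one row per death captured by this network, assigned per this network
        per_death <- stats::aggregate(
          assigned_prd ~ consolidated_id, data = mem, FUN = any
        )
        names(per_death)[2] <- "assigned_prd_any"
        rows[[length(rows) + 1L]] <- row_from(
          "network", net, confusion_from_records(per_death, outcomes)
        )
      }
    } else if (key == "year") {
      yr <- format(deaths$date_of_death, "%Y")
      for (level in sort(unique(yr[!is.na(yr)]))) {
        rows[[length(rows) + 1L]] <- row_from(
          "year", level,
          confusion_from_records(deaths[!is.na(yr) & yr == level, , drop = FALSE], outcomes)
        )
      }
    } else if (key == "area") {
      area <- area_of_stratum(deaths$stratum)
      for (level in c("urban", "rural")) {
        sel <- area == level
        if (!any(sel)) next
        rows[[length(rows) + 1L]] <- row_from(
          "area", level, confusion_from_records(deaths[sel, , drop = FALSE], outcomes)
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an accuracy report CSV
#'
#' Long-format accuracy report: one row per (stratification, level, metric)
#' with the percentage and its numerator/denominator pair, so every printed
#' value can be re-derived from counts.
#'
#' @param strat_table result of [stratified_metrics()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_accuracy_csv <- function(strat_table, path) {
  rows <- list()
  for (i in seq_len(nrow(strat_table))) {
    for (nm in c("sensitivity", "specificity", "ppv", "npv")) {
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = strat_table$stratification[i], level = strat_table$level[i],
        n = strat_table$n[i], metric = nm,
        value_pct = round_half_out(strat_table[[paste0(nm, "_pct")]][i], 1),
        numerator = strat_table[[paste0(nm, "_num")]][i],
        denominator = strat_table[[paste0(nm, "_den")]][i],
        stringsAsFactors = FALSE
      )
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
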