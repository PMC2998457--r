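test_that("accuracy metrics reproduce the published pilot rows exactly", {
  rows <- list(
    list(ct = confusion_table(23, 8, 2, 156), want = c(92, 95.1, 74.2, 98.7), n = 189),
    list(ct = confusion_table(21, 5, 1, 114), want = c(95.5, 95.8, 80.8, 99.1), n = 141),
    list(ct = confusion_table(10, 6, 2, 70), want = c(83.3, 92.1, 62.5, 97.2), n = 88),
    list(ct = confusion_table(13, 2, 0, 86), want = c(100, 97.7, 86.7, 100), n = 101)
  )
  for (r in rows) {
    met <- accuracy_metrics(r$ct)
    got <- vapply(
      met[c("sensitivity", "specificity", "ppv", "npv")],
      function(m) round_half_out(m$value, 1), numeric(1)
    )
    expect_equal(unname(got), r$want)
    expect_equal(met$n, r$n)
  }
})

test_that("zero denominators yield explicit undefined metrics, never zero", {
  met <- accuracy_metrics(confusion_table(0, 0, 0, 10))
  expect_true(met$sensitivity$undefined)
  expect_true(is.na(met$sensitivity$value))
  expect_false(met$specificity$undefined)
  expect_equal(met$specificity$value, 100)
  expect_true(met$ppv$undefined)
  expect_equal(met$npv$value, 100)
})

test_that("verification cross-tabulation counts the four cells correctly", {
  deaths <- data.frame(
    consolidated_id = sprintf("C%d", 1:6),
    assigned_prd_any = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  )
  outcomes <- data.frame(
    consolidated_id = sprintf("C%d", 1:6),
    death_confirmed = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    true_eligible_prd = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  ct <- confusion_from_records(deaths, outcomes)
  # C5 is assigned but the death was never confirmed: a false positive
  expect_equal(c(ct$tp, ct$fp, ct$fn, ct$tn), c(1L, 2L, 1L, 2L))

  expect_error(
    confusion_from_records(deaths, outcomes[-3, ]),
    "C3"
  )
  empty <- confusion_from_records(deaths[0, ], outcomes)
  expect_equal(empty$n, 0L)

  perfect <- confusion_from_records(
    data.frame(
      consolidated_id = c("C1", "C4"), assigned_prd_any = c(TRUE, FALSE)
    ),
    outcomes
  )
  expect_equal(c(perfect$fp, perfect$fn), c(0L, 0L))
})

test_that("the packaged pilot-style fixture reproduces every published stratum row", {
  cons <- pilot_consolidation()
  tab <- stratified_metrics(cons, pilot_outcomes())
  check <- function(strat, level, n, want) {
    row <- tab[tab$stratification == strat & tab$level == level, ]
    expect_equal(row$n, n)
    got <- round_half_out(unlist(
      row[c("sensitivity_pct", "specificity_pct", "ppv_pct", "npv_pct")]
    ), 1)
    expect_equal(unname(got), want)
  }
  check("total", "total", 189, c(92, 95.1, 74.2, 98.7))
  check("network", "kader", 141, c(95.5, 95.8, 80.8, 99.1))
  check("network", "rt", 156, c(91.3, 94.7, 75, 98.4))
  check("year", "2004", 88, c(83.3, 92.1, 62.5, 97.2))
  check("year", "2005", 101, c(100, 97.7, 86.7, 100))
  check("area", "urban", 85, c(88.9, 92.1, 57.1, 98.6))
  check("area", "rural", 104, c(93.8, 97.7, 88.2, 98.9))
})

test_that("year and area stratifications partition n; network rows double-count", {
  cons <- pilot_consolidation()
  tab <- stratified_metrics(cons, pilot_outcomes())
  total_n <- tab$n[tab$stratification == "total"]
  expect_equal(sum(tab$n[tab$stratification == "year"]), total_n)
  expect_equal(sum(tab$n[tab$stratification == "area"]), total_n)
  # deaths captured by both networks appear in both network rows
  expect_gt(sum(tab$n[tab$stratification == "network"]), total_n)
  expect_equal(sum(tab$n[tab$stratification == "network"]), 297)
})

test_that("stratified metrics are invariant to record order", {
  cons <- pilot_consolidation()
  shuffled <- cons
  set.seed(1)
  shuffled$deaths <- shuffled$deaths[sample(nrow(shuffled$deaths)), ]
  shuffled$members <- shuffled$members[sample(nrow(shuffled$members)), ]
  t1 <- stratified_metrics(cons, pilot_outcomes())
  t2 <- stratified_metrics(shuffled, pilot_outcomes())
  expect_equal(t1, t2)
})

test_that("all reported percentages re-derive from their count pairs", {
  cons <- pilot_consolidation()
  tab <- stratified_metrics(cons, pilot_outcomes())
  for (nm in c("sensitivity", "specificity", "ppv", "npv")) {
    pct <- tab[[paste0(nm, "_pct")]]
    num <- tab[[paste0(nm, "_num")]]
    den <- tab[[paste0(nm, "_den")]]
    expect_equal(pct, 100 * num / den)
  }
})
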