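# builders for in-code fixtures shared across test files

default_window <- function() eligibility_window("2004-01-01", "2005-12-31")

make_record <- function(record_id = "r1", network = "rt", informant_id = "i1",
                        village_id = "v1", stratum = "urban",
                        name = "sari dewi", age_years = 28,
                        date_of_death = "2004-06-01", assigned_prd = 1,
                        relative_contact = "") {
  data.frame(
    record_id = record_id, network = network, informant_id = informant_id,
    village_id = village_id, stratum = stratum, name = name,
    age_years = age_years, date_of_death = date_of_death,
    assigned_prd = assigned_prd, relative_contact = relative_contact,
    stringsAsFactors = FALSE
  )
}

# distinct synthetic names: 3-syllable tokens that rarely resemble each other
test_name <- function(i) {
  syl <- c(
    "ba", "ce", "di", "fo", "gu", "hi", "jo", "ku", "le", "mo",
    "ni", "pa", "re", "so", "tu", "vi", "wa", "yo", "za", "qe"
  )
  tok <- function(j) {
    paste0(syl[(j %% 20) + 1], syl[((j %/% 3) %% 20) + 1], syl[((j %/% 7) %% 20) + 1])
  }
  paste(tok(2 * i + 13), tok(400 + 97 - 3 * i))
}

# a dual-network stratum plus a kader-only stratum with the published capture
# structure: 30 RT-only, 13 kader-only, 73 matched, 353 kader-only-stratum,
# all verified eligible PRDs
table1_style_listings <- function() {
  i <- 0
  rows_k <- list()
  rows_r <- list()
  truth <- list()
  add_death <- function(pattern, village, stratum) {
    i <<- i + 1
    id <- sprintf("T%04d", i)
    base <- make_record(
      record_id = id, village_id = village, stratum = stratum,
      name = test_name(i), age_years = 15 + (i * 11) %% 35,
      date_of_death = sprintf(
        "%d-%02d-%02d", 2004 + i %% 2, (i * 5) %% 12 + 1, (i * 13) %% 28 + 1
      ),
      assigned_prd = 1
    )
    if (pattern %in% c("both", "k")) {
      rk <- base
      rk$record_id <- paste0(id, "-k")
      rk$network <- "kader"
      rows_k[[length(rows_k) + 1]] <<- rk
    }
    if (pattern %in% c("both", "r")) {
      rr <- base
      rr$record_id <- paste0(id, "-r")
      rr$network <- "rt"
      rows_r[[length(rows_r) + 1]] <<- rr
    }
    truth[[length(truth) + 1]] <<- data.frame(
      id = id, pattern = pattern, stringsAsFactors = FALSE
    )
  }
  # dual stratum: separate villages per capture pattern so leftover singletons
  # can never be cross-matched by the greedy resolver
  for (j in 1:73) add_death("both", sprintf("V_dual_b_%02d", j %% 8), "urban")
  for (j in 1:30) add_death("r", sprintf("V_dual_r_%02d", j %% 4), "urban")
  for (j in 1:13) add_death("k", sprintf("V_dual_k_%02d", j %% 4), "urban")
  for (j in 1:353) add_death("k", sprintf("V_single_%02d", j %% 30), "rural")
  list(
    kader = do.call(rbind, rows_k),
    rt = do.call(rbind, rows_r),
    truth = do.call(rbind, truth)
  )
}

# verification marking every consolidated death an eligible confirmed PRD
all_eligible_verification <- function(consolidation) {
  data.frame(
    consolidated_id = consolidation$deaths$consolidated_id,
    death_confirmed = TRUE, true_eligible_prd = TRUE,
    visit_date = as.Date("2006-04-15"), stringsAsFactors = FALSE
  )
}

pilot_fixture_path <- function(file) {
  system.file("extdata", file, package = "madecrc", mustWork = TRUE)
}

# consolidation of the packaged synthetic pilot fixture
pilot_consolidation <- function() {
  cfg <- pipeline_config(window = default_window())
  stage <- madecrc:::consolidate_listings(
    read_listing_csv(pilot_fixture_path("pilot_synthetic_kader.csv")),
    read_listing_csv(pilot_fixture_path("pilot_synthetic_rt.csv")),
    cfg
  )
  stage$consolidation
}

pilot_outcomes <- function() {
  read_verification_csv(pilot_fixture_path("pilot_synthetic_verification.csv"))
}
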