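#' Pipeline configuration
#'
#' Everything a reproducible run needs beyond the input files: the eligibility
#' window, matching thresholds, sampler settings, and (optionally) the
#' live-birth and cost inputs for the MMR and efficiency reports.
#'
#' @param window an [eligibility_window()].
#' @param match a [match_config()].
#' @param dedupe_within whether to deduplicate each network's listing before
#'   cross-network matching.
#' @param include_nonresident whether listings of non-resident deaths are
#'   retained (field rule is site-specific; the default excludes none because
#'   residence is not carried on the listing form — the flag is honoured when
#'   a `resident` column is present).
#' @param dual_villages optional character vector of village ids where both
#'   networks operated. When `NULL` the dual stratum is inferred as the
#'   villages with at least one RT record — correct unless RT operated
#'   somewhere and captured nothing, so passing the design explicitly is
#'   preferred.
#' @param cap_multiplier,n_iter,warmup,chains Bayesian sampler settings, see
#'   [bayesian_total()].
#' @param seed integer seed echoed into every output.
#' @param fertility_rates,populations,years_exposure,n_wra optional inputs for
#'   [estimate_live_births()] and [cost_per_woman_year()].
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(window = eligibility_window("2004-01-01", "2005-12-31"),
                            match = match_config(),
                            dedupe_within = TRUE,
                            include_nonresident = FALSE,
                            dual_villages = NULL,
                            cap_multiplier = 20,
                            n_iter = 15000, warmup = 2000, chains = 4,
                            seed = 1L,
                            fertility_rates = NULL, populations = NULL,
                            years_exposure = 2, n_wra = NULL) {
  structure(
    list(
      window = window, match = match, dedupe_within = dedupe_within,
      include_nonresident = include_nonresident,
      dual_villages = dual_villages,
      cap_multiplier = cap_multiplier, n_iter = n_iter, warmup = warmup,
      chains = chains, seed = as.integer(seed),
      fertility_rates = fertility_rates, populations = populations,
      years_exposure = years_exposure, n_wra = n_wra
    ),
    class = "pipeline_config"
  )
}

# shared preprocessing: validate -> dedupe within network -> match -> consolidate.
# Used by run_pipeline() and by tests/simulation helpers so that consolidated
# ids are identical wherever the same inputs and config are used.
consolidate_listings <- function(kader_raw, rt_raw, config,
                                 confirmations = NULL, log = NULL) {
  say <- function(fmt, ...) if (!is.null(log)) log(sprintf(fmt, ...))
  drop_nonresident <- function(df) {
    if (!config$include_nonresident && "resident" %in% names(df)) {
      df <- df[parse_logical01(df$resident) %in% TRUE, , drop = FALSE]
    }
    df
  }
  kader_raw <- drop_nonresident(kader_raw)
  rt_raw <- drop_nonresident(rt_raw)
  vk <- validate_records(kader_raw, config$window)
  vr <- validate_records(rt_raw, config$window)
  say(
    "validate: kader %d ok / %d rejected; rt %d ok / %d rejected",
    nrow(vk$records), nrow(vk$rejections), nrow(vr$records), nrow(vr$rejections)
  )
  k <- vk$records
  r <- vr$records
  if (config$dedupe_within) {
    k <- dedupe_within_network(k, config$match)
    r <- dedupe_within_network(r, config$match)
    say("dedupe: kader %d, rt %d records after within-network merge", nrow(k), nrow(r))
  }
  candidates <- propose_matches(r, k, config$match)
  matching <- resolve_matches(candidates, confirmations)
  say(
    "match: %d candidates, %d accepted pairs", nrow(candidates), nrow(matching)
  )
  cons <- consolidate(r, k, matching)
  say("consolidate: %d deaths", nrow(cons$deaths))
  list(
    consolidation = cons, matching = matching, candidates = candidates,
    rejections = rbind(vk$rejections, vr$rejections)
  )
}

#' Run the full estimation pipeline
#'
#' Executes the whole flow on listing files: validate each network's listing,
#' deduplicate within network, match across networks, consolidate, restrict to
#' verified eligible PRDs, estimate totals (Lincoln-Petersen, Chapman,
#' Bayesian; dual stratum plus kader-only extrapolation), compute informant
#' accuracy against the verification outcomes, and — when live-birth and cost
#' inputs are configured — the MMR and cost-efficiency reports. Every artifact
#' is written under `out_dir` with the configuration and seed echoed.
#'
#' Without a verification file the pipeline stops after consolidation
#' (writing the match output for the field team): listing-only estimates are
#' severely inflated by unrecognized false positives and missed matches, so
#' they are produced only with an explicit `unverified = TRUE`.
#'
#' @param kader_csv,rt_csv listing CSV paths (see [read_listing_csv()]).
#' @param verification_csv verification outcomes CSV path, or `NULL`.
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param confirmations_csv optional CSV of match confirmations
#'   (`record_a_id,record_b_id,is_same_person`).
#' @param unverified set `TRUE` to force listing-only estimates when no
#'   verification file exists.
#' @return invisibly, a list with the consolidation, estimates, accuracy
#'   table and report paths.
#' @export
run_pipeline <- function(kader_csv, rt_csv, verification_csv = NULL,
                         out_dir, config = pipeline_config(),
                         confirmations_csv = NULL, unverified = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  log <- function(msg) writeLines(paste0(format(Sys.time(), "%H:%M:%S "), msg), log_con)

  kader_raw <- read_listing_csv(kader_csv)
  rt_raw <- read_listing_csv(rt_csv)
  log(sprintf("read: kader %d rows, rt %d rows", nrow(kader_raw), nrow(rt_raw)))
  confirmations <- if (!is.null(confirmations_csv)) {
    df <- utils::read.csv(confirmations_csv, stringsAsFactors = FALSE)
    df$is_same_person <- as.logical(df$is_same_person)
    df
  }
  stage <- consolidate_listings(kader_raw, rt_raw, config, confirmations, log)
  cons <- stage$consolidation
  write_matches_csv(cons, stage$matching, file.path(out_dir, "matches.csv"))

  if (nrow(cons$deaths) == 0) {
    log("no records after validation; nothing to estimate")
    report <- list(
      seed = config$seed, n_deaths = 0,
      message = "no records in the listings"
    )
    jsonlite::write_json(
      report, file.path(out_dir, "estimates.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
    return(invisible(list(consolidation = cons, estimates = report)))
  }

  if (is.null(verification_csv) && !unverified) {
    stop(
      "no verification file: listing-only capture-recapture estimates are ",
      "severely inflated by unrecognized false positives and missed matches. ",
      "Run the follow-up visits and supply verification_csv, or pass ",
      "unverified = TRUE to proceed anyway.",
      call. = FALSE
    )
  }

  deaths <- cons$deaths
  if (!is.null(verification_csv)) {
    outcomes <- read_verification_csv(verification_csv)
    idx <- match(deaths$consolidated_id, outcomes$consolidated_id)
    if (anyNA(idx)) {
      stop(
        "verification outcomes missing for: ",
        paste(utils::head(deaths$consolidated_id[is.na(idx)], 10), collapse = ", "),
        call. = FALSE
      )
    }
    eligible <- outcomes$death_confirmed[idx] & outcomes$true_eligible_prd[idx]
    log(sprintf("verification: %d of %d deaths eligible PRDs", sum(eligible), length(eligible)))
  } else {
    outcomes <- NULL
    eligible <- deaths$assigned_prd_any & !deaths$out_of_window
    log(sprintf(
      "UNVERIFIED run: %d assigned in-window PRDs treated as eligible", sum(eligible)
    ))
  }

  # dual villages: from the study design when given, else where RT captured
  dual_villages <- if (!is.null(config$dual_villages)) {
    config$dual_villages
  } else {
    unique(deaths$village_id[deaths$captured_by_rt])
  }
  in_dual <- deaths$village_id %in% dual_villages
  cs_dual <- capture_summary_from_deaths(deaths, eligible & in_dual)
  n_single <- sum(eligible & !in_dual & deaths$captured_by_kader)
  log(sprintf(
    "capture: dual stratum n_rt=%d n_kader=%d m=%d; kader-only count %d",
    cs_dual$n_a, cs_dual$n_b, cs_dual$m, n_single
  ))

  estimates <- list(
    seed = config$seed,
    counts = list(
      dual = list(
        n_rt = cs_dual$n_a, n_kader = cs_dual$n_b, m = cs_dual$m,
        union = cs_dual$union
      ),
      single_kader = n_single
    )
  )
  if (cs_dual$m >= 1) {
    lp <- lincoln_petersen(cs_dual)
    extra <- extrapolate_single_network(n_single, lp$p_b)
    combined <- combine_strata(lp, list(extra))
    fit <- bayesian_total(
      cs_dual, n_single,
      cap_multiplier = config$cap_multiplier,
      n_iter = config$n_iter, warmup = config$warmup, chains = config$chains,
      seed = config$seed
    )
    estimates$lincoln_petersen <- list(
      total = lp$total, p_rt = lp$p_a, p_kader = lp$p_b, missed = lp$missed
    )
    estimates$chapman <- list(total = chapman(cs_dual)$total)
    estimates$extrapolation <- list(
      single_total = extra$total, combined_total = combined$total
    )
    estimates$bayes <- list(
      model = "conditional multinomial dual stratum + binomial kader-only stratum, shared kader capture probability, Beta(1,1) priors, discrete-uniform total priors",
      config = fit$config,
      total = fit$summaries$total[c("mean", "median", "ci_low", "ci_high", "draws_used")],
      N_dual = fit$summaries$N_dual[c("mean", "median", "ci_low", "ci_high")],
      N_single = fit$summaries$N_single[c("mean", "median", "ci_low", "ci_high")],
      p_rt = fit$summaries$p_a[c("mean", "ci_low", "ci_high")],
      p_kader = fit$summaries$p_b[c("mean", "ci_low", "ci_high")],
      rhat = as.list(fit$rhat), converged = fit$converged
    )
  } else {
    fit <- NULL
    log("no matched cases in dual stratum: Lincoln-Petersen undefined; Chapman only")
    estimates$chapman <- list(total = chapman(cs_dual)$total)
  }
  jsonlite::write_json(
    estimates, file.path(out_dir, "estimates.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  log("wrote estimates.json")

  accuracy <- NULL
  if (!is.null(outcomes)) {
    accuracy <- stratified_metrics(cons, outcomes)
    write_accuracy_csv(accuracy, file.path(out_dir, "accuracy.csv"))
    log("wrote accuracy.csv")
  }

  mmr_report <- NULL
  if (!is.null(config$fertility_rates) && !is.null(config$populations) &&
    !is.null(fit)) {
    lb <- estimate_live_births(
      config$fertility_rates, config$populations, config$years_exposure
    )
    mmr_post <- compute_mmr(fit, lb)
    mmr_report <- list(
      live_births = lb,
      mmr = mmr_post[c("mean", "median", "ci_low", "ci_high")],
      inputs = list(
        fertility_rates = as.list(config$fertility_rates),
        populations = as.list(config$populations),
        years = config$years_exposure
      ),
      seed = config$seed
    )
    jsonlite::write_json(
      mmr_report, file.path(out_dir, "mmr.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
    log("wrote mmr.json")
  }
  invisible(list(
    consolidation = cons, matching = stage$matching,
    capture_dual = cs_dual, n_single = n_single,
    estimates = estimates, bayes_fit = fit, accuracy = accuracy,
    mmr = mmr_report,
    paths = list(out_dir = out_dir, log = log_path)
  ))
}
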