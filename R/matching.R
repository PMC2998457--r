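#' Matching configuration
#'
#' Thresholds and weights for cross-network record matching. The score of a
#' candidate pair is a weighted mean of three similarity components: name
#' (token-set similarity on normalized tokens), age proximity (full credit for
#' a gap of at most 2 years, linear decay to 0 at 10 years) and date-of-death
#' proximity (full credit within 30 days, linear decay to 0 at 365 days). A
#' missing age or date contributes a neutral 0.5 for its component so that
#' incomplete informant forms are not penalized. Pairs scoring at least
#' `propose_threshold` are proposed; pairs at or above `auto_accept` may be
#' matched without a confirmation; the band in between is routed to the
#' follow-up visit (the confirmations map).
#'
#' @param propose_threshold minimum score for a pair to be proposed.
#' @param auto_accept score at or above which a pair needs no confirmation.
#' @param weights named numeric weights for `name`, `age`, `date`; normalized
#'   to sum to 1.
#' @return a list of class `match_config`.
#' @export
match_config <- function(propose_threshold = 0.5, auto_accept = 0.85,
                         weights = c(name = 0.5, age = 0.25, date = 0.25)) {
  stopifnot(
    propose_threshold >= 0, propose_threshold <= 1,
    auto_accept >= propose_threshold, auto_accept <= 1,
    all(c("name", "age", "date") %in% names(weights)), all(weights >= 0),
    sum(weights) > 0
  )
  structure(
    list(
      propose_threshold = propose_threshold, auto_accept = auto_accept,
      weights = weights[c("name", "age", "date")] / sum(weights)
    ),
    class = "match_config"
  )
}

#' Normalize a name into comparison tokens
#'
#' Lowercases, strips punctuation and splits on whitespace; the token list is
#' what the name-similarity component compares.
#'
#' @param name character vector of names.
#' @return a list of character vectors of tokens.
#' @export
normalize_tokens <- function(name) {
  name <- tolower(as.character(name))
  name <- gsub("[^a-z0-9 ]+", " ", name)
  lapply(strsplit(trimws(gsub(" +", " ", name)), " ", fixed = TRUE), function(t) {
    t[nzchar(t)]
  })
}

# similarity of two individual tokens: 1 - normalized edit distance
token_similarity <- function(a, b) {
  if (a == b) return(1)
  d <- utils::adist(a, b)[1, 1]
  1 - d / max(nchar(a), nchar(b))
}

#' Token-set name similarity
#'
#' Greedy best-first pairing of tokens between the two token sets by pairwise
#' token similarity (1 minus normalized edit distance); the score is the summed
#' similarity of paired tokens scaled by `2 / (|A| + |B|)` (a fuzzy Dice
#' coefficient). Identical token sets score 1; disjoint dissimilar sets score
#' near 0.
#'
#' @param tokens_a,tokens_b character vectors of normalized tokens.
#' @return a similarity in `[0, 1]`.
#' @export
token_set_similarity <- function(tokens_a, tokens_b) {
  na <- length(tokens_a)
  nb <- length(tokens_b)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  sims <- outer(tokens_a, tokens_b, Vectorize(token_similarity))
  total <- 0
  for (k in seq_len(min(na, nb))) {
    best <- which(sims == max(sims), arr.ind = TRUE)[1, , drop = TRUE]
    if (sims[best[1], best[2]] <= 0) break
    total <- total + sims[best[1], best[2]]
    sims[best[1], ] <- -1
    sims[, best[2]] <- -1
  }
  max(0, min(1, 2 * total / (na + nb)))
}

# proximity maps: full credit within `full`, linear decay to zero at `zero`
proximity_credit <- function(delta, full, zero) {
  ifelse(
    is.na(delta), 0.5,
    pmax(0, pmin(1, (zero - pmax(delta, full)) / (zero - full)))
  )
}

# score one cross-network pair; returns the component evidence too
score_pair <- function(rec_a, rec_b, config) {
  sim_name <- token_set_similarity(
    normalize_tokens(rec_a$name)[[1]], normalize_tokens(rec_b$name)[[1]]
  )
  d_age <- if (is.na(rec_a$age_years) || is.na(rec_b$age_years)) {
    NA_real_
  } else {
    abs(rec_a$age_years - rec_b$age_years)
  }
  sim_age <- proximity_credit(d_age, full = 2, zero = 10)
  d_date <- if (is.na(rec_a$date_of_death) || is.na(rec_b$date_of_death)) {
    NA_real_
  } else {
    abs(as.numeric(rec_a$date_of_death - rec_b$date_of_death))
  }
  sim_date <- proximity_credit(d_date, full = 30, zero = 365)
  w <- config$weights
  score <- unname(w["name"] * sim_name + w["age"] * sim_age + w["date"] * sim_date)
  c(score = score, sim_name = sim_name, sim_age = sim_age, sim_date = sim_date)
}

#' Propose cross-network candidate matches
#'
#' Generates candidate pairs between two validated listings from opposite
#' networks, blocked by village (records from different villages are never
#' compared), scored as described in [match_config()], filtered at the
#' proposal threshold and sorted by descending score (ties broken by record
#' ids for determinism).
#'
#' @param list_a,list_b validated listing data.frames from distinct networks.
#' @param config a [match_config()].
#' @return a data.frame with columns `record_a_id`, `record_b_id`, `score`,
#'   `sim_name`, `sim_age`, `sim_date`.
#' @export
propose_matches <- function(list_a, list_b, config = match_config()) {
  stopifnot(inherits(config, "match_config"))
  empty <- data.frame(
    record_a_id = character(), record_b_id = character(), score = numeric(),
    sim_name = numeric(), sim_age = numeric(), sim_date = numeric(),
    stringsAsFactors = FALSE
  )
  if (nrow(list_a) == 0 || nrow(list_b) == 0) return(empty)
  if (any(!nzchar(list_a$village_id)) || any(!nzchar(list_b$village_id))) {
    stop("unblockable record: village_id missing", call. = FALSE)
  }
  if (length(intersect(unique(list_a$network), unique(list_b$network)))) {
    stop("candidate lists must come from distinct networks", call. = FALSE)
  }
  shared <- intersect(unique(list_a$village_id), unique(list_b$village_id))
  rows <- list()
  for (v in shared) {
    av <- list_a[list_a$village_id == v, , drop = FALSE]
    bv <- list_b[list_b$village_id == v, , drop = FALSE]
    for (i in seq_len(nrow(av))) {
      for (j in seq_len(nrow(bv))) {
        s <- score_pair(av[i, ], bv[j, ], config)
        if (s["score"] >= config$propose_threshold) {
          rows[[length(rows) + 1L]] <- data.frame(
            record_a_id = av$record_id[i], record_b_id = bv$record_id[j],
            score = s[["score"]], sim_name = s[["sim_name"]],
            sim_age = s[["sim_age"]], sim_date = s[["sim_date"]],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$record_a_id, out$record_b_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve candidate pairs to a one-to-one matching
#'
#' Greedy descending-score selection under the one-to-one constraint: each
#' record joins at most one accepted pair. Pairs explicitly confirmed as the
#' same person (by the follow-up visit) are forced in first regardless of
#' score; pairs confirmed different are excluded regardless of score. Equal
#' scores are broken by `(record_a_id, record_b_id)` lexicographic order, so
#' resolution is deterministic.
#'
#' @param candidates a candidate data.frame from [propose_matches()].
#' @param confirmations optional data.frame with columns `record_a_id`,
#'   `record_b_id`, `is_same_person` (logical or 0/1) referencing proposed
#'   pairs.
#' @return the accepted subset of `candidates`, one-to-one in both id columns.
#' @export
resolve_matches <- function(candidates, confirmations = NULL) {
  if (nrow(candidates) == 0) return(candidates)
  key <- function(a, b) paste(a, b, sep = "\r")
  cand_key <- key(candidates$record_a_id, candidates$record_b_id)
  forced_in <- character()
  forced_out <- character()
  if (!is.null(confirmations) && nrow(confirmations)) {
    conf_key <- key(confirmations$record_a_id, confirmations$record_b_id)
    unknown <- setdiff(conf_key, cand_key)
    if (length(unknown)) {
      stop(
        "confirmations reference unknown candidate pairs: ",
        paste(gsub("\r", "/", unknown), collapse = ", "), call. = FALSE
      )
    }
    same <- as.logical(confirmations$is_same_person)
    forced_in <- conf_key[same]
    forced_out <- conf_key[!same]
  }
  forced_first <- cand_key %in% forced_in
  ord <- order(
    forced_first, candidates$score,
    candidates$record_a_id, candidates$record_b_id,
    decreasing = c(TRUE, TRUE, FALSE, FALSE), method = "radix"
  )
  cand <- candidates[ord, , drop = FALSE]
  ckey <- cand_key[ord]
  used_a <- character()
  used_b <- character()
  take <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (ckey[i] %in% forced_out) next
    if (cand$record_a_id[i] %in% used_a || cand$record_b_id[i] %in% used_b) next
    take[i] <- TRUE
    used_a <- c(used_a, cand$record_a_id[i])
    used_b <- c(used_b, cand$record_b_id[i])
  }
  out <- cand[take, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Deduplicate a single network's listing
#'
#' Two informants of the same network can report the same death; the listing
#' meeting resolves these into one consolidated entry. This applies the same
#' scorer within one listing (pairs of distinct records in the same village at
#' or above `auto_accept`) and merges connected duplicates, keeping the first
#' record (by id) as representative; `assigned_prd` is the OR over merged
#' records.
#'
#' @param records a validated listing data.frame (one network).
#' @param config a [match_config()].
#' @return the deduplicated listing.
#' @export
dedupe_within_network <- function(records, config = match_config()) {
  n <- nrow(records)
  if (n < 2) return(records)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  ord <- order(records$record_id)
  records <- records[ord, , drop = FALSE]
  for (v in unique(records$village_id)) {
    idx <- which(records$village_id == v)
    if (length(idx) < 2) next
    for (ii in seq_along(idx)[-length(idx)]) {
      for (jj in seq((ii + 1), length(idx))) {
        i <- idx[ii]; j <- idx[jj]
        s <- score_pair(records[i, ], records[j, ], config)
        if (s[["score"]] >= config$auto_accept) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  keep <- !duplicated(root)
  merged <- records[keep, , drop = FALSE]
  merged$assigned_prd <- vapply(
    root[keep], function(r) any(records$assigned_prd[root == r]), logical(1)
  )
  rownames(merged) <- NULL
  merged
}

#' Consolidate two network listings into one death list
#'
#' Each accepted cross-network pair becomes one consolidated death captured by
#' both networks; unmatched records become singleton deaths captured by one.
#' Every input record lands in exactly one consolidated death. The returned
#' capture summary counts deaths passing `keep` (by default, all), with
#' network A = RT and network B = kader.
#'
#' @param list_a,list_b validated listings from distinct networks.
#' @param matching an accepted pair data.frame from [resolve_matches()].
#' @param keep optional function `(deaths data.frame) -> logical` selecting
#'   which consolidated deaths enter the capture summary (e.g. verified
#'   eligible PRDs only).
#' @return a list with `deaths` (one row per consolidated death:
#'   `consolidated_id`, `captured_by_kader`, `captured_by_rt`,
#'   `assigned_prd_any`, `village_id`, `stratum`, `name`, `age_years`,
#'   `date_of_death`, `out_of_window`), `members` (record-level rows carrying
#'   `consolidated_id`), and `capture` (a [capture_summary()]).
#' @export
consolidate <- function(list_a, list_b, matching, keep = NULL) {
  all_records <- rbind(
    list_a[intersect(names(list_a), names(list_b))],
    list_b[intersect(names(list_a), names(list_b))]
  )
  if (anyDuplicated(all_records$record_id)) {
    stop("record ids must be unique across the two listings", call. = FALSE)
  }
  if (nrow(all_records) == 0) {
    deaths <- data.frame(
      consolidated_id = character(), captured_by_kader = logical(),
      captured_by_rt = logical(), assigned_prd_any = logical(),
      village_id = character(), stratum = character(), name = character(),
      age_years = integer(), date_of_death = as.Date(character()),
      out_of_window = logical(), stringsAsFactors = FALSE
    )
    members <- cbind(all_records, consolidated_id = character())
    return(list(
      deaths = deaths, members = members, capture = capture_summary(0, 0, 0)
    ))
  }
  group <- as.list(all_records$record_id)
  names(group) <- all_records$record_id
  if (nrow(matching)) {
    for (i in seq_len(nrow(matching))) {
      a <- matching$record_a_id[i]
      b <- matching$record_b_id[i]
      group[[a]] <- sort(c(a, b))
      group[[b]] <- NULL
    }
  }
  # stable, content-derived consolidated ids: order groups by smallest member id
  group <- group[order(vapply(group, `[`, character(1), 1))]
  ids <- sprintf("C%04d", seq_along(group))
  rec_index <- match(unlist(group), all_records$record_id)
  members <- all_records[rec_index, , drop = FALSE]
  members$consolidated_id <- rep(ids, lengths(group))
  rownames(members) <- NULL

  deaths <- do.call(rbind, lapply(seq_along(group), function(g) {
    mem <- members[members$consolidated_id == ids[g], , drop = FALSE]
    if (length(unique(mem$village_id)) != 1) {
      stop("members of one consolidated death must share a village", call. = FALSE)
    }
    dod <- mem$date_of_death[!is.na(mem$date_of_death)]
    data.frame(
      consolidated_id = ids[g],
      captured_by_kader = any(mem$network == "kader"),
      captured_by_rt = any(mem$network == "rt"),
      assigned_prd_any = any(mem$assigned_prd),
      village_id = mem$village_id[1],
      stratum = mem$stratum[1],
      name = mem$name[1],
      age_years = if (all(is.na(mem$age_years))) NA_integer_ else
        as.integer(round(mean(mem$age_years, na.rm = TRUE))),
      date_of_death = if (length(dod)) min(dod) else as.Date(NA),
      out_of_window = all(mem$out_of_window),
      stringsAsFactors = FALSE
    )
  }))
  rownames(deaths) <- NULL
  sel <- if (is.null(keep)) rep(TRUE, nrow(deaths)) else keep(deaths)
  list(
    deaths = deaths,
    members = members,
    capture = capture_summary_from_deaths(deaths, sel)
  )
}

#' Write consolidated matches to CSV
#'
#' One row per consolidated death: `consolidated_id`, the member record ids
#' joined with `;`, the capturing networks joined with `;`, and the minimum
#' accepted pair score inside the group (1 for singletons).
#'
#' @param consolidation result of [consolidate()].
#' @param matching the accepted pairs used to consolidate.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matches_csv <- function(consolidation, matching, path) {
  members <- consolidation$members
  score_min <- vapply(consolidation$deaths$consolidated_id, function(cid) {
    mem_ids <- members$record_id[members$consolidated_id == cid]
    if (length(mem_ids) < 2 || nrow(matching) == 0) return(1)
    hit <- matching$record_a_id %in% mem_ids & matching$record_b_id %in% mem_ids
    if (!any(hit)) 1 else min(matching$score[hit])
  }, numeric(1))
  out <- data.frame(
    consolidated_id = consolidation$deaths$consolidated_id,
    record_ids = vapply(consolidation$deaths$consolidated_id, function(cid) {
      paste(sort(members$record_id[members$consolidated_id == cid]), collapse = ";")
    }, character(1)),
    captured_by = ifelse(
      consolidation$deaths$captured_by_kader & consolidation$deaths$captured_by_rt,
      "kader;rt",
      ifelse(consolidation$deaths$captured_by_kader, "kader", "rt")
    ),
    score_min = score_min,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
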