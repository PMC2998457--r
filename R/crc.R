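#' Lincoln-Petersen capture-recapture estimate
#'
#' The classical two-source estimator of a closed population total:
#' `T = n_a * n_b / m`, where `n_a` and `n_b` are the counts captured by each
#' source and `m` the count captured by both. The implied capture
#' probabilities are `p_a = m / n_b` and `p_b = m / n_a` (algebraically equal
#' to `n_a / T` and `n_b / T`), and the estimated number of deaths missed by
#' both networks is `round(T) - union`. Arithmetic is carried at full
#' precision; `total` is the half-away-from-zero rounding of `total_raw`.
#'
#' Undefined when `m = 0` (no overlap): use [chapman()] or [bayesian_total()]
#' instead.
#'
#' @param capture a [capture_summary()].
#' @return an object of class `crc_estimate` with fields `total_raw`, `total`,
#'   `p_a`, `p_b`, `missed`, `method`, `capture`.
#' @examples
#' lincoln_petersen(capture_summary(n_a = 103, n_b = 86, m = 73))
#' @export
lincoln_petersen <- function(capture) {
  stopifnot(inherits(capture, "capture_summary"))
  if (capture$m == 0) {
    stop(
      "no overlap: Lincoln-Petersen undefined; use chapman() or bayesian_total()",
      call. = FALSE
    )
  }
  total_raw <- capture$n_a * capture$n_b / capture$m
  total <- as.integer(round_half_out(total_raw))
  structure(
    list(
      total_raw = total_raw, total = total,
      p_a = capture$m / capture$n_b, p_b = capture$m / capture$n_a,
      missed = total - capture$union,
      method = "lincoln_petersen", capture = capture
    ),
    class = "crc_estimate"
  )
}

#' Chapman small-sample capture-recapture estimate
#'
#' The bias-corrected two-source estimator
#' `T = (n_a + 1)(n_b + 1) / (m + 1) - 1`, defined even with no overlap
#' (`m = 0`), where Lincoln-Petersen breaks down.
#'
#' @inheritParams lincoln_petersen
#' @return a `crc_estimate` (see [lincoln_petersen()]); capture probabilities
#'   are reported as `n / total_raw` (and `NA` when the estimate is 0).
#' @examples
#' chapman(capture_summary(n_a = 5, n_b = 5, m = 0))
#' @export
chapman <- function(capture) {
  stopifnot(inherits(capture, "capture_summary"))
  total_raw <- (capture$n_a + 1) * (capture$n_b + 1) / (capture$m + 1) - 1
  total <- as.integer(round_half_out(total_raw))
  structure(
    list(
      total_raw = total_raw, total = total,
      p_a = if (total_raw > 0) capture$n_a / total_raw else NA_real_,
      p_b = if (total_raw > 0) capture$n_b / total_raw else NA_real_,
      missed = total - capture$union,
      method = "chapman", capture = capture
    ),
    class = "crc_estimate"
  )
}

#' @export
print.crc_estimate <- function(x, ...) {
  cat(sprintf("Capture-recapture estimate (%s)\n", x$method))
  cat(sprintf(
    "  counts: n_a=%d n_b=%d m=%d union=%d\n",
    x$capture$n_a, x$capture$n_b, x$capture$m, x$capture$union
  ))
  cat(sprintf("  estimated total: %d (%.2f unrounded)\n", x$total, x$total_raw))
  cat(sprintf(
    "  capture probabilities: p_a=%.2f p_b=%.2f\n", x$p_a, x$p_b
  ))
  cat(sprintf("  estimated missed by both: %d\n", x$missed))
  invisible(x)
}

#' Extrapolate a single-network count to a total
#'
#' In strata covered by only one informant network, the total is estimated by
#' dividing that network's verified count by its capture probability as
#' estimated in the dual-network stratum — using the unrounded probability
#' (`m / n_other`), not its printed two-decimal form.
#'
#' @param n_single verified count captured by the single network.
#' @param p_capture capture probability in `(0, 1]`, e.g. `est$p_b` from the
#'   dual-stratum [lincoln_petersen()] fit.
#' @return an object of class `crc_extrapolation` with `total_raw` and the
#'   rounded `total`.
#' @examples
#' dual <- lincoln_petersen(capture_summary(103, 86, 73))
#' extrapolate_single_network(353, dual$p_b)
#' @export
extrapolate_single_network <- function(n_single, p_capture) {
  if (is.na(p_capture) || p_capture <= 0 || p_capture > 1) {
    stop("p_capture must lie in (0, 1]", call. = FALSE)
  }
  if (n_single < 0) stop("n_single must be non-negative", call. = FALSE)
  total_raw <- n_single / p_capture
  structure(
    list(
      n_single = n_single, p_capture = p_capture,
      total_raw = total_raw, total = as.integer(round_half_out(total_raw))
    ),
    class = "crc_extrapolation"
  )
}

#' @export
print.crc_extrapolation <- function(x, ...) {
  cat(sprintf(
    "Single-network extrapolation: %d / %.4f = %.2f (%d rounded)\n",
    x$n_single, x$p_capture, x$total_raw, x$total
  ))
  invisible(x)
}

#' Combine stratum totals
#'
#' Sums the unrounded stratum point estimates (dual-network estimate plus any
#' single-network extrapolations) and rounds once at the end. Note that a
#' Bayesian posterior mean over the same strata is a different quantity from
#' this sum of point estimates.
#'
#' @param dual_estimate a `crc_estimate`.
#' @param single_estimates list of `crc_extrapolation` objects (may be empty).
#' @return a list with `total_raw` and rounded `total`.
#' @export
combine_strata <- function(dual_estimate, single_estimates = list()) {
  stopifnot(inherits(dual_estimate, "crc_estimate"))
  if (inherits(single_estimates, "crc_extrapolation")) {
    single_estimates <- list(single_estimates)
  }
  singles <- vapply(
    single_estimates,
    function(e) {
      stopifnot(inherits(e, "crc_extrapolation"))
      e$total_raw
    },
    numeric(1)
  )
  total_raw <- dual_estimate$total_raw + sum(singles)
  list(total_raw = total_raw, total = as.integer(round_half_out(total_raw)))
}
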