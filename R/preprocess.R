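#' Trim response times to the analysis window
#'
#' Removes trials whose RT falls below \code{lower} or above \code{upper}
#' (defaults 250 and 1500 ms, the conventional window for masked-priming
#' recognition latencies).  Bounds are inclusive: a trial at exactly 250 or
#' 1500 ms is kept.  The exclusion report flags (with an R warning) any run
#' that discards 5\% or more of the trials, the usual upper limit aimed for
#' with this window; the run itself is never aborted.
#'
#' @param trials data frame of trials with a numeric \code{rt_ms} column.
#' @param lower,upper trimming bounds in ms, \code{lower < upper}.
#' @return list with elements \code{trials} (the kept rows) and
#'   \code{report}, a list with \code{n_total}, \code{n_rt_excluded},
#'   \code{n_kept}, \code{fraction_rt_excluded}, \code{warning_flag}.
#' @export
trim_rts <- function(trials, lower = 250, upper = 1500) {
  stopifnot(is.data.frame(trials), "rt_ms" %in% names(trials))
  if (!(lower < upper)) stop("trimming needs lower < upper", call. = FALSE)
  n_total <- nrow(trials)
  keep <- trials$rt_ms >= lower & trials$rt_ms <= upper
  n_excl <- sum(!keep)
  frac <- if (n_total > 0) n_excl / n_total else 0
  flag <- frac >= 0.05
  if (flag) {
    warning(sprintf("RT trimming excluded %.1f%% of trials (aim is < 5%%)",
                    100 * frac), call. = FALSE)
  }
  list(
    trials = trials[keep, , drop = FALSE],
    report = list(n_total = n_total, n_rt_excluded = n_excl,
                  n_kept = n_total - n_excl,
                  fraction_rt_excluded = frac, warning_flag = flag)
  )
}

#' Keep only correct responses
#'
#' Incorrect responses are excluded from all RT analyses; for distractor
#' stimuli "correct" means a correct rejection.  Row order is preserved and
#' the operation is idempotent.
#'
#' @param trials data frame with a \code{correct} column coded 0/1 (or
#'   logical).
#' @return the subset of rows with \code{correct == 1}.
#' @export
filter_correct <- function(trials) {
  stopifnot(is.data.frame(trials), "correct" %in% names(trials))
  trials[as.logical(trials$correct), , drop = FALSE]
}

#' Pool response times by condition cell
#'
#' Concatenates RTs across participants within each of the 32 condition
#' cells (target nature x country x role x prime).  Every cell of the full
#' design is present in the result; cells without data map to empty vectors.
#' Intended to run on trials that have already been trimmed and
#' correctness-filtered.
#'
#' @param trials data frame with columns \code{target_nature},
#'   \code{country}, \code{role}, \code{prime}, \code{rt_ms}.
#' @return named list of numeric RT vectors, one per condition cell, in the
#'   canonical order of \code{\link{condition_keys}}; names are the
#'   \code{"target:country:role:prime"} cell ids.
#' @export
pool_by_condition <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("target_nature", "country", "role", "prime", "rt_ms")
                %in% names(trials)))
  keys <- condition_keys()
  ids <- condition_id(keys)
  pools <- stats::setNames(rep(list(numeric(0)), length(ids)), ids)
  if (nrow(trials) > 0) {
    got <- split(trials$rt_ms, factor(condition_id(trials), levels = ids))
    pools[names(got)] <- got
  }
  pools
}
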