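#' Read and write trial-level CSV tables
#'
#' The trial CSV schema is: \code{participant_id}, \code{country},
#' \code{target_nature}, \code{role}, \code{prime}, \code{rt_ms},
#' \code{correct} (0/1); UTF-8, comma-separated, header row.  The same
#' schema accepts real experimental exports.  \code{read_trials} validates
#' every column and reports the offending column and line on failure;
#' write-then-read reproduces the table exactly.
#'
#' @param path file path.
#' @param trials trial data frame.
#' @return \code{read_trials}: the validated trial data frame;
#'   \code{write_trials}: \code{path}, invisibly.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("cannot read trials: ", path, call. = FALSE)
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "country", "target_nature", "role", "prime",
            "rt_ms", "correct")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0) {
    stop("trial CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  # +1 for the header row when naming lines
  check_levels <- function(col, levels) {
    bad <- which(!(tr[[col]] %in% levels))
    if (length(bad) > 0) {
      stop(sprintf("invalid value '%s' in column '%s' at line %d",
                   tr[[col]][bad[1L]], col, bad[1L] + 1L), call. = FALSE)
    }
  }
  check_levels("country", c("spain", "usa"))
  check_levels("target_nature", c("face", "name"))
  check_levels("role", c("test", "distracting"))
  check_levels("prime", unique(condition_keys()$prime))
  check_levels("correct", c(0L, 1L))
  bad_rt <- which(!is.finite(tr$rt_ms) | tr$rt_ms <= 0)
  if (length(bad_rt) > 0) {
    stop(sprintf("invalid value '%s' in column 'rt_ms' at line %d",
                 tr$rt_ms[bad_rt[1L]], bad_rt[1L] + 1L), call. = FALSE)
  }
  tr[need]
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a condition report as TSV
#'
#' Serialises a \code{\link{run_pipeline}} report in the conventional
#' column order (hit \%, M, S, t, mu, sigma, tau, p), rounding the
#' descriptive and component columns to two decimals and the bootstrap p to
#' two decimals (so a computed 0.004 prints as 0.00).  The returned report
#' object keeps full precision; only the file is rounded.
#'
#' @param report data frame from \code{\link{run_pipeline}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(is.data.frame(report))
  out <- report
  for (col in c("hit_pct", "M", "S", "mu", "sigma", "tau",
                "sd_mu", "sd_sigma", "sd_tau")) {
    if (col %in% names(out)) out[[col]] <- sprintf("%.2f", out[[col]])
  }
  if ("t" %in% names(out)) out$t <- sprintf("%.2f", out$t)
  if ("gof_p" %in% names(out)) out$gof_p <- sprintf("%.2f", out$gof_p)
  for (col in names(out)) {
    if (is.character(out[[col]])) out[[col]][out[[col]] == "NA"] <- ""
    else if (anyNA(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "", as.character(out[[col]]))
    }
  }
  first <- c("target_nature", "country", "role", "prime",
             "hit_pct", "M", "S", "t", "mu", "sigma", "tau", "gof_p")
  out <- out[, c(first, setdiff(names(out), first)), drop = FALSE]
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
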