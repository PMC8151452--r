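#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with the reference
#' defaults: 250-1500 ms trimming window, gradient tolerance 1e-8, 1000
#' bootstrap samples for the KS p-value, 1024 iso-surface points at half a
#' log-likelihood point below the maximum, 1.96 scaling for 95\% intervals.
#'
#' @param rt_lower,rt_upper trimming bounds, ms.
#' @param eps gradient-norm convergence tolerance of the MLE.
#' @param max_iter iteration cap of the MLE.
#' @param n_boot bootstrap samples for the goodness-of-fit p-value.
#' @param gof_refit refit each bootstrap sample (Lilliefors-style)?
#' @param surface_points iso-surface points per cell (>= 1000).
#' @param surface_delta log-likelihood drop defining the surface.
#' @param compute_uncertainty sample the iso-surface per cell?  Skipping it
#'   (\code{FALSE}) leaves the sd columns empty and saves most of the
#'   runtime.
#' @param seed master seed for the bootstrap and surface sampling.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(rt_lower = 250, rt_upper = 1500,
                            eps = 1e-8, max_iter = 1e5,
                            n_boot = 1000, gof_refit = FALSE,
                            surface_points = 1024, surface_delta = 0.5,
                            compute_uncertainty = TRUE, seed = NULL) {
  stopifnot(rt_lower < rt_upper, eps > 0, n_boot >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full RT-decomposition pipeline
#'
#' From trial-level data to a condition report: per-cell hit rates are
#' computed on all trials; RTs of incorrect responses are excluded and the
#' remainder trimmed to the window; the surviving RTs are pooled across
#' participants within each of the 32 condition cells; each pooled cell is
#' fitted by maximum-likelihood gradient ascent from moment-based starts;
#' the fit quality is calibrated by parametric-bootstrap KS; parameter
#' uncertainties are optionally read off the half-point iso-likelihood
#' surface.  Failures degrade the affected row's \code{status}
#' (\code{insufficient_data} below 10 pooled RTs, \code{not_converged});
#' they never abort the run.
#'
#' @param trials trial data frame (see \code{\link{read_trials}}).
#' @param config a \code{\link{pipeline_config}}.
#' @return data frame with one row per condition cell: the key columns,
#'   \code{n_trials}, \code{hit_pct}, \code{n_pooled}, \code{M}, \code{S},
#'   \code{t}, \code{mu}, \code{sigma}, \code{tau}, \code{gof_p},
#'   \code{sd_mu}, \code{sd_sigma}, \code{sd_tau}, \code{iterations},
#'   \code{gradient_norm}, \code{status}.  Carries the trimming exclusion
#'   report in attribute \code{"exclusions"}.
#' @examples
#' \donttest{
#' trials <- generate_cohort(cohort_design(4, 14, seed = 1))
#' rep <- run_pipeline(trials, pipeline_config(n_boot = 99,
#'                                             compute_uncertainty = FALSE,
#'                                             seed = 1))
#' }
#' @export
run_pipeline <- function(trials, config = pipeline_config()) {
  stopifnot(is.data.frame(trials), inherits(config, "pipeline_config"))
  if (nrow(trials) == 0) stop("no trials to analyse", call. = FALSE)

  keys <- condition_keys()
  ids <- condition_id(keys)
  cell_of_trial <- factor(condition_id(trials), levels = ids)

  n_trials <- as.integer(table(cell_of_trial))
  hit_pct <- 100 * as.numeric(
    tapply(trials$correct, cell_of_trial, mean, default = NA_real_))

  correct <- filter_correct(trials)
  trimmed <- trim_rts(correct, config$rt_lower, config$rt_upper)
  exclusions <- trimmed$report
  exclusions$n_incorrect_excluded <- nrow(trials) - nrow(correct)
  pools <- pool_by_condition(trimmed$trials)

  nc <- nrow(keys)
  num <- function() rep(NA_real_, nc)
  out <- data.frame(
    keys, n_trials = n_trials, hit_pct = hit_pct,
    n_pooled = vapply(pools, length, integer(1))[ids],
    M = num(), S = num(), t = num(),
    mu = num(), sigma = num(), tau = num(), gof_p = num(),
    sd_mu = num(), sd_sigma = num(), sd_tau = num(),
    iterations = rep(NA_integer_, nc), gradient_norm = num(),
    status = rep("ok", nc),
    stringsAsFactors = FALSE, row.names = NULL
  )

  for (k in seq_len(nc)) {
    rts <- pools[[ids[k]]]
    if (length(rts) < 10L) {
      out$status[k] <- "insufficient_data"
      next
    }
    st <- compute_sample_stats(rts)
    out$M[k] <- st$M; out$S[k] <- st$S; out$t[k] <- st$t
    fit <- fit_exgauss(rts, eps = config$eps, max_iter = config$max_iter)
    out$mu[k] <- fit$par["mu"]
    out$sigma[k] <- fit$par["sigma"]
    out$tau[k] <- fit$par["tau"]
    out$iterations[k] <- fit$iterations
    out$gradient_norm[k] <- fit$gradient_norm
    if (!fit$converged) {
      out$status[k] <- "not_converged"
      next
    }
    gof <- exgauss_gof(rts, fit, n_boot = config$n_boot,
                       refit = config$gof_refit,
                       seed = derive_seed(config$seed, k))
    out$gof_p[k] <- gof$p_value
    if (isTRUE(config$compute_uncertainty)) {
      surf <- sample_iso_surface(rts, fit, delta = config$surface_delta,
                                 n_points = config$surface_points,
                                 seed = derive_seed(config$seed, 1000 + k))
      unc <- surface_uncertainties(surf, fit)
      out$sd_mu[k] <- unc$sd["mu"]
      out$sd_sigma[k] <- unc$sd["sigma"]
      out$sd_tau[k] <- unc$sd["tau"]
    }
  }
  attr(out, "exclusions") <- exclusions
  out
}

#' Histogram-ready binned RT counts per condition cell
#'
#' Bins the pooled (trimmed, correct-only) RTs of each condition cell on a
#' fixed grid for external plotting.  Binning is output-only: the MLE always
#' consumes the raw RT values.
#'
#' @param pools named list of pooled RT vectors from
#'   \code{\link{pool_by_condition}}.
#' @param binwidth bin width in ms.
#' @param lower,upper grid range, ms.
#' @return data frame with the cell id and key columns, \code{bin_lo},
#'   \code{bin_hi}, \code{count}.
#' @export
condition_histograms <- function(pools, binwidth = 50,
                                 lower = 250, upper = 1500) {
  stopifnot(binwidth > 0, lower < upper)
  breaks <- seq(lower, upper + binwidth, by = binwidth)
  keys <- condition_keys()
  ids <- condition_id(keys)
  res <- lapply(seq_along(ids), function(k) {
    rts <- pools[[ids[k]]]
    counts <- if (length(rts) > 0) {
      tabulate(findInterval(rts, breaks, rightmost.closed = TRUE),
               nbins = length(breaks) - 1L)
    } else {
      integer(length(breaks) - 1L)
    }
    data.frame(keys[k, , drop = FALSE],
               bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
               count = counts, row.names = NULL)
  })
  do.call(rbind, res)
}
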