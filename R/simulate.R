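#' Cohort design for the synthetic masked-priming experiment
#'
#' Describes the simulated study layout: two country groups of
#' \code{participants_per_country} university students each, every
#' participant seeing all 16 cells of their country's sub-design (target
#' face/name x test/distracting role x 4 prime conditions) at
#' \code{trials_per_cell} trials per cell.  The defaults (50 + 50
#' participants, 14 trials per cell) give the study's 224 trials per
#' participant: 2 tasks x 4 primes x (14 test + 14 distractor repetitions)
#' of the 28 test and 28 distractor stimuli.  Prime-sequence timings are
#' carried as metadata only (fixation 50 ms, prime 50 ms, mask 500 ms,
#' target up to 500 ms); they do not influence the simulated RTs.
#'
#' @param participants_per_country participants per country group.
#' @param trials_per_cell trials per participant per condition cell.
#' @param seed optional master seed; per-participant substreams are derived
#'   deterministically from it, so the same seed reproduces the same cohort
#'   bit for bit.
#' @return list of class \code{"cohort_design"}.
#' @export
cohort_design <- function(participants_per_country = 50,
                          trials_per_cell = 14,
                          seed = NULL) {
  stopifnot(participants_per_country >= 1, trials_per_cell >= 1)
  structure(list(
    participants_per_country = as.integer(participants_per_country),
    trials_per_cell = as.integer(trials_per_cell),
    prime_durations = c(fixation_ms = 50, prime_ms = 50, mask_ms = 500,
                        target_max_ms = 500),
    seed = seed
  ), class = "cohort_design")
}

#' Generate a synthetic trial-level cohort
#'
#' Draws one trial record per (participant, cell, repetition).  Clean RTs
#' are ex-Gaussian draws from the cell's (mu, sigma, tau); with probability
#' \code{contamination_rate} a trial's RT is instead a contaminant drawn
#' uniformly from outside the 250-1500 ms trimming window (on
#' \code{[80, 250) U (1500, 2500]} ms) — a synthetic-only device to give the
#' trimming stage something to remove.  Correctness is Bernoulli at the
#' cell's hit rate.  RTs are rounded to 0.001 ms so the CSV round trip is
#' exact.
#'
#' @param design a \code{\link{cohort_design}}.
#' @param specs condition table as from \code{\link{default_condition_table}}:
#'   one row per cell with \code{mu}, \code{sigma}, \code{tau},
#'   \code{hit_rate}, \code{contamination_rate}.
#' @return data frame of trials: \code{participant_id}, \code{country},
#'   \code{target_nature}, \code{role}, \code{prime}, \code{rt_ms},
#'   \code{correct} (0/1).
#' @examples
#' trials <- generate_cohort(cohort_design(2, 14, seed = 1))
#' nrow(trials)  # 2 countries x 2 participants x 224 trials
#' @export
generate_cohort <- function(design = cohort_design(),
                            specs = default_condition_table()) {
  stopifnot(inherits(design, "cohort_design"), is.data.frame(specs))
  keys <- condition_keys()
  need <- condition_id(keys)
  have <- condition_id(specs)
  missing <- setdiff(need, have)
  if (length(missing) > 0) {
    stop("missing condition spec for key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  specs <- specs[match(need, have), , drop = FALSE]
  m <- design$trials_per_cell
  out <- vector("list", 2L * design$participants_per_country)
  pid <- 0L
  for (ct in c("spain", "usa")) {
    cells <- specs[specs$country == ct, , drop = FALSE]  # 16 rows
    prefix <- if (ct == "spain") "sp" else "us"
    for (i in seq_len(design$participants_per_country)) {
      pid <- pid + 1L
      trials <- with_seed(derive_seed(design$seed, pid), {
        nt <- nrow(cells) * m
        cell_ix <- rep(seq_len(nrow(cells)), each = m)
        rt <- stats::rnorm(nt, cells$mu[cell_ix], cells$sigma[cell_ix]) +
          stats::rexp(nt, rate = 1 / cells$tau[cell_ix])
        contam <- stats::runif(nt) < cells$contamination_rate[cell_ix]
        if (any(contam)) {
          # uniform over [80, 250) U (1500, 2500]: total mass 170 + 1000 ms
          u <- stats::runif(sum(contam), 0, 1170)
          rt[contam] <- ifelse(u < 170, 80 + u, 1500 + (u - 170))
        }
        correct <- stats::rbinom(nt, 1L, cells$hit_rate[cell_ix])
        data.frame(
          participant_id = sprintf("%s%03d", prefix, i),
          country = ct,
          target_nature = cells$target_nature[cell_ix],
          role = cells$role[cell_ix],
          prime = cells$prime[cell_ix],
          rt_ms = round(rt, 3),
          correct = correct,
          stringsAsFactors = FALSE
        )
      })
      out[[pid]] <- trials
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
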