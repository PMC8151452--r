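#' The 32 condition cells of the masked-priming design
#'
#' The design crosses target nature (face vs. name) x participant country
#' (Spain vs. USA) x stimulus role (test celebrity vs. unknown distractor)
#' x prime condition (identity, related, unrelated of the same nature,
#' unrelated of a different nature), giving 2 x 2 x 2 x 4 = 32 cells.
#'
#' @return data frame with 32 rows and character columns
#'   \code{target_nature}, \code{country}, \code{role}, \code{prime}, in the
#'   canonical reporting order (all face rows first, Spain before USA, test
#'   before distracting, primes in the order above).
#' @export
condition_keys <- function() {
  primes <- c("identity", "related", "unrelated_same_nature",
              "unrelated_different_nature")
  out <- expand.grid(prime = primes, role = c("test", "distracting"),
                     country = c("spain", "usa"),
                     target_nature = c("face", "name"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out[, c("target_nature", "country", "role", "prime")]
}

#' Canonical id string for condition cells
#'
#' @param key data frame (or list) with \code{target_nature},
#'   \code{country}, \code{role}, \code{prime} entries.
#' @return character vector of \code{"target:country:role:prime"} ids.
#' @export
condition_id <- function(key) {
  paste(key$target_nature, key$country, key$role, key$prime, sep = ":")
}

#' Reference condition table: ex-Gaussian components and hit rates
#'
#' One row per condition cell with the fitted ex-Gaussian components
#' (mu, sigma, tau, in ms) and hit rates reported for the masked-priming
#' celebrity-recognition study of 50 Spanish and 50 US university students.
#' These values parameterise the synthetic cohort generator
#' (\code{\link{generate_cohort}}), so simulated data reproduce the
#' location, spread and skew observed per cell.  \code{contamination_rate}
#' (default 0.02) is the synthetic-only fraction of trials whose RT is
#' replaced by an outlier beyond the 250-1500 ms trimming window; the
#' observed study has no published per-trial data, so this knob exists
#' purely to exercise the trimming stage.
#'
#' @param contamination_rate fraction of contaminant trials per cell, in
#'   \code{[0, 0.5)}.
#' @return data frame with 32 rows: the key columns of
#'   \code{\link{condition_keys}} plus \code{mu}, \code{sigma}, \code{tau},
#'   \code{hit_rate}, \code{contamination_rate}.
#' @export
default_condition_table <- function(contamination_rate = 0.02) {
  if (!is.numeric(contamination_rate) || contamination_rate < 0 ||
      contamination_rate >= 0.5) {
    stop("contamination_rate must lie in [0, 0.5)", call. = FALSE)
  }
  keys <- condition_keys()
  # hit %, mu, sigma, tau per cell, in the canonical key order
  vals <- matrix(c(
    # face / spain / test
    81, 417.56, 18.72, 227.72,
    83, 446.41, 17.37, 228.81,
    83, 498.62, 77.04, 199.30,
    78, 481.05, 61.48, 210.93,
    # face / spain / distracting
    80, 468.39, 70.74, 237.74,
    87, 502.11, 58.64, 226.07,
    86, 483.74, 84.50, 232.73,
    86, 520.84, 71.68, 216.90,
    # face / usa / test
    71, 456.03, 56.71, 215.11,
    76, 451.39, 36.49, 250.15,
    73, 509.77, 54.78, 215.48,
    69, 482.41, 44.27, 246.38,
    # face / usa / distracting
    80, 463.75, 80.76, 249.63,
    87, 498.38, 84.62, 225.55,
    83, 469.98, 87.87, 231.21,
    86, 509.47, 82.87, 223.49,
    # name / spain / test
    79, 483.75, 67.10, 239.76,
    80, 498.17, 63.08, 235.26,
    80, 565.34, 96.59, 210.69,
    80, 532.32, 80.38, 247.98,
    # name / spain / distracting
    86, 582.47, 119.21, 283.59,
    85, 615.45,  93.19, 287.98,
    87, 614.45,  95.48, 309.80,
    86, 563.35,  87.99, 306.72,
    # name / usa / test
    78, 468.30, 60.72, 231.95,
    77, 489.53, 72.59, 229.43,
    78, 537.22, 57.63, 225.53,
    78, 506.51, 67.87, 238.97,
    # name / usa / distracting
    90, 502.44, 87.16, 292.10,
    91, 555.94, 88.33, 267.74,
    91, 547.36, 86.83, 275.37,
    88, 517.38, 88.40, 267.42
  ), ncol = 4L, byrow = TRUE)
  data.frame(
    keys,
    mu = vals[, 2L], sigma = vals[, 3L], tau = vals[, 4L],
    hit_rate = vals[, 1L] / 100,
    contamination_rate = contamination_rate,
    stringsAsFactors = FALSE
  )
}
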