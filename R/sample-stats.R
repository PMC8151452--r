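#' Pooled-sample descriptive statistics M, S and t
#'
#' Computes the mean \code{M}, the standard deviation \code{S} and the
#' skewness statistic \code{t} of a pooled response-time sample.  \code{S}
#' and \code{t} use population (1/n) moments rather than the n-1 sample
#' convention: \code{S = sqrt(mean((x - M)^2))} and
#' \code{t = mean((x - M)^3) / S^3}.  The population convention keeps the
#' moment map exactly invertible against the closed-form ex-Gaussian moments
#' (\code{\link{exgauss_moments}}), which is what the starting-value algebra
#' of \code{\link{moment_start}} relies on.
#'
#' @param rts numeric vector of response times (ms), length >= 2.
#' @return an object of class \code{"sample_stats"}: a list with elements
#'   \code{n}, \code{M}, \code{S}, \code{t}.
#' @examples
#' compute_sample_stats(c(1, 2, 3, 10))  # M = 4, S = 3.5355, t = 1.0182
#' @export
compute_sample_stats <- function(rts) {
  rts <- as.numeric(rts)
  if (length(rts) < 2L || !all(is.finite(rts))) {
    stop("degenerate sample: need at least 2 finite response times",
         call. = FALSE)
  }
  n <- length(rts)
  M <- mean(rts)
  d <- rts - M
  S <- sqrt(mean(d^2))
  if (S == 0) {
    stop("degenerate sample: all response times identical (S = 0)",
         call. = FALSE)
  }
  structure(list(n = n, M = M, S = S, t = mean(d^3) / S^3),
            class = "sample_stats")
}

#' @export
print.sample_stats <- function(x, ...) {
  cat(sprintf("RT sample: n = %d, M = %.2f ms, S = %.2f ms, t = %.3f\n",
              x$n, x$M, x$S, x$t))
  invisible(x)
}
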