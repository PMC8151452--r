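#' Kolmogorov-Smirnov statistic against a fitted ex-Gaussian
#'
#' Supremum distance between the empirical CDF of the sample and the
#' ex-Gaussian CDF at \code{p}: over the sorted sample,
#' \eqn{D = \max_i \max(i/n - F(x_i),\; F(x_i) - (i-1)/n)}.
#'
#' @param rts numeric RT vector, length >= 1.
#' @param p parameter triple (fit object, named vector or list).
#' @return the KS statistic, in \code{[0, 1]}.
#' @export
ks_statistic <- function(rts, p) {
  p <- as_exgauss_par(p)
  n <- length(rts)
  if (n < 1L) stop("KS statistic needs at least one observation", call. = FALSE)
  Fx <- pexgauss(sort(rts), p[1L], p[2L], p[3L])
  i <- seq_len(n)
  max(pmax(i / n - Fx, Fx - (i - 1) / n))
}

#' Parametric-bootstrap goodness of fit for an ex-Gaussian fit
#'
#' Calibrates the KS statistic of the data against its fitted ex-Gaussian by
#' parametric bootstrap: \code{n_boot} samples (default 1000) of the same
#' size are drawn from the fitted distribution and the p-value is the
#' fraction whose KS statistic exceeds the observed one (ties counted
#' towards the larger p).  The larger the p-value, the better the fit.
#'
#' With \code{refit = FALSE} (the default) each bootstrap KS is computed
#' against the same fixed fitted parameters.  \code{refit = TRUE} refits
#' every bootstrap sample first (the Lilliefors-style calibration, which
#' accounts for the parameters having been estimated from the data and is
#' the statistically conservative variant).
#'
#' @param rts numeric RT vector, length >= 10.
#' @param p fitted parameter triple.
#' @param n_boot number of bootstrap samples.
#' @param refit logical; refit each bootstrap sample before its KS?
#' @param seed optional seed for reproducible p-values.
#' @return object of class \code{"exgauss_gof"}: list with
#'   \code{ks_statistic}, \code{p_value}, \code{n_boot}, \code{refit},
#'   \code{n}.
#' @export
exgauss_gof <- function(rts, p, n_boot = 1000, refit = FALSE, seed = NULL) {
  par <- as_exgauss_par(p)
  n <- length(rts)
  if (n < 10L) {
    stop("insufficient data: bootstrap GoF needs at least 10 response times",
         call. = FALSE)
  }
  d_obs <- ks_statistic(rts, par)
  d_boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      y <- stats::rnorm(n, par[1L], par[2L]) + stats::rexp(n, 1 / par[3L])
      pb <- if (refit) fit_exgauss(y)$par else par
      ks_statistic(y, pb)
    }, numeric(1))
  })
  structure(list(
    ks_statistic = d_obs,
    p_value = sum(d_boot >= d_obs) / n_boot,
    n_boot = as.integer(n_boot),
    refit = refit,
    n = n
  ), class = "exgauss_gof")
}

#' @export
print.exgauss_gof <- function(x, ...) {
  cat(sprintf("KS = %.4f, bootstrap p = %.3f (%d samples%s, n = %d)\n",
              x$ks_statistic, x$p_value, x$n_boot,
              if (x$refit) ", refitted" else "", x$n))
  invisible(x)
}
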