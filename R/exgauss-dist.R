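#' The ex-Gaussian distribution
#'
#' Density, distribution function and random generation for the
#' exponentially modified Gaussian (ex-Gaussian) distribution: the sum of a
#' normal random variable with mean \code{mu} and standard deviation
#' \code{sigma} and an independent exponential random variable with mean
#' \code{tau}.  The ex-Gaussian is the standard descriptive model for
#' positively skewed response-time data: \code{mu} and \code{sigma} capture
#' the Gaussian "body" of the distribution while \code{tau} captures the
#' slow exponential tail.
#'
#' The density is
#' \deqn{f(x) = \frac{1}{\tau}
#'   \exp\!\left(\frac{\mu - x}{\tau} + \frac{\sigma^2}{2\tau^2}\right)
#'   \Phi\!\left(\frac{x-\mu}{\sigma} - \frac{\sigma}{\tau}\right)}
#' and the distribution function is
#' \deqn{F(x) = \Phi\!\left(\frac{x-\mu}{\sigma}\right) -
#'   \exp\!\left(\frac{\mu - x}{\tau} + \frac{\sigma^2}{2\tau^2}\right)
#'   \Phi\!\left(\frac{x-\mu}{\sigma} - \frac{\sigma}{\tau}\right).}
#' Both are evaluated in the log domain (via \code{pnorm(..., log.p = TRUE)})
#' so that the exponential factor never overflows, even for large
#' \code{sigma/tau} ratios where the naive product of a huge exponential and
#' a vanishing normal tail fails.
#'
#' @param x,q numeric vector of quantiles (response times, ms).
#' @param n number of draws.
#' @param mu Gaussian location, ms.
#' @param sigma Gaussian standard deviation, ms; must be > 0.
#' @param tau mean of the exponential component, ms; must be > 0.
#' @param log logical; if \code{TRUE} the log density is returned.
#' @param seed optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#'
#' @return \code{dexgauss} the (log) density, \code{pexgauss} the cumulative
#'   probability, \code{rexgauss} a numeric vector of \code{n} draws.
#'
#' @examples
#' dexgauss(0, mu = 0, sigma = 1, tau = 1)   # exp(0.5) * pnorm(-1)
#' pexgauss(645, mu = 417.56, sigma = 18.72, tau = 227.72)
#' rexgauss(5, mu = 450, sigma = 60, tau = 230, seed = 1)
#' @export
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  check_exgauss_params(mu, sigma, tau)
  lf <- -base::log(tau) + (mu - x) / tau + sigma^2 / (2 * tau^2) +
    stats::pnorm((x - mu) / sigma - sigma / tau, log.p = TRUE)
  if (log) lf else exp(lf)
}

#' @rdname dexgauss
#' @export
pexgauss <- function(q, mu, sigma, tau) {
  check_exgauss_params(mu, sigma, tau)
  z <- (q - mu) / sigma
  ltail <- (mu - q) / tau + sigma^2 / (2 * tau^2) +
    stats::pnorm(z - sigma / tau, log.p = TRUE)
  p <- stats::pnorm(z) - exp(ltail)
  # far left tail: the two terms cancel to rounding error; clamp to [0, 1]
  pmin(pmax(p, 0), 1)
}

#' @rdname dexgauss
#' @export
rexgauss <- function(n, mu, sigma, tau, seed = NULL) {
  check_exgauss_params(mu, sigma, tau)
  with_seed(seed, stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau))
}

#' Closed-form moments of an ex-Gaussian distribution
#'
#' Mean, standard deviation and skewness implied by the components:
#' mean = \eqn{\mu + \tau}, sd = \eqn{\sqrt{\sigma^2 + \tau^2}}, skewness =
#' \eqn{2\tau^3 / (\sigma^2 + \tau^2)^{3/2}}.  These are the population
#' counterparts of the sample statistics M, S and t computed by
#' \code{\link{compute_sample_stats}}, and the bridge between the two is what
#' makes moment-based starting values (\code{\link{moment_start}}) work.
#'
#' @inheritParams dexgauss
#' @return named numeric vector \code{c(mean, sd, skewness)}.
#' @examples
#' exgauss_moments(mu = 0, sigma = 3, tau = 4)  # mean 4, sd 5
#' @export
exgauss_moments <- function(mu, sigma, tau) {
  check_exgauss_params(mu, sigma, tau)
  v <- sigma^2 + tau^2
  c(mean = mu + tau, sd = sqrt(v), skewness = 2 * tau^3 / v^1.5)
}

check_exgauss_params <- function(mu, sigma, tau) {
  if (!all(is.finite(c(mu, sigma, tau)))) {
    stop("ex-Gaussian parameters must be finite", call. = FALSE)
  }
  if (any(sigma <= 0) || any(tau <= 0)) {
    stop("ex-Gaussian parameters require sigma > 0 and tau > 0", call. = FALSE)
  }
  invisible(NULL)
}

# Normalise the many ways a parameter triple can arrive (fit object, named
# vector/list, bare length-3 vector) into c(mu, sigma, tau).
as_exgauss_par <- function(p) {
  if (inherits(p, "exgauss_fit")) p <- p$par
  p <- unlist(p, use.names = TRUE)
  if (!is.null(names(p)) && all(c("mu", "sigma", "tau") %in% names(p))) {
    p <- p[c("mu", "sigma", "tau")]
  } else if (length(p) != 3L) {
    stop("expected a (mu, sigma, tau) parameter triple", call. = FALSE)
  }
  p <- as.numeric(p)
  names(p) <- c("mu", "sigma", "tau")
  p
}
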