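#' Sample the iso-likelihood surface around an ex-Gaussian MLE
#'
#' Locates points in (mu, sigma, tau) space whose log-likelihood sits
#' exactly \code{delta} below the maximum (default 0.5: in the quadratic
#' regime this surface bounds the ~68\% confidence region).  For each of
#' \code{n_points} random directions, a bisection along the ray from the
#' MLE finds the radius where the log-likelihood crosses
#' \code{max - delta}; rays that leave the positive-sigma/tau domain before
#' crossing are redrawn.
#'
#' Directions are drawn uniformly on the sphere after whitening by the
#' numerical curvature at the MLE, so elongated surfaces are sampled evenly
#' along all principal axes; if the curvature is not negative definite the
#' sampler falls back to raw directions scaled by the parameter magnitudes.
#'
#' @param rts the RT sample the fit was computed from.
#' @param fit a converged \code{\link{fit_exgauss}} result.
#' @param delta log-likelihood drop defining the surface.
#' @param n_points number of surface points, at least 1000.
#' @param seed optional seed.
#' @param tol absolute tolerance on the log-likelihood at each returned
#'   point.
#' @return object of class \code{"iso_surface"}: list with \code{points}
#'   (n_points x 3 matrix, columns mu/sigma/tau), \code{target_loglik},
#'   \code{max_loglik}, \code{delta}, \code{n_points}.
#' @export
sample_iso_surface <- function(rts, fit, delta = 0.5, n_points = 1024,
                               seed = NULL, tol = 1e-8) {
  stopifnot(inherits(fit, "exgauss_fit"))
  if (!fit$converged) {
    stop("iso-surface sampling requires a converged fit", call. = FALSE)
  }
  if (n_points < 1000) {
    stop("surface sampling uses at least 1000 points", call. = FALSE)
  }
  theta <- fit$par
  llmax <- fit$loglik
  target <- llmax - delta

  H <- exgauss_loglik_hessian(rts, theta)
  eg <- eigen(-H, symmetric = TRUE)
  L <- if (all(eg$values > 0)) {
    eg$vectors %*% diag(1 / sqrt(eg$values))
  } else {
    diag(pmax(abs(theta), 1))  # fallback: raw directions, magnitude-scaled
  }

  # lean log-likelihood (no argument re-validation): this is the hot loop
  f <- function(th) {
    mu <- th[1L]; sg <- th[2L]; ta <- th[3L]
    sum(-log(ta) + (mu - rts) / ta + sg^2 / (2 * ta^2) +
          stats::pnorm((rts - mu) / sg - sg / ta, log.p = TRUE)) - target
  }
  valid <- function(th) th[2L] > 0 && th[3L] > 0

  pts <- with_seed(seed, {
    points <- matrix(NA_real_, n_points, 3L,
                     dimnames = list(NULL, c("mu", "sigma", "tau")))
    redraws <- 0L
    for (k in seq_len(n_points)) {
      repeat {
        u <- stats::rnorm(3L)
        d <- as.numeric(L %*% (u / sqrt(sum(u * u))))
        # bracket the crossing: quadratic regime predicts radius ~ 1
        r_lo <- 0
        r_hi <- 1
        ok <- TRUE
        while (TRUE) {
          cand <- theta + r_hi * d
          if (!valid(cand)) { ok <- FALSE; break }
          fv <- f(cand)
          if (fv < 0) break
          r_lo <- r_hi
          r_hi <- 2 * r_hi
          if (r_hi > 1e3) {
            stop("iso-surface failure: no likelihood crossing within 1e3 ",
                 "scaled units (flat likelihood?)", call. = FALSE)
          }
        }
        if (ok) break
        redraws <- redraws + 1L
        if (redraws > 100L * n_points) {
          stop("iso-surface failure: rays persistently leave the ",
               "sigma, tau > 0 domain", call. = FALSE)
        }
      }
      for (it in seq_len(200L)) {
        r_mid <- (r_lo + r_hi) / 2
        fv <- f(theta + r_mid * d)
        if (abs(fv) < tol) break
        if (fv > 0) r_lo <- r_mid else r_hi <- r_mid
      }
      points[k, ] <- theta + ((r_lo + r_hi) / 2) * d
    }
    points
  })

  structure(list(points = pts, target_loglik = target, max_loglik = llmax,
                 delta = delta, n_points = as.integer(n_points)),
            class = "iso_surface")
}

#' Parameter uncertainties from the iso-likelihood surface
#'
#' Summarises the dispersion of the sampled half-point iso-likelihood
#' surface into one uncertainty per parameter: the surface's half-extent
#' along each axis, i.e. the largest absolute deviation of the surface
#' points from the MLE in that coordinate.  For a quadratic log-likelihood
#' this equals the profile-likelihood standard error (the tangent extent of
#' the 1-sigma ellipsoid), so "MLE +/- 1 sd" carries the nominal ~68\%
#' coverage; multiplying by 1.96 gives the 95\% interval.
#'
#' @param surface an \code{\link{sample_iso_surface}} result.
#' @param fit the fit the surface was sampled around.
#' @return object of class \code{"exgauss_uncertainty"}: list with
#'   \code{sd} (named vector, ms), \code{ci95} (3 x 2 matrix of lower/upper
#'   bounds, half-width 1.96 sd) and \code{par}.
#' @export
surface_uncertainties <- function(surface, fit) {
  stopifnot(inherits(surface, "iso_surface"), inherits(fit, "exgauss_fit"))
  dev <- sweep(surface$points, 2L, fit$par)
  sds <- apply(abs(dev), 2L, max)
  ci <- cbind(lower = fit$par - 1.96 * sds, upper = fit$par + 1.96 * sds)
  structure(list(sd = sds, ci95 = ci, par = fit$par),
            class = "exgauss_uncertainty")
}

#' @export
print.exgauss_uncertainty <- function(x, ...) {
  for (nm in c("mu", "sigma", "tau")) {
    cat(sprintf("  %-5s = %8.2f +/- %6.2f ms   (95%% CI %.2f .. %.2f)\n",
                nm, x$par[nm], x$sd[nm], x$ci95[nm, "lower"],
                x$ci95[nm, "upper"]))
  }
  invisible(x)
}
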