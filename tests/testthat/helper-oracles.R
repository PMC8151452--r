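# Independent oracles used across the suite.  Each deliberately avoids the
# implementation path it checks.

# central finite-difference gradient of the log-likelihood
fd_loglik_grad <- function(rts, p, rel_h = 1e-6) {
  p <- c(p$mu %||% p[["mu"]], p$sigma %||% p[["sigma"]], p$tau %||% p[["tau"]])
  vapply(1:3, function(i) {
    h <- rel_h * max(abs(p[i]), 1)
    pp <- p; pm <- p
    pp[i] <- pp[i] + h
    pm[i] <- pm[i] - h
    (exgauss_loglik(rts, pp) - exgauss_loglik(rts, pm)) / (2 * h)
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force KS: scan the empirical-vs-fitted gap at the sample points and
# just below them, via stats::ecdf (independent of the sorted-order formula)
brute_ks <- function(rts, p) {
  p <- as.numeric(unlist(p)[c("mu", "sigma", "tau")])
  Fhat <- stats::ecdf(rts)
  grid <- sort(c(rts, rts - 1e-12 * pmax(abs(rts), 1)))
  max(abs(Fhat(grid) - pexgauss(grid, p[1], p[2], p[3])))
}

# loop-based sample statistics (population moments), no vectorised shortcuts
brute_stats <- function(x) {
  n <- length(x)
  M <- 0
  for (v in x) M <- M + v / n
  v2 <- 0; v3 <- 0
  for (v in x) {
    v2 <- v2 + (v - M)^2 / n
    v3 <- v3 + (v - M)^3 / n
  }
  list(M = M, S = sqrt(v2), t = v3 / v2^1.5)
}

# numeric inversion of the ex-Gaussian CDF (for quantile-based constructions)
q_exgauss <- function(prob, mu, sigma, tau) {
  vapply(prob, function(pr) {
    stats::uniroot(function(x) pexgauss(x, mu, sigma, tau) - pr,
                   lower = mu - 10 * (sigma + tau),
                   upper = mu + 30 * (sigma + tau), tol = 1e-10)$root
  }, numeric(1))
}

# small deterministic trial table covering a handful of cells
toy_trials <- function() {
  data.frame(
    participant_id = rep(c("sp001", "us001"), each = 5),
    country = rep(c("spain", "usa"), each = 5),
    target_nature = "face",
    role = "test",
    prime = rep(c("identity", "related"), 5),
    rt_ms = c(100, 250, 300, 1500, 1600, 420, 510, 615, 700, 820),
    correct = c(1, 1, 0, 1, 1, 1, 1, 1, 0, 1),
    stringsAsFactors = FALSE
  )
}
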