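test_that("moment-based starting values invert the moment identities", {
  st <- moment_start(list(M = 645.57, S = 228.38, t = 1.98))
  tau0 <- 228.38 * (1.98 / 2)^(1 / 3)
  expect_equal(st$tau, tau0, tolerance = 1e-12)
  expect_equal(st$mu, 645.57 - tau0, tolerance = 1e-12)
  expect_equal(st$sigma, sqrt(228.38^2 - tau0^2), tolerance = 1e-12)
  # numerically: close to (417.95, 18.6, 227.62)
  expect_equal(st$mu, 417.95, tolerance = 0.01)
  expect_equal(st$sigma, 18.66, tolerance = 0.01)
  expect_equal(st$tau, 227.62, tolerance = 0.01)

  # t = 2 puts tau0 = S and sigma0 on the domain floor
  st2 <- moment_start(list(M = 600, S = 100, t = 2))
  expect_equal(st2$tau, 100)
  expect_equal(st2$sigma, 5)   # 0.05 * S

  # non-positive skew: Gaussian-dominant start
  st3 <- moment_start(list(M = 600, S = 100, t = -0.3))
  expect_equal(st3$tau, 10)
  expect_equal(st3$sigma, sqrt(100^2 - 10^2))
  expect_equal(st3$mu, 590)
})

test_that("log-likelihood is additive and computed in the log domain", {
  p <- c(mu = 0, sigma = 1, tau = 1)
  expect_equal(exgauss_loglik(0, p), log(exp(0.5) * pnorm(-1)),
               tolerance = 1e-12)  # -1.3413
  x <- rexgauss(50, 0, 1, 1, seed = 3)
  expect_equal(exgauss_loglik(c(x, x), p), 2 * exgauss_loglik(x, p),
               tolerance = 1e-12)
  # log-domain path agrees with the naive density product where that works
  naive <- sum(log(dexgauss(x, 0, 1, 1)))
  expect_equal(exgauss_loglik(x, p), naive, tolerance = 1e-9)
  # ... and survives where the naive path underflows
  far <- 5000
  expect_true(is.finite(exgauss_loglik(far, c(0, 200, 0.5))))
  expect_equal(dexgauss(far, 0, 200, 0.5), 0)  # naive density underflows
})

test_that("analytic gradient matches finite differences and symmetry", {
  set.seed(41)
  for (i in 1:5) {
    x <- rexgauss(150, runif(1, 300, 500), runif(1, 20, 90), runif(1, 150, 300))
    p <- list(mu = runif(1, 300, 500), sigma = runif(1, 20, 90),
              tau = runif(1, 150, 300))
    g <- exgauss_loglik_grad(x, p)
    fd <- fd_loglik_grad(x, p)
    expect_equal(unname(g), fd, tolerance = 1e-5)
  }

  # location family: shifting data and mu together leaves the gradient fixed
  x <- rexgauss(200, 400, 50, 200, seed = 8)
  g1 <- exgauss_loglik_grad(x, c(mu = 390, sigma = 55, tau = 210))
  g2 <- exgauss_loglik_grad(x + 137, c(mu = 527, sigma = 55, tau = 210))
  expect_equal(g1, g2, tolerance = 1e-9)
})

test_that("the ascent converges to the MLE within the gradient tolerance", {
  x <- rexgauss(5000, 400, 50, 200, seed = 13)
  fit <- fit_exgauss(x)
  expect_true(fit$converged)
  expect_lt(fit$gradient_norm, 1e-8)
  expect_gte(fit$loglik, fit$start_loglik)

  # estimates within 3 SEs of truth (SEs from the inverse numerical curvature)
  H <- exgaussrt:::exgauss_loglik_hessian(x, fit$par)
  se <- sqrt(diag(solve(-H)))
  expect_true(all(abs(fit$par - c(400, 50, 200)) < 3 * se))
})

test_that("the MLE is translation-equivariant", {
  x <- rexgauss(1000, 450, 60, 230, seed = 19)
  f1 <- fit_exgauss(x)
  f2 <- fit_exgauss(x + 100)
  expect_equal(f2$par[["mu"]], f1$par[["mu"]] + 100, tolerance = 1e-6)
  expect_equal(f2$par[["sigma"]], f1$par[["sigma"]], tolerance = 1e-6)
  expect_equal(f2$par[["tau"]], f1$par[["tau"]], tolerance = 1e-6)
})

test_that("the ascent agrees with an independent quasi-Newton optimiser", {
  x <- rexgauss(800, 417.56, 18.72, 227.72, seed = 29)
  fit <- fit_exgauss(x)
  nll <- function(p) -exgauss_loglik(x, c(mu = p[1], sigma = p[2], tau = p[3]))
  o <- optim(unlist(moment_start(compute_sample_stats(x))), nll,
             method = "L-BFGS-B", lower = c(-Inf, 1e-4, 1e-4),
             control = list(parscale = c(100, 20, 100), maxit = 2000))
  expect_equal(unname(fit$par), unname(o$par), tolerance = 1e-4)
  expect_gte(fit$loglik, -o$value - 1e-8)
})

test_that("degenerate samples are refused", {
  expect_error(fit_exgauss(rexgauss(5, 400, 50, 200, seed = 1)),
               "insufficient data")
  expect_error(fit_exgauss(rep(500, 20)), "degenerate")
})
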