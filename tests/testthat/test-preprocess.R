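test_that("sample statistics use population moments", {
  st <- compute_sample_stats(c(1, 2, 3, 10))
  expect_equal(st$M, 4)
  expect_equal(st$S, sqrt(12.5), tolerance = 1e-12)       # 3.5355
  expect_equal(st$t, 45 / 12.5^1.5, tolerance = 1e-12)    # 1.0182

  # brute-force loop oracle on random vectors
  set.seed(31)
  for (i in 1:5) {
    x <- rexgauss(200, 400, 50, 200)
    st <- compute_sample_stats(x)
    bf <- brute_stats(x)
    expect_equal(st$M, bf$M, tolerance = 1e-12)
    expect_equal(st$S, bf$S, tolerance = 1e-12)
    expect_equal(st$t, bf$t, tolerance = 1e-12)
  }

  # translation changes only M; symmetry gives t = 0
  x <- c(310, 420, 530, 900)
  a <- compute_sample_stats(x)
  b <- compute_sample_stats(x + 250)
  expect_equal(b$M, a$M + 250)
  expect_equal(b$S, a$S)
  expect_equal(b$t, a$t)
  expect_equal(compute_sample_stats(c(499, 500, 501))$t, 0)

  expect_error(compute_sample_stats(500), "degenerate")
  expect_error(compute_sample_stats(rep(500, 8)), "degenerate")
})

test_that("RT trimming keeps the inclusive window and reports exclusions", {
  tr <- data.frame(rt_ms = c(100, 250, 300, 1500, 1600), correct = 1)
  out <- suppressWarnings(trim_rts(tr))
  expect_equal(out$trials$rt_ms, c(250, 300, 1500))
  expect_equal(out$report$n_rt_excluded, 2)
  expect_true(out$report$warning_flag)

  # all inside: identity, no warning
  inside <- data.frame(rt_ms = seq(300, 1200, by = 100))
  out2 <- trim_rts(inside)
  expect_identical(out2$trials, inside)
  expect_equal(out2$report$fraction_rt_excluded, 0)
  expect_false(out2$report$warning_flag)

  # 6 of 100 outside: fraction 0.06, warning raised
  tr3 <- data.frame(rt_ms = c(rep(700, 94), rep(100, 6)))
  expect_warning(out3 <- trim_rts(tr3), "5%")
  expect_equal(out3$report$fraction_rt_excluded, 0.06)
  expect_true(out3$report$warning_flag)

  expect_error(trim_rts(inside, lower = 1500, upper = 250), "lower < upper")
  empty <- trim_rts(inside[0, , drop = FALSE])
  expect_equal(empty$report$n_total, 0)
  expect_false(empty$report$warning_flag)
})

test_that("correctness filtering is order-preserving and idempotent", {
  tt <- toy_trials()
  kept <- filter_correct(tt)
  expect_equal(nrow(kept), sum(tt$correct))
  expect_identical(kept, filter_correct(kept))
  expect_identical(kept$rt_ms, tt$rt_ms[tt$correct == 1])

  none <- tt
  none$correct <- 0
  expect_equal(nrow(filter_correct(none)), 0)
})

test_that("trimming and correctness filtering commute", {
  trials <- generate_cohort(cohort_design(3, 14, seed = 17))
  a <- suppressWarnings(trim_rts(filter_correct(trials)))$trials
  b <- filter_correct(suppressWarnings(trim_rts(trials))$trials)
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("pooling partitions the trials across the 32 cells", {
  trials <- generate_cohort(cohort_design(3, 14, seed = 23))
  clean <- suppressWarnings(trim_rts(filter_correct(trials)))$trials
  pools <- pool_by_condition(clean)
  expect_length(pools, 32)
  expect_identical(names(pools), condition_id(condition_keys()))
  expect_equal(sum(vapply(pools, length, integer(1))), nrow(clean))
  expect_true(all(vapply(pools, length, integer(1)) > 0))

  # concatenation across participants within one cell
  one <- clean[clean$target_nature == "face" & clean$country == "spain" &
                 clean$role == "test" & clean$prime == "identity", ]
  expect_equal(sort(pools[["face:spain:test:identity"]]), sort(one$rt_ms))
})
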