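test_that("the reference condition table enumerates all 32 cells once", {
  tab <- default_condition_table()
  expect_equal(nrow(tab), 32)
  expect_equal(anyDuplicated(condition_id(tab)), 0)
  expect_setequal(condition_id(tab), condition_id(condition_keys()))
  expect_true(all(tab$sigma > 0 & tab$tau > 0))
  expect_true(all(tab$hit_rate >= 0 & tab$hit_rate <= 1))

  row1 <- tab[tab$target_nature == "face" & tab$country == "spain" &
                tab$role == "test" & tab$prime == "identity", ]
  expect_equal(unlist(row1[c("mu", "sigma", "tau", "hit_rate")]),
               c(mu = 417.56, sigma = 18.72, tau = 227.72, hit_rate = 0.81))
  row2 <- tab[tab$target_nature == "name" & tab$country == "usa" &
                tab$role == "distracting" & tab$prime == "identity", ]
  expect_equal(unlist(row2[c("mu", "sigma", "tau", "hit_rate")]),
               c(mu = 502.44, sigma = 87.16, tau = 292.10, hit_rate = 0.90))
  expect_equal(unique(tab$contamination_rate), 0.02)
  expect_error(default_condition_table(0.7), "contamination_rate")
})

test_that("cohort generation is balanced, complete and seed-deterministic", {
  design <- cohort_design(3, 14, seed = 101)
  trials <- generate_cohort(design)
  expect_equal(nrow(trials), 3 * 2 * 224)
  expect_equal(length(unique(trials$participant_id)), 6)
  expect_setequal(unique(trials$country), c("spain", "usa"))

  # every participant sees each of their 16 cells exactly trials_per_cell times
  counts <- table(trials$participant_id, condition_id(trials))
  expect_true(all(counts %in% c(0L, 14L)))
  expect_true(all(rowSums(counts > 0) == 16))

  expect_identical(generate_cohort(design), trials)

  bad <- default_condition_table()[-5, ]
  expect_error(generate_cohort(design, bad), "missing condition spec")
})

test_that("per-cell samples converge to the generating distribution", {
  # one participant per country at high trial volume, no contamination
  specs <- default_condition_table(contamination_rate = 0)
  trials <- generate_cohort(cohort_design(1, 5000, seed = 55), specs)
  cell <- trials[condition_id(trials) == "face:spain:test:identity", ]
  n <- nrow(cell)
  expect_equal(n, 5000)

  truth <- exgauss_moments(417.56, 18.72, 227.72)
  st <- compute_sample_stats(cell$rt_ms)
  expect_lt(abs(st$M - truth[["mean"]]), 4 * truth[["sd"]] / sqrt(n))
  expect_lt(abs(st$S - truth[["sd"]]) / truth[["sd"]], 0.05)
  expect_lt(abs(st$t - truth[["skewness"]]), 0.25)

  # empirical hit rate near the cell's hit_rate
  hit <- mean(cell$correct)
  expect_lt(abs(hit - 0.81), 3 * sqrt(0.81 * 0.19 / n))
})

test_that("contaminants land outside the trimming window at the set rate", {
  specs <- default_condition_table(contamination_rate = 0.10)
  trials <- generate_cohort(cohort_design(4, 100, seed = 77), specs)
  out <- trials$rt_ms < 250 | trials$rt_ms > 1500
  # clean ex-Gaussian draws stray outside the window too, so the observed
  # fraction exceeds the contamination rate by the tail mass
  expect_gt(mean(out), 0.10 * (1 - 1e-3))
  expect_lt(mean(out), 0.20)
  # low-side contaminants respect the 80 ms floor (clean draws never get there)
  expect_true(all(trials$rt_ms >= 80))
})
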