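fake_invasion <- function(mean_fitness, mean_copies,
                          frac_silenced = rep(0, length(mean_fitness)),
                          frac_zero = rep(0, length(mean_fitness)),
                          stop_reason = "max_generations") {
  g <- seq_along(mean_fitness) - 1
  list(
    trajectory = tibble::tibble(
      generation = g, mean_copies = mean_copies,
      mean_cluster_insertions = 0, mean_fitness = mean_fitness,
      frac_silenced = frac_silenced, frac_zero_fitness = frac_zero),
    stop_reason = stop_reason
  )
}

base_cfg <- simulation_config()

test_that("outcome classification follows the stated precedence", {
  # extinction: minimum mean fitness below the threshold
  expect_identical(
    classify_outcome(fake_invasion(c(0.9, 0.5, 0.05), c(1, 50, 95)), base_cfg),
    "EXTINCT")
  # overflow beats loss and stability
  expect_identical(
    classify_outcome(fake_invasion(c(1, 0.9), c(100, 26000)), base_cfg),
    "TERMINATED_OVERFLOW")
  # loss of all copies
  expect_identical(
    classify_outcome(fake_invasion(c(0.99, 1, 1), c(2, 1, 0)), base_cfg),
    "LOST")
  # full silencing is controlled
  expect_identical(
    classify_outcome(fake_invasion(c(0.9, 0.8, 0.85), c(10, 20, 20),
                                   frac_silenced = c(0, 0.5, 1)), base_cfg),
    "STABLE_CONTROLLED")
  # flat copy number over the slope window is controlled
  flat <- fake_invasion(rep(0.8, 700), rep(50, 700))
  expect_identical(classify_outcome(flat, base_cfg), "STABLE_CONTROLLED")
  # steeply growing copy number is still active
  grow <- fake_invasion(seq(1, 0.55, length.out = 200),
                        seq(1, 45, length.out = 200))
  expect_identical(classify_outcome(grow, base_cfg), "ACTIVE")
  # extinction wins even when the cap was also exceeded
  expect_identical(
    classify_outcome(fake_invasion(c(0.5, 0.05), c(20000, 26000)), base_cfg),
    "EXTINCT")
})

test_that("classification is total over a varied set of real runs", {
  set.seed(51)
  sw <- run_sweep(sweep_spec(8, cluster_percent = c(0.005, 5), u = c(0.05, 0.5),
                             x = c(0.005, 0.05), N = 200, generations = 300,
                             seed_insertions = 200, master_seed = 99))
  expect_true(all(sw$status %in% c("EXTINCT", "LOST", "STABLE_CONTROLLED",
                                   "ACTIVE", "TERMINATED_OVERFLOW")))
  expect_identical(nrow(sw), 8L)
})

test_that("largest extinct clusters are returned in descending order", {
  sweep <- tibble::tibble(
    cluster_percent = c(0.01, 0.05, 0.002, 1, 3),
    status = c("EXTINCT", "EXTINCT", "EXTINCT", "STABLE_CONTROLLED", "LOST"))
  expect_equal(largest_extinct_clusters(sweep, 2), c(0.05, 0.01))
  expect_equal(largest_extinct_clusters(sweep, 50), c(0.05, 0.01, 0.002))
  none <- sweep[sweep$status == "ACTIVE", ]
  expect_length(largest_extinct_clusters(none, 10), 0)
})

test_that("extinction histogram reports empty bins as undefined, not zero", {
  sweep <- tibble::tibble(
    cluster_percent = c(0.005, 0.005, 0.05, 0.5),
    status = c("EXTINCT", "EXTINCT", "EXTINCT", "STABLE_CONTROLLED"))
  h <- extinction_fraction_by_bin(sweep, c(0.001, 0.01, 0.1, 1, 10))
  expect_equal(h$fraction_extinct, c(1, 1, 0, NA))
  expect_equal(sum(h$n_runs), 4L)
  expect_error(extinction_fraction_by_bin(sweep, c(1, 0.1)), "increasing")
})

test_that("scenario comparisons dispatch to the right tests", {
  a <- c(1, 2, 3)
  b <- c(100, 101, 102)
  w <- compare_scenarios(a, b, test = "wilcoxon")
  expect_equal(w$p_value, 0.1) # smallest attainable two-sided p for n = 3, 3
  same <- compare_scenarios(c(1, 2, 3), c(1, 2, 3), test = "wilcoxon")
  expect_gt(same$p_value, 0.95)
  kw <- compare_scenarios(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)),
                          test = "kruskal")
  expect_equal(unname(kw$statistic), 0)
  av <- compare_scenarios(rnorm(10), rnorm(10) + 5, test = "anova")
  expect_lt(av$p_value, 0.01)
  expect_error(compare_scenarios(a, numeric(0)), "non-empty")
  expect_error(compare_scenarios(a, b, c(1, 2), test = "wilcoxon"), "exactly two")
})

test_that("the rank-sum p-value agrees with complete enumeration for small groups", {
  set.seed(52)
  for (i in 1:20) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    vals <- sample.int(1000, n1 + n2) # distinct => no ties
    g1 <- vals[seq_len(n1)]
    g2 <- vals[-seq_len(n1)]
    expect_equal(compare_scenarios(g1, g2, test = "wilcoxon")$p_value,
                 enumerate_wilcoxon_p(g1, g2), tolerance = 1e-12)
  }
})

test_that("zero-fitness percentage is read at the first threshold crossing", {
  inv <- fake_invasion(c(0.9, 0.4, 0.09, 0.02), c(1, 60, 95, 120),
                       frac_zero = c(0, 0.01, 0.18, 0.5))
  expect_equal(fraction_zero_fitness_at_threshold(inv), 18)
  all_zero <- fake_invasion(c(0.05), c(200), frac_zero = c(1))
  expect_equal(fraction_zero_fitness_at_threshold(all_zero), 100)
  never <- fake_invasion(c(0.9, 0.8), c(10, 10))
  expect_true(is.na(fraction_zero_fitness_at_threshold(never)))
})
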