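test_that("an empty sweep returns an empty, well-formed table", {
  sw <- run_sweep(sweep_spec(0, master_seed = 1))
  expect_identical(nrow(sw), 0L)
  expect_true(all(c("sim", "seed", "cluster_percent", "u", "x", "status",
                    "min_fitness") %in% names(sw)))
})

test_that("sweeps are deterministic and prefix-stable under a master seed", {
  spec10 <- sweep_spec(10, cluster_percent = c(0.01, 5), u = c(0.05, 0.3),
                       x = c(0.005, 0.02), N = 100, seed_insertions = 100,
                       generations = 60, master_seed = 77)
  a <- run_sweep(spec10)
  b <- run_sweep(spec10)
  expect_identical(a, b)

  spec4 <- spec10
  spec4$n_sims <- 4L
  small <- run_sweep(spec4)
  expect_equal(small, a[1:4, ], ignore_attr = TRUE)
})

test_that("presets carry the intended parameter boxes and reject unknown names", {
  wc <- scenario_preset("worst_case", master_seed = 1)
  expect_equal(wc$u, 0.2)
  expect_equal(wc$x, 0.01)
  expect_equal(wc$h, 0)
  expect_identical(wc$fitness_form, "dominance")
  expect_equal(wc$seed_insertions, 100)
  expect_setequal(wc$N, c(20, 50, 100))

  bl <- scenario_preset("baseline")
  expect_equal(bl$cluster_percent, c(0.001, 10))
  expect_equal(bl$u, 0.1)
  expect_equal(bl$x, 0.01)
  expect_equal(bl$N, 1000)

  ep <- scenario_preset("epistasis")
  expect_equal(ep$t, c(0.75, 1.5))
  expect_identical(ep$fitness_form, "epistatic")

  me <- scenario_preset("mixed_effects")
  expect_equal(me$site_effects, c(0.1, 0.01, 0.001, 0.0001))

  dc <- scenario_preset("deleterious_clusters")
  expect_false(dc$cluster_insertions_neutral)

  expect_error(scenario_preset("fig2"), "available")
})

test_that("drawn parameters respect their sampling ranges", {
  sw <- run_sweep(sweep_spec(40, cluster_percent = c(0.001, 10),
                             u = c(0.005, 1), x = c(0.001, 0.1),
                             N = c(100, 200), generations = 5,
                             seed_insertions = 100, master_seed = 12))
  expect_true(all(sw$cluster_percent >= 0.001 & sw$cluster_percent <= 10))
  expect_true(all(sw$u >= 0.005 & sw$u <= 1))
  expect_true(all(sw$x >= 0.001 & sw$x <= 0.1))
  expect_true(all(sw$N %in% c(100, 200)))
  # log-uniform: roughly as many draws below as above the geometric midpoint
  mid <- sqrt(0.001 * 10)
  expect_gt(mean(sw$cluster_percent < mid), 0.25)
  expect_lt(mean(sw$cluster_percent < mid), 0.75)
})

test_that("without clusters, u >> x drives extinction and x > u loses the TE", {
  set.seed(61)
  grid <- expand.grid(u = c(0.005, 0.05, 0.5), x = c(0.005, 0.05, 0.5))
  for (row in seq_len(nrow(grid))) {
    u <- grid$u[row]
    x <- grid$x[row]
    if (u < 10 * x && x <= u) next # only the decided quadrants are asserted
    for (rep in 1:3) {
      cfg <- simulation_config(cluster_percent = 0, u = u,
                               fitness = fitness_model(x = x), N = 500,
                               seed_insertions = 1000, generations = 1500,
                               rng_seed = 6100 + 10 * row + rep)
      inv <- run_invasion(cfg)
      if (u >= 10 * x) {
        expect_identical(inv$status, "EXTINCT")
      } else {
        expect_identical(inv$status, "LOST")
        # moderate-effect TEs are purged before fitness drops appreciably
        if (x <= 0.05) expect_gt(inv$min_fitness, 0.8)
      }
    }
  }
})
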