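test_that("seeding places every insertion on exactly one haplotype at 1/2N", {
  set.seed(21)
  cfg <- simulation_config(N = 1000, seed_insertions = 1000)
  pop <- initialize_population(cfg)
  pos <- all_positions(pop)
  expect_length(pos, 1000)               # total diploid copies = seeds
  expect_length(unique(pos), 1000)       # distinct sites, single carrier each
  expect_identical(pop$generation, 0L)
  expect_length(pop$individuals, 1000)
})

test_that("initial mean fitness matches the closed form exactly", {
  set.seed(22)
  cfg <- simulation_config(N = 20, seed_insertions = 1000, cluster_percent = 0)
  pop <- initialize_population(cfg)
  expect_equal(mean(pop$fitness), 0.5)
  cfg2 <- simulation_config(N = 20, seed_insertions = 100, cluster_percent = 0)
  pop2 <- initialize_population(cfg2)
  expect_equal(mean(pop2$fitness), 0.95)
  expect_error(
    initialize_population(simulation_config(layout = toy_layout, N = 10,
                                            seed_insertions = 3e6)),
    "seed insertions")
})

test_that("parents are drawn fitness-proportionally, never with zero fitness", {
  set.seed(23)
  # uniform weights: chi-square goodness of fit on the first parent
  pop_u <- list(fitness = rep(1, 5))
  draws <- replicate(2e4, choose_parents(pop_u)[1])
  expect_gt(chisq.test(table(factor(draws, levels = 1:5)))$p.value, 1e-4)

  # weighted draws 0.8 : 0.2 with zero-fitness individuals present
  pop_w <- list(fitness = c(0.8, 0.2, 0, 0, 0))
  first <- replicate(2e4, choose_parents(pop_w)[1])
  expect_true(all(first %in% 1:2))
  p_hat <- mean(first == 1)
  se <- sqrt(0.8 * 0.2 / 2e4)
  expect_lt(abs(p_hat - 0.8), 3 * se)

  # parents are distinct
  prs <- replicate(200, choose_parents(pop_u))
  expect_true(all(prs[1, ] != prs[2, ]))

  # reproductive collapse: fewer than two positive-fitness individuals
  expect_error(choose_parents(list(fitness = c(1, 0))), "collapse")
  expect_error(choose_parents(list(fitness = c(0, 0, 0))), "collapse")
})

test_that("meiosis passes a homozygote through unchanged", {
  set.seed(24)
  h <- sort(sample.int(5e7, 40) - 1L)
  ind <- list(h1 = h, h2 = h)
  for (i in 1:20) expect_identical(make_gamete(ind, default_layout), h)
})

test_that("recombination fraction across a chromosome matches Haldane's map function", {
  set.seed(25)
  # markers at the two ends of chromosome 1 on opposite haplotypes;
  # d = 0.4 Morgan for 10 Mb at 4 cM/Mb => r = (1 - exp(-2d)) / 2
  ind <- make_individual(h1 = 0, h2 = 1e7 - 1)
  reps <- 1e4
  rec <- 0L
  for (i in seq_len(reps)) {
    g <- make_gamete(ind, default_layout)
    n_mark <- sum(g %in% c(0L, 1e7 - 1L))
    if (n_mark != 1L) rec <- rec + 1L # both or neither marker = recombinant
  }
  r_exp <- (1 - exp(-2 * 0.4)) / 2
  se <- sqrt(r_exp * (1 - r_exp) / reps)
  expect_lt(abs(rec / reps - r_exp), 3 * se)
})

test_that("markers on different chromosomes assort independently", {
  set.seed(26)
  ind <- make_individual(h1 = 5e6, h2 = 1e7 + 5e6) # chr 1 vs chr 2
  reps <- 1e4
  both_or_neither <- 0L
  for (i in seq_len(reps)) {
    g <- make_gamete(ind, default_layout)
    if (sum(g %in% c(5e6L, 1e7L + 5e6L)) != 1L) both_or_neither <- both_or_neither + 1L
  }
  se <- sqrt(0.25 / reps)
  expect_lt(abs(both_or_neither / reps - 0.5), 3 * se)
})

test_that("transposition is silenced by a single cluster insertion and has mean u*n/2", {
  set.seed(27)
  cm <- build_cluster_map(default_layout, 1)
  # silenced parent: one insertion inside a cluster
  silenced <- make_individual(h1 = c(5, sample(2e5:(5e7 - 1), 499)), h2 = integer(0))
  g <- sort(sample.int(5e7, 30) - 1L)
  for (i in 1:50) {
    expect_identical(transpose_into_gamete(g, silenced, 0.1, cm), g)
  }
  # u = 0: never any new insertions
  active <- make_individual(h1 = 2e5 + (1:5) * 100, h2 = 3e6 + (1:5) * 100)
  expect_identical(transpose_into_gamete(g, active, 0, cm), g)
  # mean new insertions per gamete = u * n / 2
  reps <- 1e4
  extra <- replicate(reps, length(transpose_into_gamete(g, active, 0.1, cm)) - length(g))
  se <- sd(extra) / sqrt(reps)
  expect_lt(abs(mean(extra) - 0.5), 3 * se)
})

test_that("one generation keeps N constant and creates no copies when u = 0", {
  set.seed(28)
  cfg <- simulation_config(N = 100, seed_insertions = 300, u = 0,
                           cluster_percent = 1)
  pop <- initialize_population(cfg)
  parental_sites <- unique(all_positions(pop))
  nxt <- step_generation(pop, cfg)
  expect_length(nxt$individuals, 100)
  expect_identical(nxt$generation, 1L)
  expect_true(all(unique(all_positions(nxt)) %in% parental_sites))
})

test_that("a fully silenced population gains no copies through transposition", {
  set.seed(29)
  cfg <- simulation_config(N = 60, seed_insertions = 0, u = 0.5,
                           cluster_percent = 1)
  # every individual is homozygous for a cluster insertion (so silencing
  # persists in all descendants) plus arm insertions
  inds <- lapply(seq_len(60), function(i) {
    make_individual(h1 = c(i, 2e5 + sample.int(1e6, 20)),
                    h2 = c(i, 5e6 + sample.int(1e6, 20)))
  })
  pop <- make_population(inds, cfg)
  expect_true(all(pop$cluster_insertions >= 1))
  parental_sites <- unique(all_positions(pop))
  cur <- pop
  for (i in 1:5) {
    cur <- step_generation(cur, cfg)
    expect_true(all(unique(all_positions(cur)) %in% parental_sites))
  }
})

test_that("cached fitness and cluster counts equal recomputation from haplotypes", {
  set.seed(30)
  cfg <- simulation_config(N = 50, seed_insertions = 500, cluster_percent = 2)
  pop <- step_generation(initialize_population(cfg), cfg)
  st <- trapsim:::cpp_population_stats(pop$individuals, trapsim:::engine_cfg(cfg))
  expect_equal(pop$fitness, st$fitness)
  expect_equal(pop$cluster_insertions, st$cluster_insertions)
  ref <- vapply(pop$individuals, evaluate_fitness, 0,
                map = cfg$cluster_map, model = cfg$fitness)
  expect_equal(pop$fitness, ref, tolerance = 1e-12)
})

test_that("an invasion is bit-identical under a fixed seed", {
  cfg <- simulation_config(N = 200, seed_insertions = 200, cluster_percent = 1,
                           generations = 150, rng_seed = 404)
  a <- run_invasion(cfg)
  b <- run_invasion(cfg)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$status, b$status)
  expect_identical(a$min_fitness, b$min_fitness)
})

test_that("without transposition copies decline under selection and are never extinct", {
  set.seed(31)
  cfg <- simulation_config(N = 300, seed_insertions = 1000, u = 0,
                           cluster_percent = 0, generations = 400)
  inv <- run_invasion(cfg)
  expect_false(inv$status == "EXTINCT")
  expect_lt(inv$final_mean_copies, inv$trajectory$mean_copies[1])
})

test_that("trajectory invariants hold on a controlled invasion", {
  inv <- run_invasion(simulation_config(N = 400, cluster_percent = 3,
                                        seed_insertions = 400,
                                        generations = 800, rng_seed = 5))
  traj <- inv$trajectory
  expect_lte(nrow(traj), 801)
  expect_true(all(inv$min_fitness <= traj$mean_fitness + 1e-12))
  expect_true(all(traj$frac_silenced >= 0 & traj$frac_silenced <= 1))
  expect_true(all(traj$mean_fitness >= 0 & traj$mean_fitness <= 1))
  expect_equal(traj$generation, seq_len(nrow(traj)) - 1)
})
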