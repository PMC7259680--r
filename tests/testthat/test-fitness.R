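test_that("elementary fitness functions reproduce hand-computed values", {
  expect_equal(linear_fitness(0, 0.05), 1)
  expect_equal(linear_fitness(50, 0.01), 0.5)
  expect_equal(linear_fitness(200, 0.01), 0) # clamped from -1

  expect_equal(dominance_fitness(5, 10, 0.01, 0.5), 0.8)
  expect_equal(dominance_fitness(0, 50, 0.01, 0), 1)
  expect_equal(dominance_fitness(0, 10, 0.01, 1), 0.8)

  expect_equal(epistatic_fitness(10, 0.01, 1), 0.9)
  expect_equal(epistatic_fitness(10, 0.01, 1.5), 1 - 0.01 * 10^1.5)
  expect_equal(epistatic_fitness(0, 0.01, 0.75), 1)

  expect_equal(mixed_effects_fitness(numeric(0)), 1)
  expect_equal(mixed_effects_fitness(c(0.1, 0.001)), 0.899)
  expect_equal(mixed_effects_fitness(rep(0.01, 20)), linear_fitness(20, 0.01))
})

test_that("the dominance, epistatic and site forms reduce to the linear form", {
  set.seed(11)
  i_hom <- sample(0:60, 1e4, replace = TRUE)
  i_het <- sample(0:60, 1e4, replace = TRUE)
  n <- 2 * i_hom + i_het
  expect_equal(dominance_fitness(i_hom, i_het, 0.01, 0.5),
               linear_fitness(n, 0.01))
  expect_equal(epistatic_fitness(n, 0.01, 1), linear_fitness(n, 0.01))
})

test_that("fitness is clamped to [0, 1] and non-increasing in every load term", {
  set.seed(12)
  for (i in 1:200) {
    x <- runif(1, 0, 0.2)
    n <- sample(0:400, 1)
    h <- runif(1)
    t <- runif(1, 0.5, 2)
    vals <- c(linear_fitness(n, x), dominance_fitness(n %/% 2, n %% 2, x, h),
              epistatic_fitness(n, x, t))
    expect_true(all(vals >= 0 & vals <= 1))
    expect_lte(linear_fitness(n + 1, x), linear_fitness(n, x))
    expect_lte(epistatic_fitness(n + 1, x, t), epistatic_fitness(n, x, t))
    expect_lte(dominance_fitness(n %/% 2 + 1, n %% 2, x, h),
               dominance_fitness(n %/% 2, n %% 2, x, h))
    expect_lte(dominance_fitness(n %/% 2, n %% 2 + 1, x, h),
               dominance_fitness(n %/% 2, n %% 2, x, h))
  }
})

test_that("the model constructor rejects undefined combinations", {
  expect_error(fitness_model(x = -1), "non-negative")
  expect_error(fitness_model(form = "dominance", t = 1.5), "combined")
  expect_error(fitness_model(form = "site_specific"), "site_effects")
  expect_error(fitness_model(form = "site_specific", site_effects = c(0.1, 0.01),
                             site_proportions = c(0.9, 0.2)), "sum to 1")
  expect_error(fitness_model(site_effects = c(0.1)), "site_specific")
})

test_that("cluster insertions are cost-free and excluded from n when neutral", {
  cm <- build_cluster_map(default_layout, 1) # clusters span [0, 1e5) per chromosome
  lin <- fitness_model(x = 0.01)
  # three insertions inside the chromosome-1 cluster only
  ind_clu <- make_individual(h1 = c(10, 500, 99999))
  expect_equal(evaluate_fitness(ind_clu, cm, lin), 1)
  # same insertions costed when cluster insertions are deleterious
  del <- fitness_model(x = 0.01, cluster_insertions_neutral = FALSE)
  expect_equal(evaluate_fitness(ind_clu, cm, del), 0.97)
  # ten non-cluster copies
  ind10 <- make_individual(h1 = 2e5 + (1:5) * 1000, h2 = 3e6 + (1:5) * 777)
  expect_equal(evaluate_fitness(ind10, cm, lin), 0.9)
  # epistatic form excludes cluster insertions from n as well
  epi <- fitness_model(x = 0.01, form = "epistatic", t = 1.5)
  mixed_ind <- make_individual(h1 = c(5, 2e5, 3e5)) # 1 cluster + 2 outside
  expect_equal(evaluate_fitness(mixed_ind, cm, epi), 1 - 0.01 * 2^1.5)
})

test_that("engine-cached fitness agrees with the reference R evaluation", {
  set.seed(13)
  models <- list(
    fitness_model(x = 0.01),
    fitness_model(x = 0.02, form = "dominance", h = 0.2),
    fitness_model(x = 0.005, form = "epistatic", t = 1.3),
    fitness_model(form = "site_specific",
                  site_effects = c(0.1, 0.01, 0.001, 0.0001)),
    fitness_model(x = 0.01, cluster_insertions_neutral = FALSE)
  )
  for (model in models) {
    cfg <- simulation_config(cluster_percent = 2, fitness = model, N = 30,
                             seed_insertions = 600)
    pop <- initialize_population(cfg)
    ref <- vapply(pop$individuals, evaluate_fitness, 0,
                  map = cfg$cluster_map, model = model)
    expect_equal(pop$fitness, ref, tolerance = 1e-12)
  }
})
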