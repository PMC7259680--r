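#' Configure a TE invasion simulation
#'
#' Bundles every model parameter of a single forward simulation. Defaults
#' reproduce the baseline scenario used throughout the package: a 5 x 10 Mb
#' genome at 4 cM/Mb, piRNA clusters at one chromosome end each, N = 1,000
#' diploids, transposition rate u = 0.1, linear fitness with x = 0.01,
#' invasions launched with 1,000 seed insertions (each at frequency 1/2N)
#' and followed for up to 5,000 generations. A population counts as extinct
#' when its mean fitness drops below 0.1, and runs are terminated when the
#' mean diploid copy number exceeds 25,000.
#'
#' @param layout A [genome_layout()].
#' @param cluster_percent Total piRNA cluster size, percent of the genome.
#' @param u Transposition rate per TE copy per generation in unsilenced
#'   individuals.
#' @param fitness A [fitness_model()].
#' @param N Population size (constant through time).
#' @param seed_insertions Number of TE copies used to launch the invasion,
#'   each placed on one random haplotype at a distinct random position (so
#'   each segregates at frequency 1/2N).
#' @param generations Maximum number of generations to simulate.
#' @param extinction_threshold Mean-fitness threshold below which the
#'   population is considered extinct (default 0.1).
#' @param copy_cap Mean insertions per diploid at which a run is terminated
#'   (default 25,000).
#' @param rng_seed Optional integer seed; when given, [run_invasion()] is
#'   fully reproducible.
#' @param early_stop Allow stopping once the outcome can no longer change:
#'   the run ends early when every individual is silenced and mean fitness
#'   has stayed above its running minimum for `rebound_window` consecutive
#'   generations (the minimum-fitness statistic is final at that point).
#' @param rebound_window Window length for the early-stop rule.
#'
#' @return An object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(cluster_percent = 3, rng_seed = 1)
#' @export
simulation_config <- function(layout = genome_layout(),
                              cluster_percent = 3,
                              u = 0.1,
                              fitness = fitness_model(x = 0.01),
                              N = 1000,
                              seed_insertions = 1000,
                              generations = 5000,
                              extinction_threshold = 0.1,
                              copy_cap = 25000,
                              rng_seed = NULL,
                              early_stop = TRUE,
                              rebound_window = 100) {
  stopifnot(inherits(layout, "genome_layout"), inherits(fitness, "fitness_model"))
  if (!is.finite(u) || u < 0) stop("u must be non-negative", call. = FALSE)
  if (!is.finite(N) || N < 2) stop("N must be at least 2", call. = FALSE)
  if (!is.finite(generations) || generations < 1) {
    stop("generations must be positive", call. = FALSE)
  }
  if (!is.finite(extinction_threshold) || extinction_threshold <= 0 ||
      extinction_threshold >= 1) {
    stop("extinction_threshold must lie in (0, 1)", call. = FALSE)
  }
  if (!is.finite(seed_insertions) || seed_insertions < 0) {
    stop("seed_insertions must be non-negative", call. = FALSE)
  }
  if (seed_insertions > layout$genome_size) {
    stop("more seed insertions than genome positions", call. = FALSE)
  }
  structure(
    list(
      layout = layout,
      cluster_map = build_cluster_map(layout, cluster_percent),
      cluster_percent = cluster_percent,
      u = u,
      fitness = fitness,
      N = as.integer(N),
      seed_insertions = as.integer(seed_insertions),
      generations = as.integer(generations),
      extinction_threshold = extinction_threshold,
      copy_cap = copy_cap,
      rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed),
      early_stop = isTRUE(early_stop),
      rebound_window = as.integer(rebound_window)
    ),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config> N=", x$N, ", u=", x$u, ", cluster=",
      x$cluster_percent, "%, seeds=", x$seed_insertions,
      ", generations<=", x$generations, "\n", sep = "")
  print(x$fitness)
  invisible(x)
}

# Flatten a simulation_config into the plain list the C++ engine consumes.
engine_cfg <- function(config) {
  fm <- config$fitness
  kind <- match(fm$form, c("linear", "dominance", "epistatic", "site_specific")) - 1L
  list(
    chrom_start = config$layout$chrom_start,
    chrom_len = config$layout$chrom_len,
    cluster_len = config$cluster_map$cluster_len,
    cross_mean = config$layout$cross_mean,
    genome_size = config$layout$genome_size,
    u = config$u,
    fit_kind = kind,
    x = fm$x, h = fm$h, t = fm$t,
    clusters_neutral = fm$cluster_insertions_neutral,
    site_effects = if (is.null(fm$site_effects)) numeric(0) else fm$site_effects,
    site_cum = if (is.null(fm$site_proportions)) numeric(0)
               else cumsum(fm$site_proportions),
    N = config$N,
    generations = config$generations,
    ext_threshold = config$extinction_threshold,
    copy_cap = config$copy_cap,
    early_stop = config$early_stop,
    rebound_window = config$rebound_window
  )
}

#' Seed the starting population
#'
#' Launches an invasion by distributing `seed_insertions` TE copies over the
#' population: each copy is placed at a distinct uniformly random genome
#' position on one uniformly chosen haplotype, so every insertion segregates
#' at frequency 1/2N. Placement is uniform over the whole genome, so seeds
#' may fall inside piRNA clusters.
#'
#' @param config A [simulation_config()].
#' @return An object of class `population`: a list with `individuals`
#'   (each a list of sorted global positions `h1`, `h2`), cached `fitness`
#'   and `cluster_insertions` vectors, and the `generation` counter.
#' @examples
#' set.seed(1)
#' pop <- initialize_population(simulation_config(N = 20))
#' mean(pop$fitness)
#' @export
initialize_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  N <- config$N
  k <- config$seed_insertions
  pos <- sort(sample.int(config$layout$genome_size, k) - 1L)
  hap <- sample.int(2L * N, k, replace = TRUE)
  individuals <- rep(list(list(h1 = integer(0), h2 = integer(0))), N)
  if (k > 0) {
    ind_of <- (hap - 1L) %/% 2L + 1L
    side_of <- (hap - 1L) %% 2L + 1L
    for (j in seq_len(k)) {
      i <- ind_of[j]
      s <- side_of[j]
      individuals[[i]][[s]] <- c(individuals[[i]][[s]], pos[j])
    }
    individuals <- lapply(individuals, function(ind) {
      list(h1 = sort(ind$h1), h2 = sort(ind$h2))
    })
  }
  st <- cpp_population_stats(individuals, engine_cfg(config))
  structure(
    list(individuals = individuals,
         fitness = st$fitness,
         cluster_insertions = st$cluster_insertions,
         generation = 0L),
    class = "population"
  )
}

#' @export
print.population <- function(x, ...) {
  n <- vapply(x$individuals, function(i) length(i$h1) + length(i$h2), 0)
  cat("<population> N=", length(x$individuals), ", generation ", x$generation,
      "; mean copies ", format(mean(n)), ", mean fitness ",
      format(mean(x$fitness)), "\n", sep = "")
  invisible(x)
}

#' Draw a mating pair
#'
#' Each parent is drawn with probability proportional to fitness (soft
#' selection); the two parents are distinct and zero-fitness individuals are
#' never chosen. Fewer than two individuals with positive fitness signals
#' reproductive collapse.
#'
#' @param population A [initialize_population()] result (or any object with
#'   a `fitness` vector).
#' @return Integer vector of length 2: the indices of the two parents.
#' @export
choose_parents <- function(population) {
  w <- population$fitness
  if (sum(w > 0) < 2) {
    stop("reproductive collapse: fewer than two individuals with positive fitness",
         call. = FALSE)
  }
  p1 <- sample.int(length(w), 1, prob = w)
  repeat {
    p2 <- sample.int(length(w), 1, prob = w)
    if (p2 != p1) break
  }
  c(p1, p2)
}

#' Form a haploid gamete by meiosis
#'
#' Per chromosome, the starting haplotype is a fair coin flip (independent
#' assortment) and the number of crossovers is Poisson with mean
#' `0.01 * cM/Mb * length_Mb`; crossover positions are uniform. Insertions
#' are inherited from the active haplotype in each segment.
#'
#' This is the reference R implementation of the engine's meiosis, exposed
#' for testing and instrumentation.
#'
#' @param individual A list with sorted global position vectors `h1`, `h2`.
#' @param layout A [genome_layout()].
#' @return Sorted integer vector of global insertion positions.
#' @export
make_gamete <- function(individual, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  haps <- list(as.integer(individual$h1), as.integer(individual$h2))
  out <- integer(0)
  for (k in seq_along(layout$chrom_len)) {
    s <- layout$chrom_start[k]
    e <- s + layout$chrom_len[k]
    cur <- sample(1:2, 1)
    nco <- rpois(1, layout$cross_mean[k])
    bounds <- c(s, sort(as.integer(s + runif(nco) * layout$chrom_len[k])), e)
    for (seg in seq_len(nco + 1)) {
      h <- haps[[cur]]
      out <- c(out, h[h >= bounds[seg] & h < bounds[seg + 1]])
      cur <- 3 - cur
    }
  }
  out
}

#' Add novel transposition events to a gamete
#'
#' Implements the trap-model transposition rule: if the diploid parent
#' carries at least one insertion inside a piRNA cluster, the TE family is
#' silenced and no new insertions arise (`u = 0`); otherwise the number of
#' new insertions is Poisson with mean `u * n_parent / 2` (each of the
#' parent's `n` copies produces `u` new copies per diploid generation in
#' expectation), placed at uniformly random genome positions. New insertions
#' may land inside clusters -- that is the trap mechanism. Positions already
#' occupied on this gamete are redrawn.
#'
#' @param gamete Sorted integer vector of global positions.
#' @param parent The diploid parent (list with `h1`, `h2`).
#' @param u Transposition rate per copy per generation.
#' @param map A [build_cluster_map()] result.
#' @return The gamete with new insertions merged in, sorted.
#' @export
transpose_into_gamete <- function(gamete, parent, u, map) {
  stopifnot(inherits(map, "cluster_map"), u >= 0)
  layout <- map$layout
  cluster_n <- function(h) {
    if (length(h) == 0) return(0L)
    chrom <- findInterval(h, layout$chrom_start)
    sum((h - layout$chrom_start[chrom]) < map$cluster_len[chrom])
  }
  if (u == 0) return(gamete)
  if (cluster_n(as.integer(parent$h1)) + cluster_n(as.integer(parent$h2)) > 0) {
    return(gamete)
  }
  n <- length(parent$h1) + length(parent$h2)
  m <- rpois(1, u * n / 2)
  if (m == 0) return(gamete)
  new_pos <- integer(0)
  while (length(new_pos) < m) {
    cand <- as.integer(runif(m - length(new_pos)) * layout$genome_size)
    cand <- pmin(cand, as.integer(layout$genome_size - 1))
    cand <- setdiff(unique(cand), c(gamete, new_pos))
    new_pos <- c(new_pos, cand)
  }
  sort(c(gamete, new_pos))
}

#' Advance the population by one generation
#'
#' Performs the full generation cycle in order: mate pairs are formed based
#' on fitness, haploid gametes are generated on the recombination map, novel
#' insertions are introduced into the gametes of unsilenced parents, zygotes
#' are formed, and fitness and cluster-insertion counts of the new
#' individuals are computed. Population size stays exactly N.
#'
#' @param population A `population` object.
#' @param config The matching [simulation_config()].
#' @return The next-generation `population`.
#' @examples
#' set.seed(1)
#' cfg <- simulation_config(N = 50, seed_insertions = 50)
#' pop <- initialize_population(cfg)
#' pop1 <- step_generation(pop, cfg)
#' @export
step_generation <- function(population, config) {
  stopifnot(inherits(population, "population"),
            inherits(config, "simulation_config"))
  res <- cpp_step_generation(population$individuals, engine_cfg(config))
  if (!res$ok) {
    stop("reproductive collapse: fewer than two individuals with positive fitness",
         call. = FALSE)
  }
  st <- cpp_population_stats(res$population, engine_cfg(config))
  structure(
    list(individuals = res$population,
         fitness = st$fitness,
         cluster_insertions = st$cluster_insertions,
         generation = population$generation + 1L),
    class = "population"
  )
}
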