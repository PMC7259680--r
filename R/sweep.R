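#' Specify a random parameter sweep
#'
#' A sweep runs `n_sims` independent invasions with parameters drawn per
#' simulation. Each of `cluster_percent`, `u` and `x` may be a single fixed
#' value or a length-2 range, in which case values are drawn log-uniformly
#' (cluster sizes, transposition rates and selection coefficients span
#' orders of magnitude and are examined on log axes). `N` and `h` may be a
#' single value or a set to sample uniformly; `t` may be fixed or a length-2
#' range sampled uniformly on the natural scale.
#'
#' All draws and per-simulation seeds come from a single stream started at
#' `master_seed`, so a sweep of m simulations is a prefix of a sweep of
#' M > m simulations under the same master seed, and any single simulation
#' can be reproduced bit-identically from its recorded seed.
#'
#' @param n_sims Number of simulations.
#' @param cluster_percent,u,x Fixed value or length-2 range (log-uniform).
#' @param N,h Fixed value or set (uniform over the set).
#' @param t Fixed value or length-2 range (uniform).
#' @param fitness_form One of `"linear"`, `"dominance"`, `"epistatic"`,
#'   `"site_specific"`. `"linear"` plus a drawn `h` is promoted to
#'   `"dominance"`, and a drawn `t` to `"epistatic"`.
#' @param site_effects,site_proportions Passed to [fitness_model()] for the
#'   site-specific form.
#' @param cluster_insertions_neutral Are cluster insertions cost-free?
#' @param seed_insertions,generations,extinction_threshold,copy_cap,
#'   rebound_window,early_stop Per-run settings, see [simulation_config()].
#' @param layout A [genome_layout()].
#' @param master_seed Integer master seed for the whole sweep.
#' @return An object of class `sweep_spec`.
#' @examples
#' spec <- sweep_spec(10, cluster_percent = c(0.001, 10), master_seed = 1)
#' @export
sweep_spec <- function(n_sims,
                       cluster_percent = c(0.001, 10),
                       u = 0.1,
                       x = 0.01,
                       N = 1000,
                       h = 0.5,
                       t = 1,
                       fitness_form = c("linear", "dominance", "epistatic",
                                        "site_specific"),
                       site_effects = NULL,
                       site_proportions = NULL,
                       cluster_insertions_neutral = TRUE,
                       seed_insertions = 1000,
                       generations = 5000,
                       extinction_threshold = 0.1,
                       copy_cap = 25000,
                       rebound_window = 100,
                       early_stop = TRUE,
                       layout = genome_layout(),
                       master_seed = NULL) {
  fitness_form <- match.arg(fitness_form)
  if (!is.finite(n_sims) || n_sims < 0) {
    stop("n_sims must be non-negative", call. = FALSE)
  }
  if (fitness_form == "linear" && length(h) == 1 && h != 0.5) {
    fitness_form <- "dominance"
  }
  if (fitness_form == "linear" && (length(h) > 1)) fitness_form <- "dominance"
  if (fitness_form == "linear" && (length(t) > 1 || any(t != 1))) {
    fitness_form <- "epistatic"
  }
  structure(
    list(n_sims = as.integer(n_sims),
         cluster_percent = cluster_percent, u = u, x = x, N = N, h = h, t = t,
         fitness_form = fitness_form,
         site_effects = site_effects, site_proportions = site_proportions,
         cluster_insertions_neutral = cluster_insertions_neutral,
         seed_insertions = seed_insertions, generations = generations,
         extinction_threshold = extinction_threshold, copy_cap = copy_cap,
         rebound_window = rebound_window, early_stop = early_stop,
         layout = layout, master_seed = master_seed),
    class = "sweep_spec"
  )
}

#' @export
print.sweep_spec <- function(x, ...) {
  fmt <- function(v) {
    if (length(v) == 1) format(v)
    else paste0("[", paste(format(v), collapse = ", "), "]")
  }
  cat("<sweep_spec> ", x$n_sims, " simulations; cluster% ",
      fmt(x$cluster_percent), ", u ", fmt(x$u), ", x ", fmt(x$x),
      ", N ", fmt(x$N), ", ", x$fitness_form, " fitness\n", sep = "")
  invisible(x)
}

# One log-uniform or fixed draw.
draw_log_uniform <- function(range) {
  if (length(range) == 1) return(range)
  exp(runif(1, log(range[1]), log(range[2])))
}

# One uniform-over-set or fixed draw.
draw_from_set <- function(set) {
  if (length(set) == 1) return(set)
  set[sample.int(length(set), 1)]
}

# One uniform-range or fixed draw.
draw_uniform <- function(range) {
  if (length(range) == 1) return(range)
  runif(1, range[1], range[2])
}

#' Scenario presets
#'
#' Named parameter boxes for the study designs explored by the package, at
#' desk scale (the `n_sims` default of each preset is a scaled-down replicate
#' count; pass `n_sims` to change it):
#'
#' * `"baseline"`: u = 0.1, x = 0.01, N = 1,000, additive linear fitness,
#'   cluster sizes log-uniform in 0.001-10% of the genome.
#' * `"parameter_plane"`: random (u, x) at a fixed cluster size (default 0,
#'   via `cluster_percent`), mapping the extinct / lost / stable regions.
#' * `"joint_sweep"`: u in 0.005-1, x in 0.001-0.1 and cluster size
#'   0.001-10%, all log-uniform.
#' * `"population_size"`: N sampled from {200, 2,000, 20,000}.
#' * `"dominance"`: heterozygous effect h sampled from {0, 0.5, 1}.
#' * `"epistasis"`: epistasis exponent t uniform in 0.75-1.5.
#' * `"worst_case"`: N sampled from {20, 50, 100}, recessive insertions
#'   (h = 0), u = 0.2, x = 0.01, 100 seed insertions, clusters 0.01-10%.
#' * `"deleterious_clusters"`: baseline, but cluster insertions carry the
#'   same cost as any other insertion.
#' * `"mixed_effects"`: per-site effects {0.1, 0.01, 0.001, 0.0001} in equal
#'   proportions.
#'
#' @param name Preset name.
#' @param n_sims Override the preset's scaled default replicate count.
#' @param ... Further overrides passed to [sweep_spec()] (e.g.
#'   `master_seed`, `cluster_percent`, `N`).
#' @return A [sweep_spec()].
#' @examples
#' scenario_preset("worst_case", n_sims = 5, master_seed = 1)
#' @export
scenario_preset <- function(name, n_sims = NULL, ...) {
  presets <- list(
    baseline = list(n_sims = 200, cluster_percent = c(0.001, 10),
                    u = 0.1, x = 0.01, N = 1000),
    parameter_plane = list(n_sims = 100, cluster_percent = 0,
                           u = c(0.005, 1), x = c(0.001, 0.1), N = 1000),
    joint_sweep = list(n_sims = 500, cluster_percent = c(0.001, 10),
                       u = c(0.005, 1), x = c(0.001, 0.1), N = 1000),
    population_size = list(n_sims = 150, cluster_percent = c(0.001, 10),
                           u = 0.1, x = 0.01, N = c(200, 2000, 20000)),
    dominance = list(n_sims = 150, cluster_percent = c(0.001, 10),
                     u = 0.1, x = 0.01, N = 1000, h = c(0, 0.5, 1),
                     fitness_form = "dominance"),
    epistasis = list(n_sims = 150, cluster_percent = c(0.001, 10),
                     u = 0.1, x = 0.01, N = 1000, t = c(0.75, 1.5),
                     fitness_form = "epistatic"),
    worst_case = list(n_sims = 150, cluster_percent = c(0.01, 10),
                      u = 0.2, x = 0.01, N = c(20, 50, 100), h = 0,
                      fitness_form = "dominance", seed_insertions = 100),
    deleterious_clusters = list(n_sims = 200, cluster_percent = c(0.001, 10),
                                u = 0.1, x = 0.01, N = 1000,
                                cluster_insertions_neutral = FALSE),
    mixed_effects = list(n_sims = 150, cluster_percent = c(0.001, 10),
                         u = 0.1, x = 0.01, N = 1000,
                         fitness_form = "site_specific",
                         site_effects = c(0.1, 0.01, 0.001, 0.0001))
  )
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  args <- presets[[name]]
  if (!is.null(n_sims)) args$n_sims <- n_sims
  args <- modifyList(args, list(...))
  do.call(sweep_spec, args)
}

#' Run a parameter sweep
#'
#' Runs every simulation of a [sweep_spec()] and collects one row per run.
#' Parameters and a per-simulation seed are drawn from the master-seed
#' stream before any run starts, so results are order-independent and any
#' row is reproducible in isolation via its recorded seed.
#'
#' @param spec A [sweep_spec()].
#' @param verbose Print one progress line per 25 simulations to stderr.
#' @return A tibble with one row per simulation: `sim`, `seed`, the drawn
#'   parameters, `status`, `min_fitness`, `min_fitness_generation`,
#'   `generations_run`, `max_mean_copies`, `final_mean_copies` and
#'   `frac_zero_at_threshold` (percent of zero-fitness individuals when mean
#'   fitness first reached the extinction threshold; `NA` when it never did).
#' @examples
#' sw <- run_sweep(sweep_spec(2, cluster_percent = c(0.1, 10), N = 100,
#'                            generations = 200, master_seed = 42))
#' sw$status
#' @export
run_sweep <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (!is.null(spec$master_seed)) set.seed(spec$master_seed)
  n <- spec$n_sims
  draws <- vector("list", n)
  for (i in seq_len(n)) {
    # fixed draw count per simulation => prefix-stable parameter stream
    draws[[i]] <- list(
      cluster_percent = draw_log_uniform(spec$cluster_percent),
      u = draw_log_uniform(spec$u),
      x = draw_log_uniform(spec$x),
      N = draw_from_set(spec$N),
      h = draw_from_set(spec$h),
      t = draw_uniform(spec$t),
      seed = sample.int(.Machine$integer.max, 1)
    )
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    d <- draws[[i]]
    fm <- fitness_model(
      x = d$x, form = spec$fitness_form, h = d$h, t = d$t,
      site_effects = spec$site_effects,
      site_proportions = spec$site_proportions,
      cluster_insertions_neutral = spec$cluster_insertions_neutral
    )
    cfg <- simulation_config(
      layout = spec$layout, cluster_percent = d$cluster_percent, u = d$u,
      fitness = fm, N = d$N, seed_insertions = spec$seed_insertions,
      generations = spec$generations,
      extinction_threshold = spec$extinction_threshold,
      copy_cap = spec$copy_cap, rng_seed = d$seed,
      early_stop = spec$early_stop, rebound_window = spec$rebound_window
    )
    inv <- run_invasion(cfg)
    rows[[i]] <- tibble::tibble(
      sim = i, seed = d$seed,
      cluster_percent = d$cluster_percent, u = d$u, x = d$x,
      N = d$N, h = d$h, t = d$t,
      status = inv$status,
      min_fitness = inv$min_fitness,
      min_fitness_generation = inv$min_fitness_generation,
      generations_run = inv$generations_run,
      max_mean_copies = inv$max_mean_copies,
      final_mean_copies = inv$final_mean_copies,
      frac_zero_at_threshold = fraction_zero_fitness_at_threshold(
        inv, spec$extinction_threshold)
    )
    if (verbose && i %% 25 == 0) {
      message("sweep: ", i, "/", n, " simulations done")
    }
  }
  out <- if (n > 0) do.call(rbind, rows) else tibble::tibble(
    sim = integer(0), seed = integer(0), cluster_percent = numeric(0),
    u = numeric(0), x = numeric(0), N = numeric(0), h = numeric(0),
    t = numeric(0), status = character(0), min_fitness = numeric(0),
    min_fitness_generation = numeric(0), generations_run = numeric(0),
    max_mean_copies = numeric(0), final_mean_copies = numeric(0),
    frac_zero_at_threshold = numeric(0)
  )
  attr(out, "spec") <- spec
  out
}
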